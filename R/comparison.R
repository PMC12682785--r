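#' Area between two volume curves
#'
#' Trapezoidal integral of the absolute difference between the two bootstrap
#' mean curves over the integer-year overlap grid, in z-years. Zero iff the
#' curves coincide at every shared grid point.
#'
#' @param curve_a,curve_b \code{volume_curve} objects whose grids cover
#'   \code{overlap}.
#' @param overlap a valid \code{age_range} (see [overlap_range()]).
#' @return non-negative scalar, z * years.
#' @export
area_between <- function(curve_a, curve_b, overlap) {
  if (!isTRUE(overlap$valid)) stop("no overlap between the two age ranges", call. = FALSE)
  ages <- seq.int(overlap$lo, overlap$hi)
  d <- abs(curve_on(curve_a, ages) - curve_on(curve_b, ages))
  sum((d[-1] + d[-length(d)]) / 2)  # unit spacing trapezoid
}

# Values of a fitted curve at integer ages that must be on its grid.
curve_on <- function(curve, ages) {
  idx <- match(ages, curve$grid)
  if (anyNA(idx)) {
    stop(sprintf("curve %s [%s] does not cover ages %s",
                 curve$region_code, curve$group,
                 paste(ages[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  curve$mean[idx]
}

#' Chi-squared test for the difference between two volume curves
#'
#' The statistic sums the squared pointwise curve differences standardized by
#' the pooled bootstrap variances over the J integer-year grid points of the
#' overlap: chi2 = sum_j d_j^2 / (sd_a,j^2 + sd_b,j^2). Kernel smoothing makes
#' neighbouring grid points strongly correlated, so referring chi2 to a
#' chi-squared distribution with J degrees of freedom ("nominal") is
#' anti-conservative. The default "satterthwaite" method moment-matches the
#' null distribution of the correlated quadratic form: with R the correlation
#' matrix of the pointwise differences (estimated from the bootstrap
#' replicates of both curves), the statistic is referred to c * chisq(nu)
#' with c = tr(R^2)/J and nu = J^2/tr(R^2). Both methods coincide when grid
#' points are uncorrelated (and for a single grid point).
#'
#' @param curve_a,curve_b \code{volume_curve} objects covering
#'   \code{overlap}, with bootstrap replicate matrices.
#' @param overlap a valid \code{age_range}.
#' @param method \code{"satterthwaite"} (default) or \code{"nominal"}.
#' @return list with \code{chi2}, \code{df} (effective df under
#'   satterthwaite, J under nominal), and \code{p_raw}.
#' @export
chi2_curve_test <- function(curve_a, curve_b, overlap,
                            method = c("satterthwaite", "nominal")) {
  method <- match.arg(method)
  if (!isTRUE(overlap$valid)) stop("no overlap between the two age ranges", call. = FALSE)
  ages <- seq.int(overlap$lo, overlap$hi)
  ia <- match(ages, curve_a$grid); ib <- match(ages, curve_b$grid)
  if (anyNA(ia) || anyNA(ib)) stop("curve grids do not cover the overlap", call. = FALSE)
  d <- curve_a$mean[ia] - curve_b$mean[ib]
  v <- curve_a$sd[ia]^2 + curve_b$sd[ib]^2
  if (any(v == 0)) {
    stop(sprintf("zero pooled bootstrap variance at age %s (degenerate bootstrap)",
                 paste(ages[v == 0], collapse = ", ")), call. = FALSE)
  }
  chi2 <- sum(d^2 / v)
  J <- length(ages)
  if (method == "nominal") {
    return(list(chi2 = chi2, df = J,
                p_raw = stats::pchisq(chi2, df = J, lower.tail = FALSE)))
  }
  sig <- stats::cov(curve_a$bootstrap[, ia, drop = FALSE]) +
    stats::cov(curve_b$bootstrap[, ib, drop = FALSE])
  r <- stats::cov2cor(sig)
  tr_r2 <- sum(r * r)
  cc <- tr_r2 / J
  nu <- J^2 / tr_r2
  list(chi2 = chi2, df = nu,
       p_raw = stats::pchisq(chi2 / cc, df = nu, lower.tail = FALSE))
}

#' Bonferroni adjustment for a declared family of tests
#'
#' @param p_values raw p-values in [0, 1].
#' @param m family size (default: the number of p-values supplied).
#' @return adjusted p-values, min(1, p * m).
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  pmin(1, p_values * m)
}

#' Default settings for group comparisons
#'
#' @param n_boot bootstrap replicates per curve (default 100).
#' @param candidates bandwidth candidates in years (default 5, 10, 15).
#' @param cv_folds folds for bandwidth cross-validation (default 5).
#' @param min_count,window density rule for the reliable age range: at least
#'   \code{min_count} subjects per \code{window}-year period (defaults 5 and 2).
#' @param alpha significance level on adjusted p-values (default 0.01).
#' @param chi2_method see [chi2_curve_test()].
#' @param seed integer master seed; per-region, per-group child streams are
#'   derived from it.
#' @return a named list.
#' @export
comparison_settings <- function(n_boot = 100, candidates = c(5, 10, 15),
                                cv_folds = 5, min_count = 5, window = 2,
                                alpha = 0.01,
                                chi2_method = "satterthwaite", seed = NULL) {
  stopifnot(n_boot >= 2, alpha > 0, alpha < 1)
  list(n_boot = n_boot, candidates = candidates, cv_folds = cv_folds,
       min_count = min_count, window = window, alpha = alpha,
       chi2_method = chi2_method, seed = seed)
}

#' Compare the volume curves of two biomarker groups across regions
#'
#' For each region: selects a bandwidth per side by cross-validation, fits
#' bootstrap volume curves for both groups over their reliable age ranges,
#' and computes the area between the curves and the chi-squared test on the
#' overlap. P-values are Bonferroni-adjusted over the regions of this
#' comparison. \code{group_b = "ALL"} compares against the full cohort
#' (which contains \code{group_a}); the test for such a pair is marked
#' descriptive because the two sides share subjects.
#'
#' @param nc \code{normalized_cohort} whose \code{subjects} carry a
#'   \code{group} column (see [stratify_cohort()]).
#' @param group_a,group_b group labels, or \code{"ALL"} for the full cohort.
#' @param regions region codes to compare (default: all normalized regions).
#' @param settings list from [comparison_settings()].
#' @return a data.frame of class \code{curve_comparison_set}, sorted by
#'   descending area, with columns \code{region_code}, \code{group_a},
#'   \code{group_b}, \code{overlap_lo}, \code{overlap_hi}, \code{area},
#'   \code{chi2}, \code{df}, \code{p_raw}, \code{p_adj}, \code{significant},
#'   \code{descriptive}, \code{status}. Regions whose age ranges do not
#'   overlap are kept with \code{status = "no_overlap"} and NA statistics.
#'   The fitted curves are attached as attribute \code{"curves"}.
#' @export
compare_groups <- function(nc, group_a, group_b, regions = colnames(nc$z),
                           settings = comparison_settings()) {
  stopifnot(inherits(nc, "normalized_cohort"))
  side <- function(g) {
    if (identical(g, "ALL")) seq_len(nrow(nc$subjects))
    else which(nc$subjects$group == g)
  }
  ia <- side(group_a); ib <- side(group_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("empty group in comparison: ", group_a, " vs ", group_b, call. = FALSE)
  }
  range_a <- compute_age_range(nc$subjects$age[ia], settings$min_count, settings$window)
  range_b <- compute_age_range(nc$subjects$age[ib], settings$min_count, settings$window)
  ov <- overlap_range(range_a, range_b)
  curves <- list()
  rows <- lapply(regions, function(reg) {
    base <- data.frame(region_code = reg, group_a = group_a, group_b = group_b,
                       overlap_lo = NA_integer_, overlap_hi = NA_integer_,
                       area = NA_real_, chi2 = NA_real_, df = NA_real_,
                       p_raw = NA_real_, p_adj = NA_real_,
                       significant = NA, descriptive = group_a == "ALL" || group_b == "ALL",
                       status = "no_overlap", stringsAsFactors = FALSE)
    if (!isTRUE(ov$valid)) return(base)
    fit <- function(idx, g, rng) {
      volume_curve(nc$subjects$age[idx], nc$z[idx, reg],
                   range = rng, candidates = settings$candidates,
                   k_folds = settings$cv_folds, n_boot = settings$n_boot,
                   seed = derive_seed(settings$seed, paste(reg, g)),
                   region_code = reg, group = g)
    }
    ca <- fit(ia, group_a, range_a)
    cb <- fit(ib, group_b, range_b)
    curves[[paste(reg, group_a)]] <<- ca
    curves[[paste(reg, group_b)]] <<- cb
    tst <- chi2_curve_test(ca, cb, ov, method = settings$chi2_method)
    base$overlap_lo <- ov$lo; base$overlap_hi <- ov$hi
    base$area <- area_between(ca, cb, ov)
    base$chi2 <- tst$chi2; base$df <- tst$df; base$p_raw <- tst$p_raw
    base$status <- "ok"
    base
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  if (any(ok)) {
    out$p_adj[ok] <- bonferroni_adjust(out$p_raw[ok], m = sum(ok))
    out$significant[ok] <- out$p_adj[ok] < settings$alpha
  }
  out <- out[order(-out$area, out$region_code, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, curves = curves, settings = settings,
            class = c("curve_comparison_set", "data.frame"))
}

#' @export
print.curve_comparison_set <- function(x, ...) {
  cat(sprintf("Curve comparison %s vs %s: %d regions, %d significant (adj. p < %g)\n",
              x$group_a[1], x$group_b[1], nrow(x),
              sum(x$significant, na.rm = TRUE),
              attr(x, "settings")$alpha %||% 0.01))
  if (any(x$descriptive)) cat("  (vs ALL: groups share subjects; test is descriptive)\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("region_code", "area", "chi2", "df", "p_raw", "p_adj", "significant")], 10),
                   digits = 4, row.names = FALSE)
  invisible(x)
}

#' Rank regions by area between curves
#'
#' @param comparisons a \code{curve_comparison_set} (or plain data.frame with
#'   \code{region_code} and \code{area}).
#' @param top_k number of rows to keep (default 10, as in a top-10 table).
#' @return data.frame sorted by descending area, ties broken
#'   lexicographically by region code, truncated to \code{top_k} rows.
#' @export
rank_regions <- function(comparisons, top_k = 10) {
  stopifnot(nrow(comparisons) > 0)
  df <- as.data.frame(comparisons)
  df <- df[order(-df$area, df$region_code, na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
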