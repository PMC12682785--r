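#' Nadaraya-Watson kernel regression
#'
#' Estimates the conditional mean m(g) = sum_i K((g - x_i)/h) y_i /
#' sum_i K((g - x_i)/h) with a Gaussian kernel K(u) = exp(-u^2/2) at each
#' grid point. Every estimate is a convex combination of the observed y, so
#' it always lies in [min(y), max(y)]; as h grows the curve flattens toward
#' the global mean of y.
#'
#' @param x numeric predictor (ages, years).
#' @param y numeric response (z-scored volumes), same length as \code{x}.
#' @param h bandwidth in years, > 0.
#' @param grid evaluation points (ages).
#' @return numeric vector of estimates, one per grid point.
#' @export
#' @examples
#' nw_regress(c(50, 70), c(0, 1), h = 10, grid = 60)  # 0.5 by symmetry
nw_regress <- function(x, y, h, grid) {
  stopifnot(length(x) == length(y), length(x) >= 2, h > 0)
  k <- nw_kernel_matrix(grid, x, h)
  denom <- rowSums(k)
  if (any(denom == 0)) {
    stop(sprintf("all kernel weights are numerically zero at grid point(s) %s; restrict the grid to the data's age range",
                 paste(grid[denom == 0], collapse = ", ")), call. = FALSE)
  }
  as.vector(k %*% y) / denom
}

# Gaussian kernel weights, |grid| x |x|.
nw_kernel_matrix <- function(grid, x, h) {
  u <- outer(grid, x, "-") / h
  exp(-u^2 / 2)
}

#' Cross-validated bandwidth selection
#'
#' Picks, among \code{candidates}, the bandwidth minimizing mean squared
#' prediction error under k-fold cross-validation. Folds are assigned by a
#' seeded uniform shuffle into k near-equal blocks; the CV MSE of a candidate
#' is the mean over folds of the mean squared held-out error. Ties break
#' toward the smallest bandwidth (least risk of oversmoothing masking a tie).
#'
#' @param x,y data as in [nw_regress()].
#' @param candidates bandwidths to compare (default 5, 10, 15 years).
#' @param k_folds number of folds (default 5); requires \code{length(x) >=
#'   k_folds}.
#' @param seed integer seed for the fold shuffle (independent of any
#'   bootstrap seed).
#' @return the selected bandwidth, with attribute \code{"cv_mse"} (named
#'   vector of per-candidate CV MSEs).
#' @export
select_bandwidth <- function(x, y, candidates = c(5, 10, 15), k_folds = 5, seed = NULL) {
  n <- length(x)
  stopifnot(n == length(y), n >= k_folds, k_folds >= 2, length(candidates) >= 1)
  perm <- with_seed(seed, sample.int(n))
  fold <- rep_len(seq_len(k_folds), n)[order(perm)]  # near-equal blocks after shuffle
  mse <- vapply(candidates, function(h) {
    errs <- vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      if (!any(tr)) stop("empty training fold", call. = FALSE)
      pred <- nw_regress(x[tr], y[tr], h, grid = x[!tr])
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  names(mse) <- as.character(candidates)
  # ties (up to floating-point noise) break toward the smallest bandwidth
  eps <- 1e-10 * (mean(y^2) + 1e-12)
  ord <- order(candidates)
  tied <- mse[ord] <= min(mse) + eps
  best <- candidates[ord][which(tied)[1]]
  structure(best, cv_mse = mse)
}

#' Bootstrap volume curve for one region and group
#'
#' Fits \code{n_boot} Nadaraya-Watson curves, each on a resample of the
#' (age, volume) pairs drawn with replacement to the original size, over a
#' fixed integer-year grid. The reported curve is the pointwise mean of the
#' replicates and its uncertainty the pointwise sample SD, following the
#' bootstrap-band construction. A replicate whose kernel mass underflows to
#' zero at any grid point is redrawn (counted in \code{n_redraws}).
#'
#' @param x ages; \code{length(x) >= 2}.
#' @param y z-scored volumes.
#' @param h bandwidth in years (fixed across replicates; select it first with
#'   [select_bandwidth()]).
#' @param grid integer-year evaluation grid.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed; the same seed reproduces the curve exactly.
#' @param region_code,group optional labels stored on the result.
#' @return an object of class \code{volume_curve}: list with \code{grid},
#'   \code{mean}, \code{sd}, \code{bootstrap} (n_boot x |grid| matrix),
#'   \code{bandwidth}, \code{n_subjects}, \code{n_redraws},
#'   \code{region_code}, \code{group}.
#' @export
bootstrap_curve <- function(x, y, h, grid, n_boot = 100, seed = NULL,
                            region_code = NA_character_, group = NA_character_) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2, n_boot >= 2, h > 0)
  k <- nw_kernel_matrix(grid, x, h)  # |grid| x n, fixed across replicates
  if (any(rowSums(k) == 0)) {
    stop("grid extends beyond the data's kernel support; restrict to the age range",
         call. = FALSE)
  }
  boot <- with_seed(seed, {
    counts <- matrix(0L, nrow = n, ncol = n_boot)
    for (b in seq_len(n_boot)) {
      counts[, b] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    }
    num <- k %*% (counts * y)
    den <- k %*% counts
    redraws <- 0L
    while (any(bad <- apply(den == 0, 2, any))) {
      for (b in which(bad)) {
        counts[, b] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
        redraws <- redraws + 1L
      }
      num <- k %*% (counts * y)
      den <- k %*% counts
    }
    structure(t(num / den), redraws = redraws)
  })
  m <- colMeans(boot)
  s <- apply(boot, 2, stats::sd)
  structure(list(region_code = region_code, group = group,
                 grid = as.integer(grid), mean = m, sd = s,
                 bootstrap = unclass(boot), bandwidth = h,
                 n_subjects = n, n_redraws = attr(boot, "redraws")),
            class = "volume_curve")
}

#' Fit a volume curve (bandwidth selection + bootstrap)
#'
#' Convenience fitting function for one region x group: selects the bandwidth
#' by k-fold cross-validation over the candidate set, then fits the bootstrap
#' Nadaraya-Watson curve on the integer-year grid of the supplied age range.
#' Bandwidth selection and bootstrap resampling use independent seeded
#' streams derived from \code{seed}, so re-running with a different CV seed
#' never changes the bootstrap draws for a given bandwidth.
#'
#' @param age,z subject ages and z-scored volumes.
#' @param range an \code{age_range} (see [compute_age_range()]); the grid is
#'   the integer years from \code{lo} to \code{hi} inclusive.
#' @param bandwidth fixed bandwidth, or NULL (default) to select by CV.
#' @param candidates,k_folds CV settings for [select_bandwidth()].
#' @param n_boot,seed bootstrap settings for [bootstrap_curve()].
#' @param region_code,group labels stored on the result.
#' @return a \code{volume_curve}.
#' @export
volume_curve <- function(age, z, range, bandwidth = NULL,
                         candidates = c(5, 10, 15), k_folds = 5,
                         n_boot = 100, seed = NULL,
                         region_code = NA_character_, group = NA_character_) {
  if (!isTRUE(range$valid)) stop("age range is invalid for this group", call. = FALSE)
  if (is.null(bandwidth)) {
    bandwidth <- as.numeric(select_bandwidth(age, z, candidates, k_folds,
                                             seed = derive_seed(seed, "cv")))
  }
  bootstrap_curve(age, z, bandwidth, grid = seq.int(range$lo, range$hi),
                  n_boot = n_boot, seed = derive_seed(seed, "boot"),
                  region_code = region_code, group = group)
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("Volume curve%s%s: ages %d-%d, bandwidth %g y, %d subjects, %d bootstrap replicates\n",
              if (is.na(x$region_code)) "" else paste0(" ", x$region_code),
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              min(x$grid), max(x$grid), x$bandwidth, x$n_subjects, nrow(x$bootstrap)))
  cat(sprintf("  z at endpoints: %.3f (age %d) -> %.3f (age %d)\n",
              x$mean[1], x$grid[1], x$mean[length(x$mean)], x$grid[length(x$grid)]))
  invisible(x)
}

#' Interpolate a fitted volume curve
#'
#' @param object a \code{volume_curve}.
#' @param ages ages at which to evaluate (default: the fitted grid). Linear
#'   interpolation between grid points; no extrapolation.
#' @param ... unused.
#' @return numeric vector of curve values.
#' @export
predict.volume_curve <- function(object, ages = object$grid, ...) {
  if (any(ages < min(object$grid) | ages > max(object$grid))) {
    stop("requested ages outside the fitted grid", call. = FALSE)
  }
  stats::approx(object$grid, object$mean, xout = ages)$y
}

#' Plot a volume curve with its bootstrap band
#'
#' @param x a \code{volume_curve}.
#' @param band half-width of the band in pointwise SDs (default 2).
#' @param add add to an existing plot.
#' @param col curve colour.
#' @param ... passed to \code{plot}/\code{lines}.
#' @export
plot.volume_curve <- function(x, band = 2, add = FALSE, col = "darkgreen", ...) {
  lo <- x$mean - band * x$sd
  hi <- x$mean + band * x$sd
  if (!add) {
    graphics::plot(x$grid, x$mean, type = "n", ylim = range(lo, hi),
                   xlab = "age (years)", ylab = "normalized volume (z)",
                   main = if (!is.na(x$region_code)) x$region_code else "", ...)
  }
  graphics::polygon(c(x$grid, rev(x$grid)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor(col, alpha.f = 0.2), border = NA)
  graphics::lines(x$grid, x$mean, col = col, lwd = 2, ...)
  invisible(x)
}

#' Export fitted curves as a tidy CSV
#'
#' One row per grid point: \code{region_code}, \code{group}, \code{age},
#' \code{mean}, \code{sd}, \code{bandwidth}, \code{n_subjects}.
#'
#' @param curves a \code{volume_curve} or a list of them.
#' @param path output CSV path.
#' @return invisible \code{path}.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "volume_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(region_code = cv$region_code, group = as.character(cv$group),
               age = cv$grid, mean = cv$mean, sd = cv$sd,
               bandwidth = cv$bandwidth, n_subjects = cv$n_subjects,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
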