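#' Normalize regional volumes to cohort z-scores
#'
#' Each raw regional volume is divided by the subject's total intracranial
#' volume (TIV) to correct for head size, and the resulting ratios are
#' z-scored per region. The mean and sample SD (n-1 denominator) are computed
#' over the full supplied cohort and stored, so the same scale can be reused
#' on subsets: curves of different biomarker groups then live on a common
#' scale, which the cross-group area comparison requires.
#'
#' @param cohort cohort data.frame (filtered, typically stratified).
#' @param regions region codes to normalize; defaults to all regions present.
#' @param stats optional stats data.frame (\code{region_code},
#'   \code{ratio_mean}, \code{ratio_sd}) from a previous call, to project a
#'   subset onto an existing scale instead of re-estimating.
#' @return an object of class \code{normalized_cohort}: list with
#'   \code{subjects} (the cohort data.frame), \code{z} (numeric matrix
#'   subjects x regions of dimensionless z-scores), and \code{stats}.
#' @export
normalize_volumes <- function(cohort, regions = cohort_regions(cohort), stats = NULL) {
  if (length(regions) == 0) stop("'regions' must be non-empty", call. = FALSE)
  if (any(is.na(cohort$tiv) | cohort$tiv <= 0)) stop("tiv must be positive for all subjects", call. = FALSE)
  ratios <- as.matrix(cohort[, regions, drop = FALSE]) / cohort$tiv
  if (is.null(stats)) {
    mu <- colMeans(ratios)
    sd_ <- apply(ratios, 2, stats::sd)
    zero <- sd_ == 0 | is.na(sd_)
    if (any(zero)) {
      stop("zero variance in TIV-ratio for region(s): ",
           paste(regions[zero], collapse = ", "), call. = FALSE)
    }
    stats <- data.frame(region_code = regions, ratio_mean = unname(mu),
                        ratio_sd = unname(sd_), stringsAsFactors = FALSE)
  } else {
    idx <- match(regions, stats$region_code)
    if (anyNA(idx)) stop("stats are missing regions: ",
                         paste(regions[is.na(idx)], collapse = ", "), call. = FALSE)
    stats <- stats[idx, , drop = FALSE]
  }
  z <- sweep(sweep(ratios, 2, stats$ratio_mean, "-"), 2, stats$ratio_sd, "/")
  rownames(z) <- cohort$subject_id
  structure(list(subjects = cohort, z = z, stats = stats),
            class = "normalized_cohort")
}

#' @export
print.normalized_cohort <- function(x, ...) {
  cat(sprintf("Normalized cohort: %d subjects, %d regions\n",
              nrow(x$subjects), ncol(x$z)))
  if (!is.null(x$subjects$group)) {
    print(table(x$subjects$group, dnn = NULL))
  }
  invisible(x)
}

#' Remove volumetric outliers
#'
#' Drops every subject whose z-scored volume exceeds \code{z_limit} in
#' absolute value in any analyzed region. A single pass: z-scores are not
#' recomputed after removal, so the cohort scale is unchanged.
#'
#' @param nc a \code{normalized_cohort} from [normalize_volumes()].
#' @param z_limit positive threshold in z units (default 4).
#' @return the pruned \code{normalized_cohort}, with attribute
#'   \code{"n_removed"}.
#' @export
remove_outliers <- function(nc, z_limit = 4) {
  stopifnot(inherits(nc, "normalized_cohort"), z_limit > 0)
  bad <- apply(abs(nc$z) > z_limit, 1, any)
  out <- nc
  out$subjects <- nc$subjects[!bad, , drop = FALSE]
  attr(out$subjects, "regions") <- cohort_regions(nc$subjects)
  out$z <- nc$z[!bad, , drop = FALSE]
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Reliable age range of a group
#'
#' Scans sliding windows \code{[a, a + window)} for integer starts \code{a}
#' from \code{floor(min(ages))} to \code{ceiling(max(ages)) - window}. A
#' window is dense iff it holds at least \code{min_count} ages. The range is
#' the longest contiguous run of dense windows, returned as
#' \code{[first dense a, last dense a + window]}; ties break toward the
#' younger end. With no dense window the range is invalid.
#'
#' @param ages numeric vector of ages in years.
#' @param min_count minimum subjects per window (default 5).
#' @param window window width in years (default 2).
#' @return an \code{age_range}: list \code{lo}, \code{hi} (integer years) and
#'   \code{valid}.
#' @export
compute_age_range <- function(ages, min_count = 5, window = 2) {
  stopifnot(min_count >= 1, window >= 1)
  invalid <- structure(list(lo = NA_integer_, hi = NA_integer_, valid = FALSE),
                       class = "age_range")
  if (length(ages) == 0) return(invalid)
  starts <- seq.int(floor(min(ages)), ceiling(max(ages)) - window)
  if (length(starts) == 0) return(invalid)
  dense <- vapply(starts, function(a) sum(ages >= a & ages < a + window) >= min_count,
                  logical(1))
  if (!any(dense)) return(invalid)
  runs <- rle(dense)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  dense_runs <- which(runs$values)
  best <- dense_runs[which.max(runs$lengths[dense_runs])]  # ties: earliest
  lo <- starts[begins[best]]
  hi <- starts[ends[best]] + window
  structure(list(lo = as.integer(lo), hi = as.integer(hi), valid = TRUE),
            class = "age_range")
}

#' Overlap of two age ranges
#'
#' @param a,b \code{age_range} objects.
#' @return the intersection as an \code{age_range}; invalid when disjoint or
#'   either input is invalid.
#' @export
overlap_range <- function(a, b) {
  if (!isTRUE(a$valid) || !isTRUE(b$valid)) {
    return(structure(list(lo = NA_integer_, hi = NA_integer_, valid = FALSE),
                     class = "age_range"))
  }
  lo <- max(a$lo, b$lo); hi <- min(a$hi, b$hi)
  if (lo >= hi) {
    return(structure(list(lo = NA_integer_, hi = NA_integer_, valid = FALSE),
                     class = "age_range"))
  }
  structure(list(lo = as.integer(lo), hi = as.integer(hi), valid = TRUE),
            class = "age_range")
}

#' @export
print.age_range <- function(x, ...) {
  if (isTRUE(x$valid)) cat(sprintf("age range [%d, %d] years\n", x$lo, x$hi))
  else cat("age range: invalid (no dense window)\n")
  invisible(x)
}

#' Export a normalized cohort in long format
#'
#' Writes two CSVs: the long table (\code{subject_id}, \code{region_code},
#' \code{zvolume}) and the per-region normalization stats
#' (\code{region_code}, \code{ratio_mean}, \code{ratio_sd}).
#'
#' @param nc \code{normalized_cohort}.
#' @param path path of the long-format CSV.
#' @param stats_path path of the stats CSV (default: \code{path} with
#'   \code{_stats} inserted before the extension).
#' @return invisible character vector of the two paths.
#' @export
write_normalized <- function(nc, path, stats_path = sub("(\\.[^.]+)?$", "_stats\\1", path)) {
  long <- data.frame(
    subject_id = rep(nc$subjects$subject_id, times = ncol(nc$z)),
    region_code = rep(colnames(nc$z), each = nrow(nc$z)),
    zvolume = as.vector(nc$z),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(nc$stats, stats_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, stats_path))
}
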