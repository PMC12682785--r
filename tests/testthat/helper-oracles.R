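# Independent oracles and fixture builders, written against the rules as
# stated, not against the package implementation.

# Brute-force truth table for the six group labels over the 16 A/T/N/V
# combinations, enumerated by hand from the group definitions.
oracle_truth_table <- function() {
  rows <- expand.grid(A = c(FALSE, TRUE), T = c(FALSE, TRUE),
                      N = c(FALSE, TRUE), V = c(FALSE, TRUE))
  label <- character(16)
  for (i in seq_len(16)) {
    a <- rows$A[i]; t <- rows$T[i]; n <- rows$N[i]; v <- rows$V[i]
    label[i] <-
      if (a && !v) "AD"
      else if (a && v) "AV"
      else if (!a && v && t) "EXCLUDED"
      else if (!a && v) "V"
      else if (t || n) "OP"
      else "N"
  }
  rows$label <- label
  rows
}

# Direct double-loop Nadaraya-Watson evaluation (Gaussian kernel).
oracle_nw <- function(x, y, h, grid) {
  out <- numeric(length(grid))
  for (j in seq_along(grid)) {
    num <- 0; den <- 0
    for (i in seq_along(x)) {
      w <- exp(-((grid[j] - x[i]) / h)^2 / 2)
      num <- num + w * y[i]
      den <- den + w
    }
    out[j] <- num / den
  }
  out
}

# Exhaustive-age-window oracle for the reliable age range: enumerate every
# integer window start, mark density, scan all contiguous dense runs.
oracle_age_range <- function(ages, min_count, window) {
  if (length(ages) == 0) return(NULL)
  starts <- floor(min(ages)):(ceiling(max(ages)) - window)
  if (length(starts) < 1 || starts[1] > ceiling(max(ages)) - window) return(NULL)
  dense <- sapply(starts, function(a) sum(ages >= a & ages < a + window) >= min_count)
  best <- NULL; best_len <- 0
  i <- 1
  while (i <= length(starts)) {
    if (dense[i]) {
      j <- i
      while (j < length(starts) && dense[j + 1]) j <- j + 1
      if (j - i + 1 > best_len) {
        best_len <- j - i + 1
        best <- c(starts[i], starts[j] + window)
      }
      i <- j + 1
    } else i <- i + 1
  }
  best
}

# Minimal hand-built volume_curve object for comparison-stage tests.
toy_curve <- function(grid, mean, sd = rep(1, length(grid)),
                      bootstrap = NULL, group = "N", region = "TOY") {
  if (is.null(bootstrap)) {
    bootstrap <- matrix(rep(mean, each = 2), nrow = 2)  # degenerate replicates
  }
  structure(list(region_code = region, group = group, grid = as.integer(grid),
                 mean = mean, sd = sd, bootstrap = bootstrap,
                 bandwidth = 10, n_subjects = 10, n_redraws = 0L),
            class = "volume_curve")
}

valid_range <- function(lo, hi) {
  structure(list(lo = as.integer(lo), hi = as.integer(hi), valid = TRUE),
            class = "age_range")
}

# Small cohort data.frame with sensible defaults, one region unless given.
make_cohort <- function(n, age = 65, gender = "female", abeta42 = 2000,
                        ttau = 150, ptau = 15, fazekas = 0, microbleeds = 0,
                        stroke_history = FALSE, cdr_global = 0, qc_pass = TRUE,
                        radiological_exclusion = FALSE, tiv = 1450,
                        volumes = NULL) {
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), age = age,
                   gender = gender, abeta42 = abeta42, ttau = ttau,
                   ptau = ptau, fazekas = fazekas, microbleeds = microbleeds,
                   stroke_history = stroke_history, cdr_global = cdr_global,
                   qc_pass = qc_pass,
                   radiological_exclusion = radiological_exclusion, tiv = tiv,
                   stringsAsFactors = FALSE)
  if (is.null(volumes)) volumes <- data.frame(REG1 = rep(3, n) + seq_len(n))
  df <- cbind(df, volumes)
  attr(df, "regions") <- names(volumes)
  df
}

# Small synthetic config for fast pipeline tests.
small_config <- function(group_sizes = c(N = 80, AD = 40, V = 40, AV = 30, OP = 25),
                         ...) {
  synthetic_config(
    group_sizes = group_sizes,
    regions = default_regions()[1:4],
    trajectory = default_trajectory(default_regions()[1:4]),
    effects = data.frame(group = "AD", region_code = "LLENTAV",
                         onset_age = 60, extra_slope = -0.03,
                         stringsAsFactors = FALSE),
    gender_offset = stats::setNames(rep(0, 4), default_regions()[1:4]),
    ...
  )
}
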