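#' Configuration of the synthetic biomarker-stratified cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults reproduce the structure of the study cohort the package is
#' designed for: five biomarker groups of sizes 782 (N), 178 (AD), 212 (V),
#' 118 (AV) and 90 (OP) — 1,380 subjects in total — with the motivating cohort's
#' per-group, per-gender mean ages and SDs, ages drawn from normals truncated
#' at 50, and regional volumes that decline linearly with age on a common
#' z-scale plus Gaussian noise. Pathology groups carry additional
#' region-specific atrophy accelerations after an onset age (medial-temporal
#' regions for the AD and AV groups, fronto-opercular/subcortical regions for
#' the V group), giving every pipeline stage a known ground truth.
#'
#' Biomarker values are sampled from intervals bounded away from the
#' clinical thresholds by \code{margin} (relative, default 5\%), so boundary
#' conventions can never flip a synthetic label.
#'
#' @param group_sizes named integer vector over N, AD, V, AV, OP.
#' @param female_fraction named numeric vector, fraction of women per group.
#' @param age_model data.frame \code{group}, \code{gender}, \code{mean},
#'   \code{sd}: moments of the truncated-at-50 normal age distribution.
#' @param regions character vector of region codes.
#' @param trajectory data.frame \code{region_code}, \code{baseline} (z at age
#'   50), \code{slope} (z per year), \code{quad} (z per year^2, 0 for linear),
#'   \code{ratio_mean}, \code{ratio_scale}: the affine map from the latent
#'   z-trajectory to the volume/TIV ratio.
#' @param effects data.frame \code{group}, \code{region_code},
#'   \code{onset_age}, \code{extra_slope}: extra z-decline per year applied
#'   after \code{onset_age} in that group and region. An optional
#'   \code{gender} column restricts an effect to one gender (\code{NA}: both).
#' @param noise_sd SD of the per-subject Gaussian noise, z units (default 0.5).
#' @param gender_offset named numeric per region: z offset added for male
#'   subjects (default 0).
#' @param margin relative threshold margin for biomarker sampling.
#' @param seed integer seed used by [generate_cohort()].
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(group_sizes = c(N = 782, AD = 178, V = 212, AV = 118, OP = 90),
                             female_fraction = c(N = 439/782, AD = 93/178, V = 115/212,
                                                 AV = 62/118, OP = 49/90),
                             age_model = default_age_model(),
                             regions = default_regions(),
                             trajectory = default_trajectory(regions),
                             effects = default_effects(),
                             noise_sd = 0.5,
                             gender_offset = stats::setNames(rep(0, length(regions)), regions),
                             margin = 0.05,
                             seed = 1L) {
  stopifnot(all(group_sizes >= 0), noise_sd > 0, margin >= 0, margin < 0.5)
  if (nrow(effects) > 0) {
    stopifnot(all(effects$onset_age >= 50),
              all(effects$region_code %in% regions),
              all(effects$group %in% names(group_sizes)))
  }
  stopifnot(all(trajectory$region_code == regions))
  structure(list(group_sizes = group_sizes, female_fraction = female_fraction,
                 age_model = age_model, regions = regions, trajectory = trajectory,
                 effects = effects, noise_sd = noise_sd,
                 gender_offset = gender_offset, margin = margin, seed = seed),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_age_model <- function() {
  data.frame(
    group = rep(c("N", "AD", "V", "AV", "OP"), each = 2),
    gender = rep(c("female", "male"), 5),
    mean = c(62.8, 64.2, 68.4, 68.2, 69.0, 69.5, 72.1, 73.2, 66.5, 71.0),
    sd = c(6.7, 6.8, 5.8, 6.7, 6.5, 6.9, 5.1, 5.1, 5.4, 5.7),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_config
#' @export
default_regions <- function() {
  c("LLENTAV", "LRENTAV", "LLAMYG", "LRAMYG", "LRBFBV",
    "LRMTGV", "LRPOSTGV", "LRFOPV", "LLPUTV", "LVV")
}

#' @rdname synthetic_config
#' @param regions region codes the trajectory covers.
#' @export
default_trajectory <- function(regions = default_regions()) {
  # ratio_mean spans plausible volume/TIV magnitudes; scale 10% per z unit.
  base_ratio <- seq(0.0015, 0.02, length.out = length(regions))
  data.frame(region_code = regions, baseline = 0, slope = -0.02, quad = 0,
             ratio_mean = base_ratio, ratio_scale = 0.1 * base_ratio,
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_config
#' @export
default_effects <- function() {
  mtl <- c("LLENTAV", "LRENTAV", "LLAMYG", "LRAMYG", "LRBFBV")
  vas <- c("LRPOSTGV", "LRFOPV", "LLPUTV")
  data.frame(
    group = c(rep("AD", length(mtl)), rep("AV", length(mtl)), rep("V", length(vas))),
    region_code = c(mtl, mtl, vas),
    onset_age = 60,
    extra_slope = c(rep(-0.03, length(mtl)), rep(-0.035, length(mtl)),
                    rep(-0.03, length(vas))),
    stringsAsFactors = FALSE
  )
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path YAML file path.
#' @return for \code{read_synthetic_config}, a \code{synthetic_config}; for
#'   \code{write_synthetic_config}, \code{path} invisibly.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- synthetic_config()
  for (nm in intersect(names(raw), names(cfg))) {
    val <- raw[[nm]]
    if (is.data.frame(cfg[[nm]])) val <- as.data.frame(do.call(cbind.data.frame, val))
    if (nm %in% c("group_sizes", "female_fraction", "gender_offset")) val <- unlist(val)
    cfg[[nm]] <- val
  }
  do.call(synthetic_config, cfg[setdiff(names(cfg), character())])
}

#' @rdname read_synthetic_config
#' @param config a \code{synthetic_config}.
#' @export
write_synthetic_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 22)
  invisible(path)
}

# YAML-safe representation: data frames become column lists and named
# vectors become maps (yaml drops names on atomic vectors).
config_to_list <- function(config) {
  lapply(unclass(config), function(v) {
    if (is.data.frame(v)) as.list(v)
    else if (!is.null(names(v))) as.list(v)
    else v
  })
}

# Truncated-at-50 normal draws via inverse CDF.
rtnorm50 <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(50, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

# Sample CSF biomarkers consistent with target A/T statuses, margins keeping
# every value strictly away from the thresholds.
sample_csf <- function(n, A, T_, margin) {
  ab_lo <- 1030 * (1 + margin); ab_hi <- 2500
  ptau <- numeric(n); abeta <- numeric(n)
  if (A) {
    abeta <- stats::runif(n, 500, 1030 * (1 - margin))
    ptau <- if (T_) stats::runif(n, 27 * (1 + margin), 45) else stats::runif(n, 10, 27 * (1 - margin))
  } else if (!T_) {
    abeta <- stats::runif(n, ab_lo, ab_hi)
    ptau <- stats::runif(n, 10, pmin(27 * (1 - margin), 0.023 * (1 - margin) * abeta))
  } else {
    lo <- 27 * (1 + margin) / (0.023 * (1 - margin)) + 50
    abeta <- stats::runif(n, lo, ab_hi)
    ptau <- stats::runif(n, 27 * (1 + margin), 0.023 * (1 - margin) * abeta)
  }
  list(abeta42 = abeta, ptau = ptau)
}

sample_vascular <- function(n, V) {
  fazekas <- integer(n); mb <- integer(n); stroke <- logical(n)
  if (!V) {
    fazekas <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    mb <- sample(0:3, n, replace = TRUE, prob = c(0.8, 0.1, 0.06, 0.04))
  } else {
    kind <- sample(c("faz", "mb", "stroke"), n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    fazekas <- ifelse(kind == "faz", sample(2:3, n, replace = TRUE, prob = c(0.7, 0.3)),
                      sample(0:1, n, replace = TRUE))
    mb <- ifelse(kind == "mb", sample(4:8, n, replace = TRUE), sample(0:3, n, replace = TRUE))
    stroke <- kind == "stroke"
  }
  list(fazekas = as.integer(fazekas), microbleeds = as.integer(mb), stroke = stroke)
}

# Latent noiseless z-trajectory for one group/region at given ages
# (before gender offset and noise). `gender` selects which effects apply:
# a single gender, or a female-fraction for the marginal curve.
latent_z <- function(config, group, region, ages, gender = NULL,
                     female_fraction = NULL) {
  tr <- config$trajectory[config$trajectory$region_code == region, ]
  z <- tr$baseline + tr$slope * (ages - 50) + tr$quad * (ages - 50)^2
  eff <- config$effects[config$effects$group == group &
                          config$effects$region_code == region, , drop = FALSE]
  if (nrow(eff) > 0) {
    eff_gender <- if ("gender" %in% names(eff)) eff$gender else rep(NA_character_, nrow(eff))
    for (i in seq_len(nrow(eff))) {
      contrib <- eff$extra_slope[i] * pmax(0, ages - eff$onset_age[i])
      if (is.na(eff_gender[i])) {
        z <- z + contrib
      } else if (!is.null(gender)) {
        z <- z + contrib * (gender == eff_gender[i])
      } else {
        frac <- if (eff_gender[i] == "female") female_fraction else 1 - female_fraction
        z <- z + contrib * frac
      }
    }
  }
  z
}

#' Generate a synthetic cohort
#'
#' Draws a subject-level cohort in which every subject's CSF and vascular
#' markers satisfy the A/T/N/V definition of their assigned group by
#' construction, ages follow the configured truncated normals, TIV is
#' Normal(1450, 130) truncated positive, and each raw regional volume is
#' \code{tiv * (ratio_mean + ratio_scale * z)} with
#' \code{z = baseline + slope*(age-50) + effect + gender_offset + noise}.
#' All subjects pass QC, have CDR 0 and no radiological exclusion, so the
#' full cohort survives the inclusion filters.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides \code{config$seed} when given.
#' @return a cohort data.frame (see [read_cohort()]) with an extra
#'   \code{true_group} column recording the generating group.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    blocks <- lapply(names(config$group_sizes), function(g) {
      n <- config$group_sizes[[g]]
      if (n == 0) return(NULL)
      n_f <- round(n * config$female_fraction[[g]])
      gender <- rep(c("female", "male"), c(n_f, n - n_f))
      am <- config$age_model
      age <- numeric(n)
      for (gd in c("female", "male")) {
        row <- am[am$group == g & am$gender == gd, ]
        sel <- gender == gd
        if (any(sel)) age[sel] <- rtnorm50(sum(sel), row$mean, row$sd)
      }
      # A/T/N/V pattern per subject honouring the group's free axes
      want <- switch(g,
        N  = cbind(A = FALSE, T = FALSE, N = FALSE, V = FALSE)[rep(1, n), , drop = FALSE],
        AD = cbind(A = TRUE, T = stats::runif(n) < 0.25, N = stats::runif(n) < 0.25, V = FALSE),
        AV = cbind(A = TRUE, T = stats::runif(n) < 0.25, N = stats::runif(n) < 0.25, V = TRUE),
        V  = cbind(A = FALSE, T = FALSE, N = stats::runif(n) < 0.25, V = TRUE),
        OP = {
          kind <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
          cbind(A = FALSE, T = kind != 2, N = kind != 1, V = FALSE)
        })
      abeta <- numeric(n); ptau <- numeric(n)
      for (a_ in c(TRUE, FALSE)) for (t_ in c(TRUE, FALSE)) {
        sel <- want[, "A"] == a_ & want[, "T"] == t_
        if (any(sel)) {
          csf <- sample_csf(sum(sel), a_, t_, config$margin)
          abeta[sel] <- csf$abeta42; ptau[sel] <- csf$ptau
        }
      }
      m <- config$margin
      ttau <- ifelse(want[, "N"], stats::runif(n, 300 * (1 + m), 600),
                     stats::runif(n, 100, 300 * (1 - m)))
      vasc <- list(fazekas = integer(n), microbleeds = integer(n), stroke = logical(n))
      for (v_ in c(TRUE, FALSE)) {
        sel <- want[, "V"] == v_
        if (any(sel)) {
          vs <- sample_vascular(sum(sel), v_)
          vasc$fazekas[sel] <- vs$fazekas
          vasc$microbleeds[sel] <- vs$microbleeds
          vasc$stroke[sel] <- vs$stroke
        }
      }
      tiv <- abs(stats::rnorm(n, 1450, 130))  # truncation at 0 is immaterial at this mean
      vols <- do.call(cbind, lapply(config$regions, function(reg) {
        tr <- config$trajectory[config$trajectory$region_code == reg, ]
        z <- latent_z(config, g, reg, age, gender = gender) +
          ifelse(gender == "male", config$gender_offset[[reg]], 0) +
          stats::rnorm(n, 0, config$noise_sd)
        tiv * (tr$ratio_mean + tr$ratio_scale * z)
      }))
      colnames(vols) <- config$regions
      df <- data.frame(subject_id = NA_character_, age = age, gender = gender,
                       abeta42 = abeta, ttau = ttau, ptau = ptau,
                       fazekas = vasc$fazekas, microbleeds = vasc$microbleeds,
                       stroke_history = vasc$stroke, cdr_global = 0,
                       qc_pass = TRUE, radiological_exclusion = FALSE, tiv = tiv,
                       stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(vols))
      df$true_group <- g
      df
    })
    out <- do.call(rbind, blocks)
    out$subject_id <- sprintf("S%05d", seq_len(nrow(out)))
    rownames(out) <- NULL
    attr(out, "regions") <- config$regions
    out
  })
}

#' Ground-truth mean volume curve of the generator
#'
#' The noiseless z-trajectory of one group and region, marginalized over the
#' group's gender mix at each grid age. When normalization \code{stats} (from
#' [normalize_volumes()]) are supplied, the curve is mapped through the
#' generator's affine ratio transform and the cohort's z-scaling, i.e. onto
#' the same scale as fitted [volume_curve()] objects.
#'
#' @param config a \code{synthetic_config}.
#' @param group,region group label and region code.
#' @param grid ages at which to evaluate.
#' @param stats optional normalization stats data.frame.
#' @return numeric vector, one value per grid age.
#' @export
true_mean_curve <- function(config, group, region, grid, stats = NULL) {
  stopifnot(region %in% config$regions, group %in% names(config$group_sizes))
  ff <- config$female_fraction[[group]]
  z <- latent_z(config, group, region, grid, female_fraction = ff) +
    (1 - ff) * config$gender_offset[[region]]
  if (is.null(stats)) return(z)
  tr <- config$trajectory[config$trajectory$region_code == region, ]
  st <- stats[stats$region_code == region, ]
  if (nrow(st) != 1) stop("stats do not cover region ", region, call. = FALSE)
  (tr$ratio_mean + tr$ratio_scale * z - st$ratio_mean) / st$ratio_sd
}
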