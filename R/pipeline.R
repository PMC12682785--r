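#' Configuration of a full pipeline run
#'
#' @param input_path path to a cohort CSV, or NULL to simulate.
#' @param synthetic a [synthetic_config()] used when \code{input_path} is
#'   NULL.
#' @param regions region codes to analyze (default: all in the input).
#' @param comparisons list of length-2 character vectors
#'   \code{c(group_a, group_b)}; \code{"ALL"} denotes the full cohort.
#'   Default: the reference group N against the full cohort and against each
#'   pathology group.
#' @param n_boot,candidates,cv_folds,alpha,min_count,window,chi2_method see
#'   [comparison_settings()].
#' @param z_limit outlier threshold on |z| (default 4).
#' @param gender \code{"all"}, \code{"female"}, \code{"male"}, or
#'   \code{"each"} (= all, then the female and male subsets, with
#'   normalization stats recomputed per subset).
#' @param seed master integer seed for the whole run.
#' @param output_dir directory for the output CSVs and manifest; created if
#'   needed. NULL suppresses file output.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input_path = NULL, synthetic = synthetic_config(),
                       regions = NULL,
                       comparisons = list(c("N", "ALL"), c("N", "AD"), c("N", "V"),
                                          c("N", "AV"), c("N", "OP")),
                       n_boot = 100, candidates = c(5, 10, 15), cv_folds = 5,
                       alpha = 0.01, min_count = 5, window = 2,
                       chi2_method = "satterthwaite",
                       z_limit = 4, gender = c("all", "female", "male", "each"),
                       seed = 1L, output_dir = NULL) {
  gender <- match.arg(gender)
  stopifnot(alpha > 0, alpha < 1, n_boot >= 2, z_limit > 0)
  structure(list(input_path = input_path, synthetic = synthetic,
                 regions = regions, comparisons = comparisons, n_boot = n_boot,
                 candidates = candidates, cv_folds = cv_folds, alpha = alpha,
                 min_count = min_count, window = window,
                 chi2_method = chi2_method, z_limit = z_limit,
                 gender = gender, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full age-volume curve analysis
#'
#' Executes, in order: cohort loading (CSV or synthetic), inclusion filters,
#' A/T/N/V stratification, TIV normalization and z-scoring, outlier removal,
#' per-group reliable age ranges, bootstrap volume curves per region and
#' group, all configured curve comparisons with Bonferroni correction, and
#' region ranking. With \code{gender = "each"} the analysis is rerun on the
#' female and male subsets, recomputing the normalization scale within each
#' subset. When \code{output_dir} is set, writes \code{curves.csv},
#' \code{comparisons.csv}, \code{ranking_top10.csv},
#' \code{significant_regions.csv}, \code{rejections.csv} and
#' \code{manifest.yaml} (which alone suffices to reproduce the run).
#'
#' @param config a [run_config()].
#' @return an object of class \code{volcurve_run}: list with \code{config},
#'   \code{counts} (per-stage subject flow), \code{results} (per subset: the
#'   comparison tables and fitted curves), and \code{paths} of written files.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mark_failed <- function(stage, msg) {
    if (!is.null(out_dir)) {
      yaml::write_yaml(list(status = "FAILED", stage = stage, error = msg),
                       file.path(out_dir, "manifest.yaml"))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      mark_failed(stage, conditionMessage(e))
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- run_stage("load", {
    if (!is.null(config$input_path)) read_cohort(config$input_path)
    else generate_cohort(config$synthetic, seed = derive_seed(config$seed, "cohort"))
  })
  regions <- config$regions %||% cohort_regions(cohort)
  counts <- list(n_input = nrow(cohort))

  filt <- run_stage("inclusion_filters", apply_inclusion_filters(cohort))
  counts$n_rejected <- nrow(filt$rejected)
  strat <- run_stage("stratification", stratify_cohort(filt$kept))
  counts$n_excluded_ambiguous <- nrow(strat$excluded)
  counts$group_sizes <- as.list(strat$sizes)
  rejections <- rbind(filt$rejected,
                      if (nrow(strat$excluded) > 0)
                        data.frame(subject_id = strat$excluded$subject_id,
                                   reason_code = "ambiguous_atnv",
                                   stringsAsFactors = FALSE))

  subsets <- switch(config$gender,
                    all = "all", female = "female", male = "male",
                    each = c("all", "female", "male"))
  results <- list()
  for (sub in subsets) {
    cs <- strat$cohort
    if (sub != "all") {
      cs <- cs[cs$gender == sub, , drop = FALSE]
      attr(cs, "regions") <- cohort_regions(strat$cohort)
    }
    nc <- run_stage(paste0("normalize_", sub), normalize_volumes(cs, regions))
    nc <- run_stage(paste0("outliers_", sub), remove_outliers(nc, config$z_limit))
    counts[[paste0("n_", sub)]] <- nrow(nc$subjects)
    counts[[paste0("n_outliers_", sub)]] <- attr(nc, "n_removed")
    settings <- comparison_settings(
      n_boot = config$n_boot, candidates = config$candidates,
      cv_folds = config$cv_folds, min_count = config$min_count,
      window = config$window, alpha = config$alpha,
      chi2_method = config$chi2_method,
      seed = derive_seed(config$seed, paste0("analysis_", sub)))
    comps <- run_stage(paste0("compare_", sub), {
      lapply(config$comparisons, function(pair) {
        compare_groups(nc, pair[1], pair[2], regions = regions, settings = settings)
      })
    })
    names(comps) <- vapply(config$comparisons, paste, "", collapse = "_vs_")
    results[[sub]] <- list(normalized = nc, comparisons = comps)
  }

  paths <- if (!is.null(out_dir)) {
    run_stage("write_outputs",
              write_run_outputs(results, rejections, counts, config, out_dir))
  } else character()
  structure(list(config = config, counts = counts, results = results,
                 paths = paths),
            class = "volcurve_run")
}

write_run_outputs <- function(results, rejections, counts, config, out_dir) {
  bind_subset <- function(fun) {
    do.call(rbind, unlist(lapply(names(results), function(sub) {
      lapply(names(results[[sub]]$comparisons), function(pair) {
        df <- fun(results[[sub]]$comparisons[[pair]])
        if (is.null(df) || nrow(df) == 0) return(NULL)
        cbind(subset = sub, df, stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
  }
  comparisons <- bind_subset(as.data.frame)
  ranking <- bind_subset(function(cmp) rank_regions(cmp, top_k = 10))
  signif <- bind_subset(function(cmp) {
    df <- as.data.frame(cmp)
    df[!is.na(df$significant) & df$significant, , drop = FALSE]
  })
  curve_rows <- do.call(rbind, unlist(lapply(names(results), function(sub) {
    lapply(results[[sub]]$comparisons, function(cmp) {
      cl <- attr(cmp, "curves")
      do.call(rbind, lapply(cl, function(cv) {
        data.frame(subset = sub, region_code = cv$region_code,
                   group = as.character(cv$group), age = cv$grid,
                   mean = cv$mean, sd = cv$sd, bandwidth = cv$bandwidth,
                   n_subjects = cv$n_subjects, stringsAsFactors = FALSE)
      }))
    })
  }), recursive = FALSE))
  curve_rows <- unique(curve_rows)  # shared groups appear in several pairs

  paths <- c(curves = file.path(out_dir, "curves.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"),
             ranking = file.path(out_dir, "ranking_top10.csv"),
             significant = file.path(out_dir, "significant_regions.csv"),
             rejections = file.path(out_dir, "rejections.csv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  utils::write.csv(curve_rows, paths["curves"], row.names = FALSE, quote = FALSE)
  utils::write.csv(comparisons, paths["comparisons"], row.names = FALSE, quote = FALSE)
  utils::write.csv(ranking, paths["ranking"], row.names = FALSE, quote = FALSE)
  utils::write.csv(signif, paths["significant"], row.names = FALSE, quote = FALSE)
  utils::write.csv(rejections, paths["rejections"], row.names = FALSE, quote = FALSE)
  # full precision so the manifest reproduces the run bit-exactly
  yaml::write_yaml(c(list(status = "OK"), manifest_config(config),
                     list(counts = counts)),
                   paths["manifest"], precision = 22)
  paths
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- if (is.null(config$input_path)) {
    config_to_list(config$synthetic)
  } else NULL
  cfg$output_dir <- NULL
  list(config = cfg)
}

#' Reproduce a pipeline run from its manifest
#'
#' @param manifest_path path to a \code{manifest.yaml} written by
#'   [run_pipeline()].
#' @param output_dir where to write the reproduced outputs (NULL: no files).
#' @return the \code{volcurve_run} of the reproduced analysis.
#' @export
run_from_manifest <- function(manifest_path, output_dir = NULL) {
  man <- yaml::read_yaml(manifest_path)
  if (!identical(man$status, "OK")) stop("manifest does not describe a completed run", call. = FALSE)
  cfg <- man$config
  syn <- if (!is.null(cfg$synthetic)) {
    raw <- cfg$synthetic
    for (nm in c("age_model", "trajectory", "effects")) {
      raw[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
    }
    for (nm in c("group_sizes", "female_fraction", "gender_offset")) {
      raw[[nm]] <- unlist(raw[[nm]])
    }
    do.call(synthetic_config, raw)
  } else synthetic_config()
  run_pipeline(run_config(
    input_path = cfg$input_path, synthetic = syn,
    regions = cfg$regions, comparisons = cfg$comparisons,
    n_boot = cfg$n_boot, candidates = unlist(cfg$candidates),
    cv_folds = cfg$cv_folds, alpha = cfg$alpha, min_count = cfg$min_count,
    window = cfg$window, chi2_method = cfg$chi2_method,
    z_limit = cfg$z_limit, gender = cfg$gender, seed = cfg$seed,
    output_dir = output_dir))
}

#' @export
print.volcurve_run <- function(x, ...) {
  cat("Age-volume curve analysis run\n")
  cat(sprintf("  input: %d subjects, %d rejected, %d excluded (ambiguous A-/T+/V+)\n",
              x$counts$n_input, x$counts$n_rejected, x$counts$n_excluded_ambiguous))
  cat("  groups:", paste(sprintf("%s=%d", names(x$counts$group_sizes),
                                 unlist(x$counts$group_sizes)), collapse = ", "), "\n")
  for (sub in names(x$results)) {
    n_sig <- sum(vapply(x$results[[sub]]$comparisons,
                        function(cmp) sum(cmp$significant, na.rm = TRUE), numeric(1)))
    cat(sprintf("  subset %s: %d comparisons, %d significant region results\n",
                sub, length(x$results[[sub]]$comparisons), n_sig))
  }
  invisible(x)
}
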