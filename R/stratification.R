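#' Binary A/T/N/V biomarker status
#'
#' Classifies each subject on the four binary axes used to stratify the
#' cohort:
#' \describe{
#'   \item{A (amyloid)}{positive iff CSF A-beta-42 < 1030 pg/mL or
#'     p-tau/A-beta-42 > 0.023,}
#'   \item{T (tau)}{positive iff p-tau > 27 pg/mL,}
#'   \item{N (neurodegeneration)}{positive iff t-tau > 300 pg/mL,}
#'   \item{V (vascular)}{positive iff Fazekas score > 1, more than three
#'     microbleeds, or a history of stroke.}
#' }
#' All comparisons are strict: a value exactly at a threshold is negative.
#'
#' @param cohort cohort data.frame (see [read_cohort()]), or any data.frame
#'   with columns \code{abeta42}, \code{ptau}, \code{ttau}, \code{fazekas},
#'   \code{microbleeds}, \code{stroke_history}.
#' @return data.frame with logical columns \code{A}, \code{T}, \code{N},
#'   \code{V}, one row per subject.
#' @export
#' @examples
#' classify_biomarkers(data.frame(
#'   abeta42 = c(900, 1200), ptau = c(20, 30), ttau = c(200, 100),
#'   fazekas = 0, microbleeds = 0, stroke_history = FALSE))
classify_biomarkers <- function(cohort) {
  need <- c("abeta42", "ptau", "ttau", "fazekas", "microbleeds", "stroke_history")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) stop("missing biomarker columns: ", paste(missing, collapse = ", "))
  bad <- which(is.na(cohort$abeta42) | cohort$abeta42 <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "abeta42 missing or non-positive for %d subject(s) (ratio undefined); first offender row %d",
      length(bad), bad[1]), call. = FALSE)
  }
  if (anyNA(cohort[need])) stop("missing biomarker values; reject these records upstream", call. = FALSE)
  data.frame(
    A = cohort$abeta42 < 1030 | (cohort$ptau / cohort$abeta42) > 0.023,
    T = cohort$ptau > 27,
    N = cohort$ttau > 300,
    V = cohort$fazekas > 1 | cohort$microbleeds > 3 | as.logical(cohort$stroke_history)
  )
}

#' Map A/T/N/V status to a study group
#'
#' The five study groups (plus an exclusion label) partition the 16 possible
#' A/T/N/V combinations:
#' \itemize{
#'   \item \code{AD}: A+ and V- (any T/N),
#'   \item \code{AV}: A+ and V+ (any T/N),
#'   \item \code{V}: A-, V+ and T- (any N),
#'   \item \code{EXCLUDED}: the ambiguous A-, T+, V+ profile (any N),
#'   \item \code{OP}: A- and V- with T+ or N+,
#'   \item \code{N}: all four markers negative.
#' }
#'
#' @param status data.frame of logicals \code{A}, \code{T}, \code{N},
#'   \code{V} as returned by [classify_biomarkers()].
#' @return factor with levels \code{N, AD, V, AV, OP, EXCLUDED}.
#' @export
assign_group <- function(status) {
  A <- status$A; T <- status$T; N <- status$N; V <- status$V
  out <- character(length(A))
  out[A & !V] <- "AD"
  out[A & V] <- "AV"
  out[!A & V & !T] <- "V"
  out[!A & V & T] <- "EXCLUDED"
  out[!A & !V & (T | N)] <- "OP"
  out[!A & !V & !T & !N] <- "N"
  factor(out, levels = group_levels())
}

#' @rdname assign_group
#' @export
group_levels <- function() c("N", "AD", "V", "AV", "OP", "EXCLUDED")

#' Apply cohort inclusion filters
#'
#' Keeps subjects that are cognitively unimpaired (global CDR exactly 0),
#' pass all volumetric QC grades, carry no radiological exclusion, are at
#' least 50 years old, and have complete, usable biomarker and vascular
#' readings. Each rejected subject gets exactly one machine-readable reason
#' code (the first failing check, in the order listed).
#'
#' @param cohort cohort data.frame.
#' @return list with elements \code{kept} (cohort data.frame) and
#'   \code{rejected} (data.frame \code{subject_id}, \code{reason_code}).
#' @export
apply_inclusion_filters <- function(cohort) {
  reason <- rep(NA_character_, nrow(cohort))
  mark <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, code, reason)
  }
  reason <- mark(cohort$cdr_global != 0, "cdr_nonzero")
  reason <- mark(!cohort$qc_pass, "qc_fail")
  reason <- mark(cohort$radiological_exclusion, "radiological_exclusion")
  reason <- mark(cohort$age < 50, "age_below_50")
  reason <- mark(is.na(cohort$abeta42) | is.na(cohort$ttau) | is.na(cohort$ptau),
                 "missing_biomarker")
  reason <- mark(cohort$abeta42 <= 0, "nonpositive_abeta42")
  reason <- mark(is.na(cohort$fazekas) | is.na(cohort$microbleeds) |
                   is.na(cohort$stroke_history), "missing_vascular")
  keep <- is.na(reason)
  kept <- cohort[keep, , drop = FALSE]
  attr(kept, "regions") <- cohort_regions(cohort)
  if (nrow(kept) == 0) stop("no subjects pass the inclusion filters", call. = FALSE)
  list(
    kept = kept,
    rejected = data.frame(subject_id = cohort$subject_id[!keep],
                          reason_code = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Stratify a filtered cohort into biomarker groups
#'
#' Computes A/T/N/V status for every subject, assigns the study group, and
#' attaches it as a \code{group} column. Subjects with the ambiguous
#' A-/T+/V+ profile are labelled \code{EXCLUDED}: they are reported but must
#' be dropped from analysis groups (see \code{drop_excluded}).
#'
#' @param cohort cohort data.frame that already passed
#'   [apply_inclusion_filters()].
#' @param drop_excluded drop \code{EXCLUDED} subjects from the returned
#'   cohort (default TRUE); they are always returned separately.
#' @return list with \code{cohort} (with a \code{group} factor column),
#'   \code{excluded} (the excluded subjects), and \code{sizes} (named integer
#'   vector of analysis-group sizes).
#' @export
stratify_cohort <- function(cohort, drop_excluded = TRUE) {
  status <- classify_biomarkers(cohort)
  grp <- assign_group(status)
  cohort$group <- grp
  excluded <- cohort[grp == "EXCLUDED", , drop = FALSE]
  out <- if (drop_excluded) cohort[grp != "EXCLUDED", , drop = FALSE] else cohort
  attr(out, "regions") <- cohort_regions(cohort)
  attr(excluded, "regions") <- cohort_regions(cohort)
  sizes <- table(out$group)[setdiff(group_levels(), "EXCLUDED")]
  list(cohort = out, excluded = excluded,
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}
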