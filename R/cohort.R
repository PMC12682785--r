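#' Read a subject-level cohort table
#'
#' The cohort is a plain data frame with one row per subject. The fixed
#' columns are \code{subject_id}, \code{age} (years), \code{gender}
#' (\code{"female"}/\code{"male"}), the CSF biomarkers \code{abeta42},
#' \code{ttau}, \code{ptau} (pg/mL), the vascular markers \code{fazekas}
#' (0-3), \code{microbleeds} (count), \code{stroke_history} (0/1),
#' \code{cdr_global}, \code{qc_pass} (0/1, the conjunction of the volumetric
#' QC grades), \code{radiological_exclusion} (0/1) and \code{tiv}; every
#' remaining column is taken to be a raw regional volume in the same units as
#' \code{tiv}, named by its region code (e.g. \code{LLENTAV}).
#'
#' @param path path to a UTF-8, comma-separated file with the exact header
#'   described above; booleans encoded 0/1.
#' @return a data.frame with an attribute \code{"regions"} listing the region
#'   codes found.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df data.frame with the cohort columns (see [read_cohort()]).
#' @return the data.frame with logical QC columns and a \code{"regions"}
#'   attribute.
#' @export
as_cohort <- function(df) {
  fixed <- cohort_fixed_columns()
  missing <- setdiff(fixed, names(df))
  if (length(missing) > 0) {
    stop("cohort table is missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  regions <- setdiff(names(df), fixed)
  if (length(regions) == 0) stop("cohort table has no region volume columns", call. = FALSE)
  for (col in c("stroke_history", "qc_pass", "radiological_exclusion")) {
    df[[col]] <- as.logical(as.integer(df[[col]]))
  }
  df$subject_id <- as.character(df$subject_id)
  attr(df, "regions") <- regions
  df
}

cohort_fixed_columns <- function() {
  c("subject_id", "age", "gender", "abeta42", "ttau", "ptau", "fazekas",
    "microbleeds", "stroke_history", "cdr_global", "qc_pass",
    "radiological_exclusion", "tiv")
}

#' Region codes of a cohort table
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @return character vector of region codes.
#' @export
cohort_regions <- function(cohort) {
  attr(cohort, "regions") %||% setdiff(names(cohort), cohort_fixed_columns())
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: booleans are encoded 0/1 and columns keep the
#' canonical order (fixed columns, then regions).
#'
#' @param cohort cohort data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, c(cohort_fixed_columns(), cohort_regions(cohort))]
  for (col in c("stroke_history", "qc_pass", "radiological_exclusion")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
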