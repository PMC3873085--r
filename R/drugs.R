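#' Migraine preventive medications tracked by the analysis
#'
#' The five preventive drugs whose exposure (treatment days and cumulative
#' dosage in milligrams) forms the 10-element feature vector of every cohort
#' subject.  Order is fixed; every exposure matrix, subject table and
#' configuration uses it.
#'
#' @return Character vector of length 5.
#' @export
migraine_drugs <- function() {
  c("amitriptyline", "flunarizine", "propranolol", "topiramate", "valproic_acid")
}

#' Column names of the 10-element exposure feature vector
#'
#' One `(duration_days, dosage_mg)` pair per drug, in drug order.
#'
#' @return Character vector of length 10.
#' @export
exposure_feature_names <- function() {
  as.vector(t(outer(migraine_drugs(), c("duration_days", "dosage_mg"),
                    paste, sep = "_")))
}

#' WHO defined-daily-dose reference table
#'
#' Milligrams per defined daily dose (DDD) for the five preventive drugs,
#' after the WHO ATC/DDD index.  These are external reference constants;
#' analyses may substitute their own table.
#'
#' @return Data frame with columns `drug` and `mg_per_ddd`.
#' @export
default_ddd_table <- function() {
  path <- system.file("extdata", "ddd_reference.tsv", package = "comorbscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published reference counts for the worked example
#'
#' Demographic and drug-utilization counts from a published population-based
#' migraine case-control cohort (19,356 cases, 1:5 age/sex-matched controls
#' drawn from a national claims sample).  Shipped so the odds-ratio and
#' proportion machinery can be exercised on real printed numbers without any
#' access to the (non-distributable) claims source.
#'
#' @return Data frame with columns `variable`, `case_count`, `control_count`.
#' @export
cohort_reference_counts <- function() {
  path <- system.file("extdata", "cohort_reference_counts.tsv",
                      package = "comorbscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
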