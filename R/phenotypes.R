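#' Validate a phenotype table
#'
#' A phenotype table is a tibble with one row per (individual, examination)
#' record: columns `iid` (individual id), `sex` (0 female, 1 male),
#' `ethnicity` (integer 1-4: E-A, C-A, A-A, H-A), `exam` (replication id)
#' and `value` (trait value). Repeated examinations are stacked as
#' replicate records.
#'
#' @param phenotypes a data frame with the columns above.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_phenotypes <- function(phenotypes) {
  ph <- tibble::as_tibble(phenotypes)
  need <- c("iid", "sex", "ethnicity", "exam", "value")
  if (!all(need %in% names(ph))) {
    abort(paste0("phenotype table needs columns ", paste(need, collapse = ", ")))
  }
  if (!all(ph$sex %in% c(0, 1))) abort("`sex` must be 0 (female) or 1 (male)")
  if (!all(ph$ethnicity %in% 1:4)) abort("`ethnicity` must be in 1:4")
  if (anyDuplicated(ph[, c("iid", "exam")])) {
    abort("each (iid, exam) pair may appear at most once")
  }
  per_ind <- tapply(ph$ethnicity, ph$iid, function(v) length(unique(v)))
  if (any(per_ind > 1)) abort("`ethnicity` must be constant within individual")
  per_sex <- tapply(ph$sex, ph$iid, function(v) length(unique(v)))
  if (any(per_sex > 1)) abort("`sex` must be constant within individual")
  ph
}

#' Read a phenotype table from TSV
#'
#' Expects header columns `iid`, `sex`, `ethnicity`, `exam`, `value`.
#'
#' @param path file path.
#' @return A validated phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(ph)
}

#' Write a phenotype table to TSV
#'
#' @param phenotypes a phenotype tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(validate_phenotypes(phenotypes), path, progress = FALSE)
  invisible(path)
}
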