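#' Read a long-format drug screening table
#'
#' Expects a UTF-8 CSV with header `cell_line,drug,ic50_uM` (dot decimal).
#'
#' @param path CSV path.
#' @return data frame with columns `cell_line`, `drug`, `ic50`.
#' @export
read_screen_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_line", "drug", "ic50_uM") %in% names(x)))
  data.frame(cell_line = x$cell_line, drug = x$drug, ic50 = x$ic50_uM)
}

#' Read a cell line annotation table
#'
#' Expects header `cell_line,lineage,mycn_amplified,tp53_mutant` with
#' booleans encoded 0/1.
#'
#' @param path CSV path.
#' @return data frame with logical genotype flags.
#' @export
read_annotations_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_line", "lineage", "mycn_amplified", "tp53_mutant")
                %in% names(x)))
  x$mycn_amplified <- as.logical(as.integer(x$mycn_amplified))
  x$tp53_mutant <- as.logical(as.integer(x$tp53_mutant))
  x
}

#' Read dose-response points
#'
#' Expects header `dose_uM,response,replicate` (replicate optional).
#'
#' @param path CSV path.
#' @return data frame `dose_uM`, `response`, `replicate`.
#' @export
read_dose_response_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dose_uM", "response") %in% names(x)))
  if (is.null(x$replicate)) x$replicate <- 1L
  x
}

#' Read decatenation assay data
#'
#' Expects header `run,enzyme,dose_uM,percent_decatenation`.
#'
#' @param path CSV path.
#' @return long data frame suitable for [preference_ratio()].
#' @export
read_decat_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("run", "enzyme", "dose_uM", "percent_decatenation")
                %in% names(x)))
  x
}

#' Read PK concentration-time profiles
#'
#' Expects header `subject,time_h,conc_ugL,dose_mgkg,route`.
#'
#' @param path CSV path.
#' @return data frame, one row per sample.
#' @export
read_pk_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "time_h", "conc_ugL") %in% names(x)))
  x
}

#' Write selectivity results as CSV and JSON
#'
#' @param ranked a [rank_drugs()] result.
#' @param csv_path,json_path output paths (`NULL` to skip one).
#' @return invisibly, the result table.
#' @export
write_selectivity <- function(ranked, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(ranked$results, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(results = ranked$results,
                              skipped = ranked$skipped),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(ranked$results)
}
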