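#' Sample sheets: species and sex assignments
#'
#' A sample sheet assigns a species and a sex to every sample in the
#' analysis. It is a plain `data.frame` with columns `sample_id`,
#' `species` and `sex`, carrying class `sample_sheet`.
#'
#' @param sample_id character vector of unique sample identifiers
#' @param species character vector; one of `"reticulata"`, `"wingei"`,
#'   `"picta"`, `"latipinna"`, `"holbrooki"`, `"other"`
#' @param sex character vector; one of `"M"`, `"F"`, `"unknown"`
#' @return a `sample_sheet` data.frame
#' @examples
#' sample_sheet(c("m1", "f1"), c("picta", "picta"), c("M", "F"))
#' @export
sample_sheet <- function(sample_id, species, sex) {
  sheet <- data.frame(sample_id = as.character(sample_id),
                      species = as.character(species),
                      sex = as.character(sex),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname sample_sheet
#' @param sheet a data.frame to validate
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "species", "sex")
  if (!all(required %in% names(sheet))) {
    stop_config("sample sheet must have columns ",
                paste(required, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_config("duplicated sample_id in sample sheet: ",
                paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                      collapse = ", "))
  }
  species_levels <- c("reticulata", "wingei", "picta", "latipinna",
                      "holbrooki", "other")
  bad <- setdiff(unique(sheet$species), species_levels)
  if (length(bad)) stop_config("unknown species: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(sheet$sex), c("M", "F", "unknown"))
  if (length(bad)) stop_config("unknown sex code: ", paste(bad, collapse = ", "))
  class(sheet) <- unique(c("sample_sheet", class(sheet)))
  sheet
}

#' Read / write a sample sheet as 3-column TSV
#'
#' @param path file path to a tab-separated file with header columns
#'   `sample_id`, `species`, `sex`
#' @return `read_sample_sheet` returns a validated [sample_sheet()];
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()]
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select sample ids by species and/or sex
#'
#' @param sheet a [sample_sheet()]
#' @param species optional species filter
#' @param sex optional sex filter
#' @return character vector of sample ids
#' @export
sheet_samples <- function(sheet, species = NULL, sex = NULL) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(species)) keep <- keep & sheet$species %in% species
  if (!is.null(sex)) keep <- keep & sheet$sex %in% sex
  sheet$sample_id[keep]
}
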