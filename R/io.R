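#' Read a cohort table from CSV
#'
#' CSV dialect: UTF-8, comma-separated, header row required, '.' decimal
#' separator, missing values as empty cells (never zeros). Validates that
#' ids are unique within each timepoint and that any `bmi` column agrees
#' with height/weight where both are present (rows are named in errors).
#' Unknown columns are preserved and ignored by downstream scoring.
#'
#' @param path CSV file path.
#' @param validate check id uniqueness and BMI consistency (default TRUE).
#' @return tibble of participant records.
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop_input(sprintf("cohort file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!nrow(tab)) return(tibble::as_tibble(tab))
  if (validate) {
    if ("id" %in% names(tab)) {
      tp <- if ("timepoint" %in% names(tab)) tab$timepoint else "baseline"
      dup <- duplicated(paste(tab$id, tp))
      if (any(dup)) {
        stop_input(sprintf("duplicate participant id '%s' within timepoint (row %d)",
                           tab$id[dup][1], which(dup)[1]))
      }
    }
    if (all(c("bmi", "height_m", "weight_kg") %in% names(tab))) {
      derived <- tab$weight_kg / tab$height_m^2
      bad <- which(!is.na(tab$bmi) & !is.na(derived) & abs(tab$bmi - derived) > 0.5)
      if (length(bad)) {
        stop_input(sprintf("row %d: bmi (%g) inconsistent with height/weight (%.1f)",
                           bad[1], tab$bmi[bad[1]], derived[bad[1]]))
      }
    }
  }
  tab
}

#' Write scoring or evaluation results to CSV or JSON
#'
#' CSV and JSON outputs of the same result are value-identical field by
#' field; JSON mirrors the result tibble one object per row.
#'
#' @param results a data frame (e.g. [la_score()] output).
#' @param path output path.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  results <- tibble::as_tibble(results)
  if (format == "csv") {
    readr::write_csv(results, path, na = "")
  } else if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  } else {
    stop_input(sprintf("unknown output format '%s'", format))
  }
  invisible(path)
}
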