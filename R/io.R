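#' Read and write correlation sets
#'
#' Two on-disk forms are supported: a JSON object with the six `r_*` fields
#' (plus optional `n`), and a labeled 4x4 CSV matrix with header
#' `X1, X2, Y1, Y2`. Both readers validate ranges, symmetry and the unit
#' diagonal, and report offending fields.
#'
#' @param path File path; format chosen by extension (`.json` vs anything
#'   else = CSV matrix).
#' @return [read_correlation_set()]: a `cor_set`.
#' @export
read_correlation_set <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(as_correlation_set(x))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  first <- names(df)[1]
  if (first %in% c("", "X", "row", "rowname") || !first %in% VAR_NAMES) {
    rn <- df[[1]]
    df <- df[-1]
  } else {
    rn <- VAR_NAMES
  }
  m <- as.matrix(df)
  if (!all(dim(m) == c(4, 4)) || !identical(colnames(m), VAR_NAMES)) {
    abort("Correlation CSV must be a 4x4 matrix with header X1, X2, Y1, Y2.",
          class = "prospam_error_parse")
  }
  rownames(m) <- rn
  storage.mode(m) <- "double"
  if (anyNA(m) && !anyNA(diag(m))) {
    ## off-diagonal NAs are allowed (missing correlations)
  } else if (anyNA(diag(m))) {
    abort("Correlation CSV has missing diagonal entries.", class = "prospam_error_parse")
  }
  cor_set_from_matrix(m)
}

#' @rdname read_correlation_set
#' @param cs A [correlation_set()].
#' @param format `"json"` or `"csv"`.
#' @export
write_correlation_set <- function(cs, path, format = c("json", "csv")) {
  format <- match.arg(format)
  cs <- as_correlation_set(cs)
  if (format == "json") {
    vals <- as.list(tibble::as_tibble(cs))
    if (is.na(vals$n)) vals$n <- NULL
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    m <- cor_set_matrix(cs)
    utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  }
  invisible(path)
}

#' Read and write per-study correlation tables
#'
#' The study-table CSV has columns `study, n, r_x1x2, r_x1y1, r_x1y2,
#' r_x2y1, r_x2y2, r_y1y2`; empty cells mark correlations a study did not
#' report. This is the import format for user-transcribed extracted tables
#' as well as for [make_study_fixtures()] output.
#'
#' @param path File path.
#' @return A tibble of study records.
#' @export
read_study_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("study", "n", COR_NAMES)
  miss <- setdiff(c("study", "n"), names(df))
  if (length(miss)) {
    abort(paste0("Study table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "prospam_error_parse")
  }
  for (nm in COR_NAMES) if (is.null(df[[nm]])) df[[nm]] <- NA_real_
  df <- df[need]
  if (any(!is.na(df$n) & df$n < 4)) {
    abort("Every study needs n >= 4 (Fisher-z variance 1/(n-3) must be positive).",
          class = "prospam_error_validation")
  }
  for (i in seq_len(nrow(df))) {
    vals <- unlist(df[i, COR_NAMES])
    bad <- !is.na(vals) & abs(vals) >= 1
    if (any(bad)) {
      abort(paste0("Row ", i, " (", df$study[i], "): correlation out of (-1, 1): ",
                   paste(names(vals)[bad], collapse = ", ")),
            class = "prospam_error_parse")
    }
  }
  df
}

#' @rdname read_study_table
#' @param studies Study table tibble.
#' @export
write_study_table <- function(studies, path) {
  readr::write_csv(studies, path, na = "")
  invisible(path)
}

#' Read and write raw two-wave datasets
#'
#' Plain CSV with header `X1, X2, Y1, Y2`. Readers reject non-finite values.
#'
#' @param path File path.
#' @return A tibble with the four numeric columns.
#' @export
read_two_wave <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_two_wave(df)
}

#' @rdname read_two_wave
#' @param data Two-wave data frame.
#' @export
write_two_wave <- function(data, path) {
  readr::write_csv(as_two_wave(data), path)
  invisible(path)
}

report_payload <- function(report) {
  eff_cols <- c("direction", "beta_lag_fwd", "beta_lag_rev", "beta_change",
                "beta_change_on_change")
  list(
    input = as.list(tibble::as_tibble(report$input)),
    fit = c(as.list(glance(report$fit)), list(params = as.list(tidy(report$fit)))),
    predicted = as.list(tibble::as_tibble(report$predicted)),
    input_effects = as.list(report$input_effects[eff_cols]),
    predicted_effects = as.list(report$predicted_effects[eff_cols]),
    deltas = as.list(report$deltas[eff_cols]),
    input_verdicts = as.list(report$input_verdicts),
    predicted_verdicts = as.list(report$predicted_verdicts),
    provenance = report$provenance
  )
}

#' Serialize an evaluation report
#'
#' Writes a [spam_evaluation()] report as JSON (numbers at full precision,
#' so a rewritten report is byte-identical for identical inputs).
#'
#' @param report A `spam_evaluation` object.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "spam_evaluation")) {
    abort("`report` must be a spam_evaluation object.", class = "prospam_error_validation")
  }
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
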