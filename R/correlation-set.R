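## The six pairwise correlations of a two-construct, two-occasion design,
## in the canonical column order used throughout the package.
COR_NAMES <- c("r_x1x2", "r_x1y1", "r_x1y2", "r_x2y1", "r_x2y2", "r_y1y2")
VAR_NAMES <- c("X1", "X2", "Y1", "Y2")

## (row, col) slot of each correlation in the 4x4 matrix (order X1, X2, Y1, Y2)
COR_SLOTS <- list(
  r_x1x2 = c(1L, 2L), r_x1y1 = c(1L, 3L), r_x1y2 = c(1L, 4L),
  r_x2y1 = c(2L, 3L), r_x2y2 = c(2L, 4L), r_y1y2 = c(3L, 4L)
)

#' Create a two-wave correlation set
#'
#' A correlation set holds the six pairwise Pearson correlations among two
#' constructs X and Y each measured at two occasions (variables `X1`, `X2`,
#' `Y1`, `Y2`), plus an optional sample size. It is the universal input
#' currency of the package: closed-form effects, model fitting and simulation
#' all consume it. Entries may be `NA` to represent correlations a study did
#' not report (e.g. no time-2 measure of Y).
#'
#' @param r_x1x2,r_x1y1,r_x1y2,r_x2y1,r_x2y2,r_y1y2 Pearson correlations,
#'   each strictly inside (-1, 1), or `NA` for a missing entry. `r_x1x2` and
#'   `r_y1y2` are the autocorrelations (stabilities), `r_x1y1` and `r_x2y2`
#'   the concurrent correlations, `r_x1y2` and `r_x2y1` the cross-lagged
#'   correlations.
#' @param n Optional positive integer sample size.
#'
#' @return A one-row tibble of class `cor_set` with columns
#'   `r_x1x2 ... r_y1y2` and `n`.
#' @examples
#' # Pooled loneliness / social-anxiety correlations
#' lon_sa <- correlation_set(0.603, 0.493, 0.379, 0.351, 0.552, 0.568, n = 10000)
#' cor_set_matrix(lon_sa)
#' @export
correlation_set <- function(r_x1x2, r_x1y1, r_x1y2, r_x2y1, r_x2y2, r_y1y2,
                            n = NA_integer_) {
  vals <- vapply(list(r_x1x2, r_x1y1, r_x1y2, r_x2y1, r_x2y2, r_y1y2),
                 function(v) as.numeric(v)[1], numeric(1))
  names(vals) <- COR_NAMES
  validate_correlations(vals)
  if (!is.na(n) && (!is.numeric(n) || n < 1)) {
    abort("`n` must be a positive sample size.", class = "prospam_error_validation")
  }
  out <- tibble::as_tibble(as.list(vals))
  out$n <- if (is.na(n)) NA_integer_ else as.integer(n)
  class(out) <- c("cor_set", class(out))
  out
}

validate_correlations <- function(vals) {
  bad <- !is.na(vals) & (!is.finite(vals) | abs(vals) >= 1)
  if (any(bad)) {
    abort(
      paste0("Correlations must lie strictly inside (-1, 1); offending: ",
             paste(names(vals)[bad], "=", format(vals[bad]), collapse = ", ")),
      class = "prospam_error_validation"
    )
  }
  invisible(vals)
}

#' Coerce to a correlation set
#'
#' Accepts an existing `cor_set`, a named list or one-row data frame with the
#' six `r_*` columns (missing columns become `NA`), or a 4x4 correlation
#' matrix with variables ordered `X1, X2, Y1, Y2`.
#'
#' @param x Object to coerce.
#' @param n Optional sample size, overriding any `n` carried by `x`.
#' @return A `cor_set` tibble.
#' @export
as_correlation_set <- function(x, n = NULL) {
  if (inherits(x, "cor_set")) {
    if (!is.null(n)) x$n <- as.integer(n)
    return(x)
  }
  if (is.matrix(x)) return(cor_set_from_matrix(x, n = n))
  x <- as.list(x)
  vals <- lapply(COR_NAMES, function(nm) if (is.null(x[[nm]])) NA_real_ else as.numeric(x[[nm]]))
  names(vals) <- COR_NAMES
  nn <- n %||% x[["n"]] %||% NA_integer_
  do.call(correlation_set, c(vals, list(n = if (is.null(nn) || is.na(nn)) NA_integer_ else nn)))
}

#' Assemble the 4x4 correlation matrix of a correlation set
#'
#' @param cs A [correlation_set()] (or coercible object).
#' @return A symmetric 4x4 matrix with unit diagonal, dimnames
#'   `X1, X2, Y1, Y2`. Missing entries propagate as `NA`.
#' @export
cor_set_matrix <- function(cs) {
  cs <- as_correlation_set(cs)
  m <- diag(4)
  for (nm in COR_NAMES) {
    ij <- COR_SLOTS[[nm]]
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- cs[[nm]]
  }
  dimnames(m) <- list(VAR_NAMES, VAR_NAMES)
  m
}

#' Build a correlation set from a 4x4 matrix
#'
#' @param m Symmetric 4x4 correlation matrix, variables ordered
#'   `X1, X2, Y1, Y2`, unit diagonal.
#' @param n Optional sample size.
#' @param tol Tolerance for the symmetry and unit-diagonal checks.
#' @return A `cor_set` tibble.
#' @export
cor_set_from_matrix <- function(m, n = NULL, tol = 1e-8) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L))) {
    abort("Expected a 4x4 matrix.", class = "prospam_error_validation")
  }
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) {
    abort("Correlation matrix is not symmetric.", class = "prospam_error_validation")
  }
  if (max(abs(diag(m) - 1)) > tol) {
    abort("Correlation matrix must have a unit diagonal.", class = "prospam_error_validation")
  }
  vals <- lapply(COR_SLOTS, function(ij) m[ij[1], ij[2]])
  do.call(correlation_set, c(vals, list(n = n %||% NA_integer_)))
}

#' Check positive semidefiniteness of a correlation set
#'
#' Simulation and maximum-likelihood fitting require the assembled 4x4 matrix
#' to be a valid (positive semidefinite) correlation matrix; this check is the
#' gate. Sets with missing entries are reported as not checkable (`NA`).
#'
#' @param cs A correlation set.
#' @param tol Eigenvalues above `-tol` count as non-negative.
#' @return `TRUE`, `FALSE`, or `NA` if any entry is missing.
#' @export
is_psd <- function(cs, tol = 1e-10) {
  cs <- as_correlation_set(cs)
  if (anyNA(cs[COR_NAMES])) return(NA)
  ev <- eigen(cor_set_matrix(cs), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol
}

cor_set_complete <- function(cs) !anyNA(as_correlation_set(cs)[COR_NAMES])

require_entries <- function(cs, needed) {
  miss <- needed[vapply(needed, function(nm) is.na(cs[[nm]]), logical(1))]
  if (length(miss)) {
    abort(paste0("Missing required correlation(s): ", paste(miss, collapse = ", ")),
          class = "prospam_error_missing_input")
  }
  invisible(cs)
}

#' @export
print.cor_set <- function(x, ...) {
  cat("<two-wave correlation set>\n")
  m <- cor_set_matrix(x)
  print(round(m, 4))
  psd <- is_psd(x)
  cat("n =", ifelse(is.na(x$n), "unknown", x$n),
      "| positive semidefinite:", ifelse(is.na(psd), "not checkable (missing entries)", psd), "\n")
  invisible(x)
}
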