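#' Round half away from zero
#'
#' Display rounding used for ratio tables: ties are rounded away from zero
#' (2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalize species labels for matching
#'
#' Trims, collapses runs of whitespace/underscores to a single underscore and
#' lower-cases, so that "Pan  troglodytes", "pan_troglodytes" and
#' "Pan_Troglodytes " all compare equal.
#'
#' @param x character vector of species labels.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  x <- gsub("[[:space:]_]+", "_", trimws(x))
  tolower(x)
}

# Gaussian log-density with covariance V (Cholesky-based); mu recycled.
mvn_loglik <- function(y, mu, V) {
  U <- chol(V)
  z <- backsolve(U, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

# Whiten a design/response by the upper Cholesky factor of C (C = U'U).
whiten <- function(U, A) backsolve(U, A, transpose = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
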