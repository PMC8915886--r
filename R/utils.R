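#' Cosine similarity between two vectors
#'
#' Standard cosine \eqn{\langle u,v\rangle / (\|u\|\,\|v\|)}. Used throughout
#' the package: for nearest-word lookup, topic assignment, distinctness and
#' coherence scoring, and semantic-dimension loadings.
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return A scalar in \[-1, 1\].
#' @export
#' @examples
#' cosine(c(1, 0), c(1, 1)) # sqrt(2)/2
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("cosine: vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine: zero vector")
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) stop("unit_norm: zero vector")
  x / n
}

# Row-normalize a matrix to unit L2 norm; zero rows are an error.
unit_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  if (any(n == 0)) stop("unit_rows: zero row")
  X / n
}

# Deterministic sign convention for a singular/principal vector: the entry of
# largest absolute value is made positive (first such entry on ties).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
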