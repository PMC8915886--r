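#' Default gender anchor pairs
#'
#' Standard (masculine, feminine) anchor pairs used to span a gender axis in
#' embedding space. The list is data, not code: supply your own pairs to
#' [build_dimension()] for other corpora or other dimensions.
#'
#' @return Two-column character matrix, column 1 = pole A (masculine),
#'   column 2 = pole B (feminine).
#' @export
default_gender_pairs <- function() {
  cbind(
    pole_a = c("he", "man", "him", "male", "father", "son", "husband", "brother"),
    pole_b = c("she", "woman", "her", "female", "mother", "daughter", "wife", "sister")
  )
}

#' Build a latent semantic dimension from anchor word pairs
#'
#' Mean-of-differences axis: for each surviving pair the difference
#' v(pole_b) - v(pole_a) is unit-normalized, the normalized differences are
#' averaged, and the average is normalized again. Positive loadings point
#' toward pole B (for the gender default: feminine). Pairs with either anchor
#' out of vocabulary are skipped and reported; at least one pair must survive.
#'
#' @param pairs Two-column character matrix or data.frame (pole_a, pole_b).
#' @param emb A `datm_embedding`.
#' @param name Label for the dimension (default "dimension").
#' @return A `datm_dimension`: list(name, pairs, axis, n_pairs_used,
#'   skipped_pairs).
#' @export
build_dimension <- function(pairs, emb, name = "dimension") {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("build_dimension: pairs must have two columns")
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("build_dimension: a pair has identical pole words")
  }
  idx_a <- unname(emb$vocab$index[pairs[, 1]])
  idx_b <- unname(emb$vocab$index[pairs[, 2]])
  ok <- !is.na(idx_a) & !is.na(idx_b)
  skipped <- pairs[!ok, , drop = FALSE]
  if (!any(ok)) stop("build_dimension: no anchor pair fully in vocabulary")
  diffs <- emb$vectors[idx_b[ok], , drop = FALSE] -
    emb$vectors[idx_a[ok], , drop = FALSE]
  nrm <- sqrt(rowSums(diffs^2))
  if (any(nrm == 0)) stop("build_dimension: a pair has identical vectors")
  axis <- unit_norm(colMeans(diffs / nrm))
  structure(list(name = name, pairs = pairs[ok, , drop = FALSE], axis = axis,
                 n_pairs_used = sum(ok), skipped_pairs = skipped),
            class = "datm_dimension")
}

#' @export
print.datm_dimension <- function(x, ...) {
  cat(sprintf("<datm_dimension> '%s' from %d anchor pairs\n",
              x$name, x$n_pairs_used))
  invisible(x)
}

#' Loading of a topic atom on a semantic dimension
#'
#' Cosine similarity between the atom vector and the dimension axis, in
#' \[-1, 1\]. Positive values lean toward pole B (e.g. feminine), negative
#' toward pole A (e.g. masculine). Invariant to positive rescaling of the
#' atom.
#'
#' @param atom Nonzero N-vector (an atom/topic vector).
#' @param dim A `datm_dimension`.
#' @return Scalar loading.
#' @export
topic_loading <- function(atom, dim) {
  cosine(atom, dim$axis)
}

#' Rank all topics by their loading on a dimension
#'
#' Sorts the dictionary's atoms by loading (descending: pole B first) and
#' attaches each topic's top terms so both extremes can be audited
#' qualitatively.
#'
#' @param dict A `datm_atoms`.
#' @param dim A `datm_dimension`.
#' @param emb The matching `datm_embedding`.
#' @param top_n Terms per topic in the audit column (default 7).
#' @return data.frame: topic_id, loading, top_terms (comma-joined), sorted by
#'   descending loading.
#' @export
rank_topics <- function(dict, dim, emb, top_n = 7) {
  loading <- vapply(seq_len(dict$K), function(k) {
    topic_loading(dict$atoms[k, ], dim)
  }, 0)
  terms <- vapply(seq_len(dict$K), function(k) {
    paste(nearest_words(emb, dict$atoms[k, ], n = top_n)$term, collapse = ", ")
  }, "")
  df <- data.frame(topic_id = seq_len(dict$K), loading = loading,
                   top_terms = terms, stringsAsFactors = FALSE)
  df[order(-df$loading, df$topic_id), ]
}
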