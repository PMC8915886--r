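#' Train a word embedding on a tokenized corpus
#'
#' Produces the dense semantic space in which atoms, gists and semantic
#' dimensions live. The estimator is the classical count-based one: a
#' symmetric co-occurrence matrix over a +/- `window` token context, positive
#' pointwise mutual information (PPMI) weighting, and a rank-`dim` truncated
#' SVD with square-root singular-value scaling
#' (\eqn{W = U_d \Sigma_d^{1/2}}). This spectral factorization of the PPMI
#' matrix is the standard deterministic counterpart of skip-gram with negative
#' sampling, so the resulting space supports the same geometric operations
#' (nearest words, analogy axes, sparse coding).
#'
#' Entirely deterministic: identical corpus and parameters give identical
#' vectors (signs are fixed so each dimension's largest-magnitude coordinate
#' is positive).
#'
#' @param corpus A `datm_corpus` (tokens should already be phrase-merged).
#' @param vocab A `datm_vocabulary` built from the same corpus; out-of-vocabulary
#'   tokens are skipped when counting co-occurrences.
#' @param dim Embedding dimension N (>= 2 and < vocabulary size).
#' @param window Symmetric context window in tokens (default 5).
#' @return A `datm_embedding`: list with `vocab`, `vectors` (V x N matrix with
#'   terms as rownames) and `dim`.
#' @export
train_embedding <- function(corpus, vocab, dim = 100, window = 5) {
  if (dim <= 1) stop("train_embedding: dim must be >= 2")
  nt <- sum(lengths(corpus$tokens))
  if (nt == 0) stop("train_embedding: empty corpus")
  V <- length(vocab$term)
  if (dim >= V) stop("train_embedding: dim must be < vocabulary size")
  C <- cooccurrence_counts(corpus$tokens, vocab, window)
  M <- ppmi(C)
  sv <- svd(M, nu = dim, nv = 0)
  U <- sv$u
  d <- sv$d[seq_len(dim)]
  # deterministic sign per left singular vector
  for (j in seq_len(dim)) U[, j] <- fix_sign(U[, j])
  W <- U * rep(sqrt(d), each = nrow(U))
  rownames(W) <- vocab$term
  new_embedding(W, vocab)
}

# Symmetric co-occurrence counts within +/- window, as a dense V x V matrix.
cooccurrence_counts <- function(tokens, vocab, window) {
  V <- length(vocab$term)
  ii <- integer(0); jj <- integer(0)
  idx_list <- lapply(tokens, function(tk) {
    ix <- unname(vocab$index[tk])
    ix[!is.na(ix)]
  })
  for (d in seq_len(window)) {
    for (ix in idx_list) {
      n <- length(ix)
      if (n > d) {
        ii <- c(ii, ix[seq_len(n - d)])
        jj <- c(jj, ix[(d + 1):n])
      }
    }
  }
  if (!length(ii)) stop("train_embedding: no co-occurrence pairs (documents too short?)")
  S <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(V, V))
  as.matrix(S)
}

# Positive pointwise mutual information of a symmetric count matrix.
ppmi <- function(C) {
  total <- sum(C)
  rs <- rowSums(C)
  M <- log(C * total / outer(rs, rs))
  M[!is.finite(M) | M < 0] <- 0
  M
}

#' Construct an embedding from an existing matrix of word vectors
#'
#' Used for externally trained vectors and for the simulator's planted space.
#'
#' @param vectors V x N numeric matrix; rownames are terms unless `vocab`
#'   supplies them.
#' @param vocab Optional `datm_vocabulary` aligned with the rows.
#' @return A `datm_embedding`.
#' @export
new_embedding <- function(vectors, vocab = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(vocab)) {
    if (is.null(rownames(vectors))) stop("new_embedding: need rownames or vocab")
    vocab <- new_vocabulary(rownames(vectors), rep(1, nrow(vectors)))
  }
  if (nrow(vectors) != length(vocab$term)) {
    stop("new_embedding: row count does not match vocabulary size")
  }
  if (ncol(vectors) < 2) stop("new_embedding: dim must be >= 2")
  if (any(!is.finite(vectors))) stop("new_embedding: non-finite entries")
  rownames(vectors) <- vocab$term
  structure(list(vocab = vocab, vectors = vectors, dim = ncol(vectors)),
            class = "datm_embedding")
}

#' @export
print.datm_embedding <- function(x, ...) {
  cat(sprintf("<datm_embedding> %d terms x %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Nearest words to a query point in semantic space
#'
#' Ranks the whole vocabulary by cosine similarity to `q`; the top terms of an
#' atom vector are how a topic is read. Ties are broken by ascending
#' vocabulary index so rankings are reproducible.
#'
#' @param emb A `datm_embedding`.
#' @param q Query N-vector (nonzero).
#' @param n Number of terms to return (<= vocabulary size).
#' @return data.frame with columns `term` and `cosine`, in descending cosine.
#' @export
nearest_words <- function(emb, q, n = 25) {
  V <- nrow(emb$vectors)
  if (n > V) stop("nearest_words: n exceeds vocabulary size")
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("nearest_words: zero query vector")
  norms <- sqrt(rowSums(emb$vectors^2))
  sims <- as.numeric(emb$vectors %*% q) / (norms * nq)
  ord <- order(-sims, seq_len(V))[seq_len(n)]
  data.frame(term = emb$vocab$term[ord], cosine = sims[ord],
             stringsAsFactors = FALSE)
}

#' Save / load word vectors in word2vec text format
#'
#' The header line is `V N`; each following line is `term v1 ... vN`.
#' Round-tripping reproduces vectors to better than 1e-6 per entry.
#'
#' @param emb A `datm_embedding`.
#' @param path File path.
#' @export
write_embedding <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), emb$dim), con)
  body <- vapply(seq_len(nrow(emb$vectors)), function(i) {
    paste(emb$vocab$term[i],
          paste(formatC(emb$vectors[i, ], digits = 9, format = "g"),
                collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embedding
#' @param vocab Optional `datm_vocabulary` providing counts/probabilities for
#'   the loaded terms (terms must match); otherwise uniform placeholder counts
#'   are used.
#' @export
read_embedding <- function(path, vocab = NULL) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  V <- hdr[1]; N <- hdr[2]
  if (length(lines) - 1L != V) stop("read_embedding: header/body mismatch")
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  terms <- vapply(parts, `[`, "", 1L)
  W <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(N)))
  rownames(W) <- terms
  if (!is.null(vocab)) {
    if (!identical(terms, vocab$term)) stop("read_embedding: terms do not match vocab")
    new_embedding(W, vocab)
  } else {
    new_embedding(W)
  }
}
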