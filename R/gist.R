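#' SIF configuration
#'
#' Parameters of the smooth-inverse-frequency gist estimator and the rolling
#' window scheme used to scan documents.
#'
#' @param a Smoothing weight of the SIF weights a/(p(w)+a). The single
#'   tunable collapsing the generative model's frequency/context trade-off and
#'   partition constant; default 1e-3, the usual recommended value.
#' @param window_size Tokens per rolling context window (default 10).
#' @param stride Tokens between window starts (default 5, i.e. 50% overlap).
#' @return A `datm_sif_config`.
#' @export
sif_config <- function(a = 1e-3, window_size = 10, stride = 5) {
  if (a <= 0) stop("sif_config: a must be > 0")
  if (window_size < 1) stop("sif_config: window_size must be >= 1")
  if (stride < 1) stop("sif_config: stride must be >= 1")
  structure(list(a = a, window_size = as.integer(window_size),
                 stride = as.integer(stride)),
            class = "datm_sif_config")
}

#' SIF weight of a word
#'
#' `a / (p_w + a)`: strictly decreasing in corpus frequency, 1 in the
#' rare-word limit, 1/2 at p_w = a. Frequent words contribute little to the
#' gist estimate; this is what makes an explicit stopword list unnecessary.
#'
#' @param p_w Unigram probability in \[0, 1\].
#' @param a Smoothing weight (> 0).
#' @return Weight in (0, 1\].
#' @export
sif_weight <- function(p_w, a) {
  if (any(a <= 0)) stop("sif_weight: a must be > 0")
  if (any(p_w < 0 | p_w > 1)) stop("sif_weight: p_w must be in [0, 1]")
  a / (p_w + a)
}

#' MAP estimate of the combined context vector for a window
#'
#' The maximum a posteriori estimate of the combined (local + global) context
#' vector given an observed window under the log-linear latent-variable model:
#' the SIF-weighted sum \eqn{\sum_{w \in C} \frac{a}{p(w)+a}\, \mathbf{w}}.
#' Out-of-vocabulary terms are skipped and counted.
#'
#' @param window Character vector of terms (one context window).
#' @param emb A `datm_embedding` (its vocabulary supplies p(w)).
#' @param cfg A [sif_config()].
#' @return N-vector with attributes `n_used` and `n_oov`; if no window term is
#'   in-vocabulary, a zero vector flagged with `attr(, "empty") = TRUE`.
#' @export
map_context <- function(window, emb, cfg) {
  idx <- unname(emb$vocab$index[window])
  oov <- is.na(idx)
  idx <- idx[!oov]
  N <- emb$dim
  if (!length(idx)) {
    v <- numeric(N)
    attr(v, "n_used") <- 0L
    attr(v, "n_oov") <- sum(oov)
    attr(v, "empty") <- TRUE
    return(v)
  }
  w <- sif_weight(emb$vocab$p[idx], cfg$a)
  v <- as.numeric(crossprod(emb$vectors[idx, , drop = FALSE], w))
  attr(v, "n_used") <- length(idx)
  attr(v, "n_oov") <- sum(oov)
  attr(v, "empty") <- FALSE
  v
}

#' Estimate the global context vector
#'
#' First principal component (first right singular vector, uncentered) of a
#' stack of combined-context vectors; interpreted as the corpus-wide
#' syntactic/semantic component c0 that is common to all windows and must be
#' removed to expose the local gist. Unit norm, sign fixed so the
#' largest-|entry| coordinate is positive.
#'
#' @param contexts Matrix with one context vector per row (>= 2 rows), or a
#'   list of N-vectors.
#' @return Unit N-vector c0.
#' @export
estimate_global <- function(contexts) {
  if (is.list(contexts)) contexts <- do.call(rbind, contexts)
  contexts <- as.matrix(contexts)
  if (nrow(contexts) < 2) stop("estimate_global: need at least 2 contexts")
  if (all(contexts == 0)) stop("estimate_global: all contexts are zero")
  sv <- svd(contexts, nu = 0, nv = 1)
  fix_sign(as.numeric(sv$v[, 1]))
}

#' Remove the global component from a context vector
#'
#' Subtracts the projection onto c0, leaving the local gist ct, orthogonal to
#' c0 by construction.
#'
#' @param ctilde N-vector (combined context estimate).
#' @param c0 Unit N-vector from [estimate_global()].
#' @return N-vector orthogonal to c0.
#' @export
remove_global <- function(ctilde, c0) {
  if (length(ctilde) != length(c0)) stop("remove_global: shape mismatch")
  if (abs(sqrt(sum(c0^2)) - 1) > 1e-8) stop("remove_global: c0 must be unit-norm")
  ctilde - sum(ctilde * c0) * c0
}

#' Assign a gist vector to its nearest atom (topic)
#'
#' Hard assignment: argmax over atoms of cosine similarity to the gist. Ties
#' go to the lowest topic id. A zero gist (e.g. an all-out-of-vocabulary
#' window) returns the sentinel topic id `NA`.
#'
#' @param ct N-vector local gist.
#' @param dict A `datm_atoms`.
#' @return list(topic_id, cosine); `topic_id` is `NA_integer_` for zero gists.
#' @export
assign_topic <- function(ct, dict) {
  if (is.null(dict$atoms) || !nrow(dict$atoms)) stop("assign_topic: empty dictionary")
  if (sqrt(sum(ct^2)) == 0) {
    return(list(topic_id = NA_integer_, cosine = NA_real_))
  }
  sims <- as.numeric(dict$atoms %*% ct) / sqrt(sum(ct^2)) # atoms are unit-norm
  best <- which.max(sims) # which.max takes the first (lowest id) on ties
  list(topic_id = as.integer(best), cosine = sims[best])
}

# Window start positions for a token vector of length n: starts at stride
# intervals; a document shorter than the window is a single whole-document
# window; a trailing partial window is kept only if it holds >=
# ceil(window_size/2) in-vocabulary tokens (all tokens count if in_vocab is
# not supplied).
window_starts <- function(n, window_size, stride, in_vocab = NULL) {
  if (n <= window_size) return(list(starts = 1L, ends = n))
  starts <- seq.int(1L, n - window_size + 1L, by = stride)
  ends <- starts + window_size - 1L
  last_end <- ends[length(ends)]
  if (last_end < n) {
    tail_start <- starts[length(starts)] + stride
    tail_iv <- if (is.null(in_vocab)) n - tail_start + 1L
               else sum(in_vocab[tail_start:n])
    if (tail_iv >= ceiling(window_size / 2)) {
      starts <- c(starts, tail_start)
      ends <- c(ends, n)
    }
  }
  list(starts = starts, ends = ends)
}

#' Topic sequence, distribution and binary presence for one document
#'
#' Scans the document with rolling windows (`window_size`, `stride`), maps
#' each window to its local gist (SIF sum, then c0 removal), and assigns the
#' nearest atom. The result carries the topic sequence, the distribution of
#' topics over windows (sentinel no-topic windows excluded from the
#' normalization), and the binary presence vector used for downstream
#' regression ("present in any amount").
#'
#' @param tokens Character vector of document tokens (or a single-document
#'   `datm_corpus` element).
#' @param emb A `datm_embedding`.
#' @param dict A `datm_atoms`.
#' @param cfg A [sif_config()].
#' @param c0 Unit N-vector global context from [estimate_global()].
#' @param doc_id Document id carried through to the record.
#' @return A `datm_topic_record`: list(doc_id, sequence, distribution,
#'   presence, n_windows, n_oov).
#' @export
document_topics <- function(tokens, emb, dict, cfg, c0, doc_id = "doc") {
  n <- length(tokens)
  K <- dict$K
  if (n == 0) {
    return(new_topic_record(doc_id, integer(0), K, 0L))
  }
  iv <- !is.na(emb$vocab$index[tokens])
  ws <- window_starts(n, cfg$window_size, cfg$stride, in_vocab = iv)
  seq_ids <- integer(length(ws$starts))
  n_oov <- 0L
  for (i in seq_along(ws$starts)) {
    win <- tokens[ws$starts[i]:ws$ends[i]]
    ctil <- map_context(win, emb, cfg)
    n_oov <- n_oov + attr(ctil, "n_oov")
    if (isTRUE(attr(ctil, "empty"))) {
      seq_ids[i] <- NA_integer_
      next
    }
    ct <- remove_global(as.numeric(ctil), c0)
    seq_ids[i] <- assign_topic(ct, dict)$topic_id
  }
  new_topic_record(doc_id, seq_ids, K, n_oov)
}

new_topic_record <- function(doc_id, sequence, K, n_oov) {
  ok <- sequence[!is.na(sequence)]
  distribution <- numeric(K)
  if (length(ok)) {
    tab <- tabulate(ok, nbins = K)
    distribution <- tab / sum(tab)
  }
  presence <- as.integer(distribution > 0)
  structure(list(doc_id = doc_id, sequence = sequence,
                 distribution = distribution, presence = presence,
                 n_windows = length(sequence), n_oov = n_oov),
            class = "datm_topic_record")
}

#' @export
print.datm_topic_record <- function(x, ...) {
  cat(sprintf("<datm_topic_record> %s: %d windows, %d topics present\n",
              x$doc_id, x$n_windows, sum(x$presence)))
  invisible(x)
}

#' Topic records for every document of a corpus
#'
#' Estimates c0 once from a seeded random sample of up to `c0_sample` windows
#' across the corpus (all windows if fewer), then runs [document_topics()] on
#' every document.
#'
#' @param corpus A `datm_corpus`.
#' @param emb,dict,cfg As in [document_topics()].
#' @param c0 Optional precomputed global vector; estimated when `NULL`.
#' @param c0_sample Number of windows sampled for the c0 estimate.
#' @param seed Seed for the c0 window sample.
#' @return list with `records` (list of `datm_topic_record`), `presence`
#'   (docs x K 0/1 matrix with doc_id rownames), and `c0`.
#' @export
corpus_topics <- function(corpus, emb, dict, cfg, c0 = NULL,
                          c0_sample = 10000, seed = 1L) {
  if (is.null(c0)) {
    ctx <- all_window_contexts(corpus, emb, cfg)
    if (nrow(ctx) > c0_sample) {
      set.seed(seed)
      ctx <- ctx[sort(sample.int(nrow(ctx), c0_sample)), , drop = FALSE]
    }
    ctx <- ctx[rowSums(ctx != 0) > 0, , drop = FALSE]
    c0 <- estimate_global(ctx)
  }
  records <- lapply(seq_along(corpus$doc_id), function(i) {
    document_topics(corpus$tokens[[i]], emb, dict, cfg, c0,
                    doc_id = corpus$doc_id[i])
  })
  presence <- do.call(rbind, lapply(records, `[[`, "presence"))
  rownames(presence) <- corpus$doc_id
  colnames(presence) <- paste0("topic", seq_len(dict$K))
  list(records = records, presence = presence, c0 = c0)
}

# Combined-context vectors for every window of every document (rows).
all_window_contexts <- function(corpus, emb, cfg) {
  out <- vector("list", length(corpus$doc_id))
  for (i in seq_along(corpus$doc_id)) {
    tk <- corpus$tokens[[i]]
    if (!length(tk)) next
    ws <- window_starts(length(tk), cfg$window_size, cfg$stride)
    rows <- matrix(0, length(ws$starts), emb$dim)
    for (j in seq_along(ws$starts)) {
      rows[j, ] <- as.numeric(map_context(tk[ws$starts[j]:ws$ends[j]], emb, cfg))
    }
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

#' Write topic records as one TSV row per document
#'
#' Columns: doc_id, sequence (comma-joined topic ids, `NA` for sentinel
#' windows), then K 0/1 presence columns, ready to join with metadata.
#'
#' @param topics Result of [corpus_topics()] (or a list of records).
#' @param path Output TSV path.
#' @export
write_topic_records <- function(topics, path) {
  records <- if (!is.null(topics$records)) topics$records else topics
  K <- length(records[[1]]$presence)
  df <- data.frame(
    doc_id = vapply(records, `[[`, "", "doc_id"),
    sequence = vapply(records, function(r) paste(r$sequence, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  pres <- do.call(rbind, lapply(records, `[[`, "presence"))
  colnames(pres) <- paste0("topic", seq_len(K))
  write.table(cbind(df, pres), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
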