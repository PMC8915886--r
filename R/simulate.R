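#' Simulator configuration
#'
#' Study conditions for the synthetic corpus generator. Documents are emitted
#' from the log-linear latent-variable language model: a latent gist vector
#' makes a slow mean-reverting random walk around a document-level dominant
#' atom, and each token is drawn from the mixture
#' \deqn{\Pr[w \mid c_t] = \alpha\,p(w) + (1-\alpha)\,
#'   \exp(\langle \tilde c_t, \mathbf{w}\rangle)/Z_{\tilde c_t},\qquad
#'   \tilde c_t = \beta c_0 + (1-\beta) c_t,\; c_0 \perp c_t.}
#' The partition function Z is computed exactly over the synthetic
#' vocabulary. A planted binary semantic axis (orthogonal to the atom span)
#' polarizes word vectors by the pole of their dominant atom, and a
#' document-level group label tilts the dominant-atom choice toward its
#' pole's atoms, emulating gendered language correlated with a group
#' covariate.
#'
#' @param V Vocabulary size.
#' @param N Embedding dimension (must exceed K_true + 2 so the axis and c0
#'   fit in the orthogonal complement of the atom span).
#' @param K_true Number of planted atoms.
#' @param s_true Planted sparsity: atoms per word vector.
#' @param alpha Frequency mixture weight in \[0, 1\] (1 = pure unigram).
#' @param beta Global-context weight in \[0, 1).
#' @param drift Per-step gist drift rate (0 = gist pinned to the dominant
#'   atom).
#' @param docs,doc_len Corpus shape (documents, tokens per document).
#' @param axis_gap Magnitude of the polar offset added to word vectors along
#'   the planted axis.
#' @param axis_tilt Axis component mixed into each document's gist, signed by
#'   the dominant atom's pole. This is what couples the axis to the token
#'   stream: with a positive tilt, pole-matching words (anchors included)
#'   are emitted more often in documents about pole-matching topics, the
#'   generative analog of gendered language co-occurring with gendered
#'   topics. Zero decouples the axis from emission entirely.
#' @param group_effect Log-scale tilt of the dominant-atom choice toward
#'   pole-matching atoms for each group (0 = no association).
#' @param noise_sd SD of the Gaussian noise added to word vectors before
#'   normalization.
#' @param word_scale Norm given to word vectors; controls how concentrated
#'   the emission softmax is (larger = cleaner topical separation).
#' @param zipf_exponent Exponent of the Zipfian unigram law p(rank) ~
#'   rank^-exponent.
#' @param n_anchor_pairs Number of planted anchor word pairs spanning the
#'   axis.
#' @param seed Integer seed; all outputs are reproducible from (config, seed).
#' @return A `datm_sim_config` list.
#' @export
sim_config <- function(V = 2000, N = 50, K_true = 20, s_true = 1,
                       alpha = 0.1, beta = 0.2, drift = 0.05,
                       docs = 2000, doc_len = 100,
                       axis_gap = 1.5, axis_tilt = 0.5, group_effect = 2,
                       noise_sd = 0.05, word_scale = 5,
                       zipf_exponent = 1.0, n_anchor_pairs = 8,
                       seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("sim_config: alpha must be in [0, 1]")
  if (beta < 0 || beta >= 1) stop("sim_config: beta must be in [0, 1)")
  if (drift < 0) stop("sim_config: drift must be >= 0")
  if (min(V, N, K_true, s_true, docs, doc_len) < 1) {
    stop("sim_config: sizes must be positive")
  }
  if (K_true >= V) stop("sim_config: need K_true < V")
  structure(list(V = V, N = N, K_true = K_true, s_true = s_true,
                 alpha = alpha, beta = beta, drift = drift, docs = docs,
                 doc_len = doc_len, axis_gap = axis_gap,
                 axis_tilt = axis_tilt,
                 group_effect = group_effect, noise_sd = noise_sd,
                 word_scale = word_scale, zipf_exponent = zipf_exponent,
                 n_anchor_pairs = n_anchor_pairs, seed = as.integer(seed)),
            class = "datm_sim_config")
}

#' Plant the synthetic semantic space
#'
#' Draws K_true orthonormal atoms, a planted axis and a global vector c0 in
#' the orthogonal complement of the atom span, Zipfian unigram probabilities,
#' and word vectors that are sparse nonnegative combinations of at most
#' s_true atoms plus Gaussian noise, scaled to `word_scale` and offset along
#' the axis by their dominant atom's pole. A block of mid-frequency words is
#' replaced by anchor words aligned with the axis poles, paired for
#' [build_dimension()].
#'
#' @param cfg A [sim_config()].
#' @return list: `atoms` (K x N orthonormal rows), `atom_pole` (+/-1 per
#'   atom), `vectors` (V x N, terms as rownames), `terms`, `p`, `codes`
#'   (V x K), `dominant_atom` (V-vector), `axis`, `c0`, `anchor_pairs`
#'   (character matrix), `cfg`.
#' @export
plant_space <- function(cfg) {
  V <- cfg$V; N <- cfg$N; K <- cfg$K_true
  if (N < K + 2) stop("plant_space: need N >= K_true + 2 (axis and c0 live in the complement)")
  if (cfg$s_true > K) stop("plant_space: s_true cannot exceed K_true")
  set.seed(cfg$seed)
  # orthonormal atom rows
  Q <- qr.Q(qr(matrix(rnorm(N * K), N, K)))
  atoms <- t(Q)
  atom_pole <- rep_len(c(-1L, 1L), K)
  proj_out <- function(x, basis) { # remove components along unit rows of basis
    x - as.numeric(crossprod(basis, basis %*% x))
  }
  axis <- unit_norm(proj_out(rnorm(N), atoms))
  c0 <- unit_norm(proj_out(proj_out(rnorm(N), atoms) , rbind(axis)))
  # Zipfian unigram law over ranks 1..V
  p <- (seq_len(V))^(-cfg$zipf_exponent)
  p <- p / sum(p)
  terms <- sprintf("w%04d", seq_len(V))
  # sparse nonnegative codes over atoms
  codes <- matrix(0, V, K)
  dominant <- integer(V)
  for (i in seq_len(V)) {
    supp <- sample.int(K, cfg$s_true)
    cf <- runif(cfg$s_true, 0.5, 1.5) * sample(c(-1, 1), cfg$s_true,
                                               replace = TRUE)
    codes[i, supp] <- cf
    dominant[i] <- supp[which.max(abs(cf))]
  }
  base <- codes %*% atoms
  if (cfg$noise_sd > 0) {
    base <- base + matrix(rnorm(V * N, sd = cfg$noise_sd), V, N)
  }
  W <- cfg$word_scale * unit_rows(base)
  if (cfg$axis_gap != 0) {
    W <- W + (cfg$axis_gap * atom_pole[dominant]) %o% axis
  }
  # anchor words: mid-frequency block, vectors aligned with the axis poles
  anchor_pairs <- NULL
  if (cfg$n_anchor_pairs > 0) {
    n_anchor <- 2L * cfg$n_anchor_pairs
    start <- min(max(1L, round(0.1 * V)), V - n_anchor + 1L)
    ai <- seq.int(start, length.out = n_anchor)
    pole_vec <- rep(c(-1, 1), cfg$n_anchor_pairs)
    for (j in seq_along(ai)) {
      dir <- pole_vec[j] * axis + rnorm(N, sd = cfg$noise_sd)
      W[ai[j], ] <- cfg$word_scale * unit_norm(dir)
      codes[ai[j], ] <- 0
      dominant[ai[j]] <- NA_integer_
    }
    anchor_pairs <- cbind(pole_a = terms[ai[pole_vec == -1]],
                          pole_b = terms[ai[pole_vec == 1]])
  }
  rownames(W) <- terms
  list(atoms = atoms, atom_pole = atom_pole, vectors = W, terms = terms,
       p = p, codes = codes, dominant_atom = dominant, axis = axis, c0 = c0,
       anchor_pairs = anchor_pairs, cfg = cfg)
}

#' Generate a synthetic corpus from a planted space
#'
#' Per document: a group label ("a" or "b") is drawn, the dominant atom is
#' sampled with probability tilted by `group_effect` toward atoms of the
#' group's pole (group "b" leans to pole +1), the gist walks around the
#' dominant atom, and tokens are emitted from the frequency/log-linear
#' mixture with the partition function computed exactly over the vocabulary.
#' The true (token-level) topic — the atom closest to the latent gist at each
#' position — is recorded for recovery scoring.
#'
#' @param cfg The [sim_config()] used for [plant_space()].
#' @param space Result of [plant_space()].
#' @return list: `corpus` (a `datm_corpus` whose metadata has doc_id, group,
#'   true_dominant_topic, word_count), `true_topics` (list of per-token true
#'   topic ids), `space`, `cfg`.
#' @export
generate_corpus <- function(cfg, space) {
  V <- cfg$V; N <- cfg$N; K <- cfg$K_true
  L <- cfg$doc_len; D <- cfg$docs
  set.seed(cfg$seed + 1L)
  Wt <- t(space$vectors) # N x V
  group <- sample(rep(c("a", "b"), length.out = D))
  g_sign <- ifelse(group == "b", 1, -1)
  tokens <- vector("list", D)
  true_topics <- vector("list", D)
  dom_atom <- integer(D)
  for (d in seq_len(D)) {
    wts <- exp(cfg$group_effect * space$atom_pole * g_sign[d])
    a_id <- sample.int(K, 1, prob = wts / sum(wts))
    dom_atom[d] <- a_id
    a_dom <- space$atoms[a_id, ]
    # gist walk: mean reversion to the dominant atom inside the atom span
    C <- matrix(0, N, L)
    ct <- a_dom
    for (t in seq_len(L)) {
      if (t > 1 && cfg$drift > 0) {
        eta <- rnorm(N, sd = 0.5)
        eta <- as.numeric(crossprod(space$atoms, space$atoms %*% eta))
        ct <- unit_norm((1 - cfg$drift) * ct + cfg$drift * (a_dom + eta))
      }
      C[, t] <- ct
    }
    # gendered-language coupling: the emitted gist carries an axis component
    # signed by the dominant atom's pole (truth labels stay on the span walk)
    Cem <- C
    if (cfg$axis_tilt != 0) {
      pole <- space$atom_pole[a_id]
      Cem <- C + (cfg$axis_tilt * pole) * space$axis
      Cem <- Cem / rep(sqrt(colSums(Cem^2)), each = N)
    }
    Ctil <- cfg$beta * space$c0 + (1 - cfg$beta) * Cem
    logits <- crossprod(Wt, Ctil)            # V x L
    E <- exp(logits)
    Pctx <- E / rep(colSums(E), each = V)    # exact Z per column
    P <- cfg$alpha * space$p + (1 - cfg$alpha) * Pctx
    CP <- apply(P, 2, cumsum)
    u <- runif(L)
    tok <- colSums(CP < rep(u, each = V)) + 1L
    tok[tok > V] <- V
    tokens[[d]] <- space$terms[tok]
    sims <- crossprod(t(space$atoms), C)     # K x L
    true_topics[[d]] <- apply(sims, 2, which.max)
  }
  doc_id <- sprintf("doc%05d", seq_len(D))
  metadata <- data.frame(doc_id = doc_id, group = group,
                         true_dominant_topic = dom_atom,
                         word_count = lengths(tokens),
                         stringsAsFactors = FALSE)
  list(corpus = new_corpus(doc_id, tokens, metadata),
       true_topics = true_topics, space = space, cfg = cfg)
}

#' True topic per rolling window of a simulated corpus
#'
#' Majority vote (ties to the smallest id) of the token-level true topics
#' inside each window, using the same windowing rule as [document_topics()].
#'
#' @param sim Result of [generate_corpus()].
#' @param cfg A [sif_config()] supplying window_size and stride.
#' @return list of integer vectors, one per document.
#' @export
true_window_topics <- function(sim, cfg) {
  lapply(sim$true_topics, function(z) {
    ws <- window_starts(length(z), cfg$window_size, cfg$stride)
    vapply(seq_along(ws$starts), function(i) {
      tab <- tabulate(z[ws$starts[i]:ws$ends[i]], nbins = max(z))
      which.max(tab)
    }, 0L)
  })
}

#' Match a fitted dictionary to planted atoms and score recovery
#'
#' Hungarian (optimal one-to-one) matching on |cosine| between fitted and
#' planted atom vectors, which both must live in the same space. Reports the
#' matching, per-atom matched |cosine|, and the mean. If window-level
#' assignments and truths are supplied, also reports the fraction of windows
#' whose assigned fitted atom corresponds to the planted one under the
#' matching.
#'
#' @param fitted A `datm_atoms` or a K_f x N matrix of fitted atoms.
#' @param true_atoms K_t x N matrix of planted atoms (K_f >= K_t
#'   recommended).
#' @param assigned,truth Optional integer vectors of window-level fitted /
#'   true topic ids (same length; NA assignments count as errors).
#' @return list: `matching` (fitted atom id per planted atom), `per_atom`
#'   (matched |cosine|s), `mean_abs_cosine`, and `window_accuracy` (NA when
#'   assignments are not supplied).
#' @export
evaluate_recovery <- function(fitted, true_atoms, assigned = NULL,
                              truth = NULL) {
  Fm <- if (inherits(fitted, "datm_atoms")) fitted$atoms else as.matrix(fitted)
  Tm <- as.matrix(true_atoms)
  if (!nrow(Fm) || !nrow(Tm)) stop("evaluate_recovery: empty inputs")
  S <- abs(unit_rows(Tm) %*% t(unit_rows(Fm))) # K_t x K_f
  if (nrow(S) > ncol(S)) {
    stop("evaluate_recovery: need at least as many fitted atoms as planted")
  }
  sol <- solve_assignment(1 - S)
  matching <- sol$assignment
  per_atom <- S[cbind(seq_len(nrow(S)), matching)]
  acc <- NA_real_
  if (!is.null(assigned) && !is.null(truth)) {
    if (length(assigned) != length(truth)) {
      stop("evaluate_recovery: assigned/truth length mismatch")
    }
    acc <- mean(assigned == matching[truth], na.rm = FALSE)
  }
  list(matching = matching, per_atom = per_atom,
       mean_abs_cosine = mean(per_atom), window_accuracy = acc)
}

#' Window accuracy under the best label matching
#'
#' For pipelines where fitted atoms live in a different (trained) space than
#' the planted atoms, cosine matching is unavailable; instead the fitted and
#' true window labels are matched one-to-one by maximizing agreement
#' (Hungarian on the contingency table) and accuracy is reported under that
#' matching. NA assignments (no-topic windows) count as errors.
#'
#' @param assigned Integer vector of fitted topic ids per window (NAs
#'   allowed).
#' @param truth Integer vector of true topic ids, same length.
#' @param K_fitted,K_true Label space sizes (defaults: observed maxima).
#' @return list(accuracy, matching): `matching[k]` is the fitted label paired
#'   with true label k.
#' @export
window_accuracy <- function(assigned, truth,
                            K_fitted = max(assigned, na.rm = TRUE),
                            K_true = max(truth)) {
  if (length(assigned) != length(truth)) stop("window_accuracy: length mismatch")
  ok <- !is.na(assigned)
  tab <- matrix(0, K_true, K_fitted)
  if (any(ok)) {
    tt <- table(factor(truth[ok], levels = seq_len(K_true)),
                factor(assigned[ok], levels = seq_len(K_fitted)))
    tab <- as.matrix(tt)
  }
  if (nrow(tab) > ncol(tab)) {
    stop("window_accuracy: need K_fitted >= K_true")
  }
  sol <- solve_assignment(max(tab) - tab)
  matching <- sol$assignment
  acc <- sum(tab[cbind(seq_len(K_true), matching)]) / length(truth)
  list(accuracy = acc, matching = matching)
}
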