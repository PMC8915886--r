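# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use different numerical routes than the implementation.

# Small corpus written to disk; returns the text path (and metadata path).
write_tiny_corpus <- function(lines, metadata = NULL) {
  tp <- tempfile(fileext = ".txt")
  writeLines(lines, tp)
  mp <- NULL
  if (!is.null(metadata)) {
    mp <- tempfile(fileext = ".tsv")
    write.table(metadata, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(text = tp, metadata = mp)
}

rand_unit_rows <- function(K, N) {
  A <- matrix(rnorm(K * N), K, N)
  A / sqrt(rowSums(A^2))
}

# Exhaustive-support sparse-coding oracle: enumerate all supports, least
# squares by QR on the transposed subdictionary (a different formulation than
# the implementation's normal equations).
oracle_best_rss <- function(x, atoms, s) {
  K <- nrow(atoms)
  best <- sum(x^2)
  for (supp in combn(K, s, simplify = FALSE)) {
    fit <- lm.fit(t(atoms[supp, , drop = FALSE]), x)
    rss <- sum(fit$residuals^2)
    if (rss < best) best <- rss
  }
  best
}

# Brute-force assignment oracle: all permutations (square cost, n <= 7).
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    if (length(unique(p)) == n) {
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    }
  }
  best
}

# Embedding over a planted space, with the planted unigram law as vocabulary.
planted_embedding <- function(space) {
  vocab <- new_vocabulary(space$terms, round(space$p * 1e7) + 1)
  new_embedding(space$vectors, vocab)
}
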