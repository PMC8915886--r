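test_that("plant_space produces near-orthogonal atoms and is reproducible", {
  cfg <- sim_config(V = 200, N = 40, K_true = 10, seed = 71)
  sp1 <- plant_space(cfg)
  sp2 <- plant_space(cfg)
  expect_identical(sp1$vectors, sp2$vectors)
  expect_identical(sp1$dominant_atom, sp2$dominant_atom)
  S <- sp1$atoms %*% t(sp1$atoms)
  expect_true(all(abs(S[upper.tri(S)]) <= 0.2))
  expect_equal(unname(sqrt(rowSums(sp1$atoms^2))), rep(1, 10),
               tolerance = 1e-10)
  # axis and c0 sit in the orthogonal complement of the atom span
  expect_lt(max(abs(sp1$atoms %*% sp1$axis)), 1e-10)
  expect_lt(max(abs(sp1$atoms %*% sp1$c0)), 1e-10)
  expect_lt(abs(sum(sp1$axis * sp1$c0)), 1e-10)
})

test_that("s_true = 1 with zero noise plants pure +/- atom directions", {
  cfg <- sim_config(V = 100, N = 20, K_true = 6, s_true = 1, noise_sd = 0,
                    axis_gap = 0, word_scale = 1, n_anchor_pairs = 0,
                    seed = 72)
  sp <- plant_space(cfg)
  for (i in 1:100) {
    k <- sp$dominant_atom[i]
    expect_equal(abs(cosine(sp$vectors[i, ], sp$atoms[k, ])), 1,
                 tolerance = 1e-10)
  }
})

test_that("plant_space rejects infeasible sizes", {
  expect_error(plant_space(sim_config(V = 50, N = 10, K_true = 9)),
               "N >= K_true")
  expect_error(sim_config(V = 10, K_true = 10), "K_true < V")
  expect_error(sim_config(alpha = 1.5), "alpha")
  expect_error(sim_config(beta = 1), "beta")
})

test_that("alpha = 1 reduces emission to the unigram law", {
  cfg <- sim_config(V = 200, N = 30, K_true = 10, alpha = 1, docs = 20,
                    doc_len = 5000, n_anchor_pairs = 0, seed = 9)
  sp <- plant_space(cfg)
  sim <- generate_corpus(cfg, sp)
  obs <- table(factor(unlist(sim$corpus$tokens), levels = sp$terms))
  n <- sum(obs)
  chi <- sum((as.numeric(obs) - n * sp$p)^2 / (n * sp$p))
  pval <- pchisq(chi, df = length(sp$p) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("pinned gist and high separation emit on-topic tokens", {
  cfg <- sim_config(V = 400, N = 30, K_true = 8, s_true = 1, alpha = 0,
                    drift = 0, beta = 0, axis_tilt = 0, axis_gap = 0,
                    noise_sd = 0, word_scale = 12, docs = 40, doc_len = 100,
                    n_anchor_pairs = 0, seed = 4)
  sp <- plant_space(cfg)
  sim <- generate_corpus(cfg, sp)
  frac <- mean(unlist(lapply(seq_len(40), function(d) {
    ix <- match(sim$corpus$tokens[[d]], sp$terms)
    am <- apply(sp$vectors[ix, , drop = FALSE] %*% t(sp$atoms), 1, which.max)
    am == sim$corpus$metadata$true_dominant_topic[d]
  })))
  expect_gte(frac, 0.98)
  # drift = 0: the latent truth never leaves the dominant atom
  expect_true(all(vapply(seq_len(40), function(d) {
    all(sim$true_topics[[d]] == sim$corpus$metadata$true_dominant_topic[d])
  }, TRUE)))
})

test_that("group labels associate positively with pole +1 topics", {
  cfg <- sim_config(V = 300, N = 30, K_true = 10, docs = 400, doc_len = 20,
                    group_effect = 2, n_anchor_pairs = 0, seed = 73)
  sp <- plant_space(cfg)
  sim <- generate_corpus(cfg, sp)
  md <- sim$corpus$metadata
  pole_of_doc <- sp$atom_pole[md$true_dominant_topic]
  tab <- table(md$group, factor(pole_of_doc, levels = c(-1, 1)))
  # group b should over-select pole +1 dominant atoms
  expect_gt(tab["b", "1"] / sum(tab["b", ]), tab["a", "1"] / sum(tab["a", ]))
})

test_that("generated corpora are reproducible bit for bit", {
  cfg <- sim_config(V = 150, N = 25, K_true = 6, docs = 30, doc_len = 40,
                    seed = 74)
  sp <- plant_space(cfg)
  s1 <- generate_corpus(cfg, sp)
  s2 <- generate_corpus(cfg, sp)
  expect_identical(s1$corpus$tokens, s2$corpus$tokens)
  expect_identical(s1$true_topics, s2$true_topics)
  expect_identical(s1$corpus$metadata, s2$corpus$metadata)
})

test_that("evaluate_recovery scores identity, baseline, and oracle matching", {
  cfg <- sim_config(V = 200, N = 100, K_true = 20, n_anchor_pairs = 0,
                    seed = 75)
  sp <- plant_space(cfg)
  rec <- evaluate_recovery(sp$atoms, sp$atoms)
  expect_equal(rec$mean_abs_cosine, 1, tolerance = 1e-10)
  expect_equal(rec$matching, 1:20)
  # random orthonormal baseline stays low at N = 100 (fresh draw, distinct
  # from the planted atoms' own seed)
  set.seed(7005)
  Rnd <- t(qr.Q(qr(matrix(rnorm(100 * 20), 100, 20))))
  expect_lte(evaluate_recovery(Rnd, sp$atoms)$mean_abs_cosine, 0.3)
  # matching equals brute-force enumeration for small K
  set.seed(76)
  for (r in 1:10) {
    Tm <- rand_unit_rows(4, 8)
    Fm <- rand_unit_rows(4, 8)
    S <- abs(Tm %*% t(Fm))
    got <- evaluate_recovery(Fm, Tm)
    expect_equal(sum(1 - S[cbind(1:4, got$matching)]),
                 oracle_assignment_cost(1 - S), tolerance = 1e-10)
  }
  expect_error(evaluate_recovery(matrix(0, 0, 3), sp$atoms), "empty")
})

test_that("window_accuracy is matching-invariant and counts NA as error", {
  truth <- rep(1:3, each = 10)
  expect_equal(window_accuracy(truth, truth, K_fitted = 3)$accuracy, 1)
  relab <- c(2L, 3L, 1L)[truth]
  expect_equal(window_accuracy(relab, truth, K_fitted = 3)$accuracy, 1)
  with_na <- truth
  with_na[1:3] <- NA
  expect_equal(window_accuracy(with_na, truth, K_fitted = 3)$accuracy,
               27 / 30)
})

test_that("simulator artifacts round-trip through the corpus reader", {
  cfg <- sim_config(V = 150, N = 25, K_true = 6, docs = 25, doc_len = 30,
                    seed = 77)
  sp <- plant_space(cfg)
  sim <- generate_corpus(cfg, sp)
  tp <- tempfile(fileext = ".txt"); mp <- tempfile(fileext = ".tsv")
  write_corpus(sim$corpus, tp, mp)
  back <- load_corpus(tp, mp)
  expect_identical(back$tokens, sim$corpus$tokens)
  expect_identical(back$metadata$group, sim$corpus$metadata$group)
  expect_identical(back$metadata$true_dominant_topic,
                   sim$corpus$metadata$true_dominant_topic)
})
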