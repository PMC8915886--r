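test_that("omp_code handles exact atoms, full support, and bad s", {
  set.seed(31)
  A <- rand_unit_rows(6, 8)
  # x equal to an atom: indicator code, zero residual, for any s
  for (s in 1:3) {
    code <- omp_code(A[3, ], A, s)
    expect_equal(code[3], 1, tolerance = 1e-10)
    expect_equal(sum(code != 0), 1)
  }
  # s = K with a full-rank square dictionary: exact reconstruction
  B <- rand_unit_rows(8, 8)
  x <- rnorm(8)
  code <- omp_code(x, B, 8)
  expect_lt(sqrt(sum((x - as.numeric(crossprod(B, code)))^2)), 1e-8)
  # x inside the atom span: exact at s = K even when K < N
  xs <- as.numeric(crossprod(A, rnorm(6)))
  code_s <- omp_code(xs, A, 6)
  expect_lt(sqrt(sum((xs - as.numeric(crossprod(A, code_s)))^2)), 1e-8)
  expect_error(omp_code(x, A, 0), "s out of range")
  expect_error(omp_code(rnorm(8), A, 9), "s out of range")
})

test_that("omp_code attains the exhaustive-support optimum on small dictionaries", {
  set.seed(32)
  for (r in 1:60) {
    K <- sample(3:8, 1)
    N <- sample(c(3, 4, 6, 10), 1)
    s <- min(sample(1:3, 1), K - 1, N)
    A <- rand_unit_rows(K, N)
    x <- rnorm(N)
    code <- omp_code(x, A, s)
    expect_lte(sum(code != 0), s)
    rss <- sum((x - as.numeric(crossprod(A, code)))^2)
    expect_lte(rss, oracle_best_rss(x, A, s) + 1e-9)
  }
})

test_that("ksvd_fit recovers a planted dictionary and keeps its invariants", {
  scfg <- sim_config(V = 300, N = 30, K_true = 10, s_true = 2, noise_sd = 0,
                     axis_gap = 0, axis_tilt = 0, word_scale = 1,
                     n_anchor_pairs = 0, seed = 7)
  sp <- plant_space(scfg)
  X <- sp$vectors / sqrt(rowSums(sp$vectors^2))
  fit <- ksvd_fit(X, K = 10, s = 2, iters = 20, seed = 2)
  expect_equal(unname(sqrt(rowSums(fit$atoms^2))), rep(1, 10),
               tolerance = 1e-8)
  expect_true(all(rowSums(fit$codes != 0) <= 2))
  rec <- evaluate_recovery(fit, sp$atoms)
  expect_gte(rec$mean_abs_cosine, 0.95)
  # the dictionary-update stage (supports fixed) never worsens the objective
  expect_true(all(fit$objective <= fit$objective_coding + 1e-8))
  # sign convention: each atom's largest-|coefficient| word loads positively
  for (k in 1:10) {
    i <- which.max(abs(fit$codes[, k]))
    expect_gte(fit$codes[i, k], 0)
  }
})

test_that("a rank-deficient input gives the leading singular direction", {
  # rank-1 X: with s = 1, the dominant atom must match the leading right
  # singular vector computed independently
  set.seed(33)
  v1 <- rnorm(12); v1 <- v1 / sqrt(sum(v1^2))
  cf <- runif(80, 0.5, 1.5) * sample(c(-1, 1), 80, replace = TRUE)
  X <- cf %o% v1
  fit <- ksvd_fit(X, K = 2, s = 1, iters = 5, seed = 1)
  sv <- svd(X, nu = 0, nv = 1)
  usage <- colSums(fit$codes != 0)
  main <- which.max(usage)
  expect_gte(abs(cosine(fit$atoms[main, ], sv$v[, 1])), 1 - 1e-8)
})

test_that("ksvd_fit validates its preconditions", {
  X <- rand_unit_rows(10, 5)
  expect_error(ksvd_fit(X, K = 10, s = 2), "K < V")
  expect_error(ksvd_fit(X, K = 3, s = 2, iters = 0), "iters")
  expect_error(ksvd_fit(X, K = 1, s = 1), "K >= 2")
})

test_that("reconstruction_r2 matches closed forms and is monotone in s", {
  set.seed(34)
  A <- rand_unit_rows(6, 10)
  X <- matrix(rnorm(50 * 10), 50, 10)
  codes_perfect <- X %*% t(A) %*% solve(A %*% t(A))
  # perfect reconstruction only if X lies in the atom span; build it so
  Xs <- codes_perfect %*% A
  d <- new_atom_dictionary(A, Xs %*% t(A) %*% solve(A %*% t(A)), s = 6)
  expect_equal(reconstruction_r2(Xs, d), 1, tolerance = 1e-10)
  d0 <- new_atom_dictionary(A, matrix(0, 50, 6), s = 6)
  expect_equal(reconstruction_r2(Xs, d0), 0)
  expect_error(reconstruction_r2(matrix(0, 50, 10), d0), "zero norm")
  # monotone in s for fixed atoms (feasible sets nest)
  Xu <- X / sqrt(rowSums(X^2))
  r2s <- vapply(1:4, function(s) {
    codes <- t(apply(Xu, 1, omp_code, atoms = A, s = s, refine = "none"))
    reconstruction_r2(Xu, new_atom_dictionary(A, codes, s))
  }, 0)
  expect_true(all(diff(r2s) >= -1e-10))
})

test_that("score_model hits its extreme values on constructed dictionaries", {
  # vocabulary of two blocks of identical vectors -> coherence 1
  W <- rbind(matrix(rep(c(1, 0, 0), 5), 5, 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 5), 5, 3, byrow = TRUE))
  rownames(W) <- sprintf("w%02d", 1:10)
  emb <- new_embedding(W)
  atoms <- rbind(c(1, 0, 0), c(0, 1, 0))
  codes <- cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  d <- new_atom_dictionary(atoms, codes, s = 1)
  sc <- score_model(d, emb, top_n = 5)
  expect_equal(sc$coherence, 1, tolerance = 1e-10)
  expect_equal(sc$distinctness, 1, tolerance = 1e-10) # orthonormal atoms
  expect_error(score_model(d, emb, top_n = 1), "top_n")
  expect_error(score_model(d, emb, top_n = 11), "top_n")

  # duplicate atoms are strictly less distinct than orthogonal ones
  dup <- new_atom_dictionary(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             NULL, s = 1)
  orth <- new_atom_dictionary(rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
                              NULL, s = 1)
  dist_of <- function(dd) {
    S <- dd$atoms %*% t(dd$atoms)
    1 - mean(abs(S[upper.tri(S)]))
  }
  expect_lt(dist_of(dup), dist_of(orth))
})

test_that("select_k degenerate grids follow the documented rules", {
  set.seed(35)
  scfg <- sim_config(V = 150, N = 20, K_true = 5, s_true = 2, noise_sd = 0,
                     axis_gap = 0, axis_tilt = 0, word_scale = 1,
                     n_anchor_pairs = 0, seed = 5)
  sp <- plant_space(scfg)
  emb <- planted_embedding(sp)
  X <- sp$vectors / sqrt(rowSums(sp$vectors^2))
  sel <- select_k(X, emb, k_grid = 5, s = 2, iters = 5, seed = 1)
  expect_equal(sel$chosen_k, 5)
  # identical scores across the grid -> smallest K (parsimony tie-break)
  sel2 <- select_k(X, emb, k_grid = c(4, 4), s = 2, iters = 5, seed = 1)
  expect_equal(sel2$chosen_k, 4)
  expect_equal(sel2$scores$combined[1], sel2$scores$combined[2])
  expect_error(select_k(X, emb, k_grid = integer(0)), "empty")
  expect_error(select_k(X, emb, k_grid = 150), "< V")
})

test_that("dictionary serialization round-trips atoms and codes", {
  set.seed(36)
  A <- rand_unit_rows(4, 6)
  codes <- matrix(0, 9, 4)
  codes[cbind(1:9, sample(1:4, 9, replace = TRUE))] <- rnorm(9)
  d <- new_atom_dictionary(A, codes, s = 1)
  fa <- tempfile(fileext = ".vec"); fc <- tempfile(fileext = ".tsv")
  write_dictionary(d, fa, fc)
  d2 <- read_dictionary(fa, fc, s = 1, V = 9)
  expect_equal(d2$atoms, A, tolerance = 1e-12)
  expect_equal(d2$codes, codes, tolerance = 1e-12)
})
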