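#' Sparse-code one vector against an atom dictionary
#'
#' Finds an s-sparse least-squares code of `x` over the dictionary rows. For
#' large dictionaries this is orthogonal matching pursuit: greedily select
#' the atom most correlated with the current residual, refit all selected
#' coefficients by least squares, stop after `s` atoms or when the residual
#' is numerically zero; with `refine = "swap"` the greedy support is then
#' polished by single-atom exchanges that strictly reduce the residual.
#' Greedy pursuit, however refined, can return a suboptimal support on small
#' coherent dictionaries, so whenever the support space is tiny
#' (`choose(K, s) <= exact_limit`, e.g. K <= 8 with s <= 3) the coder instead
#' guarantees the optimum by enumerating all supports with a least-squares
#' refit on each. The returned code is therefore exactly optimal in the
#' small regime and a refined pursuit solution beyond it.
#'
#' @param x N-vector to encode.
#' @param atoms K x N dictionary matrix with unit-norm rows.
#' @param s Sparsity level, 1 <= s <= min(K, N).
#' @param refine `"swap"` (default) or `"none"` (plain greedy pursuit, no
#'   exact-small guarantee; used internally by [ksvd_fit()] where speed
#'   matters).
#' @param tol Residual norm below which pursuit stops early.
#' @param exact_limit Largest `choose(K, s)` for which the optimal support is
#'   found by enumeration (only when `refine != "none"`).
#' @return A dense numeric K-vector with at most `s` nonzeros.
#' @export
omp_code <- function(x, atoms, s, refine = c("swap", "none"), tol = 1e-10,
                     exact_limit = 120) {
  refine <- match.arg(refine)
  K <- nrow(atoms); N <- ncol(atoms)
  if (s < 1 || s > min(K, N)) stop("omp_code: s out of range [1, min(K, N)]")
  if (length(x) != N) stop("omp_code: dimension mismatch")
  supp <- integer(0)
  cf <- numeric(0)
  r <- x
  for (step in seq_len(s)) {
    if (sqrt(sum(r^2)) <= tol) break
    corr <- abs(as.numeric(atoms %*% r))
    if (length(supp)) corr[supp] <- -Inf
    j <- which.max(corr)
    supp <- c(supp, j)
    fit <- ls_on_support(x, atoms, supp)
    cf <- fit$coef
    r <- fit$resid
  }
  if (refine != "none" && length(supp) > 0 && sum(r^2) > tol^2) {
    if (choose(K, s) <= exact_limit) {
      best_rss <- sum(r^2)
      for (cand in combn(K, s, simplify = FALSE)) {
        fit <- ls_on_support(x, atoms, cand)
        rss <- sum(fit$resid^2)
        if (rss < best_rss - 1e-12) {
          best_rss <- rss
          supp <- cand
          cf <- fit$coef
        }
      }
    } else {
      res <- swap_refine(x, atoms, supp, tol)
      supp <- res$supp
      cf <- res$coef
    }
  }
  code <- numeric(K)
  code[supp] <- cf
  code
}

# Least squares of x on the rows of atoms indexed by supp.
ls_on_support <- function(x, atoms, supp) {
  A <- atoms[supp, , drop = FALSE] # s x N
  G <- tcrossprod(A)
  b <- as.numeric(A %*% x)
  cf <- tryCatch(solve(G, b), error = function(e) {
    # rank-deficient support (e.g. duplicated atoms): minimum-norm fallback
    as.numeric(qr.coef(qr(t(A), LAPACK = TRUE), x))
  })
  cf[is.na(cf)] <- 0
  list(coef = as.numeric(cf), resid = x - as.numeric(crossprod(A, cf)))
}

# Single-atom swap local search on the support; accepts strict improvements.
swap_refine <- function(x, atoms, supp, tol, max_sweeps = 20) {
  K <- nrow(atoms)
  best <- ls_on_support(x, atoms, supp)
  best_rss <- sum(best$resid^2)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (pos in seq_along(supp)) {
      for (j in setdiff(seq_len(K), supp)) {
        cand <- supp
        cand[pos] <- j
        fit <- ls_on_support(x, atoms, cand)
        rss <- sum(fit$resid^2)
        if (rss < best_rss - 1e-12) {
          supp <- cand
          best <- fit
          best_rss <- rss
          improved <- TRUE
        }
      }
    }
    if (!improved || best_rss <= tol^2) break
  }
  list(supp = supp, coef = best$coef)
}

#' Fit a discourse-atom dictionary by K-SVD
#'
#' Alternates (i) OMP sparse coding of every word vector against the current
#' dictionary and (ii) per-atom rank-1 SVD updates computed on the restricted
#' residual of the words currently using that atom. Atoms that no word uses
#' are re-seeded from the worst-reconstructed word vector. On return each atom
#' is flipped, if needed, so its largest-|coefficient| word loads positively,
#' which makes top-word lists stable across runs.
#'
#' Input rows are conventionally unit-normalized word vectors (dictionary
#' learning on the unit sphere); the function does not renormalize its input.
#'
#' Like other alternating-minimization fits (compare k-means' `nstart`),
#' K-SVD can settle in a local minimum in which one planted direction is
#' shared between two atoms; `restarts` independent fits are run from
#' different seeded initializations and the one with the smallest final
#' residual is kept.
#'
#' @param X V x N matrix of word vectors (V > K).
#' @param K Number of atoms (>= 2).
#' @param s Sparsity: maximum atoms per word (default 5).
#' @param iters Number of alternating iterations (>= 1).
#' @param seed Integer seed for the initial atom draw.
#' @param restarts Independent seeded fits; the best final objective wins
#'   (default 3).
#' @return A `datm_atoms` object: `atoms` (K x N, unit rows), `codes` (V x K),
#'   `s`, `K`, `objective` (Frobenius residual after each iteration),
#'   `objective_coding` (residual right after each iteration's sparse-coding
#'   stage, before the dictionary update) and `reinit_count` (dead/duplicate
#'   atom re-seedings).
#' @export
ksvd_fit <- function(X, K, s = 5, iters = 30, seed = 1L, restarts = 3) {
  X <- as.matrix(X)
  if (restarts < 1) stop("ksvd_fit: restarts must be >= 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- ksvd_once(X, K, s, iters, seed + 7919L * (r - 1L))
    if (is.null(best) ||
        fit$objective[length(fit$objective)] <
          best$objective[length(best$objective)]) {
      best <- fit
    }
  }
  best
}

ksvd_once <- function(X, K, s, iters, seed) {
  V <- nrow(X); N <- ncol(X)
  if (K >= V) stop("ksvd_fit: need K < V")
  if (K < 2) stop("ksvd_fit: need K >= 2")
  if (iters < 1) stop("ksvd_fit: iters must be >= 1")
  if (s < 1 || s > min(K, N)) stop("ksvd_fit: s out of range")
  set.seed(seed)
  atoms <- unit_rows(X[sample.int(V, K), , drop = FALSE])
  codes <- matrix(0, V, K)
  objective <- numeric(iters)
  objective_coding <- numeric(iters)
  reinit <- 0L
  for (it in seq_len(iters)) {
    for (i in seq_len(V)) {
      codes[i, ] <- omp_code(X[i, ], atoms, s, refine = "none")
    }
    R <- X - codes %*% atoms
    objective_coding[it] <- sqrt(sum(R^2))
    for (k in seq_len(K)) {
      I <- which(codes[, k] != 0)
      if (!length(I)) {
        rn <- rowSums(R^2)
        w <- which.max(rn)
        atoms[k, ] <- unit_norm(X[w, ])
        reinit <- reinit + 1L
        next
      }
      # restricted residual including atom k's own contribution
      E <- R[I, , drop = FALSE] + codes[I, k] %o% atoms[k, ]
      sv <- svd(E, nu = 1, nv = 1)
      atoms[k, ] <- sv$v[, 1]
      new_coef <- sv$d[1] * sv$u[, 1]
      # keep running residual in sync with the updated atom
      R[I, ] <- E - new_coef %o% atoms[k, ]
      codes[I, k] <- new_coef
    }
    objective[it] <- sqrt(sum((X - codes %*% atoms)^2))
    # replace near-duplicate atoms (mutual coherence ~1) with the currently
    # worst-reconstructed word vector: standard K-SVD housekeeping that
    # prevents two atoms from splitting one planted direction. Done after the
    # objective is recorded, since re-seeding restarts those atoms.
    G <- tcrossprod(atoms)
    rn <- rowSums((X - codes %*% atoms)^2)
    for (k in 2:K) {
      if (any(abs(G[k, seq_len(k - 1)]) > 0.99)) {
        w <- which.max(rn)
        atoms[k, ] <- unit_norm(X[w, ])
        codes[, k] <- 0
        rn[w] <- 0
        reinit <- reinit + 1L
        G[k, ] <- atoms %*% atoms[k, ]
        G[, k] <- G[k, ]
      }
    }
  }
  for (k in seq_len(K)) {
    i <- which.max(abs(codes[, k]))
    if (length(i) && codes[i, k] < 0) {
      codes[, k] <- -codes[, k]
      atoms[k, ] <- -atoms[k, ]
    }
  }
  d <- new_atom_dictionary(atoms, codes, s, objective = objective,
                           reinit_count = reinit)
  d$objective_coding <- objective_coding
  d
}

#' Construct an atom dictionary from existing atoms and codes
#'
#' Low-level constructor validating the dictionary invariants: unit-norm atom
#' rows, at most `s` nonzeros per code row, K >= 2. Normally produced by
#' [ksvd_fit()].
#'
#' @param atoms K x N matrix, unit-norm rows.
#' @param codes V x K coefficient matrix (or NULL).
#' @param s Sparsity level the codes must respect.
#' @param objective,reinit_count Optional fit diagnostics.
#' @return A `datm_atoms`.
#' @export
new_atom_dictionary <- function(atoms, codes, s, objective = NULL,
                                reinit_count = NA_integer_) {
  atoms <- as.matrix(atoms)
  if (nrow(atoms) < 2) stop("atom dictionary: K must be >= 2")
  nrm <- sqrt(rowSums(atoms^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("atom dictionary: atoms must be unit-norm")
  if (!is.null(codes)) {
    codes <- as.matrix(codes)
    if (ncol(codes) != nrow(atoms)) stop("atom dictionary: codes/atoms mismatch")
    if (any(rowSums(codes != 0) > s)) stop("atom dictionary: sparsity violated")
  }
  structure(list(atoms = atoms, codes = codes, s = s, K = nrow(atoms),
                 objective = objective, reinit_count = reinit_count),
            class = "datm_atoms")
}

#' @export
print.datm_atoms <- function(x, ...) {
  cat(sprintf("<datm_atoms> K=%d atoms, N=%d dims, sparsity s=%d\n",
              x$K, ncol(x$atoms), x$s))
  invisible(x)
}

#' Reconstruction R-squared of a sparse coding
#'
#' \eqn{R^2 = 1 - \|X - C D\|_F^2 / \|X\|_F^2} (uncentered: word vectors have
#' no natural origin). Measures how well the atoms explain the semantic space.
#'
#' @param X The coded V x N matrix.
#' @param dict A `datm_atoms` with codes fitted to `X`.
#' @return Scalar in (-Inf, 1].
#' @export
reconstruction_r2 <- function(X, dict) {
  X <- as.matrix(X)
  ss <- sum(X^2)
  if (ss == 0) stop("reconstruction_r2: X has zero norm")
  if (nrow(X) != nrow(dict$codes) || ncol(X) != ncol(dict$atoms)) {
    stop("reconstruction_r2: shape mismatch")
  }
  1 - sum((X - dict$codes %*% dict$atoms)^2) / ss
}

#' Score a fitted dictionary for model selection
#'
#' Three complementary metrics:
#' * `coherence`: mean over atoms of the mean pairwise cosine among each
#'   atom's `top_n` nearest words (internal coherence of topics);
#' * `distinctness`: one minus the mean pairwise |cosine| among atom vectors
#'   (how far apart topics sit from one another);
#' * `r2`: [reconstruction_r2()] on unit-normalized embedding rows (how well
#'   atoms explain the semantic space).
#'
#' @param dict A `datm_atoms` fitted on the unit-normalized rows of `emb`.
#' @param emb The `datm_embedding` the dictionary was fitted to.
#' @param top_n Words per atom used for coherence (2 <= top_n <= V).
#' @return A one-row data.frame: K, coherence, distinctness, r2.
#' @export
score_model <- function(dict, emb, top_n = 10) {
  V <- nrow(emb$vectors)
  if (top_n < 2) stop("score_model: top_n must be >= 2")
  if (top_n > V) stop("score_model: top_n exceeds vocabulary size")
  Wu <- unit_rows(emb$vectors)
  coh <- vapply(seq_len(dict$K), function(k) {
    nw <- nearest_words(emb, dict$atoms[k, ], n = top_n)
    Vk <- Wu[unname(emb$vocab$index[nw$term]), , drop = FALSE]
    S <- tcrossprod(Vk)
    mean(S[upper.tri(S)])
  }, 0)
  A <- dict$atoms
  SA <- tcrossprod(A)
  distinct <- 1 - mean(abs(SA[upper.tri(SA)]))
  r2 <- reconstruction_r2(Wu, dict)
  data.frame(K = dict$K, coherence = mean(coh), distinctness = distinct,
             r2 = r2)
}

#' Fit and score dictionaries across a grid of K and pick one
#'
#' Fits [ksvd_fit()] at every K in `k_grid`, scores each with [score_model()],
#' and chooses the K maximizing the mean of min-max-normalized coherence,
#' distinctness and R-squared. Ties (including the all-equal case) go to the
#' smallest K (parsimony). The full score table is always returned so users
#' can overrule the default rule.
#'
#' @param X V x N unit-row matrix of word vectors to code.
#' @param emb The matching `datm_embedding` (for coherence).
#' @param k_grid Integer vector of candidate K values, all < V.
#' @param s,iters,seed Passed to [ksvd_fit()].
#' @param top_n Passed to [score_model()].
#' @return list with `scores` (data.frame over the grid), `chosen_k`, and
#'   `fits` (named list of `datm_atoms`).
#' @export
select_k <- function(X, emb, k_grid, s = 5, iters = 30, seed = 1L,
                     top_n = 10) {
  if (!length(k_grid)) stop("select_k: empty k_grid")
  if (any(k_grid >= nrow(X))) stop("select_k: every K must be < V")
  k_grid <- as.integer(k_grid)
  fits <- list()
  scores <- NULL
  for (K in k_grid) {
    fit <- ksvd_fit(X, K, s = s, iters = iters, seed = seed)
    fits[[as.character(K)]] <- fit
    scores <- rbind(scores, score_model(fit, emb, top_n = top_n))
  }
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  }
  combined <- (norm01(scores$coherence) + norm01(scores$distinctness) +
                 norm01(scores$r2)) / 3
  scores$combined <- combined
  best <- which(combined == max(combined))
  chosen <- min(k_grid[best])
  list(scores = scores, chosen_k = chosen, fits = fits)
}

#' Ranked top-terms table for every topic
#'
#' One row per (topic, rank): the `n` vocabulary terms closest to each atom
#' vector in descending cosine, the usual way discourse-atom topics are read
#' and labeled.
#'
#' @param dict A `datm_atoms`.
#' @param emb The matching `datm_embedding`.
#' @param n Terms per topic.
#' @return data.frame with columns topic_id, rank, term, cosine.
#' @export
topics_table <- function(dict, emb, n = 7) {
  do.call(rbind, lapply(seq_len(dict$K), function(k) {
    nw <- nearest_words(emb, dict$atoms[k, ], n = n)
    data.frame(topic_id = k, rank = seq_len(n), term = nw$term,
               cosine = nw$cosine, stringsAsFactors = FALSE)
  }))
}

#' Serialize / load an atom dictionary
#'
#' Atoms go to a word2vec-style text matrix (`K N` header, `atom<k> v1..vN`
#' lines); codes go to a sparse triplet TSV (word_index, atom_index,
#' coefficient).
#'
#' @param dict A `datm_atoms`.
#' @param atoms_path,codes_path Output paths.
#' @export
write_dictionary <- function(dict, atoms_path, codes_path) {
  con <- file(atoms_path, "w")
  writeLines(sprintf("%d %d", dict$K, ncol(dict$atoms)), con)
  writeLines(vapply(seq_len(dict$K), function(k) {
    paste0("atom", k, " ",
           paste(formatC(dict$atoms[k, ], digits = 17, format = "g"),
                 collapse = " "))
  }, ""), con)
  close(con)
  nz <- which(dict$codes != 0, arr.ind = TRUE)
  trip <- data.frame(word_index = nz[, 1], atom_index = nz[, 2],
                     coefficient = formatC(dict$codes[nz], digits = 17,
                                           format = "g"))
  trip <- trip[order(trip$word_index, trip$atom_index), ]
  write.table(trip, codes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(atoms_path)
}

#' @rdname write_dictionary
#' @param s Sparsity level recorded with the reloaded dictionary.
#' @param V Number of words (rows) for the codes matrix.
#' @export
read_dictionary <- function(atoms_path, codes_path, s, V) {
  lines <- readLines(atoms_path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  K <- hdr[1]; N <- hdr[2]
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  atoms <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(N)))
  trip <- read.delim(codes_path, stringsAsFactors = FALSE, comment.char = "#")
  codes <- matrix(0, V, K)
  codes[cbind(trip$word_index, trip$atom_index)] <- as.numeric(trip$coefficient)
  new_atom_dictionary(atoms, codes, s)
}
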