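#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for an n x m cost matrix (n <= m)
#' with the O(n^2 m) potential / shortest-augmenting-path formulation.
#' Used to match fitted atoms to planted atoms when evaluating dictionary
#' recovery; exported because optimal matching is useful on its own.
#'
#' @param cost Numeric n x m matrix, n <= m.
#' @return list with `assignment` (integer n-vector: column matched to each
#'   row) and `cost` (total cost of the optimal matching).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("solve_assignment: need nrow <= ncol (transpose first)")
  if (any(!is.finite(cost))) stop("solve_assignment: non-finite costs")
  # 1-based arrays with a dummy row/column 0 at index 1
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1) # row matched to each column (0 = unmatched)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free_j <- which(!used[-1])
      cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1] <- j0
      }
      jmin <- free_j[which.min(minv[free_j])]
      delta <- minv[jmin]
      used_cols <- which(used) - 1L # 0-based col ids incl. dummy 0
      u[p[used_cols + 1] + 1] <- u[p[used_cols + 1] + 1] + delta
      v[used_cols + 1] <- v[used_cols + 1] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- jmin
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assignment[p[j + 1]] <- j
  total <- sum(cost[cbind(seq_len(n), assignment)])
  list(assignment = assignment, cost = total)
}
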