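#' Minimum-cost assignment (Kuhn--Munkres / Hungarian algorithm)
#'
#' Solves the linear sum assignment problem: given an `n x m` cost matrix
#' with `n <= m`, find the column `j(i)` for each row `i`, all distinct,
#' minimizing `sum_i cost[i, j(i)]`. Implemented as the O(n^3) shortest
#' augmenting path formulation with dual potentials (the classical
#' Jonker--Volgenant refinement of Kuhn--Munkres); deterministic for a given
#' cost matrix.
#'
#' @param cost Numeric matrix, `nrow(cost) <= ncol(cost)`, finite entries.
#' @return Integer vector of length `nrow(cost)`: the assigned column of
#'   each row.
#' @examples
#' solve_assignment(matrix(c(4, 2, 1, 3), 2, 2))  # rows -> cols 2, 1
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (n > m) stop("solve_assignment: need nrow <= ncol (pad or transpose)",
                  call. = FALSE)
  if (!all(is.finite(cost)))
    stop("solve_assignment: cost entries must be finite", call. = FALSE)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)              # p[j + 1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])     # candidate columns (1-based)
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      used_j <- which(used) - 1L    # 0-based incl. virtual column 0
      u[p[used_j + 1L] + 1L] <- u[p[used_j + 1L] + 1L] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}
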