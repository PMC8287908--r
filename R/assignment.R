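#' Solve a linear sum assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix by the
#' Jonker-Volgenant shortest-augmenting-path algorithm (the Hungarian method's
#' modern O(n^3) form). Used internally to pair predicted and ground-truth
#' spots, and exported because point-set evaluation workflows occasionally
#' need the raw solver.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer vector `a` of length `nrow(cost)`: row `i` is assigned to
#'   column `a[i]`; the assignment minimizes `sum(cost[cbind(seq_len(n), a)])`.
#' @examples
#' cost <- matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3)
#' solve_assignment(cost)
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("'cost' must be a square matrix")
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  if (!all(is.finite(cost))) stop("'cost' must be finite")

  # Dual potentials u (rows), v (cols); p[j] = row matched to column j.
  # Column n+1 is the virtual start of each augmenting path.
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      k <- which.min(minv[free])
      j1 <- free[k]
      delta <- minv[j1]
      on <- which(used)
      u[p[on]] <- u[p[on]] + delta
      v[on] <- v[on] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  a <- integer(n)
  a[p[seq_len(n)]] <- seq_len(n)
  a
}
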