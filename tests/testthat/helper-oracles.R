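# Independent oracles used to validate the package's implementations.

# Exhaustive matching oracle: enumerates every permutation of the padded
# square cost matrix (costs above the cutoff and padding entries get a large
# constant), and returns the maximal number of feasible pairs together with
# the minimal total distance among maximal matchings.
brute_force_match <- function(pred, truth, cutoff) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(list(tp = 0L, total = 0))
  d <- sqrt(outer(pred[, 1], truth[, 1], `-`)^2 +
            outer(pred[, 2], truth[, 2], `-`)^2)
  n <- max(np, nt)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best_tp <- 0L
  best_total <- 0
  for (p in perms(seq_len(n))) {
    tp <- 0L
    total <- 0
    for (i in seq_len(np)) {
      j <- p[i]
      if (j <= nt && d[i, j] <= cutoff) {
        tp <- tp + 1L
        total <- total + d[i, j]
      }
    }
    if (tp > best_tp || (tp == best_tp && total < best_total)) {
      best_tp <- tp
      best_total <- total
    }
  }
  list(tp = best_tp, total = best_total)
}

# Step-function integration oracle for the single-pair F1 integral: with one
# truth and one prediction at distance d0, the F1 curve is the indicator
# cutoff >= d0; integrate it exactly over the trapezoid grid.
step_f1_integral <- function(d0, max_cutoff = 3, n_cutoffs = 50) {
  cutoffs <- seq(0, max_cutoff, length.out = n_cutoffs)
  f1 <- as.numeric(cutoffs >= d0)
  sum(diff(cutoffs) * (f1[-1] + f1[-n_cutoffs]) / 2) / max_cutoff
}

random_coords <- function(n, H = 64, W = 64) {
  cbind(runif(n, 0, H - 1), runif(n, 0, W - 1))
}
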