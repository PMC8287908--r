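#' Match predicted and ground-truth spots at a distance cutoff
#'
#' Pairs two point sets by minimum-cost bipartite assignment (Hungarian
#' method) on the Euclidean distance matrix, then keeps only pairs whose
#' distance does not exceed `cutoff`. Distances above the cutoff are replaced
#' by a large constant before solving, so the solver first maximizes the
#' number of feasible pairs and then minimizes their total distance.
#'
#' @param pred,truth coordinate tables: n x 2 matrices of (row, col) positions
#'   in pixels (may be empty).
#' @param cutoff non-negative matching radius in pixels; a pair is kept when
#'   its distance is `<= cutoff`.
#' @return an object of class `spot_match`: a list with `pairs` (data frame of
#'   `pred`, `truth` indices and `distance`), `fp`, `fn`, `cutoff`, `n_pred`,
#'   `n_truth`.
#' @examples
#' truth <- rbind(c(0, 0), c(0, 4))
#' pred  <- rbind(c(0, 3), c(0, 5))
#' match_spots(pred, truth, cutoff = 3.5)
#' @seealso [f1_score()], [f1_integral()], [rmse_spots()]
#' @export
match_spots <- function(pred, truth, cutoff = 3) {
  stopifnot_scalar(cutoff, "cutoff", min = 0)
  pred <- as_coord_matrix(pred)
  truth <- as_coord_matrix(truth)
  np <- nrow(pred); nt <- nrow(truth)
  empty_pairs <- data.frame(pred = integer(0), truth = integer(0),
                            distance = numeric(0))
  if (np == 0 || nt == 0) {
    return(structure(list(pairs = empty_pairs, fp = np, fn = nt,
                          cutoff = cutoff, n_pred = np, n_truth = nt),
                     class = "spot_match"))
  }
  d <- sqrt(outer(pred[, 1], truth[, 1], `-`)^2 +
            outer(pred[, 2], truth[, 2], `-`)^2)
  # points without any counterpart within the cutoff can never be matched;
  # dropping them first keeps the assignment problem small
  ri <- which(apply(d, 1, min) <= cutoff)
  ci <- which(apply(d, 2, min) <= cutoff)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (length(ri) > 0 && length(ci) > 0) {
    ds <- d[ri, ci, drop = FALSE]
    n <- max(length(ri), length(ci))
    big <- cutoff * n + 1
    cost <- matrix(big, n, n)
    feas <- ds
    feas[ds > cutoff] <- big
    cost[seq_along(ri), seq_along(ci)] <- feas
    a <- solve_assignment(cost)
    si <- seq_along(ri)
    ti <- a[si]
    keep <- cost[cbind(si, ti)] < big
    pairs <- data.frame(pred = ri[si[keep]], truth = ci[ti[keep]],
                        distance = ds[cbind(si[keep], ti[keep])])
  }
  structure(list(pairs = pairs, fp = np - nrow(pairs), fn = nt - nrow(pairs),
                 cutoff = cutoff, n_pred = np, n_truth = nt),
            class = "spot_match")
}

#' @export
print.spot_match <- function(x, ...) {
  cat(sprintf("spot match at cutoff %.3g px: %d pairs, %d FP, %d FN\n",
              x$cutoff, nrow(x$pairs), x$fp, x$fn))
  invisible(x)
}

#' F1 score of a spot matching
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. The degenerate case TP = FP = FN = 0
#' (both point sets empty) is defined as 0, keeping the score conservative.
#'
#' @param match a `spot_match` from [match_spots()].
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(match) {
  stopifnot(inherits(match, "spot_match"))
  tp <- nrow(match$pairs)
  denom <- 2 * tp + match$fp + match$fn
  if (denom == 0) 0 else 2 * tp / denom
}

#' F1 integral score
#'
#' Area under the F1-versus-cutoff curve: the F1 score is evaluated at
#' `n_cutoffs` linearly spaced matching radii between 0 and `max_cutoff`
#' pixels (endpoints included), integrated by the trapezoidal rule and
#' normalized by the maximal area `max_cutoff`. The score is 1 when the
#' prediction is a permutation of the truth and 0 when no prediction is
#' within `max_cutoff` of any truth, jointly capturing detection and
#' sub-pixel localization quality.
#'
#' @inheritParams match_spots
#' @param max_cutoff upper end of the cutoff range in pixels.
#' @param n_cutoffs number of cutoff values.
#' @return score in `[0, 1]`.
#' @examples
#' truth <- cbind(runif(5, 0, 64), runif(5, 0, 64))
#' f1_integral(truth, truth)            # 1: perfect prediction
#' f1_integral(truth + 10, truth)       # 0: nothing within 3 px
#' @export
f1_integral <- function(pred, truth, max_cutoff = 3, n_cutoffs = 50L) {
  pred <- as_coord_matrix(pred)
  truth <- as_coord_matrix(truth)
  cutoffs <- seq(0, max_cutoff, length.out = n_cutoffs)
  f1 <- vapply(cutoffs, function(ct) f1_score(match_spots(pred, truth, ct)),
               numeric(1))
  sum(diff(cutoffs) * (f1[-1] + f1[-length(f1)]) / 2) / max_cutoff
}

#' Localization RMSE over true positives
#'
#' Root mean square Euclidean distance `sqrt(sum(d_i^2) / n)` over the `n`
#' prediction-truth pairs matched at a 3 px cutoff. Undefined (NA) when there
#' are no true positives.
#'
#' @inheritParams match_spots
#' @param cutoff matching radius in pixels used to define true positives.
#' @return RMSE in pixels, or `NA_real_` if no pair matched.
#' @export
rmse_spots <- function(pred, truth, cutoff = 3) {
  m <- match_spots(pred, truth, cutoff)
  rmse_of_match(m)
}

rmse_of_match <- function(match) {
  d <- match$pairs$distance
  if (length(d) == 0) NA_real_ else sqrt(sum(d^2) / length(d))
}

#' Evaluate detections across a set of images
#'
#' Computes, per image, the F1 integral score, the classical F1 at a 3 px
#' cutoff and the localization RMSE over true positives, and aggregates them
#' as mean and sample standard deviation across images. The RMSE aggregate
#' covers only images with at least one true positive; the sd of a single
#' image is reported as 0.
#'
#' @param pred_sets,truth_sets equal-length lists of coordinate tables.
#' @param names optional character vector of image identifiers.
#' @return an object of class `spot_metrics`: list with `per_image` (data
#'   frame) and `summary` (data frame with `mean` and `sd` rows).
#' @export
evaluate_detections <- function(pred_sets, truth_sets, names = NULL) {
  if (length(pred_sets) != length(truth_sets))
    stop("'pred_sets' and 'truth_sets' must have equal length")
  n <- length(pred_sets)
  if (n == 0) stop("no images to evaluate")
  ids <- names %||% as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    p <- as_coord_matrix(pred_sets[[i]])
    t <- as_coord_matrix(truth_sets[[i]])
    m3 <- match_spots(p, t, 3)
    data.frame(image = ids[i], n_pred = nrow(p), n_truth = nrow(t),
               f1_integral = f1_integral(p, t), f1_at_3px = f1_score(m3),
               rmse = rmse_of_match(m3), stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  agg <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  cols <- c("f1_integral", "f1_at_3px", "rmse")
  s <- vapply(per_image[cols], agg, numeric(2))
  summary <- data.frame(statistic = c("mean", "sd"), s,
                        row.names = NULL, check.names = FALSE)
  structure(list(per_image = per_image, summary = summary),
            class = "spot_metrics")
}

#' @export
print.spot_metrics <- function(x, ...) {
  n <- nrow(x$per_image)
  cat(sprintf("spot detection metrics over %d image%s\n", n,
              if (n == 1) "" else "s"))
  m <- x$summary
  cat(sprintf("  F1 integral: %.4f ± %.4f\n",
              m$f1_integral[1], m$f1_integral[2]))
  cat(sprintf("  F1 @ 3 px:   %.4f ± %.4f\n",
              m$f1_at_3px[1], m$f1_at_3px[2]))
  if (is.finite(m$rmse[1]))
    cat(sprintf("  RMSE (px):   %.4f ± %.4f\n", m$rmse[1], m$rmse[2]))
  else cat("  RMSE (px):   undefined (no true positives)\n")
  invisible(x)
}
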