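#' Intersection-over-union of two neuron masks
#'
#' @param m1,m2 two-column integer matrices of 0-based `(row, col)` pixels
#'   on the same canvas, or single masks taken from a [mask_set()].
#' @param shape canvas shape `c(H, W)`; only used to key pixels, so any
#'   shape large enough for both masks gives the same answer.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(m1, m2, shape = NULL) {
  if (is.null(shape))
    shape <- c(max(m1[, 1L], m2[, 1L]) + 1L, max(m1[, 2L], m2[, 2L]) + 1L)
  k1 <- unique(mask_keys(m1, shape))
  k2 <- unique(mask_keys(m2, shape))
  ninter <- sum(k1 %in% k2)
  ninter / (length(k1) + length(k2) - ninter)
}

#' Assignment cost between a ground-truth and a detected mask
#'
#' The cost is `1 - IoU` when the pair overlaps substantially
#' (IoU >= `iou_threshold`) or when one mask contains the other, and
#' infinite otherwise. Containment admits heavily nested pairs (e.g. a
#' detection covering only the brightest core of a neuron) that the IoU
#' threshold alone would reject.
#'
#' @inheritParams mask_iou
#' @param gt,det two-column 0-based coordinate matrices.
#' @param iou_threshold minimum IoU for a finite cost; default 0.5.
#' @return a finite cost in `[0, 0.5]` via the IoU branch, a finite cost in
#'   `[0, 1)` via the containment branch, or `Inf`.
#' @export
pair_distance <- function(gt, det, shape = NULL, iou_threshold = 0.5) {
  if (is.null(shape))
    shape <- c(max(gt[, 1L], det[, 1L]) + 1L, max(gt[, 2L], det[, 2L]) + 1L)
  k1 <- unique(mask_keys(gt, shape))
  k2 <- unique(mask_keys(det, shape))
  ninter <- sum(k1 %in% k2)
  iou <- ninter / (length(k1) + length(k2) - ninter)
  contained <- ninter == length(k1) || ninter == length(k2)
  if (iou >= iou_threshold || contained) 1 - iou else Inf
}

#' Match detected masks to ground truth by minimum-cost assignment
#'
#' Builds the pairwise cost matrix with [pair_distance()] and solves the
#' optimal one-to-one assignment with the Hungarian algorithm. Infinite
#' costs are replaced inside the solver by a finite sentinel larger than
#' `n` times the largest finite cost, so a sentinel pair can never displace
#' any all-finite assignment; matched pairs whose true cost is infinite are
#' then discarded. The surviving pairs are the true positives.
#'
#' @param gt,det `mask_set` objects on the same canvas.
#' @param iou_threshold IoU threshold of the finite-cost condition.
#' @return an object of class `match_result`: list with `pairs` (data frame
#'   of 0-based `gt_id`, `det_id` and `cost`), `unmatched_gt`,
#'   `unmatched_det` (0-based id vectors), `n_tp`.
#' @export
match_masks <- function(gt, det, iou_threshold = 0.5) {
  stopifnot(inherits(gt, "mask_set"), inherits(det, "mask_set"))
  if (any(gt$shape != det$shape))
    stop("gt and det are on different canvases")
  ng <- length(gt$masks)
  nd <- length(det$masks)
  empty_pairs <- data.frame(gt_id = integer(), det_id = integer(),
                            cost = numeric())
  if (ng == 0L || nd == 0L) {
    res <- list(pairs = empty_pairs,
                unmatched_gt = seq_len(ng) - 1L,
                unmatched_det = seq_len(nd) - 1L,
                n_tp = 0L)
    return(structure(res, class = "match_result"))
  }
  cost <- matrix(Inf, ng, nd)
  for (i in seq_len(ng))
    for (j in seq_len(nd))
      cost[i, j] <- pair_distance(gt$masks[[i]], det$masks[[j]],
                                  shape = gt$shape,
                                  iou_threshold = iou_threshold)
  finite <- is.finite(cost)
  maxfin <- if (any(finite)) max(cost[finite]) else 0
  sentinel <- max(ng, nd) * max(maxfin, 1) + 1
  solv <- cost
  solv[!finite] <- sentinel
  # solver wants nrow <= ncol
  if (ng <= nd) {
    a <- lsap_solve(solv)
    gt_id <- seq_len(ng)
    det_id <- a
  } else {
    a <- lsap_solve(t(solv))
    det_id <- seq_len(nd)
    gt_id <- a
  }
  keep <- is.finite(cost[cbind(gt_id, det_id)])
  pairs <- data.frame(gt_id = gt_id[keep] - 1L, det_id = det_id[keep] - 1L,
                      cost = cost[cbind(gt_id, det_id)][keep])
  pairs <- pairs[order(pairs$gt_id), , drop = FALSE]
  rownames(pairs) <- NULL
  res <- list(pairs = pairs,
              unmatched_gt = setdiff(seq_len(ng), gt_id[keep]) - 1L,
              unmatched_det = setdiff(seq_len(nd), det_id[keep]) - 1L,
              n_tp = sum(keep))
  structure(res, class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d true-positive pair(s), %d unmatched GT, %d unmatched detections\n",
              x$n_tp, length(x$unmatched_gt), length(x$unmatched_det)))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `recall = N_TP / N_GT`, `precision = N_TP / N_detected`,
#' `F1 = 2 P R / (P + R)`. Degenerate denominators score 0: precision is 0
#' when nothing was detected, recall is 0 when there is no ground truth,
#' and F1 is 0 when `P + R = 0`.
#'
#' @param n_tp,n_gt,n_detected nonnegative counts with
#'   `n_tp <= min(n_gt, n_detected)`.
#' @return an object of class `metrics_report` with fields `n_tp`, `n_gt`,
#'   `n_detected`, `precision`, `recall`, `f1`.
#' @export
seg_metrics <- function(n_tp, n_gt, n_detected) {
  if (any(c(n_tp, n_gt, n_detected) < 0) || n_tp > min(n_gt, n_detected))
    stop("invalid counts: need 0 <= n_tp <= min(n_gt, n_detected)")
  precision <- if (n_detected > 0) n_tp / n_detected else 0
  recall <- if (n_gt > 0) n_tp / n_gt else 0
  structure(list(n_tp = n_tp, n_gt = n_gt, n_detected = n_detected,
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall)),
            class = "metrics_report")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall rates in `[0, 1]`.
#' @return F1 score; 0 when `precision + recall == 0`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("N_GT = %d, N_detected = %d, N_TP = %d\n",
              x$n_gt, x$n_detected, x$n_tp))
  cat(sprintf("precision = %.*f, recall = %.*f, F1 = %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f1))
  invisible(x)
}

#' @export
summary.metrics_report <- function(object, ...) print(object, ...)

#' Score a detection set against ground truth
#'
#' Full evaluation pipeline: Hungarian matching with the IoU/containment
#' cost, then precision/recall/F1 from the matched counts.
#'
#' @inheritParams match_masks
#' @return a `metrics_report`; the `match_result` is attached as attribute
#'   `"match"`.
#' @export
evaluate_masks <- function(gt, det, iou_threshold = 0.5) {
  mr <- match_masks(gt, det, iou_threshold = iou_threshold)
  rep <- seg_metrics(mr$n_tp, length(gt$masks), length(det$masks))
  attr(rep, "match") <- mr
  rep
}
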