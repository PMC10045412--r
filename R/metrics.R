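# Evaluation metrics: Dice coefficient, Aggregated Jaccard Index (AJI),
# panoptic quality (DQ, SQ, PQ), detection F1, and the joint
# detection + per-type classification score Fct.

# Intersection table between positive labels of two instance maps, plus
# per-label areas. Rows = gt labels, cols = pred labels.
overlap_table <- function(gt, pred) {
  ng <- max(gt, 0L); np <- max(pred, 0L)
  inter <- matrix(0, ng, np)
  both <- which(gt > 0 & pred > 0)
  if (length(both)) {
    tab <- table(gt = gt[both], pred = pred[both])
    inter[cbind(as.integer(rownames(tab))[row(tab)],
                as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  }
  list(inter = inter,
       area_gt = tabulate(gt[gt > 0], nbins = ng),
       area_pred = tabulate(pred[pred > 0], nbins = np))
}

#' Match predicted to ground-truth instances by IoU
#'
#' Pairs instances whose intersection-over-union exceeds 0.5; above that
#' threshold the pairing is automatically one-to-one. This is the matching
#' rule behind panoptic quality, the detection F1, and the classification
#' score.
#'
#' @param gt,pred integer instance matrices of equal shape.
#' @return list of class `"match_result"`: `pairs` (data frame with columns
#'   `gt`, `pred`, `iou`), `unmatched_gt`, `unmatched_pred`.
#' @export
match_instances <- function(gt, pred) {
  stopifnot(identical(dim(gt), dim(pred)))
  ov <- overlap_table(gt, pred)
  ng <- length(ov$area_gt); np <- length(ov$area_pred)
  pairs <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (ng && np) {
    uni <- outer(ov$area_gt, ov$area_pred, "+") - ov$inter
    iou <- ifelse(uni > 0, ov$inter / uni, 0)
    hit <- which(iou > 0.5, arr.ind = TRUE)
    pairs <- data.frame(gt = hit[, 1], pred = hit[, 2],
                        iou = iou[hit])
    pairs <- pairs[order(pairs$gt), , drop = FALSE]
  }
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(seq_len(ng), pairs$gt),
                 unmatched_pred = setdiff(seq_len(np), pairs$pred)),
            class = "match_result")
}

#' Dice coefficient of two binary masks
#'
#' `2 |X & Y| / (|X| + |Y|)`; defined as 1 when both masks are empty.
#'
#' @param X,Y binary (0/1 or logical) matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coef <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) stop("shape mismatch")
  sx <- sum(X > 0); sy <- sum(Y > 0)
  if (sx + sy == 0) return(1)
  2 * sum(X > 0 & Y > 0) / (sx + sy)
}

#' Aggregated Jaccard Index
#'
#' For each ground-truth instance in ascending label order, the unused
#' prediction with the largest Jaccard index is consumed; AJI is the summed
#' intersections over the summed unions plus the total area of predictions
#' never selected. Ground-truth instances with no overlapping unused
#' prediction contribute their full area to the union. The greedy,
#' order-dependent matching is inherent to the metric.
#'
#' @param gt,pred integer instance matrices of equal shape.
#' @return scalar in `[0, 1]`. Both maps empty gives 1; empty ground truth
#'   with a non-empty prediction gives 0.
#' @export
aji <- function(gt, pred) {
  stopifnot(identical(dim(gt), dim(pred)))
  ov <- overlap_table(gt, pred)
  ng <- length(ov$area_gt); np <- length(ov$area_pred)
  if (ng == 0) return(if (np == 0) 1 else 0)
  used <- rep(FALSE, np)
  num <- 0; den <- 0
  for (i in seq_len(ng)) {
    cand <- which(!used & ov$inter[i, ] > 0)
    if (!length(cand)) {
      den <- den + ov$area_gt[i]
      next
    }
    jac <- ov$inter[i, cand] /
      (ov$area_gt[i] + ov$area_pred[cand] - ov$inter[i, cand])
    best <- cand[which.max(jac)]
    used[best] <- TRUE
    num <- num + ov$inter[i, best]
    den <- den + ov$area_gt[i] + ov$area_pred[best] - ov$inter[i, best]
  }
  den <- den + sum(ov$area_pred[!used])
  if (den == 0) 1 else num / den
}

#' Panoptic quality
#'
#' Detection quality `DQ = |TP| / (|TP| + |FP|/2 + |FN|/2)` over IoU > 0.5
#' matches, segmentation quality `SQ` = mean IoU of the matches (0 with no
#' matches), and their product `PQ`.
#'
#' @param gt,pred integer instance matrices of equal shape.
#' @param match optionally a precomputed [match_instances()] result.
#' @return named numeric vector `c(dq, sq, pq)`. Both maps empty gives
#'   `(1, 1, 1)` (reported with a message).
#' @export
panoptic_quality <- function(gt, pred, match = NULL) {
  if (is.null(match)) match <- match_instances(gt, pred)
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  if (tp + fp + fn == 0) {
    message("panoptic_quality: empty ground truth and prediction; ",
            "returning (1, 1, 1)")
    return(c(dq = 1, sq = 1, pq = 1))
  }
  dq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0) mean(match$pairs$iou) else 0
  c(dq = dq, sq = sq, pq = dq * sq)
}

#' Detection F1 score
#'
#' `2 TP / (2 TP + FP + FN)` over the IoU > 0.5 instance matching.
#'
#' @param match a [match_instances()] result.
#' @return scalar in `[0, 1]`; 1 when there is nothing to detect and nothing
#'   predicted.
#' @export
detection_f1 <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Joint detection and classification score for one type
#'
#' Over matched instance pairs, counts correctly typed pairs of class `t`
#' (TPc), correctly non-`t` pairs (TNc), and the two disagreement cases (FPc,
#' FNc), then folds in the detection false positives/negatives:
#' `Fct = 2(TPc + TNc) / (2(TPc + TNc) + 2(FPc + FNc) + FPd + FNd)`.
#'
#' @param gt integer ground-truth instance matrix.
#' @param gt_types integer vector of ground-truth types indexed by instance
#'   label.
#' @param pred an `"instance_prediction"` from [assign_types()] (or a list
#'   with `instances` and `types`).
#' @param type_t the nucleus class scored.
#' @param match optionally a precomputed [match_instances()] result.
#' @return scalar in `[0, 1]`; a fully empty problem scores 1 (reported with
#'   a message).
#' @export
classification_score <- function(gt, gt_types, pred, type_t, match = NULL) {
  if (is.null(match)) match <- match_instances(gt, pred$instances)
  gl <- match$pairs$gt; pl <- match$pairs$pred
  tg <- gt_types[gl]
  tp_ <- pred$types[pl]
  tpc <- sum(tg == type_t & tp_ == type_t)
  tnc <- sum(tg != type_t & tp_ != type_t)
  fpc <- sum(tg != type_t & tp_ == type_t)
  fnc <- sum(tg == type_t & tp_ != type_t)
  fpd <- length(match$unmatched_pred)
  fnd <- length(match$unmatched_gt)
  den <- 2 * (tpc + tnc) + 2 * (fpc + fnc) + fpd + fnd
  if (den == 0) {
    message("classification_score: no instances anywhere; returning 1")
    return(1)
  }
  2 * (tpc + tnc) / den
}

#' Full metrics report for one image
#'
#' @param gt integer ground-truth instance matrix.
#' @param gt_types integer vector of ground-truth instance types (indexed by
#'   label), or `NULL` to skip classification scores.
#' @param pred an `"instance_prediction"` (or plain instance matrix).
#' @param n_types number of nucleus classes scored for `fct`.
#' @return list of class `"metrics_report"`: `dice`, `aji`, `dq`, `sq`, `pq`,
#'   `fd`, and `fct` (named per-type vector, if types were scored), plus the
#'   TP/FP/FN detection tallies.
#' @export
evaluate_instances <- function(gt, gt_types = NULL, pred, n_types = 3L) {
  pm <- if (inherits(pred, "instance_prediction")) pred$instances else pred
  match <- match_instances(gt, pm)
  pq <- panoptic_quality(gt, pm, match)
  rep <- list(dice = dice_coef(binarize_instances(gt), binarize_instances(pm)),
              aji = aji(gt, pm),
              dq = unname(pq["dq"]), sq = unname(pq["sq"]),
              pq = unname(pq["pq"]),
              fd = detection_f1(match),
              tp = nrow(match$pairs),
              fp = length(match$unmatched_pred),
              fn = length(match$unmatched_gt))
  if (!is.null(gt_types) && inherits(pred, "instance_prediction")) {
    rep$fct <- vapply(seq_len(n_types), function(t)
      classification_score(gt, gt_types, pred, t, match), numeric(1))
    names(rep$fct) <- paste0("type", seq_len(n_types))
  }
  structure(rep, class = "metrics_report")
}
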