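# Evaluation indices: Dice, aggregated Jaccard index (AJI), panoptic
# quality (PQ) with its segmentation/detection decomposition, per-class
# average PQ, and a brute-force assignment oracle used to validate the
# greedy PQ matching in tests.

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share one shape")
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param gt_fg,pred_fg Binary masks (any nonzero value is foreground).
#' @export
dice_score <- function(gt_fg, pred_fg) {
  check_same_shape(gt_fg, pred_fg)
  a <- gt_fg > 0; b <- pred_fg > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Pairwise intersection table between instances of two label masks:
# a matrix with one row per gt id and one column per pred id.
intersection_table <- function(gt, pred) {
  ng <- length(label_ids(gt)); np <- length(label_ids(pred))
  out <- matrix(0, ng, np)
  sel <- gt > 0L & pred > 0L
  if (any(sel)) {
    tab <- table(factor(gt[sel], levels = seq_len(ng)),
                 factor(pred[sel], levels = seq_len(np)))
    out <- matrix(as.numeric(tab), ng, np)
  }
  out
}

#' Aggregated Jaccard index
#'
#' Iterates ground-truth instances in ascending id; each picks the
#' not-yet-used predicted instance maximizing IoU (ties toward the lowest
#' predicted id), accumulating the pair's intersection into the numerator
#' and union into the denominator (or the ground-truth area when no
#' overlapping prediction remains). Every unused predicted instance's area
#' is then added to the denominator. Returns 1 when both masks are empty and
#' 0 when exactly one is.
#'
#' @param gt,pred Instance label masks.
#' @export
aji <- function(gt, pred) {
  check_same_shape(gt, pred)
  check_label_mask(gt, "gt"); check_label_mask(pred, "pred")
  ag <- instance_areas(gt); ap <- instance_areas(pred)
  if (!length(ag) && !length(ap)) return(1)
  if (!length(ag) || !length(ap)) return(0)
  inter <- intersection_table(gt, pred)
  used <- logical(length(ap))
  num <- 0; den <- 0
  for (g in seq_along(ag)) {
    cand <- which(inter[g, ] > 0 & !used)
    if (!length(cand)) { den <- den + ag[g]; next }
    iou <- inter[g, cand] / (ag[g] + ap[cand] - inter[g, cand])
    best <- cand[which.max(iou)] # which.max ties -> lowest index
    num <- num + inter[g, best]
    den <- den + ag[g] + ap[best] - inter[g, best]
    used[best] <- TRUE
  }
  den <- den + sum(ap[!used])
  num / den
}

#' Panoptic quality
#'
#' Matches ground-truth and predicted instances with IoU strictly above
#' `iou_threshold` (at 0.5 the matching is provably unique). With TP matched
#' pairs, FP unmatched predictions and FN unmatched ground-truth instances:
#' `dq = |TP| / (|TP| + |FP|/2 + |FN|/2)` (detection quality), `sq` = mean
#' IoU over matched pairs (segmentation quality, 0 without matches), and
#' `pq = sq * dq`. Two empty masks give (1, 1, 1).
#'
#' @param gt,pred Instance label masks.
#' @param iou_threshold Matching threshold; must be >= 0.5, above which
#'   greedy matching is optimal.
#' @return List with `pq`, `sq`, `dq` and `match` (pairs with IoU,
#'   unmatched ids).
#' @export
pq <- function(gt, pred, iou_threshold = 0.5) {
  check_same_shape(gt, pred)
  check_label_mask(gt, "gt"); check_label_mask(pred, "pred")
  if (iou_threshold < 0.5)
    stop("iou_threshold below 0.5 breaks uniqueness of the matching")
  ag <- instance_areas(gt); ap <- instance_areas(pred)
  if (!length(ag) && !length(ap))
    return(list(pq = 1, sq = 1, dq = 1,
                match = list(pairs = data.frame(gt_id = integer(0),
                                                pred_id = integer(0),
                                                iou = numeric(0)),
                             unmatched_gt = integer(0),
                             unmatched_pred = integer(0))))
  inter <- intersection_table(gt, pred)
  pairs <- data.frame(gt_id = integer(0), pred_id = integer(0),
                      iou = numeric(0))
  if (length(ag) && length(ap)) {
    iou <- inter / (outer(ag, ap, `+`) - inter)
    hits <- which(iou > iou_threshold, arr.ind = TRUE)
    if (nrow(hits))
      pairs <- data.frame(gt_id = hits[, 1L], pred_id = hits[, 2L],
                          iou = iou[hits])
    pairs <- pairs[order(pairs$gt_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  tp <- nrow(pairs)
  fn <- length(ag) - tp
  fp <- length(ap) - tp
  dq <- if (tp + fp + fn == 0L) 1 else tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp == 0L) 0 else mean(pairs$iou)
  list(pq = sq * dq, sq = sq, dq = dq,
       match = list(pairs = pairs,
                    unmatched_gt = setdiff(seq_along(ag), pairs$gt_id),
                    unmatched_pred = setdiff(seq_along(ap), pairs$pred_id)))
}

#' Per-class average panoptic quality
#'
#' For each class, both masks are restricted to the instances of that class
#' and [pq()] is computed on the restriction (so a correctly segmented
#' instance with the wrong class counts as a false positive for its
#' predicted class and a false negative for its true class). Reports
#' per-class PQ and the unweighted mean over classes present in the ground
#' truth.
#'
#' @param gt,pred Instance label masks.
#' @param gt_classes,pred_classes Integer vectors mapping instance id to
#'   class code in `1..n_classes`.
#' @param n_classes Number of classes K.
#' @return List with `per_class` (named numeric, NA for classes absent from
#'   gt) and `mean_pq`.
#' @export
class_average_pq <- function(gt, gt_classes, pred, pred_classes, n_classes) {
  check_same_shape(gt, pred)
  ng <- length(label_ids(gt)); np <- length(label_ids(pred))
  if (length(gt_classes) != ng || length(pred_classes) != np)
    stop("class vectors must have one entry per instance")
  if (length(gt_classes) && (any(gt_classes < 1L) || any(gt_classes > n_classes)))
    stop("gt class codes must lie in 1..n_classes")
  if (length(pred_classes) &&
      (any(pred_classes < 1L) || any(pred_classes > n_classes)))
    stop("pred class codes must lie in 1..n_classes")
  restrict <- function(lab, cls, c) {
    keep <- which(cls == c)
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
    out
  }
  per <- rep(NA_real_, n_classes)
  names(per) <- paste0("class", seq_len(n_classes))
  for (c in seq_len(n_classes)) {
    if (!any(gt_classes == c)) next
    per[c] <- pq(restrict(gt, gt_classes, c),
                 restrict(pred, pred_classes, c))$pq
  }
  list(per_class = per, mean_pq = mean(per, na.rm = TRUE))
}

#' Brute-force optimal instance matching (validation oracle)
#'
#' Exhaustively searches one-to-one assignments between ground-truth and
#' predicted instances maximizing total IoU, subject to every matched pair
#' exceeding `iou_threshold`. Exponential; refuses masks with more than 12
#' instances. Intended for validating the greedy threshold matching of
#' [pq()] in tests.
#'
#' @inheritParams pq
#' @export
brute_force_match <- function(gt, pred, iou_threshold = 0.5) {
  check_same_shape(gt, pred)
  ag <- instance_areas(gt); ap <- instance_areas(pred)
  if (length(ag) > 12L || length(ap) > 12L)
    stop("brute-force matching is limited to 12 instances per mask")
  if (!length(ag) || !length(ap))
    return(list(pairs = data.frame(gt_id = integer(0), pred_id = integer(0),
                                   iou = numeric(0)),
                unmatched_gt = seq_along(ag), unmatched_pred = seq_along(ap)))
  inter <- intersection_table(gt, pred)
  iou <- inter / (outer(ag, ap, `+`) - inter)
  feas <- iou > iou_threshold
  best <- list(score = -1, assign = integer(length(ag)))
  recurse <- function(g, assign, score) {
    if (g > length(ag)) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return(invisible())
    }
    recurse(g + 1L, assign, score) # leave g unmatched
    for (p in which(feas[g, ])) {
      if (p %in% assign) next
      assign[g] <- p
      recurse(g + 1L, assign, score + iou[g, p])
      assign[g] <- 0L
    }
  }
  recurse(1L, integer(length(ag)), 0)
  sel <- which(best$assign > 0L)
  pairs <- data.frame(gt_id = sel, pred_id = best$assign[sel],
                      iou = iou[cbind(sel, best$assign[sel])])
  list(pairs = pairs,
       unmatched_gt = setdiff(seq_along(ag), pairs$gt_id),
       unmatched_pred = setdiff(seq_along(ap), pairs$pred_id))
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Convenience wrapper computing Dice (on foreground), AJI and PQ (with its
#' SQ/DQ decomposition) for one image.
#'
#' @param gt,pred Instance label masks.
#' @return One-row data frame with dice, aji, pq, sq, dq.
#' @export
evaluate_instances <- function(gt, pred) {
  p <- pq(gt, pred)
  data.frame(dice = dice_score(gt > 0, pred > 0), aji = aji(gt, pred),
             pq = p$pq, sq = p$sq, dq = p$dq)
}
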