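#' Intersection over union of two binary masks
#'
#' @param a,b H x W 0/1 matrices of identical dimensions.
#' @return |a & b| / |a | b|; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ", call. = FALSE)
  u <- sum(a != 0 | b != 0)
  if (u == 0) return(0)
  sum(a != 0 & b != 0) / u
}

#' Greedy score-ordered matching of predictions to ground truths
#'
#' Predictions are taken in order of decreasing score (ties: lower input
#' index first); each is matched one-to-one to the still-unmatched ground
#' truth of highest IoU, provided that IoU reaches the threshold (IoU
#' ties: lower ground-truth index).
#'
#' @param preds `list(masks = <list of masks>, scores = <numeric>)`.
#' @param gts `list(masks = <list of masks>)`.
#' @param iou_threshold match threshold in (0, 1\].
#' @return data.frame with one row per prediction (in input order):
#'   `pred`, `score`, `gt` (matched ground-truth index or `NA`), `iou`.
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.5) {
  if (!(iou_threshold > 0 && iou_threshold <= 1))
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  np <- length(preds$masks); ng <- length(gts$masks)
  scores <- preds$scores %||% rep(1, np)
  res <- data.frame(pred = seq_len(np), score = scores,
                    gt = rep(NA_integer_, np), iou = rep(NA_real_, np))
  if (np == 0L) return(res)
  order_p <- order(-scores, seq_len(np))
  taken <- rep(FALSE, ng)
  for (i in order_p) {
    best <- 0; best_g <- NA_integer_
    for (g in seq_len(ng)) {
      if (taken[g]) next
      v <- mask_iou(preds$masks[[i]], gts$masks[[g]])
      if (v >= iou_threshold && v > best) { best <- v; best_g <- g }
    }
    if (!is.na(best_g)) {
      taken[best_g] <- TRUE
      res$gt[i] <- best_g; res$iou[i] <- best
    }
  }
  res
}

#' Precision and recall of a matching
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; an empty
#' denominator yields 0 by convention.
#'
#' @param matching a data.frame from [match_instances()].
#' @param n_gt total number of ground truths the matching was computed
#'   against.
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(matching, n_gt) {
  tp <- sum(!is.na(matching$gt))
  fp <- nrow(matching) - tp
  fn <- n_gt - tp
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

mask_area_px <- function(m) sum(m != 0)

bbox_mask <- function(m) {
  out <- matrix(0L, nrow(m), ncol(m))
  ij <- which(m != 0, arr.ind = TRUE)
  if (nrow(ij)) out[min(ij[, 1]):max(ij[, 1]), min(ij[, 2]):max(ij[, 2])] <- 1L
  out
}

# Core COCO-style evaluation at one IoU threshold and one gt-area range.
# preds/gts: named lists per image. Ground truths with pixel area outside
# `area_rng` become ignore-targets: predictions may match them (after real
# targets) and are then excluded from the PR curve, as are unmatched
# predictions whose own area is outside the range.
ap_core <- function(preds, gts, iou_threshold, area_rng = c(0, Inf)) {
  imgs <- names(gts)
  det <- data.frame(img = character(), idx = integer(), score = numeric())
  for (im in imgs) {
    p <- preds[[im]]
    if (!is.null(p) && length(p$masks))
      det <- rbind(det, data.frame(
        img = im, idx = seq_along(p$masks),
        score = p$scores %||% rep(1, length(p$masks))))
  }
  npig <- 0L
  gt_ignore <- lapply(imgs, function(im) {
    g <- gts[[im]]
    if (is.null(g) || !length(g$masks)) return(logical(0))
    a <- vapply(g$masks, mask_area_px, numeric(1))
    a < area_rng[1] | a > area_rng[2]
  })
  names(gt_ignore) <- imgs
  npig <- sum(vapply(gt_ignore, function(ig) sum(!ig), numeric(1)))
  if (npig == 0L) return(list(ap = NA_real_, tp = 0L, fp = 0L, n_gt = 0L))
  if (nrow(det) == 0L)
    return(list(ap = 0, tp = 0L, fp = 0L, n_gt = npig))
  det <- det[order(-det$score, match(det$img, imgs), det$idx), , drop = FALSE]
  taken <- lapply(gt_ignore, function(ig) rep(FALSE, length(ig)))
  flag <- character(nrow(det))   # "tp", "fp", "ignore"
  for (r in seq_len(nrow(det))) {
    im <- det$img[r]
    dmask <- preds[[im]]$masks[[det$idx[r]]]
    g <- gts[[im]]; ng <- if (is.null(g)) 0L else length(g$masks)
    best <- 0; best_g <- NA_integer_; best_ig <- FALSE
    for (j in seq_len(ng)) {
      if (taken[[im]][j]) next
      # once matched to a real target, never trade it for an ignore-target
      if (!is.na(best_g) && !best_ig && gt_ignore[[im]][j]) next
      v <- mask_iou(dmask, g$masks[[j]])
      if (v < iou_threshold) next
      # a real target beats any ignore-target even at lower IoU
      if (!is.na(best_g) && best_ig && !gt_ignore[[im]][j]) {
        best <- v; best_g <- j; best_ig <- FALSE; next
      }
      if (v > best) { best <- v; best_g <- j; best_ig <- gt_ignore[[im]][j] }
    }
    if (!is.na(best_g)) {
      taken[[im]][best_g] <- TRUE
      flag[r] <- if (best_ig) "ignore" else "tp"
    } else {
      a <- mask_area_px(dmask)
      flag[r] <- if (a < area_rng[1] || a > area_rng[2]) "ignore" else "fp"
    }
  }
  keep <- flag != "ignore"
  tp <- cumsum(flag[keep] == "tp")
  fp <- cumsum(flag[keep] == "fp")
  if (!length(tp))
    return(list(ap = 0, tp = 0L, fp = 0L, n_gt = npig))
  prec <- tp / (tp + fp)
  rec <- tp / npig
  # 101-point interpolation: precision at recall r = max precision at >= r
  rc <- seq(0, 1, by = 0.01)
  pint <- vapply(rc, function(r) {
    sel <- rec >= r
    if (any(sel)) max(prec[sel]) else 0
  }, numeric(1))
  list(ap = mean(pint), tp = tp[length(tp)], fp = fp[length(fp)], n_gt = npig)
}

#' Average precision over a set of images
#'
#' COCO-convention AP at one IoU threshold: detections pooled over images
#' and sorted by descending score (ties by image order, then detection
#' index), matched greedily within their image, and the area under the
#' 101-point-interpolated precision-recall curve reported.
#'
#' @param preds named list (one element per image) of
#'   `list(masks, scores)`.
#' @param gts named list per image of `list(masks)`.
#' @param iou_threshold match threshold.
#' @return AP in \[0, 1\], or `NA` when there is no ground truth at all.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  ap_core(preds, gts, iou_threshold)$ap
}

#' Full instance-segmentation evaluation report
#'
#' Computes precision and recall at IoU 0.5, AP at each threshold of
#' `iou_thresholds`, their mean (`map_50_95` for the default COCO grid
#' 0.50–0.95 in steps of 0.05), and size-stratified AP over ground-truth
#' pixel areas: small < 32^2, medium 32^2–96^2, large > 96^2 px. A stratum
#' with no ground truth reports `NA` (printed as `Nan`).
#'
#' @param preds named list per image of `list(masks, scores)`.
#' @param gts named list per image of `list(masks)`; names must match
#'   `preds` (prediction-less images may be absent from `preds`).
#' @param iou_thresholds IoU grid (default `seq(0.5, 0.95, 0.05)`).
#' @param level `"mask"` (default) or `"bbox"`; the latter evaluates the
#'   tight bounding boxes of the masks with the same machinery.
#' @return object of class `"eval_report"`.
#' @export
evaluate_instances <- function(preds, gts,
                               iou_thresholds = seq(0.5, 0.95, by = 0.05),
                               level = c("mask", "bbox")) {
  level <- match.arg(level)
  extra <- setdiff(names(preds), names(gts))
  if (length(extra))
    stop("prediction images missing from ground truth: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (level == "bbox") {
    preds <- lapply(preds, function(p) { p$masks <- lapply(p$masks, bbox_mask); p })
    gts <- lapply(gts, function(g) { g$masks <- lapply(g$masks, bbox_mask); g })
  }
  ap <- vapply(iou_thresholds, function(t) ap_core(preds, gts, t)$ap, numeric(1))
  names(ap) <- sprintf("%.2f", iou_thresholds)
  core50 <- ap_core(preds, gts, 0.5)
  n_gt <- core50$n_gt
  pr <- c(precision = if (core50$tp + core50$fp == 0) 0 else
            core50$tp / (core50$tp + core50$fp),
          recall = if (n_gt == 0) 0 else core50$tp / n_gt)
  strata <- list(small = c(0, 32^2), medium = c(32^2, 96^2),
                 large = c(96^2, Inf))
  ap_strat <- vapply(strata, function(rng)
    mean(vapply(iou_thresholds, function(t)
      ap_core(preds, gts, t, rng)$ap, numeric(1))), numeric(1))
  structure(list(
    precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    ap_by_threshold = ap,
    map_50_95 = mean(ap),
    ap_small = ap_strat[["small"]], ap_medium = ap_strat[["medium"]],
    ap_large = ap_strat[["large"]],
    level = level, n_gt = n_gt
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "Nan" else sprintf("%.3f", 100 * v)
  cat(sprintf("Instance segmentation evaluation (%s level, %d ground truths)\n",
              x$level, x$n_gt))
  cat(sprintf("  P %.3f  R %.3f\n", x$precision, x$recall))
  cat("  AP      AP50    AP75    APs     APm     APl\n")
  cat(sprintf("  %-7s %-7s %-7s %-7s %-7s %-7s\n",
              fmt(x$map_50_95), fmt(x$ap_by_threshold[["0.50"]]),
              fmt(x$ap_by_threshold[["0.75"]]), fmt(x$ap_small),
              fmt(x$ap_medium), fmt(x$ap_large)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `"eval_report"`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
eval_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
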