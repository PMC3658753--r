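# Quantitative protocols: PR sweep over the integer thresholds 0..255 with
# the strict foreground rule saliency > tau, trapezoidal ROC area, and
# moving-object extraction (threshold + opening/closing + 8-connected
# components) scored with the 30%-in-box rule.

#' Precision-recall and ROC sweep of a saliency map
#'
#' For every integer threshold `tau` in 0..255 the map is binarised with the
#' strict rule `saliency > tau` (so `tau = 255` predicts nothing) and
#' compared with a binary ground-truth mask. Precision is defined as 1 when
#' nothing is predicted; recall as 1 when the ground truth is empty. The ROC
#' area is the trapezoidal area under (FPR, TPR), with the all-foreground
#' anchor (1, 1) appended so a perfect map scores exactly 1.
#'
#' @param saliency numeric matrix, conventionally normalised to `[0, 255]`
#'   (see [normalize_map()]).
#' @param gt_mask logical or 0/1 matrix of the same dimension.
#' @return An `eval_curves` tibble with columns `threshold`, `precision`,
#'   `recall`, `tpr`, `fpr` and attribute `roc_area`.
#' @examples
#' gt <- matrix(FALSE, 4, 4); gt[1:2, 1:2] <- TRUE
#' curves <- pr_curve(255 * gt, gt)
#' attr(curves, "roc_area")
#' @export
pr_curve <- function(saliency, gt_mask) {
  s <- if (inherits(saliency, "saliency_map")) as_matrix_map(saliency) else saliency
  if (!identical(dim(s), dim(gt_mask)))
    stop("saliency and gt_mask dimensions differ", call. = FALSE)
  g <- as.logical(gt_mask)
  if (anyNA(g)) stop("gt_mask must be binary", call. = FALSE)
  v <- as.vector(s)
  taus <- 0:255
  n_all <- length(v)
  n_gt <- sum(g)
  n_bg <- n_all - n_gt
  sv_all <- sort(v)
  sv_gt <- sort(v[g])
  pred <- n_all - findInterval(taus, sv_all)   # pixels with value > tau
  tp <- n_gt - findInterval(taus, sv_gt)
  fp <- pred - tp
  precision <- ifelse(pred > 0, tp / pred, 1)
  recall <- if (n_gt > 0) tp / n_gt else rep(1, length(taus))
  fpr <- if (n_bg > 0) fp / n_bg else rep(0, length(taus))
  curves <- tibble::tibble(threshold = taus, precision = precision,
                           recall = recall, tpr = recall, fpr = fpr)
  # ROC area over the sweep, anchored at the all-foreground point
  fx <- c(1, fpr); ty <- c(1, recall)
  o <- order(fx, ty)   # ties in FPR sorted by TPR so the polyline is monotone
  area <- sum(diff(fx[o]) * (utils::head(ty[o], -1) + utils::tail(ty[o], -1)) / 2)
  structure(curves, class = c("eval_curves", class(curves)), roc_area = area)
}

#' Area under the ROC curve of a saliency map
#'
#' The trapezoidal area under the (FPR, TPR) curve produced by the 256-step
#' threshold sweep of [pr_curve()]. 1 means every ground-truth pixel outranks
#' every background pixel; a constant map scores 0.5.
#'
#' @inheritParams pr_curve
#' @return A number in `[0, 1]`.
#' @export
roc_area <- function(saliency, gt_mask) {
  attr(pr_curve(saliency, gt_mask), "roc_area")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass.
label_components8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- unclass(EBImage::bwlabel(m))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  M <- nrow(lab); N <- ncol(lab)
  a <- lab[-M, -N]; b <- lab[-1, -1]    # down-right diagonal pairs
  keep <- a > 0 & b > 0 & a != b
  if (any(keep)) mapply(union, a[keep], b[keep])
  a <- lab[-1, -N]; b <- lab[-M, -1]    # up-right diagonal pairs
  keep <- a > 0 & b > 0 & a != b
  if (any(keep)) mapply(union, a[keep], b[keep])
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, unique(roots))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract moving-object candidates from a saliency map
#'
#' Binarises the map at a threshold, cleans the mask with a morphological
#' opening followed by a closing (disc structuring element), and returns the
#' bounding boxes of the 8-connected foreground components.
#'
#' @param saliency numeric matrix (conventionally in `[0, 255]`).
#' @param threshold foreground rule is `saliency > threshold`.
#' @param morph_radius radius (pixels) of the disc structuring element;
#'   0 skips the morphology.
#' @return A `detection_result`: list with `mask` (logical matrix) and
#'   `boxes` (tibble of 0-based `x`, `y`, `w`, `h`).
#' @export
extract_moving_objects <- function(saliency, threshold, morph_radius = 1) {
  s <- if (inherits(saliency, "saliency_map")) as_matrix_map(saliency) else saliency
  mask <- s > threshold
  if (morph_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(morph_radius) + 1L, shape = "disc")
    m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    mask <- unclass(m) > 0.5
  }
  lab <- if (any(mask)) label_components8(mask) else matrix(0, nrow(mask), ncol(mask))
  n <- max(lab)
  boxes <- if (n > 0) {
    do.call(rbind, lapply(seq_len(n), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      tibble::tibble(x = min(idx[, 2]) - 1L, y = min(idx[, 1]) - 1L,
                     w = diff(range(idx[, 2])) + 1L,
                     h = diff(range(idx[, 1])) + 1L)
    }))
  } else {
    tibble::tibble(x = integer(), y = integer(), w = integer(), h = integer())
  }
  structure(list(mask = mask, boxes = tibble::as_tibble(boxes)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d box(es), %d foreground pixel(s)\n",
              nrow(x$boxes), sum(x$mask)))
  invisible(x)
}

#' Score detections against ground-truth boxes (30%-in-box rule)
#'
#' A ground-truth box counts as detected when at least 30% of its pixels are
#' foreground in the extraction mask. Recall is the fraction of ground-truth
#' boxes detected. A predicted box is a true positive when it overlaps any
#' detected ground-truth box; precision is the true-positive fraction of
#' predicted boxes (1 when nothing was predicted). Boxes are half-open
#' `[x, x+w) x [y, y+h)`, 0-based, origin top-left.
#'
#' @param result a `detection_result` from [extract_moving_objects()].
#' @param gt_boxes tibble/data.frame with 0-based `x`, `y`, `w`, `h`.
#' @return A one-row tibble: `recall`, `precision`, `n_gt`, `n_detected`,
#'   `n_pred`, `n_tp`.
#' @export
detection_metrics <- function(result, gt_boxes) {
  stopifnot(inherits(result, "detection_result"))
  mask <- result$mask
  M <- nrow(mask); N <- ncol(mask)
  n_gt <- nrow(gt_boxes)
  detected <- logical(n_gt)
  for (i in seq_len(n_gt)) {
    b <- gt_boxes[i, ]
    if (anyNA(b[c("x", "y", "w", "h")]) || b$w < 1 || b$h < 1 ||
        b$x < 0 || b$y < 0 || b$x + b$w > N || b$y + b$h > M)
      stop(sprintf("malformed or out-of-bounds ground-truth box at row %d", i),
           call. = FALSE)
    sub <- mask[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    # integer comparison so 'at least 30%' is exact at the boundary
    detected[i] <- 10L * sum(sub) >= 3L * length(sub)
  }
  pred <- result$boxes
  n_pred <- nrow(pred)
  overlaps <- function(a, b) {
    a$x < b$x + b$w && b$x < a$x + a$w && a$y < b$y + b$h && b$y < a$y + a$h
  }
  tp <- 0L
  det_boxes <- gt_boxes[detected, , drop = FALSE]
  for (i in seq_len(n_pred)) {
    hit <- FALSE
    for (j in seq_len(nrow(det_boxes)))
      if (overlaps(pred[i, ], det_boxes[j, ])) { hit <- TRUE; break }
    if (hit) tp <- tp + 1L
  }
  tibble::tibble(recall = if (n_gt > 0) mean(detected) else 1,
                 precision = if (n_pred > 0) tp / n_pred else 1,
                 n_gt = n_gt, n_detected = sum(detected),
                 n_pred = n_pred, n_tp = tp)
}

#' Default global extraction threshold
#'
#' Three times the mean saliency, the customary rule of spectral saliency
#' models for object segmentation. Computed over one map or a list of maps
#' (giving a single global threshold for a whole sequence).
#'
#' @param maps a saliency map or list of maps (normalised to `[0, 255]`).
#' @return A single threshold value.
#' @export
saliency_threshold <- function(maps) {
  if (!is.list(maps)) maps <- list(maps)
  vals <- unlist(lapply(maps, function(m)
    as.vector(if (inherits(m, "saliency_map")) as_matrix_map(m) else m)))
  3 * mean(vals)
}
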