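#' Overlap-based detection scoring
#'
#' A predicted region is a true positive iff it shares at least one pixel
#' with any ground-truth region, and a false positive otherwise; a truth
#' region counts as detected iff at least one prediction overlaps it, and is
#' counted once no matter how many predictions hit it.  Sensitivity is the
#' detected fraction of truth regions; the false-positive rate is reported
#' per image.
#'
#' @param pred_regions,truth_regions For a single image: a list of masks.
#'   For several images: a list (one element per image) of lists of masks.
#'   A mask is a logical matrix or a vector of pixel indices; all masks of
#'   one image must share one raster geometry.
#' @param n_images Number of images the predictions came from.
#' @param min_overlap Minimum number of shared pixels to count as overlap.
#' @return A `detection_report` list: `n_truth`, `n_detected`,
#'   `sensitivity` (`NA` when there are no truth regions), `n_fp`,
#'   `fp_per_image`, `n_images`.
#' @export
match_and_score <- function(pred_regions, truth_regions, n_images = 1L,
                            min_overlap = 1L) {
  imgs <- normalize_mask_sets(pred_regions, truth_regions, n_images)
  n_truth <- 0L
  n_detected <- 0L
  n_fp <- 0L
  for (img in imgs) {
    pred <- img$pred
    truth <- img$truth
    n_truth <- n_truth + length(truth)
    if (!length(pred)) next
    hit_truth <- logical(length(truth))
    for (p in pred) {
      ov <- vapply(truth, function(t) length(intersect(p, t)) >= min_overlap, logical(1))
      if (any(ov)) hit_truth <- hit_truth | ov else n_fp <- n_fp + 1L
    }
    n_detected <- n_detected + sum(hit_truth)
  }
  structure(
    list(
      n_truth = n_truth, n_detected = n_detected,
      sensitivity = if (n_truth > 0L) n_detected / n_truth else NA_real_,
      n_fp = n_fp, fp_per_image = n_fp / n_images, n_images = n_images
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> sensitivity %s (%d/%d), %.2f FP/image (%d FP, %d images)\n",
    if (is.na(x$sensitivity)) "NA" else sprintf("%.1f%%", 100 * x$sensitivity),
    x$n_detected, x$n_truth, x$fp_per_image, x$n_fp, x$n_images
  ))
  invisible(x)
}

mask_to_idx <- function(m) {
  if (is.matrix(m)) which(m > 0) else as.integer(m)
}

normalize_mask_sets <- function(pred, truth, n_images) {
  is_flat <- function(x) {
    !length(x) || is.matrix(x[[1]]) || is.numeric(x[[1]]) || is.logical(x[[1]])
  }
  if (n_images == 1L && is_flat(pred) && is_flat(truth)) {
    pred <- list(pred)
    truth <- list(truth)
  }
  if (length(pred) != n_images || length(truth) != n_images) {
    input_error("pred and truth must have one element per image")
  }
  lapply(seq_len(n_images), function(i) {
    pr <- pred[[i]]
    tr <- truth[[i]]
    geom <- unique(c(
      lapply(Filter(is.matrix, pr), dim),
      lapply(Filter(is.matrix, tr), dim)
    ))
    if (length(geom) > 1L) input_error("all masks of one image must share one geometry")
    list(pred = lapply(pr, mask_to_idx), truth = lapply(tr, mask_to_idx))
  })
}

#' Default lesion-size bins
#'
#' Half-open pixel-area intervals `(0,10)`, `[10,50)`, `[50,100)`,
#' `[100,Inf)` used for size-stratified reporting on ultrawide-field
#' images.
#'
#' @return List of `c(lower, upper)` pairs.
#' @export
default_size_bins <- function() {
  list(c(0, 10), c(10, 50), c(50, 100), c(100, Inf))
}

bin_label <- function(b) {
  if (b[1] == 0) sprintf("(0,%g)", b[2]) else if (is.infinite(b[2])) {
    sprintf("[%g,Inf)", b[1])
  } else {
    sprintf("[%g,%g)", b[1], b[2])
  }
}

#' Size-binned detection metrics
#'
#' Truth regions are assigned to bins by their own pixel area, false
#' positives by the predicted area; per-bin sensitivity and FP/image follow
#' the [match_and_score()] rules.  Bins must be disjoint, half-open
#' `[lower, upper)`, and cover the positive areas.
#'
#' @inheritParams match_and_score
#' @param bins List of `c(lower, upper)` area intervals.
#' @return Data frame with one row per bin: `bin`, `n_truth`, `n_detected`,
#'   `sensitivity`, `n_fp`, `fp_per_image`.
#' @export
size_binned_metrics <- function(pred_regions, truth_regions, n_images = 1L,
                                bins = default_size_bins()) {
  b <- do.call(rbind, bins)
  b <- b[order(b[, 1]), , drop = FALSE]
  if (any(b[-nrow(b), 2] > b[-1, 1])) config_error("size bins overlap")
  if (any(b[-nrow(b), 2] < b[-1, 1]) || !is.infinite(b[nrow(b), 2])) {
    config_error("size bins must cover (0, Inf) without gaps")
  }
  bins <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  imgs <- normalize_mask_sets(pred_regions, truth_regions, n_images)
  assign_bin <- function(area) {
    for (i in seq_along(bins)) {
      if (area >= bins[[i]][1] && area < bins[[i]][2]) {
        return(i)
      }
    }
    NA_integer_
  }
  k <- length(bins)
  n_truth <- n_det <- n_fp <- integer(k)
  for (img in imgs) {
    pred <- img$pred
    truth <- img$truth
    tbin <- vapply(truth, function(t) assign_bin(length(t)), integer(1))
    for (i in seq_along(truth)) n_truth[tbin[i]] <- n_truth[tbin[i]] + 1L
    hit <- logical(length(truth))
    for (p in pred) {
      ov <- vapply(truth, function(t) length(intersect(p, t)) >= 1L, logical(1))
      if (any(ov)) {
        hit <- hit | ov
      } else {
        pb <- assign_bin(length(p))
        n_fp[pb] <- n_fp[pb] + 1L
      }
    }
    for (i in which(hit)) n_det[tbin[i]] <- n_det[tbin[i]] + 1L
  }
  data.frame(
    bin = vapply(bins, bin_label, character(1)),
    n_truth = n_truth, n_detected = n_det,
    sensitivity = ifelse(n_truth > 0L, n_det / n_truth, NA_real_),
    n_fp = n_fp, fp_per_image = n_fp / n_images
  )
}
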