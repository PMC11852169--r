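#' Scoring parameters
#'
#' @param low_threshold Confidence below which a region is low-confidence
#'   (excluded from candidacy, kept for bookkeeping).
#' @param high_threshold Confidence at or above which a region is
#'   high-confidence (threshold boundaries read as ">= passes").
#' @param ring_width_fraction Ring width as a fraction of the region's
#'   maximum interior radius; the width is `max(1, round(r_max * fraction))`.
#' @param vessel_overlap_threshold Dark regions whose outer band contains a
#'   larger vessel-pixel fraction than this are excluded as vessel-fused.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(low_threshold = 0.15, high_threshold = 0.35,
                           ring_width_fraction = 0.25,
                           vessel_overlap_threshold = 0.35) {
  if (low_threshold < 0 || high_threshold <= low_threshold) {
    config_error("need 0 <= low_threshold < high_threshold")
  }
  structure(
    list(
      low_threshold = low_threshold, high_threshold = high_threshold,
      ring_width_fraction = ring_width_fraction,
      vessel_overlap_threshold = vessel_overlap_threshold
    ),
    class = "scoring_params"
  )
}

#' Signed Euclidean distance field of a binary mask
#'
#' Positive inside the mask, negative outside, magnitude equal to the
#' Euclidean distance to the nearest pixel on the other side (exact
#' Euclidean distance transform; equivalent within half a pixel to a
#' fast-marching signed distance).
#'
#' @param mask Logical (or 0/1) matrix; must contain at least one `TRUE`.
#' @return Numeric matrix, same shape.
#' @export
signed_distance_field <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) input_error("signed distance of an empty mask is undefined")
  m <- mask
  storage.mode(m) <- "double"
  inside <- EBImage::distmap(m)
  if (all(mask)) {
    return(matrix(as.numeric(inside), nrow(mask), ncol(mask)))
  }
  outside <- EBImage::distmap(1 - m)
  matrix(as.numeric(inside) - as.numeric(outside), nrow(mask), ncol(mask))
}

# Per-region signed-distance geometry on a padded bounding-box crop.
# Returns the crop window, the signed distance within it, the maximum
# interior distance r_max, the interior-distance centroid (full-image
# coordinates) and the ring width w.
region_geometry <- function(region, ring_width_fraction = 0.25) {
  dims <- region$dims
  nr <- dims[1]
  bb <- region$bbox
  r <- ((region$idx - 1L) %% nr) + 1L
  cl <- ((region$idx - 1L) %/% nr) + 1L

  crop <- function(pad) {
    w <- c(
      max(1L, bb[["r0"]] - pad), min(nr, bb[["r1"]] + pad),
      max(1L, bb[["c0"]] - pad), min(dims[2], bb[["c1"]] + pad)
    )
    m <- matrix(FALSE, w[2] - w[1] + 1L, w[4] - w[3] + 1L)
    m[cbind(r - w[1] + 1L, cl - w[3] + 1L)] <- TRUE
    list(win = w, mask = m)
  }

  c1 <- crop(2L)
  inside <- EBImage::distmap(c1$mask * 1)
  r_max <- max(inside)
  w <- max(1L, as.integer(round(r_max * ring_width_fraction)))

  c2 <- crop(w + 2L)
  sd <- signed_distance_field(c2$mask)
  peak <- which.max(sd)
  crows <- nrow(sd)
  centroid <- c(
    row = ((peak - 1L) %% crows) + 1L + c2$win[1] - 1L,
    col = ((peak - 1L) %/% crows) + 1L + c2$win[3] - 1L
  )
  list(win = c2$win, mask = c2$mask, sd = sd, r_max = r_max, w = w, centroid = centroid)
}

crop_to_full_idx <- function(which_local, win, dims) {
  crows <- win[2] - win[1] + 1L
  r <- ((which_local - 1L) %% crows) + 1L + win[1] - 1L
  cl <- ((which_local - 1L) %/% crows) + 1L + win[3] - 1L
  (cl - 1L) * dims[1] + r
}

#' Build the inner/outer ring pair of a candidate region
#'
#' The ring width is `w = max(1, round(r_max / 4))` by default.  The inner
#' ring is the interior band of depth `w` adjacent to the region boundary
#' (signed distance in `(0, w]`); the outer ring is the exterior band of
#' width `w` (signed distance in `[-w, 0)`), restricted to the field of
#' view.  Band means are taken on the working gray channel.
#'
#' @param gray A [gray_image()].
#' @param region A `candidate_region`.
#' @param ring_width_fraction Ring width as a fraction of `r_max`.
#' @return An object of class `ring_pair`: inner/outer pixel indices
#'   (column-major, full raster), `width_w`, `inner_mean`, `outer_mean`.
#' @export
build_ring_pair <- function(gray, region, ring_width_fraction = 0.25) {
  geo <- if (!is.null(region$geometry)) region$geometry else region_geometry(region, ring_width_fraction)
  w <- geo$w
  inner_loc <- which(geo$sd > 0 & geo$sd <= w)
  outer_loc <- which(geo$sd < 0 & geo$sd >= -w)
  inner_idx <- crop_to_full_idx(inner_loc, geo$win, region$dims)
  outer_idx <- crop_to_full_idx(outer_loc, geo$win, region$dims)
  outer_idx <- outer_idx[gray$fov[outer_idx]]
  if (!length(outer_idx)) {
    scoring_error(sprintf(
      "region %s: outer ring entirely outside the field of view",
      region$id %||% "?"
    ))
  }
  structure(
    list(
      inner_idx = inner_idx, outer_idx = outer_idx, width_w = w,
      inner_mean = mean(gray$pixels[inner_idx]),
      outer_mean = mean(gray$pixels[outer_idx])
    ),
    class = "ring_pair"
  )
}

#' Ring-contrast confidence level
#'
#' Ratio of the absolute intensity difference between the outer and inner
#' ring bands to the inner-ring intensity.  Invariant under multiplicative
#' illumination changes.  A zero inner mean (degenerate black region) gives
#' `Inf` with a warning, which buckets as high confidence.
#'
#' @param rings A `ring_pair` from [build_ring_pair()].
#' @return Nonnegative confidence value.
#' @export
confidence_level <- function(rings) {
  if (rings$inner_mean == 0) {
    warning("degenerate region with zero inner-ring intensity; confidence = Inf")
    return(Inf)
  }
  abs(rings$outer_mean - rings$inner_mean) / rings$inner_mean
}

#' Map a confidence value to its bucket
#'
#' @param confidence Nonnegative value.
#' @param params A [scoring_params()].
#' @return `"LOW"`, `"INDETERMINATE"`, or `"HIGH"` (boundaries inclusive on
#'   the upper bucket: 0.15 is indeterminate, 0.35 is high).
#' @export
bucket_confidence <- function(confidence, params = scoring_params()) {
  ifelse(confidence >= params$high_threshold, "HIGH",
    ifelse(confidence >= params$low_threshold, "INDETERMINATE", "LOW")
  )
}

#' Score, bucket, and vessel-filter candidate regions
#'
#' Each region receives its ring pair, confidence, and bucket.  Dark-polarity
#' regions whose outer band overlaps the vessel mask by more than
#' `vessel_overlap_threshold` are flagged `vessel_excluded` and no longer
#' count as high-confidence (vessel-fused spots).  Low-confidence regions
#' are retained (they do not block training patches but are bookkept).
#' Regions whose outer ring cannot be formed are dropped with a warning.
#'
#' @param regions List of `candidate_region`s from
#'   [extract_candidate_regions()].
#' @param vessel_mask Logical matrix from [derive_vessel_mask()].
#' @param gray The [gray_image()].
#' @param params A [scoring_params()].
#' @return The scored region list.
#' @export
filter_and_bucket <- function(regions, vessel_mask, gray,
                              params = scoring_params()) {
  out <- list()
  for (region in regions) {
    geo <- region_geometry(region, params$ring_width_fraction)
    region$geometry <- geo
    region$r_max <- geo$r_max
    region$centroid <- geo$centroid
    rings <- tryCatch(
      build_ring_pair(gray, region, params$ring_width_fraction),
      retilab_scoring_error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(rings)) next
    region$rings <- rings
    region$confidence <- confidence_level(rings)
    region$bucket <- bucket_confidence(region$confidence, params)
    vfrac <- if (length(rings$outer_idx)) mean(vessel_mask[rings$outer_idx]) else 0
    region$vessel_fraction <- vfrac
    region$vessel_excluded <- identical(region$polarity, "DARK") &&
      vfrac > params$vessel_overlap_threshold
    out[[length(out) + 1L]] <- region
  }
  out
}

# High-confidence regions that survived the vessel filter.
high_regions <- function(regions) {
  Filter(function(r) identical(r$bucket, "HIGH") && !isTRUE(r$vessel_excluded), regions)
}

# Union mask of indeterminate-bucket region pixels (blocks training patches).
indeterminate_mask <- function(regions, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (r in regions) {
    if (identical(r$bucket, "INDETERMINATE")) m[r$idx] <- TRUE
  }
  m
}

#' Serialize scored regions to JSON lines
#'
#' One record per region: id, polarity, area, centroid, r_max, confidence,
#' bucket, vessel_excluded, lesion_type, bbox.  Coordinates are emitted
#' 0-based (row, col), bounding boxes as half-open `[r0, r1) x [c0, c1)`.
#'
#' @param regions Scored region list.
#' @param path Output file; `NULL` returns the JSON lines as a character
#'   vector.
#' @return The JSON lines, invisibly when written to a file.
#' @export
regions_to_json <- function(regions, path = NULL) {
  lines <- vapply(regions, function(r) {
    jsonlite::toJSON(
      list(
        id = r$id, polarity = r$polarity, area = r$area,
        centroid = if (is.null(r$centroid)) NULL else as.integer(r$centroid) - 1L,
        r_max = r$r_max, confidence = r$confidence,
        bucket = r$bucket %||% NA_character_,
        vessel_excluded = isTRUE(r$vessel_excluded),
        lesion_type = r$lesion_type %||% NA_character_,
        bbox = c(r$bbox[["r0"]] - 1L, r$bbox[["r1"]], r$bbox[["c0"]] - 1L, r$bbox[["c1"]])
      ),
      auto_unbox = TRUE, null = "null", digits = NA
    )
  }, character(1))
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}
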