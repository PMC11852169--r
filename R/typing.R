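#' Lesion typing parameters
#'
#' @param pca_ratio_threshold Eigenvalue-ratio threshold separating round
#'   regions (microaneurysms) from elongated ones (hemorrhages).
#' @param ma_size_fraction Maximum microaneurysm area as a fraction of the
#'   image area (1/200th of the image).
#' @param soft_exudate_fraction Minimum fraction of shell pixels brighter
#'   than the core mean for a soft ("cotton-wool") exudate.
#' @return An object of class `typing_params`.
#' @export
typing_params <- function(pca_ratio_threshold = 1.25,
                          ma_size_fraction = 1 / 200,
                          soft_exudate_fraction = 0.15) {
  if (pca_ratio_threshold <= 0 || ma_size_fraction <= 0 ||
      soft_exudate_fraction <= 0) {
    config_error("typing thresholds must be positive")
  }
  structure(
    list(
      pca_ratio_threshold = pca_ratio_threshold,
      ma_size_fraction = ma_size_fraction,
      soft_exudate_fraction = soft_exudate_fraction
    ),
    class = "typing_params"
  )
}

#' Boundary elongation ratio via principal component analysis
#'
#' Ratio of the two eigenvalues of the 2x2 covariance matrix of the region
#' boundary coordinates (largest over smallest).  A ratio near 1 indicates
#' a round boundary; larger values indicate elongation.  Degenerate
#' (collinear) boundaries return `Inf` and classify as elongated.
#'
#' @param boundary Numeric matrix of boundary coordinates, one `(row, col)`
#'   per row.
#' @return Elongation ratio, always >= 1 (or `Inf`).
#' @export
elongation_ratio <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3L) {
    return(Inf)
  }
  ev <- eigen(stats::cov(boundary), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= max(ev[1], 0) * 1e-9) {
    return(Inf)
  }
  ev[1] / ev[2]
}

#' Classify a dark high-confidence region as microaneurysm or hemorrhage
#'
#' A microaneurysm must be both round (elongation ratio at most
#' `pca_ratio_threshold`) and small (area below `ma_size_fraction` of the
#' image area); either violation yields a hemorrhage.
#'
#' @param region A scored dark `candidate_region`.
#' @param image_area Total image area in pixels.
#' @param params A [typing_params()].
#' @return `"microaneurysm"` or `"hemorrhage"`.
#' @export
classify_bleeding <- function(region, image_area, params = typing_params()) {
  ratio <- elongation_ratio(region$boundary)
  if (ratio <= params$pca_ratio_threshold &&
      region$area < image_area * params$ma_size_fraction) {
    "microaneurysm"
  } else {
    "hemorrhage"
  }
}

#' Classify a bright high-confidence region as hard or soft exudate
#'
#' The inner ring splits the lesion into a core (signed distance greater
#' than the ring width `w`) and a shell (the inner band itself).  Hard
#' exudates fall off monotonically toward the boundary, so no shell pixel
#' exceeds the core mean; the speckled texture of a soft exudate puts a
#' substantial fraction of shell pixels above it.  The region is soft when
#' that fraction exceeds `soft_exudate_fraction`.  Lesions too small to
#' have a core default to hard with a warning.
#'
#' @param gray The [gray_image()].
#' @param region A scored bright `candidate_region` (carries its ring
#'   geometry from [filter_and_bucket()]).
#' @param params A [typing_params()].
#' @return `"hard_exudate"` or `"soft_exudate"`.
#' @export
classify_exudate <- function(gray, region, params = typing_params()) {
  geo <- if (!is.null(region$geometry)) region$geometry else region_geometry(region)
  w <- geo$w
  core_loc <- which(geo$sd > w)
  shell_loc <- which(geo$sd > 0 & geo$sd <= w)
  if (!length(core_loc)) {
    warning(sprintf(
      "region %s too small for a core; defaulting to hard exudate",
      region$id %||% "?"
    ), call. = FALSE)
    return("hard_exudate")
  }
  core_idx <- crop_to_full_idx(core_loc, geo$win, region$dims)
  shell_idx <- crop_to_full_idx(shell_loc, geo$win, region$dims)
  f <- mean(gray$pixels[shell_idx] > mean(gray$pixels[core_idx]))
  if (f > params$soft_exudate_fraction) "soft_exudate" else "hard_exudate"
}

#' Assign lesion types to high-confidence regions
#'
#' Dark regions are split into microaneurysm/hemorrhage, bright regions
#' into hard/soft exudate.  Other buckets are left untyped.
#'
#' @param gray The [gray_image()].
#' @param regions Scored region list from [filter_and_bucket()].
#' @param params A [typing_params()].
#' @return The region list with `lesion_type` set on high-confidence
#'   regions.
#' @export
type_regions <- function(gray, regions, params = typing_params()) {
  image_area <- prod(dim(gray$pixels))
  lapply(regions, function(r) {
    if (identical(r$bucket, "HIGH") && !isTRUE(r$vessel_excluded)) {
      r$lesion_type <- if (identical(r$polarity, "DARK")) {
        classify_bleeding(r, image_area, params)
      } else {
        classify_exudate(gray, r, params)
      }
    }
    r
  })
}
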