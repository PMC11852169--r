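#' @importFrom stats rnorm runif cov spline approx
#' @importFrom utils head tail write.csv
NULL

# Canonical square side per imaging profile (pixels).
PROFILE_SIDES <- c(CFP = 1000L, UWF = 1500L)

#' Lesion type codes used in indexed label masks
#'
#' Indexed mask contract shared by every module: a single-channel PNG whose
#' pixel values are 0 = background, 1 = microaneurysm, 2 = hemorrhage,
#' 3 = hard exudate, 4 = soft exudate.
#'
#' @format Named integer vector of length 4.
#' @export
LESION_TYPES <- c(
  microaneurysm = 1L,
  hemorrhage = 2L,
  hard_exudate = 3L,
  soft_exudate = 4L
)

profile_side <- function(profile) {
  if (!is.character(profile) || length(profile) != 1L ||
      !profile %in% names(PROFILE_SIDES)) {
    config_error(sprintf(
      "unknown imaging profile '%s' (expected one of: %s)",
      paste(profile, collapse = ","), paste(names(PROFILE_SIDES), collapse = ", ")
    ))
  }
  PROFILE_SIDES[[profile]]
}

#' Working grayscale image with field-of-view mask
#'
#' Container for the single working intensity channel on which every
#' geometric computation operates.  `pixels` is a numeric matrix indexed
#' `[row, col]` with values in `[0, 1]`; `fov` is a logical matrix of the
#' same shape marking the usable imaged retina (the dark surround of a
#' fundus photograph is excluded, eroded so that descriptor ray samples
#' never leave the imaged area).
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param fov Logical matrix of the same shape, or `NULL` for all-`TRUE`.
#' @param profile Imaging profile, `"CFP"` or `"UWF"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, fov = NULL, profile = "CFP") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    input_error("pixels must be a numeric matrix")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    input_error("pixel values must be finite and within [0, 1]")
  }
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!identical(dim(fov), dim(pixels))) {
    input_error("fov and pixels must have identical shape")
  }
  structure(
    list(pixels = pixels, fov = fov, profile = profile),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %dx%d, profile %s, fov coverage %.1f%%\n",
    nrow(x$pixels), ncol(x$pixels), x$profile, 100 * mean(x$fov)
  ))
  invisible(x)
}

#' Load a retinal photograph and resize it to the profile's canonical square
#'
#' Reads a PNG/JPEG/TIFF raster and resamples it (bilinear) to the uniform
#' working dimensions: 1000x1000 for the CFP profile, 1500x1500 for UWF.
#' Aspect ratio is not preserved; non-square inputs are stretched.
#'
#' @param path Path to an image file.
#' @param profile `"CFP"` or `"UWF"`.
#' @return Numeric array `[row, col, channel]` in `[0, 1]` (channel dimension
#'   kept even for grayscale input), with attribute `profile`.
#' @export
load_and_resize <- function(path, profile = "CFP") {
  side <- profile_side(profile)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    input_error(sprintf("image file not found: '%s'", path))
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      input_error(sprintf("cannot decode image file '%s': %s", path, conditionMessage(e)))
    }
  )
  dat <- EBImage::imageData(img) # [x = col, y = row, (channel)]
  if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  nch <- dim(dat)[3]
  out <- array(0, c(side, side, nch))
  for (ch in seq_len(nch)) {
    plane <- t(dat[, , ch]) # -> [row, col]
    if (!all(dim(plane) == c(side, side))) {
      # EBImage::resize operates on the first two dims; bilinear by default.
      plane <- EBImage::resize(plane, w = side, h = side)
    }
    out[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  attr(out, "profile") <- profile
  out
}

#' Extract the working intensity channel
#'
#' Fundus lesions and vessels show the strongest contrast in the green
#' channel, which is therefore used as the working channel for 3-channel
#' input; single-channel input is used as is.  A field-of-view mask is
#' estimated and attached (Otsu threshold on the red channel when available,
#' then largest component, morphological closing, and erosion by the largest
#' descriptor scale).
#'
#' @param image Array `[row, col, channel]` in `[0, 1]` (1 or 3 channels), as
#'   returned by [load_and_resize()], or a plain 2-D matrix.
#' @param max_scale Largest descriptor scale (pixels) used to erode the FOV.
#' @param profile Imaging profile recorded on the result (taken from the
#'   `profile` attribute of `image` when present).
#' @return A [gray_image()].
#' @export
to_working_gray <- function(image, max_scale = 10L, profile = NULL) {
  if (is.null(profile)) profile <- attr(image, "profile") %||% "CFP"
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (!is.array(image) || length(dim(image)) != 3L) {
    input_error("image must be a [row, col, channel] array or a matrix")
  }
  nch <- dim(image)[3]
  if (!nch %in% c(1L, 3L)) {
    input_error(sprintf("expected 1 or 3 channels, got %d", nch))
  }
  px <- if (nch == 3L) image[, , 2L] else image[, , 1L]
  if (max(px) > 1 + 1e-8) px <- px / 255 # tolerate uint8-scaled input
  px <- pmin(pmax(px, 0), 1)
  fov_src <- if (nch == 3L) image[, , 1L] else px
  fov <- estimate_fov_mask(fov_src, max_scale = max_scale)
  gray_image(px, fov = fov, profile = profile)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the field-of-view mask of a fundus photograph
#'
#' Thresholds the image (Otsu when the intensity spread allows, a fixed 0.05
#' floor otherwise), keeps the largest connected component, closes small
#' gaps, and erodes by `max_scale` so that every descriptor ray of length
#' `max_scale` started inside the mask stays inside the imaged area.
#'
#' @param gray Numeric matrix in `[0, 1]` (or a [gray_image()]).
#' @param max_scale Erosion radius in pixels.
#' @return Logical matrix; all-`FALSE` (with a warning) for an all-dark image.
#' @export
estimate_fov_mask <- function(gray, max_scale = 10L) {
  px <- if (inherits(gray, "gray_image")) gray$pixels else gray
  thr <- 0.05
  if (diff(range(px)) > 1e-6) {
    thr_otsu <- tryCatch(EBImage::otsu(EBImage::Image(px)), error = function(e) NA_real_)
    if (is.finite(thr_otsu) && thr_otsu > 0 && thr_otsu < 1) thr <- thr_otsu
  }
  raw <- px > thr
  if (!any(raw)) {
    warning("all-dark image: empty field-of-view mask")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  lab <- label8(raw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(sizes)
  keep <- EBImage::closing(keep, EBImage::makeBrush(5L, "disc")) > 0
  # frame border counts as outside so the erosion also retreats from the
  # image edge, not only from the dark surround
  keep[c(1L, nrow(keep)), ] <- FALSE
  keep[, c(1L, ncol(keep))] <- FALSE
  brush <- EBImage::makeBrush(2L * as.integer(max_scale) + 1L, "disc")
  EBImage::erode(keep, brush) > 0
}

#' Read an indexed lesion label mask
#'
#' Single-channel PNG, values 0-4 per the [LESION_TYPES] contract (stored as
#' gray levels `k/255`).
#'
#' @param path PNG file path.
#' @return Integer matrix `[row, col]` with values 0-4.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) input_error(sprintf("mask file not found: '%s'", path))
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- dat[, , 1L]
  m <- t(dat)
  storage.mode(m) <- "double"
  out <- as.integer(round(m * 255))
  if (any(out > max(LESION_TYPES))) {
    input_error(sprintf("'%s' is not an indexed lesion mask (values 0-4)", path))
  }
  matrix(out, nrow(m), ncol(m))
}

#' Write an indexed lesion label mask
#'
#' @param mask Integer matrix with values 0-4 ([LESION_TYPES] contract).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  if (any(mask < 0L) || any(mask > max(LESION_TYPES))) {
    input_error("label mask values must be integers 0-4")
  }
  EBImage::writeImage(EBImage::Image(t(mask / 255)), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
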