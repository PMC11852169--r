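#' Parameters of the multiscale contrast shape descriptor
#'
#' The descriptor compares, at every pixel, the mean intensity along line
#' segments of length `d` (one per sampled direction) with the pixel's own
#' intensity.  Blob-like lesions show a consistent contrast in *every*
#' direction; curvilinear vessels show none along their own axis, which is
#' what separates the two.
#'
#' @param scales Segment lengths `d` in pixels (each >= 2).  The default
#'   `c(3, 5, 10)` targets small to mid-size lesions on 1000x1000 images.
#' @param n_directions Number of ray directions sampled uniformly on
#'   `[0, 2*pi)`; must be even and >= 4 so every direction has its opposite.
#'   The default 32 keeps the worst-case angular mismatch small enough
#'   (5.6 degrees) that a ray of the largest default scale stays within a
#'   3-pixel-wide vessel, which is what silences line centerlines in BLOB
#'   mode.
#' @param mode `"BLOB"` (all-direction contrast, lesions) or `"LINEAR"`
#'   (best-direction contrast, vessels).
#' @param polarity `"DARK"` (bleeding: lesion darker than background) or
#'   `"BRIGHT"` (exudate: lesion brighter).  Ignored in LINEAR mode.
#' @param contrast_floor Per-scale response floor (normalized intensity
#'   units) below which responses are zeroed before the multiscale merge.
#' @param vessel_floor LINEAR response threshold for the vessel mask.
#' @param min_area Minimum candidate-region area in pixels.
#' @return An object of class `mcsd_params`.
#' @export
mcsd_params <- function(scales = c(3L, 5L, 10L), n_directions = 32L,
                        mode = c("BLOB", "LINEAR"),
                        polarity = c("DARK", "BRIGHT"),
                        contrast_floor = 0.04, vessel_floor = 0.06,
                        min_area = 2L) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  scales <- as.integer(scales)
  n_directions <- as.integer(n_directions)
  if (length(scales) < 1L || any(scales < 2L)) {
    config_error("all MCSD scales must be >= 2")
  }
  if (n_directions < 4L || n_directions %% 2L != 0L) {
    config_error("n_directions must be even and >= 4")
  }
  structure(
    list(
      scales = sort(unique(scales)), n_directions = n_directions,
      mode = mode, polarity = polarity,
      contrast_floor = contrast_floor, vessel_floor = vessel_floor,
      min_area = as.integer(min_area)
    ),
    class = "mcsd_params"
  )
}

#' Directional mean-contrast at a single pixel (reference implementation)
#'
#' Mean of `d` intensities sampled at unit arc-length offsets `1..d` along
#' the ray from `center` at angle `theta` (bilinear interpolation, border
#' values replicated outside the image), minus the center intensity.  This
#' scalar loop is the reference oracle for the vectorized field computation.
#'
#' Sign convention: a dark blob on a bright background yields a positive
#' value, a bright blob a negative one.
#'
#' @param gray A [gray_image()] or numeric matrix.
#' @param center `c(row, col)`, 1-based.
#' @param d Segment length in pixels (>= 2).
#' @param theta Angle in radians with respect to the horizontal (column)
#'   axis; the row coordinate grows with `sin(theta)`.
#' @return Signed contrast value; attribute `clamped` is `TRUE` if any
#'   sample fell outside the image and was clamped to the border.
#' @export
directional_profile_contrast <- function(gray, center, d, theta) {
  px <- if (inherits(gray, "gray_image")) gray$pixels else gray
  d <- as.integer(d)
  if (d < 2L) config_error("segment length d must be >= 2")
  nr <- nrow(px)
  nc <- ncol(px)
  r <- center[1]
  cl <- center[2]
  dy <- sin(theta)
  dx <- cos(theta)
  total <- 0
  clamped <- FALSE
  for (k in seq_len(d)) {
    yy <- r + k * dy
    xx <- cl + k * dx
    y0 <- floor(yy)
    x0 <- floor(xx)
    wy <- yy - y0
    wx <- xx - x0
    r0 <- min(max(y0, 1), nr)
    r1 <- min(max(y0 + 1, 1), nr)
    c0 <- min(max(x0, 1), nc)
    c1 <- min(max(x0 + 1, 1), nc)
    if (y0 < 1 || y0 + 1 > nr || x0 < 1 || x0 + 1 > nc) clamped <- TRUE
    total <- total + ((1 - wy) * (1 - wx) * px[r0, c0] + (1 - wy) * wx * px[r0, c1] +
      wy * (1 - wx) * px[r1, c0] + wy * wx * px[r1, c1])
  }
  structure(total / d - px[r, cl], clamped = clamped)
}

# One vectorized pass over all directions and all scales.  For each direction
# the ray samples are whole-image bilinear shifts, accumulated in k order so
# the arithmetic matches directional_profile_contrast() bit for bit.  Returns,
# per scale, the directional minimum and maximum of the signed contrast.
mcsd_scale_extrema <- function(px, scales, n_directions) {
  nr <- nrow(px)
  nc <- ncol(px)
  scales <- sort(unique(as.integer(scales)))
  dmax <- max(scales)
  thetas <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  ns <- length(scales)
  cmin <- vector("list", ns)
  cmax <- vector("list", ns)
  for (th in thetas) {
    dy <- sin(th)
    dx <- cos(th)
    acc <- matrix(0, nr, nc)
    si <- 1L
    for (k in seq_len(dmax)) {
      yy <- k * dy
      xx <- k * dx
      y0 <- floor(yy)
      x0 <- floor(xx)
      wy <- yy - y0
      wx <- xx - x0
      r0 <- pmin(pmax(rows + y0, 1), nr)
      r1 <- pmin(pmax(rows + y0 + 1, 1), nr)
      c0 <- pmin(pmax(cols + x0, 1), nc)
      c1 <- pmin(pmax(cols + x0 + 1, 1), nc)
      acc <- acc + ((1 - wy) * (1 - wx) * px[r0, c0] + (1 - wy) * wx * px[r0, c1] +
        wy * (1 - wx) * px[r1, c0] + wy * wx * px[r1, c1])
      while (si <= ns && scales[si] == k) {
        cth <- acc / k - px
        cmin[[si]] <- if (is.null(cmin[[si]])) cth else pmin(cmin[[si]], cth)
        cmax[[si]] <- if (is.null(cmax[[si]])) cth else pmax(cmax[[si]], cth)
        si <- si + 1L
      }
    }
  }
  list(scales = scales, cmin = cmin, cmax = cmax)
}

rectify_field <- function(cmin, cmax, mode, polarity) {
  if (mode == "LINEAR") {
    # Best-direction signed contrast (dark curvilinear structures).  Using
    # the signed maximum rather than max |c| keeps the halo around dark
    # blobs silent: rays from a halo pixel into the blob give a *negative*
    # contrast there, while a genuine vessel pixel always has a
    # perpendicular direction with a large positive one.
    pmax(cmax, 0)
  } else if (polarity == "DARK") {
    pmax(cmin, 0) # positive contrast required in every direction
  } else {
    pmax(-cmax, 0) # negative contrast required in every direction
  }
}

new_contrast_field <- function(values, params, d) {
  p <- params
  p$scales <- as.integer(d)
  structure(
    list(values = values, params = p, source_shape = dim(values)),
    class = "contrast_field"
  )
}

#' @export
print.contrast_field <- function(x, ...) {
  cat(sprintf(
    "<contrast_field> %dx%d, mode %s/%s, scales [%s], max %.4f\n",
    nrow(x$values), ncol(x$values), x$params$mode, x$params$polarity,
    paste(x$params$scales, collapse = ","), max(x$values)
  ))
  invisible(x)
}

#' Contrast shape descriptor field at a single scale
#'
#' Computes the signed directional contrast `c(theta)` at every pixel for
#' `n_directions` angles and reduces over directions: BLOB mode keeps the
#' extremum nearest zero on the polarity's side and rectifies it (DARK:
#' `max(0, min_theta c)`, BRIGHT: `max(0, -max_theta c)`), so only pixels
#' with a consistent all-direction contrast respond; LINEAR mode keeps
#' `max_theta |c|`.  Pixels outside the field of view are zero.
#'
#' @param gray A [gray_image()].
#' @param d Segment length in pixels.
#' @param params An [mcsd_params()] (supplies directions, mode, polarity).
#' @return A `contrast_field`.
#' @export
shape_descriptor_field <- function(gray, d, params = mcsd_params()) {
  ext <- mcsd_scale_extrema(gray$pixels, d, params$n_directions)
  v <- rectify_field(ext$cmin[[1]], ext$cmax[[1]], params$mode, params$polarity)
  v[!gray$fov] <- 0
  new_contrast_field(v, params, d)
}

#' Multiscale blob field
#'
#' Per-scale BLOB fields are floored at `contrast_floor` (responses below it
#' are zeroed, mirroring the removal of low-contrast regions) and merged by
#' pixelwise maximum, so each lesion is represented by the scale that
#' resolves it best while the merged value stays a contrast magnitude.
#'
#' @param gray A [gray_image()].
#' @param params An [mcsd_params()]; `params$polarity` selects dark or
#'   bright lesions, mode is forced to BLOB.
#' @return A `contrast_field` carrying the full scale list.
#' @export
multiscale_blob_field <- function(gray, params = mcsd_params()) {
  params$mode <- "BLOB"
  ext <- mcsd_scale_extrema(gray$pixels, params$scales, params$n_directions)
  merged <- NULL
  for (i in seq_along(ext$scales)) {
    v <- rectify_field(ext$cmin[[i]], ext$cmax[[i]], "BLOB", params$polarity)
    v[v < params$contrast_floor] <- 0
    merged <- if (is.null(merged)) v else pmax(merged, v)
  }
  merged[!gray$fov] <- 0
  new_contrast_field(merged, params, ext$scales)
}

#' Vessel mask from the linear-mode descriptor
#'
#' Marks curvilinear dark structures: pixels whose multiscale LINEAR
#' response reaches `vessel_floor` while their BLOB/DARK response stays
#' below `contrast_floor`.  Only used by the ring vessel-adjacency filter;
#' this is not a general vessel segmentation.
#'
#' @param gray A [gray_image()].
#' @param params An [mcsd_params()].
#' @return Logical matrix.
#' @export
derive_vessel_mask <- function(gray, params = mcsd_params()) {
  ext <- mcsd_scale_extrema(gray$pixels, params$scales, params$n_directions)
  lin <- blob <- NULL
  for (i in seq_along(ext$scales)) {
    vl <- rectify_field(ext$cmin[[i]], ext$cmax[[i]], "LINEAR", params$polarity)
    vb <- rectify_field(ext$cmin[[i]], ext$cmax[[i]], "BLOB", "DARK")
    lin <- if (is.null(lin)) vl else pmax(lin, vl)
    blob <- if (is.null(blob)) vb else pmax(blob, vb)
  }
  lin >= params$vessel_floor & blob < params$contrast_floor & gray$fov
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass.
label8 <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) {
    return(lab)
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  a1 <- lab[-nr, -nc]
  b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc]
  b2 <- lab[-nr, -1]
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1])
      rb <- find(pairs[i, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

region_boundary <- function(idx, dims) {
  nr <- dims[1]
  nc <- dims[2]
  inreg <- logical(nr * nc)
  inreg[idx] <- TRUE
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  on_border <- r == 1L | r == nr | cl == 1L | cl == nc
  nb_missing <- on_border
  ok <- !on_border
  if (any(ok)) {
    i <- idx[ok]
    nb_missing[ok] <- !(inreg[i - 1L] & inreg[i + 1L] & inreg[i - nr] & inreg[i + nr])
  }
  cbind(row = r[nb_missing], col = cl[nb_missing])
}

#' Extract candidate lesion regions from a contrast field
#'
#' 8-connected components of the strictly positive part of the field;
#' components smaller than `min_area` pixels are treated as noise and
#' dropped.  Regions are returned in deterministic order (bounding-box
#' top-left, row first).
#'
#' @param field A `contrast_field` (nonnegative values).
#' @param gray The [gray_image()] the field was computed on.
#' @param min_area Minimum component area in pixels (default from
#'   `field$params`).
#' @return List of `candidate_region` objects with mask indices (`idx`,
#'   column-major into the full raster), `area`, `bbox` `(r0, r1, c0, c1)`,
#'   `boundary` coordinates, `polarity`, and `peak_contrast`.
#' @export
extract_candidate_regions <- function(field, gray, min_area = NULL) {
  if (min(field$values) < 0) input_error("contrast field must be nonnegative")
  if (is.null(min_area)) min_area <- field$params$min_area %||% 2L
  mask <- field$values > 0
  if (!any(mask)) {
    return(list())
  }
  lab <- label8(mask)
  dims <- dim(mask)
  nr <- dims[1]
  pos <- which(lab > 0L)
  groups <- split(pos, lab[pos])
  regions <- list()
  for (g in groups) {
    if (length(g) < min_area) next
    r <- ((g - 1L) %% nr) + 1L
    cl <- ((g - 1L) %/% nr) + 1L
    regions[[length(regions) + 1L]] <- structure(
      list(
        idx = g,
        dims = dims,
        area = length(g),
        bbox = c(r0 = min(r), r1 = max(r), c0 = min(cl), c1 = max(cl)),
        boundary = region_boundary(g, dims),
        polarity = field$params$polarity,
        peak_contrast = max(field$values[g])
      ),
      class = "candidate_region"
    )
  }
  if (!length(regions)) {
    return(list())
  }
  ord <- order(
    vapply(regions, function(x) x$bbox[["r0"]], numeric(1)),
    vapply(regions, function(x) x$bbox[["c0"]], numeric(1)),
    vapply(regions, function(x) min(x$idx), numeric(1))
  )
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$id <- i
  regions
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf(
    "<candidate_region #%s> area %d px, polarity %s, bucket %s, confidence %s\n",
    x$id %||% "?", x$area, x$polarity, x$bucket %||% "unscored",
    if (is.null(x$confidence)) "NA" else sprintf("%.3f", x$confidence)
  ))
  invisible(x)
}

#' Build a candidate region directly from a binary mask
#'
#' Useful for applying the scoring and typing rules to ground-truth or
#' externally supplied masks.
#'
#' @param mask Logical matrix (one connected region expected).
#' @param polarity `"DARK"` or `"BRIGHT"`.
#' @return A `candidate_region`.
#' @export
region_from_mask <- function(mask, polarity = c("DARK", "BRIGHT")) {
  polarity <- match.arg(polarity)
  idx <- which(mask > 0)
  if (!length(idx)) input_error("empty mask")
  dims <- dim(mask)
  r <- ((idx - 1L) %% dims[1]) + 1L
  cl <- ((idx - 1L) %/% dims[1]) + 1L
  structure(
    list(
      idx = idx, dims = dims, area = length(idx),
      bbox = c(r0 = min(r), r1 = max(r), c0 = min(cl), c1 = max(cl)),
      boundary = region_boundary(idx, dims),
      polarity = polarity, id = 1L
    ),
    class = "candidate_region"
  )
}

region_mask <- function(region) {
  m <- matrix(FALSE, region$dims[1], region$dims[2])
  m[region$idx] <- TRUE
  m
}
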