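#' Synthetic fundus scene configuration
#'
#' Phenotype priors for the seeded scene generator: a smooth bright
#' background with an illumination gradient and Gaussian noise, dark
#' curvilinear vessels, small round dark microaneurysms, larger irregular
#' dark hemorrhages (optionally vessel-adjacent), bright hard exudates with
#' a monotone radial falloff, and bright soft exudates with a speckled
#' "cotton-wool" texture.  Contrasts are in normalized intensity units;
#' the ranges deliberately straddle the 0.15/0.35 confidence thresholds so
#' all three buckets are exercised.
#'
#' @param side Canvas side in pixels (>= 256).
#' @param n_microaneurysm,n_hemorrhage,n_hard_exudate,n_soft_exudate,n_vessels
#'   Object counts.
#' @param bg_mean,bg_amplitude,noise_sd Background level, low-frequency
#'   illumination amplitude, and pixel noise standard deviation.
#' @param vessel_width,vessel_depth Vessel Gaussian cross-section width
#'   range (pixels) and darkness range.
#' @param ma_radius,ma_contrast Microaneurysm radius (pixels) and darkness.
#' @param hem_area,hem_axis_ratio,hem_contrast Hemorrhage area range
#'   (pixels, sampled log-uniformly), elongation, and darkness.
#' @param hem_vessel_fraction Fraction of hemorrhages planted adjacent to a
#'   vessel (flagged `fused` in the records).
#' @param hex_radius,hex_contrast Hard-exudate radius and peak brightness.
#' @param sex_radius,sex_contrast,sex_speckle_fraction Soft-exudate radius,
#'   brightness, and fraction of speckled pixels.
#' @param margin Lesion-free border in pixels.
#' @param retry_budget Placement attempts per lesion before failing.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(side = 256L, n_microaneurysm = 4L, n_hemorrhage = 2L,
                         n_hard_exudate = 3L, n_soft_exudate = 1L,
                         n_vessels = 5L, bg_mean = 0.55, bg_amplitude = 0.06,
                         noise_sd = 0.01, vessel_width = c(2, 5),
                         vessel_depth = c(0.15, 0.3), ma_radius = c(1, 3),
                         ma_contrast = c(0.15, 0.35), hem_area = c(50, 2000),
                         hem_axis_ratio = c(1.5, 4),
                         hem_contrast = c(0.15, 0.35),
                         hem_vessel_fraction = 0, hex_radius = c(3, 7),
                         hex_contrast = c(0.15, 0.4), sex_radius = c(5, 10),
                         sex_contrast = c(0.15, 0.4),
                         sex_speckle_fraction = 0.3, margin = 24L,
                         retry_budget = 100L) {
  if (side < 256L) config_error("scene canvas must be at least 256x256")
  cfg <- as.list(environment())
  cfg$side <- as.integer(side)
  structure(cfg, class = "scene_config")
}

runif1 <- function(range) runif(1, range[1], range[2])

disc_offsets <- function(r) {
  ir <- ceiling(r)
  dr <- -ir:ir
  grid <- expand.grid(dr = dr, dc = dr)
  d <- sqrt(grid$dr^2 + grid$dc^2)
  list(dr = grid$dr, dc = grid$dc, d = d)
}

#' Plant one lesion phenotype into an intensity raster
#'
#' Draws the requested phenotype at `center` using the priors in `config`
#' (sampling from the current RNG stream), blends it additively with
#' clipping to `[0, 1]`, and returns the updated raster with the lesion
#' mask and its record.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param type One of `names(LESION_TYPES)`.
#' @param config A [scene_config()].
#' @param center `c(row, col)`; must leave the phenotype inside the canvas.
#' @return List with `pixels`, `idx` (mask pixel indices), and `record`.
#' @export
plant_lesion <- function(pixels, type, config, center) {
  nr <- nrow(pixels)
  r0 <- center[1]
  c0 <- center[2]
  fused <- FALSE
  axis_ratio <- NA_real_
  requested_area <- NA_real_
  if (type == "microaneurysm" || type == "hard_exudate" || type == "soft_exudate") {
    radius <- runif1(switch(type,
      microaneurysm = config$ma_radius,
      hard_exudate = config$hex_radius,
      soft_exudate = config$sex_radius
    ))
    off <- disc_offsets(radius)
    keep <- off$d <= radius
    rr <- r0 + off$dr[keep]
    cc <- c0 + off$dc[keep]
    d <- off$d[keep]
    idx <- (cc - 1L) * nr + rr
    if (type == "microaneurysm") {
      contrast <- runif1(config$ma_contrast)
      pixels[idx] <- pixels[idx] - contrast
    } else if (type == "hard_exudate") {
      contrast <- runif1(config$hex_contrast)
      pixels[idx] <- pixels[idx] + contrast * (1 - 0.4 * (d / radius)^2)
    } else {
      contrast <- runif1(config$sex_contrast)
      pixels[idx] <- pixels[idx] + 0.9 * contrast * (1 - 0.25 * (d / radius)^2)
      speck <- runif(length(idx)) < config$sex_speckle_fraction
      pixels[idx[speck]] <- pixels[idx[speck]] + 0.3 * contrast
    }
  } else if (type == "hemorrhage") {
    requested_area <- exp(runif(1, log(config$hem_area[1]), log(config$hem_area[2])))
    axis_ratio <- runif1(config$hem_axis_ratio)
    b <- sqrt(requested_area / (pi * axis_ratio))
    a <- axis_ratio * b
    phi <- runif(1, 0, pi)
    p1 <- runif(1, 0, 2 * pi)
    p2 <- runif(1, 0, 2 * pi)
    contrast <- runif1(config$hem_contrast)
    off <- disc_offsets(a * 1.2)
    u <- cos(phi) * off$dc + sin(phi) * off$dr
    v <- -sin(phi) * off$dc + cos(phi) * off$dr
    rho <- sqrt((u / a)^2 + (v / b)^2)
    ang <- atan2(v / b, u / a)
    wobble <- 1 + 0.12 * sin(2 * ang + p1) + 0.08 * sin(3 * ang + p2)
    keep <- rho <= wobble
    rr <- r0 + off$dr[keep]
    cc <- c0 + off$dc[keep]
    inside <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(pixels)
    idx <- (cc[inside] - 1L) * nr + rr[inside]
    pixels[idx] <- pixels[idx] - contrast
    radius <- b
  } else {
    input_error(sprintf("unknown lesion type '%s'", type))
  }
  pixels <- pmin(pmax(pixels, 0), 1)
  list(
    pixels = pixels, idx = idx,
    record = list(
      type = type, center = c(row = r0, col = c0), radius = radius,
      area = length(idx), requested_area = requested_area,
      contrast = contrast, axis_ratio = axis_ratio, fused = fused
    )
  )
}

#' Render a random vessel tree into a raster
#'
#' Smooth spline curves through jittered waypoints with a Gaussian
#' cross-section whose width tapers along the curve.
#'
#' @param pixels Numeric matrix.
#' @param config A [scene_config()].
#' @return List with `pixels`, `vessel_mask` (full cross-section extent),
#'   and `centerlines` (list of coordinate matrices, one per vessel).
#' @export
render_vessels <- function(pixels, config) {
  side <- nrow(pixels)
  vessel_mask <- matrix(FALSE, side, side)
  influence <- matrix(FALSE, side, side) # full photometric skirt (3 sigma)
  centerlines <- list()
  n <- config$n_vessels
  if (n < 1L) {
    return(list(
      pixels = pixels, vessel_mask = vessel_mask,
      influence = influence, centerlines = centerlines
    ))
  }
  for (v in seq_len(n)) {
    horizontal <- runif(1) < 0.5
    ends <- sort(runif(2, 0.1, 0.9)) * side
    t0 <- seq(0, 1, length.out = 6L)
    base <- seq(ends[1], ends[2], length.out = 6L)
    cross <- runif(1, 0.15, 0.85) * side + cumsum(rnorm(6L, sd = side / 14))
    cross <- pmin(pmax(cross, 3), side - 3)
    along <- seq(min(base) - 1, max(base) + 1, length.out = 6L)
    ts <- seq(0, 1, length.out = 4L * side)
    xs <- stats::spline(t0, along, xout = ts)$y
    ys <- stats::spline(t0, cross, xout = ts)$y
    if (horizontal) {
      rows <- ys
      cols <- xs
    } else {
      rows <- xs
      cols <- ys
    }
    keep <- rows >= 2 & rows <= side - 1 & cols >= 2 & cols <= side - 1
    rows <- rows[keep]
    cols <- cols[keep]
    if (length(rows) < 10L) next
    pts <- unique(cbind(round(rows), round(cols)))
    centerlines[[length(centerlines) + 1L]] <- pts
    width0 <- runif1(config$vessel_width)
    depth <- runif1(config$vessel_depth)
    nseg <- 3L
    breaks <- floor(seq(1L, nrow(pts) + 1L, length.out = nseg + 1L))
    for (s in seq_len(nseg)) {
      seg <- pts[breaks[s]:(breaks[s + 1L] - 1L), , drop = FALSE]
      if (!nrow(seg)) next
      w <- width0 * (1 - 0.4 * (s - 1) / max(1L, nseg - 1L)) # taper
      sigma <- w / 2
      pm <- matrix(1, side, side)
      pm[(seg[, 2] - 1L) * side + seg[, 1]] <- 0
      d <- matrix(as.numeric(EBImage::distmap(pm)), side, side)
      prof <- depth * exp(-d^2 / (2 * sigma^2))
      prof[d > 3 * sigma] <- 0
      pixels <- pixels - prof
      vessel_mask <- vessel_mask | (d <= w / 2)
      influence <- influence | (d <= 3 * sigma)
    }
  }
  list(
    pixels = pmin(pmax(pixels, 0), 1),
    vessel_mask = vessel_mask, influence = influence, centerlines = centerlines
  )
}

smooth_background <- function(side, mean_level, amplitude) {
  idx <- seq_len(side) / side
  bg <- matrix(mean_level, side, side)
  for (i in 1:3) {
    fr <- runif(1, 0.5, 1.5)
    fc <- runif(1, 0.5, 1.5)
    ph <- runif(2, 0, 2 * pi)
    wave <- outer(
      cos(2 * pi * fr * idx + ph[1]),
      cos(2 * pi * fc * idx + ph[2])
    )
    bg <- bg + (amplitude / 3) * wave
  }
  bg
}

#' Generate a synthetic fundus scene with ground truth
#'
#' Renders background, vessels, and the requested lesions (pairwise
#' disjoint, except hemorrhages deliberately planted against a vessel),
#' adds pixel noise, and returns the scene with per-type truth masks and a
#' per-lesion record list.  Identical seeds give bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_scene`: `gray` (a [gray_image()]),
#'   `vessel_mask`, `vessel_centerlines`, `lesion_masks` (per type),
#'   `records`, `config`, `seed`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  counts <- c(
    microaneurysm = config$n_microaneurysm,
    hemorrhage = config$n_hemorrhage,
    hard_exudate = config$n_hard_exudate,
    soft_exudate = config$n_soft_exudate
  )
  if (any(counts < 0L)) config_error("lesion counts must be nonnegative")
  side <- config$side
  with_seed(seed, {
    px <- smooth_background(side, config$bg_mean, config$bg_amplitude)
    ves <- render_vessels(px, config)
    px <- ves$pixels
    occupied <- matrix(FALSE, side, side)
    if (any(ves$influence)) {
      # non-fused lesions must stay clear of the whole vessel skirt so that
      # their outer scoring ring never samples vessel-darkened pixels
      occupied <- EBImage::dilate(ves$influence, EBImage::makeBrush(9L, "disc")) > 0
    }
    border <- config$margin
    occupied[c(seq_len(border), side - seq_len(border) + 1L), ] <- TRUE
    occupied[, c(seq_len(border), side - seq_len(border) + 1L)] <- TRUE

    lesion_masks <- lapply(names(LESION_TYPES), function(t) matrix(FALSE, side, side))
    names(lesion_masks) <- names(LESION_TYPES)
    records <- list()
    for (type in names(counts)) {
      for (i in seq_len(counts[[type]])) {
        fused <- type == "hemorrhage" && length(ves$centerlines) &&
          runif(1) < config$hem_vessel_fraction
        placed <- FALSE
        for (attempt in seq_len(config$retry_budget)) {
          if (fused) {
            cl <- ves$centerlines[[sample.int(length(ves$centerlines), 1L)]]
            pt <- cl[sample.int(nrow(cl), 1L), ]
            center <- pt + sample(-2:2, 2L, replace = TRUE)
            center <- pmin(pmax(center, border + 1L), side - border)
          } else {
            center <- c(
              sample((border + 1L):(side - border), 1L),
              sample((border + 1L):(side - border), 1L)
            )
          }
          res <- plant_lesion(px, type, config, center)
          blocked <- if (fused) {
            any(lesion_masks$microaneurysm[res$idx] | lesion_masks$hemorrhage[res$idx] |
              lesion_masks$hard_exudate[res$idx] | lesion_masks$soft_exudate[res$idx])
          } else {
            any(occupied[res$idx])
          }
          if (blocked) next
          px <- res$pixels
          res$record$fused <- fused
          res$record$idx <- res$idx
          records[[length(records) + 1L]] <- res$record
          lesion_masks[[type]][res$idx] <- TRUE
          grown <- matrix(FALSE, side, side)
          grown[res$idx] <- TRUE
          occupied <- occupied | (EBImage::dilate(grown, EBImage::makeBrush(7L, "disc")) > 0)
          placed <- TRUE
          break
        }
        if (!placed) {
          generation_error(sprintf(
            "could not place %s #%d without overlap within %d attempts",
            type, i, config$retry_budget
          ))
        }
      }
    }
    if (config$noise_sd > 0) {
      px <- px + matrix(rnorm(side^2, sd = config$noise_sd), side, side)
    }
    px <- pmin(pmax(px, 0), 1)
    structure(
      list(
        gray = gray_image(px, fov = matrix(TRUE, side, side), profile = "CFP"),
        vessel_mask = ves$vessel_mask,
        vessel_centerlines = ves$centerlines,
        lesion_masks = lesion_masks,
        records = records,
        config = config,
        seed = seed
      ),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %dx%d, %d lesions, %d vessels, seed %d\n",
    nrow(x$gray$pixels), ncol(x$gray$pixels), length(x$records),
    length(x$vessel_centerlines), x$seed
  ))
  invisible(x)
}

#' Indexed truth label mask of a scene
#'
#' @param scene A `synthetic_scene`.
#' @return Integer matrix with the [LESION_TYPES] coding.
#' @export
scene_label_mask <- function(scene) {
  side <- nrow(scene$gray$pixels)
  m <- matrix(0L, side, side)
  for (t in names(LESION_TYPES)) m[scene$lesion_masks[[t]]] <- LESION_TYPES[[t]]
  m
}

#' Per-lesion truth masks of a scene
#'
#' @param scene A `synthetic_scene`.
#' @param types Lesion types to include.
#' @return List of pixel-index vectors, one per planted lesion.
#' @export
scene_truth_regions <- function(scene, types = names(LESION_TYPES)) {
  recs <- Filter(function(r) r$type %in% types, scene$records)
  lapply(recs, function(r) r$idx)
}

#' Write a scene to disk
#'
#' Image PNG, indexed truth mask PNG, vessel mask PNG, and a records JSON.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(
    EBImage::Image(t(scene$gray$pixels)),
    file.path(dir, "image.png"), type = "png", bits.per.sample = 16L
  )
  write_label_mask(scene_label_mask(scene), file.path(dir, "truth_mask.png"))
  write_label_mask(scene$vessel_mask * 1L, file.path(dir, "vessel_mask.png"))
  recs <- lapply(scene$records, function(r) {
    r$idx <- NULL
    r$center <- as.integer(r$center) - 1L
    r
  })
  jsonlite::write_json(recs, file.path(dir, "records.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
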