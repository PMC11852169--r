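#' Patch mining parameters
#'
#' Growth schedule for clean training windows: start at `init_side`, grow by
#' `step` pixels per side while no indeterminate pixel is inside, stop at
#' `max_side`; keep the window only if the final clean side reaches
#' `min_side`.
#'
#' @param init_side,step,min_side,max_side Pixels.
#' @param max_attempts_factor Background centers are rejection-sampled up to
#'   `max_attempts_factor * quota` times.
#' @return An object of class `patch_params`.
#' @export
patch_params <- function(init_side = 10L, step = 5L, min_side = 60L,
                         max_side = 120L, max_attempts_factor = 50L) {
  structure(
    list(
      init_side = as.integer(init_side), step = as.integer(step),
      min_side = as.integer(min_side), max_side = as.integer(max_side),
      max_attempts_factor = as.integer(max_attempts_factor)
    ),
    class = "patch_params"
  )
}

#' Grow a clean square window around a center
#'
#' Starting from a `init_side` window centered on `center`, the window grows
#' by `step` pixels per side as long as it contains no indeterminate pixel;
#' on the first violation it reverts to the last clean size.  Windows are
#' clipped to the image bounds and the clipped side counts toward the size
#' tests.  Returns `NULL` when the final clean side is below `min_side`.
#'
#' @param center `c(row, col)`.
#' @param indeterminate_mask Logical matrix of blocked pixels.
#' @param bounds Raster dimensions `c(nrow, ncol)` (defaults to the mask's).
#' @param params A [patch_params()].
#' @return `c(r0, r1, c0, c1)` (1-based, inclusive) of a square clean
#'   window, or `NULL`.
#' @export
grow_clean_patch <- function(center, indeterminate_mask,
                             bounds = dim(indeterminate_mask),
                             params = patch_params()) {
  nr <- bounds[1]
  nc <- bounds[2]
  best <- NULL
  for (side in seq(params$init_side, params$max_side, by = params$step)) {
    r0 <- center[1] - side %/% 2L
    c0 <- center[2] - side %/% 2L
    win <- c(
      r0 = max(r0, 1L), r1 = min(r0 + side - 1L, nr),
      c0 = max(c0, 1L), c1 = min(c0 + side - 1L, nc)
    )
    if (any(indeterminate_mask[win[1]:win[2], win[3]:win[4]])) break
    best <- win
  }
  if (is.null(best)) {
    return(NULL)
  }
  side_eff <- min(best[2] - best[1] + 1L, best[4] - best[3] + 1L)
  if (side_eff < params$min_side) {
    return(NULL)
  }
  # center a square of the effective side inside the (possibly clipped) window
  sq <- function(lo, hi) {
    extra <- (hi - lo + 1L) - side_eff
    lo <- lo + extra %/% 2L
    c(lo, lo + side_eff - 1L)
  }
  rr <- sq(best[1], best[2])
  cc <- sq(best[3], best[4])
  c(r0 = rr[1], r1 = rr[2], c0 = cc[1], c1 = cc[2])
}

new_training_patch <- function(gray, win, label_masks, kind, type, source = NA) {
  rows <- win[1]:win[2]
  cols <- win[3]:win[4]
  structure(
    list(
      window = gray$pixels[rows, cols],
      label_masks = lapply(label_masks, function(m) m[rows, cols]),
      origin = c(row = win[[1]], col = win[[3]]),
      side = length(rows),
      kind = kind,
      type = type,
      source = source
    ),
    class = "training_patch"
  )
}

#' @export
print.training_patch <- function(x, ...) {
  cat(sprintf(
    "<training_patch> %s/%s, %dx%d at (%d,%d)\n",
    x$kind, x$type, x$side, x$side, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

# Per-type masks of high-confidence region pixels.
high_type_masks <- function(regions, dims) {
  masks <- lapply(names(LESION_TYPES), function(t) matrix(FALSE, dims[1], dims[2]))
  names(masks) <- names(LESION_TYPES)
  for (r in high_regions(regions)) {
    if (!is.null(r$lesion_type) && r$lesion_type %in% names(masks)) {
      masks[[r$lesion_type]][r$idx] <- TRUE
    }
  }
  masks
}

#' Mine balanced lesion/background training patch pairs
#'
#' One clean-window attempt is made per typed high-confidence region (grown
#' from its centroid); the label masks are the per-type unions of
#' high-confidence region pixels clipped to the window.  For every lesion
#' type, an equal number of background windows is sampled at seeded random
#' centers from the lesion-free `negatives` with the same growth procedure.
#'
#' @param image A [gray_image()].
#' @param regions Scored and typed region list for `image`.
#' @param negatives List of lesion-free [gray_image()]s (synthetic scenes or
#'   DR-negative photographs).
#' @param rng_seed Integer seed; the mining is reproducible given the seed.
#' @param params A [patch_params()].
#' @return List of `training_patch` objects (lesion patches first), balanced
#'   per type when the negatives offer enough clean area (warning
#'   otherwise).
#' @export
mine_patch_pairs <- function(image, regions, negatives, rng_seed = 1L,
                             params = patch_params()) {
  dims <- dim(image$pixels)
  ind_mask <- indeterminate_mask(regions, dims)
  type_masks <- high_type_masks(regions, dims)
  hi <- Filter(function(r) !is.null(r$lesion_type), high_regions(regions))
  if (!length(hi)) {
    warning("no typed high-confidence regions; no patches mined")
    return(list())
  }
  patches <- list()
  for (r in hi) {
    win <- grow_clean_patch(r$centroid, ind_mask, dims, params)
    if (is.null(win)) next
    patches[[length(patches) + 1L]] <-
      new_training_patch(image, win, type_masks, "LESION", r$lesion_type, r$id)
  }
  quotas <- table(factor(
    vapply(patches, function(p) p$type, character(1)),
    levels = names(LESION_TYPES)
  ))
  empty_masks <- lapply(type_masks, function(m) matrix(FALSE, dims[1], dims[2]))
  with_seed(rng_seed, {
    for (type in names(quotas)) {
      quota <- quotas[[type]]
      if (quota == 0L) next
      got <- 0L
      attempts <- 0L
      max_attempts <- params$max_attempts_factor * quota
      while (got < quota && attempts < max_attempts) {
        attempts <- attempts + 1L
        neg <- negatives[[sample.int(length(negatives), 1L)]]
        ndims <- dim(neg$pixels)
        center <- c(sample.int(ndims[1], 1L), sample.int(ndims[2], 1L))
        if (!neg$fov[center[1], center[2]]) next
        neg_ind <- attr(neg, "indeterminate_mask") %||%
          matrix(FALSE, ndims[1], ndims[2])
        win <- grow_clean_patch(center, neg_ind, ndims, params)
        if (is.null(win)) next
        nm <- if (identical(ndims, dims)) empty_masks else {
          lapply(empty_masks, function(m) matrix(FALSE, ndims[1], ndims[2]))
        }
        patches[[length(patches) + 1L]] <-
          new_training_patch(neg, win, nm, "BACKGROUND", type, NA)
        got <- got + 1L
      }
      if (got < quota) {
        warning(sprintf(
          "insufficient clean background area for type '%s': %d of %d patches",
          type, got, quota
        ), call. = FALSE)
      }
    }
  })
  patches
}

resize_plane <- function(m, side, nearest = FALSE) {
  if (all(dim(m) == side)) {
    return(m)
  }
  storage.mode(m) <- "double"
  out <- EBImage::resize(m, w = side, h = side,
                         filter = if (nearest) "none" else "bilinear")
  matrix(as.numeric(out), side, side)
}

#' Augment a training patch
#'
#' Applies a seeded random subset of eight operations: translation,
#' cropping, padding, scaling, flipping, rotating, Gaussian noise, and
#' intensity shift.  Geometric operations transform the image and all label
#' masks identically (nearest-neighbor for masks); photometric operations
#' touch the image only.  The result is resampled to `out_side`.
#'
#' @param patch A `training_patch`.
#' @param rng_seed Integer seed; the same seed reproduces the same output.
#' @param out_side Output side in pixels (the segmentation input size).
#' @return The augmented `training_patch` (side `out_side`).
#' @export
augment_patch <- function(patch, rng_seed = 1L, out_side = 96L) {
  img <- patch$window
  masks <- lapply(patch$label_masks, function(m) m * 1)
  with_seed(rng_seed, {
    use <- runif(8) < 0.5

    geom <- function(f_img, f_mask) {
      img <<- f_img(img)
      masks <<- lapply(masks, f_mask)
    }
    if (use[1]) { # scaling
      s <- as.integer(round(nrow(img) * runif(1, 0.8, 1.25)))
      geom(
        function(m) resize_plane(m, s),
        function(m) resize_plane(m, s, nearest = TRUE)
      )
    }
    if (use[2]) { # rotation by a multiple of 90 degrees
      k <- sample(1:3, 1L)
      rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
      rotk <- function(m) {
        for (i in seq_len(k)) m <- rot90(m)
        m
      }
      geom(rotk, rotk)
    }
    if (use[3]) { # flip
      horiz <- runif(1) < 0.5
      fl <- if (horiz) {
        function(m) m[, ncol(m):1, drop = FALSE]
      } else {
        function(m) m[nrow(m):1, , drop = FALSE]
      }
      geom(fl, fl)
    }
    if (use[4]) { # translation (border replicate for image, empty for masks)
      dr <- sample(-5:5, 1L)
      dc <- sample(-5:5, 1L)
      shift <- function(m, fill_edge) {
        n <- nrow(m)
        ri <- pmin(pmax(seq_len(n) - dr, 1L), n)
        ci <- pmin(pmax(seq_len(ncol(m)) - dc, 1L), ncol(m))
        m[ri, ci, drop = FALSE]
      }
      geom(function(m) shift(m, TRUE), function(m) shift(m, FALSE))
    }
    if (use[5]) { # cropping
      m0 <- max(1L, nrow(img) %/% 10L)
      geom(
        function(m) m[(m0 + 1L):(nrow(m) - m0), (m0 + 1L):(ncol(m) - m0), drop = FALSE],
        function(m) m[(m0 + 1L):(nrow(m) - m0), (m0 + 1L):(ncol(m) - m0), drop = FALSE]
      )
    }
    if (use[6]) { # padding (replicated border for image, zero for masks)
      p <- sample(2:6, 1L)
      pad <- function(m, zero) {
        n <- nrow(m)
        ri <- pmin(pmax(seq_len(n + 2L * p) - p, 1L), n)
        ci <- pmin(pmax(seq_len(ncol(m) + 2L * p) - p, 1L), ncol(m))
        out <- m[ri, ci, drop = FALSE]
        if (zero) {
          out[c(seq_len(p), n + p + seq_len(p)), ] <- 0
          out[, c(seq_len(p), ncol(m) + p + seq_len(p))] <- 0
        }
        out
      }
      geom(function(m) pad(m, FALSE), function(m) pad(m, TRUE))
    }
    if (use[7]) { # Gaussian noise (photometric)
      img <- pmin(pmax(img + matrix(rnorm(length(img), sd = 0.02), nrow(img)), 0), 1)
    }
    if (use[8]) { # intensity shift (photometric)
      img <- pmin(pmax(img + runif(1, -0.1, 0.1), 0), 1)
    }
  })
  out <- patch
  out$window <- resize_plane(img, out_side)
  out$label_masks <- lapply(masks, function(m) resize_plane(m, out_side, nearest = TRUE) > 0.5)
  out$side <- as.integer(out_side)
  out
}

#' Write a patch archive to disk
#'
#' Paired PNGs (`image_XXXX.png`, `mask_XXXX.png`; masks use the indexed
#' [LESION_TYPES] contract) plus a `manifest.csv` with patch id, kind, type,
#' origin, side, and source region.
#'
#' @param patches List of `training_patch` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_patch_archive <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    img_file <- sprintf("image_%04d.png", i)
    mask_file <- sprintf("mask_%04d.png", i)
    EBImage::writeImage(EBImage::Image(t(p$window)), file.path(dir, img_file), type = "png")
    mask <- matrix(0L, p$side, p$side)
    for (t in names(LESION_TYPES)) {
      mm <- p$label_masks[[t]]
      if (!is.null(mm)) mask[mm > 0] <- LESION_TYPES[[t]]
    }
    write_label_mask(mask, file.path(dir, mask_file))
    rows[[i]] <- data.frame(
      id = i, image = img_file, mask = mask_file, kind = p$kind, type = p$type,
      origin_row = p$origin[[1]] - 1L, origin_col = p$origin[[2]] - 1L,
      side = p$side, source = as.character(p$source %||% NA)
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
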