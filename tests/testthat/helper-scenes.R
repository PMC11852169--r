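# Shared fixture builders: tiny deterministic rasters and synthetic patches.

flat_gray <- function(side = 64L, value = 0.55) {
  gray_image(matrix(value, side, side))
}

dist_grid <- function(side, center) {
  sqrt(outer(
    seq_len(side) - center[1], seq_len(side) - center[2],
    function(a, b) a^2 + b^2
  ))
}

disc_gray <- function(side = 64L, center = c(side %/% 2, side %/% 2),
                      radius = 3, bg = 0.7, fg = 0.2) {
  px <- matrix(bg, side, side)
  px[dist_grid(side, center) <= radius] <- fg
  gray_image(px)
}

line_gray <- function(side = 64L, rows = 31:33, bg = 0.7, fg = 0.4) {
  px <- matrix(bg, side, side)
  px[rows, ] <- fg
  gray_image(px)
}

# Rotated line through the full canvas plus an off-line disc, equal contrast.
line_plus_disc <- function(side = 128L, angle, disc_center, contrast = 0.3,
                           bg = 0.6, width = 3, radius = 3, noise_sd = 0.005) {
  px <- matrix(bg, side, side)
  ctr <- (side + 1) / 2
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  dline <- abs(cos(angle) * (rr - ctr) - sin(angle) * (cc - ctr))
  px[dline <= width / 2] <- bg - contrast
  px[dist_grid(side, disc_center) <= radius] <- bg - contrast
  if (noise_sd > 0) px <- px + matrix(rnorm(side^2, sd = noise_sd), side, side)
  list(
    gray = gray_image(pmin(pmax(px, 0), 1)),
    line_mask = dline <= width / 2,
    disc_center = disc_center
  )
}

# Square synthetic training patch with an optional dark blob lesion.
synth_patch <- function(seed, lesion, side = 32L, type = "microaneurysm") {
  set.seed(seed)
  px <- matrix(0.55 + rnorm(side^2, sd = 0.02), side, side)
  mask <- matrix(FALSE, side, side)
  if (lesion) {
    r0 <- sample(10:(side - 10L), 1L)
    c0 <- sample(10:(side - 10L), 1L)
    rad <- runif(1, 2, 4)
    mask <- dist_grid(side, c(r0, c0)) <= rad
    px[mask] <- px[mask] - runif(1, 0.2, 0.35)
  }
  masks <- lapply(names(LESION_TYPES), function(t) mask & (t == type))
  names(masks) <- names(LESION_TYPES)
  structure(
    list(
      window = pmin(pmax(px, 0), 1), label_masks = masks, origin = c(1L, 1L),
      side = side, kind = if (lesion) "LESION" else "BACKGROUND",
      type = type, source = NA
    ),
    class = "training_patch"
  )
}

random_mask_set <- function(side, n) {
  replicate(n, {
    m <- matrix(FALSE, side, side)
    ctr <- c(sample.int(side, 1), sample.int(side, 1))
    m[dist_grid(side, ctr) <= runif(1, 1, 4)] <- TRUE
    m
  }, simplify = FALSE)
}
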