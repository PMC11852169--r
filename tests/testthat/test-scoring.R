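test_that("signed distance field is positive inside, negative outside, EDT-exact", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  sd1 <- signed_distance_field(m)
  expect_gt(sd1[5, 5], 0)
  expect_lte(sd1[5, 5], 1)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr || dc) expect_lt(sd1[5 + dr, 5 + dc], 0)
    }
  }

  side <- 31L
  disc <- dist_grid(side, c(16, 16)) <= 10
  sdd <- signed_distance_field(disc)
  expect_lt(abs(max(sdd) - 10), 0.5)
  # EDT oracle: brute-force nearest opposite pixel for a sample of pixels
  idx_in <- which(disc)
  idx_out <- which(!disc)
  nr <- side
  coords <- function(i) cbind(((i - 1) %% nr) + 1, ((i - 1) %/% nr) + 1)
  ci <- coords(idx_in)
  co <- coords(idx_out)
  set.seed(5)
  for (i in sample(seq_along(idx_in), 10)) {
    d_true <- min(sqrt((ci[i, 1] - co[, 1])^2 + (ci[i, 2] - co[, 2])^2))
    expect_equal(sdd[idx_in[i]], d_true, tolerance = 1e-9)
  }

  expect_false(any(signed_distance_field(matrix(TRUE, 6, 6)) < 0))
  expect_error(signed_distance_field(matrix(FALSE, 4, 4)), class = "retilab_input_error")
})

test_that("ring pair of a uniform disc has the closed-form band means and width", {
  side <- 48L
  px <- matrix(0.7, side, side)
  disc <- dist_grid(side, c(24, 24)) <= 8
  px[disc] <- 0.3
  g <- gray_image(px)
  region <- region_from_mask(disc, "DARK")
  rings <- build_ring_pair(g, region)
  expect_equal(rings$width_w, 2L) # round(8 / 4)
  expect_equal(rings$inner_mean, 0.3)
  expect_equal(rings$outer_mean, 0.7)

  small <- dist_grid(side, c(24, 24)) <= 2
  expect_equal(build_ring_pair(g, region_from_mask(small, "DARK"))$width_w, 1L)
})

test_that("outer ring respects the field of view and fails when it vanishes", {
  side <- 40L
  px <- matrix(0.6, side, side)
  disc <- dist_grid(side, c(20, 20)) <= 6
  px[disc] <- 0.2
  fov <- matrix(FALSE, side, side)
  fov[, 1:20] <- TRUE # disc flush against the fov edge at col 20
  g <- gray_image(px, fov = fov)
  region <- region_from_mask(disc, "DARK")
  rings <- build_ring_pair(g, region)
  cols <- ((rings$outer_idx - 1L) %/% side) + 1L
  expect_true(all(cols <= 20))
  expect_lt(
    length(rings$outer_idx),
    sum(signed_distance_field(disc) < 0 & signed_distance_field(disc) >= -rings$width_w)
  )

  g_none <- gray_image(px, fov = matrix(FALSE, side, side))
  expect_error(build_ring_pair(g_none, region), class = "retilab_scoring_error")
})

test_that("confidence level is the absolute ring contrast over the inner mean", {
  mk <- function(inner, outer) {
    structure(
      list(
        inner_idx = 1L, outer_idx = 2L, width_w = 1L,
        inner_mean = inner, outer_mean = outer
      ),
      class = "ring_pair"
    )
  }
  expect_equal(confidence_level(mk(0.40, 0.54)), 0.35)
  expect_equal(confidence_level(mk(0.33, 0.33)), 0)
  expect_equal(confidence_level(mk(0.20, 0.10)), 0.5)
  expect_warning(inf_conf <- confidence_level(mk(0, 0.5)), "degenerate")
  expect_identical(inf_conf, Inf)
  expect_identical(bucket_confidence(Inf), "HIGH")
  # invariance under multiplicative illumination
  k <- 1.7
  expect_equal(
    confidence_level(mk(0.2, 0.31)),
    confidence_level(mk(0.2 * k, 0.31 * k))
  )
})

test_that("bucket thresholds are honored exactly at the boundaries", {
  expect_identical(bucket_confidence(0.1499999), "LOW")
  expect_identical(bucket_confidence(0.075 / 0.5), "INDETERMINATE") # exactly 0.15
  expect_identical(bucket_confidence(0.3499999), "INDETERMINATE")
  expect_identical(bucket_confidence(0.175 / 0.5), "HIGH") # exactly 0.35
  expect_identical(bucket_confidence(0.10), "LOW")
  expect_identical(bucket_confidence(0.20), "INDETERMINATE")
})

test_that("vessel-fused dark regions are excluded, bright ones are not", {
  side <- 48L
  px <- matrix(0.7, side, side)
  disc <- dist_grid(side, c(24, 24)) <= 5
  px[disc] <- 0.3
  g <- gray_image(px)
  region <- region_from_mask(disc, "DARK")
  vessel <- matrix(FALSE, side, side)
  vessel[, 24:48] <- TRUE # roughly half of any outer band
  scored <- filter_and_bucket(list(region), vessel, g)
  expect_length(scored, 1L)
  expect_gt(scored[[1]]$vessel_fraction, 0.35)
  expect_true(scored[[1]]$vessel_excluded)
  expect_identical(scored[[1]]$bucket, "HIGH") # bucket retained, candidacy lost

  bright <- region_from_mask(disc, "BRIGHT")
  scored_b <- filter_and_bucket(list(bright), vessel, g)
  expect_false(scored_b[[1]]$vessel_excluded)

  clean <- filter_and_bucket(list(region), matrix(FALSE, side, side), g)
  expect_false(clean[[1]]$vessel_excluded)
  expect_equal(clean[[1]]$confidence, 0.4 / 0.3, tolerance = 1e-12)
})

test_that("pipeline confidence matches the closed form for planted uniform discs", {
  side <- 64L
  for (a in c(0.25, 0.4)) {
    b <- a + 0.25
    px <- matrix(b, side, side)
    disc <- dist_grid(side, c(32, 32)) <= 4
    px[disc] <- a
    g <- gray_image(px)
    f <- multiscale_blob_field(g, mcsd_params(polarity = "DARK"))
    regs <- extract_candidate_regions(f, g)
    expect_length(regs, 1L)
    scored <- filter_and_bucket(regs, matrix(FALSE, side, side), g)
    expect_lt(abs(scored[[1]]$confidence - abs(b - a) / a), 0.05)
  }
})

test_that("region JSON records carry the full scoring state", {
  g <- disc_gray(48, radius = 4, bg = 0.7, fg = 0.3)
  f <- multiscale_blob_field(g, mcsd_params(polarity = "DARK"))
  regs <- filter_and_bucket(
    extract_candidate_regions(f, g), matrix(FALSE, 48, 48), g
  )
  line <- regions_to_json(regs)
  rec <- jsonlite::fromJSON(line[[1]])
  expect_named(
    rec,
    c(
      "id", "polarity", "area", "centroid", "r_max", "confidence",
      "bucket", "vessel_excluded", "lesion_type", "bbox"
    ),
    ignore.order = TRUE
  )
  expect_identical(rec$bucket, "HIGH")
})
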