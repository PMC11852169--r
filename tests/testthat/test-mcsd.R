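test_that("descriptor parameters are validated", {
  expect_error(mcsd_params(scales = 1L), class = "retilab_config_error")
  expect_error(mcsd_params(n_directions = 7L), class = "retilab_config_error")
  expect_error(mcsd_params(n_directions = 2L), class = "retilab_config_error")
  expect_identical(mcsd_params()$scales, c(3L, 5L, 10L))
})

test_that("directional contrast is zero on a flat field and signed by polarity", {
  g <- flat_gray(32)
  for (th in c(0, pi / 3, 5)) {
    expect_equal(as.numeric(directional_profile_contrast(g, c(16, 16), 5L, th)), 0)
  }
  dark <- disc_gray(64, radius = 2, bg = 0.7, fg = 0.2)
  expect_gt(as.numeric(directional_profile_contrast(dark, c(32, 32), 10L, 1.1)), 0)
  bright <- disc_gray(64, radius = 2, bg = 0.2, fg = 0.9)
  expect_lt(as.numeric(directional_profile_contrast(bright, c(32, 32), 10L, 1.1)), 0)
})

test_that("field computation matches the per-pixel oracle loop", {
  set.seed(7)
  for (rep in 1:3) {
    g <- gray_image(matrix(runif(16 * 16), 16, 16))
    d <- c(3L, 5L, 10L)[rep]
    p <- mcsd_params(scales = d, n_directions = 8L)
    thetas <- 2 * pi * (0:7) / 8
    fields <- list(
      DARK = shape_descriptor_field(g, d, mcsd_params(scales = d, n_directions = 8L, polarity = "DARK"))$values,
      BRIGHT = shape_descriptor_field(g, d, mcsd_params(scales = d, n_directions = 8L, polarity = "BRIGHT"))$values,
      LINEAR = shape_descriptor_field(g, d, mcsd_params(scales = d, n_directions = 8L, mode = "LINEAR"))$values
    )
    for (r in seq(1, 16, by = 3)) {
      for (cl in seq(1, 16, by = 3)) {
        cs <- vapply(thetas, function(th) {
          as.numeric(directional_profile_contrast(g, c(r, cl), d, th))
        }, numeric(1))
        expect_lt(abs(max(min(cs), 0) - fields$DARK[r, cl]), 1e-9)
        expect_lt(abs(max(-max(cs), 0) - fields$BRIGHT[r, cl]), 1e-9)
        expect_lt(abs(max(max(cs), 0) - fields$LINEAR[r, cl]), 1e-9)
      }
    }
  }
})

test_that("blob mode responds to discs but not to lines; linear mode does the reverse", {
  dark <- disc_gray(64, radius = 2, bg = 0.7, fg = 0.2)
  fb <- shape_descriptor_field(dark, 10L, mcsd_params(scales = 10L, polarity = "DARK"))
  expect_gt(fb$values[32, 32], 0.9 * 0.5 * 0.8) # most samples leave the disc

  ln <- line_gray(64)
  fl_blob <- multiscale_blob_field(ln, mcsd_params(polarity = "DARK"))
  expect_equal(max(fl_blob$values[32, 10:54]), 0) # along-line direction kills it
  fl_lin <- shape_descriptor_field(ln, 10L, mcsd_params(scales = 10L, mode = "LINEAR"))
  expect_gt(fl_lin$values[32, 32], 0.2)
})

test_that("blob response is symmetric under 90-degree rotation and monotone in contrast", {
  set.seed(11)
  g <- disc_gray(48, center = c(20, 29), radius = 3, bg = 0.65, fg = 0.35)
  p <- mcsd_params(polarity = "DARK")
  f1 <- multiscale_blob_field(g, p)$values[20, 29]
  rot <- gray_image(t(g$pixels[48:1, ])) # 90-degree rotation
  f2 <- multiscale_blob_field(rot, p)$values[29, 48 - 20 + 1]
  expect_equal(f1, f2, tolerance = 1e-12)

  resp <- vapply(c(0.1, 0.2, 0.3, 0.4), function(ct) {
    multiscale_blob_field(
      disc_gray(48, radius = 3, bg = 0.65, fg = 0.65 - ct), p
    )$values[24, 24]
  }, numeric(1))
  expect_true(all(diff(resp) >= 0))
})

test_that("vessel mask recovers a planted line and ignores discs", {
  ln <- line_gray(64, bg = 0.7, fg = 0.4)
  vm <- derive_vessel_mask(ln, mcsd_params())
  expect_gte(mean(vm[32, 5:60]), 0.9)
  expect_lt(mean(vm[10, ]), 0.01)

  dark <- disc_gray(64, radius = 3, bg = 0.7, fg = 0.4)
  vm2 <- derive_vessel_mask(dark, mcsd_params())
  expect_false(vm2[32, 32])

  expect_false(any(derive_vessel_mask(flat_gray(48), mcsd_params())))
})

test_that("candidate extraction uses 8-connectivity, drops dust, orders deterministically", {
  side <- 40L
  v <- matrix(0, side, side)
  v[dist_grid(side, c(10, 10)) <= 3] <- 0.2
  v[dist_grid(side, c(30, 30)) <= 2] <- 0.3
  f <- structure(
    list(values = v, params = mcsd_params(), source_shape = c(side, side)),
    class = "contrast_field"
  )
  regs <- extract_candidate_regions(f, flat_gray(side))
  expect_length(regs, 2L)
  expect_equal(
    sort(vapply(regs, function(r) r$area, numeric(1))),
    c(sum(v == 0.3), sum(v == 0.2))
  )
  expect_equal(vapply(regs, function(r) r$id, integer(1)), 1:2)

  diagonal <- matrix(0, 8, 8)
  diagonal[3, 3] <- diagonal[4, 4] <- 1
  fd <- structure(
    list(values = diagonal, params = mcsd_params(), source_shape = c(8L, 8L)),
    class = "contrast_field"
  )
  expect_length(extract_candidate_regions(fd, flat_gray(8)), 1L)

  fz <- structure(
    list(values = matrix(0, 8, 8), params = mcsd_params(), source_shape = c(8L, 8L)),
    class = "contrast_field"
  )
  expect_length(extract_candidate_regions(fz, flat_gray(8)), 0L)

  single <- matrix(0, 8, 8)
  single[5, 5] <- 1
  fs <- structure(
    list(values = single, params = mcsd_params(), source_shape = c(8L, 8L)),
    class = "contrast_field"
  )
  expect_length(extract_candidate_regions(fs, flat_gray(8)), 0L) # min_area = 2
})

test_that("8-connected labeling agrees with a flood-fill oracle", {
  flood_count <- function(mask) {
    seen <- matrix(FALSE, nrow(mask), ncol(mask))
    count <- 0L
    for (i in which(mask)) {
      if (seen[i]) next
      count <- count + 1L
      queue <- i
      seen[i] <- TRUE
      nr <- nrow(mask)
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        r <- ((cur - 1L) %% nr) + 1L
        cl <- ((cur - 1L) %/% nr) + 1L
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- r + dr
            cc <- cl + dc
            if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask)) {
              j <- (cc - 1L) * nr + rr
              if (mask[j] && !seen[j]) {
                seen[j] <- TRUE
                queue <- c(queue, j)
              }
            }
          }
        }
      }
    }
    count
  }
  set.seed(13)
  for (rep in 1:5) {
    mask <- matrix(runif(144) < 0.35, 12, 12)
    expect_identical(max(retilab:::label8(mask)), flood_count(mask))
  }
})
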