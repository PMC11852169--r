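test_that("scene generation honors counts, disjointness, and seeding", {
  cfg <- scene_config()
  sc <- generate_scene(cfg, seed = 3)
  types <- vapply(sc$records, function(r) r$type, character(1))
  expect_equal(sum(types == "microaneurysm"), cfg$n_microaneurysm)
  expect_equal(sum(types == "hemorrhage"), cfg$n_hemorrhage)
  expect_equal(sum(types == "hard_exudate"), cfg$n_hard_exudate)
  expect_equal(sum(types == "soft_exudate"), cfg$n_soft_exudate)

  # masks pairwise disjoint
  all_idx <- unlist(lapply(sc$records, function(r) r$idx))
  expect_equal(anyDuplicated(all_idx), 0L)

  sc2 <- generate_scene(cfg, seed = 3)
  expect_identical(sc$gray$pixels, sc2$gray$pixels)
  sc3 <- generate_scene(cfg, seed = 4)
  expect_false(identical(sc$gray$pixels, sc3$gray$pixels))

  expect_error(scene_config(side = 128L), class = "retilab_config_error")
  expect_error(
    generate_scene(scene_config(n_microaneurysm = -1L), seed = 1),
    class = "retilab_config_error"
  )
})

test_that("rendered lesions are consistent with their recorded contrast", {
  sc <- generate_scene(scene_config(noise_sd = 0), seed = 6)
  px <- sc$gray$pixels
  side <- nrow(px)
  for (rec in sc$records) {
    m <- matrix(FALSE, side, side)
    m[rec$idx] <- TRUE
    ring <- EBImage::dilate(m, EBImage::makeBrush(9L, "disc")) > 0 & !m &
      !sc$vessel_mask & scene_label_mask(sc) == 0L
    local_bg <- mean(px[ring])
    inside <- mean(px[rec$idx])
    if (rec$type %in% c("microaneurysm", "hemorrhage")) {
      expect_gte(local_bg - inside, rec$contrast / 2)
    } else {
      expect_gte(inside - local_bg, rec$contrast / 2)
    }
  }
})

test_that("hemorrhage areas stay within 20 percent of the requested area", {
  for (seed in 1:4) {
    sc <- generate_scene(scene_config(n_microaneurysm = 0L, n_hard_exudate = 0L,
                                      n_soft_exudate = 0L, n_hemorrhage = 3L),
                         seed = seed)
    for (rec in sc$records) {
      expect_lt(abs(rec$area - rec$requested_area) / rec$requested_area, 0.2)
    }
  }
})

test_that("planted phenotypes satisfy the typing-rule geometry", {
  side <- 256L
  px <- matrix(0.5, side, side)
  set.seed(41)
  hex <- plant_lesion(px, "hard_exudate", scene_config(hex_radius = c(5, 5), hex_contrast = c(0.3, 0.3)), c(100, 100))
  m <- matrix(FALSE, side, side)
  m[hex$idx] <- TRUE
  reg <- region_from_mask(m, "BRIGHT")
  expect_identical(
    suppressWarnings(classify_exudate(gray_image(hex$pixels), reg)),
    "hard_exudate"
  )

  sex <- plant_lesion(px, "soft_exudate", scene_config(sex_radius = c(8, 8), sex_contrast = c(0.3, 0.3)), c(180, 180))
  m2 <- matrix(FALSE, side, side)
  m2[sex$idx] <- TRUE
  reg2 <- region_from_mask(m2, "BRIGHT")
  expect_identical(classify_exudate(gray_image(sex$pixels), reg2), "soft_exudate")

  ma <- plant_lesion(px, "microaneurysm", scene_config(ma_radius = c(2, 2), ma_contrast = c(0.25, 0.25)), c(60, 200))
  g <- gray_image(ma$pixels)
  f <- multiscale_blob_field(g, mcsd_params(polarity = "DARK"))
  regs <- extract_candidate_regions(f, g)
  hit <- which(vapply(regs, function(r) any(r$idx %in% ma$idx), logical(1)))
  expect_length(hit, 1L)
  scored <- filter_and_bucket(regs[hit], matrix(FALSE, side, side), g)
  expect_gt(scored[[1]]$confidence, 0.35) # |b - a| / a = 0.25 / 0.25 = 1
})

test_that("vessel rendering produces curvilinear structure the descriptor sees", {
  cfg <- scene_config(n_microaneurysm = 0L, n_hemorrhage = 0L,
                      n_hard_exudate = 0L, n_soft_exudate = 0L, n_vessels = 2L,
                      noise_sd = 0)
  sc <- generate_scene(cfg, seed = 11)
  expect_gt(sum(sc$vessel_mask), 0)
  expect_length(sc$vessel_centerlines, 2L)
  vm <- derive_vessel_mask(sc$gray, mcsd_params())
  cl <- do.call(rbind, sc$vessel_centerlines)
  inside <- cl[, 1] > 12 & cl[, 1] < 244 & cl[, 2] > 12 & cl[, 2] < 244
  expect_gt(mean(vm[cl[inside, , drop = FALSE]]), 0.5)

  none <- generate_scene(scene_config(n_vessels = 0L, n_microaneurysm = 0L,
                                      n_hemorrhage = 0L, n_hard_exudate = 0L,
                                      n_soft_exudate = 0L), seed = 2)
  expect_false(any(none$vessel_mask))
})

test_that("vessel-fused hemorrhages are flagged and vessel-filtered downstream", {
  cfg <- scene_config(n_microaneurysm = 0L, n_hard_exudate = 0L,
                      n_soft_exudate = 0L, n_hemorrhage = 2L,
                      hem_vessel_fraction = 1, hem_area = c(50, 200))
  sc <- generate_scene(cfg, seed = 13)
  expect_true(all(vapply(sc$records, function(r) r$fused, logical(1))))
  # fused hemorrhages touch the vessel influence zone by construction
  infl <- EBImage::dilate(sc$vessel_mask, EBImage::makeBrush(15L, "disc")) > 0
  for (rec in sc$records) expect_gt(mean(infl[rec$idx]), 0)
})

test_that("scenes round-trip to disk with truth artifacts", {
  sc <- generate_scene(scene_config(), seed = 9)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("image.png", "truth_mask.png", "vessel_mask.png", "records.json")
  ))))
  mask <- read_label_mask(file.path(dir, "truth_mask.png"))
  expect_identical(mask, scene_label_mask(sc))
  recs <- jsonlite::read_json(file.path(dir, "records.json"))
  expect_length(recs, length(sc$records))
})
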