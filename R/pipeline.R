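#' Default run configuration
#'
#' Profile-keyed defaults for the whole pipeline.  The CFP profile works at
#' 1000x1000 with descriptor scales 3/5/10; the UWF profile at 1500x1500
#' with the scales scaled by 1.5 (rounded) to keep the descriptor's reach
#' proportional to the resize factor.
#'
#' @param profile `"CFP"` or `"UWF"`.
#' @param seed Integer seed recorded in the configuration.
#' @return Nested configuration list (classes `run_config`).
#' @export
default_config <- function(profile = "CFP", seed = 1L) {
  side <- profile_side(profile)
  scales <- if (identical(profile, "UWF")) c(5L, 8L, 15L) else c(3L, 5L, 10L)
  structure(
    list(
      profile = profile,
      side = side,
      seed = as.integer(seed),
      mcsd = list(
        scales = scales, n_directions = 32L,
        contrast_floor = 0.04, vessel_floor = 0.06, min_area = 2L
      ),
      scoring = list(
        low_threshold = 0.15, high_threshold = 0.35,
        ring_width_fraction = 0.25, vessel_overlap_threshold = 0.35
      ),
      typing = list(
        pca_ratio_threshold = 1.25, ma_size_fraction = 1 / 200,
        soft_exudate_fraction = 0.15
      ),
      patches = list(
        init_side = 10L, step = 5L, min_side = 60L, max_side = 120L,
        max_attempts_factor = 50L
      ),
      segmentation = list(
        stages = 4L, base_filters = 32L, input_side = 96L,
        lr_init = 0.001, lr_factor = 0.5, lr_patience = 3L,
        early_stop_patience = 10L, batch_size = 16L, max_epochs = 100L,
        val_fraction = 0.1, augment = TRUE
      ),
      evaluation = list(bins = default_size_bins())
    ),
    class = "run_config"
  )
}

#' Load a YAML run configuration
#'
#' Values present in the file override the profile defaults; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) input_error(sprintf("config file not found: '%s'", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config(user$profile %||% "CFP", user$seed %||% 1L)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_into(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_into(cfg, user)
}

config_mcsd_params <- function(config, polarity) {
  m <- config$mcsd
  mcsd_params(
    scales = m$scales, n_directions = m$n_directions,
    mode = "BLOB", polarity = polarity,
    contrast_floor = m$contrast_floor, vessel_floor = m$vessel_floor,
    min_area = m$min_area
  )
}

config_scoring_params <- function(config) {
  do.call(scoring_params, config$scoring)
}

config_typing_params <- function(config) {
  do.call(typing_params, config$typing)
}

config_patch_params <- function(config) {
  do.call(patch_params, config$patches)
}

#' Run the stage-1 geometric lesion labeler on one image
#'
#' Executes the full annotation-free labeling chain: working-gray
#' extraction and field-of-view estimation, multiscale blob fields for both
#' polarities, vessel mask, candidate extraction, ring scoring with
#' confidence bucketing and the vessel-adjacency filter, and rule-based
#' typing.  Per-stage candidate counts are collected in `log`.
#'
#' @param image A file path, a [gray_image()], or a `synthetic_scene`.
#' @param config A [default_config()]-style list.
#' @param out Optional output directory; when given, the region records
#'   (JSON lines) and the indexed label mask PNG are written there.
#' @return List with `regions` (scored + typed), `label_mask`,
#'   `vessel_mask`, `gray`, and `log`.
#' @export
run_geometric_labeler <- function(image, config = default_config(), out = NULL) {
  gray <- if (inherits(image, "synthetic_scene")) {
    image$gray
  } else if (inherits(image, "gray_image")) {
    image
  } else {
    to_working_gray(
      load_and_resize(image, config$profile),
      max_scale = max(config$mcsd$scales), profile = config$profile
    )
  }
  p_dark <- config_mcsd_params(config, "DARK")
  p_bright <- config_mcsd_params(config, "BRIGHT")
  field_dark <- multiscale_blob_field(gray, p_dark)
  field_bright <- multiscale_blob_field(gray, p_bright)
  vessel_mask <- derive_vessel_mask(gray, p_dark)
  cands <- c(
    extract_candidate_regions(field_dark, gray),
    extract_candidate_regions(field_bright, gray)
  )
  for (i in seq_along(cands)) cands[[i]]$id <- i
  sp <- config_scoring_params(config)
  scored <- filter_and_bucket(cands, vessel_mask, gray, sp)
  typed <- type_regions(gray, scored, config_typing_params(config))
  dims <- dim(gray$pixels)
  label_mask <- matrix(0L, dims[1], dims[2])
  for (r in high_regions(typed)) {
    if (!is.null(r$lesion_type)) label_mask[r$idx] <- LESION_TYPES[[r$lesion_type]]
  }
  buckets <- table(factor(
    vapply(typed, function(r) r$bucket, character(1)),
    levels = c("LOW", "INDETERMINATE", "HIGH")
  ))
  log <- list(
    n_candidates = length(cands),
    n_scored = length(typed),
    buckets = as.list(buckets),
    n_vessel_excluded = sum(vapply(typed, function(r) isTRUE(r$vessel_excluded), logical(1)))
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    regions_to_json(typed, file.path(out, "regions.jsonl"))
    write_label_mask(label_mask, file.path(out, "label_mask.png"))
  }
  list(
    regions = typed, label_mask = label_mask, vessel_mask = vessel_mask,
    gray = gray, log = log
  )
}

#' Run the full self-supervised pipeline on a set of images
#'
#' Stage 1 labels every image; clean patches are mined (using the
#' lesion-free images as negatives); one U-Net per lesion type with enough
#' patches is smoke-trained; the trained models run tiled inference over
#' every image; detections are scored against the truth masks when
#' available.
#'
#' @param images List of [gray_image()]s or `synthetic_scene`s.
#' @param config A [default_config()]-style list.
#' @param seed Integer seed for mining and training.
#' @param truth Optional list (per image) of lists of truth masks for
#'   evaluation; `synthetic_scene`s supply their own.
#' @param types Lesion types to train.
#' @param max_epochs,input_side Training-budget overrides.
#' @param out Optional output directory for artifacts.
#' @return List with `labels`, `patches`, `models`, `detections`, and
#'   `report` (`NULL`, with a warning, when no truth is available).
#' @export
run_full_pipeline <- function(images, config = default_config(), seed = 1L,
                              truth = NULL, types = names(LESION_TYPES),
                              max_epochs = 5L, input_side = 48L, out = NULL) {
  labels <- lapply(images, run_geometric_labeler, config = config)
  grays <- lapply(labels, function(l) l$gray)
  n_high <- vapply(labels, function(l) length(high_regions(l$regions)), integer(1))
  negatives <- grays[n_high == 0L]
  if (!length(negatives)) negatives <- grays
  pp <- config_patch_params(config)
  patches <- list()
  for (i in seq_along(labels)) {
    patches <- c(patches, mine_patch_pairs(
      grays[[i]], labels[[i]]$regions, negatives,
      rng_seed = seed + i, params = pp
    ))
  }
  models <- list()
  for (type in types) {
    tp <- Filter(function(p) p$type == type, patches)
    if (sum(vapply(tp, function(p) p$kind == "LESION", logical(1))) < 2L ||
        sum(vapply(tp, function(p) p$kind == "BACKGROUND", logical(1))) < 2L) {
      warning(sprintf("not enough patches to train a '%s' model", type), call. = FALSE)
      next
    }
    cfg <- unet_config(
      stages = config$segmentation$stages,
      base_filters = config$segmentation$base_filters,
      input_side = input_side,
      lr_init = config$segmentation$lr_init,
      lr_factor = config$segmentation$lr_factor,
      lr_patience = config$segmentation$lr_patience,
      early_stop_patience = config$segmentation$early_stop_patience,
      batch_size = config$segmentation$batch_size,
      max_epochs = max_epochs,
      val_fraction = config$segmentation$val_fraction,
      augment = FALSE, seed = seed, type = type, profile = config$profile
    )
    models[[type]] <- train_unet(tp, cfg)
  }
  detections <- lapply(seq_along(images), function(i) {
    per_type <- list()
    for (type in names(models)) {
      per_type[[type]] <- infer_masks(models[[type]], grays[[i]])$regions
    }
    per_type
  })
  if (is.null(truth) && length(images) && inherits(images[[1]], "synthetic_scene")) {
    truth_by_type <- lapply(names(LESION_TYPES), function(type) {
      lapply(images, scene_truth_regions, types = type)
    })
    names(truth_by_type) <- names(LESION_TYPES)
  } else if (!is.null(truth)) {
    truth_by_type <- truth
  } else {
    truth_by_type <- NULL
  }
  report <- NULL
  if (is.null(truth_by_type)) {
    warning("no truth masks available; evaluation report omitted", call. = FALSE)
  } else {
    report <- lapply(names(models), function(type) {
      pred <- lapply(detections, function(d) lapply(d[[type]], function(r) r$idx))
      match_and_score(pred, truth_by_type[[type]], n_images = length(images))
    })
    names(report) <- names(models)
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (type in names(models)) {
      save_unet(models[[type]], file.path(out, sprintf("unet_%s.rds", type)))
    }
    if (!is.null(report)) {
      jsonlite::write_json(
        lapply(report, unclass),
        file.path(out, "report.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }
  list(
    labels = labels, patches = patches, models = models,
    detections = detections, report = report
  )
}
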