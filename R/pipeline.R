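# End-to-end orchestration: simulate -> measure -> score, driven by a
# structured config (a nested list, readable from YAML). Anything
# scientific lives in the config, which is copied into every output
# directory for provenance; per-image failures are isolated and summarized
# rather than aborting the run.

#' Default pipeline configuration
#'
#' A nested list with every tunable of the pipeline: paths, physical pixel
#' size, per-channel segmentation settings, colocalization settings,
#' scoring settings and the simulation design. Override any entry via
#' `utils::modifyList()` semantics by passing a partial list.
#'
#' @param overrides optional named list of partial overrides.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    paths = list(study = "study", out = "results"),
    pixel_size_um = 0.1136,
    channels = list(test = "red", marker = "green", nuclei = "blue"),
    segmentation = list(
      smoothing_sigma = 1, threshold_method = "otsu",
      threshold_correction = 1, min_area = 40, max_area = 1e6,
      fill_holes = TRUE,
      test = list(threshold_method = "background"), marker = list()),
    colocalization = list(threshold_method = "background",
                          mask_mode = "union"),
    scoring = list(alpha = 0.001, test = "kruskal",
                   exclude_conditions = list()),
    simulate = list(donors = 5, conditions = "all", antibodies = "all",
                    images_per_slide = 22, cells_per_image = c(1, 5),
                    noise_sd = 60, background = 200,
                    image_dim = c(192, 192), seed = 1)
  )
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  validate_pipeline_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_pipeline_config <- function(cfg) {
  assert_scalar_num(cfg$pixel_size_um, "pixel_size_um", 1e-12)
  if (!all(c("test", "marker") %in% names(cfg$channels))) {
    stopf("config field `channels` must map the test and marker roles")
  }
  assert_scalar_num(cfg$scoring$alpha, "scoring$alpha", 0, 1)
  seg_config_for(cfg, "test")  # runs segmentation_config validation
  seg_config_for(cfg, "marker")
  invisible(cfg)
}

# merged per-channel segmentation config (shared settings + role override)
seg_config_for <- function(cfg, role) {
  base <- cfg$segmentation
  override <- base[[role]] %||% list()
  merged <- utils::modifyList(base[setdiff(names(base),
                                           c("test", "marker"))], override)
  do.call(segmentation_config, merged)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified fields fall back to the defaults of [pipeline_config()];
#' the merged config is validated before any stage runs.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  pipeline_config(yaml::read_yaml(path))
}

config_channel_map <- function(cfg) {
  unlist(cfg$channels)
}

design_from_config <- function(cfg) {
  sim <- cfg$simulate
  donors <- if (length(sim$donors) == 1 && is.numeric(sim$donors)) {
    paste0("D", seq_len(sim$donors))
  } else as.character(sim$donors)
  conditions <- if (identical(sim$conditions, "all")) {
    storage_conditions()$condition
  } else alias_to_condition(as.character(sim$conditions), warn = FALSE)
  antibodies <- if (identical(sim$antibodies, "all")) {
    antibody_targets()
  } else as.character(sim$antibodies)
  study_design(donors = donors, conditions = conditions,
               antibodies = antibodies,
               images_per_slide = sim$images_per_slide,
               cells_per_image = unlist(sim$cells_per_image),
               noise_sd = sim$noise_sd, background = sim$background,
               image_dim = unlist(sim$image_dim),
               pixel_size_um = cfg$pixel_size_um,
               seed = sim$seed)
}

#' Simulate a study from a pipeline config
#'
#' Wraps [generate_study()]; writes the images, the slide manifest and a
#' provenance copy of the effective config (including the seed) into the
#' study directory.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param swap_channels fluorochrome color switch, see [generate_slide()].
#' @param overwrite allow clobbering existing images?
#' @return (invisibly) the slide manifest tibble.
#' @export
pipeline_simulate <- function(config = pipeline_config(),
                              swap_channels = FALSE, overwrite = FALSE) {
  cfg <- as_pipeline_config(config)
  design <- design_from_config(cfg)
  man <- generate_study(design, cfg$paths$study, overwrite = overwrite,
                        swap_channels = swap_channels)
  yaml::write_yaml(unclass(cfg), file.path(cfg$paths$study, "config.yaml"))
  invisible(man)
}

as_pipeline_config <- function(config) {
  if (is.character(config)) return(read_pipeline_config(config))
  if (!inherits(config, "pipeline_config")) return(pipeline_config(config))
  config
}

#' Measure every image of every discovered slide
#'
#' Runs segmentation, per-object features, red-to-green pairing and
#' image-level colocalization for each field of view. Failures are
#' isolated per image: the failing image is skipped, recorded in the
#' `errors` element, and summarized in a warning at the end.
#'
#' @param slides slide table from [discover_slides()], or a study
#'   directory path.
#' @param config a `pipeline_config`.
#' @param progress log per-slide progress messages?
#' @return list of tibbles `features` (per object, both channels), `pairs`
#'   (per red object, with distances), `coloc` (per image), plus `errors`.
#' @export
measure_study <- function(slides, config = pipeline_config(),
                          progress = FALSE) {
  cfg <- as_pipeline_config(config)
  if (is.character(slides)) {
    slides <- discover_slides(slides, channel_map = config_channel_map(cfg))
  }
  if (!nrow(slides)) stopf("no valid slides to measure")
  seg_test <- seg_config_for(cfg, "test")
  seg_marker <- seg_config_for(cfg, "marker")
  psz <- cfg$pixel_size_um

  feat_l <- pair_l <- coloc_l <- list()
  errors <- list()
  for (i in seq_len(nrow(slides))) {
    sl <- slides[i, ]
    if (progress) {
      rlang::inform(sprintf("measuring slide %d/%d: %s %s %s", i,
                            nrow(slides), sl$donor, sl$condition_alias,
                            sl$antibody))
    }
    imgs <- sl$images[[1]]
    for (j in seq_len(nrow(imgs))) {
      files <- imgs$files[[j]]
      key <- tibble(donor = sl$donor, condition = sl$condition,
                    antibody = sl$antibody, image_id = imgs$image[j])
      res <- tryCatch({
        test_path <- files$path[files$role == "test"][1]
        marker_path <- files$path[files$role == "marker"][1]
        red <- read_channel(test_path, role = "test", pixel_size_um = psz)
        green <- read_channel(marker_path, role = "marker",
                              pixel_size_um = psz)
        measure_image(red, green, seg_test, seg_marker, psz,
                      coloc_cfg = cfg$colocalization)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          mutate(key, message = conditionMessage(res))
        next
      }
      feat_l[[length(feat_l) + 1L]] <- bind_cols(
        key[rep(1, nrow(res$features)), ], res$features)
      pair_l[[length(pair_l) + 1L]] <- bind_cols(
        key[rep(1, nrow(res$pairs)), ], res$pairs)
      coloc_l[[length(coloc_l) + 1L]] <- bind_cols(key, res$coloc)
    }
  }
  errors <- bind_rows(errors)
  if (nrow(errors)) {
    rlang::warn(sprintf("%d image(s) failed and were skipped", nrow(errors)))
  }
  list(features = bind_rows(feat_l), pairs = bind_rows(pair_l),
       coloc = bind_rows(coloc_l), errors = errors)
}

# one field of view: segmentation -> features -> pairing -> colocalization
measure_image <- function(red, green, seg_test, seg_marker, pixel_size_um,
                          coloc_cfg = list()) {
  obj_r <- segment_channel(red, seg_test)
  obj_g <- segment_channel(green, seg_marker)
  feat_r <- mutate(measure_objects(obj_r, red, pixel_size_um),
                   channel = "test")
  feat_g <- mutate(measure_objects(obj_g, green, pixel_size_um),
                   channel = "marker")
  pairs <- relate_objects(obj_r, obj_g)
  pairs <- pair_distances(pairs, feat_r, feat_g, pixel_size_um)
  cl <- coloc_image(red, green,
                    threshold_method = coloc_cfg$threshold_method %||%
                      "background",
                    fixed = coloc_cfg$fixed,
                    mask_mode = coloc_cfg$mask_mode %||% "union")
  list(features = bind_rows(feat_r, feat_g), pairs = pairs, coloc = cl)
}

#' Measure a study directory and write the three result CSVs
#'
#' @param config a `pipeline_config` (or YAML path); reads slides from
#'   `paths$study` and writes `features.csv`, `pairs.csv`, `coloc.csv`
#'   and `measure_summary.json` under `paths$out`.
#' @param progress log per-slide progress?
#' @return (invisibly) the [measure_study()] result list.
#' @export
pipeline_measure <- function(config = pipeline_config(), progress = FALSE) {
  cfg <- as_pipeline_config(config)
  slides <- discover_slides(cfg$paths$study,
                            channel_map = config_channel_map(cfg))
  if (!nrow(slides)) stopf("no valid slides found under %s", cfg$paths$study)
  res <- measure_study(slides, cfg, progress = progress)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$features, file.path(cfg$paths$out, "features.csv"),
                   progress = FALSE)
  readr::write_csv(res$pairs, file.path(cfg$paths$out, "pairs.csv"),
                   progress = FALSE)
  readr::write_csv(res$coloc, file.path(cfg$paths$out, "coloc.csv"),
                   progress = FALSE)
  summary <- list(n_slides = nrow(slides),
                  n_images = sum(slides$n_images),
                  n_failed_images = nrow(res$errors),
                  pairing = as.list(pairing_summary(res$pairs)))
  jsonlite::write_json(summary,
                       file.path(cfg$paths$out, "measure_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$paths$out, "config.yaml"))
  invisible(res)
}

#' Score measured results: aggregate, screen, rank, report
#'
#' Reads the three measurement CSVs from `paths$out` (or takes a
#' [measure_study()] result directly), aggregates to slide level, screens
#' parameters across storage conditions, ranks conditions and antibodies,
#' and writes the heatmap-ready report CSVs plus a JSON sidecar with the
#' screen p-values. Ranking is skipped with a message when fewer than two
#' conditions are present.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param measurements optional [measure_study()] result; read from disk
#'   when omitted.
#' @return list: `table` (slide-level parameter table), `screen`,
#'   `ranks_condition`, `ranks_antibody`, `overall_condition`,
#'   `overall_antibody` (each possibly NULL if skipped), `report_files`.
#' @export
pipeline_score <- function(config = pipeline_config(), measurements = NULL) {
  cfg <- as_pipeline_config(config)
  if (is.null(measurements)) {
    rd <- function(f) readr::read_csv(file.path(cfg$paths$out, f),
                                      show_col_types = FALSE,
                                      progress = FALSE)
    measurements <- list(features = rd("features.csv"),
                         pairs = rd("pairs.csv"), coloc = rd("coloc.csv"))
  }
  table <- aggregate_parameters(measurements$features, measurements$pairs,
                                measurements$coloc, level = "slide")
  screen <- screen_parameters(table, alpha = cfg$scoring$alpha,
                              method = cfg$scoring$test)
  excl <- unlist(cfg$scoring$exclude_conditions)
  subset <- if (length(excl)) {
    setdiff(unique(table$condition), alias_to_condition(excl, warn = FALSE))
  } else NULL

  if (length(unique(table$condition)) < 2) {
    rlang::inform("fewer than 2 conditions: condition ranking skipped")
    ranks_c <- overall_c <- NULL
  } else {
    ranks_c <- rank_entities(table, axis = "condition")
    overall_c <- overall_performance(ranks_c)
  }
  ranks_a <- rank_entities(table, axis = "antibody")
  overall_a <- overall_performance(ranks_a)
  ranks_a_sub <- overall_a_sub <- NULL
  if (!is.null(subset)) {
    ranks_a_sub <- rank_entities(table, axis = "antibody",
                                 condition_subset = subset)
    overall_a_sub <- overall_performance(ranks_a_sub)
  }

  out_dir <- file.path(cfg$paths$out, "report")
  files <- performance_report(table, out_dir,
                              condition_subset = subset)
  write_parameter_table(table, file.path(cfg$paths$out,
                                         "parameter_table.csv"))
  jsonlite::write_json(
    list(alpha = cfg$scoring$alpha,
         screen = screen,
         n_slides = nrow(distinct(table, .data$donor, .data$condition,
                                  .data$antibody))),
    file.path(cfg$paths$out, "screen.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(table = table, screen = screen, ranks_condition = ranks_c,
       ranks_antibody = ranks_a, ranks_antibody_subset = ranks_a_sub,
       overall_condition = overall_c, overall_antibody = overall_a,
       overall_antibody_subset = overall_a_sub, report_files = files)
}
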