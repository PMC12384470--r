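# Simulated study designer: donors x storage conditions x antibodies, with a
# per-slide degradation fraction delta looked up from a (condition, antibody)
# map. Every slide draws from its own RNG stream derived from the master seed
# and the slide identity by a stable hash, so regeneration is bit-identical
# and independent of generation order.

#' Default degradation map over the 7 x 8 study design
#'
#' Deltas follow the observed quality gradient of the storage conditions
#' (continuous frozen storage best, prolonged room temperature worst) with
#' per-antibody sensitivity multipliers following the observed antibody
#' ordering (RSPH4A least storage-sensitive, CCDC39 most). The numeric
#' values are free design parameters of the simulator, chosen to span the
#' intact-to-degraded range; they are not measured quantities.
#'
#' @return tibble with columns `condition`, `antibody`, `delta`.
#' @export
default_delta_map <- function() {
  base <- c("-80_28d" = 0.05, "-20_28d" = 0.12, "-20_8w" = 0.33,
            "-20/RT/-80" = 0.28, "4/RT/-80" = 0.38,
            "RT/RT/-80" = 0.62, "RT_28d" = 0.70)
  mult <- c(RSPH4A = 0.70, DNAH5 = 0.80, GAS8 = 0.90, RSPH9 = 1.00,
            SPEF2 = 1.10, CCDC40 = 1.20, DNALI1 = 1.30, CCDC39 = 1.40)
  grid <- tidyr::expand_grid(condition = names(base), antibody = names(mult))
  grid$delta <- pmin(1, base[grid$condition] * mult[grid$antibody])
  grid
}

#' Specify a simulated slide-storage study
#'
#' The default design mirrors the acquisition geometry of the study it
#' emulates: 5 donors, 7 storage conditions, 8 antibodies (280 slides),
#' 22 field-of-view images per slide, each tile showing 1-5 ciliated cells.
#'
#' @param donors character vector of donor ids.
#' @param conditions storage conditions (subset of
#'   `storage_conditions()$condition`, canonical names or aliases).
#' @param antibodies antibody targets (subset of `antibody_targets()`).
#' @param images_per_slide number of field-of-view images per slide.
#' @param cells_per_image integer length-2 range of cells per image.
#' @param delta_map tibble (condition, antibody, delta in \[0,1\]) giving
#'   the degradation fraction per design cell; must cover the design.
#' @param noise_sd,background imaging noise model, see [degradation_model()].
#' @param image_dim image size in pixels (rows, cols).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param seed master integer seed.
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design(donors = c("D1", "D2"), antibodies = "DNAH5",
#'                   images_per_slide = 2)
#' study_manifest(d)
#' @export
study_design <- function(donors = paste0("D", 1:5),
                         conditions = storage_conditions()$condition,
                         antibodies = antibody_targets(),
                         images_per_slide = 22,
                         cells_per_image = c(1, 5),
                         delta_map = default_delta_map(),
                         noise_sd = 60, background = 200,
                         image_dim = c(192, 192),
                         pixel_size_um = 0.1136,
                         seed = 1L) {
  conditions <- alias_to_condition(conditions, warn = FALSE)
  bad_c <- setdiff(conditions, storage_conditions()$condition)
  if (length(bad_c)) {
    stopf("unknown storage condition(s): %s", paste(bad_c, collapse = ", "))
  }
  bad_a <- setdiff(antibodies, antibody_targets())
  if (length(bad_a)) {
    stopf("unknown antibody target(s): %s", paste(bad_a, collapse = ", "))
  }
  assert_scalar_num(images_per_slide, "images_per_slide", 0)
  if (length(cells_per_image) != 2 || cells_per_image[1] < 1 ||
      cells_per_image[2] < cells_per_image[1]) {
    stopf("cells_per_image must be an increasing range of at least 1")
  }
  delta_map <- as_tibble(delta_map)
  if (!all(c("condition", "antibody", "delta") %in% names(delta_map))) {
    stopf("delta_map needs columns condition, antibody, delta")
  }
  if (any(delta_map$delta < 0 | delta_map$delta > 1)) {
    stopf("delta_map values must lie in [0, 1]")
  }
  grid <- tidyr::expand_grid(condition = conditions, antibody = antibodies)
  missing <- anti_join(grid, delta_map, by = c("condition", "antibody"))
  if (nrow(missing)) {
    stopf("delta_map is missing entries for: %s",
          paste(paste(missing$condition, missing$antibody, sep = " x "),
                collapse = "; "))
  }
  structure(list(donors = donors, conditions = conditions,
                 antibodies = antibodies,
                 images_per_slide = as.integer(images_per_slide),
                 cells_per_image = as.integer(cells_per_image),
                 delta_map = delta_map, noise_sd = noise_sd,
                 background = background, image_dim = as.integer(image_dim),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("<study_design> %d donor(s) x %d condition(s) x ",
                     "%d antibod(ies) = %d slides, %d image(s)/slide\n"),
              length(x$donors), length(x$conditions), length(x$antibodies),
              length(x$donors) * length(x$conditions) * length(x$antibodies),
              x$images_per_slide))
  invisible(x)
}

#' Enumerate the slides of a study design
#'
#' Pure bookkeeping: one row per donor x condition x antibody with the
#' slide's degradation delta and derived RNG seed. No images are rendered.
#'
#' @param design a [study_design()].
#' @return tibble with columns donor, condition, condition_alias, antibody,
#'   delta, seed, n_images.
#' @export
study_manifest <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- tidyr::expand_grid(donor = design$donors,
                             condition = design$conditions,
                             antibody = design$antibodies)
  grid <- left_join(grid, design$delta_map, by = c("condition", "antibody"))
  grid$condition_alias <- condition_to_alias(grid$condition, warn = FALSE)
  grid$seed <- mapply(slide_seed, design$seed, grid$donor, grid$condition,
                      grid$antibody)
  grid$n_images <- design$images_per_slide
  select(grid, "donor", "condition", "condition_alias", "antibody",
         "delta", "seed", "n_images")
}

slide_file_name <- function(donor, alias, antibody, img, channel) {
  sprintf("%s__%s__%s__img%03d__%s.tif", donor, alias, antibody, img, channel)
}

write_channel_tiff <- function(mat, path) {
  q <- pmin(pmax(round(mat), 0), 65535)
  tiff::writeTIFF(q / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Generate the images of one slide
#'
#' Renders `images_per_slide` fields of view and writes one grayscale
#' 16-bit TIFF per channel under the naming convention
#' `<donor>__<condition_alias>__<antibody>__img<NNN>__<channel>.tif`.
#' Rendering draws from a dedicated RNG stream seeded by `seed`, so the
#' same call regenerates byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param donor,condition,antibody slide identity; condition may be a
#'   canonical name or alias.
#' @param deg a [degradation_model()] for this slide.
#' @param images_per_slide number of fields of view.
#' @param seed integer seed for this slide's RNG stream.
#' @param cells_per_image range of cells per field.
#' @param image_dim image size (rows, cols).
#' @param overwrite allow clobbering existing files?
#' @param swap_channels write the marker signal under the `red` filename
#'   and the test signal under `green` (fluorochrome color switch).
#' @return tibble manifest of written files (one row per image x channel),
#'   empty if `images_per_slide` is 0.
#' @export
generate_slide <- function(dir, donor, condition, antibody, deg,
                           images_per_slide, seed,
                           cells_per_image = c(1, 5),
                           image_dim = c(192, 192),
                           overwrite = FALSE, swap_channels = FALSE) {
  stopifnot(inherits(deg, "degradation_model"))
  alias <- condition_to_alias(alias_to_condition(condition, warn = FALSE),
                              warn = FALSE)
  if (images_per_slide == 0) {
    return(tibble(donor = character(), condition_alias = character(),
                  antibody = character(), image = integer(),
                  channel = character(), path = character()))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chan_file <- c(green = "green", red = "red", blue = "blue")
  if (swap_channels) chan_file[c("green", "red")] <- c("red", "green")

  rows <- list()
  with_seed(seed, {
    for (img in seq_len(images_per_slide)) {
      specs <- random_field_specs(image_dim, cells_per_image)
      fld <- render_cell(specs, deg, dim = image_dim)
      for (sig in c("green", "red", "blue")) {
        fn <- slide_file_name(donor, alias, antibody, img, chan_file[[sig]])
        path <- file.path(dir, fn)
        if (file.exists(path) && !overwrite) {
          stopf("output file already exists (use overwrite = TRUE): %s", path)
        }
        write_channel_tiff(fld[[sig]], path)
        rows[[length(rows) + 1L]] <-
          tibble(donor = donor, condition_alias = alias, antibody = antibody,
                 image = img, channel = chan_file[[sig]], path = path)
      }
    }
  })
  bind_rows(rows)
}

#' Generate a full simulated study on disk
#'
#' One slide per donor x condition x antibody; images under `dir`, plus a
#' `manifest.json` listing every slide with its delta, seed and the study
#' pixel size. Regeneration from the same design is bit-identical.
#'
#' @param design a [study_design()].
#' @param dir output directory.
#' @param overwrite allow clobbering existing image files?
#' @param swap_channels fluorochrome color switch, see [generate_slide()].
#' @return (invisibly) the slide manifest tibble, as [study_manifest()].
#' @export
generate_study <- function(design, dir, overwrite = FALSE,
                           swap_channels = FALSE) {
  stopifnot(inherits(design, "study_design"))
  man <- study_manifest(design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(man))) {
    deg <- degradation_model(man$delta[i], noise_sd = design$noise_sd,
                             background = design$background)
    generate_slide(dir, man$donor[i], man$condition[i], man$antibody[i],
                   deg, design$images_per_slide, man$seed[i],
                   cells_per_image = design$cells_per_image,
                   image_dim = design$image_dim,
                   overwrite = overwrite, swap_channels = swap_channels)
  }
  manifest <- list(pixel_size_um = design$pixel_size_um,
                   master_seed = design$seed,
                   image_dim = design$image_dim,
                   swap_channels = swap_channels,
                   condition_aliases = storage_conditions(),
                   slides = man)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
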