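# Channel image I/O and slide discovery.
#
# Channel role (test antibody vs axoneme marker vs nuclei) is carried by the
# filename suffix and by an explicit role argument, never inferred from
# pixel content: the fluorochrome color-switch experiment requires roles to
# be reassignable independently of the fluorophore.

#' A single-channel grayscale image
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param role one of `"test"`, `"marker"`, `"nuclei"`.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @return an object of class `channel_image` (the pixel matrix with
#'   `role` and `pixel_size_um` attributes).
#' @export
channel_image <- function(pixels, role = c("test", "marker", "nuclei"),
                          pixel_size_um = 0.1136) {
  role <- match.arg(role)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stopf("pixels must be finite and non-negative")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(pixels, role = role, pixel_size_um = pixel_size_um,
            class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %dx%d, role = %s, %.4f um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "role"), attr(x, "pixel_size_um"),
              min(x), max(x)))
  invisible(x)
}

#' Read a grayscale TIFF channel
#'
#' Accepts single-plane 8- or 16-bit grayscale files and preserves the
#' stored integer intensities losslessly. Multi-plane or RGB files are
#' rejected with instructions to export one file per channel.
#'
#' @param path TIFF file.
#' @param role channel role, see [channel_image()].
#' @param pixel_size_um physical pixel size in micrometres.
#' @return a [channel_image()].
#' @export
read_channel <- function(path, role = c("test", "marker", "nuclei"),
                         pixel_size_um = 0.1136) {
  role <- match.arg(role)
  if (!file.exists(path)) stopf("file not found: %s", path)
  planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(planes) != 1L) {
    stopf("%s has %d planes; export each channel as a separate single-plane file",
          path, length(planes))
  }
  px <- planes[[1]]
  if (length(dim(px)) == 3L) {
    stopf("%s is an RGB/multi-sample image; export each channel as a separate grayscale file",
          path)
  }
  channel_image(px, role = role, pixel_size_um = pixel_size_um)
}

#' Write a grayscale 16-bit TIFF channel
#'
#' Intensities are clipped to \[0, 65535\] and rounded; a value written and
#' read back through [read_channel()] round-trips exactly.
#'
#' @param img numeric matrix or [channel_image()].
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
write_channel <- function(img, path) {
  write_channel_tiff(unclass(img), path)
}

slide_file_regex <- "^(.+)__(.+)__(.+)__img([0-9]+)__([A-Za-z]+)\\.tif$"

#' Discover slides from a directory of per-channel TIFFs
#'
#' Parses the naming convention
#' `<donor>__<condition_alias>__<antibody>__img<NNN>__<channel>.tif`,
#' groups files by slide and image index, and validates that every image
#' set contains both the test and the marker channel. Image sets missing
#' either channel are excluded and listed in the validation report.
#' Discovery is order-independent: results do not depend on the directory
#' listing order.
#'
#' @param root directory containing the TIFFs.
#' @param channel_map named character vector assigning the `test`,
#'   `marker` and (optionally) `nuclei` roles to filename channel tokens;
#'   swap `test` and `marker` to process a color-switched study.
#' @return tibble with one row per slide: donor, condition (canonical where
#'   recognized), condition_alias, antibody, n_images and a list-column
#'   `images` of per-image file tibbles. The excluded incomplete image sets
#'   are attached as attribute `"validation"` (also a tibble), and a
#'   warning summarizes them.
#' @export
discover_slides <- function(root,
                            channel_map = c(test = "red", marker = "green",
                                            nuclei = "blue")) {
  if (!dir.exists(root)) stopf("directory not found: %s", root)
  if (!all(c("test", "marker") %in% names(channel_map))) {
    stopf("channel_map must name at least the test and marker roles")
  }
  files <- sort(list.files(root, pattern = "\\.tif$"))
  empty <- tibble(donor = character(), condition = character(),
                  condition_alias = character(), antibody = character(),
                  n_images = integer(), images = list())
  if (!length(files)) {
    attr(empty, "validation") <- tibble(donor = character(),
                                        condition_alias = character(),
                                        antibody = character(),
                                        image = integer(),
                                        missing = character())
    return(empty)
  }
  m <- regmatches(files, regexec(slide_file_regex, files))
  parsed <- purrr::map_dfr(seq_along(files), function(i) {
    g <- m[[i]]
    if (length(g) != 6) return(NULL)
    tibble(donor = g[2], condition_alias = g[3], antibody = g[4],
           image = as.integer(g[5]), channel = g[6],
           path = file.path(root, files[i]))
  })
  if (!nrow(parsed)) {
    attr(empty, "validation") <- tibble(donor = character(),
                                        condition_alias = character(),
                                        antibody = character(),
                                        image = integer(),
                                        missing = character())
    return(empty)
  }
  role_of <- setNames(names(channel_map), channel_map)
  parsed$role <- unname(role_of[parsed$channel])
  parsed <- filter(parsed, !is.na(.data$role))

  sets <- parsed |>
    group_by(.data$donor, .data$condition_alias, .data$antibody,
             .data$image) |>
    summarise(roles = list(sort(.data$role)),
              files = list(dplyr::pick("role", "channel", "path")),
              .groups = "drop")
  sets$complete <- purrr::map_lgl(sets$roles,
                                  ~ all(c("test", "marker") %in% .x))
  bad <- filter(sets, !.data$complete)
  if (nrow(bad)) {
    bad$missing <- purrr::map_chr(bad$roles, function(r) {
      paste(setdiff(c("test", "marker"), r), collapse = "+")
    })
    rlang::warn(sprintf("%d image set(s) missing a test or marker channel were excluded",
                        nrow(bad)))
  } else {
    bad$missing <- character(0)
  }
  good <- filter(sets, .data$complete)
  slides <- good |>
    group_by(.data$donor, .data$condition_alias, .data$antibody) |>
    summarise(n_images = dplyr::n(),
              images = list(dplyr::pick("image", "files")),
              .groups = "drop")
  slides$condition <- alias_to_condition(slides$condition_alias)
  slides <- select(slides, "donor", "condition", "condition_alias",
                   "antibody", "n_images", "images")
  attr(slides, "validation") <- select(bad, "donor", "condition_alias",
                                       "antibody", "image", "missing")
  slides
}

# ---- tabular I/O -----------------------------------------------------------

parameter_table_cols <- c("donor", "condition", "antibody", "parameter",
                          "value")

#' Read and write long-format parameter tables
#'
#' Plain CSV with header `donor, condition, antibody, parameter, value`.
#' Values round-trip at full double precision (readr writes ~15 significant
#' digits). Reading a file without the expected columns raises a schema
#' error naming the missing ones.
#'
#' @param tbl a tibble with at least the parameter-table columns.
#' @param path CSV file path.
#' @return `read_parameter_table()`: the tibble; `write_parameter_table()`:
#'   (invisibly) `path`.
#' @export
write_parameter_table <- function(tbl, path) {
  missing <- setdiff(parameter_table_cols, names(tbl))
  if (length(missing)) {
    stopf("parameter table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(parameter_table_cols, names(tbl))
  if (length(missing)) {
    stopf("%s is not a parameter table; missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  tbl
}
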