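# broom-style tidiers for the fitted/derived objects.

#' Tidy a rank matrix into a long tibble
#'
#' @param x a `rank_matrix`.
#' @param ... unused.
#' @return tibble: parameter, entity, value (entity mean value on which
#'   the rank was computed, `NA` for matrices built from printed ranks),
#'   rank.
#' @export
tidy.rank_matrix <- function(x, ...) {
  x$ranks
}

#' One-row summary of a rank matrix
#'
#' @param x a `rank_matrix`.
#' @param ... unused.
#' @return tibble: axis, n_parameters, n_entities, best_entity,
#'   best_overall_rank, worst_entity, worst_overall_rank.
#' @export
glance.rank_matrix <- function(x, ...) {
  ov <- overall_performance(x)
  tibble(axis = x$axis,
         n_parameters = length(x$parameters),
         n_entities = length(x$entities),
         best_entity = ov$entity[1],
         best_overall_rank = ov$overall_rank[1],
         worst_entity = ov$entity[nrow(ov)],
         worst_overall_rank = ov$overall_rank[nrow(ov)])
}

#' Tidy a study design into its slide manifest
#'
#' @param x a `study_design`.
#' @param ... unused.
#' @return the [study_manifest()] tibble.
#' @export
tidy.study_design <- function(x, ...) study_manifest(x)

#' One-row summary of a study design
#'
#' @param x a `study_design`.
#' @param ... unused.
#' @return tibble with the design dimensions and totals.
#' @export
glance.study_design <- function(x, ...) {
  n_slides <- length(x$donors) * length(x$conditions) * length(x$antibodies)
  tibble(n_donors = length(x$donors),
         n_conditions = length(x$conditions),
         n_antibodies = length(x$antibodies),
         n_slides = n_slides,
         images_per_slide = x$images_per_slide,
         n_images = n_slides * x$images_per_slide,
         pixel_size_um = x$pixel_size_um)
}
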