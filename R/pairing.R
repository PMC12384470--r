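# Red-to-green object pairing by pixel overlap.
#
# Each red (test-antibody) object is assigned to the green (axoneme marker)
# object with which it shares the most pixels; ties break to the lower
# green id. Red objects overlapping no green pixel stay unpaired. The
# unique-pair filter downstream keeps only pairs whose green object has
# exactly one red child, so measured objects are unambiguous one-to-one
# red/marker matches from the same cell.

#' Relate red objects to green objects by maximal pixel overlap
#'
#' @param red,green `labeled_objects` for the two channels (same shape).
#' @return tibble with one row per red object: `red_id`, `green_id`
#'   (`NA` if unpaired), `overlap_px` (0 if unpaired) and
#'   `green_multiplicity` (number of red children of that green object;
#'   `NA` for unpaired reds). Deterministic and independent of object
#'   enumeration order.
#' @export
relate_objects <- function(red, green) {
  stopifnot(inherits(red, "labeled_objects"),
            inherits(green, "labeled_objects"))
  if (!identical(dim(red$label_map), dim(green$label_map))) {
    stopf("red and green label maps must share the same shape")
  }
  if (red$n_objects == 0) {
    return(tibble(red_id = integer(0), green_id = integer(0),
                  overlap_px = integer(0), green_multiplicity = integer(0)))
  }
  both <- red$label_map > 0 & green$label_map > 0
  out <- tibble(red_id = seq_len(red$n_objects),
                green_id = NA_integer_, overlap_px = 0L)
  if (any(both)) {
    ov <- tibble(red_id = red$label_map[both],
                 green_id = green$label_map[both]) |>
      dplyr::count(.data$red_id, .data$green_id, name = "overlap_px")
    best <- ov |>
      arrange(.data$red_id, dplyr::desc(.data$overlap_px), .data$green_id) |>
      group_by(.data$red_id) |>
      dplyr::slice(1) |>
      ungroup()
    i <- match(out$red_id, best$red_id)
    hit <- !is.na(i)
    out$green_id[hit] <- best$green_id[i[hit]]
    out$overlap_px[hit] <- best$overlap_px[i[hit]]
  }
  mult <- out |>
    filter(!is.na(.data$green_id)) |>
    dplyr::count(.data$green_id, name = "green_multiplicity")
  out$green_multiplicity <-
    mult$green_multiplicity[match(out$green_id, mult$green_id)]
  out
}

#' Centroid distances for paired objects
#'
#' Euclidean distance between the geometric (unweighted) centroids of each
#' paired red object and its green partner, in pixels and micrometres
#' (`distance_um = distance_px * pixel_size_um`). Unpaired records get
#' `NA` distances.
#'
#' @param pairs output of [relate_objects()].
#' @param red_feats,green_feats per-object feature tables from
#'   [measure_objects()] for the red and green channels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @return `pairs` with `distance_px` and `distance_um` columns added.
#' @export
pair_distances <- function(pairs, red_feats, green_feats,
                           pixel_size_um = 0.1136) {
  rf <- select(red_feats, red_id = "object_id",
               r_row = "centroid_row", r_col = "centroid_col")
  gf <- select(green_feats, green_id = "object_id",
               g_row = "centroid_row", g_col = "centroid_col")
  out <- pairs |>
    left_join(rf, by = "red_id") |>
    left_join(gf, by = "green_id") |>
    mutate(distance_px = sqrt((.data$r_row - .data$g_row)^2 +
                                (.data$r_col - .data$g_col)^2),
           distance_um = .data$distance_px * pixel_size_um) |>
    select(-"r_row", -"r_col", -"g_row", -"g_col")
  out
}

#' Keep only unambiguous one-to-one pairs
#'
#' Retains records whose green object has exactly one red child; unpaired
#' records are removed. This is the filter applied before all per-object
#' parameter summaries.
#'
#' @param pairs output of [relate_objects()] (with `green_multiplicity`).
#' @return filtered tibble.
#' @export
filter_unique_pairs <- function(pairs) {
  filter(pairs, !is.na(.data$green_id), .data$green_multiplicity == 1L)
}

#' Pairing summary: how many red objects found a marker partner
#'
#' Either pass a pair table, or pass the two totals directly (e.g. counts
#' reported by another pipeline run).
#'
#' @param pairs output of [relate_objects()], possibly over many images.
#' @param n_red_total,n_paired explicit totals, used when `pairs` is
#'   missing.
#' @return one-row tibble: `n_red_total`, `n_paired`, `percent_paired`
#'   (rounded to the nearest percent; `NA` when there are no red objects).
#' @examples
#' pairing_summary(tibble::tibble(red_id = 1:4, green_id = c(1, 1, NA, 2)))
#' pairing_summary(n_red_total = 200, n_paired = 150)
#' @export
pairing_summary <- function(pairs = NULL, n_red_total = NULL,
                            n_paired = NULL) {
  if (is.null(pairs)) {
    if (is.null(n_red_total) || is.null(n_paired)) {
      stopf("provide either `pairs` or both `n_red_total` and `n_paired`")
    }
    n_total <- n_red_total
  } else {
    n_total <- nrow(pairs)
    n_paired <- sum(!is.na(pairs$green_id))
  }
  tibble(n_red_total = n_total, n_paired = n_paired,
         percent_paired = if (n_total == 0) NA_real_ else
           round(100 * n_paired / n_total))
}
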