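# Rank-based scoring: aggregate per-object/per-image measurements to slide
# and design-cell means, screen parameters for association with storage
# condition, build direction-aware rank matrices over conditions or
# antibodies, and average per-parameter ranks into one overall performance
# metric per entity.

scored_parameters <- function() default_direction_map()$parameter

#' Aggregate measurements into a long parameter table
#'
#' Per-object parameters (area, compactness, eccentricity, mass
#' displacement) come from red-channel objects restricted to unambiguous
#' one-to-one pairs (see [filter_unique_pairs()]); the centroid distance
#' comes from the same pairs; the colocalization parameters are image-level
#' and averaged per slide. Aggregation is hierarchical: per-slide mean per
#' parameter, then (for `level = "group"`) the mean of slide means across
#' donors per condition x antibody. Slides with zero surviving objects
#' contribute no rows for the object parameters; they are reported in the
#' `n_slides_missing` attribute.
#'
#' @param features per-object feature table (from [pipeline_measure()] or
#'   [measure_study()]), with columns donor, condition, antibody, image_id,
#'   channel, object_id and the measured features.
#' @param pairs pair table with distances and `green_multiplicity`.
#' @param coloc image-level colocalization table.
#' @param level `"slide"` (default) or `"group"` (condition x antibody
#'   means across donors).
#' @return long tibble: donor (absent for `"group"`), condition, antibody,
#'   parameter, value.
#' @export
aggregate_parameters <- function(features, pairs, coloc,
                                 level = c("slide", "group")) {
  level <- match.arg(level)
  keys <- c("donor", "condition", "antibody")

  up <- filter_unique_pairs(pairs)
  red <- filter(features, .data$channel == "test")
  obj <- inner_join(red, select(up, dplyr::all_of(c(keys, "image_id")),
                                object_id = "red_id", "distance_um"),
                    by = c(keys, "image_id", "object_id"))

  obj_long <- obj |>
    select(dplyr::all_of(keys),
           AreaShape_Area = "area_px",
           AreaShape_Compactness = "compactness",
           AreaShape_Eccentricity = "eccentricity",
           Intensity_MassDisplacement = "mass_displacement_px",
           Distance_Centroid_mCilia = "distance_um") |>
    tidyr::pivot_longer(-dplyr::all_of(keys), names_to = "parameter",
                        values_to = "value")

  col_long <- coloc |>
    select(dplyr::all_of(keys),
           Correlation_RWC_RED_GREEN = "rwc_red_green",
           Correlation_RWC_GREEN_RED = "rwc_green_red",
           Correlation_Pearson = "pearson") |>
    tidyr::pivot_longer(-dplyr::all_of(keys), names_to = "parameter",
                        values_to = "value")

  slide <- bind_rows(obj_long, col_long) |>
    filter(is.finite(.data$value)) |>
    group_by(across(dplyr::all_of(c(keys, "parameter")))) |>
    summarise(value = mean(.data$value), .groups = "drop")

  # slides present in the design but with no surviving object measurements
  all_slides <- distinct(features, across(dplyr::all_of(keys)))
  have <- distinct(filter(slide,
                          .data$parameter %in% scored_parameters()[1]),
                   across(dplyr::all_of(keys)))
  n_missing <- nrow(anti_join(all_slides, have, by = keys))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "%d slide(s) had no unique-pair objects and are missing from object parameters",
      n_missing))
  }
  out <- if (level == "group") {
    slide |>
      group_by(.data$condition, .data$antibody, .data$parameter) |>
      summarise(value = mean(.data$value), n_donors = dplyr::n(),
                .groups = "drop")
  } else slide
  attr(out, "n_slides_missing") <- n_missing
  out
}

#' Screen parameters for association with storage condition
#'
#' For each parameter, tests whether the per-slide values differ across
#' storage conditions (slides pooled over donors and antibodies). The
#' default test is Kruskal-Wallis (rank-based, no distributional
#' assumptions on the skewed object features); one-way ANOVA is available.
#' Parameters are flagged significant at `p < alpha` (no multiple-testing
#' correction beyond the stringent fixed threshold; Benjamini-Hochberg
#' adjusted p-values are reported alongside for reference).
#'
#' @param table slide-level parameter table from [aggregate_parameters()].
#' @param alpha significance threshold (default 0.001).
#' @param method `"kruskal"` or `"anova"`.
#' @return tibble: parameter, n_conditions, n_slides, statistic, df,
#'   p_value, p_adjusted (BH), significant. Parameters with fewer than two
#'   conditions of two observations are skipped with a warning.
#' @export
screen_parameters <- function(table, alpha = 0.001,
                              method = c("kruskal", "anova")) {
  method <- match.arg(method)
  res <- table |>
    group_by(.data$parameter) |>
    dplyr::group_modify(function(d, key) {
      counts <- table(d$condition)
      if (length(counts) < 2 || sum(counts >= 2) < 2) {
        rlang::warn(sprintf(
          "parameter %s skipped: needs >= 2 conditions with >= 2 observations",
          key$parameter))
        return(tibble(n_conditions = length(counts), n_slides = nrow(d),
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_))
      }
      if (method == "kruskal") {
        kt <- kruskal.test(d$value, factor(d$condition))
        tibble(n_conditions = length(counts), n_slides = nrow(d),
               statistic = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value)
      } else {
        ft <- stats::oneway.test(value ~ condition, data = d,
                                 var.equal = TRUE)
        tibble(n_conditions = length(counts), n_slides = nrow(d),
               statistic = unname(ft$statistic),
               df = unname(ft$parameter[1]), p_value = ft$p.value)
      }
    }) |>
    ungroup()
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}

#' Rank conditions or antibodies per parameter
#'
#' Builds a direction-aware rank matrix: for each parameter, entities on
#' the chosen axis are ranked 1..n, 1 = best, according to the parameter's
#' better-direction. Entity values are design-cell means averaged over the
#' other axis (conditions are scored on values averaged across antibodies,
#' antibodies on values averaged across all storage conditions); the
#' alternative of ranking conditions within each antibody and averaging
#' the ranks is available via `rank_within_antibody = TRUE`. Ties receive
#' average ranks (with a message).
#'
#' @param table slide- or group-level parameter table (long format, see
#'   [aggregate_parameters()]); only parameters present in `direction`
#'   may appear — a parameter without a direction is an error naming it.
#' @param direction a direction map tibble (parameter, direction), default
#'   [default_direction_map()]. The table is first filtered to the mapped
#'   parameters if `restrict = TRUE` (default), so extra diagnostic
#'   parameters in `table` are ignored rather than fatal.
#' @param axis `"condition"` or `"antibody"`.
#' @param condition_subset optional subset of storage conditions to score
#'   on (e.g. all conditions except prolonged room temperature).
#' @param rank_within_antibody for `axis = "condition"` only: rank
#'   conditions separately within each antibody, then average the ranks.
#' @param restrict drop parameters missing from `direction` instead of
#'   erroring.
#' @return an object of class `rank_matrix`.
#' @export
rank_entities <- function(table, direction = default_direction_map(),
                          axis = c("condition", "antibody"),
                          condition_subset = NULL,
                          rank_within_antibody = FALSE,
                          restrict = TRUE) {
  axis <- match.arg(axis)
  direction <- as_tibble(direction)
  if (restrict) {
    table <- filter(table, .data$parameter %in% direction$parameter)
  }
  missing_dir <- setdiff(unique(table$parameter), direction$parameter)
  if (length(missing_dir)) {
    stopf("no better-direction defined for parameter(s): %s",
          paste(missing_dir, collapse = ", "))
  }
  if (!is.null(condition_subset)) {
    condition_subset <- alias_to_condition(condition_subset, warn = FALSE)
    table <- filter(table, .data$condition %in% condition_subset)
  }
  if (!nrow(table)) stopf("no rows left to rank")

  keys <- c("condition", "antibody")
  cell <- if ("donor" %in% names(table)) {
    table |>
      group_by(across(dplyr::all_of(c(keys, "parameter")))) |>
      summarise(value = mean(.data$value), .groups = "drop")
  } else table

  dir_of <- setNames(direction$direction, direction$parameter)
  rank_dir <- function(v, dir) {
    r <- if (dir == "higher") rank(-v, ties.method = "average")
         else rank(v, ties.method = "average")
    if (anyDuplicated(r)) rlang::inform("ties in entity ranking: average ranks used")
    r
  }

  if (axis == "condition" && rank_within_antibody) {
    ranks <- cell |>
      group_by(.data$parameter, .data$antibody) |>
      mutate(rank = rank_dir(.data$value,
                             dir_of[[.data$parameter[1]]])) |>
      group_by(.data$parameter, .data$condition) |>
      summarise(value = mean(.data$value), rank = mean(.data$rank),
                .groups = "drop") |>
      rename(entity = "condition")
  } else {
    other <- if (axis == "condition") "antibody" else "condition"
    ranks <- cell |>
      group_by(across(dplyr::all_of(c("parameter", axis)))) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      group_by(.data$parameter) |>
      mutate(rank = rank_dir(.data$value, dir_of[[.data$parameter[1]]])) |>
      ungroup() |>
      rename(entity = dplyr::all_of(axis))
  }
  new_rank_matrix(select(ranks, "parameter", "entity", "value", "rank"),
                  axis = axis)
}

new_rank_matrix <- function(ranks, axis) {
  structure(list(ranks = ranks, axis = axis,
                 entities = sort(unique(ranks$entity)),
                 parameters = unique(ranks$parameter)),
            class = "rank_matrix")
}

#' Build a rank matrix from a wide per-parameter rank table
#'
#' Accepts a data frame whose first column names the parameter and whose
#' remaining columns hold each entity's rank for that parameter — the
#' layout of a printed per-parameter rank table. Each row must be a valid
#' rank vector over the entities (a permutation of 1..n, or its average-tie
#' generalization, which sums to n(n+1)/2).
#'
#' @param df wide data frame of ranks.
#' @param axis which axis the entities live on (annotation only).
#' @return an object of class `rank_matrix`.
#' @export
as_rank_matrix <- function(df, axis = c("condition", "antibody")) {
  axis <- match.arg(axis)
  df <- as.data.frame(df)
  if (ncol(df) < 2) stopf("need a parameter column plus entity columns")
  entities <- names(df)[-1]
  n <- length(entities)
  for (i in seq_len(nrow(df))) {
    r <- as.numeric(df[i, -1])
    if (any(!is.finite(r)) || abs(sum(r) - n * (n + 1) / 2) > 1e-9 ||
        min(r) < 1 || max(r) > n) {
      stopf("row %d ('%s') is not a valid rank vector over %d entities",
            i, df[i, 1], n)
    }
  }
  long <- tidyr::pivot_longer(as_tibble(df),
                              -1, names_to = "entity", values_to = "rank")
  names(long)[1] <- "parameter"
  long$value <- NA_real_
  new_rank_matrix(select(long, "parameter", "entity", "value", "rank"),
                  axis = axis)
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d parameter(s) x %d %s(s)\n",
              length(x$parameters), length(x$entities), x$axis))
  print(overall_performance(x))
  invisible(x)
}

#' Overall performance: mean of per-parameter ranks
#'
#' Averages each entity's ranks across all parameters into a single
#' performance metric (1 = best). `overall_rank` is the mean reported at
#' one decimal; entities are ordered best to worst.
#'
#' @param x a `rank_matrix` (from [rank_entities()] or
#'   [as_rank_matrix()]) or a wide per-parameter rank data frame.
#' @param ... passed to methods.
#' @return tibble: entity, mean_rank (full precision), overall_rank
#'   (1 decimal), ordered best to worst.
#' @examples
#' df <- data.frame(parameter = c("a", "b"), X = c(1, 2), Y = c(2, 1),
#'                  Z = c(3, 3))
#' overall_performance(df)
#' @export
overall_performance <- function(x, ...) UseMethod("overall_performance")

#' @export
overall_performance.rank_matrix <- function(x, ...) {
  x$ranks |>
    group_by(.data$entity) |>
    summarise(mean_rank = mean(.data$rank), .groups = "drop") |>
    mutate(overall_rank = round(.data$mean_rank, 1)) |>
    arrange(.data$mean_rank, .data$entity)
}

#' @export
overall_performance.data.frame <- function(x, axis = "condition", ...) {
  overall_performance(as_rank_matrix(x, axis = axis))
}

#' Write heatmap-ready parameter and rank tables
#'
#' One CSV per scored parameter (antibody x condition matrix of design-cell
#' mean values, both axes ordered from most to least marker-like according
#' to that parameter's better-direction), plus the condition and antibody
#' overall-rank tables, and — when `condition_subset` is given — a second
#' antibody ranking restricted to that subset. Outputs are deterministic:
#' re-running on identical inputs rewrites identical bytes.
#'
#' @param table slide-level parameter table from [aggregate_parameters()].
#' @param out_dir output directory (created if needed).
#' @param direction direction map, default [default_direction_map()].
#' @param condition_subset optional condition subset for the antibody
#'   re-ranking variant.
#' @return (invisibly) character vector of written file paths.
#' @export
performance_report <- function(table, out_dir,
                               direction = default_direction_map(),
                               condition_subset = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir_of <- setNames(direction$direction, direction$parameter)
  keys <- c("condition", "antibody")
  cell <- table |>
    filter(.data$parameter %in% direction$parameter) |>
    group_by(across(dplyr::all_of(c(keys, "parameter")))) |>
    summarise(value = mean(.data$value), .groups = "drop")

  paths <- character(0)
  for (p in sort(unique(cell$parameter))) {
    d <- filter(cell, .data$parameter == p)
    sgn <- if (dir_of[[p]] == "higher") -1 else 1
    ab_order <- d |> group_by(.data$antibody) |>
      summarise(v = mean(.data$value), .groups = "drop") |>
      arrange(sgn * .data$v) |> pull("antibody")
    cond_order <- d |> group_by(.data$condition) |>
      summarise(v = mean(.data$value), .groups = "drop") |>
      arrange(sgn * .data$v) |> pull("condition")
    wide <- d |>
      mutate(antibody = factor(.data$antibody, levels = ab_order),
             condition = factor(.data$condition, levels = cond_order)) |>
      arrange(.data$antibody) |>
      tidyr::pivot_wider(id_cols = "antibody", names_from = "condition",
                         values_from = "value",
                         names_sort = FALSE) |>
      select("antibody", dplyr::all_of(cond_order))
    f <- file.path(out_dir, paste0("parameter_", p, ".csv"))
    readr::write_csv(wide, f, progress = FALSE)
    paths <- c(paths, f)
  }

  rk_cond <- overall_performance(
    rank_entities(table, direction, axis = "condition"))
  rk_ab <- overall_performance(
    rank_entities(table, direction, axis = "antibody"))
  f1 <- file.path(out_dir, "overall_rank_conditions.csv")
  f2 <- file.path(out_dir, "overall_rank_antibodies.csv")
  readr::write_csv(rk_cond, f1, progress = FALSE)
  readr::write_csv(rk_ab, f2, progress = FALSE)
  paths <- c(paths, f1, f2)
  if (!is.null(condition_subset)) {
    rk_sub <- overall_performance(
      rank_entities(table, direction, axis = "antibody",
                    condition_subset = condition_subset))
    f3 <- file.path(out_dir, "overall_rank_antibodies_subset.csv")
    readr::write_csv(rk_sub, f3, progress = FALSE)
    paths <- c(paths, f3)
  }
  invisible(paths)
}
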