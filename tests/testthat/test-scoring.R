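# small synthetic measurement tables for aggregation/ranking tests
toy_measurements <- function() {
  features <- tibble::tibble(
    donor = "D1", condition = "-80_28d", antibody = "DNAH5",
    image_id = 1L, channel = "test", object_id = 1:3,
    area_px = c(10, 20, 30), compactness = c(1, 2, 3),
    eccentricity = c(.5, .6, .7), mass_displacement_px = c(0, 1, 2))
  pairs <- tibble::tibble(
    donor = "D1", condition = "-80_28d", antibody = "DNAH5",
    image_id = 1L, red_id = 1:3, green_id = 1:3, overlap_px = 5L,
    green_multiplicity = 1L, distance_px = c(1, 2, 3),
    distance_um = c(1, 2, 3) * 0.1136)
  coloc <- tibble::tibble(
    donor = "D1", condition = "-80_28d", antibody = "DNAH5",
    image_id = 1L, rwc_red_green = 0.8, rwc_green_red = 0.5,
    pearson = 0.9)
  list(features = features, pairs = pairs, coloc = coloc)
}

test_that("aggregation takes slide means then donor means", {
  m <- toy_measurements()
  tbl <- aggregate_parameters(m$features, m$pairs, m$coloc)
  area <- tbl$value[tbl$parameter == "AreaShape_Area"]
  expect_equal(area, 20)  # mean of 10, 20, 30
  expect_equal(tbl$value[tbl$parameter == "Correlation_RWC_RED_GREEN"], 0.8)

  # five donors with slide means 1..5 -> group mean 3
  f5 <- purrr::map_dfr(1:5, function(d) {
    f <- m$features
    f$donor <- paste0("D", d)
    f$area_px <- as.numeric(d)
    f
  })
  p5 <- purrr::map_dfr(1:5, function(d) {
    p <- m$pairs; p$donor <- paste0("D", d); p
  })
  c5 <- purrr::map_dfr(1:5, function(d) {
    cc <- m$coloc; cc$donor <- paste0("D", d); cc
  })
  grp <- aggregate_parameters(f5, p5, c5, level = "group")
  expect_equal(grp$value[grp$parameter == "AreaShape_Area"], 3)
  expect_equal(grp$n_donors[grp$parameter == "AreaShape_Area"], 5)
  # a missing donor leaves the mean over the remaining four
  grp4 <- aggregate_parameters(f5[f5$donor != "D5", ],
                               p5[p5$donor != "D5", ],
                               c5[c5$donor != "D5", ], level = "group")
  expect_equal(grp4$value[grp4$parameter == "AreaShape_Area"], 2.5)
})

test_that("objects failing the unique-pair filter are excluded from means", {
  m <- toy_measurements()
  m$pairs$green_id <- c(1L, 1L, 2L)
  m$pairs$green_multiplicity <- c(2L, 2L, 1L)
  tbl <- aggregate_parameters(m$features, m$pairs, m$coloc)
  expect_equal(tbl$value[tbl$parameter == "AreaShape_Area"], 30)
})

test_that("parameter screening flags real differences only", {
  flat <- tidyr::expand_grid(donor = paste0("D", 1:5),
                             condition = storage_conditions()$condition,
                             antibody = "DNAH5",
                             parameter = "AreaShape_Area")
  flat$value <- 1
  res_flat <- screen_parameters(flat)
  expect_false(res_flat$significant)

  # strong monotone condition effect, mild donor noise
  eff <- flat
  eff$parameter <- "Correlation_RWC_RED_GREEN"
  cond_levels <- storage_conditions()$condition
  eff$value <- withr::with_seed(2, {
    1 - 0.1 * match(eff$condition, cond_levels) + rnorm(nrow(eff), 0, 0.01)
  })
  res_eff <- screen_parameters(eff, alpha = 0.001)
  expect_true(res_eff$significant)
  expect_lt(res_eff$p_value, 0.001)

  # alpha = 1: every testable (non-degenerate) parameter passes
  jit <- flat
  jit$value <- withr::with_seed(6, rnorm(nrow(jit)))
  res_all <- screen_parameters(dplyr::bind_rows(jit, eff), alpha = 1)
  expect_true(all(res_all$significant))

  # insufficient replication: skipped with a warning
  tiny <- flat[flat$donor == "D1", ]
  expect_warning(res_tiny <- screen_parameters(tiny), "skipped")
  expect_true(is.na(res_tiny$p_value))

  # ANOVA alternative runs on the same data
  res_aov <- screen_parameters(eff, method = "anova")
  expect_lt(res_aov$p_value, 0.001)
})

test_that("entity ranking follows the better-direction", {
  tbl <- tibble::tibble(
    donor = "D1",
    condition = c("-80_28d", "-20_28d", "RT_28d"),
    antibody = "DNAH5",
    parameter = "AreaShape_Area",
    value = c(3, 1, 2))
  rk_lower <- rank_entities(tbl, axis = "condition")
  ranks <- tidy(rk_lower)
  expect_equal(ranks$rank[match(c("-80_28d", "-20_28d", "RT_28d"),
                                ranks$entity)], c(3, 1, 2))
  dir_hi <- default_direction_map()
  dir_hi$direction[dir_hi$parameter == "AreaShape_Area"] <- "higher"
  rk_higher <- rank_entities(tbl, direction = dir_hi, axis = "condition")
  ranks_hi <- tidy(rk_higher)
  expect_equal(ranks_hi$rank[match(c("-80_28d", "-20_28d", "RT_28d"),
                                   ranks_hi$entity)], c(1, 3, 2))
  # a parameter without a direction errors by name
  tbl2 <- tbl
  tbl2$parameter <- "Mystery_Param"
  expect_error(rank_entities(tbl2, axis = "condition", restrict = FALSE),
               "Mystery_Param")
})

test_that("rank matrices from wide tables validate permutation rows", {
  ok <- data.frame(parameter = c("a", "b"),
                   X = c(1, 2), Y = c(2, 1), Z = c(3, 3))
  rm <- as_rank_matrix(ok)
  expect_s3_class(rm, "rank_matrix")
  expect_true(all(tidy(rm)$rank >= 1 & tidy(rm)$rank <= 3))
  bad <- data.frame(parameter = "a", X = 1, Y = 1, Z = 2)
  expect_error(as_rank_matrix(bad), "not a valid rank vector")
  # average-tie generalization is accepted
  ties <- data.frame(parameter = "a", X = 1.5, Y = 1.5, Z = 3)
  expect_s3_class(as_rank_matrix(ties), "rank_matrix")
})

test_that("overall performance averages rank columns", {
  allk <- data.frame(parameter = c("a", "b", "c"),
                     X = c(2, 2, 2), Y = c(1, 1, 1), Z = c(3, 3, 3))
  ov <- overall_performance(allk)
  expect_equal(ov$mean_rank[ov$entity == "X"], 2)
  expect_equal(ov$entity[1], "Y")   # ordered best to worst
  expect_equal(ov$overall_rank, c(1, 2, 3))
})

test_that("reference rank tables reproduce their printed overall ranks", {
  cond <- readr::read_csv(
    system.file("extdata", "reference_condition_ranks.csv",
                package = "ciliarank"), show_col_types = FALSE)
  # every parameter row is a permutation of 1..7
  for (i in seq_len(nrow(cond))) {
    expect_setequal(as.numeric(cond[i, -1]), 1:7)
  }
  ov <- overall_performance(as.data.frame(cond))
  printed_order <- names(cond)[-1]
  expect_equal(ov$overall_rank[match(printed_order, ov$entity)],
               c(1.0, 2.2, 3.5, 4.0, 4.3, 6.3, 6.7))
})

test_that("rank ties get average ranks with a message", {
  tbl <- tibble::tibble(
    donor = "D1", condition = c("-80_28d", "-20_28d"), antibody = "DNAH5",
    parameter = "AreaShape_Area", value = c(2, 2))
  expect_message(rk <- rank_entities(tbl, axis = "condition"), "ties")
  expect_equal(sort(tidy(rk)$rank), c(1.5, 1.5))
})

test_that("performance report writes deterministic heatmap-ready CSVs", {
  tbl <- tidyr::expand_grid(
    donor = c("D1", "D2"),
    condition = c("-80_28d", "RT_28d"),
    antibody = c("DNAH5", "CCDC39"),
    parameter = default_direction_map()$parameter)
  tbl$value <- withr::with_seed(4, runif(nrow(tbl), 1, 10))
  out1 <- withr::local_tempdir()
  files <- performance_report(tbl, out1)
  expect_equal(sum(grepl("^parameter_", basename(files))), 6)
  expect_equal(sum(grepl("^overall_rank", basename(files))), 2)
  out2 <- withr::local_tempdir()
  files2 <- performance_report(tbl, out2)
  for (k in seq_along(files)) {
    expect_identical(readLines(files[k]), readLines(files2[k]))
  }
  # condition-subset variant emits the extra antibody ranking
  files3 <- performance_report(tbl, withr::local_tempdir(),
                               condition_subset = "-80_28d")
  expect_true(any(grepl("antibodies_subset", files3)))
})

test_that("tidiers summarize rank matrices and designs", {
  ok <- data.frame(parameter = c("a", "b"),
                   X = c(1, 2), Y = c(2, 1), Z = c(3, 3))
  rm <- as_rank_matrix(ok, axis = "antibody")
  g <- glance(rm)
  expect_equal(g$n_parameters, 2)
  expect_equal(g$n_entities, 3)
  expect_equal(g$worst_entity, "Z")
  d <- study_design(donors = c("D1", "D2"), antibodies = "DNAH5",
                    images_per_slide = 3)
  gd <- glance(d)
  expect_equal(gd$n_slides, 14)
  expect_equal(gd$n_images, 42)
  expect_equal(nrow(tidy(d)), 14)
})
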