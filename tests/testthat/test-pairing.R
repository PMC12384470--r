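make_objs <- function(lab) {
  ciliarank:::new_labeled_objects(lab, max(lab), 0)
}

test_that("containment, non-overlap and max-overlap assignment", {
  red <- matrix(0L, 20, 20); green <- matrix(0L, 20, 20)
  red[5:8, 5:8] <- 1L          # inside green 1
  green[3:10, 3:10] <- 1L
  red[15:18, 15:18] <- 2L      # overlaps nothing
  p <- relate_objects(make_objs(red), make_objs(green))
  expect_equal(p$green_id[p$red_id == 1], 1L)
  expect_equal(p$overlap_px[p$red_id == 1], 16L)  # whole red area
  expect_true(is.na(p$green_id[p$red_id == 2]))
  expect_equal(p$overlap_px[p$red_id == 2], 0L)
})

test_that("red object overlapping two greens goes to the larger overlap", {
  red <- matrix(0L, 20, 40); green <- matrix(0L, 20, 40)
  green[5:14, 1:20] <- 1L
  green[5:14, 21:40] <- 2L
  red[10:13, 15:25] <- 1L  # 4 rows: cols 15:20 in green 1, 21:25 in green 2
  p <- relate_objects(make_objs(red), make_objs(green))
  # brute-force overlap count
  ov1 <- sum(red == 1 & green == 1)
  ov2 <- sum(red == 1 & green == 2)
  expect_gt(ov1, ov2)
  expect_equal(p$green_id, 1L)
  expect_equal(p$overlap_px, ov1)
})

test_that("equal overlaps break to the lower green id", {
  red <- matrix(0L, 10, 20); green <- matrix(0L, 10, 20)
  green[3:6, 1:10] <- 2L   # enumeration order should not matter
  green[3:6, 11:20] <- 1L
  red[4:5, 9:12] <- 1L     # 4 px in each green
  g <- make_objs(green)
  p <- relate_objects(make_objs(red), g)
  expect_equal(p$green_id, 1L)
})

test_that("pairing is invariant to object enumeration order", {
  red <- matrix(0L, 30, 30); green <- matrix(0L, 30, 30)
  red[2:5, 2:5] <- 1L;  red[10:13, 10:13] <- 2L; red[20:25, 20:25] <- 3L
  green[1:6, 1:6] <- 1L; green[9:14, 9:14] <- 2L; green[19:26, 19:26] <- 3L
  p1 <- relate_objects(make_objs(red), make_objs(green))
  # relabel both maps in reverse order
  red2 <- matrix(0L, 30, 30); green2 <- matrix(0L, 30, 30)
  red2[red > 0] <- 4L - red[red > 0]
  green2[green > 0] <- 4L - green[green > 0]
  p2 <- relate_objects(make_objs(red2), make_objs(green2))
  merged <- merge(as.data.frame(p1),
                  transform(as.data.frame(p2),
                            red_id = 4L - red_id, green_id = 4L - green_id),
                  by = "red_id")
  expect_equal(merged$green_id.x, merged$green_id.y)
  expect_equal(merged$overlap_px.x, merged$overlap_px.y)
})

test_that("unique-pair filter keeps exactly the single-child pairs", {
  pairs <- tibble::tibble(
    red_id = 1:5,
    green_id = c(1L, 1L, 2L, NA, 3L),
    overlap_px = c(5L, 4L, 9L, 0L, 2L),
    green_multiplicity = c(2L, 2L, 1L, NA, 1L))
  kept <- filter_unique_pairs(pairs)
  expect_equal(kept$red_id, c(3L, 5L))
  # one green with two red children: both removed
  expect_false(any(kept$green_id == 1))
})

test_that("green multiplicity counts red children", {
  red <- matrix(0L, 20, 20); green <- matrix(0L, 20, 20)
  green[2:18, 2:9] <- 1L
  green[2:18, 12:19] <- 2L
  red[3:5, 3:5] <- 1L; red[10:12, 3:5] <- 2L  # both in green 1
  red[3:5, 13:15] <- 3L                        # alone in green 2
  p <- relate_objects(make_objs(red), make_objs(green))
  expect_equal(p$green_multiplicity[p$red_id %in% 1:2], c(2L, 2L))
  expect_equal(p$green_multiplicity[p$red_id == 3], 1L)
  expect_equal(filter_unique_pairs(p)$red_id, 3L)
})

test_that("centroid distances use the linear micrometre factor", {
  feats <- function(r, c) tibble::tibble(object_id = 1L, centroid_row = r,
                                         centroid_col = c)
  pairs <- tibble::tibble(red_id = 1L, green_id = 1L, overlap_px = 3L,
                          green_multiplicity = 1L)
  same <- pair_distances(pairs, feats(5, 5), feats(5, 5), 0.1136)
  expect_equal(same$distance_px, 0)
  tri <- pair_distances(pairs, feats(0, 0), feats(3, 4), 0.1136)
  expect_equal(tri$distance_px, 5)
  expect_equal(tri$distance_um, 5 * 0.1136)
  ten <- pair_distances(pairs, feats(0, 0), feats(0, 10), 0.1136)
  expect_equal(ten$distance_um, 1.136)
  # unpaired record: undefined distance
  unp <- pair_distances(tibble::tibble(red_id = 1L, green_id = NA_integer_,
                                       overlap_px = 0L,
                                       green_multiplicity = NA_integer_),
                        feats(0, 0), feats(3, 4), 0.1136)
  expect_true(is.na(unp$distance_px))
})

test_that("pairing summary reports rounded percentages and edge cases", {
  expect_equal(pairing_summary(n_red_total = 31566,
                               n_paired = 23347)$percent_paired, 74)
  all_p <- tibble::tibble(red_id = 1:3, green_id = c(1L, 2L, 3L))
  expect_equal(pairing_summary(all_p)$percent_paired, 100)
  none <- tibble::tibble(red_id = 1:3, green_id = rep(NA_integer_, 3))
  expect_equal(pairing_summary(none)$percent_paired, 0)
  empty <- tibble::tibble(red_id = integer(0), green_id = integer(0))
  expect_true(is.na(pairing_summary(empty)$percent_paired))
})

test_that("intact synthetic renders pair completely with >=1 px overlap", {
  specs <- withr::with_seed(31,
    ciliarank:::random_field_specs(c(192, 192), c(2, 2)))
  f <- withr::with_seed(31,
    render_cell(specs, degradation_model(0, noise_sd = 0),
                dim = c(192, 192)))
  obj_r <- segment_channel(channel_image(f$red, "test"))
  obj_g <- segment_channel(channel_image(f$green, "marker"))
  p <- relate_objects(obj_r, obj_g)
  expect_equal(pairing_summary(p)$percent_paired, 100)
  expect_true(all(p$overlap_px >= 1))
})
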