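test_that("cell_spec validates its geometry fields", {
  good <- fixture_cell()
  expect_s3_class(good, "cell_spec")
  expect_error(cell_spec(c(10, 10), c(-1, 5), c(5, 10),
                         data.frame(length = 5, width = 1, orientation = 0),
                         c(12, 10), c(3, 3)), "positive")
  expect_error(cell_spec(c(10, 10), c(5, 5), c(5, 10),
                         data.frame(length = numeric(0), width = numeric(0),
                                    orientation = numeric(0)),
                         c(12, 10), c(3, 3)), "ridges")
  expect_error(degradation_model(1.2), "delta")
  expect_error(degradation_model(0.5, noise_sd = -1), "noise_sd")
})

test_that("intact render confines red to the tuft; degraded empties it", {
  spec <- fixture_cell()
  deg0 <- degradation_model(0, noise_sd = 0, background = 200)
  f0 <- withr::with_seed(1, render_cell(spec, deg0, dim = c(96, 96)))
  tuft <- f0$truth$tuft
  cyto_only <- f0$truth$cytoplasm & !tuft
  # delta = 0: red carries exactly the (rescaled) green tuft signal, so the
  # red and green foregrounds coincide at matched thresholds
  expect_equal(f0$red - 200, (2500 / 3000) * (f0$green - 200),
               tolerance = 1e-12)
  # cytoplasm away from the tuft holds background only (up to ridge skirts)
  expect_lt(mean(f0$red[cyto_only]) - 200, 15)

  deg1 <- degradation_model(1, noise_sd = 0, background = 200)
  f1 <- withr::with_seed(1, render_cell(spec, deg1, dim = c(96, 96)))
  tuft_out <- tuft & !f0$truth$cytoplasm
  expect_lt(mean(f1$red[tuft_out]) - 200, 5)
  # red mass concentrated in the cytoplasm
  expect_gt(sum(f1$red[f1$truth$cytoplasm] - 200),
            0.9 * sum(f1$red - 200))
})

test_that("the render follows the stated mixture formula pixel-wise", {
  spec <- fixture_cell()
  dim <- c(96, 96)
  f0 <- withr::with_seed(7, render_cell(spec, degradation_model(0, 0, 200),
                                        dim = dim))
  f1 <- withr::with_seed(7, render_cell(spec, degradation_model(1, 0, 200),
                                        dim = dim))
  fh <- withr::with_seed(7, render_cell(spec, degradation_model(0.5, 0, 200),
                                        dim = dim))
  # red(delta) - bg = (1-delta)*(red(0) - bg) + delta*(red(1) - bg)
  mix <- 0.5 * (f0$red - 200) + 0.5 * (f1$red - 200) + 200
  expect_equal(fh$red, mix, tolerance = 1e-12)
  # mean red over the tuft mask decomposes accordingly
  tuft <- f0$truth$tuft
  expect_equal(mean(fh$red[tuft]),
               0.5 * mean(f0$red[tuft]) + 0.5 * mean(f1$red[tuft]),
               tolerance = 1e-12)
})

test_that("total red mass is invariant to delta and tuft fraction decreases", {
  spec <- fixture_cell()
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  mass <- frac <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    f <- withr::with_seed(3, render_cell(spec,
                                         degradation_model(deltas[i], 0, 0),
                                         dim = c(96, 96)))
    mass[i] <- sum(f$red)
    frac[i] <- sum(f$red[f$truth$tuft]) / sum(f$red)
  }
  expect_equal(max(mass) - min(mass), 0, tolerance = 1e-6)
  expect_true(all(diff(frac) < 0))
})

test_that("mass displacement within the intact object grows with delta", {
  for (seed in c(1, 5, 9)) {
    mask <- local({
      specs <- withr::with_seed(seed,
        ciliarank:::random_field_specs(c(192, 192), c(1, 1)))
      f0 <- withr::with_seed(seed,
        render_cell(specs, degradation_model(0, noise_sd = 0),
                    dim = c(192, 192)))
      o <- segment_channel(channel_image(f0$red, "test"))
      object_mask(o, 1)
    })
    md <- vapply(seq(0, 1, by = 0.25), function(d) {
      specs <- withr::with_seed(seed,
        ciliarank:::random_field_specs(c(192, 192), c(1, 1)))
      f <- withr::with_seed(seed,
        render_cell(specs, degradation_model(d, noise_sd = 0),
                    dim = c(192, 192)))
      mass_displacement(mask, f$red)
    }, numeric(1))
    expect_true(all(diff(md) >= 0))
  }
})

test_that("out-of-grid geometry errors name the offending cell", {
  ok <- fixture_cell()
  bad <- ok
  bad$body_center <- c(5, 5)  # extent spills over the border
  expect_error(render_cell(list(ok, bad), degradation_model(0), c(96, 96)),
               "cell 2")
})

test_that("generate_slide writes the expected files deterministically", {
  dir1 <- withr::local_tempdir()
  deg <- degradation_model(0.3)
  man <- generate_slide(dir1, "D1", "-80_28d", "DNAH5", deg,
                        images_per_slide = 2, seed = 99,
                        cells_per_image = c(1, 2), image_dim = c(128, 128))
  expect_equal(nrow(man), 6)  # 2 images x 3 channels
  expect_true(all(file.exists(man$path)))
  expect_match(basename(man$path[1]), "^D1__m80_28d__DNAH5__img001__")
  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  man2 <- generate_slide(dir2, "D1", "-80_28d", "DNAH5", deg,
                         images_per_slide = 2, seed = 99,
                         cells_per_image = c(1, 2), image_dim = c(128, 128))
  for (k in seq_len(nrow(man))) {
    expect_identical(readBin(man$path[k], "raw", 5e5),
                     readBin(man2$path[k], "raw", 5e5))
  }
  # collision without overwrite flag
  expect_error(generate_slide(dir1, "D1", "-80_28d", "DNAH5", deg, 1, 99,
                              cells_per_image = c(1, 2),
                              image_dim = c(128, 128)), "exists")
  # zero images: empty manifest, no files
  dir3 <- withr::local_tempdir()
  man0 <- generate_slide(dir3, "D9", "RT_28d", "GAS8", deg, 0, 1)
  expect_equal(nrow(man0), 0)
  expect_equal(length(list.files(dir3)), 0)
})

test_that("study designs enumerate slides and validate the delta map", {
  d <- study_design()
  man <- study_manifest(d)
  expect_equal(nrow(man), 280)  # 5 x 7 x 8
  expect_equal(nrow(dplyr::distinct(man, donor, condition, antibody)), 280)
  expect_true(all(man$delta >= 0 & man$delta <= 1))

  d1 <- study_design(donors = "D1", conditions = "-80_28d",
                     antibodies = "DNAH5")
  expect_equal(nrow(study_manifest(d1)), 1)

  dm <- default_delta_map()
  expect_error(study_design(delta_map = dm[-1, ]), "missing entries")
  expect_error(study_design(conditions = "-15_3d"), "unknown storage")
  expect_error(study_design(antibodies = "ACTB"), "unknown antibody")
})

test_that("small generated studies are reproducible with stable manifests", {
  design <- study_design(donors = c("D1", "D2"),
                         conditions = c("-80_28d", "RT_28d"),
                         antibodies = c("DNAH5", "CCDC39"),
                         images_per_slide = 1, cells_per_image = c(1, 1),
                         image_dim = c(128, 128), seed = 5)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m1 <- generate_study(design, dir1)
  m2 <- generate_study(design, dir2)
  expect_equal(nrow(m1), 8)
  expect_identical(m1, m2)
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  # per-slide seeds independent of generation order: regenerate one slide
  dir3 <- withr::local_tempdir()
  row <- m1[m1$donor == "D2" & m1$antibody == "CCDC39" &
              m1$condition == "RT_28d", ]
  generate_slide(dir3, row$donor, row$condition, row$antibody,
                 degradation_model(row$delta), 1, row$seed,
                 cells_per_image = c(1, 1), image_dim = c(128, 128))
  f3 <- list.files(dir3, full.names = TRUE)
  f1 <- file.path(dir1, basename(f3))
  for (k in seq_along(f3)) {
    expect_identical(readBin(f1[k], "raw", 5e5), readBin(f3[k], "raw", 5e5))
  }
})
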