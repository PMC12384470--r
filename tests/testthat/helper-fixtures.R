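# Programmatic mask and image fixtures shared across test files.

disc_mask <- function(radius, dim = 2 * radius + 11,
                      center = c((dim + 1) / 2, (dim + 1) / 2)) {
  m <- matrix(FALSE, dim, dim)
  d2 <- (row(m) - center[1])^2 + (col(m) - center[2])^2
  m[d2 <= radius^2] <- TRUE
  m
}

line_mask <- function(length, dim_r = 5, dim_c = length + 10, row = 3,
                      col0 = 6) {
  m <- matrix(FALSE, dim_r, dim_c)
  m[row, col0:(col0 + length - 1)] <- TRUE
  m
}

ellipse_fixture <- function(a, b, dim = 2 * max(a, b) + 11) {
  ctr <- (dim + 1) / 2
  m <- matrix(FALSE, dim, dim)
  q <- ((row(m) - ctr) / a)^2 + ((col(m) - ctr) / b)^2
  m[q <= 1] <- TRUE
  m
}

annulus_mask <- function(outer, inner, dim = 2 * outer + 11) {
  ctr <- (dim + 1) / 2
  m <- matrix(FALSE, dim, dim)
  d2 <- (row(m) - ctr)^2 + (col(m) - ctr)^2
  m[d2 <= outer^2 & d2 >= inner^2] <- TRUE
  m
}

# irregular blob from a seeded random walk dilation
blob_mask <- function(seed, dim = 41, steps = 120) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, dim, dim)
    p <- c(ceiling(dim / 2), ceiling(dim / 2))
    m[p[1], p[2]] <- TRUE
    for (i in seq_len(steps)) {
      p <- pmin(pmax(p + sample(c(-1L, 0L, 1L), 2, replace = TRUE), 2L),
                dim - 1L)
      m[p[1], p[2]] <- TRUE
    }
    m
  })
}

# a single standard cell spec placed mid-grid, geometry fully inside
fixture_cell <- function(dim = 96) {
  cell_spec(body_center = c(dim * 0.55, dim * 0.5),
            body_axes = c(20, 14),
            tuft_anchor = c(dim * 0.55 - 20, dim * 0.5),
            tuft_ridges = data.frame(length = c(15, 13, 16),
                                     width = c(1.2, 1.1, 1.3),
                                     orientation = c(-pi / 2, -pi / 2 - 0.3,
                                                     -pi / 2 + 0.3)),
            nucleus_center = c(dim * 0.55 + 7, dim * 0.5),
            nucleus_axes = c(9, 7))
}

default_small_cfg <- function(study_dir, out_dir, ...) {
  pipeline_config(list(paths = list(study = study_dir, out = out_dir), ...))
}
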