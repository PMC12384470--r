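# Synthetic two-channel slide generator.
#
# Emulates confocal tile images of ciliated epithelial cells: a stable
# elongated "axoneme marker" signal in the green channel (a tuft of thin
# ridges at the apical cell surface), a test-antibody signal in the red
# channel that is either cilia-colocalized or diffused into the cytoplasm
# depending on a degradation fraction delta, a DAPI-like nucleus blob in
# blue, plus additive background and Gaussian noise. The red channel's
# integrated signal mass is invariant to delta by construction, so delta
# degrades *localization* only — the phenotype the measured parameters are
# designed to detect.

#' Degradation model for a stored slide
#'
#' @param delta fraction in \[0, 1\] of the red (test-antibody) signal mass
#'   displaced from the ciliary tuft into a diffuse cytoplasmic pool.
#'   0 = intact epitope (all signal in cilia), 1 = fully degraded.
#' @param noise_sd standard deviation of additive Gaussian read-out noise,
#'   in intensity units of the 16-bit range.
#' @param background constant background level, same units.
#' @return an object of class `degradation_model`.
#' @examples
#' degradation_model(0.4)
#' @export
degradation_model <- function(delta, noise_sd = 60, background = 200) {
  assert_scalar_num(delta, "delta", 0, 1)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(background, "background", 0)
  structure(list(delta = delta, noise_sd = noise_sd, background = background),
            class = "degradation_model")
}

#' @export
print.degradation_model <- function(x, ...) {
  cat(sprintf("<degradation_model> delta = %.3g, noise_sd = %.3g, background = %.3g\n",
              x$delta, x$noise_sd, x$background))
  invisible(x)
}

#' Geometric specification of one synthetic ciliated cell
#'
#' Describes an elliptical cell body, an apical anchor point on the body
#' boundary from which a tuft of thin ridge primitives (the cilia) emanates
#' outward, and an elliptical nucleus placed inside the body away from the
#' tuft. Ridges are rendered as anti-aliased line segments with a Gaussian
#' cross-profile, giving the thin stretched objects that the shape
#' parameters must discriminate from round diffuse blobs.
#'
#' @param body_center numeric length-2 (row, col), pixels.
#' @param body_axes numeric length-2 semi-axes (row, col), pixels, > 0.
#' @param tuft_anchor numeric length-2 (row, col) on the body boundary.
#' @param tuft_ridges data frame with columns `length` (px), `width`
#'   (Gaussian cross-profile sigma, px) and `orientation` (radians, in the
#'   row/col plane); one row per ridge, 1..`max_ridges` rows.
#' @param nucleus_center,nucleus_axes nucleus ellipse (row, col), pixels.
#' @param intensity_scale per-cell brightness multiplier (biological
#'   cell-to-cell variation).
#' @param max_ridges upper bound on the ridge count.
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(body_center, body_axes, tuft_anchor, tuft_ridges,
                      nucleus_center, nucleus_axes,
                      intensity_scale = 1, max_ridges = 8) {
  if (length(body_center) != 2 || length(body_axes) != 2 ||
      length(tuft_anchor) != 2 || length(nucleus_center) != 2 ||
      length(nucleus_axes) != 2) {
    stopf("cell geometry fields must all have length 2 (row, col)")
  }
  if (any(body_axes <= 0) || any(nucleus_axes <= 0)) {
    stopf("body_axes and nucleus_axes must be positive")
  }
  tuft_ridges <- as_tibble(tuft_ridges)
  need <- c("length", "width", "orientation")
  if (!all(need %in% names(tuft_ridges))) {
    stopf("tuft_ridges needs columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(tuft_ridges) < 1 || nrow(tuft_ridges) > max_ridges) {
    stopf("number of ridges must be in 1..%d", max_ridges)
  }
  if (any(tuft_ridges$length <= 0) || any(tuft_ridges$width <= 0)) {
    stopf("ridge length and width must be positive")
  }
  structure(list(body_center = as.numeric(body_center),
                 body_axes = as.numeric(body_axes),
                 tuft_anchor = as.numeric(tuft_anchor),
                 tuft_ridges = tuft_ridges,
                 nucleus_center = as.numeric(nucleus_center),
                 nucleus_axes = as.numeric(nucleus_axes),
                 intensity_scale = intensity_scale),
            class = "cell_spec")
}

# Bounding box (min_row, max_row, min_col, max_col) that encloses the cell's
# body, nucleus and ridge extent (4 sigma beyond each ridge tip).
cell_extent <- function(spec) {
  b <- rbind(spec$body_center - spec$body_axes,
             spec$body_center + spec$body_axes,
             spec$nucleus_center - spec$nucleus_axes,
             spec$nucleus_center + spec$nucleus_axes)
  r <- spec$tuft_ridges
  pad <- 4 * r$width
  tips <- cbind(spec$tuft_anchor[1] + (r$length + pad) * cos(r$orientation),
                spec$tuft_anchor[2] + (r$length + pad) * sin(r$orientation))
  base <- cbind(spec$tuft_anchor[1] - pad * cos(r$orientation),
                spec$tuft_anchor[2] - pad * sin(r$orientation))
  pts <- rbind(b, tips, base, matrix(spec$tuft_anchor, 1))
  c(min(pts[, 1]) - 2, max(pts[, 1]) + 2, min(pts[, 2]) - 2, max(pts[, 2]) + 2)
}

# Unit-amplitude tuft signal (sum of Gaussian-profile ridges) on a dim grid.
render_tuft_signal <- function(spec, dim) {
  sig <- matrix(0, dim[1], dim[2])
  a <- spec$tuft_anchor
  for (k in seq_len(nrow(spec$tuft_ridges))) {
    rg <- spec$tuft_ridges[k, ]
    u <- c(cos(rg$orientation), sin(rg$orientation))
    pad <- ceiling(4 * rg$width)
    p0 <- a; p1 <- a + rg$length * u
    r0 <- max(1L, floor(min(p0[1], p1[1])) - pad)
    r1 <- min(dim[1], ceiling(max(p0[1], p1[1])) + pad)
    c0 <- max(1L, floor(min(p0[2], p1[2])) - pad)
    c1 <- min(dim[2], ceiling(max(p0[2], p1[2])) + pad)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dr <- outer(rr - a[1], rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - a[2])
    t_ <- pmin(pmax(dr * u[1] + dc * u[2], 0), rg$length)
    d2 <- (dr - t_ * u[1])^2 + (dc - t_ * u[2])^2
    sig[rr, cc] <- sig[rr, cc] + exp(-d2 / (2 * rg$width^2))
  }
  sig
}

ellipse_mask <- function(center, axes, dim) {
  q <- outer(((seq_len(dim[1]) - center[1]) / axes[1])^2,
             rep(1, dim[2])) +
       outer(rep(1, dim[1]), ((seq_len(dim[2]) - center[2]) / axes[2])^2)
  q <= 1
}

#' Render one synthetic cell into three channel grids
#'
#' The green channel carries the tuft (axoneme marker) signal; the red
#' channel carries a mixture `(1 - delta) * tuft + delta * diffuse`, where
#' the diffuse component is spread uniformly over the cytoplasm and scaled
#' so that the red channel's total signal mass is independent of `delta`;
#' the blue channel carries a soft nucleus blob. Background and Gaussian
#' noise (drawn from the current RNG stream) are added to every channel.
#'
#' @param spec a [cell_spec()], or a list of them for a multi-cell field.
#' @param deg a [degradation_model()].
#' @param dim integer length-2 grid size (rows, cols).
#' @param green_amp,red_amp,blue_amp peak signal amplitudes (16-bit units).
#' @param mask_level fraction of unit tuft amplitude above which a pixel
#'   belongs to the ground-truth tuft mask.
#' @return a list with matrices `green`, `red`, `blue` and `truth`, a list
#'   of logical masks `tuft`, `cytoplasm`, `nucleus` plus `n_cells`.
#' @examples
#' spec <- cell_spec(c(48, 48), c(20, 14), c(28, 48),
#'                   data.frame(length = 15, width = 1.2, orientation = -pi / 2),
#'                   c(55, 48), c(9, 7))
#' set.seed(1)
#' f <- render_cell(spec, degradation_model(0, noise_sd = 0), dim = c(96, 96))
#' @export
render_cell <- function(spec, deg, dim = c(192, 192),
                        green_amp = 3000, red_amp = 2500, blue_amp = 1500,
                        mask_level = 0.25) {
  specs <- if (inherits(spec, "cell_spec")) list(spec) else spec
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "cell_spec"))) {
    stopf("`spec` must be a cell_spec or a list of cell_spec objects")
  }
  stopifnot(inherits(deg, "degradation_model"))
  dim <- as.integer(dim)

  for (i in seq_along(specs)) {
    ext <- cell_extent(specs[[i]])
    if (ext[1] < 1 || ext[3] < 1 || ext[2] > dim[1] || ext[4] > dim[2]) {
      stopf("cell %d geometry extends outside the %dx%d grid", i, dim[1], dim[2])
    }
  }

  green <- red <- blue <- matrix(0, dim[1], dim[2])
  tuft_mask <- cyto_mask <- nuc_mask <- matrix(FALSE, dim[1], dim[2])

  for (spec_i in specs) {
    sc <- spec_i$intensity_scale
    tuft <- render_tuft_signal(spec_i, dim)
    cyto <- ellipse_mask(spec_i$body_center, spec_i$body_axes, dim)
    nuc <- ellipse_mask(spec_i$nucleus_center, spec_i$nucleus_axes, dim)

    g_sig <- green_amp * sc * tuft
    r_tuft <- red_amp * sc * tuft
    # Cytoplasmic pool with the same integrated mass as the tuft, so total
    # red mass is delta-invariant and delta degrades localization only.
    # Unassembled/displaced protein accumulates in the apical cytoplasm:
    # density decays with distance from the ciliary base (anchor) and is
    # modulated by a smooth blotch field, because nonspecific cytoplasmic
    # staining is patchy and polarized, not flat — the degraded object must
    # stay an asymmetric, ragged extension of the tuft rather than turning
    # into a clean symmetric ellipse.
    diffuse <- matrix(0, dim[1], dim[2])
    if (any(cyto)) {
      idx <- which(cyto)
      rr <- ((idx - 1) %% dim[1]) + 1
      cc <- ((idx - 1) %/% dim[1]) + 1
      d_anchor <- sqrt((rr - spec_i$tuft_anchor[1])^2 +
                         (cc - spec_i$tuft_anchor[2])^2)
      grad <- exp(-d_anchor / 15)
      blotch <- EBImage::gblur(matrix(runif(prod(dim)), dim[1]),
                               sigma = 5)[idx]
      blotch <- (blotch - min(blotch)) /
        max(max(blotch) - min(blotch), 1e-12)
      dens <- grad * (0.5 + blotch)
      diffuse[idx] <- sum(r_tuft) * dens / sum(dens)
    }
    r_sig <- (1 - deg$delta) * r_tuft + deg$delta * diffuse

    qn <- 1 - pmin(outer(((seq_len(dim[1]) - spec_i$nucleus_center[1]) /
                            spec_i$nucleus_axes[1])^2, rep(1, dim[2])) +
                     outer(rep(1, dim[1]),
                           ((seq_len(dim[2]) - spec_i$nucleus_center[2]) /
                              spec_i$nucleus_axes[2])^2), 1)
    b_sig <- blue_amp * sc * sqrt(pmax(qn, 0))

    green <- green + g_sig
    red <- red + r_sig
    blue <- blue + b_sig
    tuft_mask <- tuft_mask | (tuft > mask_level)
    cyto_mask <- cyto_mask | cyto
    nuc_mask <- nuc_mask | nuc
  }

  add_bg_noise <- function(m) {
    m <- m + deg$background
    if (deg$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, deg$noise_sd), nrow(m))
    }
    pmax(m, 0)
  }
  list(green = add_bg_noise(green), red = add_bg_noise(red),
       blue = add_bg_noise(blue),
       truth = list(tuft = tuft_mask, cytoplasm = cyto_mask,
                    nucleus = nuc_mask, n_cells = length(specs)))
}

# Draw one cell whose full extent fits inside the grid, using the current
# RNG stream. Centers of earlier cells are avoided where space permits.
random_cell_spec <- function(dim, existing_centers = NULL) {
  a <- runif(1, 18, 26); b <- runif(1, 12, 18)
  n_r <- sample(3:6, 1)
  lens <- runif(n_r, 12, 20)
  wids <- runif(n_r, 1.0, 1.6)
  bound <- max(a, b) + max(lens) + 8
  lo <- ceiling(bound) + 1
  hi_r <- dim[1] - ceiling(bound) - 1
  hi_c <- dim[2] - ceiling(bound) - 1
  if (hi_r <= lo || hi_c <= lo) {
    stopf("grid %dx%d too small for a cell of extent %.0f px",
          dim[1], dim[2], 2 * bound)
  }
  center <- NULL
  for (try in 1:40) {
    cand <- c(runif(1, lo, hi_r), runif(1, lo, hi_c))
    ok <- TRUE
    if (!is.null(existing_centers) && nrow(existing_centers) > 0) {
      d <- sqrt((existing_centers[, 1] - cand[1])^2 +
                  (existing_centers[, 2] - cand[2])^2)
      ok <- all(d > 52)
    }
    center <- cand
    if (ok) break
  }
  phi <- runif(1, 0, 2 * pi)
  anchor <- center + c(a * cos(phi), b * sin(phi))
  nrm <- c(cos(phi) / a, sin(phi) / b)
  nrm <- nrm / sqrt(sum(nrm^2))
  # orientation convention: direction vector (cos theta, sin theta) in
  # (row, col) coordinates, so theta = atan2(col_comp, row_comp)
  base_ang <- atan2(nrm[2], nrm[1])
  oris <- base_ang + runif(n_r, -0.35, 0.35)
  nuc_center <- center - 0.35 * c(a * cos(phi), b * sin(phi))
  cell_spec(body_center = center, body_axes = c(a, b), tuft_anchor = anchor,
            tuft_ridges = tibble(length = lens, width = wids,
                                 orientation = oris),
            nucleus_center = nuc_center, nucleus_axes = c(0.45 * a, 0.45 * b),
            intensity_scale = runif(1, 0.8, 1.2))
}

# A full field of view: 1..k cells placed with overlap avoidance.
random_field_specs <- function(dim, cells_range) {
  n <- if (cells_range[1] == cells_range[2]) cells_range[1] else
    sample(cells_range[1]:cells_range[2], 1)
  specs <- list()
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    sp <- random_cell_spec(dim, centers)
    specs[[i]] <- sp
    centers <- rbind(centers, sp$body_center)
  }
  specs
}
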