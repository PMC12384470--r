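# Per-object shape and intensity parameters.
#
# All moments are computed on pixel centers (integer row/col coordinates),
# with no subpixel interpolation, so every value is reproducible by a
# brute-force sum over the mask pixels.

mask_coords <- function(mask) {
  if (!any(mask)) stopf("mask is empty")
  idx <- which(mask)
  nr <- nrow(mask)
  list(r = ((idx - 1) %% nr) + 1, c = ((idx - 1) %/% nr) + 1, idx = idx)
}

#' Eccentricity of a binary object
#'
#' Elongation of the ellipse with the same second central moments as the
#' object: with eigenvalues `l1 >= l2` of the 2x2 central-moment matrix,
#' returns `sqrt(1 - l2/l1)`. 0 for a disc, approaching 1 for a line.
#' Rotation- and translation-invariant. A single-pixel object has
#' degenerate moments and returns 0 by convention (with a message).
#'
#' @param mask logical matrix, at least one `TRUE` pixel.
#' @return value in \[0, 1\].
#' @examples
#' m <- matrix(FALSE, 41, 41)
#' m[abs(row(m) - 21) + 0 <= 20 & abs(col(m) - 21) <= 1] <- TRUE
#' eccentricity(m)
#' @export
eccentricity <- function(mask) {
  p <- mask_coords(mask)
  n <- length(p$r)
  mu_r <- mean(p$r); mu_c <- mean(p$c)
  u20 <- sum((p$r - mu_r)^2) / n
  u02 <- sum((p$c - mu_c)^2) / n
  u11 <- sum((p$r - mu_r) * (p$c - mu_c)) / n
  tr <- u20 + u02
  det_ <- u20 * u02 - u11^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) {
    rlang::inform("degenerate (single-pixel) object: eccentricity set to 0")
    return(0)
  }
  sqrt(1 - max(l2, 0) / l1)
}

#' Compactness of a binary object
#'
#' Radial-variance definition: `2 * pi * MSD / area`, where MSD is the mean
#' squared Euclidean distance of the object's pixels from their centroid.
#' A filled disc scores ~1; elongated, irregular or holed shapes score
#' higher. This is perimeter-free and therefore robust to boundary noise;
#' the `perimeter^2 / (4 pi area)` alternative is available via
#' `method = "perimeter"`.
#'
#' @param mask logical matrix, at least one `TRUE` pixel.
#' @param method `"radial"` (default) or `"perimeter"`.
#' @return non-negative value (~1 for a disc under `"radial"`).
#' @export
compactness <- function(mask, method = c("radial", "perimeter")) {
  method <- match.arg(method)
  p <- mask_coords(mask)
  n <- length(p$r)
  if (method == "radial") {
    msd <- sum((p$r - mean(p$r))^2 + (p$c - mean(p$c))^2) / n
    return(2 * pi * msd / n)
  }
  # pixel-edge boundary length, corrected by pi/4 (the exposed-edge count of
  # a rasterized disc is 8r, pi/4 of which recovers the true 2*pi*r)
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  inner <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  edges <- sum(inner & !m[1:nrow(mask), 2:(ncol(mask) + 1)]) +
    sum(inner & !m[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)]) +
    sum(inner & !m[2:(nrow(mask) + 1), 1:ncol(mask)]) +
    sum(inner & !m[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)])
  per <- edges * pi / 4
  per^2 / (4 * pi * n)
}

#' Intensity mass displacement of an object
#'
#' Euclidean distance, in pixels, between the object's geometric centroid
#' and its intensity-weighted centroid. 0 for a uniformly or symmetrically
#' stained object; large for asymmetric (e.g. diffuse cytoplasmic) signal.
#' Invariant to uniform intensity rescaling, but not to intensity offsets
#' (an added constant pulls the weighted centroid toward the geometric
#' one). An all-zero intensity within the mask returns 0 by convention.
#'
#' @param mask logical matrix, at least one `TRUE` pixel.
#' @param intensity numeric matrix of non-negative intensities, same shape.
#' @return displacement in pixels (>= 0).
#' @export
mass_displacement <- function(mask, intensity) {
  intensity <- unclass(intensity)
  if (!identical(dim(mask), dim(intensity))) {
    stopf("mask and intensity must share the same shape")
  }
  p <- mask_coords(mask)
  w <- intensity[p$idx]
  if (any(w < 0)) stopf("intensities must be non-negative")
  tw <- sum(w)
  if (tw == 0) {
    rlang::inform("all-zero intensity within mask: mass displacement set to 0")
    return(0)
  }
  sqrt((sum(w * p$r) / tw - mean(p$r))^2 +
         (sum(w * p$c) / tw - mean(p$c))^2)
}

#' Measure every object of a labeled map against an intensity image
#'
#' One row per object: pixel and physical area (`area_um2 = area_px *
#' pixel_size_um^2`; the linear pixel size is squared for areal measures),
#' eccentricity, compactness, geometric and intensity-weighted centroids,
#' mass displacement, and basic intensity statistics
#' (`integrated_intensity = mean_intensity * area_px`).
#'
#' @param objs a `labeled_objects` result from [segment_channel()].
#' @param img a [channel_image()] or numeric matrix, same shape as the
#'   label map; its `pixel_size_um` attribute (or the argument) sets the
#'   physical scale.
#' @param pixel_size_um physical pixel size; defaults to the image's.
#' @return tibble with one row per object (empty for an empty label map).
#' @export
measure_objects <- function(objs, img, pixel_size_um = NULL) {
  stopifnot(inherits(objs, "labeled_objects"))
  px <- unclass(img)
  if (!identical(dim(objs$label_map), dim(px))) {
    stopf("label map (%s) and image (%s) shapes differ",
          paste(dim(objs$label_map), collapse = "x"),
          paste(dim(px), collapse = "x"))
  }
  psz <- pixel_size_um %||% attr(img, "pixel_size_um") %||% 0.1136
  cols <- c("object_id", "area_px", "area_um2", "eccentricity",
            "compactness", "centroid_row", "centroid_col",
            "weighted_centroid_row", "weighted_centroid_col",
            "mass_displacement_px", "mean_intensity",
            "integrated_intensity", "max_intensity", "min_intensity")
  if (objs$n_objects == 0) {
    out <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$object_id <- integer(0)
    return(out)
  }
  lab <- objs$label_map
  idx <- which(lab > 0)
  l <- lab[idx]
  nr <- nrow(lab)
  r <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  w <- px[idx]

  n <- as.vector(rowsum(rep(1, length(l)), l))
  sr <- as.vector(rowsum(r, l)); sc <- as.vector(rowsum(cc, l))
  mr <- sr / n; mc <- sc / n
  s_r2 <- as.vector(rowsum(r^2, l)); s_c2 <- as.vector(rowsum(cc^2, l))
  s_rc <- as.vector(rowsum(r * cc, l))
  u20 <- s_r2 / n - mr^2
  u02 <- s_c2 / n - mc^2
  u11 <- s_rc / n - mr * mc

  tr <- u20 + u02
  disc <- sqrt(pmax(tr^2 / 4 - (u20 * u02 - u11^2), 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- ifelse(l1 > 0, sqrt(1 - pmax(l2, 0) / l1), 0)
  comp <- 2 * pi * tr / n  # MSD = u20 + u02

  sw <- as.vector(rowsum(w, l))
  swr <- as.vector(rowsum(w * r, l)); swc <- as.vector(rowsum(w * cc, l))
  wr <- ifelse(sw > 0, swr / sw, mr)
  wc <- ifelse(sw > 0, swc / sw, mc)
  md <- sqrt((wr - mr)^2 + (wc - mc)^2)

  tibble(object_id = seq_len(objs$n_objects),
         area_px = n,
         area_um2 = n * psz^2,
         eccentricity = ecc,
         compactness = comp,
         centroid_row = mr, centroid_col = mc,
         weighted_centroid_row = wr, weighted_centroid_col = wc,
         mass_displacement_px = md,
         mean_intensity = sw / n,
         integrated_intensity = sw,
         max_intensity = as.vector(tapply(w, l, max)),
         min_intensity = as.vector(tapply(w, l, min)))
}
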