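# Image-level channel-relationship measures: the directional rank-weighted
# colocalization coefficient (RWC) in both directions, and Pearson
# correlation. RWC is rank-based, so it is invariant to strictly monotone
# intensity transforms of either channel (as long as threshold membership
# is preserved); it is bounded in [0, 1] and is NOT symmetric in its
# arguments, unlike Pearson.

#' Per-channel foreground thresholds for colocalization
#'
#' The default `"background"` method estimates the background level
#' robustly (median + 3 MAD of the whole channel) so that *any* signal
#' above background — including weak diffuse cytoplasmic signal, which is
#' exactly what storage degradation produces — counts as foreground.
#' Otsu, which places its threshold between the background mode and the
#' bright ciliary signal, would leave intermediate diffuse intensities
#' outside the analysis mask and blind the coefficient to them.
#'
#' @param red,green numeric matrices of the two channels (same shape).
#' @param method `"background"`, `"otsu"` or `"fixed"`.
#' @param fixed named list/vector with entries `red` and `green` when
#'   `method = "fixed"`.
#' @return named numeric: `threshold_red`, `threshold_green`. A constant
#'   channel gets its constant value as threshold (no pixel is strictly
#'   above it, so downstream colocalization is empty) with a warning.
#' @export
coloc_thresholds <- function(red, green,
                             method = c("background", "otsu", "fixed"),
                             fixed = NULL) {
  method <- match.arg(method)
  red <- unclass(red); green <- unclass(green)
  if (!identical(dim(red), dim(green))) {
    stopf("red and green must share the same shape")
  }
  if (method == "fixed") {
    if (is.null(fixed) || !all(c("red", "green") %in% names(fixed))) {
      stopf("fixed thresholds need named entries `red` and `green`")
    }
    return(c(threshold_red = as.numeric(fixed[["red"]]),
             threshold_green = as.numeric(fixed[["green"]])))
  }
  one <- function(ch, name) {
    rng <- range(ch)
    if (rng[1] == rng[2]) {
      rlang::warn(sprintf("constant %s channel: no foreground above threshold",
                          name))
      return(rng[1])
    }
    if (method == "background") {
      return(stats::median(ch) + 3 * stats::mad(ch))
    }
    norm <- (ch - rng[1]) / (rng[2] - rng[1])
    rng[1] + EBImage::otsu(norm, range = c(0, 1)) * (rng[2] - rng[1])
  }
  c(threshold_red = one(red, "red"), threshold_green = one(green, "green"))
}

#' Directional rank-weighted colocalization coefficient
#'
#' Within the analysis mask, both channels' intensities are ranked
#' (midranks for ties). With `D_i = |rank_primary(i) - rank_secondary(i)|`
#' and `Rmax = max_i D_i`, each pixel gets weight
#' `W_i = (Rmax - D_i) / Rmax` (all weights 1 when `Rmax = 0`).
#' Colocalized pixels are those strictly above both channel thresholds;
#' the coefficient is `sum_coloc primary_i * W_i / sum_mask primary_i`,
#' in \[0, 1\]. Directional: `rwc(red, green, ...)` differs from
#' `rwc(green, red, ...)` in general.
#'
#' @param primary,secondary numeric matrices (same shape).
#' @param thr_primary,thr_secondary foreground thresholds (strict).
#' @param mask logical analysis mask (default: whole image).
#' @return value in \[0, 1\]; 0 (with a warning) if the primary channel
#'   has zero total intensity in the mask.
#' @examples
#' p <- matrix(c(4, 3, 2, 1), 2)
#' s <- matrix(c(1, 2, 3, 4), 2)
#' rwc(p, s, 0, 0)  # 1/3
#' @export
rwc <- function(primary, secondary, thr_primary, thr_secondary,
                mask = NULL) {
  primary <- unclass(primary); secondary <- unclass(secondary)
  if (!identical(dim(primary), dim(secondary))) {
    stopf("primary and secondary must share the same shape")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(primary))
  if (!any(mask)) stopf("analysis mask is empty")
  p <- primary[mask]; s <- secondary[mask]
  tot <- sum(p)
  if (tot == 0) {
    rlang::warn("zero total primary intensity in mask: RWC set to 0")
    return(0)
  }
  rp <- rank(p, ties.method = "average")
  rs <- rank(s, ties.method = "average")
  d <- abs(rp - rs)
  rmax <- max(d)
  w <- if (rmax == 0) rep(1, length(d)) else (rmax - d) / rmax
  coloc <- p > thr_primary & s > thr_secondary
  sum(p[coloc] * w[coloc]) / tot
}

#' Pearson correlation between two channels over a mask
#'
#' Standard product-moment correlation of the masked pixel intensities;
#' symmetric in its arguments. Zero variance in either channel leaves the
#' correlation undefined: `NA` is returned with a warning.
#'
#' @param red,green numeric matrices (same shape).
#' @param mask logical analysis mask (default: whole image); must contain
#'   at least 2 pixels.
#' @return value in \[-1, 1\], or `NA`.
#' @export
coloc_pearson <- function(red, green, mask = NULL) {
  red <- unclass(red); green <- unclass(green)
  if (!identical(dim(red), dim(green))) {
    stopf("red and green must share the same shape")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(red))
  r <- red[mask]; g <- green[mask]
  if (length(r) < 2) stopf("mask must contain at least 2 pixels")
  if (sd(r) == 0 || sd(g) == 0) {
    rlang::warn("zero variance in a channel: Pearson correlation undefined")
    return(NA_real_)
  }
  cor(r, g)
}

#' Image-level colocalization summary for one red/green pair
#'
#' Computes per-channel thresholds, both RWC directions and the Pearson
#' correlation over the analysis mask. The default mask is the union of
#' the two channels' foregrounds (pixels above threshold in at least one
#' channel), which excludes empty background that would otherwise inflate
#' rank agreement; set `mask_mode = "image"` for the whole image.
#'
#' @param red,green [channel_image()]s or numeric matrices (same shape).
#' @param threshold_method,fixed see [coloc_thresholds()].
#' @param mask_mode `"union"` (default) or `"image"`.
#' @return one-row tibble: `rwc_red_green`, `rwc_green_red`, `pearson`,
#'   `threshold_red`, `threshold_green`, `n_coloc_pixels`, `n_mask_pixels`.
#' @export
coloc_image <- function(red, green,
                        threshold_method = c("background", "otsu", "fixed"),
                        fixed = NULL, mask_mode = c("union", "image")) {
  mask_mode <- match.arg(mask_mode)
  thr <- coloc_thresholds(red, green, method = threshold_method,
                          fixed = fixed)
  red <- unclass(red); green <- unclass(green)
  fg_r <- red > thr[["threshold_red"]]
  fg_g <- green > thr[["threshold_green"]]
  mask <- if (mask_mode == "union") fg_r | fg_g else array(TRUE, dim(red))
  if (!any(mask)) {
    rlang::warn("no foreground pixel in either channel: empty colocalization")
    return(tibble(rwc_red_green = 0, rwc_green_red = 0, pearson = NA_real_,
                  threshold_red = thr[["threshold_red"]],
                  threshold_green = thr[["threshold_green"]],
                  n_coloc_pixels = 0L, n_mask_pixels = 0L))
  }
  tibble(
    rwc_red_green = rwc(red, green, thr[["threshold_red"]],
                        thr[["threshold_green"]], mask),
    rwc_green_red = rwc(green, red, thr[["threshold_green"]],
                        thr[["threshold_red"]], mask),
    pearson = coloc_pearson(red, green, mask),
    threshold_red = thr[["threshold_red"]],
    threshold_green = thr[["threshold_green"]],
    n_coloc_pixels = sum(fg_r & fg_g),
    n_mask_pixels = sum(mask)
  )
}
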