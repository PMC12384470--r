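# Controlled vocabulary for the slide-storage study design: the seven
# time x temperature histories and the eight antibody targets, plus
# filesystem-safe aliases used in generated filenames (canonical names
# contain "/" and "-", which cannot appear in file names).

.condition_vocab <- tibble::tibble(
  condition = c("-80_28d", "-20_28d", "-20_8w", "-20/RT/-80",
                "4/RT/-80", "RT/RT/-80", "RT_28d"),
  alias     = c("m80_28d", "m20_28d", "m20_8w", "m20_RT_m80",
                "t4_RT_m80", "RT_RT_m80", "RT_28d")
)

.antibody_vocab <- c("DNAH5", "DNALI1", "RSPH4A", "RSPH9",
                     "GAS8", "CCDC39", "CCDC40", "SPEF2")

#' Controlled vocabularies for the storage-condition study design
#'
#' `storage_conditions()` returns the seven slide storage conditions
#' (time x temperature histories between slide preparation and staining)
#' together with the filesystem-safe aliases used in generated image file
#' names. `antibody_targets()` returns the eight axonemal protein targets
#' of the diagnostic antibody panel.
#'
#' @return `storage_conditions()`: a tibble with columns `condition`
#'   (canonical name) and `alias` (filename-safe token).
#'   `antibody_targets()`: a character vector of length 8.
#' @examples
#' storage_conditions()
#' antibody_targets()
#' @export
storage_conditions <- function() .condition_vocab

#' @rdname storage_conditions
#' @export
antibody_targets <- function() .antibody_vocab

#' Map between canonical condition names and filename aliases
#'
#' Unknown tokens are passed through unchanged with a warning, so slide
#' sets using a vocabulary other than the seven-condition study design can
#' still be processed.
#'
#' @param x character vector of condition names or aliases.
#' @param warn emit a warning for tokens outside the vocabulary?
#' @return character vector of the same length.
#' @export
condition_to_alias <- function(x, warn = TRUE) {
  i <- match(x, .condition_vocab$condition)
  out <- ifelse(is.na(i), x, .condition_vocab$alias[i])
  unknown <- is.na(i) & !(x %in% .condition_vocab$alias)
  if (warn && any(unknown)) {
    rlang::warn(paste0("condition token(s) outside the study vocabulary: ",
                       paste(unique(x[unknown]), collapse = ", ")))
  }
  out
}

#' @rdname condition_to_alias
#' @export
alias_to_condition <- function(x, warn = TRUE) {
  i <- match(x, .condition_vocab$alias)
  out <- ifelse(is.na(i), x, .condition_vocab$condition[i])
  unknown <- is.na(i) & !(x %in% .condition_vocab$condition)
  if (warn && any(unknown)) {
    rlang::warn(paste0("condition token(s) outside the study vocabulary: ",
                       paste(unique(x[unknown]), collapse = ", ")))
  }
  out
}

#' Default better-direction map for the scored parameters
#'
#' For each headline parameter, states whether a lower or a higher value
#' indicates staining more similar to the stable axoneme marker: small,
#' regular (low compactness), elongated (high eccentricity) objects with
#' symmetric intensity, strong red-to-green rank colocalization and short
#' centroid distance to the paired marker object.
#'
#' @return a tibble with columns `parameter` and `direction`
#'   (`"lower"` or `"higher"`).
#' @export
default_direction_map <- function() {
  tibble::tibble(
    parameter = c("AreaShape_Area", "AreaShape_Compactness",
                  "AreaShape_Eccentricity", "Intensity_MassDisplacement",
                  "Correlation_RWC_RED_GREEN", "Distance_Centroid_mCilia"),
    direction = c("lower", "lower", "higher", "lower", "higher", "lower")
  )
}

# Conditions whose storage history includes a prolonged room-temperature
# period; the antibody re-ranking variant drops these.
prolonged_rt_conditions <- function() c("RT/RT/-80", "RT_28d")
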