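#' Tissue volume from a label map
#'
#' Voxel-count volume of one tissue class: count times the voxel volume,
#' reported in cm^3.
#'
#' @param map a [label_map()].
#' @param tissue_class tissue name (e.g. `"muscle"`) or integer code.
#' @return volume in cm^3.
#' @export
volume_from_labels <- function(map, tissue_class) {
  stopifnot(inherits(map, "label_map"))
  code <- resolve_class(map, tissue_class)
  sum(map$labels == code) * voxel_volume_mm3(map) / 1000
}

#' Soft-tissue composition percentage
#'
#' The percentage a tissue contributes to the combined muscle plus
#' subcutaneous fat volume: `100 * V_tissue / (V_musc + V_fat)`. Muscle and
#' fat percentages of one leg sum to 100.
#'
#' @param v_tissue volume of the tissue of interest (one of the other two).
#' @param v_musc,v_fat muscle and subcutaneous fat volumes (same units).
#' @return percentage in [0, 100].
#' @examples
#' tissue_percent(1262.4, 1262.4, 765.5)  # muscle share, ~62.3
#' @export
tissue_percent <- function(v_tissue, v_musc, v_fat) {
  denom <- v_musc + v_fat
  if (any(denom <= 0))
    stop("undefined composition: V_musc + V_fat must be > 0", call. = FALSE)
  100 * v_tissue / denom
}

#' Contralateral volume ratio
#'
#' Plain quotient of two paired-leg values. Orientation convention:
#' affected/unaffected for unilateral cases, right/left for controls and
#' bilateral cases.
#'
#' @param numerator_vol,denominator_vol paired-leg values.
#' @return the ratio.
#' @export
contralateral_ratio <- function(numerator_vol, denominator_vol) {
  if (any(denominator_vol == 0))
    stop("undefined ratio: zero denominator", call. = FALSE)
  numerator_vol / denominator_vol
}

#' Assemble the full measurement record for one leg
#'
#' Computes all per-leg quantities from a segmented label map: whole-leg
#' volume (all non-background voxels) within the leg extent, muscle and
#' subcutaneous fat volumes within the soft-tissue extent, tibia and fibula
#' volumes from the full map, the soft-tissue composition percentages, and
#' the supplied intramuscular-fat statistic.
#'
#' @param map a segmented [label_map()].
#' @param config a [segmentation_config()] carrying the extents (`NULL`
#'   extents mean the full slice range).
#' @param ta_value the leg's TA_Musc percentage, if computed.
#' @param side,side_status leg annotations carried through to the record.
#' @return a one-row data frame of class `leg_measurement` with columns
#'   V_Leg, V_Musc, V_Fat, V_Tibia, V_Fibula (cm^3), Muscle_pct, Fat_pct,
#'   TA_Musc, side, side_status.
#' @export
measure_leg <- function(map, config = segmentation_config(), ta_value = NA_real_,
                        side = NA_character_, side_status = NA_character_) {
  stopifnot(inherits(map, "label_map"))
  nz <- dim(map$labels)[3]
  full <- c(1L, nz)
  leg_extent <- config$leg_extent %||% full
  soft_extent <- config$soft_tissue_extent %||% full

  leg_map <- crop_axial_extent(map, leg_extent)
  v_leg <- sum(leg_map$labels != 0L) * voxel_volume_mm3(map) / 1000

  soft_map <- crop_axial_extent(map, soft_extent)
  v_musc <- volume_from_labels(soft_map, "muscle") +
    volume_from_labels(soft_map, "intramuscular_fat") +
    volume_from_labels(soft_map, "artery")
  v_fat <- volume_from_labels(soft_map, "subcut_fat")

  v_tibia <- volume_from_labels(map, "tibia")
  v_fibula <- volume_from_labels(map, "fibula")

  muscle_pct <- tissue_percent(v_musc, v_musc, v_fat)
  fat_pct <- tissue_percent(v_fat, v_musc, v_fat)

  out <- data.frame(V_Leg = v_leg, V_Musc = v_musc, V_Fat = v_fat,
                    V_Tibia = v_tibia, V_Fibula = v_fibula,
                    Muscle_pct = muscle_pct, Fat_pct = fat_pct,
                    TA_Musc = ta_value, side = side, side_status = side_status,
                    stringsAsFactors = FALSE)
  class(out) <- c("leg_measurement", class(out))
  out
}
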