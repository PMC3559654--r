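#' Configure the intramuscular-fat statistic
#'
#' Parameters of the high-intensity muscle pixel statistic: each muscle
#' voxel is compared against a local reference intensity computed from the
#' neighbouring muscle voxels in its axial slice ("pixels", hence an
#' in-plane 2D window), and counted as high if it exceeds
#' `threshold_multiplier` times that reference.
#'
#' @param window_radius_voxels in-plane square window radius (>= 1);
#'   default 5 voxels.
#' @param reference_statistic `"median"` (robust when speckles cluster;
#'   default) or `"mean"`.
#' @param threshold_multiplier intensity ratio cut (> 1); default 1.5.
#' @param min_neighbors minimum muscle voxels required in a window for a
#'   valid reference; voxels failing this are excluded from both counts.
#' @return an object of class `ta_config`.
#' @export
ta_config <- function(window_radius_voxels = 5L,
                      reference_statistic = c("median", "mean"),
                      threshold_multiplier = 1.5,
                      min_neighbors = 10L) {
  reference_statistic <- match.arg(reference_statistic)
  if (window_radius_voxels < 1L)
    stop("`window_radius_voxels` must be >= 1", call. = FALSE)
  if (threshold_multiplier <= 1)
    stop("`threshold_multiplier` must be > 1", call. = FALSE)
  if (min_neighbors < 1L)
    stop("`min_neighbors` must be >= 1", call. = FALSE)
  structure(list(window_radius_voxels = as.integer(window_radius_voxels),
                 reference_statistic = reference_statistic,
                 threshold_multiplier = threshold_multiplier,
                 min_neighbors = as.integer(min_neighbors)),
            class = "ta_config")
}

#' Local muscle reference intensity
#'
#' For every muscle voxel, the median (or mean) intensity of the muscle
#' voxels inside the in-plane square window of the configured radius,
#' excluding the centre voxel itself. Voxels with fewer than
#' `min_neighbors` muscle neighbours are flagged invalid.
#'
#' @param grid a [voxel_grid()].
#' @param muscle_mask logical array (same shape) marking muscle voxels, or a
#'   [label_map()] whose muscle class is used.
#' @param config a [ta_config()].
#' @return list with `reference` (numeric array, `NA` outside the mask),
#'   `n_neighbors` (integer array) and `valid` (logical array: masked voxels
#'   with enough neighbours).
#' @export
local_muscle_reference <- function(grid, muscle_mask, config = ta_config()) {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- as_muscle_mask(muscle_mask, dim(grid$values))
  if (!any(mask))
    stop("empty muscle region", call. = FALSE)
  res <- .local_masked_reference(as.vector(grid$values), as.vector(mask),
                                 dim(grid$values),
                                 config$window_radius_voxels,
                                 config$reference_statistic == "median")
  ref <- array(res$reference, dim = dim(grid$values))
  cnt <- array(res$n_neighbors, dim = dim(grid$values))
  list(reference = ref, n_neighbors = cnt,
       valid = mask & cnt >= config$min_neighbors)
}

as_muscle_mask <- function(muscle_mask, dims) {
  if (inherits(muscle_mask, "label_map")) {
    mask <- muscle_mask$labels == TISSUE_CODES[["muscle"]]
  } else {
    mask <- muscle_mask
    storage.mode(mask) <- "logical"
  }
  stopifnot(identical(dim(mask), dims))
  mask
}

#' Intramuscular-fat statistic: percentage of high-intensity muscle voxels
#'
#' The proportion of valid muscle voxels whose intensity exceeds
#' `threshold_multiplier` (default 1.5) times their local muscle reference:
#' `100 * Pixel_High / Pixel_Musc`. A proxy for intra- and inter-muscular
#' adipose tissue, which appears as bright speckles inside muscle on
#' T1-weighted images.
#'
#' @inheritParams local_muscle_reference
#' @return percentage in [0, 100].
#' @examples
#' vals <- array(100, c(20, 20, 3))
#' vals[10, 10, 2] <- 300
#' mask <- array(TRUE, c(20, 20, 3))
#' ta_musc(voxel_grid(vals), mask)  # one high voxel in 1200
#' @export
ta_musc <- function(grid, muscle_mask, config = ta_config()) {
  ref <- local_muscle_reference(grid, muscle_mask, config)
  valid <- ref$valid
  n_musc <- sum(valid)
  if (n_musc == 0)
    stop("empty muscle region after validity filtering", call. = FALSE)
  high <- valid & grid$values > config$threshold_multiplier * ref$reference
  100 * sum(high, na.rm = TRUE) / n_musc
}

#' Contralateral ratio of intramuscular-fat statistics
#'
#' Quotient of two legs' TA_Musc values, with the same orientation rules as
#' the volume ratios (affected/unaffected for unilateral cases, right/left
#' otherwise).
#'
#' @param ta_a,ta_b TA_Musc percentages of the two legs.
#' @return the ratio.
#' @export
ta_ratio_contralateral <- function(ta_a, ta_b) {
  contralateral_ratio(ta_a, ta_b)
}
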