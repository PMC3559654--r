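#' Read a 3D image volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @return a [voxel_grid()] with spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("malformed NIfTI header: non-positive pixdim in ", path, call. = FALSE)
  voxel_grid(array(as.numeric(img), dim = d), spacing = sp)
}

#' Write a voxel grid or label map as NIfTI-1
#'
#' Round-trips values, shape and spacing within float precision. Label maps
#' are written as integer volumes.
#'
#' @param x a [voxel_grid()] or [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    arr <- x$values
  } else if (inherits(x, "label_map")) {
    arr <- x$labels
  } else stop("`x` must be a voxel_grid or label_map", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from a NIfTI-1 file
#'
#' @param path path to the file.
#' @param class_names named integer code map (default [TISSUE_CODES]).
#' @return a [label_map()].
#' @export
read_label_map <- function(path, class_names = TISSUE_CODES) {
  g <- read_volume(path)
  lab <- g$values
  if (max(abs(lab - round(lab))) > 1e-6)
    stop("volume does not contain integer labels: ", path, call. = FALSE)
  label_map(array(as.integer(round(lab)), dim = dim(lab)),
            spacing = g$spacing, class_names = class_names)
}

MEASUREMENT_NAMES <- c("V_Leg", "V_Musc", "V_Fat", "V_Tibia", "V_Fibula",
                       "TA_Musc")

# Validate a long-format measurement table.
validate_measurement_table <- function(df) {
  needed <- c("participant", "group", "side", "side_status", "measurement",
              "value", "units")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(df$measurement %in% MEASUREMENT_NAMES))
    stop("unknown measurement names: ",
         paste(setdiff(df$measurement, MEASUREMENT_NAMES), collapse = ", "),
         call. = FALSE)
  if (!all(df$side_status %in% c("right", "left", "affected", "unaffected")))
    stop("invalid side_status values", call. = FALSE)
  key <- paste(df$participant, df$side, df$measurement)
  if (anyDuplicated(key))
    stop("duplicate (participant, side, measurement) entries", call. = FALSE)
  vols <- df$measurement != "TA_Musc"
  if (any(df$value[vols] <= 0))
    stop("volumes must be positive", call. = FALSE)
  ta <- df$value[!vols]
  if (any(ta < 0 | ta > 100))
    stop("TA_Musc must lie in [0, 100]", call. = FALSE)
  df
}

#' Read / write a per-leg measurement table
#'
#' Long-format CSV with one value per (participant, side, measurement):
#' columns `participant`, `group` (control / unilateral / bilateral), `side`
#' (right / left), `side_status` (right / left / affected / unaffected),
#' `measurement` (V_Leg, V_Musc, V_Fat, V_Tibia, V_Fibula in cm^3; TA_Musc
#' in percent), `value`, `units`.
#'
#' @param path CSV path.
#' @return a validated data frame.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_measurement_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurement_table
#' @param df a measurement table data frame.
#' @export
write_measurement_table <- function(df, path) {
  validate_measurement_table(df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load the published per-leg measurement fixture
#'
#' The package ships the printed per-leg values of the source cohort study
#' verbatim (volumes to 1 decimal in cm^3, TA_Musc in percent): 11
#' participants (5 controls, 4 unilateral, 2 bilateral clubfoot), 2 legs
#' each, 6 measurements per leg. No re-derivation is done at load time.
#'
#' @return a measurement table data frame (see [read_measurement_table()]).
#' @examples
#' tab <- load_paper_fixture()
#' subset(tab, participant == "C1" & measurement == "V_Leg")
#' @export
load_paper_fixture <- function() {
  read_measurement_table(system.file("extdata", "ctev_leg_measurements.csv",
                                     package = "legquant", mustWork = TRUE))
}

#' Load the printed derived columns of the published tables
#'
#' The ratio and composition columns exactly as printed (kept as character
#' strings so each cell retains its own decimal precision), used to check
#' that quantities recomputed from the fixture volumes reproduce the tables.
#'
#' @return data frame with columns `participant`, `quantity`, `side`,
#'   `printed`.
#' @export
load_printed_derived <- function() {
  read.csv(system.file("extdata", "ctev_printed_derived.csv",
                       package = "legquant", mustWork = TRUE),
           stringsAsFactors = FALSE, colClasses = "character")
}

# Decimal places implied by a printed numeric string ("1.0" -> 1, "51" -> 0).
printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}
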