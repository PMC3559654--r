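#' Tissue class codes
#'
#' Integer label codes used throughout the package for tissue classes in a
#' [label_map()]. Background is always 0; intramuscular fat is kept as a
#' separate class in ground-truth maps even though it counts toward muscle
#' volume in volumetry.
#'
#' @format a named integer vector.
#' @export
TISSUE_CODES <- c(
  background        = 0L,
  muscle            = 1L,
  subcut_fat        = 2L,
  tibia             = 3L,
  fibula            = 4L,
  intramuscular_fat = 5L,
  artery            = 6L
)

#' Construct a voxel grid (3D scalar image volume)
#'
#' The basic image substrate: a 3D numeric array with physical voxel spacing
#' in millimetres and an origin offset. The axial (through-leg) axis is the
#' third array axis by convention; axial "slices" are planes of constant
#' third index.
#'
#' @param values 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm offset of the first voxel.
#' @return an object of class `voxel_grid` with elements `values`, `spacing`,
#'   `origin`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Construct a label map (3D integer tissue-class volume)
#'
#' @param labels 3D integer array of non-negative class codes, aligned
#'   voxel-for-voxel with its paired [voxel_grid()].
#' @param spacing,origin as in [voxel_grid()].
#' @param class_names named integer vector mapping tissue name to code
#'   (default [TISSUE_CODES]); every nonzero label present in `labels` must
#'   appear among its values.
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      class_names = TISSUE_CODES) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("labels must be non-negative", call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, class_names)
  if (length(unknown))
    stop("labels present without a class name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)", call. = FALSE)
  structure(list(labels = labels, spacing = spacing, origin = as.numeric(origin),
                 class_names = class_names),
            class = "label_map")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range: ", paste(signif(range(x$values), 5), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(factor(as.vector(x$labels), levels = x$class_names,
                      labels = names(x$class_names)))
  tab <- tab[tab > 0]
  for (i in seq_along(tab))
    cat(sprintf("  %-18s %d voxels\n", names(tab)[i], as.integer(tab[i])))
  invisible(x)
}

# Resolve a tissue class given by name or code to its integer code.
resolve_class <- function(map, tissue_class) {
  cn <- map$class_names
  if (is.character(tissue_class)) {
    if (!tissue_class %in% names(cn))
      stop("unknown tissue class: ", tissue_class, call. = FALSE)
    unname(cn[tissue_class])
  } else {
    code <- as.integer(tissue_class)
    if (!code %in% c(0L, cn))
      stop("unknown tissue class code: ", code, call. = FALSE)
    code
  }
}

# Voxel volume in mm^3.
voxel_volume_mm3 <- function(x) prod(x$spacing)
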