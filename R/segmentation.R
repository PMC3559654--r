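#' Configure the tissue segmentation protocol
#'
#' Parameters of the automated emulation of a semi-automated
#' threshold-and-paint segmentation protocol: intensity thresholding
#' (multi-level Otsu or fixed cut points) followed by morphological cleanup
#' (in-plane closing and small-object removal), which stands in for manual
#' correction, plus the axial extents over which the leg and the soft
#' tissues are measured.
#'
#' Slice extents are given as inclusive 1-based `(first, last)` index pairs
#' along the third (axial) array axis; `NULL` means the full range.
#'
#' @param threshold_mode `"otsu-multiclass"` (default) or `"fixed"`.
#' @param fixed_thresholds for `"fixed"` mode, two strictly increasing
#'   intensity cut points separating dark / mid / bright classes.
#' @param closing_radius_voxels radius of the in-plane binary closing applied
#'   per tissue class; 0 (the default) disables closing, which suffices at
#'   the study SNRs where threshold noise is negligible — closing is useful
#'   for lower-quality images but erodes thin structures like the fibula.
#' @param min_component_voxels connected components smaller than this are
#'   merged into their surrounding class.
#' @param leg_extent inclusive slice range over which the whole-leg volume is
#'   measured.
#' @param soft_tissue_extent inclusive slice range over which muscle and
#'   subcutaneous fat are measured.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_mode = c("otsu-multiclass", "fixed"),
                                fixed_thresholds = NULL,
                                closing_radius_voxels = 0,
                                min_component_voxels = 27,
                                leg_extent = NULL,
                                soft_tissue_extent = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed") {
    if (is.null(fixed_thresholds) || length(fixed_thresholds) != 2L ||
        diff(fixed_thresholds) <= 0)
      stop("`fixed_thresholds` must be two strictly increasing cut points",
           call. = FALSE)
  }
  check_extent <- function(extent, what) {
    if (is.null(extent)) return(NULL)
    extent <- as.integer(extent)
    if (length(extent) != 2L || extent[1] > extent[2] || extent[1] < 1L)
      stop("`", what, "` must be an inclusive (first, last) pair with ",
           "first <= last and first >= 1", call. = FALSE)
    extent
  }
  structure(list(threshold_mode = threshold_mode,
                 fixed_thresholds = fixed_thresholds,
                 closing_radius_voxels = as.integer(closing_radius_voxels),
                 min_component_voxels = as.integer(min_component_voxels),
                 leg_extent = check_extent(leg_extent, "leg_extent"),
                 soft_tissue_extent = check_extent(soft_tissue_extent,
                                                   "soft_tissue_extent")),
            class = "segmentation_config")
}

#' Restrict a volume or label map to an axial slice range
#'
#' Voxels outside the inclusive slice range are set to background (0);
#' voxels inside are unchanged.
#'
#' @param x a [voxel_grid()] or [label_map()].
#' @param extent inclusive 1-based `(first, last)` slice pair along the
#'   axial (third) axis.
#' @return an object of the same type as `x`.
#' @export
crop_axial_extent <- function(x, extent) {
  arr <- if (inherits(x, "voxel_grid")) x$values
         else if (inherits(x, "label_map")) x$labels
         else stop("`x` must be a voxel_grid or label_map", call. = FALSE)
  nz <- dim(arr)[3]
  extent <- as.integer(extent)
  if (length(extent) != 2L || extent[1] > extent[2])
    stop("extent must be an ordered (first, last) pair", call. = FALSE)
  if (extent[1] < 1L || extent[2] > nz)
    stop("extent [", extent[1], ", ", extent[2], "] outside slice range 1..",
         nz, call. = FALSE)
  keep <- seq(extent[1], extent[2])
  out <- arr
  out[, , setdiff(seq_len(nz), keep)] <- if (inherits(x, "label_map")) 0L else 0
  if (inherits(x, "voxel_grid")) {
    voxel_grid(out, spacing = x$spacing, origin = x$origin)
  } else {
    label_map(out, spacing = x$spacing, origin = x$origin,
              class_names = x$class_names)
  }
}

# Multi-level Otsu: two thresholds maximising between-class variance over a
# three-class split of the intensity histogram.
otsu_two_thresholds <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!all(is.finite(rng)) || diff(rng) < 1e-8)
    stop("degenerate image: fewer intensity modes than tissue classes",
         call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_bins)
  p <- counts / sum(counts)
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  # class k spans bins (a, b]: weight cw[b]-cw[a], first moment cm[b]-cm[a];
  # maximise sum_k m_k^2 / w_k (equivalent to between-class variance)
  best <- -Inf; best_t <- c(NA, NA)
  for (t1 in 1:(n_bins - 2L)) {
    w1 <- cw[t1]; m1 <- cm[t1]
    if (w1 <= 0) next
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- cw[t2] - w1;        m2 <- cm[t2] - m1
    w3 <- cw[n_bins] - cw[t2]; m3 <- cm[n_bins] - cm[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    crit <- rep(-Inf, length(t2))
    crit[ok] <- m1^2 / w1 + m2[ok]^2 / w2[ok] + m3[ok]^2 / w3[ok]
    j <- which.max(crit)
    if (crit[j] > best) {
      best <- crit[j]
      best_t <- c(breaks[t1 + 1L], breaks[t2[j] + 1L])
    }
  }
  if (!all(is.finite(best_t)))
    stop("degenerate image: fewer intensity modes than tissue classes",
         call. = FALSE)
  # refine each cut to the midpoint of the adjacent class means: the
  # variance-optimal cut can sit arbitrarily close to a class mode when the
  # histogram has wide empty gaps, whereas the equidistant decision boundary
  # is robust to intensity perturbation
  cls <- findInterval(values, best_t) + 1L
  mu <- vapply(1:3, function(k) mean(values[cls == k]), numeric(1))
  if (any(!is.finite(mu)))
    stop("degenerate image: fewer intensity modes than tissue classes",
         call. = FALSE)
  c((mu[1] + mu[2]) / 2, (mu[2] + mu[3]) / 2)
}

# Component ids of `cc` touching any face of the 3D array.
face_touching_ids <- function(cc, dims) {
  ids <- c(cc[c(1, dims[1]), , ], cc[, c(1, dims[2]), ], cc[, , c(1, dims[3])])
  setdiff(unique(ids), 0L)
}

# Per-slice (in-plane 2D) connected components, labelled uniquely across
# slices. Used to resolve background versus bone: cortical bone is enclosed
# by soft tissue in every axial section, while background reaches the
# in-plane image border, even though the two may touch axially beyond the
# leg ends.
cc_label_inplane <- function(mask, dims) {
  cc <- array(0L, dim = dims)
  offset <- 0L
  for (z in seq_len(dims[3])) {
    sl <- .cc_label_3d(as.vector(mask[, , z]), c(dims[1], dims[2], 1L), 6L)
    pos <- sl > 0L
    sl[pos] <- sl[pos] + offset
    cc[, , z] <- sl
    if (any(pos)) offset <- max(sl)
  }
  cc
}

# In-plane border-touching component ids, per slice.
border_touching_ids_inplane <- function(cc, dims) {
  ids <- c(cc[c(1, dims[1]), , ], cc[, c(1, dims[2]), ])
  setdiff(unique(ids), 0L)
}

# Component ids (of `cc`, computed on a mask) 6-adjacent to `other` mask.
ids_adjacent_to <- function(cc, other, dims) {
  ids <- integer(0)
  shift_collect <- function(axis, by) {
    idx_src <- slice.index(cc, axis)
    # voxels of cc whose neighbour at +by along axis is in `other`
    n <- dims[axis]
    if (axis == 1) {
      a <- cc[-n, , , drop = FALSE]; b <- other[-1, , , drop = FALSE]
      c(a[b], cc[-1, , ][other[-n, , ]])
    } else if (axis == 2) {
      a <- cc[, -n, , drop = FALSE]; b <- other[, -1, , drop = FALSE]
      c(a[b], cc[, -1, ][other[, -n, ]])
    } else {
      a <- cc[, , -n, drop = FALSE]; b <- other[, , -1, drop = FALSE]
      c(a[b], cc[, , -1][other[, , -n]])
    }
  }
  for (ax in 1:3) ids <- c(ids, shift_collect(ax))
  setdiff(unique(ids), 0L)
}

# Merge connected components smaller than min_size into the majority class
# among their 6-neighbour voxels.
remove_small_components <- function(labels, dims, min_size) {
  if (min_size <= 1L) return(labels)
  for (code in setdiff(sort(unique(as.vector(labels))), 0L)) {
    mask <- labels == code
    cc <- array(.cc_label_3d(as.vector(mask), dims, 6L), dim = dims)
    sizes <- tabulate(cc[cc > 0L])
    small <- which(sizes < min_size)
    for (id in small) {
      vox <- which(cc == id)
      nb <- integer(0)
      for (v in vox) {
        z <- (v - 1L) %/% (dims[1] * dims[2])
        rem <- (v - 1L) %% (dims[1] * dims[2])
        y <- rem %/% dims[1]; x <- rem %% dims[1]
        for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
          xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
          if (xx < 0 || xx >= dims[1] || yy < 0 || yy >= dims[2] ||
              zz < 0 || zz >= dims[3]) next
          w <- zz * dims[1] * dims[2] + yy * dims[1] + xx + 1L
          if (!(w %in% vox)) nb <- c(nb, labels[w])
        }
      }
      if (length(nb)) {
        tab <- table(nb)
        labels[vox] <- as.integer(names(tab)[which.max(tab)])
      }
    }
  }
  labels
}

# In-plane binary closing via the compiled dilate/erode kernels.
binary_close_inplane <- function(mask, dims, radius) {
  if (radius <= 0L) return(mask)
  d <- .morph_inplane(as.vector(mask), dims, radius, 1L)
  array(.morph_inplane(d, dims, radius, 0L), dim = dims)
}

#' Segment a leg volume into tissue classes
#'
#' Emulates a semi-automated protocol: three-class intensity thresholding
#' (dark / mid / bright), resolution of the dark class into background versus
#' cortical bone by connectivity (dark components touching the image faces
#' are background; enclosed dark components are bone), resolution of the
#' bright class into the subcutaneous fat shell (bright components adjacent
#' to background) versus intramuscular fat (bright islands enclosed by
#' muscle, which stay labelled muscle for volumetry — they are detected
#' later by the intramuscular-fat statistic, not excluded from muscle
#' volume), then per-class in-plane closing and small-object removal in
#' place of manual correction. Bone components are split into tibia (larger)
#' and fibula (smaller), with ties broken by greater mean cross-sectional
#' area.
#'
#' @param grid a finite-valued [voxel_grid()].
#' @param config a [segmentation_config()].
#' @return a [label_map()] partitioning every voxel into background, muscle,
#'   subcutaneous fat, tibia or fibula.
#' @export
segment_tissues <- function(grid, config = segmentation_config()) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(config, "segmentation_config"))
  vals <- grid$values
  if (!all(is.finite(vals)))
    stop("image contains non-finite intensities", call. = FALSE)
  dims <- dim(vals)

  thr <- if (config$threshold_mode == "fixed") config$fixed_thresholds
         else otsu_two_thresholds(as.vector(vals))

  dark <- vals < thr[1]
  bright <- vals >= thr[2]

  labels <- array(TISSUE_CODES[["muscle"]], dim = dims)

  # dark: background reaches the in-plane image border in its slice,
  # enclosed dark is bone (resolved per axial slice, since bone may touch
  # background axially beyond the leg ends)
  cc_dark <- cc_label_inplane(dark, dims)
  bg_ids <- border_touching_ids_inplane(cc_dark, dims)
  is_bg <- cc_dark > 0L & (cc_dark %in% bg_ids)
  labels[is_bg] <- TISSUE_CODES[["background"]]
  bone_temp <- 99L
  labels[dark & !is_bg] <- bone_temp

  # bright: the fat shell is adjacent to background, enclosed bright stays
  # muscle (intramuscular fat)
  cc_bright <- array(.cc_label_3d(as.vector(bright), dims, 6L), dim = dims)
  fat_ids <- ids_adjacent_to(cc_bright, labels == TISSUE_CODES[["background"]],
                             dims)
  labels[cc_bright > 0L & (cc_bright %in% fat_ids)] <- TISSUE_CODES[["subcut_fat"]]

  # morphological cleanup in place of manual painting
  if (config$closing_radius_voxels > 0L) {
    for (code in c(TISSUE_CODES[["subcut_fat"]], TISSUE_CODES[["muscle"]],
                   bone_temp)) {
      closed <- binary_close_inplane(labels == code, dims,
                                     config$closing_radius_voxels)
      labels[closed & labels != code] <- code
    }
  }
  labels <- remove_small_components(labels, dims, config$min_component_voxels)

  # split bone into tibia / fibula by component size
  bone_mask <- labels == bone_temp
  if (!any(bone_mask))
    stop("degenerate image: no enclosed dark (bone) component found",
         call. = FALSE)
  cc_bone <- array(.cc_label_3d(as.vector(bone_mask), dims, 6L), dim = dims)
  sizes <- tabulate(cc_bone[cc_bone > 0L])
  n_slices_spanned <- vapply(seq_along(sizes), function(id) {
    length(unique(which(apply(cc_bone == id, 3, any))))
  }, numeric(1))
  mean_area <- sizes / pmax(1, n_slices_spanned)
  ord <- order(sizes, mean_area, decreasing = TRUE)
  tib_id <- ord[1]
  labels[cc_bone == tib_id] <- TISSUE_CODES[["tibia"]]
  if (length(ord) >= 2L) {
    fib_id <- ord[2]
    labels[cc_bone == fib_id] <- TISSUE_CODES[["fibula"]]
    if (length(ord) > 2L) {
      # stray bone fragments join the nearer major bone (by centroid)
      centroid <- function(id) colMeans(which(cc_bone == id, arr.ind = TRUE))
      c_tib <- centroid(tib_id); c_fib <- centroid(fib_id)
      for (id in ord[-(1:2)]) {
        c_id <- centroid(id)
        tgt <- if (sum((c_id - c_tib)^2) <= sum((c_id - c_fib)^2))
          TISSUE_CODES[["tibia"]] else TISSUE_CODES[["fibula"]]
        labels[cc_bone == id] <- tgt
      }
    }
  } else {
    labels[cc_bone > 0L] <- TISSUE_CODES[["tibia"]]
  }

  label_map(labels, spacing = grid$spacing, origin = grid$origin)
}

#' Subtract the diastolic from the systolic angiography volume
#'
#' @param systolic,diastolic [voxel_grid()]s of identical shape and spacing.
#' @return a [voxel_grid()] of voxelwise differences.
#' @export
mra_subtract <- function(systolic, diastolic) {
  stopifnot(inherits(systolic, "voxel_grid"), inherits(diastolic, "voxel_grid"))
  if (!identical(dim(systolic$values), dim(diastolic$values)) ||
      max(abs(systolic$spacing - diastolic$spacing)) > 1e-8)
    stop("systolic and diastolic volumes are not aligned (shape or spacing ",
         "mismatch)", call. = FALSE)
  voxel_grid(systolic$values - diastolic$values,
             spacing = systolic$spacing, origin = systolic$origin)
}

#' Segment arteries from a subtraction angiography difference image
#'
#' Thresholds the difference image at a multiple of its robust noise
#' standard deviation (median absolute deviation estimate) and removes
#' small connected components.
#'
#' @param difference a [voxel_grid()] from [mra_subtract()].
#' @param threshold_sd_mult threshold in units of the robust noise sd
#'   (default 5).
#' @param min_component_voxels small-object removal size.
#' @return a [label_map()] with artery voxels labelled.
#' @export
segment_arteries <- function(difference, threshold_sd_mult = 5,
                             min_component_voxels = 10L) {
  stopifnot(inherits(difference, "voxel_grid"))
  vals <- difference$values
  dims <- dim(vals)
  noise_sd <- mad(as.vector(vals))
  mask <- if (noise_sd > 0) vals >= threshold_sd_mult * noise_sd
          else vals > 0   # noise-free difference: any positive signal
  if (any(mask) && min_component_voxels > 1L) {
    cc <- array(.cc_label_3d(as.vector(mask), dims, 26L), dim = dims)
    sizes <- tabulate(cc[cc > 0L])
    keep <- which(sizes >= min_component_voxels)
    mask <- cc > 0L & (cc %in% keep)
  }
  labels <- array(ifelse(mask, TISSUE_CODES[["artery"]],
                         TISSUE_CODES[["background"]]), dim = dims)
  label_map(labels, spacing = difference$spacing, origin = difference$origin)
}

#' Dice overlap coefficient between two segmentations of one tissue
#'
#' `2|A∩B| / (|A|+|B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b [label_map()]s (with `tissue_class` naming the class to
#'   compare) or logical arrays/masks.
#' @param tissue_class tissue name or code, required for label maps.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b, tissue_class = NULL) {
  as_mask <- function(x) {
    if (inherits(x, "label_map")) {
      if (is.null(tissue_class))
        stop("`tissue_class` required for label maps", call. = FALSE)
      x$labels == resolve_class(x, tissue_class)
    } else x
  }
  ma <- as_mask(a); mb <- as_mask(b)
  stopifnot(identical(dim(ma), dim(mb)))
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(NA_real_)
  2 * sum(ma & mb) / denom
}

#' Collapse a ground-truth label map to segmentation-comparable classes
#'
#' Ground-truth phantoms distinguish intramuscular fat and artery voxels;
#' the tissue segmentation deliberately labels both as muscle (speckles are
#' detected by the intramuscular-fat statistic, and arterial blood has
#' muscle-like T1 intensity). This helper relabels those classes as muscle
#' so truth and segmentation can be compared class by class.
#'
#' @param map a ground-truth [label_map()].
#' @return a [label_map()] with classes background, muscle, subcutaneous
#'   fat, tibia, fibula.
#' @export
consolidate_truth <- function(map) {
  stopifnot(inherits(map, "label_map"))
  lab <- map$labels
  lab[lab == TISSUE_CODES[["intramuscular_fat"]]] <- TISSUE_CODES[["muscle"]]
  lab[lab == TISSUE_CODES[["artery"]]] <- TISSUE_CODES[["muscle"]]
  label_map(lab, spacing = map$spacing, origin = map$origin,
            class_names = map$class_names)
}
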