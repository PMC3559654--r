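#' Specify a synthetic lower-leg phantom
#'
#' Defines a seeded, analytically controllable 3D lower-leg phantom: a set of
#' concentric elliptic cylinders (subcutaneous fat shell around a muscle
#' core) with two embedded bone cylinders (tibia large, fibula small), an
#' optional axial artery tube, and intramuscular-fat speckle clusters inside
#' the muscle. Intensities follow a T1-weighted-like convention: muscle at a
#' fixed mean of 100 arbitrary units, subcutaneous (and intramuscular) fat
#' bright and cortical bone dark, both solved from Michelson contrasts
#' |S1-S2|/(S1+S2) against muscle. Additive Gaussian noise per class with
#' sd = class mean / SNR (the study-condition SNRs are high enough that a
#' Gaussian approximation to Rician noise is appropriate).
#'
#' The defaults emulate a control-sized adult lower leg at the reported
#' imaging conditions: 1 mm isotropic voxels, subcutaneous-fat SNR 180,
#' muscle SNR 57, fat/muscle contrast 0.52 and bone/muscle contrast 0.75.
#'
#' @param grid_shape integer length-3, voxel counts per axis (axial = third).
#' @param voxel_size numeric length-3, mm per voxel.
#' @param leg_length_mm axial extent of the leg in mm.
#' @param target_volumes named numeric, target tissue volumes in cm^3 for
#'   `muscle`, `subcut_fat`, `tibia`, `fibula`. Muscle counts include the
#'   intramuscular-fat speckles carved out of it.
#' @param speckle_fraction fraction of muscle voxels replaced by
#'   intramuscular-fat speckles, in [0, 0.5].
#' @param snr_fat,snr_muscle signal-to-noise ratios (> 1; `Inf` = noiseless).
#' @param contrast_fat_muscle,contrast_bone_muscle Michelson contrasts in (0,1).
#' @param artery_radius_mm radius of the axial artery tube; 0 for none.
#' @param seed integer RNG seed; all randomness flows from it via named
#'   streams.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160, 160, 300),
                         voxel_size = c(1, 1, 1),
                         leg_length_mm = 270,
                         target_volumes = c(muscle = 1150, subcut_fat = 760,
                                            tibia = 245, fibula = 43),
                         speckle_fraction = 0.015,
                         snr_fat = 180,
                         snr_muscle = 57,
                         contrast_fat_muscle = 0.52,
                         contrast_bone_muscle = 0.75,
                         artery_radius_mm = 2.5,
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  needed <- c("muscle", "subcut_fat", "tibia", "fibula")
  if (!all(needed %in% names(target_volumes)))
    stop("`target_volumes` must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  target_volumes <- target_volumes[needed]
  if (any(target_volumes <= 0))
    stop("all target volumes must be > 0", call. = FALSE)
  if (speckle_fraction < 0 || speckle_fraction > 0.5)
    stop("`speckle_fraction` must be in [0, 0.5]", call. = FALSE)
  if (snr_fat <= 1 || snr_muscle <= 1)
    stop("SNR values must be > 1", call. = FALSE)
  if (contrast_fat_muscle <= 0 || contrast_fat_muscle >= 1 ||
      contrast_bone_muscle <= 0 || contrast_bone_muscle >= 1)
    stop("contrasts must lie in (0, 1)", call. = FALSE)
  if (leg_length_mm <= 0)
    stop("`leg_length_mm` must be > 0", call. = FALSE)
  if (artery_radius_mm < 0)
    stop("`artery_radius_mm` must be >= 0", call. = FALSE)

  spec <- structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    leg_length_mm = leg_length_mm, target_volumes = target_volumes,
    speckle_fraction = speckle_fraction,
    snr_fat = snr_fat, snr_muscle = snr_muscle,
    contrast_fat_muscle = contrast_fat_muscle,
    contrast_bone_muscle = contrast_bone_muscle,
    artery_radius_mm = artery_radius_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  check_phantom_feasibility(spec)
  spec
}

# In-plane ellipse aspect ratio (minor/major) of the leg cross-section.
PHANTOM_ASPECT <- 0.78

# Verify that the requested cross-sectional areas fit inside the grid,
# naming the first tissue whose addition overflows the available area.
check_phantom_feasibility <- function(spec) {
  vz <- spec$voxel_size[3]
  n_sl <- round(spec$leg_length_mm / vz)
  if (n_sl < 1 || n_sl > spec$grid_shape[3])
    stop("leg axial extent (", n_sl, " slices) does not fit the grid",
         call. = FALSE)
  # largest ellipse with the fixed aspect ratio, leaving a 2-voxel margin
  half_x <- spec$grid_shape[1] * spec$voxel_size[1] / 2 - 2 * spec$voxel_size[1]
  half_y <- spec$grid_shape[2] * spec$voxel_size[2] / 2 - 2 * spec$voxel_size[2]
  a_max <- min(half_x, half_y / PHANTOM_ASPECT)
  if (a_max <= 0) stop("grid too small for any leg cross-section", call. = FALSE)
  area_max <- pi * a_max^2 * PHANTOM_ASPECT
  order_tissues <- c("muscle", "tibia", "fibula", "subcut_fat")
  cum_area <- cumsum(spec$target_volumes[order_tissues]) * 1000 / spec$leg_length_mm
  over <- which(cum_area > area_max)
  if (length(over))
    stop("target volumes geometrically infeasible: adding '",
         order_tissues[over[1]], "' needs ", round(cum_area[over[1]]),
         " mm^2 per slice but only ", round(area_max), " mm^2 fit",
         call. = FALSE)
  invisible(TRUE)
}

# Class mean intensities and noise sds implied by a spec. Muscle is fixed at
# 100 a.u.; fat and bone solved from the Michelson contrasts. Bone and
# background carry the muscle-level noise floor.
phantom_intensity_model <- function(spec) {
  musc <- 100
  cf <- spec$contrast_fat_muscle
  cb <- spec$contrast_bone_muscle
  fat  <- musc * (1 + cf) / (1 - cf)
  bone <- musc * (1 - cb) / (1 + cb)
  sd_musc <- musc / spec$snr_muscle
  sd_fat  <- fat / spec$snr_fat
  means <- c(background = 0, muscle = musc, subcut_fat = fat, tibia = bone,
             fibula = bone, intramuscular_fat = fat, artery = musc)
  sds <- c(background = sd_musc, muscle = sd_musc, subcut_fat = sd_fat,
           tibia = sd_musc, fibula = sd_musc, intramuscular_fat = sd_fat,
           artery = sd_musc)
  sds[!is.finite(sds)] <- 0
  list(means = means, sds = sds)
}

# Build the axial cross-section label matrix and slice range for a spec.
# Regions are selected by taking exactly the k nearest pixels in the
# elliptical metric (nested), so realized per-slice counts equal their
# targets; bones are the k nearest in-plane pixels around their centres
# among muscle-core pixels, which keeps them disjoint by construction.
phantom_cross_section <- function(spec) {
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  vx <- spec$voxel_size[1]; vy <- spec$voxel_size[2]; vz <- spec$voxel_size[3]
  n_sl <- round(spec$leg_length_mm / vz)
  vox_vol <- vx * vy * vz

  # per-slice pixel quotas for each tissue
  k_of <- function(v_cm3) round(v_cm3 * 1000 / vox_vol / n_sl)
  k_musc <- k_of(spec$target_volumes[["muscle"]])
  k_fat  <- k_of(spec$target_volumes[["subcut_fat"]])
  k_tib  <- k_of(spec$target_volumes[["tibia"]])
  k_fib  <- k_of(spec$target_volumes[["fibula"]])
  if (min(k_musc, k_fat, k_tib, k_fib) < 1)
    stop("a tissue's per-slice quota is below one voxel; increase its ",
         "target volume or coarsen the grid", call. = FALSE)

  cx <- nx * vx / 2; cy <- ny * vy / 2
  px <- (seq_len(nx) - 0.5) * vx
  py <- (seq_len(ny) - 0.5) * vy
  X <- matrix(px, nx, ny)
  Y <- matrix(py, nx, ny, byrow = TRUE)
  d2 <- (X - cx)^2 + ((Y - cy) / PHANTOM_ASPECT)^2
  ord <- order(d2, seq_along(d2))   # deterministic tie-break by index

  # artery pixel set from pure geometry (inside the muscle core)
  k_inner_nb <- k_musc + k_tib + k_fib   # without artery, for placement radii
  a_inner <- sqrt(k_inner_nb * vx * vy / (pi * PHANTOM_ASPECT))
  b_inner <- a_inner * PHANTOM_ASPECT
  if (spec$artery_radius_mm > 0) {
    ax <- cx + 0.10 * a_inner
    ay <- cy - 0.45 * b_inner
    art_idx <- which((X - ax)^2 + (Y - ay)^2 <= spec$artery_radius_mm^2)
  } else art_idx <- integer(0)
  k_art <- length(art_idx)

  k_inner <- k_musc + k_tib + k_fib + k_art
  k_leg <- k_inner + k_fat
  if (k_leg > nx * ny)
    stop("target volumes geometrically infeasible: adding 'subcut_fat' ",
         "exceeds the in-plane grid", call. = FALSE)

  cross <- matrix(TISSUE_CODES[["background"]], nx, ny)
  cross[ord[seq_len(k_leg)]] <- TISSUE_CODES[["subcut_fat"]]
  inner_idx <- ord[seq_len(k_inner)]
  cross[inner_idx] <- TISSUE_CODES[["muscle"]]

  # bones: exact-count nearest-pixel discs inside the muscle core, placed
  # radius-aware so that small (affected) legs keep the bones separated and
  # inside the core
  r_tib <- sqrt(k_tib * vx * vy / pi)
  r_fib <- sqrt(k_fib * vx * vy / pi)
  margin <- max(vx, vy)
  tib_cx <- cx + min(0.38 * a_inner, a_inner - r_tib - margin)
  tib_cy <- cy
  fib_cx <- tib_cx - (r_tib + r_fib + 1.5 * margin)
  fib_cy <- cy + 0.20 * b_inner
  inside_core <- function(ccx, ccy, r) {
    sqrt((ccx - cx)^2 + ((ccy - cy) / PHANTOM_ASPECT)^2) + r + margin <=
      a_inner
  }
  if (!inside_core(fib_cx, fib_cy, r_fib)) fib_cy <- cy  # drop the y offset
  if (!inside_core(tib_cx, tib_cy, r_tib) ||
      !inside_core(fib_cx, fib_cy, r_fib))
    stop("target volumes geometrically infeasible: 'tibia' and 'fibula' ",
         "cross-sections do not fit inside the muscle core", call. = FALSE)

  take_nearest <- function(cand_idx, ccx, ccy, k, tissue) {
    if (k > length(cand_idx))
      stop("target volumes geometrically infeasible: '", tissue,
           "' does not fit inside the muscle core", call. = FALSE)
    dd <- (X[cand_idx] - ccx)^2 + (Y[cand_idx] - ccy)^2
    cand_idx[order(dd, cand_idx)[seq_len(k)]]
  }
  musc_pool <- setdiff(inner_idx, art_idx)
  tib_idx <- take_nearest(musc_pool, tib_cx, tib_cy, k_tib, "tibia")
  musc_pool <- setdiff(musc_pool, tib_idx)
  fib_idx <- take_nearest(musc_pool, fib_cx, fib_cy, k_fib, "fibula")

  cross[tib_idx] <- TISSUE_CODES[["tibia"]]
  cross[fib_idx] <- TISSUE_CODES[["fibula"]]
  cross[intersect(art_idx, inner_idx)] <- TISSUE_CODES[["artery"]]

  z0 <- floor((spec$grid_shape[3] - n_sl) / 2) + 1L
  list(cross = cross, z_range = c(z0, z0 + n_sl - 1L), n_slices = n_sl)
}

#' Generate a synthetic lower-leg phantom
#'
#' Builds the intensity volume and ground-truth label map defined by a
#' [phantom_spec()]. The label map is a partition: every voxel carries
#' exactly one class of background, muscle, subcutaneous fat, tibia, fibula,
#' intramuscular fat or artery. Identical spec and seed give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `leg_phantom` with elements `grid` (a
#'   [voxel_grid()]), `truth` (a [label_map()]) and `spec`.
#' @examples
#' ph <- generate_leg_phantom(phantom_spec(
#'   grid_shape = c(48, 48, 30), voxel_size = c(3, 3, 4), leg_length_mm = 100,
#'   target_volumes = c(muscle = 220, subcut_fat = 150, tibia = 48, fibula = 9),
#'   artery_radius_mm = 0, seed = 1))
#' ph$truth
#' @export
generate_leg_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_phantom_feasibility(spec)
  cs <- phantom_cross_section(spec)
  dims <- spec$grid_shape
  labels <- array(TISSUE_CODES[["background"]], dim = dims)
  for (z in cs$z_range[1]:cs$z_range[2]) labels[, , z] <- cs$cross

  # intramuscular-fat speckles: seeded spherical clusters (radius 1-2 voxels)
  # at uniformly random muscle locations; only current muscle voxels are
  # converted, so bone/artery overlap is rejected implicitly.
  if (spec$speckle_fraction > 0) {
    musc_code <- TISSUE_CODES[["muscle"]]
    imf_code <- TISSUE_CODES[["intramuscular_fat"]]
    n_musc <- sum(labels == musc_code)
    n_target <- round(spec$speckle_fraction * n_musc)
    if (n_target > 0) {
      offsets <- lapply(1:3, function(r) {
        g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
        g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
      })
      fat_code <- TISSUE_CODES[["subcut_fat"]]
      bg_code <- TISSUE_CODES[["background"]]
      labels <- with_stream(spec$seed, "speckle", {
        placed <- 0L
        nxy <- dims[1] * dims[2]
        musc_idx <- which(labels == musc_code)
        while (placed < n_target) {
          centre <- musc_idx[sample.int(length(musc_idx), 1L)]
          if (labels[centre] != musc_code) next   # already speckled
          r <- sample(1:2, 1L)
          z <- (centre - 1L) %/% nxy + 1L
          rem <- (centre - 1L) %% nxy
          y <- rem %/% dims[1] + 1L
          x <- rem %% dims[1] + 1L
          neighborhood <- function(off) {
            xs <- x + off$dx; ys <- y + off$dy; zs <- z + off$dz
            ok <- xs >= 1 & xs <= dims[1] & ys >= 1 & ys <= dims[2] &
                  zs >= 1 & zs <= dims[3]
            list(lin = (zs[ok] - 1L) * nxy + (ys[ok] - 1L) * dims[1] + xs[ok],
                 clipped = !all(ok))
          }
          # intramuscular fat sits interior to the muscle: reject placements
          # whose surroundings touch the subcutaneous shell or background,
          # so speckles never merge with the fat shell
          ring <- neighborhood(offsets[[r + 1L]])
          if (ring$clipped ||
              any(labels[ring$lin] %in% c(fat_code, bg_code))) next
          lin <- neighborhood(offsets[[r]])$lin
          lin <- lin[labels[lin] == musc_code]
          if (placed + length(lin) > n_target)
            lin <- lin[sample.int(length(lin), n_target - placed)]
          labels[lin] <- imf_code
          placed <- placed + length(lin)
        }
        labels
      })
    }
  }

  model <- phantom_intensity_model(spec)
  values <- model$means[as.vector(labels) + 1L]
  if (any(model$sds > 0)) {
    noise <- with_stream(spec$seed, "noise", rnorm(length(values)))
    values <- values + noise * model$sds[as.vector(labels) + 1L]
  }
  values <- array(values, dim = dims)

  structure(list(
    grid = voxel_grid(values, spacing = spec$voxel_size),
    truth = label_map(labels, spacing = spec$voxel_size),
    spec = spec,
    z_range = cs$z_range),
    class = "leg_phantom")
}

#' Generate a systole/diastole pair for subtraction angiography
#'
#' Produces two intensity volumes with identical anatomy whose only
#' systematic difference is elevated arterial signal during systole, so
#' that subtracting the diastolic from the systolic volume leaves bright
#' arteries on a noise-only background. Noise is drawn independently for the
#' two cardiac phases.
#'
#' @param spec a [phantom_spec()]; `artery_radius_mm = 0` gives a no-vessel
#'   pair whose difference is pure zero-mean noise.
#' @param artery_boost added mean arterial intensity (a.u.) during systole.
#' @return list with `systolic`, `diastolic` ([voxel_grid()]s) and
#'   `artery_truth` (a [label_map()] with the artery class only).
#' @export
generate_mra_pair <- function(spec, artery_boost = 50) {
  stopifnot(inherits(spec, "phantom_spec"))
  cs <- phantom_cross_section(spec)
  dims <- spec$grid_shape
  labels <- array(TISSUE_CODES[["background"]], dim = dims)
  for (z in cs$z_range[1]:cs$z_range[2]) labels[, , z] <- cs$cross

  model <- phantom_intensity_model(spec)
  base <- model$means[as.vector(labels) + 1L]
  sds <- model$sds[as.vector(labels) + 1L]
  art <- as.vector(labels) == TISSUE_CODES[["artery"]]

  dia <- base
  sys <- base + ifelse(art, artery_boost, 0)
  if (any(model$sds > 0)) {
    dia <- dia + with_stream(spec$seed, "mra_diastole", rnorm(length(dia))) * sds
    sys <- sys + with_stream(spec$seed, "mra_systole", rnorm(length(sys))) * sds
  }
  art_labels <- array(ifelse(art, TISSUE_CODES[["artery"]],
                             TISSUE_CODES[["background"]]), dim = dims)
  list(systolic  = voxel_grid(array(sys, dims), spacing = spec$voxel_size),
       diastolic = voxel_grid(array(dia, dims), spacing = spec$voxel_size),
       artery_truth = label_map(art_labels, spacing = spec$voxel_size))
}

#' Realized tissue volumes of a label map
#'
#' Voxel-count volumes (cm^3) per tissue class present in the map.
#'
#' @param map a [label_map()].
#' @return named numeric vector of volumes in cm^3.
#' @export
realized_volumes <- function(map) {
  stopifnot(inherits(map, "label_map"))
  vv <- voxel_volume_mm3(map)
  counts <- table(factor(as.vector(map$labels), levels = map$class_names,
                         labels = names(map$class_names)))
  out <- as.numeric(counts) * vv / 1000
  names(out) <- names(counts)
  out
}
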