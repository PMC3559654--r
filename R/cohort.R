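#' Specify a synthetic study cohort
#'
#' Defines the group structure and contralateral effect sizes for a cohort
#' of paired-leg phantoms: controls (no systematic asymmetry), unilateral
#' cases (one affected leg with reduced muscle/bone and slightly increased
#' subcutaneous fat) and bilateral cases (both legs affected). The default
#' effect-ratio distributions are the reported affected:unaffected volume
#' ratios for a treated clubfoot cohort — muscle 0.60 +/- 0.078, tibia
#' 0.92 +/- 0.06, fibula 0.89 +/- 0.068, subcutaneous fat 1.05 +/- 0.069 —
#' and the control right:left distributions are centred at 1 with the
#' reported control spreads.
#'
#' @param n_control,n_unilateral,n_bilateral group sizes (>= 0).
#' @param effect_ratios named list of `c(mean, sd)` affected:unaffected
#'   multiplier distributions per tissue (`muscle`, `subcut_fat`, `tibia`,
#'   `fibula`). Means must lie in (0, 2], sds must be >= 0.
#' @param control_ratios same structure, used for control (and bilateral
#'   right:left) pairs; centred at 1 by default.
#' @param ta_affected_multiplier factor applied to the base
#'   `speckle_fraction` in affected legs (intramuscular-fat enrichment).
#' @param seed integer seed; all draws flow from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 5, n_unilateral = 4, n_bilateral = 2,
                        effect_ratios = list(
                          muscle     = c(mean = 0.60, sd = 0.078),
                          subcut_fat = c(mean = 1.05, sd = 0.069),
                          tibia      = c(mean = 0.92, sd = 0.060),
                          fibula     = c(mean = 0.89, sd = 0.068)),
                        control_ratios = list(
                          muscle     = c(mean = 1.00, sd = 0.034),
                          subcut_fat = c(mean = 1.00, sd = 0.057),
                          tibia      = c(mean = 1.00, sd = 0.023),
                          fibula     = c(mean = 1.00, sd = 0.034)),
                        ta_affected_multiplier = 5,
                        seed = 1L) {
  stopifnot(n_control >= 0, n_unilateral >= 0, n_bilateral >= 0)
  check_ratios <- function(lst, what) {
    needed <- c("muscle", "subcut_fat", "tibia", "fibula")
    if (!all(needed %in% names(lst)))
      stop("`", what, "` must name: ", paste(needed, collapse = ", "),
           call. = FALSE)
    for (nm in needed) {
      m <- lst[[nm]][1]; s <- lst[[nm]][2]
      if (m <= 0 || m > 2) stop("`", what, "` mean for ", nm,
                                " must be in (0, 2]", call. = FALSE)
      if (s < 0) stop("`", what, "` sd for ", nm, " must be >= 0",
                      call. = FALSE)
    }
    lst[needed]
  }
  structure(list(
    n_control = as.integer(n_control),
    n_unilateral = as.integer(n_unilateral),
    n_bilateral = as.integer(n_bilateral),
    effect_ratios = check_ratios(effect_ratios, "effect_ratios"),
    control_ratios = check_ratios(control_ratios, "control_ratios"),
    ta_affected_multiplier = ta_affected_multiplier,
    seed = as.integer(seed)),
    class = "cohort_spec")
}

# Build a phantom_spec with scaled target volumes / speckle fraction,
# derived deterministically from a base spec.
scale_phantom_spec <- function(base, multipliers = NULL, speckle_mult = 1,
                               seed = base$seed) {
  tv <- base$target_volumes
  if (!is.null(multipliers)) tv <- tv * multipliers[names(tv)]
  phantom_spec(grid_shape = base$grid_shape, voxel_size = base$voxel_size,
               leg_length_mm = base$leg_length_mm, target_volumes = tv,
               speckle_fraction = min(0.5, base$speckle_fraction * speckle_mult),
               snr_fat = base$snr_fat, snr_muscle = base$snr_muscle,
               contrast_fat_muscle = base$contrast_fat_muscle,
               contrast_bone_muscle = base$contrast_bone_muscle,
               artery_radius_mm = base$artery_radius_mm, seed = seed)
}

#' Generate a synthetic cohort of paired-leg phantom specifications
#'
#' For every participant, draws per-tissue contralateral multipliers from the
#' cohort's effect (or control) distributions and derives a pair of
#' [phantom_spec()]s: the second leg carries the base target volumes and the
#' first leg carries them scaled by the drawn multipliers. Unilateral
#' participants' legs are labelled affected/unaffected; control and bilateral
#' legs right/left (bilateral participants get affected-style effect draws
#' and intramuscular-fat enrichment on both legs, each drawn independently
#' against the base so their right:left ratio is the quotient of two draws).
#' All ground-truth multipliers are recorded for parameter-recovery testing.
#'
#' Phantom volumes themselves are generated lazily: each returned leg holds a
#' `phantom_spec` (with its own derived seed) that [generate_leg_phantom()]
#' turns into images on demand, which keeps cohort objects small.
#'
#' @param cspec a [cohort_spec()].
#' @param base a [phantom_spec()] giving the unaffected-leg geometry and
#'   imaging conditions.
#' @return an object of class `leg_cohort`: list with `participants` (each
#'   with `id`, `group`, `laterality` and a two-element `legs` list of
#'   phantom specs keyed by side status) and `truth` (data frame of the
#'   drawn multipliers: participant, group, side, tissue, multiplier).
#' @export
generate_unilateral_cohort <- function(cspec, base) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(base, "phantom_spec"))
  tissues <- c("muscle", "subcut_fat", "tibia", "fibula")

  ids <- c(if (cspec$n_control > 0) paste0("C", seq_len(cspec$n_control)),
           if (cspec$n_unilateral > 0) paste0("U", seq_len(cspec$n_unilateral)),
           if (cspec$n_bilateral > 0) paste0("B", seq_len(cspec$n_bilateral)))
  groups <- c(rep("control", cspec$n_control),
              rep("unilateral", cspec$n_unilateral),
              rep("bilateral", cspec$n_bilateral))

  draw <- function(par) max(1e-3, rnorm(1, par[1], par[2]))

  participants <- list()
  truth <- list()
  with_stream(cspec$seed, "multipliers", {
    for (i in seq_along(ids)) {
      id <- ids[i]; group <- groups[i]
      if (group == "control") {
        m <- vapply(cspec$control_ratios, draw, numeric(1))
        legs <- list(
          right = scale_phantom_spec(base, m, seed = stream_seed(cspec$seed, paste0(id, ":right"))),
          left  = scale_phantom_spec(base, seed = stream_seed(cspec$seed, paste0(id, ":left"))))
        truth[[length(truth) + 1L]] <- data.frame(
          participant = id, group = group, side = "right",
          tissue = tissues, multiplier = unname(m[tissues]))
        laterality <- "none"
      } else if (group == "unilateral") {
        m <- vapply(cspec$effect_ratios, draw, numeric(1))
        legs <- list(
          affected = scale_phantom_spec(base, m,
            speckle_mult = cspec$ta_affected_multiplier,
            seed = stream_seed(cspec$seed, paste0(id, ":affected"))),
          unaffected = scale_phantom_spec(base,
            seed = stream_seed(cspec$seed, paste0(id, ":unaffected"))))
        truth[[length(truth) + 1L]] <- data.frame(
          participant = id, group = group, side = "affected",
          tissue = tissues, multiplier = unname(m[tissues]))
        laterality <- "left"
      } else {
        m_r <- vapply(cspec$effect_ratios, draw, numeric(1))
        m_l <- vapply(cspec$effect_ratios, draw, numeric(1))
        legs <- list(
          right = scale_phantom_spec(base, m_r,
            speckle_mult = cspec$ta_affected_multiplier,
            seed = stream_seed(cspec$seed, paste0(id, ":right"))),
          left = scale_phantom_spec(base, m_l,
            speckle_mult = cspec$ta_affected_multiplier,
            seed = stream_seed(cspec$seed, paste0(id, ":left"))))
        truth[[length(truth) + 1L]] <- data.frame(
          participant = id, group = group,
          side = rep(c("right", "left"), each = length(tissues)),
          tissue = rep(tissues, 2),
          multiplier = c(unname(m_r[tissues]), unname(m_l[tissues])))
        laterality <- "bilateral"
      }
      participants[[id]] <- list(id = id, group = group,
                                 laterality = laterality, legs = legs)
    }
  })
  structure(list(participants = participants,
                 truth = do.call(rbind, truth),
                 base = base, cspec = cspec),
            class = "leg_cohort")
}

#' @export
print.leg_cohort <- function(x, ...) {
  n <- table(vapply(x$participants, `[[`, character(1), "group"))
  cat("<leg_cohort> ", length(x$participants), " participants (",
      paste(names(n), as.integer(n), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
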