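#' Run the full cohort analysis pipeline
#'
#' Produces a cohort report from either a per-leg measurement table (the
#' image stages are skipped) or a synthetic phantom cohort (each leg is
#' generated, segmented and measured first). The report contains the
#' per-leg measurements with soft-tissue composition, per-participant
#' contralateral ratios, group summaries, and the three headline group
#' contrasts: each measurement's contralateral-ratio contrast (control
#' right:left versus unilateral affected:unaffected), the muscle-percentage
#' contrast and the intramuscular-fat contrast (control legs versus one
#' value per affected participant, bilateral legs averaged).
#'
#' @param x a measurement table data frame (see [read_measurement_table()])
#'   or a [generate_unilateral_cohort()] cohort.
#' @param ... passed to methods.
#' @return an object of class `cohort_report`: list with `leg_table`,
#'   `ratio_table`, `summaries` and `contrasts`.
#' @export
run_pipeline <- function(x, ...) UseMethod("run_pipeline")

#' @rdname run_pipeline
#' @export
run_pipeline.data.frame <- function(x, ...) {
  wide <- measurement_table_to_wide(validate_measurement_table(x))
  build_cohort_report(wide)
}

#' @rdname run_pipeline
#' @param seg_config a [segmentation_config()]; extents default to the
#'   phantom's axial leg range, with the soft-tissue extent inset by 10% of
#'   the leg slices at each end.
#' @param ta_cfg a [ta_config()].
#' @export
run_pipeline.leg_cohort <- function(x, seg_config = NULL,
                                    ta_cfg = ta_config(), ...) {
  rows <- list()
  for (p in x$participants) {
    for (side_status in names(p$legs)) {
      spec <- p$legs[[side_status]]
      ph <- generate_leg_phantom(spec)
      cfg <- seg_config %||% default_phantom_seg_config(ph)
      seg <- segment_tissues(ph$grid, cfg)
      muscle_mask <- seg$labels == TISSUE_CODES[["muscle"]]
      ta <- ta_musc(ph$grid, muscle_mask, ta_cfg)
      side <- if (side_status %in% c("right", "left")) side_status
              else if (identical(p$laterality, "right"))
                c(affected = "right", unaffected = "left")[[side_status]]
              else c(affected = "left", unaffected = "right")[[side_status]]
      meas <- measure_leg(seg, cfg, ta_value = ta, side = side,
                          side_status = side_status)
      meas$participant <- p$id
      meas$group <- p$group
      rows[[length(rows) + 1L]] <- meas
    }
  }
  wide <- do.call(rbind, rows)
  class(wide) <- "data.frame"
  build_cohort_report(wide)
}

# Segmentation config matched to a phantom's axial geometry.
default_phantom_seg_config <- function(ph) {
  z <- ph$z_range
  inset <- max(1L, round(0.1 * diff(z)))
  segmentation_config(leg_extent = z,
                      soft_tissue_extent = c(z[1] + inset, z[2] - inset))
}

# Long fixture-style measurement table -> wide per-leg table with
# composition percentages.
measurement_table_to_wide <- function(tab) {
  keys <- unique(tab[, c("participant", "group", "side", "side_status")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- tab[tab$participant == k$participant & tab$side == k$side, ]
    vals <- setNames(sub$value, sub$measurement)
    if (!all(c("V_Musc", "V_Fat") %in% names(vals)))
      stop("incomplete record: ", k$participant, " ", k$side, call. = FALSE)
    data.frame(participant = k$participant, group = k$group, side = k$side,
               side_status = k$side_status,
               V_Leg = vals[["V_Leg"]] %||% NA_real_,
               V_Musc = vals[["V_Musc"]], V_Fat = vals[["V_Fat"]],
               V_Tibia = vals[["V_Tibia"]] %||% NA_real_,
               V_Fibula = vals[["V_Fibula"]] %||% NA_real_,
               Muscle_pct = tissue_percent(vals[["V_Musc"]], vals[["V_Musc"]],
                                           vals[["V_Fat"]]),
               Fat_pct = tissue_percent(vals[["V_Fat"]], vals[["V_Musc"]],
                                        vals[["V_Fat"]]),
               TA_Musc = vals[["TA_Musc"]] %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Contralateral ratio table: one row per participant, one ratio column per
# measurement. Orientation: affected/unaffected for unilateral
# participants, right/left otherwise.
ratio_table_from_wide <- function(wide) {
  meas_cols <- c("V_Leg", "V_Musc", "V_Fat", "V_Tibia", "V_Fibula", "TA_Musc")
  out <- list()
  for (id in unique(wide$participant)) {
    sub <- wide[wide$participant == id, ]
    if (nrow(sub) != 2L)
      stop("incomplete record: participant ", id, " needs two legs",
           call. = FALSE)
    if (sub$group[1] == "unilateral") {
      num <- sub[sub$side_status == "affected", ]
      den <- sub[sub$side_status == "unaffected", ]
      orientation <- "affected:unaffected"
    } else {
      num <- sub[sub$side == "right", ]
      den <- sub[sub$side == "left", ]
      orientation <- "right:left"
    }
    row <- data.frame(participant = id, group = sub$group[1],
                      orientation = orientation, stringsAsFactors = FALSE)
    for (mc in meas_cols)
      row[[paste0(mc, "_ratio")]] <-
        if (is.na(num[[mc]]) || is.na(den[[mc]]) || den[[mc]] == 0) NA_real_
        else contralateral_ratio(num[[mc]], den[[mc]])
    out[[id]] <- row
  }
  do.call(rbind, out)
}

build_cohort_report <- function(wide) {
  ratios <- ratio_table_from_wide(wide)
  meas_cols <- c("V_Leg", "V_Musc", "V_Fat", "V_Tibia", "V_Fibula", "TA_Musc")

  summaries <- list()
  for (grp in intersect(c("control", "unilateral", "bilateral"),
                        unique(ratios$group))) {
    for (mc in meas_cols) {
      v <- ratios[[paste0(mc, "_ratio")]][ratios$group == grp]
      v <- v[!is.na(v)]
      if (length(v))
        summaries[[paste(grp, mc, "ratio", sep = "_")]] <- summarize_values(v)
    }
  }

  control_legs <- wide[wide$group == "control", ]
  unaff_legs <- wide[wide$side_status == "unaffected", ]
  per_part <- function(col) {
    per_participant_affected_average(data.frame(
      participant = wide$participant, group = wide$group,
      side_status = wide$side_status, value = wide[[col]],
      stringsAsFactors = FALSE))
  }
  if (nrow(control_legs)) {
    summaries$control_muscle_pct <- summarize_values(control_legs$Muscle_pct)
    if (!all(is.na(control_legs$TA_Musc)))
      summaries$control_ta_musc <- summarize_values(control_legs$TA_Musc)
  }
  if (nrow(unaff_legs)) {
    summaries$unaffected_muscle_pct <- summarize_values(unaff_legs$Muscle_pct)
    if (!all(is.na(unaff_legs$TA_Musc)))
      summaries$unaffected_ta_musc <- summarize_values(unaff_legs$TA_Musc)
  }
  affected_pct <- per_part("Muscle_pct")
  if (length(affected_pct))
    summaries$affected_muscle_pct <- summarize_values(affected_pct)
  affected_ta <- tryCatch(per_part("TA_Musc"), error = function(e) numeric(0))
  if (length(affected_ta) && !all(is.na(affected_ta)))
    summaries$affected_ta_musc <- summarize_values(affected_ta)

  contrasts <- list()
  ctrl <- ratios[ratios$group == "control", ]
  uni <- ratios[ratios$group == "unilateral", ]
  if (nrow(ctrl) && nrow(uni)) {
    for (mc in setdiff(meas_cols, "TA_Musc")) {
      cx <- ctrl[[paste0(mc, "_ratio")]]; cy <- uni[[paste0(mc, "_ratio")]]
      if (!anyNA(cx) && !anyNA(cy))
        contrasts[[paste0(mc, "_ratio")]] <- ks_two_sample(cx, cy)
    }
  }
  if (nrow(control_legs) && length(affected_pct))
    contrasts$muscle_pct <- ks_two_sample(control_legs$Muscle_pct,
                                          affected_pct)
  if (nrow(control_legs) && length(affected_ta) &&
      !all(is.na(control_legs$TA_Musc)) && !all(is.na(affected_ta)))
    contrasts$ta_musc <- ks_two_sample(control_legs$TA_Musc, affected_ta)

  structure(list(leg_table = wide, ratio_table = ratios,
                 summaries = summaries, contrasts = contrasts),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", nrow(x$leg_table), " legs, ",
      nrow(x$ratio_table), " participants\n", sep = "")
  for (nm in names(x$contrasts)) {
    k <- x$contrasts[[nm]]
    cat(sprintf("  contrast %-14s D = %.3g, p = %.4g\n", nm, k$D, k$p_value))
  }
  invisible(x)
}

#' End-to-end parameter recovery on synthetic cohorts
#'
#' For each replicate, generates a cohort of paired-leg phantoms, runs the
#' full image pipeline (segmentation, volumetry), and compares each
#' unilateral participant's measured affected:unaffected volume ratio to the
#' generator's recorded ground-truth multiplier. Reports per-tissue bias and
#' RMSE of the estimates.
#'
#' @param cspec a [cohort_spec()]; each replicate derives its own seed.
#' @param base a [phantom_spec()] for the unaffected leg.
#' @param n_replicates number of seeded replicates (>= 1).
#' @param seg_config optional [segmentation_config()].
#' @return data frame with one row per tissue: `measurement`,
#'   `mean_estimate`, `mean_truth`, `bias`, `rmse`, `n_pairs`.
#' @export
parameter_recovery <- function(cspec, base, n_replicates = 5,
                               seg_config = NULL) {
  stopifnot(n_replicates >= 1)
  tissue_to_col <- c(muscle = "V_Musc_ratio", subcut_fat = "V_Fat_ratio",
                     tibia = "V_Tibia_ratio", fibula = "V_Fibula_ratio")
  est <- list(); tru <- list()
  for (r in seq_len(n_replicates)) {
    cs <- cspec
    cs$seed <- stream_seed(cspec$seed, paste0("replicate", r))
    cohort <- generate_unilateral_cohort(cs, base)
    rep_report <- run_pipeline(cohort, seg_config = seg_config)
    ratios <- rep_report$ratio_table
    uni <- ratios[ratios$group == "unilateral", ]
    truth <- cohort$truth[cohort$truth$group == "unilateral", ]
    for (tis in names(tissue_to_col)) {
      e <- uni[[tissue_to_col[[tis]]]][match(truth$participant[truth$tissue == tis],
                                             uni$participant)]
      t_ <- truth$multiplier[truth$tissue == tis]
      est[[tis]] <- c(est[[tis]], e)
      tru[[tis]] <- c(tru[[tis]], t_)
    }
  }
  do.call(rbind, lapply(names(tissue_to_col), function(tis) {
    d <- est[[tis]] - tru[[tis]]
    data.frame(measurement = tissue_to_col[[tis]],
               tissue = tis,
               mean_estimate = mean(est[[tis]]),
               mean_truth = mean(tru[[tis]]),
               bias = mean(d),
               rmse = sqrt(mean(d^2)),
               n_pairs = length(d),
               stringsAsFactors = FALSE)
  }))
}

#' Write the report's tables as CSV files
#'
#' One CSV per published-table analogue, with report rounding conventions:
#' volumes and percentages to 1 decimal, ratios to 2 decimals (internal
#' computation is always full precision). An empty report yields files with
#' headers only.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- report$leg_table
  ratios <- report$ratio_table
  r1 <- function(x) round_half_up(x, 1)
  r2 <- function(x) round_half_up(x, 2)

  leg <- data.frame(participant = wide$participant, group = wide$group,
                    side = wide$side, side_status = wide$side_status,
                    V_Leg = r1(wide$V_Leg), stringsAsFactors = FALSE)
  leg <- merge(leg, ratios[, c("participant", "orientation", "V_Leg_ratio")],
               by = "participant", sort = FALSE)
  leg$V_Leg_ratio <- r2(leg$V_Leg_ratio)

  soft <- data.frame(participant = wide$participant, side = wide$side,
                     side_status = wide$side_status,
                     V_Musc = r1(wide$V_Musc), V_Fat = r1(wide$V_Fat),
                     Muscle_pct = r1(wide$Muscle_pct),
                     Fat_pct = r1(wide$Fat_pct), stringsAsFactors = FALSE)
  soft <- merge(soft, within(ratios[, c("participant", "V_Musc_ratio",
                                        "V_Fat_ratio")], {
    V_Musc_ratio <- r2(V_Musc_ratio); V_Fat_ratio <- r2(V_Fat_ratio)
  }), by = "participant", sort = FALSE)

  bones <- data.frame(participant = wide$participant, side = wide$side,
                      side_status = wide$side_status,
                      V_Tibia = r1(wide$V_Tibia),
                      V_Fibula = r1(wide$V_Fibula), stringsAsFactors = FALSE)
  bones <- merge(bones, within(ratios[, c("participant", "V_Tibia_ratio",
                                          "V_Fibula_ratio")], {
    V_Tibia_ratio <- r2(V_Tibia_ratio); V_Fibula_ratio <- r2(V_Fibula_ratio)
  }), by = "participant", sort = FALSE)

  ta <- data.frame(participant = wide$participant, side = wide$side,
                   side_status = wide$side_status,
                   TA_Musc = r2(wide$TA_Musc), stringsAsFactors = FALSE)
  ta <- merge(ta, within(ratios[, c("participant", "TA_Musc_ratio")], {
    TA_Musc_ratio <- r2(TA_Musc_ratio)
  }), by = "participant", sort = FALSE)

  paths <- c(leg_volumes = file.path(dir, "leg_volumes.csv"),
             soft_tissue = file.path(dir, "soft_tissue_composition.csv"),
             bone_volumes = file.path(dir, "bone_volumes.csv"),
             ta_musc = file.path(dir, "ta_musc.csv"))
  write.csv(leg, paths[["leg_volumes"]], row.names = FALSE)
  write.csv(soft, paths[["soft_tissue"]], row.names = FALSE)
  write.csv(bones, paths[["bone_volumes"]], row.names = FALSE)
  write.csv(ta, paths[["ta_musc"]], row.names = FALSE)
  invisible(paths)
}
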