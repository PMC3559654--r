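# Shared phantom specifications for the test suite. Imaging conditions
# (SNRs, contrasts, composition proportions) follow the study defaults;
# grids are small so the suite stays fast.

# Workhorse spec: 2 x 2 x 3 mm voxels, control-proportioned tissue volumes.
small_spec <- function(speckle_fraction = 0.015, artery_radius_mm = 2.5,
                       seed = 7, ...) {
  phantom_spec(grid_shape = c(64, 64, 48), voxel_size = c(2, 2, 3),
               leg_length_mm = 120,
               target_volumes = c(muscle = 220, subcut_fat = 150,
                                  tibia = 48, fibula = 9),
               speckle_fraction = speckle_fraction,
               artery_radius_mm = artery_radius_mm, seed = seed, ...)
}

# Minimal spec for replicated cohort experiments.
tiny_spec <- function(seed = 1, speckle_fraction = 0, ...) {
  phantom_spec(grid_shape = c(32, 32, 24), voxel_size = c(4, 4, 5),
               leg_length_mm = 100,
               target_volumes = c(muscle = 220, subcut_fat = 150,
                                  tibia = 48, fibula = 9),
               speckle_fraction = speckle_fraction, artery_radius_mm = 0,
               seed = seed, ...)
}

# One generated+segmented workhorse phantom, cached across tests.
.cache <- new.env(parent = emptyenv())
cached_phantom <- function() {
  if (is.null(.cache$ph)) {
    .cache$ph <- generate_leg_phantom(small_spec())
    .cache$seg <- segment_tissues(.cache$ph$grid)
  }
  list(ph = .cache$ph, seg = .cache$seg)
}

# Independent brute-force two-sample KS oracle: full enumeration of all
# C(n+m, n) label assignments of the pooled values.
brute_force_ks <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ks_d <- function(a, b) {
    u <- sort(unique(c(a, b)))
    max(abs(vapply(u, function(v)
      sum(a <= v) / length(a) - sum(b <= v) / length(b), numeric(1))))
  }
  d_obs <- ks_d(x, y)
  ds <- apply(utils::combn(n + m, n), 2, function(idx)
    ks_d(pooled[idx], pooled[-idx]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# Per-leg values of one derived column as a per-participant data frame.
wide_fixture <- function() {
  legquant:::measurement_table_to_wide(load_paper_fixture())
}
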