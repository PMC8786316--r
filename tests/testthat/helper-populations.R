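# Shared builders for planted populations and small synthetic sessions.

default_grid <- stimulus_grid()

# Planted two-factor tensor: a common ramp (time factor) plus a
# stimulus-ordered constant offset (stimulus factor), with optional noise.
planted_two_factor <- function(n_units = 80, n_bins = 40, noise_sd = 0.01,
                               grid = default_grid, seed = 1) {
  withr::with_seed(seed, {
    ramp <- seq(0, 1, length.out = n_bins)
    ramp <- ramp / sqrt(sum(ramp^2))
    amp <- (grid$durations - grid$mean) / grid$range
    a_time <- stats::rnorm(n_units)
    a_stim <- stats::rnorm(n_units)
    vals <- array(0, c(n_units, length(grid$durations), n_bins))
    for (j in seq_along(grid$durations)) {
      for (u in seq_len(n_units)) {
        vals[u, j, ] <- a_time[u] * ramp + a_stim[u] * amp[j] +
          stats::rnorm(n_bins, 0, noise_sd)
      }
    }
    list(sdf = sdf_tensor(vals, grid$durations, zscored = TRUE),
         ramp = ramp, amp = amp, a_time = a_time, a_stim = a_stim)
  })
}

# Perfectly scaling tensor: every unit's trace depends on t/s only, so its
# center of mass in seconds is proportional to the duration.
perfectly_scaling_tensor <- function(n_units = 20, n_bins = 40,
                                     grid = default_grid, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(0, c(n_units, length(grid$durations), n_bins))
    x <- (seq_len(n_bins) - 0.5) / n_bins
    for (u in seq_len(n_units)) {
      peak <- stats::runif(1, 0.2, 0.8)
      shape <- exp(-(x - peak)^2 / 0.02)
      for (j in seq_along(grid$durations)) vals[u, j, ] <- shape
    }
    sdf_tensor(vals, grid$durations, zscored = FALSE)
  })
}

# Poisson session of unrelated-noise units (constant rate), the pure-noise
# population used in null calibrations.
noise_session <- function(n_units = 30, n_trials = 70, rate = 8, seed = 1) {
  cfg <- session_config(
    n_trials = n_trials,
    stereotypes = rep(list(stereotype_params("unrelated_noise",
                                             baseline = rate)), n_units),
    observer = observer_params(0.7, 0.05, 0.05),
    seed = seed)
  generate_session(cfg)
}

# Heterogeneous stereotype lists for decoder experiments.
linear_pool <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      stereotype_params("linear_increasing",
                        baseline = stats::runif(1, 1, 4),
                        slope = stats::runif(1, 1.5, 4))
    })
  })
}

ramp_pool <- function(n, seed = 2) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      stereotype_params("ramp_to_threshold_up",
                        baseline = stats::runif(1, 1, 4),
                        amplitude = stats::runif(1, 8, 16))
    })
  })
}

# Largest principal angle (degrees) between a vector and a reference.
vector_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}
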