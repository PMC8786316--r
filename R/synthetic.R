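#' Stimulus grid for the interval reproduction task
#'
#' The task draws stimulus durations from a discrete uniform grid. The default
#' grid is the seven durations 3, 3.75, ..., 7.5 s with 0.75 s spacing, whose
#' mean (5.25 s) serves as the reference duration for scaling analyses.
#'
#' @param durations Strictly increasing, uniformly spaced durations in seconds.
#' @return An object of class `stimulus_grid` with elements `durations`,
#'   `spacing`, `mean` and `range`.
#' @export
#' @examples
#' g <- stimulus_grid()
#' g$mean  # 5.25
stimulus_grid <- function(durations = seq(3, 7.5, by = 0.75)) {
  durations <- as.numeric(durations)
  if (length(durations) < 1L || anyNA(durations)) {
    stop("stimulus grid must contain at least one finite duration")
  }
  if (length(durations) > 1L) {
    d <- diff(durations)
    if (any(d <= 0)) stop("stimulus grid durations must be strictly increasing")
    if (max(d) - min(d) > 1e-9) stop("stimulus grid must be uniformly spaced")
    spacing <- d[1L]
  } else {
    spacing <- NA_real_
  }
  structure(
    list(durations = durations, spacing = spacing,
         mean = mean(durations),
         range = max(durations) - min(durations)),
    class = "stimulus_grid"
  )
}

#' Observer model parameters
#'
#' A minimal generative observer producing the regression effect (central
#' tendency) and scalar variability. The stimulus is measured with
#' multiplicative noise (Weber fraction `w_m`), the internal estimate is
#' shrunk toward a prior mean `mu` with weight `lambda`, and the reproduction
#' adds multiplicative production noise (Weber fraction `w_p`):
#' \deqn{m = s (1 + w_m z_1), \quad c = \lambda m + (1-\lambda)\mu, \quad
#'   r = c (1 + w_p z_2)}
#' with independent standard normal \eqn{z_1, z_2}. The expected reproduction
#' is linear in the stimulus with slope `lambda`, and for `w_m = 0` the
#' coefficient of variation of `r` given `s` equals `w_p` for every stimulus.
#'
#' @param lambda Shrinkage weight in \[0, 1\]; 1 = veridical, 0 = pure prior.
#' @param w_m Measurement Weber fraction (>= 0).
#' @param w_p Production Weber fraction (>= 0).
#' @param mu Prior mean in seconds; defaults to the grid mean 5.25 s.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(lambda = 0.7, w_m = 0.1, w_p = 0.1, mu = 5.25) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (w_m < 0 || w_p < 0) stop("Weber fractions must be non-negative")
  if (mu <= 0) stop("prior mean must be positive")
  structure(list(lambda = lambda, w_m = w_m, w_p = w_p, mu = mu),
            class = "observer_params")
}

#' Optimal shrinkage weight for the observer model
#'
#' The shrinkage weight minimizing expected squared reproduction error under
#' the generative model, for a measurement Weber fraction `w_m` and a stimulus
#' grid: `lambda = var(s) / (var(s) + w_m^2 * E[s^2])`. Noisier measurements
#' get down-weighted in favor of the prior, coupling regression strength to
#' variability the way optimal-estimation accounts of the central tendency do.
#'
#' @param w_m Measurement Weber fraction.
#' @param grid A [stimulus_grid()].
#' @return Shrinkage weight in \[0, 1\].
#' @export
optimal_lambda <- function(w_m, grid = stimulus_grid()) {
  s <- grid$durations
  v <- mean(s^2) - mean(s)^2
  v / (v + w_m^2 * mean(s^2))
}

#' Sample stimuli from the grid
#'
#' Draws `n_trials` durations from the discrete uniform distribution over the
#' grid.
#'
#' @param grid A [stimulus_grid()].
#' @param n_trials Number of trials (>= 0).
#' @param seed Optional integer seed; when given, sampling is reproducible and
#'   the global RNG state is untouched.
#' @return Numeric vector of durations in seconds.
#' @export
sample_stimuli <- function(grid, n_trials, seed = NULL) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (n_trials < 0) stop("n_trials must be non-negative")
  if (n_trials == 0) return(numeric(0))
  d <- grid$durations
  with_seed_opt(seed, d[sample.int(length(d), n_trials, replace = TRUE)])
}

#' Simulate one observer reproduction
#'
#' @param s Stimulus duration in seconds (> 0). Vectorized.
#' @param p An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return Reproduced duration(s) in seconds, clipped to be positive.
#' @export
simulate_observer_trial <- function(s, p, seed = NULL) {
  stopifnot(inherits(p, "observer_params"))
  if (any(s <= 0)) stop("stimulus durations must be positive")
  with_seed_opt(seed, {
    n <- length(s)
    m <- s * (1 + p$w_m * stats::rnorm(n))
    center <- p$lambda * m + (1 - p$lambda) * p$mu
    r <- center + p$w_p * center * stats::rnorm(n)
    pmax(r, .Machine$double.eps)
  })
}

#' Adaptive feedback update
#'
#' A reproduction counts as "in" when it falls within `(1 +/- k)` times the
#' stimulus. The tolerance then narrows by 3 percentage points on a rewarded
#' trial and widens by 3 otherwise; it is floored at 0.
#'
#' @param r Reproduced duration (s).
#' @param s Stimulus duration (s).
#' @param k Current tolerance (fraction >= 0).
#' @return List with `in_out` (logical reward flag) and `k_next`.
#' @export
#' @examples
#' update_feedback(5, 5, 0.15)  # in, k drops to 0.12
update_feedback <- function(r, s, k) {
  if (k < 0) stop("tolerance k must be non-negative")
  in_out <- r >= (1 - k) * s & r <= (1 + k) * s
  k_next <- ifelse(in_out, pmax(0, k - 0.03), k + 0.03)
  list(in_out = in_out, k_next = k_next)
}

STEREOTYPE_TYPES <- c("linear_increasing", "ramp_to_threshold_up",
                      "ramp_to_threshold_down", "phasic_absolute",
                      "phasic_relative", "stimulus_constant",
                      "unrelated_noise")

#' Stereotype timing-neuron parameters
#'
#' Idealized firing-rate profiles found in interval-timing data:
#' \describe{
#'   \item{linear_increasing}{rate climbs at a fixed slope `a` (Hz/s) for all
#'     durations, so the end-of-interval rate grows with the duration.}
#'   \item{ramp_to_threshold_up / _down}{rate ramps between `baseline` and
#'     `baseline + amplitude` with a duration-dependent slope so the same end
#'     level is reached at the end of every interval (up) or the start level
#'     decays to baseline (down).}
#'   \item{phasic_absolute}{Gaussian bump at a fixed clock time `peak_time`
#'     with SD `peak_sd` seconds.}
#'   \item{phasic_relative}{Gaussian bump at a fixed phase of the interval,
#'     `phase * s`, with SD `peak_sd * s`.}
#'   \item{stimulus_constant}{constant rate whose level is ordered by the
#'     stimulus: `baseline + amplitude * (s - grid_mean)/grid_range`.}
#'   \item{unrelated_noise}{constant baseline, unrelated to the task.}
#' }
#' All profiles are rectified at 0 Hz.
#'
#' @param type One of the profile names above.
#' @param baseline Baseline rate (Hz).
#' @param amplitude Profile amplitude `A` (Hz).
#' @param slope Ramp slope `a` (Hz/s), linear_increasing only.
#' @param peak_time Peak clock time (s), phasic_absolute only.
#' @param phase Peak phase in \[0, 1\], phasic_relative only.
#' @param peak_sd Bump SD: seconds (phasic_absolute) or fraction of the
#'   interval (phasic_relative).
#' @param rate_noise_sd SD (Hz) of an additive per-trial rate offset.
#' @param speed_gain Additive rate gain (Hz per cm/s) applied to the running
#'   speed during the reproduction phase.
#' @param grid_mean,grid_range Stimulus-grid mean and range used by
#'   `stimulus_constant` tuning.
#' @return An object of class `stereotype_params`.
#' @export
stereotype_params <- function(type,
                              baseline = 2,
                              amplitude = 10,
                              slope = 2,
                              peak_time = 2,
                              phase = 0.5,
                              peak_sd = if (identical(type, "phasic_relative")) 0.1 else 0.5,
                              rate_noise_sd = 0,
                              speed_gain = 0,
                              grid_mean = 5.25,
                              grid_range = 4.5) {
  type <- match.arg(type, STEREOTYPE_TYPES)
  if (baseline < 0 || amplitude < 0) stop("baseline and amplitude must be >= 0")
  if (type == "phasic_relative" && (phase < 0 || phase > 1)) {
    stop("phasic_relative phase must lie in [0, 1]")
  }
  structure(list(type = type, baseline = baseline, amplitude = amplitude,
                 slope = slope, peak_time = peak_time, phase = phase,
                 peak_sd = peak_sd, rate_noise_sd = rate_noise_sd,
                 speed_gain = speed_gain, grid_mean = grid_mean,
                 grid_range = grid_range),
            class = "stereotype_params")
}

#' Stereotype firing rate at elapsed time t
#'
#' @param params A [stereotype_params()] object.
#' @param s Interval duration the profile is parameterized by (s).
#' @param t Elapsed time(s) within \[0, s\]. Vectorized.
#' @param rate_offset Additive rate offset (Hz) applied before rectification,
#'   used for per-trial rate noise.
#' @return Rate(s) in Hz, rectified at 0.
#' @export
#' @examples
#' p <- stereotype_params("linear_increasing", baseline = 1, slope = 2)
#' stereotype_rate(p, s = 5, t = 3)  # 7 Hz
stereotype_rate <- function(params, s, t, rate_offset = 0) {
  stopifnot(inherits(params, "stereotype_params"))
  if (any(t < -1e-12) || any(t > s + 1e-12)) {
    stop("t must lie within [0, s]")
  }
  r <- switch(params$type,
    linear_increasing = params$baseline + params$slope * t,
    ramp_to_threshold_up = params$baseline + params$amplitude * t / s,
    ramp_to_threshold_down = params$baseline + params$amplitude * (1 - t / s),
    phasic_absolute = params$baseline +
      params$amplitude * exp(-(t - params$peak_time)^2 / (2 * params$peak_sd^2)),
    phasic_relative = params$baseline +
      params$amplitude * exp(-(t - params$phase * s)^2 /
                               (2 * (params$peak_sd * s)^2)),
    stimulus_constant = rep(params$baseline +
      params$amplitude * (s - params$grid_mean) / params$grid_range,
      length(t)),
    unrelated_noise = rep(params$baseline, length(t))
  )
  pmax(0, r + rate_offset)
}

#' Generate an inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at an upper
#' rate bound and accepted with probability `rate(t) / bound`, yielding an
#' inhomogeneous Poisson process with the requested intensity.
#'
#' @param rate A non-negative rate function of time (Hz), or a single number
#'   for a homogeneous process.
#' @param duration Duration in seconds.
#' @param rate_max Optional upper bound on the rate over \[0, duration\]; when
#'   missing it is computed on a fine grid (with a small safety margin).
#' @param seed Optional integer seed.
#' @return Sorted spike timestamps in \[0, duration\].
#' @export
generate_spike_train <- function(rate, duration, rate_max = NULL, seed = NULL) {
  if (duration < 0) stop("duration must be non-negative")
  if (is.numeric(rate)) {
    const <- rate[1L]
    rate <- function(t) rep(const, length(t))
  }
  grid <- seq(0, duration, length.out = 2001L)
  vals <- rate(grid)
  if (any(vals < 0)) stop("rate must be non-negative on [0, duration]")
  if (is.null(rate_max)) rate_max <- max(vals) * 1.001
  if (rate_max <= 0 || duration == 0) return(numeric(0))
  with_seed_opt(seed, {
    n_cand <- stats::rpois(1L, rate_max * duration)
    if (n_cand == 0L) return(numeric(0))
    cand <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < pmin(1, rate(cand) / rate_max)
    cand[keep]
  })
}

#' Session configuration for the synthetic generator
#'
#' Bundles everything `generate_session()` needs. Stereotype mixtures are
#' given as a named list of [stereotype_params()] together with unit counts.
#'
#' @param n_trials Number of trials.
#' @param grid A [stimulus_grid()].
#' @param observer An [observer_params()].
#' @param stereotypes List of [stereotype_params()] (one per unit), or a
#'   single `stereotype_params` recycled to `n_units`.
#' @param n_units Number of units when `stereotypes` is a single profile.
#' @param k0 Initial feedback tolerance.
#' @param gap_range Uniform range (s) of the reaction-time gap between
#'   measurement end and reproduction begin.
#' @param speed_mean,speed_sd Mean and SD (cm/s) of the smoothed running-speed
#'   trace during reproduction.
#' @param speed_dt Speed sampling interval (s).
#' @param iti Inter-trial interval (s) used to place trials in session time.
#' @param seed Integer seed (required; the whole session derives from it).
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_trials = 50,
                           grid = stimulus_grid(),
                           observer = observer_params(),
                           stereotypes = stereotype_params("linear_increasing"),
                           n_units = 20,
                           k0 = 0.15,
                           gap_range = c(1, 3),
                           speed_mean = 30,
                           speed_sd = 5,
                           speed_dt = 0.05,
                           iti = 3.5,
                           seed = 1L) {
  if (inherits(stereotypes, "stereotype_params")) {
    stereotypes <- rep(list(stereotypes), n_units)
  }
  if (!all(vapply(stereotypes, inherits, TRUE, "stereotype_params"))) {
    stop("stereotypes must be stereotype_params objects")
  }
  if (length(stereotypes) < 1L) stop("at least one unit is required")
  structure(list(n_trials = n_trials, grid = grid, observer = observer,
                 stereotypes = stereotypes, n_units = length(stereotypes),
                 k0 = k0, gap_range = gap_range, speed_mean = speed_mean,
                 speed_sd = speed_sd, speed_dt = speed_dt, iti = iti,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Build a stereotype mixture
#'
#' Convenience constructor: `mixture` is a named numeric vector of fractions
#' (must sum to 1) over stereotype types; `n_units` profiles are created with
#' shared extra arguments.
#'
#' @param mixture Named fractions over stereotype types, summing to 1.
#' @param n_units Total unit count.
#' @param ... Passed to [stereotype_params()] for every unit.
#' @return List of `stereotype_params`, length `n_units`.
#' @export
stereotype_mixture <- function(mixture, n_units, ...) {
  if (abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture fractions must sum to 1")
  }
  if (is.null(names(mixture)) || !all(names(mixture) %in% STEREOTYPE_TYPES)) {
    stop("mixture must be named by stereotype types")
  }
  counts <- round(mixture * n_units)
  # fix rounding so counts sum to n_units
  while (sum(counts) != n_units) {
    i <- which.max(mixture * n_units - counts)
    if (sum(counts) < n_units) counts[i] <- counts[i] + 1
    else {
      i <- which.min(mixture * n_units - counts)
      counts[i] <- counts[i] - 1
    }
  }
  types <- rep(names(counts), counts)
  lapply(types, function(ty) stereotype_params(ty, ...))
}

# Smoothed positive speed trace on a regular grid (cm/s).
make_speed_trace <- function(duration, dt, mean_speed, sd_speed) {
  n <- max(2L, ceiling(duration / dt) + 1L)
  raw <- stats::rnorm(n, mean_speed, sd_speed)
  w <- stats::dnorm(-10:10, 0, 4)
  sm <- stats::filter(c(rep(raw[1], 10), raw, rep(raw[n], 10)), w / sum(w),
                      sides = 2)
  sm <- as.numeric(sm)[11:(10 + n)]
  data.frame(time = seq(0, by = dt, length.out = n), speed = pmax(0, sm))
}

# Spikes for one unit on one phase: inhomogeneous Poisson of the stereotype
# rate plus a per-trial constant rate offset and optional speed modulation.
phase_spikes <- function(params, s_profile, duration, speed = NULL) {
  offset <- if (params$rate_noise_sd > 0) {
    stats::rnorm(1L, 0, params$rate_noise_sd)
  } else 0
  if (duration <= 0) return(numeric(0))
  rate_fn <- function(t) {
    r <- stereotype_rate(params, s_profile, pmin(t, s_profile), rate_offset = offset)
    if (!is.null(speed) && params$speed_gain != 0) {
      v <- stats::approx(speed$time, speed$speed, xout = t, rule = 2)$y
      r <- pmax(0, r + params$speed_gain * v)
    }
    r
  }
  generate_spike_train(rate_fn, duration)
}

#' Generate a synthetic session
#'
#' Runs the task simulator end to end: stimuli are sampled from the grid, the
#' observer model produces reproductions, the feedback tolerance adapts by
#' +/- 3 percentage points per trial, and each unit emits Poisson spikes from
#' its stereotype profile in both phases. During measurement the profile is
#' parameterized by the stimulus duration; during reproduction it is
#' parameterized by the trial's reproduced duration, except for
#' `stimulus_constant` units which keep their stimulus tuning. A
#' reaction-time gap drawn uniformly from `gap_range` separates the phases
#' (no spikes are generated in the gap). Running speed is near zero during
#' measurement and a smoothed positive trace during reproduction.
#'
#' @param config A [session_config()].
#' @return A list of class `session` with elements `trials` (data.frame:
#'   trial, stimulus, reproduction, k, reward, gain, t_start, t0-t3),
#'   `spikes` (a [spike_data] object, timestamps relative to trial start),
#'   `speed` (list of per-trial data.frames with columns time, speed, in
#'   trial-relative time), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed_opt(config$seed, {
    n <- config$n_trials
    stim <- sample_stimuli(config$grid, n)
    repr <- simulate_observer_trial(stim, config$observer)
    k <- numeric(n); reward <- logical(n)
    kcur <- config$k0
    for (i in seq_len(n)) {
      k[i] <- kcur
      fb <- update_feedback(repr[i], stim[i], kcur)
      reward[i] <- fb$in_out
      kcur <- fb$k_next
    }
    gain <- stats::runif(n, 0.25, 2.25)
    gap <- stats::runif(n, config$gap_range[1], config$gap_range[2])
    t0 <- rep(0, n); t1 <- stim; t2 <- t1 + gap; t3 <- t2 + repr
    t_start <- cumsum(c(0, (t3 + config$iti)[-n]))

    speed <- lapply(seq_len(n), function(i) {
      tr <- make_speed_trace(t3[i], config$speed_dt,
                             config$speed_mean, config$speed_sd)
      tr$speed[tr$time < t2[i]] <- 0  # stationary before reproduction
      tr
    })

    spikes <- lapply(config$stereotypes, function(p) {
      lapply(seq_len(n), function(i) {
        s_meas <- phase_spikes(p, stim[i], stim[i])
        sp <- speed[[i]]
        sp_rel <- data.frame(time = sp$time - t2[i], speed = sp$speed)
        s_prof <- if (p$type == "stimulus_constant") stim[i] else repr[i]
        s_rep <- phase_spikes(p, s_prof, repr[i], speed = sp_rel)
        sort(c(s_meas, t2[i] + s_rep))
      })
    })

    trials <- data.frame(trial = seq_len(n), stimulus = stim,
                         reproduction = repr, k = k, reward = reward,
                         gain = gain, t_start = t_start,
                         t0 = t0, t1 = t1, t2 = t2, t3 = t3)
    structure(list(trials = trials,
                   spikes = spike_data(spikes, trials),
                   speed = speed,
                   config = config),
              class = "session")
  })
}

#' Spike data container
#'
#' @param spikes List over units; each element a list over trials of sorted
#'   spike timestamps in seconds from trial start.
#' @param trials Trial table with phase markers `t0`, `t1`, `t2`, `t3`
#'   (measurement begin/end, reproduction begin/end) and `stimulus`.
#' @return An object of class `spike_data`.
#' @export
spike_data <- function(spikes, trials) {
  stopifnot(is.list(spikes), is.data.frame(trials))
  need <- c("stimulus", "t0", "t1", "t2", "t3")
  if (!all(need %in% names(trials))) {
    stop("trials must contain columns: ", paste(need, collapse = ", "))
  }
  bad <- with(trials, any(!(t0 < t1 & t1 <= t2 & t2 < t3)))
  if (bad) stop("phase markers must satisfy t0 < t1 <= t2 < t3")
  structure(list(spikes = spikes, trials = trials,
                 n_units = length(spikes),
                 n_trials = nrow(trials)),
            class = "spike_data")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("synthetic session: %d trials, %d units, seed %d\n",
              nrow(x$trials), x$spikes$n_units, x$config$seed))
  invisible(x)
}

#' Noiseless SDF tensor from stereotype rate profiles
#'
#' Evaluates each unit's stereotype rate at the centers of `n_bins`
#' time-normalized bins for every grid duration and z-scores per unit,
#' producing the idealized (noise-free) population used for theoretical
#' predictions -- e.g. what a decoder can read out from pure linear-increasing
#' vs pure ramp-to-threshold populations.
#'
#' @param stereotypes List of [stereotype_params()], one per unit.
#' @param grid A [stimulus_grid()] defining the durations.
#' @param n_bins Normalized bin count (default 40).
#' @param zscore Z-score per unit (default TRUE).
#' @return An [sdf_tensor()] of dimension units x durations x n_bins.
#' @export
stereotype_sdf_tensor <- function(stereotypes, grid = stimulus_grid(),
                                  n_bins = 40, zscore = TRUE) {
  if (inherits(stereotypes, "stereotype_params")) stereotypes <- list(stereotypes)
  durs <- grid$durations
  vals <- array(0, dim = c(length(stereotypes), length(durs), n_bins))
  tt_frac <- (seq_len(n_bins) - 0.5) / n_bins
  for (u in seq_along(stereotypes)) {
    for (j in seq_along(durs)) {
      vals[u, j, ] <- stereotype_rate(stereotypes[[u]], durs[j],
                                      tt_frac * durs[j])
    }
  }
  out <- sdf_tensor(vals, durs, durs)
  if (zscore) out <- zscore_tensor(out)
  out
}

#' Flatten a session's speed traces to session time
#'
#' @param session A [generate_session()] result.
#' @return data.frame with columns `time` (session time, s) and `speed`.
#' @export
session_speed_trace <- function(session) {
  out <- lapply(seq_len(nrow(session$trials)), function(i) {
    sp <- session$speed[[i]]
    data.frame(time = sp$time + session$trials$t_start[i], speed = sp$speed)
  })
  do.call(rbind, out)
}

#' Flatten one unit's spikes to session time
#'
#' @param session A [generate_session()] result.
#' @param unit Unit index.
#' @return Numeric vector of spike times in session time.
#' @export
unit_session_spikes <- function(session, unit) {
  sp <- session$spikes$spikes[[unit]]
  unlist(lapply(seq_along(sp), function(i) {
    sp[[i]] + session$trials$t_start[i]
  }))
}
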