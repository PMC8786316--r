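#' Center of mass of a firing-rate trace
#'
#' The rate-weighted mean time of a trace on `[0, duration]`, with bin centers
#' as time points. Because z-scored traces contain negative values, the trace
#' is first shifted by its minimum so the weights are non-negative; the shift
#' is applied uniformly to data and controls. An all-zero weight vector has no
#' defined center of mass (NA).
#'
#' @param trace Numeric trace (one unit, one stimulus).
#' @param duration Real duration of the trace in seconds (> 0).
#' @return Center of mass in seconds, or NA.
#' @export
#' @examples
#' center_of_mass(seq(0, 1, length.out = 50), 3)  # linear ramp: 2/3 * 3
center_of_mass <- function(trace, duration) {
  if (duration <= 0) stop("duration must be positive")
  w <- trace - min(trace)
  if (sum(w) == 0) return(NA_real_)
  n <- length(trace)
  tt <- (seq_len(n) - 0.5) / n * duration
  sum(tt * w) / sum(w)
}

#' Temporal-scaling indices from centers of mass
#'
#' For every unit, the center of mass (in seconds) of its trace at each
#' stimulus is divided by the unit's center of mass at the reference stimulus
#' (by default 5.25 s, the grid mean). A unit whose response rescales
#' perfectly with the interval has indices equal to the duration ratios
#' (0.57 at 3 s up to 1.43 at 7.5 s for the default grid); a fixed-clock unit
#' has indices near 1. Units with an undefined reference center of mass are
#' excluded.
#'
#' @param sdf A z-scored [sdf_tensor()]. The time base of each stimulus is
#'   `sdf$durations` (the stimulus itself during measurement, the mean
#'   reproduced duration during reproduction).
#' @param reference Reference stimulus (must be in `sdf$stimuli`).
#' @return data.frame of class `scaling_result` with columns `unit`,
#'   `stimulus`, `com_frac` (fraction of the interval), `com_s` (seconds) and
#'   `index`.
#' @export
scaling_indices <- function(sdf, reference = 5.25) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  jref <- match(reference, sdf$stimuli)
  if (is.na(jref)) stop("reference stimulus not in the tensor")
  com <- matrix(NA_real_, sdf$n_units, length(sdf$stimuli))
  for (j in seq_along(sdf$stimuli)) {
    for (u in seq_len(sdf$n_units)) {
      com[u, j] <- center_of_mass(sdf$values[u, j, ], sdf$durations[j])
    }
  }
  keep <- which(!is.na(com[, jref]))
  res <- expand.grid(unit = keep, stimulus = sdf$stimuli)
  j_of <- match(res$stimulus, sdf$stimuli)
  res$com_s <- com[cbind(res$unit, j_of)]
  res$com_frac <- res$com_s / sdf$durations[j_of]
  res$index <- res$com_s / com[res$unit, jref]
  res <- res[, c("unit", "stimulus", "com_frac", "com_s", "index")]
  class(res) <- c("scaling_result", "data.frame")
  res
}

#' Shuffled-identity control for scaling indices
#'
#' Permutes unit labels independently per stimulus (via
#' [control_sdfs()] `mode = "shuffled"`) before computing scaling indices,
#' breaking the within-unit pairing of centers of mass across stimuli.
#'
#' @param sdf A z-scored [sdf_tensor()].
#' @param reference Reference stimulus.
#' @param seed Optional integer seed.
#' @return A `scaling_result` data.frame as in [scaling_indices()].
#' @export
shuffled_scaling_indices <- function(sdf, reference = 5.25, seed = NULL) {
  scaling_indices(control_sdfs(sdf, "shuffled", seed = seed), reference)
}

#' Bootstrapped two-sample Kolmogorov-Smirnov tests on index subsets
#'
#' Repeatedly subsamples a fraction of each index set without replacement and
#' applies the two-sample KS test, returning the p-value distribution and the
#' share of runs below 0.05. Subsampling makes the test's verdict reflect
#' effect size rather than raw sample count.
#'
#' @param indices_data Numeric vector (e.g. data scaling indices at one
#'   stimulus).
#' @param indices_control Numeric vector (e.g. shuffled-control indices).
#' @param frac Subsample fraction (default 0.1).
#' @param runs Number of bootstrap runs (default 10000).
#' @param seed Optional integer seed.
#' @param alpha Level used for the summary fraction.
#' @return List with `p_values` (length `runs`) and `frac_significant`.
#' @export
bootstrap_ks_scaling <- function(indices_data, indices_control, frac = 0.1,
                                 runs = 10000, seed = NULL, alpha = 0.05) {
  indices_data <- indices_data[!is.na(indices_data)]
  indices_control <- indices_control[!is.na(indices_control)]
  if (length(indices_data) == 0L || length(indices_control) == 0L) {
    stop("both index sets must be non-empty")
  }
  n1 <- floor(frac * length(indices_data))
  n2 <- floor(frac * length(indices_control))
  if (n1 < 5L || n2 < 5L) stop("subsample would contain fewer than 5 values")
  if (runs == 0L) return(list(p_values = numeric(0), frac_significant = NaN))
  p <- with_seed_opt(seed, {
    vapply(seq_len(runs), function(i) {
      x <- sample(indices_data, n1)
      y <- sample(indices_control, n2)
      suppressWarnings(stats::ks.test(x, y)$p.value)
    }, 1.0)
  })
  list(p_values = p, frac_significant = mean(p < alpha))
}
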