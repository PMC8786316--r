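#' Spike density functions from causal count bins
#'
#' For each unit and stimulus, spikes are counted in right-aligned (causal,
#' "looking into the past") windows of `bin_width` seconds, averaged over the
#' stimulus' trials, and divided by the window width to give firing rates.
#' Bins are laid out from the alignment point; the partial bin at the
#' non-aligned edge is dropped. Reproduction-phase trials should be warped to
#' the per-stimulus mean duration first (see [warp_reproduction_trials()]);
#' measurement trials share their duration by design.
#'
#' @param spikes A [spike_data()] object.
#' @param phase `"measurement"` (window `[t0, t1]`) or `"reproduction"`
#'   (`[t2, t3]`).
#' @param align `"begin"` or `"end"` of the phase.
#' @param bin_width Window width in seconds (default 0.1).
#' @return An object of class `sdf_raw`: per-stimulus units x bins rate
#'   matrices (Hz), plus stimuli, per-stimulus durations, alignment and phase.
#' @export
compute_sdf <- function(spikes, phase = c("measurement", "reproduction"),
                        align = c("begin", "end"), bin_width = 0.1) {
  stopifnot(inherits(spikes, "spike_data"))
  phase <- match.arg(phase)
  align <- match.arg(align)
  tr <- spikes$trials
  a <- if (phase == "measurement") tr$t0 else tr$t2
  b <- if (phase == "measurement") tr$t1 else tr$t3
  stimuli <- sort(unique(tr$stimulus))
  n_units <- spikes$n_units

  values <- vector("list", length(stimuli))
  durations <- numeric(length(stimuli))
  for (j in seq_along(stimuli)) {
    idx <- which(tr$stimulus == stimuli[j])
    dur <- b[idx] - a[idx]
    short <- dur < bin_width
    if (any(short)) {
      warning(sprintf("%d trial(s) shorter than one bin skipped", sum(short)))
      idx <- idx[!short]; dur <- dur[!short]
    }
    if (length(idx) == 0L) stop("no usable trials for stimulus ", stimuli[j])
    dbar <- mean(dur)
    n_bins <- floor(dbar / bin_width + 1e-9)
    counts <- matrix(0, n_units, n_bins)
    for (i in idx) {
      for (u in seq_len(n_units)) {
        st <- spikes$spikes[[u]][[i]]
        st <- st[st > a[i] & st <= b[i]]
        if (length(st) == 0L) next
        bin <- if (align == "begin") {
          pmax(1L, ceiling((st - a[i]) / bin_width - 1e-12))
        } else {
          n_bins - floor((b[i] - st) / bin_width - 1e-12)
        }
        bin <- bin[bin >= 1L & bin <= n_bins]
        if (length(bin)) {
          tb <- tabulate(bin, nbins = n_bins)
          counts[u, ] <- counts[u, ] + tb
        }
      }
    }
    values[[j]] <- counts / (length(idx) * bin_width)
    durations[j] <- dbar
  }
  structure(list(values = values, stimuli = stimuli, durations = durations,
                 alignment = align, phase = phase, bin_width = bin_width,
                 n_units = n_units),
            class = "sdf_raw")
}

#' Warp reproduction-phase spike times to the mean reproduced duration
#'
#' Per stimulus, each trial's reproduction-phase spike times are linearly
#' rescaled so the trial's reproduced duration maps onto the stimulus' mean
#' reproduced duration. This removes response-variability edge effects before
#' averaging spike density functions. Per-trial spike counts are preserved.
#'
#' @param spikes A [spike_data()] object.
#' @return A new `spike_data` with warped reproduction spikes and updated `t3`
#'   markers.
#' @export
warp_reproduction_trials <- function(spikes) {
  stopifnot(inherits(spikes, "spike_data"))
  tr <- spikes$trials
  dur <- tr$t3 - tr$t2
  if (any(dur <= 0)) stop("reproduction durations must be positive")
  mean_dur <- stats::ave(dur, tr$stimulus, FUN = mean)
  scale <- mean_dur / dur
  new_spikes <- lapply(spikes$spikes, function(unit) {
    lapply(seq_along(unit), function(i) {
      st <- unit[[i]]
      in_rep <- st > tr$t2[i] & st <= tr$t3[i]
      st[in_rep] <- tr$t2[i] + (st[in_rep] - tr$t2[i]) * scale[i]
      sort(st)
    })
  })
  tr$t3 <- tr$t2 + mean_dur
  spike_data(new_spikes, tr)
}

#' SDF tensor constructor
#'
#' A units x stimuli x bins firing-rate array on a common (time-normalized)
#' bin grid. Usually produced by [normalize_and_zscore()]; exposed so planted
#' populations can be built directly.
#'
#' @param values Numeric array `units x stimuli x bins`.
#' @param stimuli Stimulus durations (s), one per slice.
#' @param durations Real duration (s) of each stimulus' traces (defaults to
#'   `stimuli`; for the reproduction phase, the mean reproduced durations).
#' @param alignment,phase Bookkeeping labels.
#' @param zscored Logical flag.
#' @return An object of class `sdf_tensor`.
#' @export
sdf_tensor <- function(values, stimuli, durations = stimuli,
                       alignment = "begin", phase = "measurement",
                       zscored = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[2L] == length(stimuli),
            length(durations) == length(stimuli))
  structure(list(values = values, stimuli = stimuli, durations = durations,
                 alignment = alignment, phase = phase,
                 n_units = dim(values)[1L], n_bins = dim(values)[3L],
                 bin_width = "normalized", zscored = zscored),
            class = "sdf_tensor")
}

#' @export
print.sdf_tensor <- function(x, ...) {
  cat(sprintf("sdf_tensor: %d units x %d stimuli x %d bins (%s, %s%s)\n",
              x$n_units, length(x$stimuli), x$n_bins, x$phase, x$alignment,
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

# Linear interpolation of one trace onto n_bins samples (bin centers).
resample_trace <- function(y, n_bins) {
  n <- length(y)
  if (n == n_bins) return(y)
  x <- (seq_len(n) - 0.5) / n
  xout <- (seq_len(n_bins) - 0.5) / n_bins
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Time-normalize and z-score an SDF
#'
#' Each unit x stimulus trace is linearly interpolated to `n_bins` samples so
#' traces of different real duration become comparable. Each unit is then
#' z-scored across the concatenation of all its stimulus traces within the
#' phase, preserving across-stimulus amplitude ordering. Constant traces
#' z-score to all zeros.
#'
#' @param sdf An `sdf_raw` (from [compute_sdf()]) or an `sdf_tensor`.
#' @param n_bins Number of normalized bins (>= 2); default 40.
#' @param zscore Apply the per-unit z-scoring (default TRUE).
#' @return An [sdf_tensor()].
#' @export
normalize_and_zscore <- function(sdf, n_bins = 40, zscore = TRUE) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (inherits(sdf, "sdf_raw")) {
    n_units <- sdf$n_units
    n_stim <- length(sdf$stimuli)
    vals <- array(0, dim = c(n_units, n_stim, n_bins))
    for (j in seq_len(n_stim)) {
      for (u in seq_len(n_units)) {
        vals[u, j, ] <- resample_trace(sdf$values[[j]][u, ], n_bins)
      }
    }
    out <- sdf_tensor(vals, sdf$stimuli, sdf$durations,
                      alignment = sdf$alignment, phase = sdf$phase)
  } else if (inherits(sdf, "sdf_tensor")) {
    vals <- array(0, dim = c(sdf$n_units, length(sdf$stimuli), n_bins))
    for (j in seq_along(sdf$stimuli)) {
      for (u in seq_len(sdf$n_units)) {
        vals[u, j, ] <- resample_trace(sdf$values[u, j, ], n_bins)
      }
    }
    out <- sdf_tensor(vals, sdf$stimuli, sdf$durations,
                      alignment = sdf$alignment, phase = sdf$phase,
                      zscored = sdf$zscored)
  } else {
    stop("sdf must be an sdf_raw or sdf_tensor")
  }
  if (zscore) out <- zscore_tensor(out)
  out
}

# Per-unit z-score across the concatenated stimulus traces.
zscore_tensor <- function(x) {
  for (u in seq_len(x$n_units)) {
    tr <- x$values[u, , , drop = FALSE]
    m <- mean(tr)
    s <- stats::sd(as.numeric(tr))
    x$values[u, , ] <- if (is.na(s) || s == 0) 0 else (tr - m) / s
  }
  x$zscored <- TRUE
  x
}

#' Control (surrogate) SDF tensors
#'
#' Two controls for population analyses: `"shuffled"` permutes unit
#' identities independently for every stimulus (destroys cross-stimulus
#' pairing of a cell's traces while preserving each stimulus' trace multiset);
#' `"noise"` permutes each trace's bins over time (destroys temporal
#' structure while preserving each trace's value distribution).
#'
#' @param sdf A z-scored [sdf_tensor()].
#' @param mode `"shuffled"` or `"noise"`.
#' @param seed Optional integer seed.
#' @return An `sdf_tensor` of the same shape.
#' @export
control_sdfs <- function(sdf, mode = c("shuffled", "noise"), seed = NULL) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  if (!isTRUE(sdf$zscored)) stop("control_sdfs expects a z-scored tensor")
  mode <- match.arg(mode)
  with_seed_opt(seed, {
    if (mode == "shuffled") {
      for (j in seq_along(sdf$stimuli)) {
        perm <- sample.int(sdf$n_units)
        sdf$values[, j, ] <- sdf$values[perm, j, ]
      }
    } else {
      for (u in seq_len(sdf$n_units)) {
        for (j in seq_along(sdf$stimuli)) {
          sdf$values[u, j, ] <- sdf$values[u, j, sample.int(sdf$n_bins)]
        }
      }
    }
    sdf
  })
}

#' Causal half-Gaussian smoothing
#'
#' Convolution with a half-Gaussian kernel whose support lies at non-positive
#' lags only (looking into the past), matching the right-aligned count
#' windows. The kernel sums to 1; near the start of a trace the available
#' kernel mass is renormalized so constant traces stay constant. Intended for
#' visualization.
#'
#' @param sdf An `sdf_raw` or [sdf_tensor()].
#' @param sd_bins Kernel standard deviation in bins (default 3).
#' @return Object of the same class with smoothed traces.
#' @export
smooth_half_gaussian <- function(sdf, sd_bins = 3) {
  if (inherits(sdf, "sdf_raw")) {
    sdf$values <- lapply(sdf$values, function(m) {
      t(apply(m, 1L, smooth_vec_causal, sd_bins = sd_bins))
    })
  } else if (inherits(sdf, "sdf_tensor")) {
    for (u in seq_len(sdf$n_units)) {
      for (j in seq_along(sdf$stimuli)) {
        sdf$values[u, j, ] <- smooth_vec_causal(sdf$values[u, j, ], sd_bins)
      }
    }
  } else {
    stop("sdf must be an sdf_raw or sdf_tensor")
  }
  sdf
}

smooth_vec_causal <- function(y, sd_bins) {
  L <- ceiling(4 * sd_bins)
  w <- stats::dnorm(0:L, 0, sd_bins)
  w <- w / sum(w)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0:min(L, i - 1L)
    out[i] <- sum(w[k + 1L] * y[i - k]) / sum(w[k + 1L])
  }
  out
}
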