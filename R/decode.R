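#' Design matrix for linear time decoding
#'
#' Stacks each unit's time-normalized SDFs for all stimuli into a design
#' matrix `R` with `bins * stimuli` rows and one column per unit. The target
#' `t` is real elapsed time: at normalized bin `i` of stimulus `s` it equals
#' `i / n_bins * duration(s)` seconds, so the final target per stimulus is
#' that stimulus' duration.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param durations Real duration per stimulus (defaults to `sdf$durations`).
#' @return List with `R` (matrix) and `t` (seconds per row), rows stacked
#'   stimulus by stimulus.
#' @export
build_design <- function(sdf, durations = sdf$durations) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  if (any(durations <= 0)) stop("durations must be positive")
  if (length(durations) != length(sdf$stimuli)) {
    stop("one duration per stimulus is required")
  }
  n_bins <- sdf$n_bins
  blocks <- lapply(seq_along(sdf$stimuli), function(j) {
    m <- t(matrix(sdf$values[, j, ], nrow = sdf$n_units))
    m
  })
  R <- do.call(rbind, blocks)
  tt <- unlist(lapply(durations, function(d) seq_len(n_bins) / n_bins * d))
  list(R = R, t = tt)
}

#' Fit the Wiener-filter time decoder
#'
#' Least-squares weights solving `R beta + b = t` (a multiple linear
#' regression with a bias term, as in standard Wiener-filter decoders). To
#' avoid overfitting, zero-mean Gaussian noise with `noise_sd` (default 0.5,
#' on the z-scored rate scale) is added to the SDFs at fit time; with
#' `noise_sd = 0` the minimum-norm pseudoinverse solution is returned.
#'
#' @param R Design matrix (rows = bins * stimuli, columns = units).
#' @param t Target elapsed time per row (seconds).
#' @param noise_sd SD of the Gaussian regularization noise (default 0.5).
#' @param seed Optional integer seed for the noise.
#' @return Object of class `time_decoder`: `beta` (weight per unit) and
#'   `intercept` (seconds).
#' @export
fit_time_decoder <- function(R, t, noise_sd = 0.5, seed = NULL) {
  stopifnot(is.matrix(R), nrow(R) == length(t), nrow(R) >= 1L)
  with_seed_opt(seed, {
    Rn <- if (noise_sd > 0) R + stats::rnorm(length(R), 0, noise_sd) else R
    w <- as.numeric(MASS::ginv(cbind(1, Rn)) %*% t)
    structure(list(beta = w[-1L], intercept = w[1L]), class = "time_decoder")
  })
}

# Accept a fitted time_decoder or a bare numeric weight vector (intercept 0).
as_decoder <- function(beta) {
  if (inherits(beta, "time_decoder")) return(beta)
  structure(list(beta = as.numeric(beta), intercept = 0), class = "time_decoder")
}

#' Decode elapsed time and the final-value regression slope
#'
#' Applies the decoder to each stimulus' SDF block (no noise is added at
#' decode time). The final decoded value per stimulus is the last bin's
#' readout; the regression slope of final decoded time on true duration
#' across stimuli quantifies the regression effect of the readout (1 = a
#' veridical code, 0 = the readout collapses to the mean duration).
#'
#' @param beta A fitted `time_decoder` from [fit_time_decoder()], or a bare
#'   numeric weight vector (intercept 0).
#' @param sdf A z-scored, time-normalized [sdf_tensor()] over the same units.
#' @param durations Real duration per stimulus (defaults to `sdf$durations`).
#' @return Object of class `decode_result`: `decoded` (stimuli x bins,
#'   seconds), `finals`, `slope`, `intercept`, `stimuli`, `durations`.
#' @export
decode_and_slope <- function(beta, sdf, durations = sdf$durations) {
  dec <- as_decoder(beta)
  stopifnot(inherits(sdf, "sdf_tensor"), length(dec$beta) == sdf$n_units)
  n_stim <- length(sdf$stimuli)
  decoded <- matrix(0, n_stim, sdf$n_bins)
  for (j in seq_len(n_stim)) {
    m <- t(matrix(sdf$values[, j, ], nrow = sdf$n_units))
    decoded[j, ] <- as.numeric(m %*% dec$beta) + dec$intercept
  }
  finals <- decoded[, sdf$n_bins]
  if (n_stim >= 2L && stats::sd(finals) > 0) {
    fit <- stats::lm(finals ~ durations)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  } else {
    slope <- 0; intercept <- mean(finals)
  }
  structure(list(decoded = decoded, finals = finals, slope = slope,
                 intercept = intercept, stimuli = sdf$stimuli,
                 durations = durations),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d stimuli, final-value slope %.3f\n",
              length(x$stimuli), x$slope))
  invisible(x)
}

#' Bootstrap time decoding over random unit subsets
#'
#' Per run, a subset of `subset_size` units is drawn without replacement, the
#' decoder is fit (with regularization noise) and time is decoded from the
#' same subset. Reports the mean and SD of the decoded trajectories and the
#' median and interquartile range of the final-value regression slopes.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param durations Real duration per stimulus.
#' @param subset_size Units per run (default 20).
#' @param runs Bootstrap runs (default 1000).
#' @param noise_sd Fit-time noise SD (default 0.5).
#' @param units_pool Optional unit indices to sample from (default: all).
#' @param seed Optional integer seed.
#' @return List with `decoded_mean`, `decoded_sd` (stimuli x bins), `slopes`
#'   (per run), `slope_median`, `slope_iqr`, `finals_mean`.
#' @export
bootstrap_decode <- function(sdf, durations = sdf$durations, subset_size = 20,
                             runs = 1000, noise_sd = 0.5, units_pool = NULL,
                             seed = NULL) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  if (is.null(units_pool)) units_pool <- seq_len(sdf$n_units)
  if (length(units_pool) < subset_size) {
    stop("not enough units for the requested subset size")
  }
  n_stim <- length(sdf$stimuli)
  acc <- array(0, c(runs, n_stim, sdf$n_bins))
  slopes <- numeric(runs)
  with_seed_opt(seed, {
    for (b in seq_len(runs)) {
      sel <- units_pool[sample.int(length(units_pool), subset_size)]
      sub <- sdf_tensor(sdf$values[sel, , , drop = FALSE], sdf$stimuli,
                        sdf$durations, sdf$alignment, sdf$phase,
                        zscored = sdf$zscored)
      des <- build_design(sub, durations)
      beta <- fit_time_decoder(des$R, des$t, noise_sd = noise_sd)
      dec <- decode_and_slope(beta, sub, durations)
      acc[b, , ] <- dec$decoded
      slopes[b] <- dec$slope
    }
  })
  list(decoded_mean = apply(acc, c(2, 3), mean),
       decoded_sd = apply(acc, c(2, 3), stats::sd),
       slopes = slopes,
       slope_median = stats::median(slopes),
       slope_iqr = unname(diff(stats::quantile(slopes, c(0.25, 0.75)))),
       finals_mean = apply(acc[, , sdf$n_bins, drop = FALSE], 2, mean),
       stimuli = sdf$stimuli, durations = durations)
}

#' Regression slope as a function of the slope-changing cell fraction
#'
#' Mixes two unit pools -- slope-changing (ramp-to-threshold-like) and linear
#' increasing -- at each fraction `p`, bootstraps the decoder on 20-cell
#' subsets drawn with `round(p * subset_size)` units from the slope-changing
#' pool, and records the median final-value slope. The more slope-changing
#' cells, the stronger the regression effect (slope decreases toward 0).
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()] containing both
#'   pools.
#' @param pool_changing,pool_linear Unit index vectors of the two pools.
#' @param fractions Fractions of slope-changing cells (default 0, 0.2, ..., 1).
#' @param subset_size,runs,noise_sd As in [bootstrap_decode()].
#' @param durations Real duration per stimulus.
#' @param seed Optional integer seed.
#' @return data.frame with `fraction`, `slope_median`, `slope_iqr`.
#' @export
mixture_sweep <- function(sdf, pool_changing, pool_linear,
                          fractions = seq(0, 1, by = 0.2), subset_size = 20,
                          runs = 200, noise_sd = 0.5,
                          durations = sdf$durations, seed = NULL) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  with_seed_opt(seed, {
    rows <- lapply(fractions, function(p) {
      n_ch <- round(p * subset_size)
      n_li <- subset_size - n_ch
      if (n_ch > length(pool_changing) || n_li > length(pool_linear)) {
        stop("a pool is too small for fraction ", p)
      }
      slopes <- vapply(seq_len(runs), function(b) {
        sel <- c(pool_changing[sample.int(length(pool_changing), n_ch)],
                 pool_linear[sample.int(length(pool_linear), n_li)])
        sub <- sdf_tensor(sdf$values[sel, , , drop = FALSE], sdf$stimuli,
                          sdf$durations, sdf$alignment, sdf$phase,
                          zscored = sdf$zscored)
        des <- build_design(sub, durations)
        beta <- fit_time_decoder(des$R, des$t, noise_sd = noise_sd)
        decode_and_slope(beta, sub, durations)$slope
      }, 1.0)
      data.frame(fraction = p, slope_median = stats::median(slopes),
                 slope_iqr = unname(diff(stats::quantile(slopes, c(0.25, 0.75)))))
    })
    do.call(rbind, rows)
  })
}
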