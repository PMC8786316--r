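#' Marginalize an SDF tensor into time-course and stimulus parts
#'
#' The time marginal is the mean over stimuli (units x bins); the stimulus
#' marginal is the residual after subtracting the time marginal from every
#' stimulus slice. The two parts add back to the tensor exactly and are
#' orthogonal (the stimulus marginal sums to zero over stimuli), so their
#' variances account for the full tensor variance.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @return List with `time_marginal` (units x bins) and `stimulus_marginal`
#'   (units x stimuli x bins).
#' @export
marginalize <- function(sdf) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  tm <- apply(sdf$values, c(1, 3), mean)
  sm <- sweep(sdf$values, c(1, 3), tm, "-")
  list(time_marginal = tm, stimulus_marginal = sm)
}

# Fix component signs: largest-magnitude element positive. Flips the matching
# scores so the product is unchanged.
fix_signs <- function(components, scores) {
  for (k in seq_len(nrow(components))) {
    i <- which.max(abs(components[k, ]))
    if (components[k, i] < 0) {
      components[k, ] <- -components[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  list(components = components, scores = scores)
}

#' Demixed principal component analysis of an SDF tensor
#'
#' Population activity is separated by [marginalize()] into a
#' stimulus-independent time course and a stimulus-dependent residual, and a
#' singular-value decomposition is applied to each marginalization (units x
#' flattened-time matrices). Time components are, by construction, identical
#' across stimuli ("perfect demixing"); the stimulus component is one spatial
#' component whose per-stimulus traces carry stimulus-ordered amplitudes.
#' Explained variances are percentages of the full tensor variance, so time
#' components, stimulus components and the residual add to 100.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param n_time_pcs Number of time-course components (default 3).
#' @param n_stim_pcs Number of stimulus components (default 1).
#' @return An object of class `decomp_result` with elements:
#'   `time_components` (n_time_pcs x bins), `time_scores` (units x
#'   n_time_pcs), `stim_components` (n_stim_pcs x stimuli x bins),
#'   `stim_scores`, `stim_amplitudes` (n_stim_pcs x stimuli; per-stimulus
#'   mean of each stimulus component), `ev_time`, `ev_stim` (percent of
#'   tensor variance), per-stimulus `trajectories` in the retained component
#'   space, plus stimuli, durations and bookkeeping.
#' @export
demixed_pca <- function(sdf, n_time_pcs = 3, n_stim_pcs = 1) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  n_units <- sdf$n_units
  n_stim <- length(sdf$stimuli)
  n_bins <- sdf$n_bins
  if (n_units < max(n_time_pcs, n_stim_pcs)) {
    stop("need at least as many units as requested components")
  }
  marg <- marginalize(sdf)
  total_ss <- sum(sdf$values^2)

  # time marginal: units x bins
  kt <- min(n_time_pcs, n_bins)
  st <- svd(marg$time_marginal, nu = kt, nv = kt)
  time_components <- t(st$v)
  time_scores <- st$u %*% diag(st$d[seq_len(kt)], kt)
  fx <- fix_signs(time_components, time_scores)
  time_components <- fx$components; time_scores <- fx$scores
  ev_time <- 100 * n_stim * st$d[seq_len(kt)]^2 / total_ss

  # stimulus marginal: units x (stimuli * bins)
  sm_flat <- matrix(marg$stimulus_marginal, n_units, n_stim * n_bins)
  ks <- min(n_stim_pcs, n_stim * n_bins)
  ss <- svd(sm_flat, nu = ks, nv = ks)
  stim_flat <- t(ss$v)
  stim_scores <- ss$u %*% diag(ss$d[seq_len(ks)], ks)
  fx <- fix_signs(stim_flat, stim_scores)
  stim_flat <- fx$components; stim_scores <- fx$scores
  ev_stim <- 100 * ss$d[seq_len(ks)]^2 / total_ss
  stim_components <- array(0, dim = c(ks, n_stim, n_bins))
  for (k in seq_len(ks)) {
    stim_components[k, , ] <- matrix(stim_flat[k, ], n_stim, n_bins)
  }
  stim_amplitudes <- apply(stim_components, c(1, 2), mean)
  # orient stimulus components so amplitudes increase with duration
  for (k in seq_len(ks)) {
    if (length(sdf$stimuli) > 1L && stats::sd(stim_amplitudes[k, ]) > 0 &&
        stats::sd(sdf$stimuli) > 0 &&
        isTRUE(stats::cor(stim_amplitudes[k, ], sdf$stimuli) < 0)) {
      stim_components[k, , ] <- -stim_components[k, , ]
      stim_scores[, k] <- -stim_scores[, k]
      stim_amplitudes[k, ] <- -stim_amplitudes[k, ]
    }
  }

  # degenerate marginalizations yield zero components with 0% EV
  zero_t <- st$d[seq_len(kt)] < 1e-12 * max(st$d[1], 1e-300)
  time_components[zero_t, ] <- 0; time_scores[, zero_t] <- 0
  ev_time[zero_t] <- 0
  zero_s <- ss$d[seq_len(ks)] < 1e-12 * max(st$d[1], ss$d[1], 1e-300)
  stim_components[zero_s, , ] <- 0; stim_scores[, zero_s] <- 0
  ev_stim[zero_s] <- 0
  if (any(zero_s)) stim_amplitudes <- apply(stim_components, c(1, 2), mean)

  # per-stimulus trajectories: tensor projected onto unit-space directions
  ut <- st$u; us <- ss$u
  trajectories <- lapply(seq_len(n_stim), function(j) {
    slice <- sdf$values[, j, , drop = TRUE]
    if (n_units == 1L) slice <- matrix(slice, nrow = 1L)
    cbind(t(slice) %*% ut, t(slice) %*% us)
  })

  structure(list(kind = "demixed",
                 time_components = time_components,
                 time_scores = time_scores,
                 stim_components = stim_components,
                 stim_scores = stim_scores,
                 stim_amplitudes = stim_amplitudes,
                 ev_time = ev_time, ev_stim = ev_stim,
                 trajectories = trajectories,
                 stimuli = sdf$stimuli, durations = sdf$durations,
                 n_bins = n_bins, n_units = n_units,
                 total_ss = total_ss, values = sdf$values),
            class = "decomp_result")
}

#' Conventional PCA of an SDF tensor
#'
#' Standard SVD-based principal components of the full units x
#' (stimuli * bins) matrix. Unlike demixed components, per-stimulus
#' trajectories of each conventional component mix time-course and stimulus
#' information.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param n_pcs Number of components (default 3).
#' @return A `decomp_result` with `kind = "conventional"`: `components`
#'   (n_pcs x stimuli x bins), `scores`, `ev` (percent of tensor variance)
#'   and per-stimulus `trajectories`.
#' @export
conventional_pca <- function(sdf, n_pcs = 3) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  n_units <- sdf$n_units
  n_stim <- length(sdf$stimuli)
  n_bins <- sdf$n_bins
  flat <- matrix(sdf$values, n_units, n_stim * n_bins)
  k <- min(n_pcs, n_stim * n_bins, n_units)
  sv <- svd(flat, nu = k, nv = k)
  comp_flat <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  fx <- fix_signs(comp_flat, scores)
  comp_flat <- fx$components; scores <- fx$scores
  total_ss <- sum(sdf$values^2)
  ev <- 100 * sv$d[seq_len(k)]^2 / total_ss
  components <- array(0, dim = c(k, n_stim, n_bins))
  for (i in seq_len(k)) components[i, , ] <- matrix(comp_flat[i, ], n_stim, n_bins)
  trajectories <- lapply(seq_len(n_stim), function(j) {
    slice <- sdf$values[, j, , drop = TRUE]
    if (n_units == 1L) slice <- matrix(slice, nrow = 1L)
    t(slice) %*% sv$u
  })
  structure(list(kind = "conventional",
                 components = components, scores = scores, ev = ev,
                 trajectories = trajectories,
                 stimuli = sdf$stimuli, durations = sdf$durations,
                 n_bins = n_bins, n_units = n_units,
                 total_ss = total_ss, values = sdf$values),
            class = "decomp_result")
}

#' @export
print.decomp_result <- function(x, ...) {
  if (x$kind == "demixed") {
    cat(sprintf("demixed PCA: %d units, EV time PCs %s%%, stimulus PCs %s%%\n",
                x$n_units, paste(round(x$ev_time, 1), collapse = "/"),
                paste(round(x$ev_stim, 1), collapse = "/")))
  } else {
    cat(sprintf("conventional PCA: %d units, EV %s%%\n",
                x$n_units, paste(round(x$ev, 1), collapse = "/")))
  }
  invisible(x)
}

#' State-space trajectory length and mean speed per stimulus
#'
#' Trajectory length is the summed Euclidean step size of the per-stimulus
#' trajectory in the top-k component space; mean speed divides the length by
#' the real duration of the stimulus' traces.
#'
#' @param decomp A [demixed_pca()] or [conventional_pca()] result.
#' @param top_k Number of leading components spanning the state space.
#' @return data.frame with `stimulus`, `duration`, `length`, `speed`.
#' @export
trajectory_metrics <- function(decomp, top_k = 3) {
  stopifnot(inherits(decomp, "decomp_result"))
  out <- lapply(seq_along(decomp$stimuli), function(j) {
    traj <- decomp$trajectories[[j]]
    k <- min(top_k, ncol(traj))
    traj <- traj[, seq_len(k), drop = FALSE]
    if (nrow(traj) < 2L) {
      len <- 0
    } else {
      steps <- diff(traj)
      len <- sum(sqrt(rowSums(steps^2)))
    }
    dur <- decomp$durations[j]
    data.frame(stimulus = decomp$stimuli[j], duration = dur,
               length = len, speed = len / dur)
  })
  do.call(rbind, out)
}

#' Stratified bootstrap of the demixed decomposition
#'
#' Repeats [demixed_pca()] on random unit subsets of fraction `frac`, drawn
#' without replacement within strata (e.g. animal of origin) so every stratum
#' contributes proportionally. Component signs are aligned to the full-data
#' decomposition before aggregating, yielding spread bands per bin and the
#' distribution of correlations between time-PC-1 scores and
#' stimulus-PC-1 scores.
#'
#' @param sdf A z-scored, time-normalized [sdf_tensor()].
#' @param frac Subset fraction (default 0.1).
#' @param runs Number of bootstrap runs (default 1000).
#' @param strata Optional factor of length units; NULL = one stratum.
#' @param n_time_pcs,n_stim_pcs Passed to [demixed_pca()].
#' @param seed Optional integer seed.
#' @return List with `full` (full-data decomposition), `time_bands` and
#'   `stim_bands` (mean/sd/quantile arrays over runs), `score_cor`
#'   (data.frame per run: r, p of the PC1 vs stimulus-PC1 score correlation),
#'   and `ev_time`/`ev_stim` run matrices.
#' @export
bootstrap_decomp <- function(sdf, frac = 0.1, runs = 1000, strata = NULL,
                             n_time_pcs = 3, n_stim_pcs = 1, seed = NULL) {
  stopifnot(inherits(sdf, "sdf_tensor"))
  n_units <- sdf$n_units
  if (is.null(strata)) strata <- rep(1L, n_units)
  strata <- as.factor(strata)
  idx_by <- split(seq_len(n_units), strata)
  take <- vapply(idx_by, function(ix) floor(frac * length(ix)), 1.0)
  if (any(take < 1L)) stop("a stratum is smaller than frac * size")
  full <- demixed_pca(sdf, n_time_pcs, n_stim_pcs)
  kt <- nrow(full$time_components)
  ks <- dim(full$stim_components)[1L]

  time_runs <- array(NA_real_, c(runs, kt, sdf$n_bins))
  stim_runs <- array(NA_real_, c(runs, ks, length(sdf$stimuli), sdf$n_bins))
  ev_time <- matrix(NA_real_, runs, kt)
  ev_stim <- matrix(NA_real_, runs, ks)
  score_r <- numeric(runs); score_p <- numeric(runs)

  with_seed_opt(seed, {
    for (b in seq_len(runs)) {
      sel <- sort(unlist(mapply(function(ix, m) ix[sample.int(length(ix), m)],
                                idx_by, take, SIMPLIFY = FALSE)))
      sub <- sdf_tensor(sdf$values[sel, , , drop = FALSE], sdf$stimuli,
                        sdf$durations, sdf$alignment, sdf$phase,
                        zscored = sdf$zscored)
      d <- demixed_pca(sub, n_time_pcs, n_stim_pcs)
      for (k in seq_len(kt)) {
        v <- d$time_components[k, ]
        sgn_scores <- 1
        if (sum(v * full$time_components[k, ]) < 0) { v <- -v; sgn_scores <- -1 }
        time_runs[b, k, ] <- v
        if (k == 1L) ts1 <- sgn_scores * d$time_scores[, 1L]
      }
      for (k in seq_len(ks)) {
        v <- d$stim_components[k, , ]
        sgn_scores <- 1
        if (sum(v * full$stim_components[k, , ]) < 0) { v <- -v; sgn_scores <- -1 }
        stim_runs[b, k, , ] <- v
        if (k == 1L) ss1 <- sgn_scores * d$stim_scores[, 1L]
      }
      ev_time[b, ] <- d$ev_time
      ev_stim[b, ] <- d$ev_stim
      z <- pearson_rp(ts1, ss1)
      score_r[b] <- z$r; score_p[b] <- z$p
    }
  })

  band <- function(a, dims) {
    list(mean = apply(a, dims, mean), sd = apply(a, dims, stats::sd),
         lo = apply(a, dims, stats::quantile, 0.025),
         hi = apply(a, dims, stats::quantile, 0.975))
  }
  list(full = full,
       time_bands = band(time_runs, c(2, 3)),
       stim_bands = band(stim_runs, c(2, 3, 4)),
       score_cor = data.frame(r = score_r, p = score_p),
       ev_time = ev_time, ev_stim = ev_stim)
}
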