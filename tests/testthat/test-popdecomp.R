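test_that("marginalization reconstructs the tensor exactly", {
  pl <- planted_two_factor(n_units = 10, seed = 21)
  m <- marginalize(pl$sdf)
  recon <- sweep(m$stimulus_marginal, c(1, 3), m$time_marginal, "+")
  expect_equal(recon, pl$sdf$values, tolerance = 1e-12)
  # tensor identical across stimuli -> zero stimulus marginal
  vals <- array(rep(seq_len(20), each = 5 * 7), c(5, 7, 20))
  for (j in 1:7) vals[, j, ] <- vals[, 1, ]
  m2 <- marginalize(sdf_tensor(vals, stimulus_grid()$durations, zscored = TRUE))
  expect_true(all(abs(m2$stimulus_marginal) < 1e-12))
})

test_that("planted stimulus-offset population has constant, ordered marginal traces", {
  g <- stimulus_grid()
  vals <- array(0, c(6, 7, 30))
  amp <- (g$durations - g$mean) / g$range
  for (u in 1:6) for (j in 1:7) vals[u, j, ] <- u * amp[j]
  m <- marginalize(sdf_tensor(vals, g$durations, zscored = TRUE))
  for (j in 1:7) {
    tr <- m$stimulus_marginal[1, j, ]
    expect_lt(diff(range(tr)), 1e-12)  # constant in time
  }
  expect_identical(order(m$stimulus_marginal[1, , 1]), 1:7)
})

test_that("a population of identical ramps is rank one in the time marginal", {
  g <- stimulus_grid()
  ramp <- seq(0, 1, length.out = 40)
  vals <- array(0, c(8, 7, 40))
  for (u in 1:8) for (j in 1:7) vals[u, j, ] <- u * ramp
  tz <- sdf_tensor(vals, g$durations, zscored = FALSE)
  d <- demixed_pca(tz, n_time_pcs = 3)
  expect_lt(vector_angle_deg(d$time_components[1, ], ramp), 1e-6)
  expect_equal(sum(d$ev_time), d$ev_time[1], tolerance = 1e-9)
  expect_equal(d$ev_time[1] + sum(d$ev_stim), 100, tolerance = 1e-9)
})

test_that("planted two-factor population is recovered with small subspace angle", {
  pl <- planted_two_factor(n_units = 80, noise_sd = 0.01, seed = 3)
  d <- demixed_pca(pl$sdf)
  expect_lt(vector_angle_deg(d$time_components[1, ], pl$ramp), 5)
  # stimulus component: constant-in-time traces with duration-ordered amps
  expect_gt(stats::cor(d$stim_amplitudes[1, ], pl$sdf$stimuli), 0.99)
  # scores recover the planted loadings (up to scale)
  expect_gt(abs(stats::cor(d$time_scores[, 1], pl$a_time)), 0.99)
  expect_gt(abs(stats::cor(d$stim_scores[, 1], pl$a_stim)), 0.99)
})

test_that("EV accounting sums to 100% with the residual", {
  s <- noise_session(n_units = 12, n_trials = 30, seed = 22)
  tz <- normalize_and_zscore(compute_sdf(s$spikes, "measurement", "begin"), 40)
  d <- demixed_pca(tz, n_time_pcs = 12, n_stim_pcs = 12)
  expect_true(all(d$ev_time >= 0) && all(d$ev_stim >= 0))
  expect_lte(sum(d$ev_time) + sum(d$ev_stim), 100 + 1e-9)
  # with all components retained the variance is fully accounted for
  full_stim <- demixed_pca(tz, n_time_pcs = 12, n_stim_pcs = 12)
  m <- marginalize(tz)
  ev_t_all <- 100 * 7 * sum(svd(m$time_marginal)$d^2) / sum(tz$values^2)
  ev_s_all <- 100 * sum(svd(matrix(m$stimulus_marginal, 12))$d^2) /
    sum(tz$values^2)
  expect_equal(ev_t_all + ev_s_all, 100, tolerance = 1e-9)
})

test_that("conventional PCA agrees with demixed components on one stimulus", {
  pl <- planted_two_factor(seed = 23)
  one <- sdf_tensor(pl$sdf$values[, 4, , drop = FALSE], 5.25, zscored = TRUE)
  dd <- demixed_pca(one, n_time_pcs = 2, n_stim_pcs = 1)
  cc <- conventional_pca(one, n_pcs = 2)
  expect_lt(vector_angle_deg(cc$components[1, 1, ], dd$time_components[1, ]),
            1e-6)
  # EV non-increasing
  expect_true(all(diff(cc$ev) <= 1e-9))
})

test_that("conventional PC1 trajectories differ across stimuli, demixed do not", {
  pl <- planted_two_factor(seed = 24)
  cc <- conventional_pca(pl$sdf, n_pcs = 2)
  spread_conv <- stats::sd(cc$components[1, , 1])
  expect_gt(spread_conv, 1e-6)
  dd <- demixed_pca(pl$sdf)
  # demixing exactness: time components replicated per stimulus are identical
  for (k in 1:3) {
    per_stim <- matrix(rep(dd$time_components[k, ], each = 7), 7)
    expect_true(all(apply(per_stim, 2, function(col) diff(range(col)) == 0)))
  }
})

test_that("trajectory metrics separate measurement- and reproduction-like codes", {
  # absolute-clock ramps: equal speed, length proportional to duration
  lin <- stereotype_sdf_tensor(linear_pool(30, seed = 25))
  tm_lin <- trajectory_metrics(conventional_pca(lin, 3), top_k = 3)
  sp <- tm_lin$speed
  expect_lt((max(sp) - min(sp)) / stats::median(sp), 0.05)
  len_ratio <- tm_lin$length[7] / tm_lin$length[1]
  expect_equal(len_ratio, 7.5 / 3, tolerance = 0.05)
  # time-rescaled profiles: equal length, speed ~ 1/duration
  ram <- stereotype_sdf_tensor(ramp_pool(30, seed = 26))
  tm_ram <- trajectory_metrics(conventional_pca(ram, 3), top_k = 3)
  expect_lt((max(tm_ram$length) - min(tm_ram$length)) /
              stats::median(tm_ram$length), 0.05)
  expect_equal(tm_ram$speed[1] / tm_ram$speed[7], 7.5 / 3, tolerance = 0.05)
  # single-point trajectory has zero length
  single <- structure(list(kind = "conventional",
                           trajectories = list(matrix(1, 1, 2)),
                           stimuli = 3, durations = 3),
                      class = "decomp_result")
  expect_equal(trajectory_metrics(single, 2)$length, 0)
})

test_that("bootstrap with frac 1 reproduces the full decomposition", {
  pl <- planted_two_factor(n_units = 20, seed = 27)
  bs <- bootstrap_decomp(pl$sdf, frac = 1, runs = 1, seed = 1)
  expect_equal(bs$time_bands$mean[1, ], bs$full$time_components[1, ],
               tolerance = 1e-9)
  expect_equal(as.numeric(bs$stim_bands$mean[1, , ]),
               as.numeric(bs$full$stim_components[1, , ]), tolerance = 1e-9)
})

test_that("bootstrap bands cover the full-data component", {
  pl <- planted_two_factor(n_units = 60, noise_sd = 0.05, seed = 28)
  bs <- bootstrap_decomp(pl$sdf, frac = 0.2, runs = 120, seed = 2)
  inside <- bs$full$time_components[1, ] >= bs$time_bands$lo[1, ] &
    bs$full$time_components[1, ] <= bs$time_bands$hi[1, ]
  expect_gte(mean(inside), 0.95)
})

test_that("score correlations are positive when ramp amplitude is yoked to tuning", {
  withr::with_seed(29, {
    n_u <- 60; n_b <- 40
    ramp <- seq(0, 1, length.out = n_b)
    g <- stimulus_grid()
    amp <- (g$durations - g$mean) / g$range
    a <- stats::runif(n_u, 0.5, 2)   # shared loading for both factors
    vals <- array(0, c(n_u, 7, n_b))
    for (u in seq_len(n_u)) {
      for (j in 1:7) {
        vals[u, j, ] <- a[u] * ramp + a[u] * amp[j] +
          stats::rnorm(n_b, 0, 0.05)
      }
    }
    tz <- sdf_tensor(vals, g$durations, zscored = TRUE)
    bs <- bootstrap_decomp(tz, frac = 0.2, runs = 100, seed = 3)
    sig_pos <- mean(bs$score_cor$r > 0 & bs$score_cor$p < 0.05)
    expect_gt(sig_pos, 0.9)
  })
})

test_that("strata errors and determinism are enforced", {
  pl <- planted_two_factor(n_units = 12, seed = 30)
  expect_error(bootstrap_decomp(pl$sdf, frac = 0.1, runs = 2,
                                strata = rep(1:4, each = 3)),
               "stratum")
  b1 <- bootstrap_decomp(pl$sdf, frac = 0.5, runs = 5, seed = 7)
  b2 <- bootstrap_decomp(pl$sdf, frac = 0.5, runs = 5, seed = 7)
  expect_equal(b1$score_cor, b2$score_cor)
})
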