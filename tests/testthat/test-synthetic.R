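test_that("stimulus grid validates spacing and exposes the 5.25 s mean", {
  g <- stimulus_grid()
  expect_length(g$durations, 7L)
  expect_equal(g$mean, 5.25)
  expect_equal(g$spacing, 0.75)
  expect_error(stimulus_grid(c(3, 4, 4)), "strictly increasing")
  expect_error(stimulus_grid(c(3, 4, 6)), "uniformly spaced")
})

test_that("stimulus sampling stays on the grid and is uniform", {
  g <- stimulus_grid()
  expect_identical(sample_stimuli(g, 0), numeric(0))
  x <- sample_stimuli(g, 1000, seed = 1)
  expect_true(all(x %in% g$durations))
  expect_identical(x, sample_stimuli(g, 1000, seed = 1))
  # chi-square goodness of fit against the discrete uniform at n = 7000
  x <- sample_stimuli(g, 7000, seed = 2)
  counts <- table(factor(x, levels = g$durations))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("observer model has the exact limiting behaviors", {
  g <- stimulus_grid()
  ident <- observer_params(lambda = 1, w_m = 0, w_p = 0, mu = 5.25)
  expect_equal(simulate_observer_trial(g$durations, ident, seed = 1),
               g$durations)
  prior <- observer_params(lambda = 0, w_m = 0, w_p = 0, mu = 5.25)
  expect_equal(simulate_observer_trial(g$durations, prior, seed = 1),
               rep(5.25, 7))
})

test_that("observer regression slope converges to lambda", {
  # closed form: E[r|s] = lambda*s + (1-lambda)*mu
  g <- stimulus_grid()
  obs <- observer_params(lambda = 0.7, w_m = 0.1, w_p = 0.1)
  s <- rep(g$durations, each = 10000)
  r <- simulate_observer_trial(s, obs, seed = 3)
  fit <- stats::lm(r ~ s)
  expect_equal(unname(coef(fit)[2]), 0.70, tolerance = 0.02 / 0.70)
})

test_that("feedback tolerance adapts by 3 points and floors at 0", {
  expect_equal(update_feedback(5, 5, 0.15), list(in_out = TRUE, k_next = 0.12))
  expect_equal(update_feedback(10, 5, 0.15), list(in_out = FALSE, k_next = 0.18))
  expect_equal(update_feedback(5, 5, 0.02)$k_next, 0)
  # boundary: reward iff r within (1 +/- k) * s
  expect_true(update_feedback(5 * 1.15, 5, 0.15)$in_out)
  expect_false(update_feedback(5 * 1.16, 5, 0.15)$in_out)
})

test_that("stereotype rates match their closed forms", {
  g <- stimulus_grid()
  up <- stereotype_params("ramp_to_threshold_up", baseline = 2, amplitude = 10)
  for (s in g$durations) {
    expect_equal(stereotype_rate(up, s, s), 12)  # same end level for every s
    expect_equal(stereotype_rate(up, s, 0), 2)
  }
  lin <- stereotype_params("linear_increasing", baseline = 1, slope = 2)
  expect_equal(stereotype_rate(lin, 5, 0), 1)
  expect_equal(stereotype_rate(lin, 5, 3), 7)
  expect_error(stereotype_rate(lin, 5, 6), "within")
  down <- stereotype_params("ramp_to_threshold_down", baseline = 2, amplitude = 10)
  expect_equal(stereotype_rate(down, 6, 0), 12)
  expect_equal(stereotype_rate(down, 6, 6), 2)
  # rectification
  neg <- stereotype_params("linear_increasing", baseline = 0, slope = 1)
  expect_equal(stereotype_rate(neg, 5, 1, rate_offset = -10), 0)
})

test_that("Poisson generator matches count statistics and time rescaling", {
  expect_identical(generate_spike_train(0, 5, seed = 1), numeric(0))
  # homogeneous 10 Hz, 5 s: mean count 50, SE of the mean over 1000 repeats
  # is sqrt(50/1000) ~ 0.22; allow 3 SE
  counts <- withr::with_seed(4, {
    vapply(1:1000, function(i) length(generate_spike_train(10, 5)), 1L)
  })
  expect_lt(abs(mean(counts) - 50), 0.7)
  # time-rescaling: transformed ISIs of a ramp-rate train are Exp(1)
  p <- stereotype_params("linear_increasing", baseline = 2, slope = 3)
  lam <- function(t) 2 * t + 3 * t^2 / 2
  isi <- unlist(lapply(1:50, function(i) {
    tr <- generate_spike_train(function(t) stereotype_rate(p, 7.5, t), 7.5,
                               seed = 200 + i)
    diff(c(0, lam(tr)))
  }))
  expect_gt(suppressWarnings(stats::ks.test(isi, "pexp", 1)$p.value), 0.01)
})

test_that("sessions have consistent shape and are seed-deterministic", {
  cfg <- session_config(n_trials = 12, n_units = 5, seed = 99)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes$spikes, s2$spikes$spikes)
  expect_equal(s1$spikes$n_units, 5L)
  expect_equal(nrow(s1$trials), 12L)
  with(s1$trials, {
    expect_true(all(t0 < t1 & t1 <= t2 & t2 < t3))
    expect_equal(t1 - t0, stimulus)
    expect_equal(t3 - t2, reproduction)
  })
  # reward flag is consistent with the tolerance window
  with(s1$trials, {
    inside <- reproduction >= (1 - k) * stimulus &
      reproduction <= (1 + k) * stimulus
    expect_equal(reward, inside)
  })
})

test_that("stereotype mixtures must sum to one and fill unit counts", {
  expect_error(stereotype_mixture(c(linear_increasing = 0.5), 10), "sum to 1")
  mix <- stereotype_mixture(c(linear_increasing = 0.5, unrelated_noise = 0.5), 9)
  expect_length(mix, 9L)
  types <- vapply(mix, function(p) p$type, "")
  expect_equal(sort(unique(types)),
               c("linear_increasing", "unrelated_noise"))
})

test_that("linear-increasing sessions show end-of-measurement rates ordered by stimulus", {
  cfg <- session_config(
    n_trials = 210,
    stereotypes = rep(list(stereotype_params("linear_increasing",
                                             baseline = 5, slope = 5)), 3),
    observer = observer_params(1, 0, 0), seed = 7)
  s <- generate_session(cfg)
  raw <- compute_sdf(s$spikes, "measurement", "end")
  # mean rate over the last 1 s (10 bins) per stimulus
  ends <- vapply(seq_along(raw$stimuli), function(j) {
    m <- raw$values[[j]]
    mean(m[, (ncol(m) - 9):ncol(m)])
  }, 1.0)
  expect_identical(order(ends), seq_along(raw$stimuli))
})

test_that("feedback walk is bounded and a competent observer earns rewards", {
  cfg <- session_config(n_trials = 300, n_units = 1,
                        observer = observer_params(0.95, 0.02, 0.05),
                        seed = 13)
  s <- generate_session(cfg)
  expect_true(all(s$trials$k >= 0))
  expect_gt(mean(s$trials$reward), 0.5)
})

test_that("observer exhibits scalar variability (constant CV when w_m = 0)", {
  g <- stimulus_grid()
  obs <- observer_params(lambda = 1, w_m = 0, w_p = 0.1)
  s <- rep(g$durations, each = 4000)
  r <- simulate_observer_trial(s, obs, seed = 21)
  cvs <- vapply(split(r, s), function(x) stats::sd(x) / mean(x), 1.0)
  expect_lt(max(cvs) / min(cvs), 1.1)
  expect_equal(mean(cvs), 0.1, tolerance = 0.05)
})

test_that("stereotype tensors are z-scored and session CSV round-trips", {
  tz <- stereotype_sdf_tensor(linear_pool(5))
  expect_s3_class(tz, "sdf_tensor")
  for (u in 1:5) {
    expect_equal(mean(tz$values[u, , ]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(as.numeric(tz$values[u, , ])), 1, tolerance = 1e-9)
  }
  s <- generate_session(session_config(n_trials = 6, n_units = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_session_csv(s, dir)
  back <- read_session_csv(dir)
  expect_equal(back$trials$stimulus, s$trials$stimulus)
  expect_equal(back$spikes$spikes[[2]][[3]], s$spikes$spikes[[2]][[3]],
               tolerance = 1e-8)
})
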