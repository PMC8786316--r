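
# planted population where each unit is an exact mixture of the demixed
# factors, so reconstruction EVs have known values
planted_decomp <- function(w_time = 1, w_stim = 0, n_filler = 30, seed = 31) {
  withr::with_seed(seed, {
    g <- stimulus_grid()
    n_b <- 40
    ramp <- seq(0, 1, length.out = n_b); ramp <- ramp - mean(ramp)
    ramp <- ramp / sqrt(sum(ramp^2))
    amp <- (g$durations - g$mean) / g$range
    vals <- array(0, c(n_filler + 1, 7, n_b))
    # filler units define the factors; unit 1 is the probe
    for (u in 2:(n_filler + 1)) {
      vals[u, , ] <- outer(rep(stats::rnorm(1), 7), ramp) *
        stats::runif(1, 0.5, 2)
      vals[u, , ] <- vals[u, , ] + stats::rnorm(1) * outer(amp, rep(1, n_b))
    }
    # probe directions normalized to unit tensor sum-of-squares so the EV
    # split between factors is w_time^2 : w_stim^2
    time_dir <- outer(rep(1, 7), ramp) / sqrt(7)
    stim_dir <- outer(amp, rep(1, n_b)) / sqrt(sum(amp^2) * n_b)
    vals[1, , ] <- w_time * time_dir + w_stim * stim_dir
    tz <- sdf_tensor(vals, g$durations, zscored = TRUE)
    demixed_pca(tz, n_time_pcs = 3, n_stim_pcs = 1)
  })
}

test_that("reconstruction EV is exact for pure and mixed units", {
  d <- planted_decomp(w_time = 1, w_stim = 0)
  expect_equal(reconstruct_unit(d, 1, c("PC1"))$ev, 100, tolerance = 0.5)
  expect_equal(reconstruct_unit(d, 1, character(0))$ev, 0)
  # 60/40 split of variance between orthogonal factors
  d2 <- planted_decomp(w_time = sqrt(0.6), w_stim = sqrt(0.4), seed = 32)
  expect_equal(reconstruct_unit(d2, 1, "PC1")$ev, 60, tolerance = 2)
  expect_equal(reconstruct_unit(d2, 1, c("PC1", "stimPC1"))$ev, 100,
               tolerance = 2)
})

test_that("angle rule includes components above the 22.5 degree ratio", {
  # the time score of the probe is w_time / sqrt(7) because time components
  # are replicated over the 7 stimuli; choose weights by target score ratio
  d <- planted_decomp(w_time = sqrt(7), w_stim = 1, seed = 33)
  a <- assign_category(d, 1, phase = "measurement", ev_threshold = 6)
  # equal scores -> 45 degrees -> both contribute
  expect_equal(unname(abs(a$scores["PC1"] / a$scores["stimPC1"])), 1,
               tolerance = 0.05)
  expect_setequal(a$category, c("PC1", "stimPC1"))
  # ratio 0.2 -> 11.3 degrees -> strongest only
  d2 <- planted_decomp(w_time = sqrt(7), w_stim = 0.2, seed = 34)
  a2 <- assign_category(d2, 1, phase = "measurement", ev_threshold = 6)
  expect_identical(a2$category, "PC1")
  # ratio 0.5 is above tan(22.5 deg) ~ 0.414 -> both contribute
  d3 <- planted_decomp(w_time = sqrt(7), w_stim = 0.5, seed = 35)
  a3 <- assign_category(d3, 1, phase = "measurement", ev_threshold = 6)
  expect_setequal(a3$category, c("PC1", "stimPC1"))
  # EV below threshold -> unrelated regardless of scores
  a4 <- assign_category(d, 1, phase = "measurement", ev_threshold = 101)
  expect_identical(a4$label, "unrelated")
})

test_that("category count is the power-set size", {
  expect_equal(category_space_size(2), 4)
  expect_equal(category_space_size(4), 16)
  expect_equal(category_space_size(0), 1)
  expect_error(category_space_size(-1), "non-negative")
})

test_that("raising the EV threshold never rescues a unit from unrelated", {
  pl <- planted_two_factor(n_units = 25, noise_sd = 0.3, seed = 36)
  d <- demixed_pca(pl$sdf)
  thresholds <- c(2, 10, 30, 60, 90)
  unrelated <- vapply(thresholds, function(th) {
    sum(categorize_units(d, "measurement", ev_threshold = th)$label ==
          "unrelated")
  }, 1L)
  expect_true(all(diff(unrelated) >= 0))
})

test_that("categories are invariant to global component sign flips", {
  pl <- planted_two_factor(n_units = 30, noise_sd = 0.05, seed = 37)
  d <- demixed_pca(pl$sdf)
  d_flip <- d
  d_flip$time_components[1, ] <- -d_flip$time_components[1, ]
  d_flip$time_scores[, 1] <- -d_flip$time_scores[, 1]
  a <- categorize_units(d, "measurement")
  b <- categorize_units(d_flip, "measurement")
  expect_identical(a$label, b$label)
})

test_that("planted single-type populations are categorized correctly at high SNR", {
  # linear-increasing-like: ramp loading only
  withr::with_seed(38, {
    g <- stimulus_grid()
    n_b <- 40
    ramp <- seq(-1, 1, length.out = n_b) / sqrt(n_b)
    vals <- array(0, c(40, 7, n_b))
    for (u in 1:40) {
      vals[u, , ] <- stats::runif(1, 0.5, 2) * outer(rep(1, 7), ramp) +
        stats::rnorm(7 * n_b, 0, 0.01)
    }
    tz <- sdf_tensor(vals, g$durations, zscored = TRUE)
    d <- demixed_pca(tz)
    cats <- categorize_units(d, "measurement")
    expect_gte(mean(cats$label == "PC1"), 0.95)
  })
})

test_that("categorization accuracy degrades gracefully along an SNR ladder", {
  acc <- vapply(c(0.02, 0.3, 1.5), function(noise) {
    pl <- planted_two_factor(n_units = 40, noise_sd = noise, seed = 39)
    d <- demixed_pca(pl$sdf)
    cats <- categorize_units(d, "measurement", ev_threshold = 6)
    mean(cats$label != "unrelated")
  }, 1.0)
  expect_true(all(diff(acc) <= 0.05))  # non-increasing up to small wiggle
  expect_gt(acc[1], 0.9)
})

test_that("chance category counts flag a ramp-heavy population", {
  # 20 units with a consistent ramp loading across stimuli + 20 noise units;
  # shuffling traces across stimuli and cells dilutes the per-cell loadings,
  # so the PC1-only category is enriched in the data
  withr::with_seed(40, {
    g <- stimulus_grid(); n_b <- 40
    ramp <- seq(-1, 1, length.out = n_b)
    vals <- array(stats::rnorm(40 * 7 * n_b, 0, 0.7), c(40, 7, n_b))
    for (u in 1:20) {
      a <- stats::runif(1, 1, 2) * sample(c(-1, 1), 1)
      vals[u, , ] <- a * outer(rep(1, 7), ramp) +
        stats::rnorm(7 * n_b, 0, 0.1)
    }
    tz <- sdf_tensor(vals, g$durations, zscored = TRUE)
    cc <- chance_category_counts(tz, phase = "measurement", runs = 150,
                                 seed = 4)
    expect_true(all(cc$p >= 0 & cc$p <= 1))
    expect_equal(sum(cc$observed), 40)
    pc1 <- cc[cc$label == "PC1", ]
    expect_gt(pc1$observed, pc1$surrogate_mean)
    expect_lt(pc1$p, 0.05)
    expect_identical(pc1$direction, ">")
  })
})

test_that("transition tables conserve units and compute activity shares", {
  pl <- planted_two_factor(n_units = 20, noise_sd = 0.05, seed = 41)
  d <- demixed_pca(pl$sdf)
  am <- categorize_units(d, "measurement")
  ar <- categorize_units(d, "reproduction")
  tt <- transition_table(am, ar)
  expect_equal(sum(tt$table), 20)
  expect_equal(sum(tt$activity_shares), 1)
  # all-unrelated edge case
  am0 <- am; am0$label <- "unrelated"
  ar0 <- ar; ar0$label <- "unrelated"
  tt0 <- transition_table(am0, ar0)
  expect_equal(unname(tt0$activity_shares["neither"]), 1)
  expect_equal(sum(tt0$table != 0), 1)
  expect_error(transition_table(am[1:10, ], ar), "same units")
})
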