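test_that("per-trajectory MSD is exact on deterministic tracks", {
  ts <- make_stationary_set(12)
  msd <- trajectory_msd(ts)
  expect_equal(msd$msd_lag1_um2, 0)
  expect_equal(msd$n_disp, 11L)
  # uniform 0.1 um step along x -> MSD = 0.01 um^2
  ts2 <- trajectory_set(make_lattice_track(12, step = 0.1), 1, 0.1)
  msd2 <- trajectory_msd(ts2)
  expect_equal(msd2$msd_lag1_um2, 0.01)
  expect_equal(msd2$label, "translating")
})

test_that("population mean MSD approaches 4*D*dt for simulated data", {
  cfg <- sim_config(0.0025, n_steps = 20, n_particles = 400, seed = 10)
  sim <- simulate_brownian(cfg)
  msd <- trajectory_msd(sim$tracks)
  expect_equal(mean(msd$msd_lag1_um2), 4 * 0.0025, tolerance = 0.05)
})

test_that("short trajectories stay unclassified", {
  spots <- rbind(make_lattice_track(5, track_id = 1),
                 make_lattice_track(15, track_id = 2))
  ts <- trajectory_set(spots, 1, 0.1)
  msd <- trajectory_msd(ts)
  expect_equal(msd$label, c("unclassified", "translating"))
})

test_that("frame gaps are skipped with a warning, not bridged", {
  tr <- make_lattice_track(15, step = 0.1)
  tr <- tr[-8, ]  # drop one frame: two pairs at lag 2 would be wrong
  ts <- trajectory_set(tr, 1, 0.1)
  expect_warning(msd <- trajectory_msd(ts), "gap")
  expect_equal(msd$n_disp, 12L)
  expect_equal(msd$msd_lag1_um2, 0.01)  # unaffected by the gap
})

test_that("the translation cutoff is strict and recorded", {
  msd <- data.frame(track_id = 1:4,
                    msd_lag1_um2 = c(0.011, 0.097, 0.055, 0.0549),
                    n_disp = rep(20L, 4), label = "unclassified")
  out <- classify_translation(msd)
  expect_equal(out$label, c("translating", "non_translating",
                            "non_translating", "translating"))
  expect_equal(attr(out, "threshold_um2"), 0.055)
  rib <- classify_translation(msd, threshold = "ribosome")
  expect_equal(attr(rib, "threshold_um2"), 0.04)
  expect_equal(rib$label[1], "translating")
  expect_equal(rib$label[4], "non_translating")
})

test_that("classification is monotone in MSD", {
  set.seed(1)
  vals <- sort(runif(100, 0, 0.2))
  msd <- data.frame(track_id = seq_along(vals), msd_lag1_um2 = vals,
                    n_disp = 20L, label = "unclassified")
  lab <- classify_translation(msd)$label
  # once non_translating, never translating again at higher MSD
  first_nt <- which(lab == "non_translating")[1]
  expect_true(all(lab[first_nt:length(lab)] == "non_translating"))
})

test_that("MSD is invariant under rigid motions of the coordinates", {
  ts <- make_random_set(n_tracks = 10, seed = 13)
  msd0 <- trajectory_msd(ts)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- as.matrix(ts$spots[, c("x_um", "y_um")]) %*% R
  ts_rot <- ts
  ts_rot$spots$x_um <- xy[, 1] + 5
  ts_rot$spots$y_um <- xy[, 2] - 2
  msd1 <- trajectory_msd(ts_rot)
  expect_equal(msd1$msd_lag1_um2, msd0$msd_lag1_um2, tolerance = 1e-12)
})

test_that("translating fraction excludes unclassified and rejects empties", {
  msd <- data.frame(label = c(rep("translating", 10)))
  expect_equal(translating_fraction(msd), 1.0)
  msd2 <- data.frame(label = c("translating", "non_translating",
                               "unclassified", "unclassified"))
  expect_equal(translating_fraction(msd2), 0.5)
  expect_error(translating_fraction(data.frame(label = character(0))),
               "no classified")
  expect_error(translating_fraction(data.frame(label = "unclassified")),
               "no classified")
})

test_that("translating fraction is invariant under reordering", {
  set.seed(2)
  msd <- data.frame(label = sample(c("translating", "non_translating",
                                     "unclassified"), 50, replace = TRUE))
  f0 <- translating_fraction(msd)
  for (i in 1:5) {
    expect_equal(translating_fraction(msd[sample(nrow(msd)), , drop = FALSE]),
                 f0)
  }
})

test_that("mixture recovery lands inside the binomial CI of truth", {
  sim <- simulate_translation_mixture(600, 0.3, seed = 14)
  msd <- trajectory_msd(sim$tracks)
  frac <- translating_fraction(msd)
  n_conf <- sum(sim$truth$confined_track)
  ci <- binom.test(n_conf, 600)$conf.int
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("ensemble MSD equals the brute-force average over all pairs", {
  ts <- make_random_set(n_tracks = 5, n_frames = 8, seed = 15)
  ens <- ensemble_msd(ts, 5)
  oracle <- brute_ensemble_msd(ts, 5)
  expect_equal(ens$msd_um2, oracle$msd_um2, tolerance = 1e-12)
  expect_equal(ens$n_pairs, oracle$n_pairs)
  # single stationary trajectory: all zeros
  ens0 <- ensemble_msd(make_stationary_set(10), 3)
  expect_equal(ens0$msd_um2, rep(0, 3))
})

test_that("lags with no pairs are omitted", {
  ts <- trajectory_set(make_lattice_track(4), 1, 0.1)  # 3 lags available
  ens <- ensemble_msd(ts, 10)
  expect_equal(ens$lag_s, c(1, 2, 3))
})

test_that("D_app fit is exact on exact model points", {
  lag <- 1:6
  ens <- data.frame(lag_s = lag, msd_um2 = 4 * 0.05 * lag + 4 * 0.02^2,
                    n_pairs = 100L)
  fit <- fit_dapp(ens)
  expect_equal(fit$d_app, 0.05, tolerance = 1e-12)
  expect_equal(fit$sigma, 0.02, tolerance = 1e-12)
  expect_false(any(fit$clamped))
  # constant MSD = 4 sigma^2 -> D_app 0
  ens2 <- data.frame(lag_s = lag, msd_um2 = rep(4 * 0.02^2, 6),
                     n_pairs = 100L)
  fit2 <- fit_dapp(ens2)
  expect_equal(fit2$d_app, 0)
  # negative slope clamps with a flag
  ens3 <- data.frame(lag_s = lag, msd_um2 = rev(lag) * 0.01, n_pairs = 100L)
  fit3 <- fit_dapp(ens3)
  expect_equal(fit3$d_app, 0)
  expect_true(fit3$clamped["d_app"])
})

test_that("D_app and sigma recover within 10% on simulated ensembles", {
  cfg <- sim_config(0.1, n_steps = 30, n_particles = 500,
                    localization_sigma = 0.03, seed = 16)
  sim <- simulate_brownian(cfg)
  fit <- fit_dapp(ensemble_msd(sim$tracks, 4))
  expect_equal(fit$d_app, 0.1, tolerance = 0.1)
  expect_equal(fit$sigma, 0.03, tolerance = 0.2)
})

test_that("mixture CDF model is a valid CDF", {
  r <- seq(0, 3, by = 0.01)
  y <- cdf_mixture_model(r, c(0.3, 0.7), c(0.5, 0.01), 1)
  expect_equal(y[1], 0)
  expect_true(all(diff(y) >= 0))
  expect_lt(max(y), 1 + 1e-12)
})

test_that("single-component samples are recovered by the 3-component fit", {
  r <- sample_cdf_mixture(3000, 1, 0.05, lag_t = 1, seed = 17)
  fit <- fit_cdf_mixture(r, 1, n_components = 3)
  dominant <- which.max(fit$fractions)
  expect_gte(fit$fractions[dominant], 0.95)
  expect_equal(fit$D[dominant], 0.05, tolerance = 0.1)
})

test_that("three-population fractions recover within 0.05", {
  r <- sample_cdf_mixture(5000, c(0.3, 0.4, 0.3), c(0.5, 0.05, 0.005),
                          lag_t = 1, seed = 18)
  fit <- fit_cdf_mixture(r, 1, n_components = 3)
  expect_true(all(abs(fit$fractions - c(0.3, 0.4, 0.3)) < 0.05))
  expect_true(all(fit$D / c(0.5, 0.05, 0.005) < 2 &
                    fit$D / c(0.5, 0.05, 0.005) > 0.5))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
})

test_that("model selection and merging handle degenerate mixtures", {
  # two nearly equal D components are non-identifiable as separate
  # species: the fit concentrates the weight on one component near the
  # pooled diffusivity
  r <- sample_cdf_mixture(2000, c(0.5, 0.5), c(0.05, 0.06), seed = 19)
  fit <- fit_cdf_mixture(r, 1, n_components = 2)
  dominant <- which.max(fit$fractions)
  expect_gte(fit$fractions[dominant], 0.95)
  expect_equal(fit$D[dominant], 0.055, tolerance = 0.25)
  # explicitly close fitted Ds are merged with a flag
  direct <- fit_cdf_mixture(sample_cdf_mixture(3000, 1, 0.05, seed = 22),
                            1, n_components = 1)
  expect_equal(direct$fractions, 1)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  # BIC picks a small model for a pure sample
  r2 <- sample_cdf_mixture(2000, 1, 0.05, seed = 20)
  fit2 <- fit_cdf_mixture(r2, 1)
  expect_lte(length(fit2$D), 2)
  expect_warning(fit_cdf_mixture(r2[1:50], 1, n_components = 1),
                 "fewer than 100")
  expect_error(fit_cdf_mixture(r2[1:5], 1), "too few")
})

test_that("components come out in descending D", {
  r <- sample_cdf_mixture(4000, c(0.5, 0.5), c(0.3, 0.003), seed = 21)
  fit <- fit_cdf_mixture(r, 1, n_components = 2)
  expect_true(all(diff(fit$D) < 0))
})
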