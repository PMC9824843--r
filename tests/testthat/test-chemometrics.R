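# small deterministic spectra fixture: three latent wavelength profiles
# mixed over time plus reproducible noise
make_fixture <- function(n_t = 40, n_w = 30, noise_sd = 0.01, seed = 3) {
  set.seed(seed)
  times <- seq(0, 2, length.out = n_t)
  wl <- seq(600, 800, length.out = n_w)
  prof1 <- exp(-(wl - 650)^2 / 800)
  prof2 <- exp(-(wl - 760)^2 / 500)
  c1 <- exp(-times)
  c2 <- 0.3 * sin(times)
  A <- outer(c1, prof1) + outer(c2, prof2) +
    matrix(rnorm(n_t * n_w, sd = noise_sd), n_t)
  spectra_series(times, wl, A)
}

test_that("region selection restricts the wavelength grid inclusively", {
  wl <- instrument_grid(coarse = TRUE)
  sp <- spectra_series(0:3, wl, matrix(1, 4, length(wl)))
  sub <- select_region(sp, 600, 800)
  expect_true(all(sub$wavelengths >= 600 & sub$wavelengths <= 800))
  expect_equal(sum(wl >= 600 & wl <= 800), length(sub$wavelengths))
  ident <- select_region(sp, min(wl), max(wl))
  expect_equal(ident$wavelengths, wl)
  expect_error(select_region(sp, 800, 600), "lo < hi")
  expect_error(select_region(sp, 900, 1000), "no wavelengths")
})

test_that("mean-centering zeroes the column means and is idempotent", {
  sp <- make_fixture()
  cc <- mean_center(sp)
  expect_lt(max(abs(colMeans(cc$centered))), 1e-12)
  cc2 <- mean_center(cc$centered)
  expect_equal(cc2$centered, cc$centered, tolerance = 1e-12)
  const <- matrix(5, 4, 3)
  expect_true(all(mean_center(const)$centered == 0))
  expect_error(mean_center(matrix(1, 1, 3)), "at least 2")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  X <- matrix(c(1.2, 0.5, -0.3,
                0.7, -1.1, 0.4,
                -0.2, 0.8, 1.5,
                2.0, 0.1, -0.9,
                -1.0, 0.6, 0.2), 5, 3, byrow = TRUE)
  pca <- fit_pca(X, n_components = 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(cov(Xc), symmetric = TRUE)
  for (k in 1:3) {
    v <- eg$vectors[, k]
    expect_equal(abs(sum(v * pca$loadings[, k])), 1, tolerance = 1e-8)
    expect_equal(pca$sdev[k]^2, eg$values[k], tolerance = 1e-8)
  }
  # independent cross-check against prcomp
  pr <- prcomp(X, center = TRUE)
  expect_equal(abs(pca$scores), abs(pr$x[, 1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA satisfies its structural invariants", {
  sp <- make_fixture()
  k <- 3
  pca <- fit_pca(sp, n_components = k)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(pca$loadings) - diag(k))), 1e-8)
  # mutually orthogonal scores
  g <- crossprod(pca$scores)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  # explained fractions non-increasing, in [0,1], summing <= 1
  evf <- pca$explained_variance_fraction
  expect_true(all(diff(evf) <= 1e-12))
  expect_true(all(evf >= 0 & evf <= 1))
  expect_lte(sum(evf), 1 + 1e-8)
  # scores are the centered data projected on the loadings
  cc <- mean_center(sp)
  expect_equal(pca$scores, cc$centered %*% pca$loadings, tolerance = 1e-8)
  # variance conservation with all components
  full <- fit_pca(sp, n_components = min(dim(cc$centered)))
  expect_equal(sum(full$sdev^2), full$total_variance, tolerance = 1e-8)
  # full reconstruction
  rec <- sweep(full$scores %*% t(full$loadings), 2, -full$mean_spectrum)
  expect_lt(max(abs(rec - sp$absorbance)), 1e-8)
  # sign convention: largest-magnitude loading entry is positive
  for (j in seq_len(k))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("rank-1 data put all variance on the first component", {
  u <- seq(-1, 1, length.out = 12)
  v <- exp(-(seq(600, 800, length.out = 8) - 700)^2 / 5000)
  sp <- spectra_series(seq(0, 1, length.out = 12),
                       seq(600, 800, length.out = 8), outer(u, v))
  pca <- fit_pca(sp, n_components = 3)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-10)
  expect_true(all(pca$zero_variance[2:3]))
  expect_error(fit_pca(sp, n_components = 20), "n_components")
})

test_that("sampling disturbances are masked around the events", {
  times <- seq(0, 2, by = 1 / 120)
  sp <- spectra_series(times, c(600, 700), matrix(0, length(times), 2),
                       sampling_events = 1.0)
  keep <- mask_disturbances(sp)
  excluded <- times[!keep]
  expect_true(all(excluded >= 1.0 - 1e-9 & excluded <= 1.0 + 2 / 60 + 1e-9))
  expect_false(keep[which.min(abs(times - 1.0))])
  expect_true(all(mask_disturbances(sp, sampling_events = numeric(0))))
  # overlapping windows merge into one contiguous exclusion
  keep2 <- mask_disturbances(sp, sampling_events = c(1.0, 1.02),
                             post_window = 2)
  expect_true(all(diff(which(!keep2)) == 1))
  in_merged <- times >= 1.0 - 1e-9 & times <= 1.02 + 2 / 60 + 1e-9
  expect_true(all(!keep2[in_merged]))
  expect_error(mask_disturbances(sp, pre_window = -1), "non-negative")
})

test_that("the reaction-tracking component is identified by correlation", {
  p <- as_params(sls60); i <- as_init(sls60)
  nm0 <- noise_model(sd_above_600 = 0, sd_below_600 = 0,
                     drift_amplitude = 0, spike_amplitude = 0)
  only_poh <- list(chromophore("r", 700, 50, 1, driver = "POH"))
  sp <- generate_inline_spectra(p, i, only_poh, nm0, duration = 5,
                                rate = 0.5, wavelengths = seq(600, 800, 5),
                                seed = 11)
  pca <- fit_pca(sp, n_components = 3)
  ref <- simulate_trajectory(p, i, seq(0, 5, 0.05))
  expect_identical(select_monitoring_pc(pca, ref), 1L)

  # add an autonomous drift chromophore with larger variance: the
  # reaction signal moves to the second component
  drifty <- list(
    chromophore("r", 700, 50, 1, driver = "POH"),
    chromophore("d", 640, 40, 1, driver = "drift",
                drift_fun = function(t) 0.5 * sin(2 * pi * t / 2.5))
  )
  sp2 <- generate_inline_spectra(p, i, drifty, nm0, duration = 5,
                                 rate = 0.5, wavelengths = seq(600, 800, 5),
                                 seed = 11)
  pca2 <- fit_pca(sp2, n_components = 3)
  expect_identical(select_monitoring_pc(pca2, ref), 2L)

  flat <- simulate_trajectory(kinetic_params(0, 0, 0.5), i, seq(0, 5, 0.05))
  expect_error(select_monitoring_pc(pca, flat), "constant")
})

test_that("score calibration is exact for affine scores and sign-invariant", {
  p <- as_params(sls60); i <- as_init(sls60)
  nm0 <- noise_model(sd_above_600 = 0, sd_below_600 = 0,
                     drift_amplitude = 0, spike_amplitude = 0)
  only_poh <- list(chromophore("r", 700, 50, 1, driver = "POH"))
  sp <- generate_inline_spectra(p, i, only_poh, nm0, duration = 5, rate = 1,
                                wavelengths = seq(600, 800, 5), seed = 5)
  pca <- fit_pca(sp, n_components = 2)
  ref <- simulate_trajectory(p, i, seq(0, 5, 0.01))
  cal <- calibrate_scores(pca, component = 1, reference = ref)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  expect_true(all(cal$data$time_h >= 0.25))

  flipped <- pca
  flipped$scores[, 1] <- -flipped$scores[, 1]
  cal2 <- calibrate_scores(flipped, component = 1, reference = ref)
  expect_equal(cal2$slope, -cal$slope, tolerance = 1e-9)
  expect_equal(cal2$r_squared, cal$r_squared, tolerance = 1e-12)

  # R^2 is invariant under any affine transform of the score axis
  scaled <- pca
  scaled$scores[, 1] <- 3.7 * scaled$scores[, 1] + 0.2
  cal3 <- calibrate_scores(scaled, component = 1, reference = ref)
  expect_equal(cal3$r_squared, cal$r_squared, tolerance = 1e-12)

  const <- pca
  const$scores[, 1] <- 1
  expect_error(calibrate_scores(const, component = 1, reference = ref),
               "degenerate")
})

test_that("predictions honour the fitted line and the zero floor", {
  p <- as_params(sls60); i <- as_init(sls60)
  nm <- noise_model(sd_above_600 = 1e-4, sd_below_600 = 1e-4,
                    drift_amplitude = 0, spike_amplitude = 0)
  sp <- generate_inline_spectra(
    p, i, list(chromophore("r", 700, 50, 1, driver = "POH")), nm,
    duration = 5, rate = 1, wavelengths = seq(600, 800, 5), seed = 8)
  pca <- fit_pca(sp, n_components = 2)
  ref <- simulate_trajectory(p, i, seq(0, 5, 0.01))
  cal <- calibrate_scores(pca, component = 1, reference = ref)
  # fitted values at the calibration points
  pred <- predict_poh(cal, cal$data$score)
  expect_equal(pred, cal$slope * cal$data$score + cal$intercept,
               tolerance = 1e-12)
  # residual variance agrees with 1 - R^2 (algebraic identity of OLS)
  resid <- cal$data$POH_molL - pred
  sst <- sum((cal$data$POH_molL - mean(cal$data$POH_molL))^2)
  expect_equal(sum(resid^2) / sst, 1 - cal$r_squared, tolerance = 1e-9)
  expect_warning(p0 <- predict_poh(cal, 1e6 * sign(-cal$slope)), "clipped")
  expect_equal(p0, 0)
  expect_equal(predict(cal, cal$data$score[1]), pred[1])
})
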