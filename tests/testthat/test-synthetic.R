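test_that("in-line generator produces the instrument geometry", {
  sp <- generate_inline_spectra(as_params(sls60), as_init(sls60),
                                noise = noise_model(), seed = 1)
  # two acquisitions per minute over 5 h, 342-825 nm at 0.24 nm
  expect_equal(length(sp$times), 601L)
  expect_equal(length(sp$wavelengths), 2013L)
  expect_equal(dim(sp$absorbance), c(601L, 2013L))
  expect_equal(sp$wavelengths[1], 342)
  expect_equal(diff(sp$wavelengths)[1], 0.24)
  expect_lte(max(sp$wavelengths), 825)
  expect_equal(sp$sampling_events, 0:5)
})

test_that("generation is bit-reproducible under the seed contract", {
  a <- generate_inline_spectra(as_params(sls60), as_init(sls60),
                               wavelengths = instrument_grid(TRUE), seed = 9)
  b <- generate_inline_spectra(as_params(sls60), as_init(sls60),
                               wavelengths = instrument_grid(TRUE), seed = 9)
  c <- generate_inline_spectra(as_params(sls60), as_init(sls60),
                               wavelengths = instrument_grid(TRUE), seed = 10)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c$absorbance))
  expect_error(generate_inline_spectra(as_params(sls60), as_init(sls60),
                                       seed = NULL), "seed")
})

test_that("noise-free absorbance is linear in the chromophore amplitudes", {
  nm0 <- noise_model(sd_above_600 = 0, sd_below_600 = 0,
                     drift_amplitude = 0, spike_amplitude = 0)
  ch1 <- list(chromophore("r", 700, 50, 1.0, driver = "POH"),
              chromophore("p", 480, 80, 0.7, driver = "x"))
  ch2 <- list(chromophore("r", 700, 50, 2.0, driver = "POH"),
              chromophore("p", 480, 80, 1.4, driver = "x"))
  wl <- instrument_grid(TRUE)
  a <- generate_inline_spectra(as_params(sls60), as_init(sls60), ch1, nm0,
                               rate = 0.5, wavelengths = wl, seed = 2)
  b <- generate_inline_spectra(as_params(sls60), as_init(sls60), ch2, nm0,
                               rate = 0.5, wavelengths = wl, seed = 2)
  expect_equal(b$absorbance, 2 * a$absorbance, tolerance = 1e-12)
})

test_that("sampling spikes appear only inside the event windows", {
  nm <- noise_model(sd_above_600 = 0, sd_below_600 = 0,
                    drift_amplitude = 0, spike_amplitude = 0.05,
                    spike_duration_min = 2)
  ch <- list(chromophore("r", 700, 50, 1, driver = "POH"))
  wl <- seq(600, 800, 10)
  sp <- generate_inline_spectra(as_params(sls60), as_init(sls60), ch, nm,
                                rate = 2, wavelengths = wl, seed = 3)
  clean <- generate_inline_spectra(as_params(sls60), as_init(sls60), ch,
                                   noise_model(0, 0, 0, 8, 0, 2), rate = 2,
                                   wavelengths = wl, seed = 3)
  d <- sp$absorbance - clean$absorbance
  hit <- rowSums(abs(d)) > 0
  in_window <- Reduce(`|`, lapply(0:5, function(e)
    sp$times >= e & sp$times <= e + 2 / 60))
  expect_identical(hit, in_window)
  expect_equal(max(d), 0.05)
})

test_that("off-line generator reproduces the trajectory when clean", {
  tr <- simulate_trajectory(as_params(sls60), as_init(sls60), 0:5)
  nm0 <- noise_model(offline_sd = 0, offline_delay_h = 0)
  obs <- generate_offline_series(tr, noise = nm0, seed = 1, replicates = 1)
  expect_equal(obs$time_h, 0:5)
  expect_equal(obs$F_molL, tr$F_molL, tolerance = 1e-12)
  expect_equal(obs$POH_molL, tr$POH_molL, tolerance = 1e-12)
  # duplicate sampling doubles the rows at each nominal time
  obs2 <- generate_offline_series(tr, noise = nm0, seed = 1)
  expect_equal(nrow(obs2), 12L)
  expect_equal(obs2$time_h, rep(0:5, each = 2))
})

test_that("analysis delay reports the later true concentration", {
  tr <- simulate_trajectory(as_params(sls60), as_init(sls60),
                            seq(0, 6, 0.01))
  nm <- noise_model(offline_sd = 0, offline_delay_h = 0.25)
  obs <- generate_offline_series(tr, times = 0:5, noise = nm, seed = 1,
                                 replicates = 1)
  truth <- simulate_trajectory(as_params(sls60), as_init(sls60),
                               sort(unique(c(0, 0:5 + 0.25))))
  at <- match(0:5 + 0.25, truth$time_h)
  expect_equal(obs$POH_molL, truth$POH_molL[at], tolerance = 1e-10)
  expect_equal(obs$F_molL, truth$F_molL[at], tolerance = 1e-10)
})

test_that("noiseless off-line output closes the fitting loop", {
  for (s in list(sls60, hls50)) {
    tr <- simulate_trajectory(as_params(s), as_init(s), 0:5)
    obs <- generate_offline_series(
      tr, noise = noise_model(offline_sd = 0, offline_delay_h = 0), seed = 1)
    model <- if (s$k2 > 0) "with_secondary" else "single"
    k <- coef(fit_kinetics(obs, as_init(s), model = model))
    expect_equal(k[["k1"]], s$k1, tolerance = 0.01)
    expect_equal(k[["f_nonreactive"]], s$f, tolerance = 0.015)
  }
})

test_that("zero phenolic content leaves the alkaline spectra unchanged", {
  sp <- generate_ionization_spectra(list(oh_I_II = 0, oh_total = 0))
  expect_equal(sp$pH12$absorbance, sp$pH6$absorbance, tolerance = 1e-14)
  expect_equal(sp$NaOH$absorbance, sp$pH6$absorbance, tolerance = 1e-14)
})

test_that("ionization bands sit at 300 and 360 nm within a grid step", {
  sp <- generate_ionization_spectra(list(oh_I_II = 1.76, oh_total = 2.69))
  d <- ionization_difference(sp$pH12, sp$pH6, sp$mass_conc, sp$path)
  expect_lte(abs(d$maxima$wavelength_nm[1] - 300), 0.5)
  expect_lte(abs(d$maxima$wavelength_nm[2] - 360), 0.5)
})

test_that("the full monitoring pipeline tracks the latent decay", {
  # default chromophores and stated noise model, coarse grid
  p <- as_params(sls60); i <- as_init(sls60)
  sp <- generate_inline_spectra(p, i, wavelengths = instrument_grid(TRUE),
                                seed = 14)
  reg <- select_region(sp)
  pca <- fit_pca(reg, n_components = 3)
  keep <- mask_disturbances(reg) & reg$times >= 0.25
  truth <- simulate_trajectory(p, i, seq(0, 5, 0.01))
  pc <- select_monitoring_pc(pca, truth, mask = keep)
  ref_poh <- approx(truth$time_h, truth$POH_molL, reg$times[keep])$y
  expect_gte(abs(cor(pca$scores[keep, pc], ref_poh)), 0.97)
})
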