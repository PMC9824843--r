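#' Latent chromophore description for spectrum synthesis
#'
#' A chromophore is a non-negative extinction profile over the wavelength
#' grid (a mixture of Gaussian bands) together with a concentration
#' driver: tied to the total phenolic hydroxyl concentration (`"POH"`),
#' to the reaction extent (`"x"`), or to an autonomous function of time
#' (`"drift"`).
#'
#' @param name Label.
#' @param centers,widths,amplitudes Gaussian band parameters: centers and
#'   standard-deviation widths in nm, amplitudes in L mol^-1 cm^-1 (for
#'   concentration drivers) or AU (for drift drivers).
#' @param driver One of `"POH"`, `"x"`, `"drift"`.
#' @param drift_fun For `driver = "drift"`: function of time (hours)
#'   returning the driver value; default a slow linear ramp.
#' @return An object of class `"chromophore"`.
#' @export
chromophore <- function(name, centers, widths, amplitudes,
                        driver = c("POH", "x", "drift"),
                        drift_fun = NULL) {
  driver <- match.arg(driver)
  if (length(centers) != length(widths) ||
      length(centers) != length(amplitudes))
    stop("'centers', 'widths', 'amplitudes' must have equal length",
         call. = FALSE)
  if (any(widths <= 0) || any(amplitudes < 0))
    stop("widths must be positive, amplitudes non-negative", call. = FALSE)
  if (driver == "drift" && is.null(drift_fun))
    drift_fun <- function(t) 1 + 0.01 * t
  structure(list(name = name, centers = centers, widths = widths,
                 amplitudes = amplitudes, driver = driver,
                 drift_fun = drift_fun),
            class = "chromophore")
}

# evaluate a chromophore's extinction profile on a wavelength grid
chromophore_profile <- function(ch, wavelengths) {
  prof <- numeric(length(wavelengths))
  for (j in seq_along(ch$centers))
    prof <- prof + ch$amplitudes[j] *
      exp(-(wavelengths - ch$centers[j])^2 / (2 * ch$widths[j]^2))
  prof
}

#' Default latent chromophore set
#'
#' Three components, a deliberately neutral model of what could plausibly
#' produce the visible-range signal (no chemical identification is
#' claimed): a reactant-linked band in the 600-800 nm monitoring region
#' driven by [POH], a product-linked band at shorter wavelengths driven
#' by the reaction extent, and a slowly drifting medium component.
#'
#' @return List of [chromophore()] objects.
#' @export
default_chromophores <- function() {
  list(
    chromophore("reactant", centers = 680, widths = 60, amplitudes = 2.0,
                driver = "POH"),
    chromophore("product", centers = 480, widths = 80, amplitudes = 1.5,
                driver = "x"),
    chromophore("medium", centers = 420, widths = 120, amplitudes = 0.3,
                driver = "drift")
  )
}

#' Noise and disturbance model for synthetic data
#'
#' Captures the statistical structure the monitoring analysis has to cope
#' with: wavelength-dependent iid noise (markedly higher below 600 nm),
#' a slow flat baseline drift, transient spikes when off-line samples are
#' withdrawn, and measurement error plus analysis delay on the off-line
#' assays (the assay takes about 15 min, during which the sampled aliquot
#' keeps reacting slowly).
#'
#' @param sd_above_600,sd_below_600 iid absorbance noise sd, AU.
#' @param drift_amplitude,drift_period_h Baseline sinusoid, AU and hours.
#' @param spike_amplitude Spike height at sampling events, AU.
#' @param spike_duration_min Spike duration, minutes.
#' @param offline_sd Off-line concentration measurement sd, mol/L.
#' @param offline_delay_h Off-line analysis delay, hours.
#' @param seed Default integer seed for the generators.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd_above_600 = 0.002, sd_below_600 = 0.02,
                        drift_amplitude = 0.005, drift_period_h = 8,
                        spike_amplitude = 0.05, spike_duration_min = 2,
                        offline_sd = 0.005, offline_delay_h = 0.25,
                        seed = NULL) {
  v <- c(sd_above_600, sd_below_600, drift_amplitude, drift_period_h,
         spike_amplitude, spike_duration_min, offline_sd, offline_delay_h)
  if (any(!is.finite(v)) || any(v < 0))
    stop("noise model parameters must be finite and non-negative",
         call. = FALSE)
  structure(list(sd_above_600 = sd_above_600, sd_below_600 = sd_below_600,
                 drift_amplitude = drift_amplitude,
                 drift_period_h = drift_period_h,
                 spike_amplitude = spike_amplitude,
                 spike_duration_min = spike_duration_min,
                 offline_sd = offline_sd, offline_delay_h = offline_delay_h,
                 seed = seed),
            class = "noise_model")
}

#' Instrument wavelength grid
#'
#' The visible range 342-825 nm at the instrument resolution of 0.24 nm
#' (2013 points), or a 2.4 nm coarse grid (202 points) for fast runs.
#'
#' @param coarse Use the 10x coarser grid.
#' @return Numeric wavelength vector, nm.
#' @export
instrument_grid <- function(coarse = FALSE) {
  if (coarse) seq(342, by = 2.4, length.out = 202L)
  else seq(342, by = 0.24, length.out = 2013L)
}

#' Generate a synthetic in-line spectra time series
#'
#' Simulates the reaction trajectory and builds Beer-Lambert mixtures of
#' the latent chromophore profiles, then adds the baseline drift, the
#' sampling-event spikes and the wavelength-dependent iid noise of the
#' noise model:
#' `A(lambda, t) = sum_c eps_c(lambda) C_c(t) + baseline + spike + noise`.
#' At the default two acquisitions per minute over 5 h this yields 601
#' spectra (including t = 0).
#'
#' @param params A [kinetic_params()] object.
#' @param init An [initial_conditions()] object.
#' @param chromophores List of [chromophore()]s; default
#'   [default_chromophores()].
#' @param noise A [noise_model()].
#' @param duration Run length, hours.
#' @param rate Acquisitions per minute.
#' @param wavelengths Wavelength grid; default [instrument_grid()].
#' @param sampling_interval Off-line sampling interval (hours) generating
#'   the spike events; `NULL` for no events.
#' @param seed Integer seed; required (falls back to `noise$seed`).
#' @return A [spectra_series()] with `sampling_events` set.
#' @export
generate_inline_spectra <- function(params, init,
                                    chromophores = default_chromophores(),
                                    noise = noise_model(),
                                    duration = 5, rate = 2,
                                    wavelengths = instrument_grid(),
                                    sampling_interval = 1,
                                    seed = noise$seed) {
  if (is.null(seed))
    stop("a 'seed' is required for reproducible generation", call. = FALSE)
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = 1 / (rate * 60))
  traj <- simulate_trajectory(params, init, times)
  events <- if (is.null(sampling_interval)) numeric(0)
            else seq(0, duration, by = sampling_interval)

  A <- matrix(0, length(times), length(wavelengths))
  for (ch in chromophores) {
    conc <- switch(ch$driver,
                   POH = traj$POH_molL,
                   x = traj$x_molL,
                   drift = ch$drift_fun(times))
    A <- A + outer(conc, chromophore_profile(ch, wavelengths))
  }
  if (noise$drift_amplitude > 0)
    A <- A + noise$drift_amplitude *
      sin(2 * pi * times / noise$drift_period_h)
  if (noise$spike_amplitude > 0 && length(events))
    for (e in events) {
      hit <- times >= e & times <= e + noise$spike_duration_min / 60
      A[hit, ] <- A[hit, ] + noise$spike_amplitude
    }
  sds <- ifelse(wavelengths < 600, noise$sd_below_600, noise$sd_above_600)
  if (any(sds > 0))
    A <- A + matrix(stats::rnorm(length(A), sd = rep(sds, each = length(times))),
                    nrow = length(times))

  spectra_series(times, wavelengths, A, sampling_events = events)
}

#' Generate an off-line assay series from a trajectory
#'
#' Emulates the hourly off-line monitoring: concentrations are read from
#' the trajectory at `t + delay` (the sampled aliquot keeps reacting
#' slowly during the analysis), perturbed with iid Gaussian measurement
#' error, and clipped at zero. When the trajectory carries its kinetic
#' parameters the delayed values are re-simulated exactly rather than
#' interpolated.
#'
#' @param trajectory A `"reaction_trajectory"`.
#' @param interval Sampling interval, hours (default 1); ignored when
#'   `times` is given.
#' @param noise A [noise_model()]; `offline_sd` is the measurement sd.
#' @param delay Analysis delay, hours; default `noise$offline_delay_h`.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched
#'   (caller-managed).
#' @param times Explicit nominal sampling times, hours.
#' @param replicates Independent samples withdrawn at each nominal time;
#'   the default 2 mirrors the duplicate hourly sampling of the standard
#'   procedure.
#' @return Data frame (classes `"offline_series"`, `"data.frame"`) with
#'   columns `time_h`, `F_molL`, `POH_molL` (one row per sample, so
#'   `replicates` rows per nominal time).
#' @export
generate_offline_series <- function(trajectory, interval = 1,
                                    noise = noise_model(),
                                    delay = noise$offline_delay_h,
                                    seed = noise$seed, times = NULL,
                                    replicates = 2) {
  stopifnot(inherits(trajectory, "reaction_trajectory"))
  if (is.null(times))
    times <- seq(0, max(trajectory$time_h), by = interval)
  if (replicates < 1L)
    stop("'replicates' must be at least 1", call. = FALSE)
  times <- rep(times, each = as.integer(replicates))
  if (!is.null(seed)) set.seed(as.integer(seed))

  params <- attr(trajectory, "params")
  init <- attr(trajectory, "init")
  shifted <- times + delay
  if (!is.null(params) && !is.null(init)) {
    grid <- sort(unique(c(0, shifted)))
    tr2 <- simulate_trajectory(params, init, grid)
    i <- match(shifted, grid)
    Fv <- tr2$F_molL[i]
    Pv <- tr2$POH_molL[i]
  } else {
    if (max(shifted) > max(trajectory$time_h) + 1e-9)
      stop("trajectory does not cover the sampling times plus delay",
           call. = FALSE)
    Fv <- stats::approx(trajectory$time_h, trajectory$F_molL, shifted)$y
    Pv <- stats::approx(trajectory$time_h, trajectory$POH_molL, shifted)$y
  }
  if (noise$offline_sd > 0) {
    Fv <- Fv + stats::rnorm(length(Fv), sd = noise$offline_sd)
    Pv <- Pv + stats::rnorm(length(Pv), sd = noise$offline_sd)
  }
  out <- data.frame(time_h = times, F_molL = pmax(Fv, 0),
                    POH_molL = pmax(Pv, 0))
  class(out) <- c("offline_series", "data.frame")
  out
}

#' Generate a triple of UV ionization spectra
#'
#' Synthesises the pH 6 (reference), pH 12 and 0.2 M NaOH UV spectra of a
#' lignosulphonate solution whose phenolic hydroxyl contents are known.
#' The alkaline-minus-reference differences are two-Gaussian curves with
#' bands at 300 and 360 nm whose heights invert exactly through
#' [phenolic_oh_content()] with the same coefficient set, closing the
#' quantification loop. A common baseline absorbance (which cancels in
#' the difference) and optional iid noise are added.
#'
#' @param content A [phenolic_oh_content()]-like list with `oh_I_II` and
#'   `oh_total` (percent, dry LS basis).
#' @param coefficients The [zakis_coefficients()] set; must match the one
#'   used for quantification.
#' @param wavelengths Grid over 190-400 nm; the default 0.5 nm step puts
#'   the band centers exactly on the grid.
#' @param mass_conc Cuvette LS concentration, g/L (procedure value 0.08).
#' @param path Path length, cm.
#' @param band_width Gaussian band sd, nm.
#' @param noise_sd iid absorbance noise sd, AU.
#' @param seed Integer seed (needed only when `noise_sd > 0`).
#' @return List with elements `pH6`, `pH12`, `NaOH` (data frames with
#'   `wavelength_nm`, `absorbance`), plus `mass_conc` and `path`.
#' @export
generate_ionization_spectra <- function(content,
                                        coefficients = zakis_coefficients(),
                                        wavelengths = seq(190, 400, by = 0.5),
                                        mass_conc = 0.08, path = 1,
                                        band_width = 10, noise_sd = 0,
                                        seed = NULL) {
  if (is.null(content$oh_I_II) || is.null(content$oh_total))
    stop("'content' must carry 'oh_I_II' and 'oh_total'", call. = FALSE)
  stopifnot(inherits(coefficients, "zakis_coefficients"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  r <- coefficients$peak_ratio
  denom <- coefficients$a300 + r * coefficients$a360
  h300 <- c(pH12 = content$oh_I_II, NaOH = content$oh_total) / denom
  g300 <- exp(-(wavelengths - 300)^2 / (2 * band_width^2))
  g360 <- exp(-(wavelengths - 360)^2 / (2 * band_width^2))

  # baseline lignin UV absorptivity, common to all three solutions
  base_eps <- 60 * exp(-(wavelengths - 205)^2 / (2 * 20^2)) +
    15 * exp(-(wavelengths - 280)^2 / (2 * 12^2))
  ref <- mass_conc * path * base_eps

  mk <- function(h) {
    a <- ref + mass_conc * path * (h * g300 + r * h * g360)
    if (noise_sd > 0) a <- a + stats::rnorm(length(a), sd = noise_sd)
    data.frame(wavelength_nm = wavelengths, absorbance = a)
  }
  ref_df <- data.frame(wavelength_nm = wavelengths, absorbance =
                         if (noise_sd > 0)
                           ref + stats::rnorm(length(ref), sd = noise_sd)
                         else ref)
  list(pH6 = ref_df, pH12 = mk(h300[["pH12"]]), NaOH = mk(h300[["NaOH"]]),
       mass_conc = mass_conc, path = path)
}
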