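#' Time series of in-line visible spectra
#'
#' The data matrix of the monitoring stage: one absorbance spectrum per
#' acquisition time on a common wavelength grid, optionally annotated with
#' the times at which off-line samples were withdrawn from the reactor
#' (those acquisitions are perturbed and can be masked out downstream).
#'
#' @param times Acquisition times, hours, strictly increasing, >= 0.
#' @param wavelengths Wavelength grid, nm, strictly increasing.
#' @param absorbance Matrix `length(times) x length(wavelengths)`, AU.
#' @param sampling_events Optional numeric vector of sampling times, hours.
#' @return An object of class `"spectra_series"`.
#' @export
spectra_series <- function(times, wavelengths, absorbance,
                           sampling_events = NULL) {
  absorbance <- as.matrix(absorbance)
  if (any(!is.finite(times)) || any(times < 0) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("'times' must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(!is.finite(wavelengths)) ||
      (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)))
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  if (nrow(absorbance) != length(times) ||
      ncol(absorbance) != length(wavelengths))
    stop("'absorbance' must be length(times) x length(wavelengths)",
         call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("'absorbance' must be finite", call. = FALSE)
  structure(list(times = as.numeric(times),
                 wavelengths = as.numeric(wavelengths),
                 absorbance = unname(absorbance),
                 sampling_events = sampling_events),
            class = "spectra_series")
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf("In-line spectra: %d acquisitions x %d wavelengths\n",
              length(x$times), length(x$wavelengths)))
  cat(sprintf("  t = %g-%g h, lambda = %g-%g nm\n",
              min(x$times), max(x$times),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$sampling_events))
    cat(sprintf("  %d sampling events\n", length(x$sampling_events)))
  invisible(x)
}

#' Restrict a spectra series to a wavelength region
#'
#' The default region, 600-800 nm, excludes the noisy short-wavelength
#' part of the visible range before principal component analysis.
#'
#' @param spectra A [spectra_series()].
#' @param lo,hi Region bounds, nm (inclusive).
#' @return A [spectra_series()] on the restricted grid.
#' @export
select_region <- function(spectra, lo = 600, hi = 800) {
  stopifnot(inherits(spectra, "spectra_series"))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("need finite bounds with lo < hi", call. = FALSE)
  keep <- spectra$wavelengths >= lo & spectra$wavelengths <= hi
  if (!any(keep))
    stop(sprintf("no wavelengths in [%g, %g] nm", lo, hi), call. = FALSE)
  out <- spectra_series(spectra$times, spectra$wavelengths[keep],
                        spectra$absorbance[, keep, drop = FALSE],
                        spectra$sampling_events)
  attr(out, "region") <- c(lo, hi)
  out
}

#' Mean-center a spectra matrix
#'
#' Subtracts each wavelength's time average, the standard preprocessing
#' before PCA of spectral time series.
#'
#' @param x A [spectra_series()] or a numeric matrix (rows = spectra).
#' @return List with `centered` (matrix) and `mean_spectrum`.
#' @export
mean_center <- function(x) {
  m <- if (inherits(x, "spectra_series")) x$absorbance else as.matrix(x)
  if (nrow(m) < 2L)
    stop("need at least 2 spectra to mean-center", call. = FALSE)
  mu <- colMeans(m)
  list(centered = sweep(m, 2L, mu), mean_spectrum = mu)
}

#' Principal component analysis of a spectra time series
#'
#' Decomposes the mean-centered data matrix as `X = T P' + E` via
#' singular value decomposition: columns of the loadings `P` are
#' orthonormal wavelength profiles, rows of the scores `T` are the
#' per-spectrum projections, and components are ordered by decreasing
#' explained variance. Each loading column is oriented so that its entry
#' of largest magnitude is positive (the sign of a principal component is
#' otherwise arbitrary). Components beyond the numerical rank of the
#' matrix are flagged as zero-variance.
#'
#' @param x A [spectra_series()] (centered internally; the mean spectrum
#'   is stored on the model) or an already-centered numeric matrix.
#' @param n_components Number of components to retain (default 3).
#' @return An object of class `"spectra_pca"`: `mean_spectrum`,
#'   `loadings` (wavelengths x components), `scores` (times x
#'   components), `sdev`, `explained_variance_fraction`, `zero_variance`
#'   (logical per component), plus `times`/`wavelengths`/`region` when
#'   fitted from a spectra series.
#' @export
fit_pca <- function(x, n_components = 3) {
  is_series <- inherits(x, "spectra_series")
  cc <- mean_center(x)
  X <- cc$centered
  n <- nrow(X)
  r_max <- min(dim(X))
  if (n_components < 1L || n_components > r_max)
    stop("'n_components' must be in 1..min(n_times, n_wavelengths)",
         call. = FALSE)
  sv <- svd(X, nu = n_components, nv = n_components)
  d <- sv$d
  var_all <- d^2 / (n - 1)
  total_var <- sum(var_all)
  dk <- d[seq_len(n_components)]
  tol <- max(dim(X)) * .Machine$double.eps * max(d, 0)
  zero_var <- dk <= tol

  loadings <- sv$v
  scores <- sv$u %*% diag(dk, n_components, n_components)
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(n_components)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  evf <- if (total_var > 0) var_all[seq_len(n_components)] / total_var
         else rep(0, n_components)

  structure(
    list(mean_spectrum = cc$mean_spectrum,
         loadings = loadings, scores = scores, sdev = dk / sqrt(n - 1),
         explained_variance_fraction = evf,
         zero_variance = zero_var,
         n_components = n_components,
         total_variance = total_var,
         times = if (is_series) x$times,
         wavelengths = if (is_series) x$wavelengths,
         sampling_events = if (is_series) x$sampling_events,
         region = if (is_series) attr(x, "region")),
    class = "spectra_pca"
  )
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("PCA of in-line spectra: %d components\n", x$n_components))
  cat("  explained variance fraction:",
      paste(sprintf("%.4f", x$explained_variance_fraction), collapse = " "),
      "\n")
  if (!is.null(x$region))
    cat(sprintf("  region: %g-%g nm\n", x$region[1], x$region[2]))
  invisible(x)
}

#' Mask acquisitions disturbed by reactor sampling
#'
#' Withdrawing an off-line sample perturbs the immersed probe and shows up
#' as transient spikes in the scores. This marks acquisitions within
#' `[event - pre_window, event + post_window]` of any sampling event for
#' exclusion.
#'
#' @param spectra A [spectra_series()] (or a `"spectra_pca"` model).
#' @param sampling_events Sampling times, hours; defaults to the ones
#'   stored on `spectra`.
#' @param pre_window,post_window Window sizes in minutes (defaults 0 and 2).
#' @return Logical vector over acquisition times: `TRUE` = retained.
#' @export
mask_disturbances <- function(spectra, sampling_events = NULL,
                              pre_window = 0, post_window = 2) {
  times <- if (inherits(spectra, c("spectra_series", "spectra_pca")))
    spectra$times else as.numeric(spectra)
  if (is.null(sampling_events) &&
      inherits(spectra, c("spectra_series", "spectra_pca")))
    sampling_events <- spectra$sampling_events
  if (pre_window < 0 || post_window < 0)
    stop("windows must be non-negative", call. = FALSE)
  keep <- rep(TRUE, length(times))
  for (e in sampling_events)
    keep <- keep & !(times >= e - pre_window / 60 &
                       times <= e + post_window / 60)
  keep
}

# interpolate the reference [POH] trajectory onto arbitrary times
interp_reference <- function(reference, times) {
  stopifnot(inherits(reference, "reaction_trajectory"))
  if (min(times) < min(reference$time_h) - 1e-9 ||
      max(times) > max(reference$time_h) + 1e-9)
    stop("reference trajectory does not cover the spectra times",
         call. = FALSE)
  stats::approx(reference$time_h, reference$POH_molL, xout = times,
                rule = 2)$y
}

#' Select the principal component that tracks the reaction
#'
#' Among the first `n_candidates` components, returns the one whose score
#' series correlates most strongly (in absolute Pearson correlation) with
#' the reference phenolic-hydroxyl decay, interpolated onto the retained
#' acquisition times. Which component carries the reaction signal varies
#' between runs (it was the first or the second depending on temperature
#' in the motivating experiments), so an automated rule is used; ties go
#' to the lower index.
#'
#' @param model A `"spectra_pca"` fitted from a spectra series.
#' @param reference A `"reaction_trajectory"` covering the spectra times.
#' @param mask Logical retain-mask over acquisitions (e.g. from
#'   [mask_disturbances()]); `NULL` keeps all.
#' @param n_candidates How many leading components to consider.
#' @return Integer component index (1-based).
#' @export
select_monitoring_pc <- function(model, reference, mask = NULL,
                                 n_candidates = 3) {
  stopifnot(inherits(model, "spectra_pca"))
  if (is.null(model$times))
    stop("model must be fitted from a spectra_series (times unknown)",
         call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(model$times))
  if (sum(mask) < 3L)
    stop("fewer than 3 retained time points", call. = FALSE)
  ref <- interp_reference(reference, model$times[mask])
  if (stats::sd(ref) == 0)
    stop("reference [POH] is constant over the retained times; ",
         "correlation undefined", call. = FALSE)
  kmax <- min(n_candidates, model$n_components)
  cors <- vapply(seq_len(kmax), function(k) {
    s <- model$scores[mask, k]
    if (stats::sd(s) == 0) return(0)
    abs(stats::cor(s, ref))
  }, numeric(1))
  which.max(cors)  # ties: first (lowest index) wins
}

#' Calibrate a principal-component score against the modelled [POH] decay
#'
#' Ordinary least squares of the modelled phenolic hydroxyl concentration
#' (the reference trajectory interpolated onto the retained acquisition
#' times) on the selected component's score. The regression direction
#' makes the calibration directly predictive: `[POH] = slope * score +
#' intercept`; R-squared is the same either way for simple linear
#' regression. Acquisitions within the initial exclusion window (default
#' the first 15 min, where the off-line assay delay makes the reference
#' unreliable) and masked disturbances are dropped.
#'
#' @param model A `"spectra_pca"` fitted from a spectra series.
#' @param component Component index; `NULL` auto-selects via
#'   [select_monitoring_pc()].
#' @param reference A `"reaction_trajectory"` covering the spectra times.
#' @param excluded_initial_window Hours excluded at the start (default
#'   0.25 h = 15 min).
#' @param mask Logical retain-mask over acquisitions; `NULL` keeps all.
#' @return An object of class `"monitoring_calibration"`: component
#'   index, `slope`, `intercept`, `r_squared`, exclusion bookkeeping,
#'   the wavelength region, and the (score, POH) pairs used.
#' @export
calibrate_scores <- function(model, component = NULL, reference,
                             excluded_initial_window = 0.25, mask = NULL) {
  stopifnot(inherits(model, "spectra_pca"))
  if (is.null(model$times))
    stop("model must be fitted from a spectra_series (times unknown)",
         call. = FALSE)
  times <- model$times
  if (is.null(mask)) mask <- rep(TRUE, length(times))
  if (length(mask) != length(times))
    stop("'mask' length must match the number of acquisitions",
         call. = FALSE)
  keep <- mask & times >= excluded_initial_window
  if (sum(keep) < 3L)
    stop("fewer than 3 retained points after exclusions", call. = FALSE)
  if (is.null(component))
    component <- select_monitoring_pc(model, reference, mask = keep)
  if (component < 1L || component > model$n_components)
    stop("'component' out of range", call. = FALSE)

  score <- model$scores[keep, component]
  if (stats::sd(score) == 0)
    stop("selected score is constant; calibration is degenerate",
         call. = FALSE)
  poh <- interp_reference(reference, times[keep])
  fit <- stats::lm(poh ~ score)
  r2 <- summary(fit)$r.squared

  structure(
    list(component_index = as.integer(component),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         excluded_initial_window = excluded_initial_window,
         excluded_times = times[!keep],
         region = model$region,
         n_points = sum(keep),
         data = data.frame(time_h = times[keep], score = score,
                           POH_molL = poh)),
    class = "monitoring_calibration"
  )
}

#' @export
print.monitoring_calibration <- function(x, ...) {
  cat("In-line monitoring calibration (score -> [POH])\n")
  cat(sprintf("  component PC%d, slope = %.5g, intercept = %.5g mol/L\n",
              x$component_index, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f over %d retained acquisitions\n",
              x$r_squared, x$n_points))
  if (!is.null(x$region))
    cat(sprintf("  region %g-%g nm; first %g h excluded\n",
                x$region[1], x$region[2], x$excluded_initial_window))
  invisible(x)
}

#' Predict [POH] from a score value
#'
#' Applies the fitted affine map of a [calibrate_scores()] calibration.
#' Predictions are clipped at zero (with a warning) since concentrations
#' cannot be negative.
#'
#' @param calibration A `"monitoring_calibration"`.
#' @param score Numeric score value(s).
#' @return Predicted type I+II phenolic hydroxyl concentration(s), mol/L.
#' @export
predict_poh <- function(calibration, score) {
  stopifnot(inherits(calibration, "monitoring_calibration"))
  p <- calibration$slope * score + calibration$intercept
  if (any(p < 0)) {
    warning("negative predicted concentration clipped at 0")
    p <- pmax(p, 0)
  }
  p
}

#' @rdname predict_poh
#' @param object A `"monitoring_calibration"`.
#' @param ... Unused.
#' @export
predict.monitoring_calibration <- function(object, score, ...) {
  predict_poh(object, score)
}

#' Plot a monitoring calibration
#'
#' Score versus modelled [POH] with the fitted line.
#'
#' @param x A `"monitoring_calibration"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.monitoring_calibration <- function(x, ...) {
  graphics::plot(x$data$score, x$data$POH_molL,
                 xlab = sprintf("PC%d score", x$component_index),
                 ylab = "[POH] (mol/L)", pch = 20, col = "grey40", ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("R^2 = %.3f", x$r_squared), side = 3, adj = 1)
  invisible(x)
}
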