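#' Fit the methylolation kinetic model to off-line assay data
#'
#' Estimates the rate constant `k1`, the non-reactive phenolic fraction
#' and (optionally) the secondary-reaction constant `k2` by least squares
#' on off-line time series of free formaldehyde and type I+II phenolic
#' hydroxyl concentrations.
#'
#' The objective is the summed squared residual of the simulated versus
#' observed `F` and `POH` series, jointly and unweighted by default
#' (per-series weights and single-series fitting are available). The
#' optimiser is bound-constrained quasi-Newton (L-BFGS-B) started from a
#' fixed grid of initial guesses (`k1` in 0.1/0.5/1/2/5, `k2` in 0/0.1,
#' `f` in 0.5/0.7/0.9); the best final SSE wins, ties broken by smallest
#' `k1`, so the result is deterministic for a given data set.
#'
#' @param offline Data frame with columns `time_h`, `F_molL`, `POH_molL`
#'   (missing values allowed as `NA`), e.g. from
#'   [generate_offline_series()] or [read_offline_series()].
#' @param init An [initial_conditions()] object.
#' @param model `"single"` fixes `k2 = 0`; `"with_secondary"` also fits
#'   the quadratic formaldehyde loss term.
#' @param weights Length-2 numeric, weights of the F and POH series in the
#'   objective (default equal).
#' @param use_series Which series enter the objective: both (default),
#'   or only one of them.
#' @param temperature_C Stored on the result as metadata.
#' @return An object of class `"methylolation_fit"` with components
#'   `params` ([kinetic_params()]), `sse`, `residuals`, `fitted`
#'   (trajectory at the data times), `convergence` (0 = converged),
#'   `degenerate` (TRUE when the optimum sits at the `k1 = 0` boundary or
#'   the data show no consumption), `n_points`, `data`, `init`.
#' @examples
#' p <- kinetic_params(1.53, 0, 0.71, 60)
#' i <- initial_conditions(0.59, 0.36)
#' obs <- as.data.frame(simulate_trajectory(p, i, 0:5))[, 1:3]
#' fit <- fit_kinetics(obs, i, model = "single")
#' coef(fit)
#' @export
fit_kinetics <- function(offline, init,
                         model = c("single", "with_secondary"),
                         weights = c(F = 1, POH = 1),
                         use_series = c("both", "POH", "F"),
                         temperature_C = NA_real_) {
  model <- match.arg(model)
  use_series <- match.arg(use_series)
  stopifnot(inherits(init, "initial_conditions"))
  offline <- as.data.frame(offline)
  req <- c("time_h", "F_molL", "POH_molL")
  if (!all(req %in% names(offline)))
    stop("'offline' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (length(weights) != 2L || any(weights < 0))
    stop("'weights' must be two non-negative numbers (F, POH)", call. = FALSE)

  keep <- is.finite(offline$time_h) &
    (is.finite(offline$F_molL) | is.finite(offline$POH_molL))
  offline <- offline[keep, , drop = FALSE]
  offline <- offline[order(offline$time_h), , drop = FALSE]
  n_obs <- sum(is.finite(offline$F_molL)) + sum(is.finite(offline$POH_molL))
  n_free <- if (model == "with_secondary") 3L else 2L
  if (nrow(offline) < 4L)
    stop("need at least 4 time points with measurements", call. = FALSE)
  if (n_obs <= n_free)
    stop("fewer observations than free parameters", call. = FALSE)

  t_obs <- offline$time_h
  sim_times <- sort(unique(c(0, t_obs)))
  idx <- match(t_obs, sim_times)
  wF <- if (use_series %in% c("both", "F")) weights[[1]] else 0
  wP <- if (use_series %in% c("both", "POH")) weights[[2]] else 0
  if (wF == 0 && wP == 0)
    stop("at least one series must carry positive weight", call. = FALSE)

  obj <- function(par) {
    k1 <- par[1]
    k2 <- if (model == "with_secondary") par[2] else 0
    f <- par[length(par)]
    tr <- try(simulate_trajectory(
      kinetic_params(k1, k2, f), init, sim_times), silent = TRUE)
    if (inherits(tr, "try-error")) return(1e10)
    rF <- offline$F_molL - tr$F_molL[idx]
    rP <- offline$POH_molL - tr$POH_molL[idx]
    wF * sum(rF^2, na.rm = TRUE) + wP * sum(rP^2, na.rm = TRUE)
  }

  k1_grid <- c(0.1, 0.5, 1, 2, 5)
  f_grid <- c(0.5, 0.7, 0.9)
  if (model == "with_secondary") {
    starts <- expand.grid(k1 = k1_grid, k2 = c(0, 0.1), f = f_grid,
                          KEEP.OUT.ATTRS = FALSE)
    lower <- c(0, 0, 0)
    upper <- c(100, 10, 1 - 1e-6)
  } else {
    starts <- expand.grid(k1 = k1_grid, f = f_grid, KEEP.OUT.ATTRS = FALSE)
    lower <- c(0, 0)
    upper <- c(100, 1 - 1e-6)
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- try(stats::optim(
      as.numeric(starts[s, ]), obj, method = "L-BFGS-B",
      lower = lower, upper = upper,
      control = list(maxit = 500, factr = 1e4)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[1] < best$par[1]))
      best <- res
  }
  if (is.null(best))
    stop("all optimiser starts failed", call. = FALSE)

  k1 <- best$par[1]
  k2 <- if (model == "with_secondary") best$par[2] else 0
  f <- best$par[length(best$par)]
  params <- kinetic_params(k1, k2, f, temperature_C)

  tr <- simulate_trajectory(params, init, sim_times)
  resid <- data.frame(
    time_h = t_obs,
    F = offline$F_molL - tr$F_molL[idx],
    POH = offline$POH_molL - tr$POH_molL[idx]
  )
  no_consumption <-
    (all(!is.finite(offline$F_molL)) ||
       diff(range(offline$F_molL, na.rm = TRUE)) < 1e-12) &&
    (all(!is.finite(offline$POH_molL)) ||
       diff(range(offline$POH_molL, na.rm = TRUE)) < 1e-12)
  structure(
    list(params = params, sse = best$value, residuals = resid,
         fitted = tr[idx, , drop = FALSE],
         convergence = best$convergence,
         converged = best$convergence == 0L,
         degenerate = k1 <= 1e-6 || no_consumption,
         n_points = nrow(offline), n_obs = n_obs,
         model = model, weights = weights, use_series = use_series,
         data = offline, init = init),
    class = "methylolation_fit"
  )
}

#' @export
coef.methylolation_fit <- function(object, ...) {
  p <- object$params
  if (object$model == "with_secondary")
    c(k1 = p$k1, k2 = p$k2, f_nonreactive = p$f_nonreactive)
  else
    c(k1 = p$k1, f_nonreactive = p$f_nonreactive)
}

#' @export
print.methylolation_fit <- function(x, ...) {
  cat(sprintf("Methylolation kinetic fit (%s model)\n", x$model))
  print(round(coef(x), 6))
  cat(sprintf("SSE = %.3g over %d observations (%d time points)\n",
              x$sse, x$n_obs, x$n_points))
  if (!x$converged) cat("warning: optimiser did not report convergence\n")
  if (x$degenerate) cat("note: fit is degenerate (no measurable reaction)\n")
  invisible(x)
}

#' @export
summary.methylolation_fit <- function(object, ...) {
  r <- c(object$residuals$F, object$residuals$POH)
  r <- r[is.finite(r)]
  structure(
    list(fit = object,
         rmse = sqrt(mean(r^2)),
         resid_range = range(r)),
    class = "summary.methylolation_fit"
  )
}

#' @export
print.summary.methylolation_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("residual RMSE = %.3g mol/L, range [%.3g, %.3g]\n",
              x$rmse, x$resid_range[1], x$resid_range[2]))
  invisible(x)
}

#' Predict concentration trajectories from a fitted kinetic model
#'
#' @param object A `"methylolation_fit"`.
#' @param times Times (hours) to predict at; must start at 0. Defaults to
#'   a dense grid over the observed range.
#' @param ... Unused.
#' @return A `"reaction_trajectory"` at the requested times.
#' @export
predict.methylolation_fit <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(0, max(object$data$time_h), length.out = 201L)
  simulate_trajectory(object$params, object$init, times)
}

#' @export
fitted.methylolation_fit <- function(object, ...) {
  as.data.frame(object$fitted)
}

#' @export
residuals.methylolation_fit <- function(object, ...) {
  object$residuals
}

#' Simulate replicate off-line data sets from a fitted kinetic model
#'
#' Parametric-bootstrap style: regenerates noisy off-line series from the
#' fitted trajectory using the given noise model.
#'
#' @param object A `"methylolation_fit"`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed (required for reproducibility).
#' @param noise A [noise_model()]; its `offline_sd` and `offline_delay_h`
#'   drive the replicates.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like the input data.
#' @export
simulate.methylolation_fit <- function(object, nsim = 1, seed = NULL,
                                       noise = noise_model(), ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_trajectory(object$params, object$init,
                            sort(unique(c(0, object$data$time_h))))
  lapply(seq_len(nsim), function(i) {
    generate_offline_series(tr,
                            interval = NULL, times = object$data$time_h,
                            noise = noise, seed = NULL, replicates = 1)
  })
}

#' Plot a kinetic fit: observations and fitted decay curves
#'
#' @param x A `"methylolation_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.methylolation_fit <- function(x, ...) {
  dense <- predict(x)
  yl <- range(c(x$data$F_molL, x$data$POH_molL, dense$F_molL, dense$POH_molL),
              na.rm = TRUE)
  graphics::plot(dense$time_h, dense$F_molL, type = "l", col = "firebrick",
                 xlab = "time (h)", ylab = "concentration (mol/L)",
                 ylim = yl, ...)
  graphics::lines(dense$time_h, dense$POH_molL, col = "steelblue")
  graphics::points(x$data$time_h, x$data$F_molL, col = "firebrick", pch = 19)
  graphics::points(x$data$time_h, x$data$POH_molL, col = "steelblue", pch = 17)
  graphics::legend("topright", bty = "n", lty = 1, pch = c(19, 17),
                   col = c("firebrick", "steelblue"),
                   legend = c("[F]", "[POH] (type I+II)"))
  invisible(x)
}
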