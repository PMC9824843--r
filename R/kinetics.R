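#' Kinetic parameters of the methylolation reaction
#'
#' Bundles the rate constants and the non-reactive phenolic fraction that
#' define the second-order model of lignosulphonate hydroxymethylation,
#'
#' \deqn{-d[F]/dt = k_1 [POH] [F] + k_2 [F]^2}
#'
#' where \eqn{[F]} is free formaldehyde and \eqn{[POH]} the reactive pool of
#' type I+II phenolic hydroxyl groups. A fixed fraction of the phenolic
#' groups is treated as chemically inert (blocked ring positions) and never
#' enters the rate law; see [reactive_pool()]. The quadratic term models a
#' secondary formaldehyde-consuming reaction (e.g. Cannizzaro) and is absent
#' when `k2 = 0`.
#'
#' @param k1 Main rate constant, L mol^-1 h^-1. Must be non-negative
#'   (zero is the degenerate no-reaction limit).
#' @param k2 Secondary-reaction rate constant, L mol^-1 h^-1; `0` disables
#'   the secondary reaction.
#' @param f_nonreactive Fraction of phenolic groups unavailable to react,
#'   in `[0, 1)`.
#' @param temperature_C Reaction temperature in Celsius. Metadata only: no
#'   Arrhenius relation is modelled.
#' @return An object of class `"kinetic_params"`.
#' @seealso [simulate_trajectory()], [fit_kinetics()]
#' @examples
#' kinetic_params(k1 = 1.53, f_nonreactive = 0.71, temperature_C = 60)
#' @export
kinetic_params <- function(k1, k2 = 0, f_nonreactive = 0,
                           temperature_C = NA_real_) {
  if (!is.numeric(k1) || length(k1) != 1L || !is.finite(k1) || k1 < 0)
    stop("'k1' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(k2) || length(k2) != 1L || !is.finite(k2) || k2 < 0)
    stop("'k2' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(f_nonreactive) || length(f_nonreactive) != 1L ||
      !is.finite(f_nonreactive) ||
      f_nonreactive < 0 || f_nonreactive >= 1)
    stop("'f_nonreactive' must lie in [0, 1)", call. = FALSE)
  structure(
    list(k1 = as.numeric(k1), k2 = as.numeric(k2),
         f_nonreactive = as.numeric(f_nonreactive),
         temperature_C = as.numeric(temperature_C)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Methylolation kinetic parameters\n")
  cat(sprintf("  k1 = %g L mol^-1 h^-1", x$k1))
  if (x$k2 > 0) cat(sprintf(", k2 = %g L mol^-1 h^-1", x$k2))
  cat(sprintf("\n  non-reactive phenolic fraction = %g", x$f_nonreactive))
  if (is.finite(x$temperature_C))
    cat(sprintf("  (T = %g degC)", x$temperature_C))
  cat("\n")
  invisible(x)
}

#' Initial concentrations for a methylolation run
#'
#' @param F0 Initial free-formaldehyde concentration, mol/L.
#' @param POH0 Initial concentration of type I+II phenolic hydroxyl groups
#'   (reactive and non-reactive together), mol/L.
#' @return An object of class `"initial_conditions"`.
#' @examples
#' initial_conditions(F0 = 0.59, POH0 = 0.36)
#' @export
initial_conditions <- function(F0, POH0) {
  if (!is.numeric(F0) || length(F0) != 1L || !is.finite(F0) || F0 <= 0)
    stop("'F0' must be a single positive number", call. = FALSE)
  if (!is.numeric(POH0) || length(POH0) != 1L || !is.finite(POH0) || POH0 <= 0)
    stop("'POH0' must be a single positive number", call. = FALSE)
  structure(list(F0 = as.numeric(F0), POH0 = as.numeric(POH0)),
            class = "initial_conditions")
}

#' Reactive pool of phenolic hydroxyl groups
#'
#' The concentration of phenolic groups available to react with
#' formaldehyde at the start of the reaction:
#' `POH0 * (1 - f_nonreactive)`. The remainder is treated as inert and
#' constant throughout the run.
#'
#' @param POH0 Total initial type I+II phenolic concentration, mol/L.
#' @param f_nonreactive Non-reactive fraction, in `[0, 1)`.
#' @return Reactive phenolic concentration, mol/L.
#' @examples
#' reactive_pool(0.36, 0.71)  # 0.1044
#' @export
reactive_pool <- function(POH0, f_nonreactive) {
  if (!is.numeric(POH0) || any(!is.finite(POH0)) || any(POH0 <= 0))
    stop("'POH0' must be positive and finite", call. = FALSE)
  if (!is.numeric(f_nonreactive) || any(!is.finite(f_nonreactive)) ||
      any(f_nonreactive < 0) || any(f_nonreactive >= 1))
    stop("'f_nonreactive' must lie in [0, 1)", call. = FALSE)
  POH0 * (1 - f_nonreactive)
}

# closed-form extent of a second-order A + B -> C reaction with
# A0 = F0, B0 = reactive pool; handles the equal-concentration limit
second_order_extent <- function(k1, A0, B0, t) {
  if (k1 == 0) return(rep(0, length(t)))
  if (abs(A0 - B0) < 1e-10 * max(A0, B0)) {
    # 1/(b - x) - 1/b = k t  =>  x = b^2 k t / (1 + b k t)
    b <- (A0 + B0) / 2
    return(b^2 * k1 * t / (1 + b * k1 * t))
  }
  e <- exp((A0 - B0) * k1 * t)
  A0 * B0 * (e - 1) / (A0 * e - B0)
}

#' Simulate a methylolation reaction trajectory
#'
#' Integrates the kinetic model over the requested time grid. With no
#' secondary reaction (`k2 = 0`) the exact closed-form solution of the
#' second-order rate law is used (including the equal-initial-concentration
#' limit `1/(b-x) - 1/b = k1 t`). With `k2 > 0` the coupled system
#' `dF/dt = -k1 POH_r F - k2 F^2`, `dPOH_r/dt = -k1 POH_r F` is integrated
#' with an adaptive solver (lsoda, atol 1e-9, rtol 1e-8).
#'
#' Reported `POH` is the total type I+II concentration: the reactive pool
#' plus the constant non-reactive remainder `POH0 * f_nonreactive`.
#'
#' @param params A [kinetic_params()] object.
#' @param init An [initial_conditions()] object.
#' @param times Numeric vector of times in hours, strictly increasing,
#'   starting at 0.
#' @return A `"reaction_trajectory"`: a data frame with columns `time_h`,
#'   `F_molL`, `POH_molL` and `x_molL` (reaction extent, formaldehyde
#'   consumed by the main reaction measured as `F0 - F` when `k2 = 0`),
#'   carrying `params` and `init` as attributes.
#' @examples
#' p <- kinetic_params(1.53, 0, 0.71, 60)
#' i <- initial_conditions(0.59, 0.36)
#' tr <- simulate_trajectory(p, i, seq(0, 5, by = 0.5))
#' tr[tr$time_h == 5, ]
#' @export
simulate_trajectory <- function(params, init, times) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(init, "initial_conditions"))
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("'times' must be finite numeric", call. = FALSE)
  if (times[1] != 0)
    stop("'times' must start at 0", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)

  B0 <- reactive_pool(init$POH0, params$f_nonreactive)
  inert <- init$POH0 - B0

  if (params$k2 == 0) {
    x <- second_order_extent(params$k1, init$F0, B0, times)
    F <- init$F0 - x
    P <- B0 - x
  } else {
    rhs <- function(t, y, parms) {
      with(as.list(c(y, parms)), {
        main <- k1 * P * F
        list(c(F = -main - k2 * F^2, P = -main))
      })
    }
    sol <- deSolve::ode(
      y = c(F = init$F0, P = B0), times = times, func = rhs,
      parms = c(k1 = params$k1, k2 = params$k2),
      method = "lsoda", atol = 1e-9, rtol = 1e-8
    )
    F <- sol[, "F"]
    P <- sol[, "P"]
    if (any(F < -1e-7) || any(P < -1e-7))
      stop("integrator produced negative concentrations (step-size failure)",
           call. = FALSE)
    F <- pmax(F, 0)
    P <- pmax(P, 0)
    x <- B0 - P  # main-reaction extent; F also lost to the secondary term
  }

  out <- data.frame(time_h = times, F_molL = F, POH_molL = P + inert,
                    x_molL = x)
  attr(out, "params") <- params
  attr(out, "init") <- init
  class(out) <- c("reaction_trajectory", "data.frame")
  out
}

#' Reaction extent from a trajectory
#'
#' The extent `x(t) = F0 - F(t)`: moles of formaldehyde consumed per litre.
#' When the trajectory was simulated without a secondary reaction this
#' equals the phenolic-side consumption (conservation is verified to
#' 1e-9 mol/L and violation raises an error); with `k2 > 0` the
#' formaldehyde-side extent exceeds the phenolic-side extent.
#'
#' @param trajectory A `"reaction_trajectory"`.
#' @param init The [initial_conditions()] the trajectory was simulated
#'   from; defaults to the ones stored on the trajectory.
#' @return Numeric vector of extents, mol/L, one per time point.
#' @export
extent <- function(trajectory, init = attr(trajectory, "init")) {
  stopifnot(inherits(trajectory, "reaction_trajectory"))
  if (is.null(init))
    stop("'init' missing and not stored on the trajectory", call. = FALSE)
  x <- init$F0 - trajectory$F_molL
  params <- attr(trajectory, "params")
  if (!is.null(params) && params$k2 == 0) {
    B0 <- reactive_pool(init$POH0, params$f_nonreactive)
    inert <- init$POH0 - B0
    x_poh <- B0 - (trajectory$POH_molL - inert)
    if (max(abs(x - x_poh)) > 1e-9)
      stop("conservation violated: formaldehyde- and phenolic-side extents ",
           "disagree beyond 1e-9 mol/L", call. = FALSE)
  }
  x
}

#' @export
print.reaction_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Methylolation trajectory: %d time points over %g h\n",
              nrow(x), max(x$time_h)))
  if (!is.null(p))
    cat(sprintf("  k1 = %g, k2 = %g, f_nonreactive = %g\n",
                p$k1, p$k2, p$f_nonreactive))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}
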