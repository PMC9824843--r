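# Independent fixed-step Euler integrator used as the numerical oracle for
# trajectory checks. Deliberately naive: it shares no code with the
# package's closed-form or adaptive-solver paths.
euler_oracle <- function(k1, k2, f, F0, POH0, times, dt = 1e-5) {
  B0 <- POH0 * (1 - f)
  n <- round(max(times) / dt)
  Fv <- numeric(n + 1L)
  Pv <- numeric(n + 1L)
  Fv[1] <- F0
  Pv[1] <- B0
  for (i in seq_len(n)) {
    main <- k1 * Pv[i] * Fv[i]
    Fv[i + 1L] <- Fv[i] - dt * (main + k2 * Fv[i]^2)
    Pv[i + 1L] <- Pv[i] - dt * main
  }
  idx <- round(times / dt) + 1L
  data.frame(time_h = times, F = Fv[idx], POH_r = Pv[idx])
}

# parameter sets studied at 50-60 degC (rate constants in L mol^-1 h^-1,
# initial concentrations in mol/L)
sls60 <- list(k1 = 1.53, k2 = 0, f = 0.71, F0 = 0.59, POH0 = 0.36)
hls50 <- list(k1 = 2.02, k2 = 0.06, f = 0.86, F0 = 0.79, POH0 = 0.38)
hls60 <- list(k1 = 1.32, k2 = 0.14, f = 0.79, F0 = 0.79, POH0 = 0.38)

as_params <- function(s) kinetic_params(s$k1, s$k2, s$f)
as_init <- function(s) initial_conditions(s$F0, s$POH0)

noiseless_series <- function(s, times = 0:5) {
  tr <- simulate_trajectory(as_params(s), as_init(s), times)
  as.data.frame(tr)[, c("time_h", "F_molL", "POH_molL")]
}
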