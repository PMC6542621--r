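#' Published experiment presets
#'
#' Returns a complete run specification (parameters plus stimulation
#' protocol or sweep specification) for the published protocols:
#' \describe{
#'   \item{fig2}{association formation: tuning noise mean 0.25, then OU
#'     inputs with means 0.9 and 0.75, \code{n_eps = 20}.}
#'   \item{fig3_grid}{input phase diagram at \code{n_eps = 20}.}
#'   \item{fig4_scan}{inflexion-point scans at zero and maximal input,
#'     \code{n_eps} swept.}
#'   \item{fig5_regimes}{regime partition of the (target rate, inhibition)
#'     parameter plane.}
#'   \item{fig6_areadisc}{discrimination-area sweep of the
#'     within-population inhibition at \code{theta = 0.8}.}
#'   \item{fig7}{self-organized discrimination: tuning noise mean 0.05,
#'     OU means 0.85 and 0.7, \code{n_eps = 12}, inhibitory plasticity
#'     enabled (up-state 0.8, down-state 0.5, rate-sum gate 0.2, rate
#'     difference tolerance 0.05, unit learning rates).}
#' }
#'
#' @param name preset name.
#' @param accel common acceleration factor applied to both plasticity
#'   timescales (equilibria are unchanged; transients and therefore
#'   simulated durations shrink accordingly).
#' @return list with elements \code{name}, \code{params}, and either
#'   \code{protocol} (plus \code{eq_window}, \code{eq_tol}) for simulation
#'   presets or a sweep specification for analysis presets.
#' @export
#' @examples
#' pr <- preset("fig2", accel = 10)
#' pr$params$n_eps
preset <- function(name, accel = 1) {
  known <- c("fig2", "fig3_grid", "fig4_scan", "fig5_regimes",
             "fig6_areadisc", "fig7")
  if (!name %in% known)
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  tuning_t <- 600 / accel      # t = 10 in units of 1/mu = 60 s
  eq_window <- 100 / accel
  eq_tol <- 1e-5 * accel
  switch(name,
    fig2 = list(
      name = name,
      params = accelerate_timescales(
        model_parameters(list(n_eps = 20)), accel),
      protocol = stim_protocol(
        phase_noise(tuning_t, mean = 0.25, sd = 0.025),
        phase_ou(6000 / accel, means = c(0.9, 0.75),
                 noise_mean = 0.25, noise_sd = 0.025)),
      eq_window = eq_window, eq_tol = eq_tol),
    fig3_grid = list(
      name = name,
      params = model_parameters(list(n_eps = 20)),
      I1 = seq(0, 1.2, length.out = 13), I2 = seq(0, 1.2, length.out = 13)),
    fig4_scan = list(
      name = name,
      params = model_parameters(list(n_eps = 12)),
      inputs = list(zero = c(0, 0), max = c(1, 1)),
      n_eps_range = 1:35),
    fig5_regimes = list(
      name = name,
      params = model_parameters(),
      F_T_grid = seq(0.01, 0.49, by = 0.02),
      theta_grid = seq(0.05, 0.95, by = 0.05)),
    fig6_areadisc = list(
      name = name,
      params = model_parameters(list(theta = 0.8, theta_P = 0.5)),
      theta = 0.8, theta_P_grid = seq(0.1, 0.8, by = 0.05)),
    fig7 = list(
      name = name,
      params = accelerate_timescales(
        model_parameters(list(
          n_eps = 12,
          inh_plasticity = list(enabled = TRUE, theta_u = 0.8,
                                theta_d = 0.5, theta_F = 0.2,
                                delta_F = 0.05, rho_u = 1, rho_d = 1))),
        accel),
      protocol = stim_protocol(
        phase_noise(tuning_t, mean = 0.05, sd = 0.025),
        phase_ou(9000 / accel, means = c(0.85, 0.7),
                 noise_mean = 0.05, noise_sd = 0.025)),
      eq_window = eq_window, eq_tol = eq_tol)
  )
}

#' Run a simulation preset
#'
#' Convenience wrapper: builds the preset and calls
#' \code{\link{simulate_network}} with its protocol and equilibrium
#' settings.
#'
#' @param name a simulation preset name (\code{"fig2"} or \code{"fig7"}).
#' @param seed master seed.
#' @param accel timescale acceleration factor.
#' @param ... passed on to \code{\link{simulate_network}}.
#' @return a \code{memorg_trajectory}.
#' @export
run_preset <- function(name, seed = 1L, accel = 1, ...) {
  pr <- preset(name, accel = accel)
  if (is.null(pr$protocol))
    stop("preset '", name, "' is not a simulation preset", call. = FALSE)
  simulate_network(pr$protocol, pr$params, seed = seed,
                   eq_window = pr$eq_window, eq_tol = pr$eq_tol, ...)
}
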