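#' Model parameters for the plastic recurrent network
#'
#' Builds the full parameter set of the model with the published defaults and
#' applies user overrides.  All rates and weights are normalized: firing rates
#' are fractions of the maximal rate \code{F_max}, synaptic weights are
#' fractions of the maximal weight \code{omega_max} (see
#' \code{\link{derive_constants}}).
#'
#' The defaults describe a network of \code{n = 100} all-to-all connected
#' rate neurons, two stimulated populations of \code{n_P = 10} neurons each,
#' Hebbian rate \code{mu = 1/60} per second, scaling rate
#' \code{gamma = 1/5400} per second, normalized target rate
#' \code{F_T = 0.05} and baseline inhibitory weight \code{theta = 0.5}.
#'
#' @param overrides named list of parameter values replacing the defaults.
#'   Unknown names are an error.
#' @param validate if \code{TRUE} (default) invariant violations raise an
#'   error naming the offending field.
#' @return an object of class \code{memorg_params} (a named list).
#' @export
#' @examples
#' p <- model_parameters()
#' p$theta
#' p2 <- model_parameters(list(theta = 0.8, theta_P = 0.5))
model_parameters <- function(overrides = list(), validate = TRUE) {
  defaults <- list(
    # network
    n      = 100L,   # neurons in the recurrent network
    n_P    = 10L,    # neurons per stimulated population
    n_Pex  = 10L,    # input-layer neurons per population
    # neuron model
    tau    = 1,        # membrane time constant [s]
    R      = 0.1,      # membrane resistance (enters only via products)
    F_max  = 100,      # maximal firing rate [Hz]
    beta   = 0.00035,  # sigmoid steepness [1/mV]
    n_eps  = 12,       # sigmoid inflexion in units of u_max
    # plasticity
    mu     = 1 / 60,   # Hebbian rate [1/s]
    gamma  = 1 / 5400, # scaling rate [1/s]
    F_T    = 0.05,     # normalized target rate, in (0,1)
    # inhibition
    theta   = 0.5,     # normalized baseline inhibitory weight
    theta_P = NULL,    # within-population inhibitory weight; NULL -> theta
    # input
    w_ex     = 1,      # normalized external synapse weight
    ou_delta = 0.025,  # OU drift constant (per 1 ms step)
    ou_sigma = 0.0125, # OU diffusion constant (per 1 ms step)
    ou_dt0   = 0.001,  # reference step of the printed OU constants [s]
    # integration
    dt = 0.001,        # Euler step [s]
    # conventions
    drive_convention = "scaled",   # "scaled" or "literal"
    background_inhibition_corrected = FALSE,
    # inhibitory plasticity block
    inh_plasticity = list(
      enabled = FALSE,
      theta_u = 0.8, theta_d = 0.5,
      theta_F = 0.2,   # gate on F_i + F_j (= 2 * F_min at defaults)
      delta_F = 0.05,  # tolerance on |F_i - F_j|
      rho_u = 1, rho_d = 1
    )
  )
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("overrides must be a named list", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in nm) {
      if (k == "inh_plasticity") {
        sub <- overrides[[k]]
        bad <- setdiff(names(sub), names(defaults$inh_plasticity))
        if (length(bad))
          stop("unknown inh_plasticity field(s): ",
               paste(bad, collapse = ", "), call. = FALSE)
        defaults$inh_plasticity[names(sub)] <- sub
      } else {
        defaults[[k]] <- overrides[[k]]
      }
    }
  }
  if (is.null(defaults$theta_P)) defaults$theta_P <- defaults$theta
  defaults$n   <- as.integer(defaults$n)
  defaults$n_P <- as.integer(defaults$n_P)
  defaults$n_Pex <- as.integer(defaults$n_Pex)
  class(defaults) <- "memorg_params"
  if (validate) {
    viol <- validate_parameters(defaults)
    if (length(viol))
      stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "),
           call. = FALSE)
  }
  defaults
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters and returns a
#' character vector of human-readable violations (empty when valid).
#'
#' @param params a \code{memorg_params} object (or plain named list with the
#'   same fields).
#' @return character vector of violation descriptions; \code{character(0)}
#'   when all invariants hold.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  p <- params
  if (!is.numeric(p$n) || p$n < 2) add("n must be an integer >= 2")
  if (!is.numeric(p$n_P) || p$n_P < 1) add("n_P must be a positive integer")
  if (is.numeric(p$n) && is.numeric(p$n_P) && 2 * p$n_P > p$n)
    add("2*n_P exceeds n")
  if (!is.numeric(p$n_Pex) || p$n_Pex < 1) add("n_Pex must be positive")
  if (!is.numeric(p$tau) || p$tau <= 0) add("tau must be positive")
  if (!is.numeric(p$F_max) || p$F_max <= 0) add("F_max must be positive")
  if (!is.numeric(p$beta) || p$beta <= 0) add("beta must be positive")
  if (!is.numeric(p$n_eps) || p$n_eps <= 0) add("n_eps must be positive")
  if (!is.numeric(p$F_T) || p$F_T <= 0 || p$F_T >= 1)
    add("F_T out of (0,1)")
  if (!is.numeric(p$theta) || p$theta <= 0 || p$theta >= 1)
    add("theta out of (0,1)")
  if (!is.null(p$theta_P) &&
      (!is.numeric(p$theta_P) || p$theta_P <= 0 || p$theta_P >= 1))
    add("theta_P out of (0,1)")
  if (!is.numeric(p$mu) || !is.numeric(p$gamma) ||
      p$gamma <= 0 || p$mu <= p$gamma)
    add("mu > gamma > 0 required")
  if (!is.numeric(p$dt) || p$dt <= 0) add("dt must be positive")
  if (!p$drive_convention %in% c("scaled", "literal"))
    add("drive_convention must be 'scaled' or 'literal'")
  ip <- p$inh_plasticity
  if (!is.null(ip)) {
    if (ip$theta_d > ip$theta_u) add("theta_d must not exceed theta_u")
    if (ip$delta_F < 0) add("delta_F must be non-negative")
    if (ip$rho_u < 0 || ip$rho_d < 0) add("rho_u, rho_d must be non-negative")
  }
  v
}

#' Derived constants of the normalized model
#'
#' Computes the scales implied by the primary parameters:
#' \describe{
#'   \item{omega_max}{maximal synaptic weight,
#'     \eqn{\mu F_{max}^2 / (\gamma (F_{max} - F_T F_{max}))}; weights are
#'     normalized by this value.}
#'   \item{u_max}{maximal membrane potential evoked by a single maximally
#'     strong synapse at maximal presynaptic rate,
#'     \eqn{R\,\omega_{max}(1-\tilde\theta)} (scaled convention).}
#'   \item{epsilon}{sigmoid inflexion point, \code{n_eps * u_max}.}
#'   \item{K}{dimensionless drive gain multiplying the normalized recurrent
#'     and external input sums, \eqn{\beta R \omega_{max}} under the default
#'     \code{"scaled"} convention (normalized rates absorb one factor of
#'     \code{F_max}); \eqn{\beta R F_{max}\omega_{max}} under
#'     \code{"literal"}.}
#'   \item{beta_eps}{the threshold term \eqn{\beta\epsilon} of the activity
#'     equation, equal to \code{K * n_eps * (1 - theta)}.}
#'   \item{F_min}{lower edge of the plasticity-dominated activity regime,
#'     \code{2 * F_T}.}
#'   \item{tau_w}{weight-dynamics time constant, \code{1/mu}; all equilibrium
#'     quantities are independent of it (only transients change).}
#' }
#'
#' @param params a \code{memorg_params} object.
#' @return a named list of class \code{memorg_constants}.
#' @export
#' @examples
#' dc <- derive_constants(model_parameters())
#' dc$omega_max  # ~9473.7 at the defaults
#' dc$K          # ~0.3316
derive_constants <- function(params) {
  p <- params
  omega_max <- p$mu * p$F_max^2 / (p$gamma * (p$F_max - p$F_T * p$F_max))
  scale <- if (identical(p$drive_convention, "literal")) p$F_max else 1
  u_max <- p$R * scale * omega_max * (1 - p$theta)
  K <- p$beta * p$R * scale * omega_max
  out <- list(
    omega_max = omega_max,
    u_max     = u_max,
    epsilon   = p$n_eps * u_max,
    K         = K,
    beta_eps  = K * p$n_eps * (1 - p$theta),
    F_min     = 2 * p$F_T,
    tau_w     = 1 / p$mu
  )
  class(out) <- "memorg_constants"
  out
}

#' @export
print.memorg_params <- function(x, ...) {
  dc <- derive_constants(x)
  cat("Plastic-network model parameters\n")
  cat(sprintf("  network : n = %d, n_P = %d (+%d background), n_Pex = %d\n",
              x$n, x$n_P, x$n - 2L * x$n_P, x$n_Pex))
  cat(sprintf("  neuron  : tau = %gs, F_max = %g Hz, beta = %g/mV, n_eps = %g\n",
              x$tau, x$F_max, x$beta, x$n_eps))
  cat(sprintf("  synapse : mu = %g/s, gamma = %g/s, F_T = %g, theta = %g, theta_P = %g\n",
              x$mu, x$gamma, x$F_T, x$theta, x$theta_P))
  cat(sprintf("  derived : omega_max = %.4g, K = %.5g, F_min = %g, tau_w = %gs\n",
              dc$omega_max, dc$K, dc$F_min, dc$tau_w))
  cat(sprintf("  inhibitory plasticity: %s\n",
              if (isTRUE(x$inh_plasticity$enabled)) "enabled" else "off"))
  invisible(x)
}

#' Accelerate the plasticity timescales
#'
#' Multiplies both plasticity rates \code{mu} and \code{gamma} by a common
#' factor.  Because \code{omega_max} depends only on the ratio
#' \code{mu/gamma}, every equilibrium quantity of the model is unchanged;
#' transients (and hence simulation wall time) contract by the factor.
#'
#' @param params a \code{memorg_params} object.
#' @param factor positive acceleration factor.
#' @return updated \code{memorg_params}.
#' @export
accelerate_timescales <- function(params, factor) {
  stopifnot(is.numeric(factor), factor > 0)
  params$mu <- params$mu * factor
  params$gamma <- params$gamma * factor
  params
}
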