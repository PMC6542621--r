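#' Stimulation protocol phases
#'
#' A protocol is an ordered list of phases.  \code{phase_noise} describes a
#' tuning phase in which every neuron receives iid Gaussian input noise
#' through its \code{n_Pex} input neurons (each draw clipped to [0,1]);
#' \code{phase_ou} describes a stimulation phase in which the two input
#' layers fire as Ornstein-Uhlenbeck processes with population-specific
#' means while background neurons keep receiving the tuning noise.
#'
#' @param duration phase duration in seconds (for \code{phase_ou} with
#'   \code{until_equilibrium = TRUE} this is the maximal duration).
#' @param mean,sd mean and standard deviation of the tuning noise.
#' @param means length-2 vector of OU stationary means for populations 1, 2.
#' @param noise_mean,noise_sd tuning-noise parameters kept for the
#'   background neurons during the OU phase.
#' @param until_equilibrium stop the phase early once all mean synaptic
#'   weight classes are stationary (see \code{\link{simulate_network}}).
#' @return a phase description (named list).
#' @export
phase_noise <- function(duration, mean = 0.05, sd = 0.025) {
  stopifnot(duration > 0)
  list(type = "noise", duration = duration, mean = mean, sd = sd)
}

#' @rdname phase_noise
#' @export
phase_ou <- function(duration, means, noise_mean = 0.05, noise_sd = 0.025,
                     until_equilibrium = TRUE) {
  stopifnot(duration > 0, length(means) == 2)
  list(type = "ou", duration = duration, means = as.numeric(means),
       noise_mean = noise_mean, noise_sd = noise_sd,
       until_equilibrium = until_equilibrium)
}

#' @rdname phase_noise
#' @param ... phases in order.
#' @export
stim_protocol <- function(...) {
  phases <- list(...)
  stopifnot(length(phases) > 0)
  structure(phases, class = "memorg_protocol")
}

# Largest absolute least-squares slope (per second) among the weight-class
# columns of a sample window; used for online equilibrium detection, which is
# robust to the stochastic input jitter that a raw finite-difference test
# picks up.
max_class_slope <- function(samples) {
  cols <- intersect(c("w11", "w22", "w21", "w12", "wB_mean",
                      "inh_11", "inh_22", "inh_12", "inh_21"),
                    colnames(samples))
  tt <- samples$t - mean(samples$t)
  vt <- sum(tt^2)
  if (vt == 0) return(Inf)
  max(vapply(cols, function(cl) {
    x <- samples[[cl]]
    if (anyNA(x)) return(0)
    abs(sum(tt * x) / vt)
  }, numeric(1)))
}

#' Simulate the full plastic recurrent network
#'
#' Runs the stimulation protocol phase by phase with the explicit-Euler
#' scheme of \code{\link{step_network}}, implemented in compiled code.
#' Three RNG streams (initial state, tuning noise, OU inputs) are derived
#' from the master seed so that runs are bit-reproducible.
#'
#' Phases marked \code{until_equilibrium} stop once the largest absolute
#' least-squares slope of every population-averaged synaptic weight class
#' over the trailing \code{eq_window} seconds falls below \code{eq_tol}
#' (weight units per second), or at the phase duration limit.
#'
#' @param protocol a \code{\link{stim_protocol}}.
#' @param params a \code{memorg_params}.
#' @param seed master integer seed.
#' @param sample_every sampling interval for population averages, seconds.
#' @param eq_window,eq_tol equilibrium-detection window (s) and slope
#'   tolerance (1/s).  When accelerating the plasticity timescales by a
#'   factor c (see \code{\link{accelerate_timescales}}), divide
#'   \code{eq_window} and multiply \code{eq_tol} by c.
#' @return object of class \code{memorg_trajectory}: list with
#'   \code{samples} (data frame of population averages over time),
#'   \code{final_state}, \code{final_averages}, \code{equilibrium} flag,
#'   \code{params}, \code{seed}, \code{protocol}.
#' @export
simulate_network <- function(protocol, params, seed = 1L, sample_every = 1,
                             eq_window = 100, eq_tol = 1e-5) {
  stopifnot(inherits(protocol, "memorg_protocol"))
  layout <- build_layout(params)
  dc <- derive_constants(params)
  ip <- params$inh_plasticity
  set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  state <- init_state(params, layout, seed = stream_seeds[1L])

  dt <- params$dt
  sample_steps <- max(1L, as.integer(round(sample_every / dt)))
  all_samples <- list()
  equilibrium <- FALSE

  for (phase_i in seq_along(protocol)) {
    ph <- protocol[[phase_i]]
    set.seed(stream_seeds[if (ph$type == "noise") 2L else 3L] + phase_i)
    if (ph$type == "ou") state$F_ex <- rep(ph$means, each = params$n_Pex)
    remaining <- ph$duration
    check_eq <- ph$type == "ou" && isTRUE(ph$until_equilibrium)
    chunk_s <- if (check_eq) max(eq_window / 2, 10 * sample_every)
               else remaining
    phase_samples <- list()
    phase_t0 <- state$t
    while (remaining > dt / 2) {
      nsteps <- as.integer(round(min(chunk_s, remaining) / dt))
      if (nsteps < 1L) break
      res <- simulate_phase_cpp(
        state$F, state$W, state$W_inh, state$F_ex, layout$pop_id,
        nsteps, dt, state$t,
        mode = if (ph$type == "ou") 1L else 0L,
        noise_mean = if (ph$type == "ou") ph$noise_mean else ph$mean,
        noise_sd = if (ph$type == "ou") ph$noise_sd else ph$sd,
        ou_means = if (ph$type == "ou") ph$means else c(0, 0),
        ou_delta = params$ou_delta, ou_sigma = params$ou_sigma,
        ou_h = dt / params$ou_dt0,
        n_pex = params$n_Pex, w_ex = params$w_ex,
        K = dc$K, beta_eps = dc$beta_eps,
        tau = params$tau, tau_w = dc$tau_w, F_T = params$F_T,
        inh_plastic = isTRUE(ip$enabled),
        theta_u = ip$theta_u, theta_d = ip$theta_d,
        theta_F = ip$theta_F, delta_F = ip$delta_F,
        rho_u = ip$rho_u, rho_d = ip$rho_d,
        sample_every = sample_steps)
      state$F <- res$F; state$W <- res$W; state$W_inh <- res$W_inh
      state$F_ex <- res$F_ex; state$t <- res$t
      smp <- as.data.frame(res$samples)
      colnames(smp) <- c("t", "F1", "F2", "FB", "w11", "w22", "w21", "w12",
                         "wB_mean", "inh_11", "inh_22", "inh_12", "inh_21")
      phase_samples[[length(phase_samples) + 1L]] <- smp
      remaining <- remaining - nsteps * dt
      if (check_eq) {
        acc <- do.call(rbind, phase_samples)
        win <- acc[acc$t >= state$t - eq_window, , drop = FALSE]
        if (diff(range(win$t)) >= eq_window - sample_every &&
            max_class_slope(win) < eq_tol) {
          equilibrium <- TRUE
          break
        }
      }
    }
    all_samples[[phase_i]] <- do.call(rbind, phase_samples)
  }

  samples <- do.call(rbind, all_samples)
  rownames(samples) <- NULL
  structure(list(
    samples = samples,
    final_state = state,
    final_averages = population_averages(state, layout),
    equilibrium = equilibrium,
    params = params, layout = layout,
    seed = seed, protocol = protocol
  ), class = "memorg_trajectory")
}

#' @export
print.memorg_trajectory <- function(x, ...) {
  cat(sprintf("Network trajectory: %d neurons, %d samples, t in [%g, %g] s\n",
              x$params$n, nrow(x$samples),
              min(x$samples$t), max(x$samples$t)))
  cat(sprintf("  equilibrium reached: %s\n",
              if (x$equilibrium) "yes" else "no (phase duration limit)"))
  fa <- x$final_averages
  cat(sprintf("  final rates    F1 = %.3f  F2 = %.3f  FB = %.3f\n",
              fa["F1"], fa["F2"], fa["FB"]))
  cat(sprintf("  final weights  w11 = %.3f w22 = %.3f w21 = %.3f w12 = %.3f\n",
              fa["w11"], fa["w22"], fa["w21"], fa["w12"]))
  invisible(x)
}
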