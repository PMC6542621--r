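#' Population layout of the network
#'
#' Assigns deterministic contiguous index blocks: neurons \code{1..n_P} form
#' population 1, \code{(n_P+1)..2n_P} population 2, and the remainder the
#' background population.  Each stimulated population owns an input-layer
#' block of \code{n_Pex} external neurons.
#'
#' @param params a \code{memorg_params} object.
#' @return list of class \code{memorg_layout} with index vectors
#'   \code{pop1}, \code{pop2}, \code{background}, \code{eps1}, \code{eps2}
#'   and a per-neuron population id vector \code{pop_id}
#'   (1, 2 or 0 for background).
#' @export
build_layout <- function(params) {
  n <- params$n; n_P <- params$n_P; n_Pex <- params$n_Pex
  pop1 <- seq_len(n_P)
  pop2 <- seq_len(n_P) + n_P
  background <- if (n > 2L * n_P) seq.int(2L * n_P + 1L, n) else integer(0)
  pop_id <- integer(n)
  pop_id[pop1] <- 1L
  pop_id[pop2] <- 2L
  structure(list(
    pop1 = pop1, pop2 = pop2, background = background,
    eps1 = seq_len(n_Pex), eps2 = seq_len(n_Pex) + n_Pex,
    pop_id = pop_id
  ), class = "memorg_layout")
}

#' Initial network state
#'
#' Excitatory weights start distributed around the balanced state,
#' Normal(theta, sd_w) floored at 0; rates start Normal(0.07, sd_F) clipped
#' to (0,1); inhibitory weights are constant at theta when inhibitory
#' plasticity is off, otherwise Normal(theta, sd_w) clipped to
#' [theta_d, theta_u].
#'
#' @param params a \code{memorg_params} object.
#' @param layout a \code{memorg_layout}; built from \code{params} if missing.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param sd_w,sd_F initial spread of weights and rates.
#' @return list of class \code{memorg_state} with fields \code{t}, \code{F},
#'   \code{W} (row = postsynaptic), \code{W_inh}, \code{F_ex}.
#' @export
init_state <- function(params, layout = build_layout(params), seed = NULL,
                       sd_w = 0.025, sd_F = 0.005) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  W <- matrix(pmax(0, stats::rnorm(n * n, params$theta, sd_w)), n, n)
  F <- pmin(0.999, pmax(0.001, stats::rnorm(n, 0.07, sd_F)))
  ip <- params$inh_plasticity
  if (isTRUE(ip$enabled)) {
    W_inh <- matrix(stats::rnorm(n * n, params$theta, sd_w), n, n)
    W_inh <- pmin(pmax(W_inh, ip$theta_d), ip$theta_u)
  } else {
    W_inh <- matrix(params$theta, n, n)
  }
  structure(list(
    t = 0, F = F, W = W, W_inh = W_inh,
    F_ex = numeric(2L * params$n_Pex)
  ), class = "memorg_state")
}

#' One Euler-Maruyama step of the input-layer Ornstein-Uhlenbeck processes
#'
#' Each input neuron relaxes toward its population target mean with drift
#' constant \code{ou_delta} and receives Gaussian diffusion of scale
#' \code{ou_sigma}.  The printed constants are per-step quantities at the
#' reference step \code{ou_dt0} (1 ms); at step \code{dt} the drift is scaled
#' by \code{dt/ou_dt0} and the diffusion by \code{sqrt(dt/ou_dt0)}.  Rates
#' are clipped to [0, 1].
#'
#' @param F_ex numeric vector of current input-neuron rates.
#' @param targets per-entry target means (recycled).
#' @param params a \code{memorg_params} object.
#' @param dt step size in seconds (defaults to \code{params$dt}).
#' @return updated rate vector.
#' @export
ou_step <- function(F_ex, targets, params, dt = params$dt) {
  stopifnot(dt > 0)
  h <- dt / params$ou_dt0
  x <- F_ex + params$ou_delta * (targets - F_ex) * h +
    params$ou_sigma * sqrt(h) * stats::rnorm(length(F_ex))
  pmin(1, pmax(0, x))
}

#' Dimensionless total drive on each neuron
#'
#' \eqn{g_i = K [ \sum_j (\tilde\omega_{ij} - \tilde\omega^-_{ij}) \tilde F_j
#' + \sum_{k \in \epsilon_{p(i)}} w_{ex} \tilde F^{ex}_k ]}, where the
#' external sum runs over the input-layer block of the neuron's population;
#' background neurons receive the external term \code{ext_background}
#' (their tuning-noise drive, 0 by default).
#'
#' @param state a \code{memorg_state}.
#' @param params a \code{memorg_params}.
#' @param layout a \code{memorg_layout}.
#' @param ext_background optional numeric vector (length of the background
#'   population) of external drive sums for background neurons.
#' @return numeric vector of drives \code{g}.
#' @export
total_drive <- function(state, params, layout = build_layout(params),
                        ext_background = 0) {
  K <- derive_constants(params)$K
  ext <- numeric(params$n)
  ext[layout$pop1] <- params$w_ex * sum(state$F_ex[layout$eps1])
  ext[layout$pop2] <- params$w_ex * sum(state$F_ex[layout$eps2])
  if (length(layout$background))
    ext[layout$background] <- ext_background
  rec <- as.vector((state$W - state$W_inh) %*% state$F)
  K * (rec + ext)
}

#' Time derivative of the normalized firing rates
#'
#' \eqn{\dot{\tilde F}_i = \tau^{-1} (1-\tilde F_i)\tilde F_i
#' [\ln(1/\tilde F_i - 1) + g_i - K n_\epsilon (1-\tilde\theta)]}.
#'
#' @param F vector of normalized rates in (0,1).
#' @param drives vector of dimensionless drives (see
#'   \code{\link{total_drive}}).
#' @param params a \code{memorg_params}.
#' @return vector \code{dF/dt}.
#' @export
activity_derivative <- function(F, drives, params) {
  if (any(!is.finite(F)) || any(!is.finite(drives)))
    stop("non-finite values in the activity state", call. = FALSE)
  dc <- derive_constants(params)
  (1 / params$tau) * (1 - F) * F * (log(1 / F - 1) + drives - dc$beta_eps)
}

#' Time derivative of the excitatory weight matrix
#'
#' Hebbian growth plus quadratic homeostatic scaling toward the target rate:
#' \eqn{\dot{\tilde\omega}_{ij} = \tau_\omega^{-1}[\tilde F_i \tilde F_j +
#' \frac{F_T - \tilde F_i}{1 - F_T}\tilde\omega_{ij}^2]} (row i =
#' postsynaptic; autapses included).
#'
#' @param state a \code{memorg_state} (fields \code{F}, \code{W} used).
#' @param params a \code{memorg_params}.
#' @return matrix \code{dW/dt}.
#' @export
exc_weight_derivative <- function(state, params) {
  tau_w <- derive_constants(params)$tau_w
  F <- state$F
  (outer(F, F) + ((params$F_T - F) / (1 - params$F_T)) * state$W^2) / tau_w
}

#' Time derivative of the inhibitory weight matrix
#'
#' Gated attractor rule: each inhibitory synapse is pulled toward the
#' up-state \code{theta_u} when the rate difference exceeds the tolerance
#' (\eqn{\Delta F > \delta F}) or the rate sum is below threshold
#' (\eqn{\Sigma F < \theta_F}), and toward the down-state \code{theta_d}
#' when \eqn{\Delta F < \delta F} and \eqn{\Sigma F > \theta_F}; both
#' branches are rate-gated by \eqn{\tilde F_i \tilde F_j} and inactive on
#' exact-equality boundaries.
#'
#' @param state a \code{memorg_state} (fields \code{F}, \code{W_inh} used).
#' @param params a \code{memorg_params} with the inhibitory plasticity
#'   block enabled.
#' @return matrix \code{dW_inh/dt}.
#' @export
inh_weight_derivative <- function(state, params) {
  ip <- params$inh_plasticity
  tau_w <- derive_constants(params)$tau_w
  F <- state$F
  SF <- outer(F, F, `+`)
  DF <- abs(outer(F, F, `-`))
  up   <- (DF > ip$delta_F) | (SF < ip$theta_F)
  down <- (DF < ip$delta_F) & (SF > ip$theta_F)
  gate <- outer(F, F)
  (gate * (ip$rho_u * (ip$theta_u - state$W_inh) * up +
           ip$rho_d * (ip$theta_d - state$W_inh) * down)) / tau_w
}

#' One explicit-Euler step of the full network (reference implementation)
#'
#' All derivatives are evaluated on the pre-step state (fully simultaneous
#' update); rates are clipped to (0,1) and excitatory weights floored at 0.
#' This R implementation defines the scheme; \code{\link{simulate_network}}
#' runs the identical update in compiled code.
#'
#' @param state a \code{memorg_state}.
#' @param params a \code{memorg_params}.
#' @param layout a \code{memorg_layout}.
#' @param ext_background external drive sums for background neurons.
#' @return the advanced \code{memorg_state}.
#' @export
step_network <- function(state, params, layout = build_layout(params),
                         ext_background = 0) {
  g <- total_drive(state, params, layout, ext_background)
  dF <- activity_derivative(state$F, g, params)
  dW <- exc_weight_derivative(state, params)
  dt <- params$dt
  new_F <- pmin(pmax(state$F + dt * dF, 1e-6), 1 - 1e-6)
  new_W <- pmax(state$W + dt * dW, 0)
  if (isTRUE(params$inh_plasticity$enabled)) {
    state$W_inh <- state$W_inh + dt * inh_weight_derivative(state, params)
  }
  if (any(!is.finite(new_F)) || any(!is.finite(new_W)))
    stop("non-finite values produced by the Euler step", call. = FALSE)
  state$F <- new_F
  state$W <- new_W
  state$t <- state$t + dt
  state
}

#' Population-averaged state variables
#'
#' Arithmetic means over the index classes of the layout: mean rates of the
#' two stimulated populations and the background, the four mean excitatory
#' weight classes (intra-1, intra-2, inter 1->2, inter 2->1), the mean
#' background-to-population weight, and the four inhibitory class means.
#' Intra-class means include the autapse entries.
#'
#' @param state a \code{memorg_state}.
#' @param layout a \code{memorg_layout}.
#' @return named numeric vector with elements \code{F1, F2, FB, w11, w22,
#'   w21, w12, wB_mean, inh_11, inh_22, inh_12, inh_21}.  \code{w21} is the
#'   mean weight with presynaptic neuron in population 1 and postsynaptic in
#'   population 2.
#' @export
population_averages <- function(state, layout) {
  p1 <- layout$pop1; p2 <- layout$pop2; bg <- layout$background
  c(F1 = mean(state$F[p1]),
    F2 = mean(state$F[p2]),
    FB = if (length(bg)) mean(state$F[bg]) else NA_real_,
    w11 = mean(state$W[p1, p1]),
    w22 = mean(state$W[p2, p2]),
    w21 = mean(state$W[p2, p1]),
    w12 = mean(state$W[p1, p2]),
    wB_mean = if (length(bg)) mean(state$W[c(p1, p2), bg]) else NA_real_,
    inh_11 = mean(state$W_inh[p1, p1]),
    inh_22 = mean(state$W_inh[p2, p2]),
    inh_12 = mean(state$W_inh[p1, p2]),
    inh_21 = mean(state$W_inh[p2, p1]))
}

#' Equilibrium test on a trajectory window
#'
#' TRUE when the largest absolute finite-difference rate of change of every
#' mean synaptic weight class over the window is below \code{tol} (per
#' second).  The window must span at least \code{min_span} seconds.
#'
#' @param window data frame with a \code{t} column and weight-class columns
#'   (any of \code{w11, w22, w21, w12, wB_mean, inh_11, inh_22, inh_12,
#'   inh_21} that are present are used).
#' @param tol tolerance in weight units per second.
#' @param min_span minimal time span of the window in seconds.
#' @return logical flag.
#' @export
equilibrium_reached <- function(window, tol = 1e-5, min_span = 100) {
  if (is.null(dim(window)) || nrow(window) < 2L)
    stop("window must contain at least two samples", call. = FALSE)
  if (diff(range(window$t)) < min_span) return(FALSE)
  cols <- intersect(c("w11", "w22", "w21", "w12", "wB_mean",
                      "inh_11", "inh_22", "inh_12", "inh_21"),
                    colnames(window))
  dtv <- diff(window$t)
  for (cl in cols) {
    r <- abs(diff(window[[cl]])) / dtv
    if (any(is.finite(r) & r >= tol)) return(FALSE)
  }
  TRUE
}
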