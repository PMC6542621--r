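# shared fixtures: a small network for fast dynamical tests and an
# independent ODE oracle for the weight equilibrium

tiny_params <- function(...) {
  model_parameters(modifyList(list(n = 20L, n_P = 4L, n_Pex = 4L), list(...)))
}

# independent oracle: integrate the weight ODE at clamped rates with deSolve
# (falls back to fine-step RK4 by hand if deSolve is unavailable)
integrate_clamped_weight <- function(F_post, F_pre, params, w0 = 0.5,
                                     t_end = 5000 * derive_constants(params)$tau_w) {
  tau_w <- derive_constants(params)$tau_w
  rhs <- function(t, y, parms) {
    list((F_post * F_pre + (params$F_T - F_post) / (1 - params$F_T) * y^2) /
           tau_w)
  }
  if (requireNamespace("deSolve", quietly = TRUE)) {
    out <- deSolve::ode(y = c(w = w0), times = c(0, t_end), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    unname(out[nrow(out), "w"])
  } else {
    h <- tau_w / 200
    w <- w0
    for (i in seq_len(ceiling(t_end / h))) {
      k1 <- rhs(0, w, NULL)[[1]]
      k2 <- rhs(0, w + h / 2 * k1, NULL)[[1]]
      k3 <- rhs(0, w + h / 2 * k2, NULL)[[1]]
      k4 <- rhs(0, w + h * k3, NULL)[[1]]
      w <- w + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    w
  }
}

# deterministic (noise-free) protocol used by invariance tests
quiet_protocol <- function(tuning_t, ou_t, means, noise_mean = 0.05) {
  stim_protocol(
    phase_noise(tuning_t, mean = noise_mean, sd = 0),
    phase_ou(ou_t, means = means, noise_mean = noise_mean, noise_sd = 0,
             until_equilibrium = FALSE))
}
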