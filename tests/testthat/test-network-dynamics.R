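test_that("layout assigns contiguous, disjoint population blocks", {
  p <- model_parameters()
  lay <- build_layout(p)
  expect_length(lay$background, 80L)
  expect_length(intersect(lay$pop1, lay$pop2), 0L)
  lay2 <- build_layout(model_parameters(list(n = 4L, n_P = 1L, n_Pex = 1L)))
  expect_identical(lay2$background, c(3L, 4L))
  # boundary: no background at all
  lay3 <- build_layout(model_parameters(list(n = 2L, n_P = 1L, n_Pex = 1L)))
  expect_length(lay3$background, 0L)
})

test_that("initial states are reproducible and centered on the balanced state", {
  p <- model_parameters()
  s1 <- init_state(p, seed = 7)
  s2 <- init_state(p, seed = 7)
  expect_identical(s1, s2)
  expect_equal(mean(s1$W), 0.5, tolerance = 0.01)
  expect_equal(mean(s1$F), 0.07, tolerance = 0.01)
  expect_true(all(s1$W >= 0))
  expect_true(all(s1$F > 0 & s1$F < 1))
  # zero spread collapses onto the balanced state exactly
  s0 <- init_state(p, seed = 1, sd_w = 0, sd_F = 0)
  expect_true(all(s0$W == 0.5))
  expect_true(all(s0$F == 0.07))
  # plastic inhibitory weights start inside the attractor interval
  pp <- model_parameters(list(inh_plasticity = list(enabled = TRUE)))
  sp <- init_state(pp, seed = 3)
  expect_true(all(sp$W_inh >= 0.5 & sp$W_inh <= 0.8))
})

test_that("OU input steps drift toward the target and match its stationary mean", {
  p <- model_parameters()
  # drift fixed point
  set.seed(1)
  p0 <- p; p0$ou_sigma <- 0
  expect_equal(ou_step(rep(0.9, 4), 0.9, p0), rep(0.9, 4))
  # pure drift approaches the target monotonically
  x <- 0
  path <- replicate(200, x <<- ou_step(x, 0.9, p0))
  expect_true(all(diff(path) >= 0))
  expect_lt(abs(path[200] - 0.9 * (1 - (1 - p$ou_delta)^200)), 1e-9)
  # stationary mean equals the drift target (Monte-Carlo, fixed seed)
  set.seed(42)
  x <- 0.5
  n_it <- 20000
  xs <- numeric(n_it)
  for (i in seq_len(n_it)) xs[i] <- x <- ou_step(x, 0.5, p)
  se <- sd(xs) / sqrt(n_it / 50)   # conservative for autocorrelation
  expect_lt(abs(mean(xs) - 0.5), 3 * se + 1e-3)
})

test_that("total drive reproduces its defining cases", {
  p <- model_parameters(list(n = 4L, n_P = 1L, n_Pex = 1L))
  lay <- build_layout(p)
  st <- init_state(p, lay, seed = 1, sd_w = 0, sd_F = 0)
  K <- derive_constants(p)$K
  # zero rates, zero input -> zero drive
  st$F <- rep(1e-12, 4) * 0
  st$F_ex <- c(0, 0)
  expect_equal(total_drive(st, p, lay), rep(0, 4))
  # balanced weights cancel inhibition exactly
  st$F <- rep(0.3, 4)
  expect_equal(total_drive(st, p, lay), rep(0, 4), tolerance = 1e-12)
  # single saturated presynaptic neuron at maximal weight
  st$F <- c(0, 0, 1, 0)
  st$W[] <- p$theta
  st$W[1, 3] <- 1
  g <- total_drive(st, p, lay)
  expect_equal(g[1], K * (1 - p$theta), tolerance = 1e-12)
  expect_equal(g[1], 0.16579, tolerance = 1e-4)
})

test_that("activity derivative vanishes at the sigmoid fixed point and boundaries", {
  p <- model_parameters()
  dc <- derive_constants(p)
  # inversion: ln(1/F - 1) = beta_eps - g
  g <- 0.8
  Fstar <- 1 / (1 + exp(dc$beta_eps - g))
  expect_equal(activity_derivative(Fstar, g, p), 0, tolerance = 1e-12)
  # zero drive at the defaults (n_eps = 12)
  F0 <- 1 / (1 + exp(dc$K * 12 * 0.5))
  expect_equal(F0, 0.12032, tolerance = 1e-4)
  expect_equal(activity_derivative(F0, 0, p), 0, tolerance = 1e-12)
  # boundary factors force the derivative to zero
  expect_equal(activity_derivative(c(1e-12, 1 - 1e-12), c(0, 0), p),
               c(0, 0), tolerance = 1e-9)
  expect_error(activity_derivative(c(NaN, 0.5), c(0, 0), p), "non-finite")
})

test_that("excitatory weight derivative has the published equilibrium structure", {
  p <- model_parameters(list(n = 2L, n_P = 1L, n_Pex = 1L))
  st <- init_state(p, seed = 1, sd_w = 0, sd_F = 0)
  # saturated rates with maximal weight: 1 + (0.05-1)/0.95 = 0
  st$F <- c(1, 1); st$W[] <- 1
  expect_equal(exc_weight_derivative(st, p), matrix(0, 2, 2),
               tolerance = 1e-12)
  # weights cannot become negative: derivative at w = 0 is positive
  st$F <- c(0.3, 0.4); st$W[] <- 0
  expect_true(all(exc_weight_derivative(st, p) > 0))
  # clamped-rate equilibrium: w* = sqrt(0.19) at F = 0.1
  st$F <- c(0.1, 0.1); st$W[] <- sqrt(0.19)
  expect_equal(exc_weight_derivative(st, p), matrix(0, 2, 2),
               tolerance = 1e-12)
})

test_that("clamped-rate integration converges to the closed form, independent of tau_w", {
  p <- model_parameters()
  rates <- expand.grid(Fi = c(0.12, 0.3, 0.6, 0.9), Fj = c(0.15, 0.5, 0.95))
  for (k in seq_len(nrow(rates))) {
    w_num <- integrate_clamped_weight(rates$Fi[k], rates$Fj[k], p)
    w_cf <- weight_equilibrium(rates$Fj[k], rates$Fi[k], p$F_T)
    expect_equal(w_num, w_cf, tolerance = 1e-3)
  }
  # accelerating the timescales changes transients only
  p_fast <- accelerate_timescales(p, 10)
  expect_equal(integrate_clamped_weight(0.3, 0.5, p_fast),
               integrate_clamped_weight(0.3, 0.5, p), tolerance = 1e-6)
})

test_that("inhibitory plasticity rule gates up- and down-states correctly", {
  p <- model_parameters(list(inh_plasticity = list(enabled = TRUE)))
  tau_w <- derive_constants(p)$tau_w
  st <- init_state(model_parameters(list(
    n = 2L, n_P = 1L, n_Pex = 1L,
    inh_plasticity = list(enabled = TRUE))), seed = 1, sd_w = 0, sd_F = 0)
  p2 <- model_parameters(list(n = 2L, n_P = 1L, n_Pex = 1L,
                              inh_plasticity = list(enabled = TRUE)))
  # silent neurons: rate gate kills all change
  st$F <- c(0, 0)
  expect_equal(inh_weight_derivative(st, p2), matrix(0, 2, 2))
  # similar high rates: down-branch active but already at theta_d
  st$F <- c(0.8, 0.8); st$W_inh[] <- 0.5
  expect_equal(inh_weight_derivative(st, p2), matrix(0, 2, 2))
  # dissimilar high rates: pulled toward the up-state
  st$F <- c(0.9, 0.75); st$W_inh[] <- 0.5
  d <- inh_weight_derivative(st, p2)
  expect_equal(d[1, 2], 0.9 * 0.75 * 1 * (0.8 - 0.5) / tau_w,
               tolerance = 1e-12)
  expect_equal(d[1, 2], 0.2025 / tau_w, tolerance = 1e-12)
  # exact-equality boundary on the rate-sum gate leaves weights untouched
  p3 <- model_parameters(list(n = 2L, n_P = 1L, n_Pex = 1L,
                              inh_plasticity = list(enabled = TRUE,
                                                    theta_F = 1)))
  st$F <- c(0.5, 0.5)      # SF = theta_F exactly, DF = 0 < delta_F
  st$W_inh[] <- 0.6
  expect_equal(inh_weight_derivative(st, p3), matrix(0, 2, 2))
})

test_that("the compiled stepper agrees with the R reference scheme", {
  p <- tiny_params(ou_sigma = 0)
  lay <- build_layout(p)
  dc <- derive_constants(p)
  ip <- p$inh_plasticity
  mean0 <- 0.2
  st_r <- init_state(p, lay, seed = 5)
  st_r$F_ex <- rep(mean0, 2L * p$n_Pex)
  st_c <- st_r
  nsteps <- 50L
  for (s in seq_len(nsteps))
    st_r <- step_network(st_r, p, lay,
                         ext_background = p$w_ex * p$n_Pex * mean0)
  res <- memorg:::simulate_phase_cpp(
    st_c$F, st_c$W, st_c$W_inh, st_c$F_ex, lay$pop_id,
    nsteps, p$dt, 0, 0L, mean0, 0, c(0, 0),
    p$ou_delta, 0, 1, p$n_Pex, p$w_ex,
    dc$K, dc$beta_eps, p$tau, dc$tau_w, p$F_T,
    FALSE, ip$theta_u, ip$theta_d, ip$theta_F, ip$delta_F,
    ip$rho_u, ip$rho_d, nsteps)
  expect_equal(res$F, st_r$F, tolerance = 1e-12)
  expect_equal(res$W, st_r$W, tolerance = 1e-12)
})

test_that("Euler trajectories converge as the step shrinks (3-neuron system)", {
  run_dt <- function(dt) {
    p <- model_parameters(list(n = 3L, n_P = 1L, n_Pex = 1L, dt = dt,
                               ou_sigma = 0))
    lay <- build_layout(p)
    st <- init_state(p, lay, seed = 2)
    st$F_ex <- c(0.6, 0.3)
    for (s in seq_len(round(2 / dt)))
      st <- step_network(st, p, lay, ext_background = 0.1)
    st
  }
  s1 <- run_dt(0.002)
  s2 <- run_dt(0.001)
  s3 <- run_dt(0.0005)
  e12 <- max(abs(s1$F - s2$F))
  e23 <- max(abs(s2$F - s3$F))
  expect_lt(e23, e12)            # first-order error shrinks with dt
  expect_lt(e23 / e12, 0.7)      # roughly halves
  expect_lt(max(abs(s2$F - s3$F)), 1e-3)
})

test_that("stepping preserves the state invariants", {
  p <- tiny_params()
  lay <- build_layout(p)
  st <- init_state(p, lay, seed = 11)
  st$F_ex <- rep(0.7, 2L * p$n_Pex)
  set.seed(1)
  for (s in 1:100) {
    st$F_ex <- ou_step(st$F_ex, rep(c(0.9, 0.2), each = p$n_Pex), p)
    st <- step_network(st, p, lay)
    expect_true(all(st$F > 0 & st$F < 1))
    expect_true(all(st$W >= 0))
  }
  # a derivative-free state stays put
  dc <- derive_constants(p)
  st$W[] <- 1; st$F[] <- 1 - 1e-6; st$F_ex[] <- 0
  before <- st$F
  st2 <- step_network(st, p, lay)
  expect_lt(max(abs(st2$F - before)), 1e-4)
})

test_that("population averages are class means with the expected bounds", {
  p <- tiny_params()
  lay <- build_layout(p)
  st <- init_state(p, lay, seed = 9)
  # uniform weights: every class mean equals the constant
  st$W[] <- 0.37
  pa <- population_averages(st, lay)
  expect_equal(unname(pa[c("w11", "w22", "w21", "w12", "wB_mean")]),
               rep(0.37, 5))
  # block-structured weights: class means recover the block constants
  st$W[lay$pop1, lay$pop1] <- 0.9
  st$W[lay$pop2, lay$pop2] <- 0.8
  st$W[lay$pop2, lay$pop1] <- 0.7
  st$W[lay$pop1, lay$pop2] <- 0.6
  pa <- population_averages(st, lay)
  expect_equal(unname(pa[c("w11", "w22", "w21", "w12")]),
               c(0.9, 0.8, 0.7, 0.6))
  # random state: every mean inside the range of its class entries
  st <- init_state(p, lay, seed = 10)
  pa <- population_averages(st, lay)
  expect_true(pa["w11"] >= min(st$W[lay$pop1, lay$pop1]) &&
              pa["w11"] <= max(st$W[lay$pop1, lay$pop1]))
  expect_true(pa["F1"] >= min(st$F[lay$pop1]) &&
              pa["F1"] <= max(st$F[lay$pop1]))
})

test_that("equilibrium detection accepts constant and rejects drifting windows", {
  tt <- seq(0, 120, by = 1)
  const_win <- data.frame(t = tt, w11 = 0.7, w22 = 0.7, w21 = 0.5, w12 = 0.5)
  expect_true(equilibrium_reached(const_win))
  drift_win <- const_win
  drift_win$w11 <- 0.7 + 1e-3 * tt
  expect_false(equilibrium_reached(drift_win))
  # insufficient span
  expect_false(equilibrium_reached(const_win[1:50, ]))
  expect_error(equilibrium_reached(const_win[1, , drop = FALSE]),
               "two samples")
})
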