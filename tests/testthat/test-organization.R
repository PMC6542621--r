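test_that("memory bounds are the roots of the intra-weight condition", {
  b <- memory_bounds(0.5, 0.05)
  expect_true(b$exists)
  expect_equal(b$F_bar, 0.067119, tolerance = 1e-5)
  expect_equal(b$F_underbar, 0.196039, tolerance = 1e-5)
  expect_equal(b$nm_width, 0.128920, tolerance = 1e-5)
  # each root maps back to the reference weight exactly
  expect_equal(weight_equilibrium(b$F_bar, b$F_bar, 0.05), 0.5,
               tolerance = 1e-12)
  expect_equal(weight_equilibrium(b$F_underbar, b$F_underbar, 0.05), 0.5,
               tolerance = 1e-12)
  # weak inhibition: the no-memory band disappears
  b2 <- memory_bounds(0.3, 0.05)
  expect_false(b2$exists)
  expect_equal(b2$D_disc, 0.09 - 0.19, tolerance = 1e-12)
  # band width identity: theta * sqrt(D) / (1 - F_T)
  for (th in c(0.5, 0.7, 0.9)) {
    b3 <- memory_bounds(th, 0.05)
    expect_equal(b3$nm_width, th * sqrt(th^2 - 0.19) / 0.95,
                 tolerance = 1e-12)
  }
})

test_that("separatrix values and crossing self-consistency", {
  expect_equal(separatrix(1, 0.5, 0.05), 0.25, tolerance = 1e-12)
  # limit toward the target rate
  expect_lt(separatrix(0.05 + 1e-9, 0.5, 0.05), 1e-6)
  expect_error(separatrix(0.04, 0.5, 0.05), "F_other")
  # on the separatrix the directed weight equals the reference
  for (F2 in c(0.2, 0.5, 0.9)) {
    s <- separatrix(F2, 0.5, 0.05)
    expect_equal(weight_equilibrium(s, F2, 0.05), 0.5, tolerance = 1e-12)
  }
})

test_that("weight configurations map onto the published label table", {
  th <- 0.5
  expect_equal(classify_weights(0.9, 0.9, 0.9, 0.9, th, th), "asc")
  expect_equal(classify_weights(0.9, 0.9, 0.9, 0.3, th, th), "s21")
  expect_equal(classify_weights(0.9, 0.9, 0.3, 0.9, th, th), "s12")
  expect_equal(classify_weights(0.9, 0.9, 0.3, 0.3, th, th), "disc")
  expect_equal(classify_weights(0.4, 0.9, 0.9, 0.9, th, th), "nm")
  expect_equal(classify_weights(0.9, 0.4, 0.9, 0.9, th, th), "nm")
  # exact ties resolve to the weaker side
  expect_equal(classify_weights(0.9, 0.9, th, th, th, th), "disc")
  expect_equal(classify_weights(th, 0.9, 0.9, 0.9, th, th), "nm")
})

test_that("activity pairs classify through the implied weights", {
  p <- model_parameters()
  expect_equal(classify_activities(0.92, 0.85, p), "asc")
  expect_equal(classify_activities(0.1, 0.1, p), "nm")
  expect_equal(classify_activities(0.06, 0.5, p), "s12")
  expect_equal(classify_activities(0.5, 0.06, p), "s21")
  expect_error(classify_activities(0.04, 0.5, p), "target rate")
  # label boundaries sit exactly on the separatrices / memory bounds
  b <- memory_bounds(p$theta_P, p$F_T)
  eps <- 1e-6
  # crossing the upper memory bound switches no-memory off (population 1 is
  # still below the separatrix of F2 = 0.9, so the label becomes s12)
  expect_equal(classify_activities(b$F_underbar + eps, 0.9, p), "s12")
  expect_equal(classify_activities(b$F_underbar - eps, 0.9, p), "nm")
  s <- separatrix(0.9, p$theta, p$F_T)
  expect_equal(classify_activities(0.9, s + eps, p), "asc")
  expect_equal(classify_activities(0.9, s - eps, p), "s21")
})

test_that("regime measures partition the parameter plane as published", {
  r3 <- regime_measures(0.5, 0.05)
  expect_equal(r3$D_disc, 0.06, tolerance = 1e-12)
  expect_equal(r3$S, 0.15, tolerance = 1e-12)
  expect_equal(r3$regime, "III")
  r1 <- regime_measures(0.2, 0.05)
  expect_equal(r1$regime, "I")
  r2 <- regime_measures(0.35, 0.05)
  expect_equal(r2$regime, "II")
  # closed-form boundaries
  F_T <- 0.08
  expect_equal(regime_measures(sqrt(2 * F_T) + 1e-9, F_T)$S, 0,
               tolerance = 1e-6)
  expect_equal(regime_measures(sqrt(4 * F_T * (1 - F_T)) + 1e-9, F_T)$D_disc,
               0, tolerance = 1e-6)
})

test_that("plasticity-dominated area and its critical target rate", {
  expect_equal(area_sp(0.05), 0.81, tolerance = 1e-12)
  expect_equal(area_sp(0.25), 0.25, tolerance = 1e-12)
  expect_equal(area_sp(0.5), 0)
  expect_equal(area_sp(0.7), 0)
  expect_equal(critical_target_rate(), 0.5, tolerance = 1e-9)
})

test_that("no memory band always lies below the plasticity-dominated regime", {
  # wherever the band exists, its lower edge stays under 2 F_T
  for (F_T in seq(0.01, 0.49, by = 0.02)) {
    th_min <- sqrt(4 * F_T * (1 - F_T))
    if (th_min >= 1) next
    for (th in seq(min(th_min + 0.01, 0.99), 0.99, length.out = 8)) {
      b <- memory_bounds(th, F_T)
      if (b$exists) expect_lt(b$F_bar, 2 * F_T)
    }
  }
})

test_that("equal inhibition everywhere forbids discrimination", {
  # exhaustive activity grids across a parameter grid
  for (F_T in seq(0.02, 0.4, length.out = 10)) {
    for (th in seq(0.1, 0.9, length.out = 10)) {
      expect_equal(area_disc(th, th, F_T, grid_n = 200), 0)
    }
  }
})

test_that("weaker within-population inhibition opens a discrimination area", {
  expect_gt(area_disc(0.8, 0.5, 0.05), 0)
  expect_equal(area_disc(0.8, 0.8, 0.05), 0)
  expect_equal(area_disc(0.8, 0.85, 0.05), 0)
  sweep <- vapply(seq(0.2, 0.8, by = 0.1), function(tp)
    area_disc(0.8, tp, 0.05), numeric(1))
  expect_true(all(diff(sweep) <= 1e-12))
})

test_that("input phase diagram shows the published corner structure", {
  p <- model_parameters()   # n_eps = 12
  pd <- input_phase_diagram(p, I1 = seq(0, 1, length.out = 5),
                            grid_n = 120)
  expect_equal(pd$label[1, 1], "nm")    # weak inputs: no memory
  nI <- length(pd$I1)
  expect_equal(pd$label[nI, nI], "asc") # strong inputs: association
  # swap symmetry with label transposition
  lt <- t(pd$label)
  lt[lt == "s12"] <- "tmp"; lt[lt == "s21"] <- "s12"; lt[lt == "tmp"] <- "s21"
  expect_equal(pd$label, lt)
  # asymmetric intermediate inputs: sequence from stronger to weaker input
  pd2 <- input_phase_diagram(p, I1 = 0.14, I2 = 0.37, grid_n = 120)
  expect_equal(pd2$label[1, 1], "s12")
  pd3 <- input_phase_diagram(p, I1 = 0.37, I2 = 0.14, grid_n = 120)
  expect_equal(pd3$label[1, 1], "s21")
})

test_that("triple constraint propagation narrows the feasible organizations", {
  labs <- triple_feasibility(
    boxes = list(c(0.65, 0.8), c(0.65, 0.75), c(0.1, 0.95)),
    theta = 0.8, theta_P = 0.5, F_T = 0.05, grid_n = 21)
  expect_equal(labs[["1-2"]], "asc")
  # an unconstrained pair realizes every static organization
  wide <- triple_feasibility(
    boxes = list(c(0.65, 0.8), c(0.051, 0.999), c(0.051, 0.999)),
    theta = 0.8, theta_P = 0.5, F_T = 0.05, grid_n = 41)
  expect_setequal(wide[["2-3"]], c("nm", "disc", "s12", "s21", "asc"))
  # degenerate point boxes give a single label
  pt <- triple_feasibility(
    boxes = list(c(0.7, 0.7), c(0.7, 0.7), c(0.7, 0.7)),
    theta = 0.5, theta_P = 0.5, F_T = 0.05)
  expect_length(pt[["1-2"]], 1L)
})

test_that("parameter phase diagram reproduces the regime contours", {
  pp <- parameter_phase_diagram(F_T_grid = c(0.05), theta_grid = c(0.2, 0.35, 0.5))
  expect_equal(as.vector(pp$regime), c("I", "II", "III"))
  # boundary contours in closed form
  F_T <- 0.1
  pp2 <- parameter_phase_diagram(
    F_T_grid = F_T,
    theta_grid = c(sqrt(2 * F_T) - 0.01, sqrt(2 * F_T) + 0.01,
                   sqrt(4 * F_T * (1 - F_T)) + 0.01))
  expect_equal(as.vector(pp2$regime), c("I", "II", "III"))
})

test_that("inflexion scans recover the published operating windows", {
  p <- model_parameters()
  sc <- nepsilon_scan(p, c(0, 0), n_eps_range = 6:18)
  labs <- sc$table$label
  # association -> no-memory -> scaling-association along the scan
  expect_true(any(labs == "nm"))
  first_nm <- sc$table$n_eps[which(labs == "nm")[1]]
  expect_true(all(labs[sc$table$n_eps < first_nm] == "asc"))
  last_nm <- sc$table$n_eps[max(which(labs == "nm"))]
  expect_true(all(labs[sc$table$n_eps > last_nm] == "asc"))
  # scaling branch: rates below the lower memory bound after the band
  b <- memory_bounds(p$theta, p$F_T)
  tail_rows <- sc$table[sc$table$n_eps > last_nm, ]
  expect_true(all(tail_rows$F1 < b$F_bar))
})
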