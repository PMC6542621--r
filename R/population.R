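#' Equilibrium synaptic weight at clamped rates
#'
#' Setting the plasticity rule \eqn{\dot\omega \propto F_{post}F_{pre} +
#' \frac{F_T - F_{post}}{1-F_T}\omega^2} to zero gives the closed form
#' \deqn{\omega^* = \sqrt{F_{pre} F_{post} (1 - F_T) / (F_{post} - F_T)},}
#' valid for postsynaptic rates above the target rate.  The intra-population
#' case is \code{F_pre = F_post}.
#'
#' @param F_pre,F_post normalized pre- and postsynaptic rates (vectorized).
#' @param F_T normalized target rate.
#' @return equilibrium weight(s).
#' @export
#' @examples
#' weight_equilibrium(0.1, 0.1, 0.05)  # sqrt(0.19) = 0.43589
weight_equilibrium <- function(F_pre, F_post, F_T = 0.05) {
  if (any(F_post <= F_T))
    stop("no fixed point below the target rate (F_post <= F_T)",
         call. = FALSE)
  sqrt(F_pre * F_post * (1 - F_T) / (F_post - F_T))
}

#' Dimensionless drive on a population at equilibrium
#'
#' Folds the adiabatically eliminated weights into the drive of the reduced
#' two-population system:
#' \deqn{g_p = K n_P [ I_p + \sum_{p'} (w_{p p'} - \tilde\theta_{p p'})
#'   F_{p'} ],}
#' with \eqn{w_{p p'}} the equilibrium weight (postsynaptic population p)
#' and the inhibitory reference \code{theta_P} for \eqn{p' = p},
#' \code{theta} otherwise.
#'
#' @param F1,F2 population rates (each above \code{F_T}).
#' @param input length-2 vector of folded inputs \code{c(I1, I2)}.
#' @param params a \code{memorg_params}.
#' @return length-2 vector of drives \code{c(g1, g2)}.
#' @export
population_drive <- function(F1, F2, input, params) {
  K <- derive_constants(params)$K
  F_T <- params$F_T
  w11 <- weight_equilibrium(F1, F1, F_T)
  w22 <- weight_equilibrium(F2, F2, F_T)
  w12 <- weight_equilibrium(F2, F1, F_T)  # pre 2 -> post 1
  w21 <- weight_equilibrium(F1, F2, F_T)  # pre 1 -> post 2
  g1 <- K * params$n_P *
    (input[1] + (w11 - params$theta_P) * F1 + (w12 - params$theta) * F2)
  g2 <- K * params$n_P *
    (input[2] + (w22 - params$theta_P) * F2 + (w21 - params$theta) * F1)
  c(g1, g2)
}

#' Fixed-point residual of a population's activity equation
#'
#' The nontrivial bracket of the reduced activity equation:
#' \eqn{\ln(1/F_p - 1) + g_p - K n_\epsilon (1-\tilde\theta)}.  Interior
#' equilibria are its roots; the boundary roots of the full equation at 0
#' and 1 are not reported.
#'
#' @param F_p rate of the population under consideration.
#' @param F_other rate of the other population.
#' @param I_p folded input to the population.
#' @param I_other folded input to the other population.
#' @param params a \code{memorg_params}.
#' @param pop which population (1 or 2) \code{F_p} refers to; relevant only
#'   when \code{theta_P != theta} (the system is otherwise symmetric).
#' @return residual value.
#' @export
fp_residual <- function(F_p, F_other, I_p, params, I_other = 0, pop = 1L) {
  dc <- derive_constants(params)
  if (pop == 1L) {
    g <- population_drive(F_p, F_other, c(I_p, I_other), params)[1L]
  } else {
    g <- population_drive(F_other, F_p, c(I_other, I_p), params)[2L]
  }
  log(1 / F_p - 1) + g - dc$beta_eps
}

# vectorized residual matrices over a rate grid (both populations),
# used by the fixed-point scan; returns list(R1, R2) with R1[i,j] the
# residual of population 1 at (F1 = f[i], F2 = f[j]).
residual_grid <- function(f, input, params) {
  dc <- derive_constants(params)
  K <- dc$K; F_T <- params$F_T; nP <- params$n_P
  wpp <- sqrt(f * f * (1 - F_T) / (f - F_T))          # intra, per rate
  # w_post_pre[i, j] = weight pre rate f[j] -> post rate f[i]
  wpost <- sqrt(outer(f * (1 - F_T) / (f - F_T), f))
  lg <- log(1 / f - 1)
  G1 <- K * nP * (input[1] + (wpp - params$theta_P) * f)          # by F1
  G2 <- K * nP * (input[2] + (wpp - params$theta_P) * f)          # by F2
  cross1 <- K * nP * (wpost - params$theta) * rep(f, each = length(f))
  # cross1[i,j]: contribution of F2 = f[j] to population 1 at F1 = f[i]
  R1 <- lg + G1 - dc$beta_eps + cross1
  # R2[i, j]: residual of population 2 at (F1 = f[i], F2 = f[j])
  R2 <- matrix(lg + G2 - dc$beta_eps, nrow = length(f),
               ncol = length(f), byrow = TRUE) +
    t(K * nP * (wpost - params$theta) * rep(f, each = length(f)))
  list(R1 = R1, R2 = R2)
}

#' Nullcline of one population
#'
#' All roots \eqn{F_p} of \code{\link{fp_residual}} on the admissible
#' interval \eqn{(F_T, 1)} for a fixed rate of the other population,
#' obtained by a sign-change scan refined by bisection.
#'
#' @param F_other rate of the other population.
#' @param I_p folded input to this population.
#' @param params a \code{memorg_params}.
#' @param grid_n number of scan points (>= 100).
#' @param I_other folded input to the other population (enters only through
#'   symmetry bookkeeping; the residual of population p does not depend on
#'   it).
#' @param pop which population (1 or 2).
#' @return numeric vector of roots (possibly empty).
#' @export
nullcline <- function(F_other, I_p, params, grid_n = 400, I_other = 0,
                      pop = 1L) {
  stopifnot(grid_n >= 100)
  lo <- params$F_T + 1e-6
  hi <- 1 - 1e-6
  f <- seq(lo, hi, length.out = grid_n)
  r <- vapply(f, fp_residual, numeric(1), F_other = F_other, I_p = I_p,
              params = params, I_other = I_other, pop = pop)
  idx <- which(r[-1] * r[-length(r)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(x)
      fp_residual(x, F_other, I_p, params, I_other, pop),
      lower = f[i], upper = f[i + 1], tol = 1e-10)$root
  }, numeric(1))
  exact <- f[r == 0]
  sort(unique(c(roots, exact)))
}

# 2x2 Jacobian (finite differences) of the reduced adiabatic dynamics
# dF_p/dt = (1/tau)(1-F_p)F_p * residual_p at a point.
reduced_jacobian <- function(F1, F2, input, params, h = 1e-7) {
  vf <- function(x) {
    r1 <- fp_residual(x[1], x[2], input[1], params, input[2], pop = 1L)
    r2 <- fp_residual(x[2], x[1], input[2], params, input[1], pop = 2L)
    c((1 - x[1]) * x[1] * r1, (1 - x[2]) * x[2] * r2) / params$tau
  }
  x0 <- c(F1, F2)
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- h
    J[, k] <- (vf(x0 + e) - vf(x0 - e)) / (2 * h)
  }
  J
}

# damped Newton polish of a candidate fixed point; returns c(F1, F2) or NULL
newton_polish <- function(x0, input, params, lo, hi, tol = 1e-12,
                          maxit = 60) {
  res <- function(x) c(
    fp_residual(x[1], x[2], input[1], params, input[2], pop = 1L),
    fp_residual(x[2], x[1], input[2], params, input[1], pop = 2L))
  x <- x0
  for (it in seq_len(maxit)) {
    r <- res(x)
    if (max(abs(r)) < tol) return(x)
    h <- 1e-7
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      xp <- pmin(hi, pmax(lo, x + e)); xm <- pmin(hi, pmax(lo, x - e))
      J[, k] <- (res(xp) - res(xm)) / (xp[k] - xm[k])
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- pmin(hi, pmax(lo, x - lambda * step))
      if (max(abs(res(xn))) < max(abs(r)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) < 1e-14) {x <- xn; break}
    x <- xn
  }
  if (max(abs(res(x))) < 1e-9) x else NULL
}

#' Fixed points of the reduced two-population system
#'
#' Locates all interior equilibria of the population activity equations on
#' the admissible square \eqn{(F_T, 1)^2} by a grid scan for sign changes of
#' both residuals followed by a damped-Newton polish; duplicates are merged,
#' stability is read off the numerical Jacobian of the reduced adiabatic
#' dynamics, and each point is labeled via
#' \code{\link{classify_activities}}.
#'
#' @param input length-2 vector \code{c(I1, I2)} of folded population
#'   inputs.
#' @param params a \code{memorg_params}.
#' @param grid_n scan resolution per axis.
#' @return object of class \code{memorg_fps}: data frame with columns
#'   \code{F1, F2, w11, w22, w21, w12, stable, label, converged} and
#'   attributes \code{bistable} (>= 2 stable points) and \code{input}.
#' @export
#' @examples
#' fps <- find_fixed_points(c(0, 0), model_parameters())
#' fps
find_fixed_points <- function(input, params, grid_n = 200) {
  lo <- params$F_T + 1e-6
  hi <- 1 - 1e-6
  f <- seq(lo, hi, length.out = grid_n)
  rg <- residual_grid(f, input, params)
  s1 <- rg$R1 > 0
  s2 <- rg$R2 > 0
  # cells whose corners show a sign change in both residuals
  cand <- which(
    (s1[-grid_n, -grid_n] != s1[-1, -grid_n] |
     s1[-grid_n, -grid_n] != s1[-grid_n, -1] |
     s1[-grid_n, -grid_n] != s1[-1, -1]) &
    (s2[-grid_n, -grid_n] != s2[-1, -grid_n] |
     s2[-grid_n, -grid_n] != s2[-grid_n, -1] |
     s2[-grid_n, -grid_n] != s2[-1, -1]), arr.ind = TRUE)
  pts <- list(); conv <- logical(0)
  if (nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      x0 <- c((f[i] + f[i + 1]) / 2, (f[j] + f[j + 1]) / 2)
      x <- newton_polish(x0, input, params, lo, hi)
      if (is.null(x)) {
        pts[[length(pts) + 1L]] <- x0; conv <- c(conv, FALSE)
      } else {
        pts[[length(pts) + 1L]] <- x; conv <- c(conv, TRUE)
      }
    }
  }
  # merge duplicates (polished roots take precedence over flagged cells)
  ord <- order(!conv)
  pts <- pts[ord]; conv <- conv[ord]
  keep <- list(); keep_conv <- logical(0)
  for (k in seq_along(pts)) {
    dup <- FALSE
    for (m in seq_along(keep))
      if (max(abs(pts[[k]] - keep[[m]])) < 1e-6) { dup <- TRUE; break }
    if (!dup) {
      keep[[length(keep) + 1L]] <- pts[[k]]
      keep_conv <- c(keep_conv, conv[k])
    }
  }
  n_fp <- length(keep)
  out <- data.frame(F1 = numeric(n_fp), F2 = numeric(n_fp),
                    w11 = numeric(n_fp), w22 = numeric(n_fp),
                    w21 = numeric(n_fp), w12 = numeric(n_fp),
                    stable = logical(n_fp), label = character(n_fp),
                    converged = logical(n_fp))
  for (k in seq_len(n_fp)) {
    F1 <- keep[[k]][1]; F2 <- keep[[k]][2]
    # only polished roots qualify as equilibria; unconverged candidates are
    # reported (flagged) but never counted as stable states
    stable <- FALSE
    if (keep_conv[k]) {
      J <- reduced_jacobian(F1, F2, input, params)
      stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
    }
    out[k, c("F1", "F2")] <- c(F1, F2)
    out$w11[k] <- weight_equilibrium(F1, F1, params$F_T)
    out$w22[k] <- weight_equilibrium(F2, F2, params$F_T)
    out$w21[k] <- weight_equilibrium(F1, F2, params$F_T)
    out$w12[k] <- weight_equilibrium(F2, F1, params$F_T)
    out$stable[k] <- stable
    out$label[k] <- classify_activities(F1, F2, params)
    out$converged[k] <- keep_conv[k]
  }
  structure(out, class = c("memorg_fps", "data.frame"),
            bistable = sum(out$stable & out$converged) >= 2L, input = input)
}

#' @export
print.memorg_fps <- function(x, ...) {
  inp <- attr(x, "input")
  cat(sprintf("Fixed points of the reduced model at I = (%g, %g):\n",
              inp[1], inp[2]))
  if (!nrow(x)) {
    cat("  none in the interior (F_T, 1)^2\n")
  } else {
    print.data.frame(cbind(round(x[, 1:6], 5), x[, 7:9]), row.names = FALSE)
  }
  cat(sprintf("  bistable: %s\n", attr(x, "bistable")))
  invisible(x)
}

#' Fixed point reached from a given initial condition
#'
#' Forward-integrates the reduced adiabatic dynamics
#' \eqn{\dot F_p \propto (1-F_p)F_p\,r_p(F_1,F_2)} from \code{init} until
#' the motion stalls, selecting the attractor a simulation started at the
#' network's initial rates would reach.  In bistable input regimes the
#' result is init-dependent.
#'
#' @param input length-2 folded input vector.
#' @param params a \code{memorg_params}.
#' @param init initial rate pair (default \code{c(0.07, 0.07)}, the full
#'   simulation's initial rate level).
#' @param dt integration step (in units of \code{tau}).
#' @param t_max maximal integration time.
#' @return one-row \code{memorg_fps}-style data frame (with label and
#'   stability), or an error if the integration does not settle.
#' @export
reachable_fixed_point <- function(input, params, init = c(0.07, 0.07),
                                  dt = 0.05, t_max = 5000) {
  lo <- params$F_T + 1e-6
  hi <- 1 - 1e-6
  x <- pmin(hi, pmax(lo, init))
  t <- 0
  # per-component step control: the vector field is stiff on the scaling
  # branch (equilibrium weights diverge as rates approach F_T), so the step
  # is halved on a sign flip of the derivative and grown slowly otherwise
  h <- rep(dt, 2)
  d_prev <- c(0, 0)
  repeat {
    r1 <- fp_residual(x[1], x[2], input[1], params, input[2], pop = 1L)
    r2 <- fp_residual(x[2], x[1], input[2], params, input[1], pop = 2L)
    d <- c((1 - x[1]) * x[1] * r1, (1 - x[2]) * x[2] * r2) / params$tau
    flip <- d * d_prev < 0
    h[flip] <- pmax(h[flip] * 0.5, 1e-6)
    h[!flip] <- pmin(h[!flip] * 1.05, dt)
    d_prev <- d
    x_new <- pmin(hi, pmax(lo, x + h * d))
    moved <- max(abs(x_new - x))
    x <- x_new
    t <- t + max(h)
    if (max(abs(d)) < 1e-10 || moved < 1e-14) break
    if (t > t_max)
      stop("reduced dynamics did not settle within t_max", call. = FALSE)
  }
  polished <- newton_polish(x, input, params, lo, hi)
  if (!is.null(polished)) x <- polished
  J <- reduced_jacobian(x[1], x[2], input, params)
  data.frame(
    F1 = x[1], F2 = x[2],
    w11 = weight_equilibrium(x[1], x[1], params$F_T),
    w22 = weight_equilibrium(x[2], x[2], params$F_T),
    w21 = weight_equilibrium(x[1], x[2], params$F_T),
    w12 = weight_equilibrium(x[2], x[1], params$F_T),
    stable = all(Re(eigen(J, only.values = TRUE)$values) < 0),
    label = classify_activities(x[1], x[2], params),
    converged = !is.null(polished))
}

#' Fold full-network inputs onto the reduced input plane
#'
#' Places a full-network run on the \eqn{(\Im_1, \Im_2)} plane of the
#' reduced model: \eqn{I_p = \tilde F^{ex}_p w_{ex} +
#' (n_B/n_P^{ex}) \tilde F_B\, w_{pB}}.  With
#' \code{params$background_inhibition_corrected = TRUE} the background term
#' is inhibition-corrected, \eqn{(n_B/n_P^{ex}) \tilde F_B (w_{pB} -
#' \tilde\theta)}, which is the folding consistent with the full-network
#' drive algebra.
#'
#' @param F1ex,F2ex external input means of the two populations.
#' @param F_B background rate.
#' @param w_pB length-1 or -2 mean background-to-population weight.
#' @param params a \code{memorg_params}.
#' @return length-2 input vector \code{c(I1, I2)}.
#' @export
map_network_inputs <- function(F1ex, F2ex, F_B, w_pB, params) {
  w_pB <- rep_len(w_pB, 2L)
  n_B <- params$n - 2L * params$n_P
  corr <- if (isTRUE(params$background_inhibition_corrected))
    params$theta else 0
  c(F1ex * params$w_ex + n_B / params$n_Pex * F_B * (w_pB[1] - corr),
    F2ex * params$w_ex + n_B / params$n_Pex * F_B * (w_pB[2] - corr))
}
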