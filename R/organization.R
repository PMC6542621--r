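#' Memory-state bounds in activity space
#'
#' A population is a memory representation when its intra-population
#' equilibrium weight exceeds the inhibitory reference
#' \code{theta_intra}.  Solving
#' \code{weight_equilibrium(F, F, F_T) = theta_intra} gives the quadratic
#' \eqn{(1-F_T)F^2 - \tilde\theta^2 F + \tilde\theta^2 F_T = 0}; its two
#' roots (when real and inside \eqn{(F_T, 1)}) delimit the no-memory band:
#' below \code{F_bar} the scaling branch keeps the weight above inhibition,
#' above \code{F_underbar} the correlation branch does.
#'
#' @param theta_intra inhibitory reference weight for the intra-population
#'   comparison.
#' @param F_T normalized target rate.
#' @return list of class \code{memorg_bounds}: \code{exists}, \code{F_bar}
#'   (upper edge of the lower memory interval), \code{F_underbar} (lower
#'   edge of the upper memory interval), \code{nm_width}, and the
#'   discriminant \code{D_disc}.
#' @export
#' @examples
#' memory_bounds(0.5, 0.05)  # roots 0.067119 and 0.196039
memory_bounds <- function(theta_intra, F_T) {
  stopifnot(theta_intra > 0, theta_intra < 1, F_T > 0, F_T < 1)
  D_disc <- theta_intra^2 - 4 * F_T * (1 - F_T)
  if (D_disc < 0) {
    return(structure(list(exists = FALSE, F_bar = NA_real_,
                          F_underbar = NA_real_, nm_width = 0,
                          D_disc = D_disc), class = "memorg_bounds"))
  }
  D <- sqrt(D_disc)
  F_bar <- (theta_intra^2 - theta_intra * D) / (2 * (1 - F_T))
  F_underbar <- (theta_intra^2 + theta_intra * D) / (2 * (1 - F_T))
  exists <- F_bar > F_T && F_underbar < 1
  structure(list(exists = exists, F_bar = F_bar, F_underbar = F_underbar,
                 nm_width = F_underbar - F_bar, D_disc = D_disc),
            class = "memorg_bounds")
}

#' Separatrix between directed functional relations
#'
#' The presynaptic rate at which the directed equilibrium inter-population
#' weight equals the inhibitory reference \code{theta}:
#' \deqn{S(F_{other}) = \tilde\theta^2 (1 - F_T/F_{other}) / (1 - F_T).}
#' A presynaptic rate above the separatrix makes the directed weight exceed
#' inhibition (the relation becomes excitatory-dominated).
#'
#' @param F_other rate of the postsynaptic population (must exceed
#'   \code{F_T}).
#' @param theta inhibitory reference weight.
#' @param F_T normalized target rate.
#' @return threshold presynaptic rate (vectorized in \code{F_other}).
#' @export
#' @examples
#' separatrix(1, 0.5, 0.05)  # theta^2 = 0.25
separatrix <- function(F_other, theta, F_T) {
  if (any(F_other <= F_T))
    stop("separatrix undefined for F_other <= F_T", call. = FALSE)
  theta^2 * (1 - F_T / F_other) / (1 - F_T)
}

#' Classify a weight configuration into a functional organization
#'
#' Applies the weight-based definitions: no memory (\code{nm}) when either
#' intra-population weight fails to exceed its inhibitory reference;
#' otherwise the two directed inter-population weights are compared against
#' their references, giving discrimination (\code{disc}, both below),
#' sequence (\code{s21}/\code{s12}, one above) or association (\code{asc},
#' both above).  Ties resolve to the non-exceeding side (tolerance 1e-9).
#'
#' @param w11,w22 intra-population mean excitatory weights.
#' @param w21 mean weight presynaptic population 1 -> postsynaptic 2.
#' @param w12 mean weight presynaptic population 2 -> postsynaptic 1.
#' @param theta_inter inhibitory reference(s) for the inter comparisons
#'   (length 1 or 2: references for w21 and w12).
#' @param theta_intra inhibitory reference(s) for the intra comparisons
#'   (length 1 or 2: references for w11 and w22).
#' @return one of \code{"nm"}, \code{"disc"}, \code{"s12"}, \code{"s21"},
#'   \code{"asc"}.
#' @export
#' @examples
#' classify_weights(0.9, 0.9, 0.9, 0.3, 0.5, 0.5)  # "s21"
classify_weights <- function(w11, w22, w21, w12, theta_inter, theta_intra) {
  tol <- 1e-9
  theta_intra <- rep_len(theta_intra, 2L)
  theta_inter <- rep_len(theta_inter, 2L)
  if (w11 <= theta_intra[1] + tol || w22 <= theta_intra[2] + tol)
    return("nm")
  up21 <- w21 > theta_inter[1] + tol
  up12 <- w12 > theta_inter[2] + tol
  if (up21 && up12) "asc"
  else if (up21) "s21"
  else if (up12) "s12"
  else "disc"
}

#' Classify a pair of population activities
#'
#' Computes the implied equilibrium weights at the given rates and applies
#' \code{\link{classify_weights}} with the within-population inhibitory
#' reference \code{params$theta_P} and the inter-population reference
#' \code{params$theta}.
#'
#' @param F1,F2 population rates in \eqn{(F_T, 1)}.
#' @param params a \code{memorg_params}.
#' @return organization label (see \code{\link{classify_weights}}).
#' @export
#' @examples
#' classify_activities(0.1, 0.1, model_parameters())    # "nm"
#' classify_activities(0.92, 0.85, model_parameters())  # "asc"
classify_activities <- function(F1, F2, params) {
  F_T <- params$F_T
  classify_weights(
    w11 = weight_equilibrium(F1, F1, F_T),
    w22 = weight_equilibrium(F2, F2, F_T),
    w21 = weight_equilibrium(F1, F2, F_T),
    w12 = weight_equilibrium(F2, F1, F_T),
    theta_inter = params$theta,
    theta_intra = params$theta_P)
}

#' Regime measures of the parameter plane
#'
#' Two scalar measures partition the (target rate, inhibition) parameter
#' plane: the discriminant \eqn{D_{disc} = \tilde\theta^2 - 4F_T(1-F_T)}
#' (no-memory band exists when positive) and
#' \eqn{S = \tilde\theta^2 - 2F_T} (separatrices reach into the
#' plasticity-dominated activity regime when positive).  Regime I
#' (\eqn{D_{disc}<0, S<0}): only associations; regime II
#' (\eqn{D_{disc}<0, S>0}): associations and sequences; regime III
#' (\eqn{D_{disc}>0, S>0}): associations, sequences and the no-memory
#' state.
#'
#' @param theta inhibitory weight.
#' @param F_T normalized target rate.
#' @return list of class \code{memorg_regime}: \code{D_disc}, \code{D}
#'   (\code{sqrt(D_disc)} when non-negative, else \code{NA}), \code{S},
#'   \code{A_SP}, \code{regime}.
#' @export
#' @examples
#' regime_measures(0.5, 0.05)$regime  # "III"
regime_measures <- function(theta, F_T) {
  D_disc <- theta^2 - 4 * F_T * (1 - F_T)
  S <- theta^2 - 2 * F_T
  regime <- if (D_disc < 0 && S < 0) "I"
    else if (D_disc < 0 && S > 0) "II"
    else if (D_disc > 0 && S > 0) "III"
    else "other"
  structure(list(D_disc = D_disc,
                 D = if (D_disc >= 0) sqrt(D_disc) else NA_real_,
                 S = S, A_SP = area_sp(F_T), regime = regime),
            class = "memorg_regime")
}

#' Area of the plasticity-dominated activity regime
#'
#' The square \eqn{[2F_T, 1]^2} of the activity plane in which
#' correlation-based plasticity (rather than homeostatic up-scaling)
#' governs the equilibrium weights; its area is \eqn{(1-2F_T)^2} for
#' \eqn{F_T < 0.5} and zero beyond.
#'
#' @param F_T normalized target rate in (0,1) (vectorized).
#' @return area value(s).
#' @export
area_sp <- function(F_T) {
  stopifnot(all(F_T > 0), all(F_T < 1))
  ifelse(F_T < 0.5, (1 - 2 * F_T)^2, 0)
}

#' Critical target rate at which the plasticity-dominated regime vanishes
#'
#' Finds the smallest target rate with \code{area_sp(F_T) = 0} by bisection
#' on the (non-increasing) area function.
#'
#' @param tol bisection tolerance.
#' @return the critical normalized target rate.
#' @export
critical_target_rate <- function(tol = 1e-12) {
  lo <- 1e-9
  hi <- 1 - 1e-9
  # area_sp is non-increasing: bisect for the first zero
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (area_sp(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Area of the discrimination regime in activity space
#'
#' Fraction of the admissible activity square \eqn{(F_T, 1)^2} classified
#' as discrimination under within-population inhibition \code{theta_P} and
#' inter-population inhibition \code{theta}, by uniform-grid integration.
#' Zero whenever \code{theta_P >= theta} (discrimination requires weaker
#' inhibition inside the populations than between them).
#'
#' @param theta inter-population inhibitory weight.
#' @param theta_P within-population inhibitory weight.
#' @param F_T normalized target rate.
#' @param grid_n grid resolution per axis (>= 200).
#' @return fraction in [0, 1] of the admissible square.
#' @export
area_disc <- function(theta, theta_P, F_T, grid_n = 300) {
  stopifnot(grid_n >= 200)
  f <- seq(F_T + 1e-6, 1 - 1e-6, length.out = grid_n)
  # disc at (F1, F2): both intra weights above theta_P, both inter weights
  # below theta; all four comparisons reduce to closed-form thresholds.
  b <- memory_bounds(theta_P, F_T)
  mem <- if (b$exists) (f < b$F_bar) | (f > b$F_underbar)
         else rep(TRUE, grid_n)
  sep <- separatrix(f, theta, F_T)   # threshold on the presynaptic rate
  # disc[i, j] (F1 = f[i], F2 = f[j]): memory in both and
  # F1 < sep(F2)  (w21 < theta)  and  F2 < sep(F1)  (w12 < theta)
  below21 <- outer(f, sep, `<`)       # F1[i] < sep(F2[j])
  below12 <- t(below21)               # F2[j] < sep(F1[i])
  disc <- outer(mem, mem, `&`) & below21 & below12
  mean(disc)
}

#' Input phase diagram of functional organizations
#'
#' Evaluates \code{\link{find_fixed_points}} on a grid of folded input
#' pairs and records, per cell, the organization label of the unique stable
#' fixed point, \code{"bs"} when at least two stable points coexist, and
#' \code{"nm"} when no interior fixed point exists.
#'
#' @param params a \code{memorg_params}.
#' @param I1,I2 numeric grid vectors of folded inputs.
#' @param grid_n fixed-point scan resolution per cell.
#' @return object of class \code{memorg_phase}: list with \code{I1},
#'   \code{I2}, matrices \code{label}, \code{n_stable}, \code{F1},
#'   \code{F2} (reachable/stable rates), \code{flagged} (solver
#'   non-convergence), and the parameter echo.
#' @export
input_phase_diagram <- function(params, I1 = seq(0, 1, length.out = 21),
                                I2 = I1, grid_n = 150) {
  label <- matrix(NA_character_, length(I1), length(I2))
  n_stable <- matrix(0L, length(I1), length(I2))
  F1m <- matrix(NA_real_, length(I1), length(I2))
  F2m <- matrix(NA_real_, length(I1), length(I2))
  flagged <- matrix(FALSE, length(I1), length(I2))
  for (i in seq_along(I1)) for (j in seq_along(I2)) {
    fps <- find_fixed_points(c(I1[i], I2[j]), params, grid_n = grid_n)
    st <- fps[fps$stable, , drop = FALSE]
    n_stable[i, j] <- nrow(st)
    flagged[i, j] <- any(!fps$converged)
    if (nrow(st) == 0L) {
      label[i, j] <- "nm"
    } else if (nrow(st) >= 2L) {
      label[i, j] <- "bs"
      F1m[i, j] <- st$F1[1]; F2m[i, j] <- st$F2[1]
    } else {
      label[i, j] <- st$label
      F1m[i, j] <- st$F1; F2m[i, j] <- st$F2
    }
  }
  structure(list(I1 = I1, I2 = I2, label = label, n_stable = n_stable,
                 F1 = F1m, F2 = F2m, flagged = flagged, params = params),
            class = "memorg_phase")
}

#' @export
print.memorg_phase <- function(x, ...) {
  cat(sprintf("Input phase diagram: %d x %d grid\n",
              length(x$I1), length(x$I2)))
  tb <- table(x$label)
  cat("  labels: ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "),
      "\n")
  invisible(x)
}

#' Scan of the activation-threshold position
#'
#' For each value of \code{n_eps} (the sigmoid inflexion in units of the
#' maximal single-synapse potential), computes the fixed point reached from
#' the default initial rates at the given input, with its organization
#' label.  Also reports the \code{n_eps} whose reached rate is closest to
#' the plasticity-dominance threshold \code{F_min = 2 F_T}, and the label
#' transition boundaries along the scan.
#'
#' @param params a \code{memorg_params} (its \code{n_eps} is overridden).
#' @param input length-2 folded input vector.
#' @param n_eps_range integer vector of inflexion values to scan.
#' @param init initial rate pair for the reachability integration.
#' @return list of class \code{memorg_scan}: data frame \code{table}
#'   (\code{n_eps, F1, F2, label}), \code{n_eps_opt} (argmin
#'   \eqn{|F - F_{min}|}), and \code{transitions} (data frame of label
#'   changes).
#' @export
nepsilon_scan <- function(params, input = c(0, 0), n_eps_range = 1:35,
                          init = c(0.07, 0.07)) {
  rows <- lapply(n_eps_range, function(ne) {
    p <- params; p$n_eps <- ne
    fp <- reachable_fixed_point(input, p, init = init)
    data.frame(n_eps = ne, F1 = fp$F1, F2 = fp$F2, label = fp$label)
  })
  tab <- do.call(rbind, rows)
  F_min <- 2 * params$F_T
  dist <- abs(tab$F1 - F_min)
  trans_idx <- which(tab$label[-1] != tab$label[-nrow(tab)])
  transitions <- data.frame(
    n_eps_before = tab$n_eps[trans_idx],
    n_eps_after = tab$n_eps[trans_idx + 1L],
    from = tab$label[trans_idx],
    to = tab$label[trans_idx + 1L])
  structure(list(table = tab,
                 n_eps_opt = tab$n_eps[which.min(dist)],
                 transitions = transitions),
            class = "memorg_scan")
}

#' @export
print.memorg_scan <- function(x, ...) {
  cat("Inflexion-point scan:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  n_eps closest to F_min: %d\n", x$n_eps_opt))
  invisible(x)
}

#' Parameter phase diagram over target rate and inhibition
#'
#' Evaluates \code{\link{regime_measures}} on a grid of \code{(F_T, theta)}
#' pairs; the contours \eqn{\tilde\theta = \sqrt{2F_T}} (S = 0) and
#' \eqn{\tilde\theta = \sqrt{4F_T(1-F_T)}} (D = 0) bound the three regimes.
#'
#' @param F_T_grid,theta_grid numeric grid vectors.
#' @param inputs optional list of cells (list of \code{c(F_T, theta)}) at
#'   which a nested \code{\link{input_phase_diagram}} is computed.
#' @param params base parameters for the nested diagrams.
#' @return list of class \code{memorg_param_phase}: grids, \code{regime}
#'   character matrix, \code{D_disc} and \code{S} matrices, and
#'   \code{nested} diagrams (possibly empty).
#' @export
parameter_phase_diagram <- function(F_T_grid = seq(0.01, 0.49, by = 0.02),
                                    theta_grid = seq(0.05, 0.95, by = 0.05),
                                    inputs = list(),
                                    params = model_parameters()) {
  regime <- matrix(NA_character_, length(F_T_grid), length(theta_grid))
  Dm <- matrix(NA_real_, length(F_T_grid), length(theta_grid))
  Sm <- matrix(NA_real_, length(F_T_grid), length(theta_grid))
  for (i in seq_along(F_T_grid)) for (j in seq_along(theta_grid)) {
    rm_ <- regime_measures(theta_grid[j], F_T_grid[i])
    regime[i, j] <- rm_$regime
    Dm[i, j] <- rm_$D_disc
    Sm[i, j] <- rm_$S
  }
  nested <- lapply(inputs, function(cell) {
    p <- params
    p$F_T <- cell[1]; p$theta <- cell[2]; p$theta_P <- cell[2]
    input_phase_diagram(p, I1 = seq(0, 1, length.out = 11))
  })
  structure(list(F_T = F_T_grid, theta = theta_grid, regime = regime,
                 D_disc = Dm, S = Sm, nested = nested),
            class = "memorg_param_phase")
}

#' Feasible organizations among three constrained populations
#'
#' Given per-population activity boxes (closed rate intervals), determines
#' for every ordered pair of populations the set of organization labels
#' attainable anywhere on the box product, by grid sampling of
#' \code{\link{classify_activities}} (corners included).
#'
#' @param boxes list of three length-2 vectors \code{c(lo, hi)} with
#'   \code{F_T < lo <= hi < 1}.
#' @param theta inter-population inhibitory weight.
#' @param theta_P within-population inhibitory weight.
#' @param F_T normalized target rate.
#' @param grid_n samples per box edge.
#' @return named list (\code{"1-2"}, \code{"1-3"}, \code{"2-3"}) of label
#'   sets (character vectors).
#' @export
triple_feasibility <- function(boxes, theta, theta_P, F_T, grid_n = 41) {
  stopifnot(length(boxes) == 3)
  for (b in boxes)
    stopifnot(length(b) == 2, b[1] <= b[2], b[1] > F_T, b[2] < 1)
  p <- model_parameters(list(theta = theta, theta_P = theta_P, F_T = F_T))
  pair_labels <- function(a, b) {
    fa <- if (a[1] == a[2]) a[1] else seq(a[1], a[2], length.out = grid_n)
    fb <- if (b[1] == b[2]) b[1] else seq(b[1], b[2], length.out = grid_n)
    labs <- character(0)
    for (x in fa) for (y in fb)
      labs <- union(labs, classify_activities(x, y, p))
    sort(labs)
  }
  list("1-2" = pair_labels(boxes[[1]], boxes[[2]]),
       "1-3" = pair_labels(boxes[[1]], boxes[[3]]),
       "2-3" = pair_labels(boxes[[2]], boxes[[3]]))
}
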