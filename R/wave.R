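#' Parameters of the reduced one-equation thrombin-wave model
#'
#' The spatial clot-growth model reduces, under quasi-stationary flow and
#' frozen factor supplies, to a single reaction-diffusion equation for the
#' thrombin concentration T(y, t) across the vessel, with reaction term
#' \deqn{\Phi(T, y) = (k1 \phi_0 + k2 Ba(y) + k3 T + k4 T^2 + k5 T^3)(P_0 - T) - \sigma(y) T,}
#' where \eqn{\sigma(y) = k6 A_0 + a \gamma} collects antithrombin
#' neutralization and removal by the shear flow, and \eqn{Ba(y) = B_0
#' e^{-\lambda y}} is the stationary boundary layer of factors IXa/Xa
#' emitted at the injured wall (decay \eqn{\lambda} = \code{Ba_decay}).
#' Defaults come from the packaged \code{"table2"} set with platelet-rich
#' plasma (\code{phi0} = 300e9/L) at shear rate 25 s^-1.
#'
#' @param ... Named overrides: \code{k1}...\code{k6}, \code{P0}, \code{A0},
#'   \code{B0}, \code{phi0}, \code{a}, \code{gamma}, \code{D}, \code{Tstar},
#'   \code{Ba_decay}.
#' @param set A \code{parameter_set} of tier \code{"flow"} supplying defaults.
#' @return A named list of class \code{wave_params}.
#' @export
wave_params <- function(..., set = load_parameters("table2")) {
  stopifnot(inherits(set, "parameter_set"), set$tier == "flow")
  v <- set$values
  defaults <- list(k1 = v$k1, k2 = v$k2, k3 = v$k3, k4 = v$k4, k5 = v$k5,
                   k6 = v$k6, P0 = v$P0, A0 = v$A0, B0 = v$B0,
                   phi0 = v$phi_f0, a = v$a, gamma = 25, D = v$D,
                   Tstar = v$Tstar, Ba_decay = v$Ba_decay)
  p <- .merge_params(defaults, list(...))
  for (k in names(p)) {
    x <- p[[k]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop("wave parameter '", k, "' must be a single nonnegative finite number")
    }
  }
  if (p$P0 <= 0) stop("P0 must be positive")
  structure(p, class = "wave_params")
}

#' Stationary IXa/Xa boundary-layer profile
#'
#' Exponential decay of the initiation-phase factors away from the injured
#' wall, \code{B0 * exp(-Ba_decay * y)}.
#'
#' @param y Distance from the injured wall (mm), nonnegative.
#' @param params A \code{wave_params} object.
#' @return Ba(y) in nM, same length as \code{y}.
#' @export
ba_profile <- function(y, params) {
  stopifnot(inherits(params, "wave_params"), all(y >= 0))
  params$B0 * exp(-params$Ba_decay * y)
}

# effective thrombin sink (s^-1)
.sigma_of <- function(params) params$k6 * params$A0 + params$a * params$gamma

# coefficients of the quartic reaction polynomial in T (ascending powers)
.phi_coefs <- function(params, y) {
  c0 <- params$k1 * params$phi0 + params$k2 * ba_profile(y, params)
  sig <- .sigma_of(params)
  c(c0 * params$P0,
    params$k3 * params$P0 - c0 - sig,
    params$k4 * params$P0 - params$k3,
    params$k5 * params$P0 - params$k4,
    -params$k5)
}

#' Reaction term of the thrombin-wave equation
#'
#' Evaluates \eqn{\Phi(T, y)}: cubic self-amplification and constant
#' platelet/boundary-layer production, saturated by prothrombin depletion
#' \eqn{(P_0 - T)}, minus the linear sink \eqn{\sigma(y) T}.
#'
#' @param T Thrombin concentration (nM), scalar or vector.
#' @param y Distance from the injured wall (mm), scalar.
#' @param params A \code{wave_params} object.
#' @return Reaction rate (nM/s), same length as \code{T}.
#' @export
reaction_term <- function(T, y, params) {
  stopifnot(inherits(params, "wave_params"), length(y) == 1L, y >= 0)
  A <- .phi_coefs(params, y)
  A[1] + A[2] * T + A[3] * T^2 + A[4] * T^3 + A[5] * T^4
}

# derivative of the reaction polynomial
.phi_deriv <- function(A, T) A[2] + 2 * A[3] * T + 3 * A[4] * T^2 + 4 * A[5] * T^3

#' Equilibria of the thrombin reaction term
#'
#' Locates all real zeros of \eqn{\Phi(\cdot, y)} in \eqn{[0, P_0]} by a
#' dense sign scan (resolution \code{1e-3 * P0}) refined by bisection, and
#' classifies their stability from the sign of the derivative. In the
#' bistable regime the lowest stable root \code{T0} is the quiescent state
#' and the highest stable root \code{T2} the clotted state.
#'
#' @param params A \code{wave_params} object.
#' @param y Distance from the injured wall (mm).
#' @return An object of class \code{equilibrium_set}: list with
#'   \code{roots} (ascending), \code{stable} (logical), \code{T0},
#'   \code{T2}, and \code{bistable} (at least two stable roots separated by
#'   an unstable one).
#' @export
find_equilibria <- function(params, y = 0) {
  stopifnot(inherits(params, "wave_params"))
  A <- .phi_coefs(params, y)
  f <- function(T) A[1] + A[2] * T + A[3] * T^2 + A[4] * T^3 + A[5] * T^4
  grid <- seq(0, params$P0, length.out = 1001L)
  fv <- f(grid)
  roots <- numeric(0)
  scale <- max(abs(fv), 1e-300)
  for (i in seq_len(length(grid) - 1L)) {
    if (abs(fv[i]) <= 1e-14 * scale) {
      roots <- c(roots, grid[i])
    } else if (fv[i] * fv[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                       tol = 1e-12 * params$P0)$root)
    }
  }
  if (abs(fv[length(grid)]) <= 1e-14 * scale) roots <- c(roots, params$P0)
  roots <- sort(unique(roots))
  if (length(roots) > 1L) {
    roots <- roots[c(TRUE, diff(roots) > 1e-9 * params$P0)]
  }
  stable <- .phi_deriv(A, roots) < 0
  if (!length(roots) || !any(stable)) {
    stop("degenerate equilibrium set: no stable zero of the reaction term at y = ", y)
  }
  st <- roots[stable]
  structure(list(roots = roots, stable = stable,
                 T0 = min(st), T2 = max(st),
                 bistable = sum(stable) >= 2L), class = "equilibrium_set")
}

#' @exportS3Method base::print
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set> roots (nM):",
      paste(sprintf("%.4g%s", x$roots, ifelse(x$stable, "*", "")),
            collapse = ", "),
      if (x$bistable) " [bistable]" else " [monostable]", "\n")
  cat("  (* = stable)  T0 =", signif(x$T0, 6), " T2 =", signif(x$T2, 6), "\n")
  invisible(x)
}

# closed-form integral of the reaction polynomial between two thrombin levels
.phi_integral <- function(A, lo, hi) {
  F <- function(T) A[1] * T + A[2] * T^2 / 2 + A[3] * T^3 / 3 +
    A[4] * T^4 / 4 + A[5] * T^5 / 5
  F(hi) - F(lo)
}

#' Wave-propagation criterion
#'
#' For a bistable reaction term the thrombin front advances (the clot grows)
#' exactly when the integral of \eqn{\Phi} between the two stable equilibria
#' is positive. The integral is evaluated in closed form from the polynomial
#' antiderivative.
#'
#' @param params A \code{wave_params} object.
#' @param y Distance from the injured wall (mm).
#' @return List with \code{propagates} (logical) and \code{integral}
#'   (nM^2/s).
#' @export
wave_criterion <- function(params, y = 0) {
  eq <- find_equilibria(params, y)
  if (!eq$bistable) {
    stop("wave criterion undefined: reaction term is not bistable at y = ", y)
  }
  A <- .phi_coefs(params, y)
  I <- .phi_integral(A, eq$T0, eq$T2)
  list(propagates = I > 0, integral = I)
}

# propagation status handling the monostable regimes:
#  +1 propagate, -1 decay, sign of the bistable integral in between.
# A monostable state is called "clotted" when its only stable root exceeds
# half the prothrombin supply.
.propagation_status <- function(params, y) {
  eq <- tryCatch(find_equilibria(params, y), error = function(e) NULL)
  if (is.null(eq)) return(-1)
  if (eq$bistable) {
    A <- .phi_coefs(params, y)
    I <- .phi_integral(A, eq$T0, eq$T2)
    return(if (I > 0) 1 else -1)
  }
  if (eq$T2 > params$P0 / 2) 1 else -1
}

#' Shear-rate threshold of clot propagation
#'
#' The sink \eqn{\sigma = k6 A_0 + a \gamma} grows linearly with the wall
#' shear rate. Below the threshold \eqn{\gamma^*} the propagation integral
#' is positive and the clot invades the vessel; above it the front recedes.
#' \eqn{\gamma^*} is found by bisection on the propagation criterion (the
#' equilibria are recomputed at every shear rate) to a tolerance of
#' \code{tol} (default 1e-3 s^-1).
#'
#' @param params A \code{wave_params} object (its \code{gamma} is ignored).
#' @param y Distance from the injured wall (mm).
#' @param gamma_max Upper end of the search bracket (s^-1).
#' @param tol Bisection tolerance (s^-1).
#' @return \code{gamma_star} (s^-1).
#' @export
shear_threshold <- function(params, y = 0, gamma_max = 2000, tol = 1e-3) {
  stopifnot(inherits(params, "wave_params"), gamma_max > 0)
  at_gamma <- function(g) { p <- params; p$gamma <- g; p }
  if (.propagation_status(at_gamma(0), y) < 0) {
    stop("no propagation at gamma = 0; shear threshold undefined")
  }
  if (.propagation_status(at_gamma(gamma_max), y) > 0) {
    stop("threshold not found: propagation persists over the whole bracket [0, ",
         gamma_max, "] s^-1")
  }
  lo <- 0; hi <- gamma_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.propagation_status(at_gamma(mid), y) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Printed closed-form shear threshold (secondary evaluator)
#'
#' Closed-form counterpart of [shear_threshold()] obtained by solving the
#' propagation integral for the shear rate at a frozen clotted level
#' \code{T2} and quiescent level 0: the production integral
#' \eqn{\int_0^{T_2}(k1\phi_0 + k2 Ba + k3T + k4T^2 + k5T^3)(P_0-T)\,dT}
#' balanced against \eqn{(k6 A_0 + a\gamma) T_2^2/2}. The published formula
#' prints with inconsistent powers in its first term and an undefined
#' velocity profile; this evaluator normalizes it to the exact frozen-T2
#' integral and is provided for comparison only — the bisection of
#' [shear_threshold()] is the model's own governing condition.
#'
#' @param params A \code{wave_params} object.
#' @param y Distance from the injured wall (mm).
#' @param T2 Clotted thrombin level (nM); default: the high stable
#'   equilibrium at \code{gamma = 0}.
#' @return \code{gamma_star} (s^-1) under the frozen-equilibria
#'   approximation.
#' @export
shear_threshold_closed_form <- function(params, y = 0, T2 = NULL) {
  stopifnot(inherits(params, "wave_params"))
  if (is.null(T2)) {
    p0 <- params; p0$gamma <- 0
    T2 <- find_equilibria(p0, y)$T2
  }
  c0 <- params$k1 * params$phi0 + params$k2 * ba_profile(y, params)
  # production integral: (c0 + k3 T + k4 T^2 + k5 T^3)(P0 - T) from 0 to T2
  prod_coefs <- c(c0 * params$P0,
                  params$k3 * params$P0 - c0,
                  params$k4 * params$P0 - params$k3,
                  params$k5 * params$P0 - params$k4,
                  -params$k5)
  Iprod <- .phi_integral(prod_coefs, 0, T2)
  (Iprod - params$k6 * params$A0 * T2^2 / 2) / (params$a * T2^2 / 2)
}

#' Simulate the 1D thrombin wave
#'
#' Method-of-lines integration of the reduced thrombin equation on
#' \eqn{[0, L]} (distance from the injured wall) with zero-flux boundaries.
#' By default thrombin starts at zero everywhere and initiation emerges from
#' the boundary-layer production term \code{k2 Ba(y)} together with the
#' platelet term \code{k1 phi0}.
#'
#' @param params A \code{wave_params} object.
#' @param L Domain length (mm, default 1: the vessel diameter).
#' @param t_end Duration (s).
#' @param h Grid spacing (mm, default 0.02).
#' @param dt_out Output interval (s).
#' @param initial Optional initial thrombin profile (numeric vector over the
#'   grid); default zero.
#' @param rtol,atol Solver tolerances.
#' @return An object of class \code{wave_field}: list with \code{y} (grid,
#'   mm), \code{times} (s), \code{T} (matrix, time x node, nM) and
#'   \code{params}.
#' @export
simulate_wave <- function(params, L = 1, t_end = 1200, h = 0.02, dt_out = 5,
                          initial = NULL, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "wave_params"), L > 0, h > 0, t_end > 0)
  y <- seq(0, L, by = h)
  n <- length(y)
  if (is.null(initial)) initial <- rep(0, n)
  stopifnot(length(initial) == n, all(initial >= 0))
  Ba <- ba_profile(y, params)
  sig <- .sigma_of(params)
  rhs <- function(t, T, parms) {
    phi <- (params$k1 * params$phi0 + params$k2 * Ba + params$k3 * T +
              params$k4 * T^2 + params$k5 * T^3) * (params$P0 - T) - sig * T
    list(params$D * .lap1d(T, h) + phi)
  }
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode.1D(initial, times, rhs, NULL, nspec = 1,
                         method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out[, -1]))) {
    stop("integration failure in the thrombin-wave solver")
  }
  structure(list(y = y, times = times, T = unname(out[, -1, drop = FALSE]),
                 params = params), class = "wave_field")
}

#' @exportS3Method base::print
print.wave_field <- function(x, ...) {
  cat("<wave_field> ", length(x$y), " nodes x ", length(x$times),
      " times; final max T ", signif(max(x$T[nrow(x$T), ]), 4), " nM\n",
      sep = "")
  invisible(x)
}

#' Occluded fraction of the vessel
#'
#' Share of the cross-section where thrombin exceeds the occlusion
#' threshold, as a percentage of the vessel diameter.
#'
#' @param field A \code{wave_field}.
#' @param t Time (s) at which to evaluate (nearest stored sample is used).
#' @param Tstar Occlusion threshold (nM); defaults to the model parameter.
#' @param diameter Vessel diameter (mm); defaults to the domain length.
#' @return Occluded percentage in \code{[0, 100]}.
#' @export
occluded_fraction <- function(field, t, Tstar = NULL, diameter = NULL) {
  stopifnot(inherits(field, "wave_field"),
            t >= min(field$times), t <= max(field$times))
  if (is.null(Tstar)) Tstar <- field$params$Tstar
  if (is.null(diameter)) diameter <- max(field$y)
  i <- which.min(abs(field$times - t))
  prof <- field$T[i, ]
  h <- field$y[2] - field$y[1]
  # each node represents a cell of width h (half cells at the ends)
  w <- rep(h, length(prof)); w[c(1, length(prof))] <- h / 2
  100 * sum(w[prof > Tstar]) / diameter
}

#' Time of clotting initiation
#'
#' First time at which the maximal thrombin concentration across the vessel
#' exceeds the occlusion threshold; \code{NA} if never.
#'
#' @param field A \code{wave_field}.
#' @param Tstar Threshold (nM); defaults to the model parameter.
#' @return Initiation time (s) or \code{NA}.
#' @export
initiation_time <- function(field, Tstar = NULL) {
  stopifnot(inherits(field, "wave_field"))
  if (is.null(Tstar)) Tstar <- field$params$Tstar
  mx <- apply(field$T, 1, max)
  i <- which(mx > Tstar)[1]
  if (is.na(i)) NA_real_ else field$times[i]
}

#' Final clot size from the propagation criterion
#'
#' The boundary-layer production decays with distance from the wall, so the
#' propagation integral can change sign at some depth: the clot stops
#' growing there. Returns the smallest such depth (by bisection), or the
#' domain length when the criterion stays positive throughout.
#'
#' @param params A \code{wave_params} object.
#' @param L Domain length (mm).
#' @param tol Bisection tolerance (mm).
#' @return \code{y_stop} (mm).
#' @export
clot_final_size <- function(params, L = 1, tol = 1e-4) {
  stopifnot(inherits(params, "wave_params"), L > 0)
  if (.propagation_status(params, 0) < 0) {
    stop("no propagation at the injured wall (y = 0); clot size undefined")
  }
  if (.propagation_status(params, L) > 0) return(L)
  lo <- 0; hi <- L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.propagation_status(params, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Export a wave field to CSV
#'
#' Long format: one row per (time, y) pair with the thrombin concentration.
#'
#' @param field A \code{wave_field}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_wave_csv <- function(field, path) {
  stopifnot(inherits(field, "wave_field"))
  df <- data.frame(
    t_s = rep(field$times, each = length(field$y)),
    y_mm = rep(field$y, length(field$times)),
    T_nM = as.vector(t(field$T))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
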