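#' Rate constants of the six-species amplification cascade
#'
#' The propagation phase of coagulation is a chain of thrombin-dependent
#' activations: thrombin activates factors V, VIII and XI; XIa activates IX;
#' IXa (alone and in the VIIIa-IXa complex) activates X; and Xa (alone and
#' in the Va-Xa prothrombinase complex) converts prothrombin to thrombin.
#' Each activated factor is cleared at a first-order inhibition rate
#' \code{h1...h5}. Under fast equilibration the chain lumps into cubic
#' thrombin kinetics (see [lump_constants()]).
#'
#' @param khat1,khat2,khat3,khat4,khat5,khat6 Activation rate constants of
#'   the chain (thrombin -> Va, VIIIa, XIa; XIa -> IXa; IXa -> Xa;
#'   Xa -> thrombin).
#' @param khat55 Rate of X activation by the VIIIa-IXa complex
#'   (nM^-1 s^-1 per IXa).
#' @param khat66 Rate of prothrombin activation by the Va-Xa complex
#'   (nM^-1 s^-1 per Xa).
#' @param h1,h2,h3,h4,h5 Inhibition rates (s^-1), strictly positive.
#' @param sigma Linear thrombin sink (s^-1): antithrombin neutralization
#'   plus flow removal.
#' @param P Prothrombin supply (nM).
#' @param D Diffusion coefficient (mm^2/s) shared by all factors.
#' @return A named list of class \code{cascade_rates}.
#' @seealso [default_cascade_rates()] for the packaged set consistent with
#'   the lumped constants of the flow-model table.
#' @export
cascade_rates <- function(khat1, khat2, khat3, khat4, khat5, khat6,
                          khat55, khat66, h1, h2, h3, h4, h5,
                          sigma = 0, P = 1400, D = 5e-5) {
  r <- list(khat1 = khat1, khat2 = khat2, khat3 = khat3, khat4 = khat4,
            khat5 = khat5, khat6 = khat6, khat55 = khat55, khat66 = khat66,
            h1 = h1, h2 = h2, h3 = h3, h4 = h4, h5 = h5,
            sigma = sigma, P = P, D = D)
  for (k in names(r)) {
    v <- r[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("cascade rate '", k, "' must be a single nonnegative finite number")
    }
  }
  if (any(unlist(r[c("h1", "h2", "h3", "h4", "h5")]) <= 0)) {
    stop("inhibition rates h1..h5 must be strictly positive")
  }
  structure(r, class = "cascade_rates")
}

#' Default cascade rates reproducing the lumped flow-model constants
#'
#' The published model prints only the lumped cubic coefficients
#' (\code{k3}, \code{k4}, \code{k5}); the underlying activation/inhibition
#' rates are not given. This constructor inverts the lumping formulas under
#' a documented convention: all inhibition rates equal \code{h}, a common
#' activation/inhibition ratio \code{r} for the thrombin-driven activations
#' (\code{khat1 = khat2 = khat3 = khat4 = r h}), and a symmetric split
#' \code{khat5 = khat6}. The two complex rates \code{khat55}, \code{khat66}
#' are then the roots of a quadratic fixed by \code{k4} and \code{k5}. By
#' construction \code{lump_constants()} returns exactly the requested
#' \code{k3}, \code{k4}, \code{k5}.
#'
#' \code{h} defaults to 10 s^-1: the detailed-equilibrium reduction assumes
#' the intermediate factors equilibrate faster than the thrombin front
#' passes (a few seconds), which requires sub-second relaxation times.
#'
#' @param k3,k4,k5 Target lumped coefficients (defaults: flow-model table).
#' @param r Activation/inhibition ratio of the thrombin-driven steps
#'   (dimensionless per nM; default 0.05, giving intermediate-factor levels
#'   a few percent of the thrombin level).
#' @param h Common inhibition rate (s^-1, default 10).
#' @param sigma,P,D Passed to [cascade_rates()].
#' @return A \code{cascade_rates} object.
#' @export
default_cascade_rates <- function(k3 = 1.5e-5, k4 = 8e-6, k5 = 1e-10,
                                  r = 0.05, h = 10,
                                  sigma = 0, P = 1400, D = 5e-5) {
  stopifnot(k3 > 0, k4 > 0, k5 >= 0, r > 0, h > 0)
  u <- k3 / r^2            # khat5*khat6/h5
  s <- k4 / r^3            # sum of the two complex-route terms
  pr <- k3 * k5 / r^6      # their product
  disc <- s^2 - 4 * pr
  if (disc < 0) stop("k3, k4, k5 not realizable with this r (negative discriminant)")
  v <- (s + sqrt(disc)) / 2
  w <- (s - sqrt(disc)) / 2
  k56 <- sqrt(u * h)
  cascade_rates(khat1 = r * h, khat2 = r * h, khat3 = r * h, khat4 = r * h,
                khat5 = k56, khat6 = k56,
                khat55 = v * h / k56, khat66 = w * h / k56,
                h1 = h, h2 = h, h3 = h, h4 = h, h5 = h,
                sigma = sigma, P = P, D = D)
}

#' Lump the cascade into cubic thrombin kinetics
#'
#' Under detailed equilibrium of the intermediate factors, the six-species
#' chain collapses onto a single thrombin equation whose production term is
#' the cubic \code{(k3 T + k4 T^2 + k5 T^3) P}. The three coefficients are
#' explicit products and sums of the activation and inhibition rates.
#'
#' @param rates A \code{cascade_rates} object.
#' @return Named numeric vector \code{c(k3, k4, k5)}.
#' @export
lump_constants <- function(rates) {
  stopifnot(inherits(rates, "cascade_rates"))
  with(rates, c(
    k3 = khat3 * khat4 * khat5 * khat6 / (h3 * h4 * h5),
    k4 = khat2 * khat3 * khat4 * khat55 * khat6 / (h2 * h3 * h4 * h5) +
         khat1 * khat3 * khat4 * khat5 * khat66 / (h1 * h3 * h4 * h5),
    k5 = khat1 * khat2 * khat3 * khat4 * khat55 * khat66 /
         (h1 * h2 * h3 * h4 * h5)
  ))
}

#' Detailed-equilibrium concentrations at a given thrombin level
#'
#' Evaluates the algebraic map expressing every intermediate factor as a
#' function of thrombin when activation and inhibition balance: Va, VIIIa
#' and XIa are proportional to thrombin; IXa follows XIa; Xa combines the
#' direct IXa route and the VIIIa-IXa complex route.
#'
#' @param T Thrombin concentration (nM), scalar or vector, nonnegative.
#' @param rates A \code{cascade_rates} object.
#' @return Data frame with columns \code{Va}, \code{VIIIa}, \code{XIa},
#'   \code{IXa}, \code{Xa}, \code{T} (one row per input thrombin value).
#' @export
equilibrium_map <- function(T, rates) {
  stopifnot(inherits(rates, "cascade_rates"), is.numeric(T), all(T >= 0))
  with(rates, {
    XIa <- khat3 / h3 * T
    IXa <- khat3 * khat4 / (h3 * h4) * T
    data.frame(
      Va = khat1 / h1 * T,
      VIIIa = khat2 / h2 * T,
      XIa = XIa,
      IXa = IXa,
      Xa = IXa * (khat5 / h5 + khat55 * khat2 / (h2 * h5) * T),
      T = T
    )
  })
}

# second-order zero-flux Laplacian on a uniform grid (mirror ghosts)
.lap1d <- function(v, h) {
  n <- length(v)
  (c(v[-1], v[n - 1]) - 2 * v + c(v[2], v[-n])) / h^2
}

#' Simulate the full amplification cascade on a 1D interval
#'
#' Method-of-lines integration of the six coupled reaction-diffusion
#' equations with zero-flux boundaries. Thrombin production draws on a
#' prothrombin pool in local conservation with thrombin (supply
#' \code{P - T}, floored at zero), the same closure used by the reduced
#' one-equation model, so that both tiers share the bistable front
#' structure. With \code{D = 0} and spatially uniform data the system
#' reduces to the pure kinetics.
#'
#' @param rates A \code{cascade_rates} object.
#' @param initial Either a single thrombin profile (numeric vector over the
#'   grid; intermediates start on the equilibrium map) or a data frame as
#'   returned by [equilibrium_map()] with one row per grid node.
#' @param L Domain length (mm).
#' @param h Grid spacing (mm, default 0.02).
#' @param t_end Duration (s).
#' @param dt_out Output interval (s).
#' @param rtol,atol Solver tolerances.
#' @return A list of class \code{cascade_trajectory}: \code{y} (grid),
#'   \code{times}, and \code{fields}, a 3-d array (time x node x species)
#'   with species \code{Va}, \code{VIIIa}, \code{XIa}, \code{IXa},
#'   \code{Xa}, \code{T}.
#' @export
simulate_cascade <- function(rates, initial, L = 3, h = 0.02,
                             t_end = 100, dt_out = 5,
                             rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(rates, "cascade_rates"), L > 0, h > 0, t_end > 0)
  y <- seq(0, L, by = h)
  n <- length(y)
  if (is.data.frame(initial)) {
    stopifnot(nrow(initial) == n)
    Y0 <- as.matrix(initial[, c("Va", "VIIIa", "XIa", "IXa", "Xa", "T")])
  } else {
    stopifnot(is.numeric(initial), length(initial) == n)
    Y0 <- as.matrix(equilibrium_map(initial, rates)[,
      c("Va", "VIIIa", "XIa", "IXa", "Xa", "T")])
  }
  rhs <- function(t, Yv, parms) {
    m <- matrix(Yv, nrow = n)
    Va <- m[, 1]; VIIIa <- m[, 2]; XIa <- m[, 3]
    IXa <- m[, 4]; Xa <- m[, 5]; T <- m[, 6]
    with(rates, {
      prod <- (khat6 * Xa + khat66 * Xa * Va) * pmax(P - T, 0)
      list(c(
        D * .lap1d(Va, h) + khat1 * T - h1 * Va,
        D * .lap1d(VIIIa, h) + khat2 * T - h2 * VIIIa,
        D * .lap1d(XIa, h) + khat3 * T - h3 * XIa,
        D * .lap1d(IXa, h) + khat4 * XIa - h4 * IXa,
        D * .lap1d(Xa, h) + khat5 * IXa + khat55 * VIIIa * IXa - h5 * Xa,
        D * .lap1d(T, h) + prod - sigma * T
      ))
    })
  }
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode.1D(as.vector(Y0), times, rhs, NULL, nspec = 6,
                         dimens = n, method = "lsoda",
                         rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out[, -1]))) {
    stop("integration failure in the cascade solver (non-finite state or early stop)")
  }
  fields <- array(out[, -1], dim = c(length(times), n, 6),
                  dimnames = list(NULL, NULL,
                                  c("Va", "VIIIa", "XIa", "IXa", "Xa", "T")))
  structure(list(y = y, times = times, fields = fields, rates = rates),
            class = "cascade_trajectory")
}

#' @exportS3Method base::print
print.cascade_trajectory <- function(x, ...) {
  cat("<cascade_trajectory> ", length(x$y), " nodes x ", length(x$times),
      " times; final max T ",
      signif(max(x$fields[length(x$times), , "T"]), 4), " nM\n", sep = "")
  invisible(x)
}

# leading-edge position of a right-moving front: rightmost crossing of
# `level` from above, linearly interpolated; NA if the level is not bracketed
.front_position <- function(profile, y, level) {
  idx <- which(profile > level)
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  if (i == length(profile)) return(NA_real_)
  y[i] + (level - profile[i]) / (profile[i + 1] - profile[i]) * (y[i + 1] - y[i])
}

# linear fit of front position over the samples after `burn` fraction
.front_speed <- function(Tmat, times, y, level, burn = 1 / 3) {
  pos <- apply(Tmat, 1, .front_position, y = y, level = level)
  ok <- which(!is.na(pos) & times >= burn * times[length(times)])
  if (length(ok) < 3L) return(NA_real_)
  unname(stats::coef(stats::lm(pos[ok] ~ times[ok]))[2])
}

#' Compare the full cascade against its lumped reduction
#'
#' Runs the six-species cascade and the one-equation lumped model (cubic
#' production with coefficients from [lump_constants()], prothrombin supply
#' \code{P - T}, sink \code{sigma}) from the same thrombin seed, estimates
#' both front speeds from the half-plateau level set, and reports their
#' relative discrepancy together with the post-transient sup-norm thrombin
#' mismatch.
#'
#' @param rates A \code{cascade_rates} object.
#' @param L,h,t_end,dt_out Domain and integration controls (see
#'   [simulate_cascade()]).
#' @param seed_width Width (mm) of the initial clotted region (thrombin at
#'   the high equilibrium for \code{y < seed_width}, zero beyond).
#' @return A list: \code{speed_full}, \code{speed_reduced} (mm/s, \code{NA}
#'   if no front), \code{rel_speed_diff}, \code{sup_T_diff} (nM, after the
#'   first third of the run), \code{no_wave} (TRUE when neither model
#'   propagates), \code{T2} (the high thrombin equilibrium used).
#' @export
compare_reduction <- function(rates, L = 3, h = 0.02, t_end = 120,
                              dt_out = 5, seed_width = 0.4) {
  stopifnot(inherits(rates, "cascade_rates"))
  lk <- lump_constants(rates)
  # equilibria of the lumped reaction term
  wp <- wave_params(k1 = 0, k2 = 0, k3 = lk[["k3"]], k4 = lk[["k4"]],
                    k5 = lk[["k5"]], k6 = 0, A0 = 0, B0 = 0, phi0 = 0,
                    a = 1, gamma = rates$sigma, P0 = rates$P, D = rates$D)
  eq <- tryCatch(find_equilibria(wp, y = 0), error = function(e) NULL)
  if (is.null(eq) || is.na(eq$T2) || eq$T2 <= 0) {
    return(list(speed_full = NA_real_, speed_reduced = NA_real_,
                rel_speed_diff = NA_real_, sup_T_diff = NA_real_,
                no_wave = TRUE, T2 = NA_real_))
  }
  T2 <- eq$T2
  y <- seq(0, L, by = h)
  Tseed <- ifelse(y < seed_width, T2, 0)

  wf <- simulate_wave(wp, L = L, t_end = t_end, h = h, dt_out = dt_out,
                      initial = Tseed)
  full <- simulate_cascade(rates, Tseed, L = L, h = h, t_end = t_end,
                           dt_out = dt_out)
  Tfull <- full$fields[, , "T"]
  v_red <- .front_speed(wf$T, wf$times, y, T2 / 2)
  v_full <- .front_speed(Tfull, full$times, y, T2 / 2)
  post <- full$times >= t_end / 3
  list(
    speed_full = v_full,
    speed_reduced = v_red,
    rel_speed_diff = if (is.na(v_full) || is.na(v_red)) NA_real_ else
      abs(v_full - v_red) / abs(v_red),
    sup_T_diff = max(abs(Tfull[post, , drop = FALSE] - wf$T[post, , drop = FALSE])),
    no_wave = is.na(v_full) && is.na(v_red),
    T2 = T2
  )
}
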