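#' Initial fields of a channel scenario
#'
#' Plasma levels for prothrombin, antithrombin and fibrinogen; no thrombin,
#' fibrin or activated factors; free platelets at the plasma density and
#' activated platelets seeded on the injury patch.
#'
#' @param geom A \code{channel_geometry}.
#' @param values Named list of flow-tier parameter values (see
#'   [load_parameters()]).
#' @param phi_f0 Free-platelet density (1e9/L); overrides the parameter
#'   set (0 for normal pooled plasma, 300 for platelet-rich plasma).
#' @return Named list of nx x ny field matrices.
#' @export
initial_fields <- function(geom, values, phi_f0 = values$phi_f0) {
  stopifnot(inherits(geom, "channel_geometry"))
  zero <- matrix(0, geom$nx, geom$ny)
  phic <- zero
  if (length(geom$patch_cols)) phic[geom$patch_cols, 1] <- values$phi_c0
  list(P = zero + values$P0, T = zero, Ba = zero, A = zero + values$A0,
       Fg = zero + values$Fg0, F = zero, Fp = zero,
       phif = zero + phi_f0, phic = phic)
}

# parameter vector handed to the compiled stepper
.stepper_pars <- function(values, phi_f0, perm, react = TRUE) {
  list(k1 = values$k1, k2 = values$k2, k3 = values$k3, k4 = values$k4,
       k5 = values$k5, k6 = values$k6, k7 = values$k7, k8 = values$k8,
       k9 = values$k9, k10 = values$k10, K10 = values$K10,
       k11 = values$k11, k12 = values$k12, k13 = values$k13,
       D = values$D, Dp = values$Dp, phi_max = values$phi_max,
       B0 = values$B0, P0 = values$P0, A0 = values$A0, Fg0 = values$Fg0,
       phi_f0 = phi_f0, phi_c0 = values$phi_c0,
       alpha1 = values$alpha1, beta1 = values$beta1,
       alpha = perm$alpha, Fp_ref = perm$Fp_ref, Fp_cap = perm$Fp_cap,
       react = react)
}

#' Advance the transported species and platelets
#'
#' One or more finite-volume steps of the seven clotting factors and the
#' two platelet classes against a frozen velocity field: upwind advection,
#' central diffusion, pointwise kinetics, the saturating platelet mobility,
#' and the tissue-factor surface reaction on the patch. Fibrin polymer is
#' immobile. Exposed mainly for testing; scenario runs use
#' [run_scenario()].
#'
#' @param fields Named list of field matrices (see [initial_fields()]).
#' @param flow_state A \code{flow_state} providing face velocities, or
#'   \code{NULL} for a quiescent closed box.
#' @param geom A \code{channel_geometry}.
#' @param values Flow-tier parameter values.
#' @param dt Time step (s).
#' @param nsteps Number of steps (default 1).
#' @param phi_f0 Inlet/initial free-platelet density.
#' @param react Apply kinetics and the patch reaction (set \code{FALSE} for
#'   pure-transport tests).
#' @param closed Treat the inlet/outlet as impermeable walls (conservation
#'   tests).
#' @param perm A \code{permeability_params}.
#' @return List with the updated \code{fields}, the recorded
#'   \code{timeline} (t, max Fp near patch, max 1/K_f near patch, max T)
#'   and \code{min_value}, the most negative field value encountered.
#' @export
step_species <- function(fields, flow_state, geom, values, dt, nsteps = 1L,
                         phi_f0 = values$phi_f0, react = TRUE,
                         closed = FALSE, perm = permeability_params()) {
  stopifnot(inherits(geom, "channel_geometry"), dt > 0, nsteps >= 1)
  if (is.null(flow_state)) {
    u <- matrix(0, geom$nx + 1, geom$ny)
    v <- matrix(0, geom$nx, geom$ny + 1)
  } else {
    u <- flow_state$u; v <- flow_state$v
  }
  out <- step_species_cpp(fields, u, v,
                          list(nx = geom$nx, ny = geom$ny, h = geom$h),
                          .stepper_pars(values, phi_f0, perm, react),
                          dt, as.integer(nsteps), 0,
                          as.integer(max(nsteps, 1L)),
                          as.integer(geom$patch_cols - 1L),
                          as.integer(geom$near_cols - 1L),
                          closed)
  tol <- -1e-9 * max(values$P0, values$A0, values$Fg0)
  if (out$min_value < tol) {
    stop("positivity violation in species transport (min value ",
         format(out$min_value), ")")
  }
  list(fields = out[c("P", "T", "Ba", "A", "Fg", "F", "Fp", "phif", "phic")],
       timeline = out$timeline, min_value = out$min_value)
}

#' Run a channel clot-growth scenario
#'
#' Couples the quasi-steady Stokes-Brinkman flow with factor transport,
#' platelet aggregation and the tissue-factor surface reaction. The flow is
#' re-solved whenever the clot resistance field has changed appreciably
#' since the last solve (and at least every \code{flow_every} seconds once
#' a clot is present). Initiation is declared when the hydraulic resistance
#' near the patch reaches \code{init_resistance} (the isosurface level used
#' to delimit the clot body); occlusion when a resistive band spans the
#' channel height and the flow rate has fallen below 1\% of the clot-free
#' value.
#'
#' @param geom A \code{channel_geometry}.
#' @param gamma Wall shear rate (s^-1).
#' @param plasma \code{"PRP"} (free platelets at the plasma density of the
#'   parameter set) or \code{"NPP"} (no free platelets).
#' @param t_end Simulated time horizon (s).
#' @param set Flow-tier \code{parameter_set}.
#' @param flow A \code{flow_params}; its \code{gamma} is overridden.
#' @param perm A \code{permeability_params}.
#' @param dt Base time step (s, default from the parameter set); reduced
#'   automatically to respect the advective CFL limit.
#' @param chunk Interval (s) between event checks (default 5).
#' @param flow_every Maximal flow age (s) once clotting has started.
#' @param init_resistance Initiation threshold on 1/K_f (mm^-2, default 10).
#' @param stop_at Stop early at \code{"occlusion"} (default),
#'   \code{"initiation"}, or run to \code{"t_end"}.
#' @return An object of class \code{scenario_result}: \code{initiation_time}
#'   and \code{occlusion_time} (s, \code{NA} if not reached), the
#'   \code{occluded} flag, a \code{timeline} data frame (t_s, maxFp_nM,
#'   maxInvKf_mm2, maxT_nM, flowrate), the final \code{fields} and
#'   \code{flow_state}.
#' @export
run_scenario <- function(geom, gamma, plasma = c("PRP", "NPP"), t_end = 600,
                         set = load_parameters("table2"),
                         flow = flow_params(gamma = gamma),
                         perm = permeability_params(),
                         dt = NULL, chunk = 5, flow_every = 10,
                         init_resistance = 10,
                         stop_at = c("occlusion", "initiation", "t_end")) {
  plasma <- match.arg(plasma)
  stop_at <- match.arg(stop_at)
  stopifnot(inherits(geom, "channel_geometry"), gamma >= 0, t_end > 0)
  values <- set$values
  phi_f0 <- if (plasma == "PRP") values$phi_f0 else 0
  flow$gamma <- gamma
  fields <- initial_fields(geom, values, phi_f0)
  perm$phi_max <- values$phi_max

  fs <- solve_channel_flow(geom, flow)
  Q0 <- fs$flowrate
  pars <- .stepper_pars(values, phi_f0, perm, react = TRUE)
  grid <- list(nx = geom$nx, ny = geom$ny, h = geom$h)
  dt0 <- if (is.null(dt)) values$dt else dt

  t <- 0
  initiation <- NA_real_
  occlusion <- NA_real_
  occluded <- FALSE
  last_solve_t <- 0
  timeline <- list()
  while (t < t_end - 1e-9) {
    umax <- max(abs(fs$u), abs(fs$v), 1e-12)
    dtn <- min(dt0, 0.8 * geom$h / umax)
    nsteps <- max(1L, ceiling(min(chunk, t_end - t) / dtn))
    out <- step_species_cpp(fields, fs$u, fs$v, grid, pars, dtn,
                            as.integer(nsteps), t, as.integer(nsteps),
                            as.integer(geom$patch_cols - 1L),
                            as.integer(geom$near_cols - 1L), FALSE)
    fields <- out[c("P", "T", "Ba", "A", "Fg", "F", "Fp", "phif", "phic")]
    t <- out$t_end
    maxR <- out$timeline[nrow(out$timeline), 3]
    if (is.na(initiation) && maxR >= init_resistance) {
      # locate the crossing inside the chunk
      tl <- out$timeline
      k <- which(tl[, 3] >= init_resistance)[1]
      initiation <- tl[k, 1]
      if (stop_at == "initiation") {
        timeline[[length(timeline) + 1]] <-
          cbind(out$timeline, flowrate = fs$flowrate)
        break
      }
    }
    clot_active <- maxR >= init_resistance / 10
    if (clot_active && (t - last_solve_t) >= flow_every - 1e-9) {
      invKf <- permeability_resistance(fields$Fp, pmin(fields$phic,
                                       perm$phi_max * (1 - 1e-9)), perm)
      fs <- solve_channel_flow(geom, flow, invKf, p_in = fs$p_in)
      last_solve_t <- t
      band <- any(apply(invKf >= init_resistance, 1, all))
      if (!occluded && band && fs$flowrate < 0.01 * Q0) {
        occlusion <- t
        occluded <- TRUE
      }
    }
    timeline[[length(timeline) + 1]] <-
      cbind(out$timeline, flowrate = fs$flowrate)
    if (occluded && stop_at == "occlusion") break
  }
  tl <- do.call(rbind, timeline)
  tl <- tl[!duplicated(tl[, 1]), , drop = FALSE]
  timeline_df <- data.frame(t_s = tl[, 1], maxFp_nM = tl[, 2],
                            maxInvKf_mm2 = tl[, 3], maxT_nM = tl[, 4],
                            flowrate = tl[, 5])
  structure(list(initiation_time = initiation, occlusion_time = occlusion,
                 occluded = occluded, timeline = timeline_df,
                 fields = fields, flow_state = fs, gamma = gamma,
                 plasma = plasma, geom = geom, Q0 = Q0),
            class = "scenario_result")
}

#' @exportS3Method base::print
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$plasma, " at gamma = ", x$gamma, " s^-1\n",
      "  initiation: ", ifelse(is.na(x$initiation_time), "not reached",
                               paste0(signif(x$initiation_time, 4), " s")),
      "\n  occlusion:  ", ifelse(is.na(x$occlusion_time), "not reached",
                                 paste0(signif(x$occlusion_time, 4), " s")),
      "\n", sep = "")
  invisible(x)
}
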