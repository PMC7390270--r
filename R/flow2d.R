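#' Channel geometry for the 2D clot-growth model
#'
#' Planar-channel reduction of the vessel: length \code{L} along the flow,
#' height \code{H} equal to the vessel diameter, with a tissue-factor patch
#' of width \code{patch_width} on the bottom wall starting at
#' \code{patch_start} from the inlet. Cell-centered grid of spacing
#' \code{h}; the patch is the set of bottom-wall faces inside the patch
#' interval.
#'
#' @param L Channel length (mm, default 8).
#' @param H Channel height (mm, default 1).
#' @param patch_start Patch start (mm, default 2).
#' @param patch_width Patch width (mm, default 0.2).
#' @param h Grid spacing (mm, default 0.04); must divide \code{L} and
#'   \code{H}.
#' @return A list of class \code{channel_geometry} with the grid sizes
#'   \code{nx}, \code{ny} and the patch column indices.
#' @export
channel_geometry <- function(L = 8, H = 1, patch_start = 2,
                             patch_width = 0.2, h = 0.04) {
  stopifnot(L > 0, H > 0, h > 0, patch_start > 0, patch_width >= 0,
            patch_start + patch_width <= L)
  nx <- round(L / h); ny <- round(H / h)
  if (abs(nx * h - L) > 1e-9 * L || abs(ny * h - H) > 1e-9 * H) {
    stop("grid spacing h must divide both L and H")
  }
  centers <- (seq_len(nx) - 0.5) * h
  patch_cols <- which(centers > patch_start & centers < patch_start + patch_width)
  near_cols <- which(centers > patch_start - 0.2 &
                     centers < patch_start + patch_width + 0.2)
  structure(list(L = L, H = H, patch_start = patch_start,
                 patch_width = patch_width, h = h, nx = nx, ny = ny,
                 x = centers, y = (seq_len(ny) - 0.5) * h,
                 patch_cols = patch_cols, near_cols = near_cols),
            class = "channel_geometry")
}

#' Flow parameters of the plasma
#'
#' @param rho Plasma density (kg/mm^3, default 1.06e-6).
#' @param nu Kinematic viscosity (mm^2/s, default 1.3).
#' @param gamma Target wall shear rate (s^-1).
#' @param p_out Outlet pressure (default 0).
#' @return A list of class \code{flow_params}; \code{mu = rho * nu} is the
#'   dynamic viscosity.
#' @export
flow_params <- function(rho = 1.06e-6, nu = 1.3, gamma = 25, p_out = 0) {
  stopifnot(rho > 0, nu > 0, gamma >= 0)
  structure(list(rho = rho, nu = nu, mu = rho * nu, gamma = gamma,
                 p_out = p_out), class = "flow_params")
}

#' Clot permeability parameters (Davies drag law)
#'
#' @param alpha Fibrin fiber radius (mm, default 6e-4).
#' @param phi_max Maximal platelet packing density (1e9/L, default 400).
#' @param Fp_ref Fibrin-polymer normalization (nM, default 7000).
#' @param Fp_cap Cap of the normalized solid fraction (default 0.7).
#' @return A list of class \code{permeability_params}.
#' @export
permeability_params <- function(alpha = 6e-4, phi_max = 400,
                                Fp_ref = 7000, Fp_cap = 0.7) {
  stopifnot(alpha > 0, phi_max > 0, Fp_ref > 0, Fp_cap > 0)
  structure(list(alpha = alpha, phi_max = phi_max, Fp_ref = Fp_ref,
                 Fp_cap = Fp_cap), class = "permeability_params")
}

#' Hydraulic resistance of the clot
#'
#' Davies drag law for fibrous media, amplified by clot-bound platelets:
#' \deqn{1/K_f = \frac{16}{\alpha^2} \tilde F_p^{3/2} (1 + 56 \tilde F_p^3)
#'   \frac{\phi_{max} + \phi_c}{\phi_{max} - \phi_c},}
#' with \eqn{\tilde F_p = \min(F_{p,cap}, F_p / F_{p,ref})}.
#'
#' @param Fp Fibrin-polymer concentration (nM), scalar, vector or matrix.
#' @param phi_c Clot-platelet density (1e9/L), same shape as \code{Fp}.
#' @param params A \code{permeability_params} object.
#' @return Inverse permeability 1/K_f (mm^-2), same shape as \code{Fp}.
#' @export
permeability_resistance <- function(Fp, phi_c, params = permeability_params()) {
  stopifnot(inherits(params, "permeability_params"),
            all(Fp >= 0), all(is.finite(Fp)))
  if (any(phi_c >= params$phi_max)) {
    stop("singular resistance: clot platelet density at or above phi_max")
  }
  Ft <- pmin(params$Fp_cap, Fp / params$Fp_ref)
  out <- (16 / params$alpha^2) * Ft^1.5 * (1 + 56 * Ft^3) *
    (params$phi_max + phi_c) / (params$phi_max - phi_c)
  out[Ft <= 0] <- 0
  if (is.matrix(Fp)) dim(out) <- dim(Fp)
  out
}

#' Inlet pressure for a target wall shear rate
#'
#' In a planar channel of height H the pressure drop \eqn{\Delta p = 2 L
#' \gamma \mu / H} produces a clot-free Poiseuille flow with wall shear
#' exactly \eqn{\gamma}. (The cylindrical-vessel counterpart
#' \eqn{4 L \gamma \mu / D} is available via
#' [inlet_pressure_cylindrical()] for reference.)
#'
#' @param gamma Wall shear rate (s^-1).
#' @param geom A \code{channel_geometry}.
#' @param flow A \code{flow_params}.
#' @return Inlet pressure (relative to the outlet).
#' @export
inlet_pressure <- function(gamma, geom, flow) {
  stopifnot(gamma >= 0, inherits(geom, "channel_geometry"),
            inherits(flow, "flow_params"))
  2 * geom$L * gamma * flow$mu / geom$H + flow$p_out
}

#' @rdname inlet_pressure
#' @export
inlet_pressure_cylindrical <- function(gamma, geom, flow) {
  stopifnot(gamma >= 0)
  4 * geom$L * gamma * flow$mu / geom$H + flow$p_out
}

#' Quasi-steady Stokes-Brinkman channel flow
#'
#' Solves the steady Stokes equations with a Brinkman drag
#' \eqn{-\mu u / K_f} on a staggered (MAC) grid: velocity unknowns on cell
#' faces, pressure in cell centers, pressure Dirichlet conditions at inlet
#' and outlet, no-slip walls. Plasma inertia is negligible at these scales,
#' so the flow is treated as instantaneous for the current resistance
#' field. The discrete solution is divergence-free to solver precision.
#'
#' @param geom A \code{channel_geometry}.
#' @param flow A \code{flow_params}.
#' @param invKf Inverse-permeability field (nx x ny matrix, mm^-2), or
#'   \code{NULL} for a clot-free channel.
#' @param p_in Inlet pressure; default from [inlet_pressure()] at
#'   \code{flow$gamma}.
#' @return A list of class \code{flow_state}: \code{u} ((nx+1) x ny face
#'   velocities, mm/s), \code{v} (nx x (ny+1), wall rows zero), \code{p}
#'   (nx x ny), \code{flowrate} (mm^2/s), \code{div_residual} (max
#'   divergence), \code{wall_shear} (realized bottom-wall shear averaged
#'   over the mid-channel, s^-1).
#' @export
solve_channel_flow <- function(geom, flow, invKf = NULL, p_in = NULL) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(flow, "flow_params"))
  nx <- geom$nx; ny <- geom$ny; h <- geom$h; mu <- flow$mu
  if (is.null(invKf)) invKf <- matrix(0, nx, ny)
  stopifnot(nrow(invKf) == nx, ncol(invKf) == ny, all(invKf >= 0))
  if (is.null(p_in)) p_in <- inlet_pressure(flow$gamma, geom, flow)
  p_out <- flow$p_out

  Nu <- (nx + 1) * ny
  Nv <- nx * max(ny - 1, 0)
  Np <- nx * ny
  iu <- function(f, j) f + 1 + (nx + 1) * (j - 1)      # f in 0..nx
  iv <- function(i, j) Nu + i + nx * (j - 1)           # j in 1..ny-1
  ip <- function(i, j) Nu + Nv + i + nx * (j - 1)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  b <- numeric(Nu + Nv + Np)
  add <- function(r, c, val) {
    ti <<- c(ti, r); tj <<- c(tj, c); tx <<- c(tx, val)
  }
  c1 <- mu / h^2

  # --- u-momentum rows ---
  fs <- rep(0:nx, times = ny)
  js <- rep(seq_len(ny), each = nx + 1)
  rows <- iu(fs, js)
  # x-direction viscous sides (Neumann ghosts at inlet/outlet faces)
  west <- fs >= 1
  add(rows[west], iu(fs[west] - 1, js[west]), rep(-c1, sum(west)))
  east <- fs <= nx - 1
  add(rows[east], iu(fs[east] + 1, js[east]), rep(-c1, sum(east)))
  diagu <- ifelse(west, c1, 0) + ifelse(east, c1, 0)
  # y-direction viscous sides. At wall-adjacent rows the transverse second
  # derivative uses the one-sided quadratic through u(0) = 0, u(h/2),
  # u(3h/2), which is exact for the Poiseuille parabola; interior rows use
  # the standard central stencil.
  south <- js >= 2
  at_wall <- (js == 1 | js == ny) & ny >= 2
  coef_in <- ifelse(at_wall, 4 / 3 * c1, c1)
  add(rows[south], iu(fs[south], js[south] - 1), -coef_in[south])
  north <- js <= ny - 1
  add(rows[north], iu(fs[north], js[north] + 1), -coef_in[north])
  diagu <- diagu + ifelse(south, c1, 3 * c1) + ifelse(north, c1, 3 * c1)
  # Brinkman drag at the face (adjacent-cell average)
  wcell <- pmax(fs, 1); ecell <- pmin(fs + 1, nx)
  rface <- (invKf[cbind(wcell, js)] + invKf[cbind(ecell, js)]) / 2
  diagu <- diagu + mu * rface
  add(rows, rows, diagu)
  # pressure gradient
  interior <- fs >= 1 & fs <= nx - 1
  add(rows[interior], ip(fs[interior] + 1, js[interior]),
      rep(1 / h, sum(interior)))
  add(rows[interior], ip(fs[interior], js[interior]),
      rep(-1 / h, sum(interior)))
  inletf <- fs == 0
  add(rows[inletf], ip(1, js[inletf]), rep(2 / h, sum(inletf)))
  b[rows[inletf]] <- 2 * p_in / h
  outletf <- fs == nx
  add(rows[outletf], ip(nx, js[outletf]), rep(-2 / h, sum(outletf)))
  b[rows[outletf]] <- -2 * p_out / h

  # --- v-momentum rows (interior horizontal faces) ---
  if (ny > 1) {
    is <- rep(seq_len(nx), times = ny - 1)
    jsv <- rep(seq_len(ny - 1), each = nx)
    rv <- iv(is, jsv)
    westv <- is >= 2
    add(rv[westv], iv(is[westv] - 1, jsv[westv]), rep(-c1, sum(westv)))
    eastv <- is <= nx - 1
    add(rv[eastv], iv(is[eastv] + 1, jsv[eastv]), rep(-c1, sum(eastv)))
    diagv <- ifelse(westv, c1, 2 * c1) + ifelse(eastv, c1, 2 * c1)
    southv <- jsv >= 2
    add(rv[southv], iv(is[southv], jsv[southv] - 1), rep(-c1, sum(southv)))
    northv <- jsv <= ny - 2
    add(rv[northv], iv(is[northv], jsv[northv] + 1), rep(-c1, sum(northv)))
    # wall-adjacent sides: the wall value v = 0 contributes only to the diagonal
    diagv <- diagv + c1 + c1
    rfacev <- (invKf[cbind(is, jsv)] + invKf[cbind(is, jsv + 1)]) / 2
    diagv <- diagv + mu * rfacev
    add(rv, rv, diagv)
    add(rv, ip(is, jsv + 1), rep(1 / h, length(rv)))
    add(rv, ip(is, jsv), rep(-1 / h, length(rv)))
  }

  # --- continuity rows ---
  isc <- rep(seq_len(nx), times = ny)
  jsc <- rep(seq_len(ny), each = nx)
  rc <- ip(isc, jsc)
  add(rc, iu(isc, jsc), rep(1, length(rc)))
  add(rc, iu(isc - 1, jsc), rep(-1, length(rc)))
  hasN <- jsc <= ny - 1
  add(rc[hasN], iv(isc[hasN], jsc[hasN]), rep(1, sum(hasN)))
  hasS <- jsc >= 2
  add(rc[hasS], iv(isc[hasS], jsc[hasS] - 1), rep(-1, sum(hasS)))

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = rep(Nu + Nv + Np, 2))
  sol <- as.numeric(Matrix::solve(A, b))

  u <- matrix(sol[seq_len(Nu)], nx + 1, ny)
  v <- matrix(0, nx, ny + 1)
  if (ny > 1) {
    v[, 2:ny] <- matrix(sol[Nu + seq_len(Nv)], nx, ny - 1)
  }
  p <- matrix(sol[Nu + Nv + seq_len(Np)], nx, ny)

  divres <- max(abs((u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) +
                    (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE])) / h)
  Q <- h * sum(u[1, ])
  # realized bottom-wall shear: one-sided quadratic through u(h/2), u(3h/2)
  mid <- max(1, round(nx / 2))
  shear <- if (ny >= 2) {
    (9 * u[mid, 1] - u[mid, 2]) / (3 * h)
  } else u[mid, 1] / (h / 2)
  structure(list(u = u, v = v, p = p, flowrate = Q, div_residual = divres,
                 wall_shear = shear, p_in = p_in, geom = geom, flow = flow),
            class = "flow_state")
}

#' @exportS3Method base::print
print.flow_state <- function(x, ...) {
  cat("<flow_state> ", x$geom$nx, "x", x$geom$ny,
      " cells; flow rate ", signif(x$flowrate, 4),
      " mm^2/s; wall shear ", signif(x$wall_shear, 4),
      " s^-1; max |div u| ", format(x$div_residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Advance the flow to the current clot resistance
#'
#' The flow responds quasi-statically to clot growth (plasma inertia is
#' negligible), so a "flow step" is a fresh steady Stokes-Brinkman solve
#' against the supplied resistance field.
#'
#' @param state A \code{flow_state} (supplies geometry, parameters and
#'   inlet pressure).
#' @param invKf Inverse-permeability field (nx x ny, mm^-2).
#' @return An updated \code{flow_state}.
#' @export
step_flow <- function(state, invKf) {
  stopifnot(inherits(state, "flow_state"))
  solve_channel_flow(state$geom, state$flow, invKf, p_in = state$p_in)
}

#' Apply the tissue-factor surface reaction to the IXa/Xa field
#'
#' Saturating Robin influx on the patch faces of the bottom wall:
#' \eqn{D \partial Ba/\partial n = \alpha_1 (B^0 - Ba) / (1 + \beta_1 (B^0 -
#' Ba))}, applied implicitly (backward Euler) to the patch-adjacent cells,
#' so the near-saturated regime is stable at any time step. Cells outside
#' the patch are untouched (zero flux at the intact wall).
#'
#' @param Ba IXa/Xa concentration field (nx x ny matrix, nM).
#' @param dt Time step (s).
#' @param geom A \code{channel_geometry} (supplies the patch columns and h).
#' @param alpha1,beta1,B0 Surface-reaction constants (defaults: packaged
#'   flow set).
#' @return The updated \code{Ba} matrix.
#' @export
apply_patch_bc <- function(Ba, dt, geom, alpha1 = 7.7e4, beta1 = 0.225,
                           B0 = 200) {
  stopifnot(is.matrix(Ba), inherits(geom, "channel_geometry"),
            nrow(Ba) == geom$nx, ncol(Ba) == geom$ny, dt > 0)
  cols <- geom$patch_cols
  if (!length(cols) || alpha1 == 0) return(Ba)
  gap <- B0 - Ba[cols, 1]
  gap[gap < 0] <- 0
  cc <- dt / geom$h * alpha1
  if (beta1 > 0) {
    bb <- 1 + cc - gap * beta1
    x <- (-bb + sqrt(bb^2 + 4 * beta1 * gap)) / (2 * beta1)
    x <- pmin(pmax(x, 0), gap)
  } else {
    x <- gap / (1 + cc)
  }
  Ba[cols, 1] <- B0 - x
  Ba
}
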