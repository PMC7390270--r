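# Independent reference implementations used as oracles. These deliberately
# avoid the package's own solver paths: fixed-step classical RK4 for the
# generation kinetics, direct polynomial algebra for the reaction term, and
# a plain explicit front tracker for wave fields.

# classical fixed-step RK4 for the four-variable generation kinetics
rk4_generation <- function(p, t_end, dt, out_every) {
  rhs <- function(y) {
    Xa <- y[1]; II <- y[2]; IIa <- y[3]; AT <- y[4]
    act <- p$a1 * p$TF * p$VIIa + (p$a2 + p$a3 * p$phi0) * IIa
    conv <- (p$b1 * Xa + p$k3 * IIa + p$k4 * IIa^2 + p$k5 * IIa^3) * II
    c(act * (p$X0 - Xa) - p$a4 * Xa * AT,
      -conv,
      conv - p$b2 * AT * IIa,
      -p$a4 * Xa * AT - p$b2 * IIa * AT)
  }
  n <- round(t_end / dt)
  stride <- round(out_every / dt)
  y <- c(0, p$II0, 0, p$ATIII0)
  out <- matrix(NA_real_, n %/% stride + 1, 5)
  out[1, ] <- c(0, y)
  k <- 1
  for (i in seq_len(n)) {
    k1v <- rhs(y)
    k2v <- rhs(y + dt / 2 * k1v)
    k3v <- rhs(y + dt / 2 * k2v)
    k4v <- rhs(y + dt * k3v)
    y <- y + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (i %% stride == 0) {
      k <- k + 1
      out[k, ] <- c(i * dt, y)
    }
  }
  colnames(out) <- c("time", "Xa", "II", "IIa", "ATIII")
  out
}

# direct term-by-term evaluation of the wave reaction polynomial
phi_direct <- function(T, y, p) {
  Ba <- p$B0 * exp(-p$Ba_decay * y)
  sig <- p$k6 * p$A0 + p$a * p$gamma
  (p$k1 * p$phi0 + p$k2 * Ba + p$k3 * T + p$k4 * T^2 + p$k5 * T^3) *
    (p$P0 - T) - sig * T
}

# level-set front position clamped to the domain: 0 when the front is
# extinct, L when the high state fills the domain
front_positions <- function(Tmat, y, level) {
  L <- max(y)
  apply(Tmat, 1, function(Tr) {
    idx <- which(Tr > level)
    if (!length(idx)) return(0)
    i <- max(idx)
    if (i == length(Tr)) return(L)
    stats::approx(Tr[i:(i + 1)], y[i:(i + 1)], xout = level)$y
  })
}

# displacement of the front over the final third of the run, falling back
# to the whole run when the final-third window is saturated
front_displacement <- function(Tmat, y, level) {
  pos <- front_positions(Tmat, y, level)
  n <- length(pos)
  disp <- pos[n] - pos[ceiling(2 * n / 3)]
  if (abs(disp) < 1e-9) disp <- pos[n] - pos[1]
  disp
}

# total "mass" of a 1D nodal profile under the trapezoidal rule
trapz_mass <- function(profile, h) {
  h * (sum(profile) - (profile[1] + profile[length(profile)]) / 2)
}

desk_geom <- function(patch_width = 0.2) {
  channel_geometry(L = 4, H = 1, patch_start = 1, patch_width = patch_width,
                   h = 0.04)
}
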