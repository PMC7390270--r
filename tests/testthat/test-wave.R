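test_that("reaction term matches direct polynomial evaluation", {
  p <- wave_params()
  # anchors of the algebra
  p0 <- wave_params(phi0 = 0, B0 = 0)
  expect_equal(reaction_term(0, 0, p0), 0)  # origin is an equilibrium
  sig <- p$k6 * p$A0 + p$a * p$gamma
  expect_equal(reaction_term(p$P0, 0.3, p), -sig * p$P0)  # production vanishes at P0

  set.seed(5)
  for (i in 1:20) {
    q <- wave_params(gamma = stats::runif(1, 0, 200),
                     phi0 = stats::runif(1, 0, 400))
    Tv <- stats::runif(3, 0, q$P0)
    yv <- stats::runif(1, 0, 1)
    expect_equal(reaction_term(Tv, yv, q), phi_direct(Tv, yv, q),
                 tolerance = 1e-12)
  }
})

test_that("boundary-layer profile is exponential and solves its stationary problem", {
  p <- wave_params()
  expect_equal(ba_profile(0, p), p$B0)
  pflat <- wave_params(Ba_decay = 0)
  expect_equal(ba_profile(c(0, 0.3, 1), pflat), rep(pflat$B0, 3))

  # independent finite-difference solve of D B'' = D lambda^2 B with
  # B(0) = B0 and the analytic value at the far end
  lam <- p$Ba_decay
  L <- 0.4; h <- 1e-3
  y <- seq(0, L, h)
  n <- length(y)
  main <- rep(-2 / h^2 - lam^2, n - 2)
  off <- rep(1 / h^2, n - 3)
  A <- Matrix::bandSparse(n - 2, n - 2, k = -1:1,
                          diagonals = list(off, main, off))
  rhs <- rep(0, n - 2)
  rhs[1] <- -p$B0 / h^2
  rhs[n - 2] <- -p$B0 * exp(-lam * L) / h^2
  sol <- as.numeric(Matrix::solve(A, rhs))
  expect_lt(max(abs(sol - ba_profile(y[2:(n - 1)], p))) / p$B0, 1e-4)
})

test_that("equilibria agree with a companion-matrix root finder", {
  # strong sink: single stable root near zero
  phuge <- wave_params(gamma = 1e5, phi0 = 0, B0 = 0)
  eq <- find_equilibria(phuge, 0)
  expect_equal(sum(eq$stable), length(eq$roots[eq$stable]))
  expect_lt(eq$T2, 1e-3 * phuge$P0)

  # stability of the origin flips exactly where k3 P0 crosses sigma
  pz <- wave_params(phi0 = 0, B0 = 0, a = 1)
  sig0 <- pz$k6 * pz$A0
  gamma_flip <- pz$k3 * pz$P0 - sig0
  for (eps in c(-1e-3, 1e-3)) {
    pz$gamma <- gamma_flip + eps
    eqz <- find_equilibria(pz, 0)
    i0 <- which.min(abs(eqz$roots))
    expect_equal(abs(eqz$roots[i0]) < 1e-9, TRUE)
    expect_equal(eqz$stable[i0], eps > 0)
  }

  # bistable draws against polyroot on the same quartic
  set.seed(9)
  found <- 0
  while (found < 5) {
    q <- wave_params(phi0 = 0, B0 = 0,
                     k3 = 1.5e-5 * exp(stats::runif(1, -0.5, 0.5)),
                     k4 = 8e-6 * exp(stats::runif(1, -0.5, 0.5)),
                     gamma = stats::runif(1, 10, 150))
    eq <- tryCatch(find_equilibria(q, 0), error = function(e) NULL)
    if (is.null(eq) || !eq$bistable) next
    found <- found + 1
    cf <- c((q$k1 * q$phi0 + q$k2 * q$B0) * q$P0,
            q$k3 * q$P0 - (q$k6 * q$A0 + q$a * q$gamma),
            q$k4 * q$P0 - q$k3, q$k5 * q$P0 - q$k4, -q$k5)
    r <- polyroot(cf)
    rr <- sort(Re(r[abs(Im(r)) < 1e-8 * Mod(r) | Mod(r) < 1e-30]))
    rr <- rr[rr >= -1e-9 & rr <= q$P0]
    for (root in eq$roots) {
      expect_lt(min(abs(rr - root)) / max(root, 1), 1e-6)
    }
  }
})

test_that("closed-form propagation integral matches adaptive quadrature", {
  set.seed(13)
  found <- 0
  while (found < 5) {
    q <- wave_params(phi0 = stats::runif(1, 0, 200),
                     gamma = stats::runif(1, 100, 700))
    eq <- tryCatch(find_equilibria(q, 0), error = function(e) NULL)
    if (is.null(eq) || !eq$bistable) next
    found <- found + 1
    wc <- wave_criterion(q, 0)
    ref <- stats::integrate(function(T) reaction_term(T, 0, q),
                            eq$T0, eq$T2, rel.tol = 1e-12,
                            abs.tol = 1e-12)$value
    expect_lt(abs(wc$integral - ref) / max(abs(ref), 1e-8), 1e-10)
  }
  expect_error(wave_criterion(wave_params(gamma = 0), 0), "not bistable")
})

test_that("shear threshold behaves as the criterion's stall point", {
  p <- wave_params(phi0 = 300)
  gs <- shear_threshold(p, y = 0)
  # the integral changes sign across the threshold
  for (s in c(-1, 1)) {
    p$gamma <- gs + s * 0.5
    wc <- wave_criterion(p, 0)
    expect_equal(wc$propagates, s < 0)
  }
  # near the stall the integral itself is close to zero
  p$gamma <- gs
  wc <- wave_criterion(p, 0)
  scale <- abs(wave_criterion(wave_params(phi0 = 300, gamma = 0.9 * gs),
                              0)$integral)
  expect_lt(abs(wc$integral), 0.05 * scale)

  # no flow removal: sigma is gamma-independent, threshold cannot exist
  expect_error(shear_threshold(wave_params(a = 0), y = 0),
               "threshold not found")

  # monotone and nearly linear in the platelet count
  phis <- seq(0, 400, 100)
  gstars <- vapply(phis, function(ph)
    shear_threshold(wave_params(phi0 = ph), y = 0), numeric(1))
  expect_true(all(diff(gstars) > 0))
  r2 <- summary(stats::lm(gstars ~ phis))$r.squared
  expect_gt(r2, 0.99)

  # the frozen-T2 closed form is a biased but same-scale approximation of
  # the exact stall point (it ignores the shear dependence of T0 and T2)
  cf <- shear_threshold_closed_form(wave_params(phi0 = 300), y = 0)
  expect_lt(abs(cf - gs) / gs, 0.3)
})

test_that("heat-equation limit conserves mass and respects the maximum principle", {
  p <- wave_params(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0, a = 0,
                   B0 = 0, phi0 = 0)
  y <- seq(0, 1, 0.02)
  gauss <- 300 * exp(-((y - 0.5) / 0.08)^2)
  wf <- simulate_wave(p, L = 1, t_end = 400, dt_out = 100, initial = gauss,
                      rtol = 1e-10, atol = 1e-10)
  m0 <- trapz_mass(gauss, 0.02)
  for (k in seq_along(wf$times)) {
    expect_lt(abs(trapz_mass(wf$T[k, ], 0.02) - m0) / m0, 1e-8)
    expect_lt(max(wf$T[k, ]), max(gauss) * (1 + 1e-8))
    expect_gt(min(wf$T[k, ]), -1e-8 * max(gauss))
  }
})

test_that("occluded fraction and initiation time read the field correctly", {
  p <- wave_params()
  y <- seq(0, 1, 0.02)
  zeroes <- matrix(0, 3, length(y))
  wf <- structure(list(y = y, times = c(0, 400, 800), T = zeroes, params = p),
                  class = "wave_field")
  expect_equal(occluded_fraction(wf, 800), 0)
  expect_true(is.na(initiation_time(wf)))
  wf$T[3, ] <- 500
  expect_equal(occluded_fraction(wf, 800), 100)
  expect_equal(initiation_time(wf), 800)
  wf$T[3, ] <- ifelse(y <= 0.5, 500, 0)
  frac <- occluded_fraction(wf, 800)
  expect_gt(frac, 45); expect_lt(frac, 55)
})

test_that("sub-threshold shear gives early initiation, super-threshold none", {
  p <- wave_params(phi0 = 300, gamma = 25)
  wf <- simulate_wave(p, t_end = 900, dt_out = 5)
  tinit <- initiation_time(wf)
  expect_lt(tinit, 800)
  expect_equal(occluded_fraction(wf, 800), 100)

  gs <- shear_threshold(p, y = 0)
  p$gamma <- 1.5 * gs
  wf2 <- simulate_wave(p, t_end = 1200, dt_out = 20)
  expect_lt(max(wf2$T), p$Tstar)
})

# a configuration in which the wall boundary layer decides how deep the
# clot grows: platelet-free plasma, surface production strong enough to
# matter against the cubic feedback, shear a little above the far-field
# stall so growth must arrest at finite depth
.layer_limited_params <- function(Ba_decay = 23) {
  p <- wave_params(phi0 = 0, k2 = 7.5e-3, Ba_decay = Ba_decay)
  far <- shear_threshold(wave_params(phi0 = 0, B0 = 0), y = 0)
  p$gamma <- far + 40
  p
}

test_that("clot size shrinks as the boundary layer thins", {
  sizes <- vapply(c(8, 16, 32), function(lam)
    clot_final_size(.layer_limited_params(lam), L = 1), numeric(1))
  expect_true(all(sizes > 0 & sizes < 1))
  expect_true(all(diff(sizes) < 0))

  # a y-independent positive criterion fills the whole domain
  pfull <- wave_params(phi0 = 300, gamma = 0, Ba_decay = 0)
  expect_equal(clot_final_size(pfull, L = 1), 1)
})

test_that("predicted clot size brackets the simulated thrombin extent", {
  p <- .layer_limited_params(16)
  ystop <- clot_final_size(p, L = 1)
  expect_gt(ystop, 0.02); expect_lt(ystop, 1)
  wf <- simulate_wave(p, L = 1, t_end = 3000, dt_out = 100)
  prof <- wf$T[nrow(wf$T), ]
  extent <- max(c(0, wf$y[prof > p$Tstar]))
  expect_lt(abs(extent - ystop), max(0.3 * ystop, 0.08))
})
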