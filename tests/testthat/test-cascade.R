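test_that("lumping formulas evaluate the printed algebra exactly", {
  unit <- cascade_rates(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(unname(lump_constants(unit)), c(1, 2, 1))

  nocomplex <- cascade_rates(1, 1, 2, 3, 4, 5, 0, 0, 1, 1, 0.5, 0.5, 2)
  lk <- lump_constants(nocomplex)
  expect_equal(lk[["k4"]], 0)
  expect_equal(lk[["k5"]], 0)
  expect_equal(lk[["k3"]], 2 * 3 * 4 * 5 / (0.5 * 0.5 * 2))

  # random positive draws against independent term-by-term evaluation
  set.seed(11)
  for (i in 1:10) {
    v <- exp(stats::runif(13, -2, 2))
    cr <- cascade_rates(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                        v[9], v[10], v[11], v[12], v[13])
    lk <- lump_constants(cr)
    k3_ref <- v[3] * v[4] * v[5] * v[6] / (v[11] * v[12] * v[13])
    k4_ref <- v[2] * v[3] * v[4] * v[7] * v[6] / (v[10] * v[11] * v[12] * v[13]) +
      v[1] * v[3] * v[4] * v[5] * v[8] / (v[9] * v[11] * v[12] * v[13])
    k5_ref <- v[1] * v[2] * v[3] * v[4] * v[7] * v[8] /
      (v[9] * v[10] * v[11] * v[12] * v[13])
    expect_equal(unname(lk), c(k3_ref, k4_ref, k5_ref), tolerance = 1e-12)
  }
})

test_that("lumping is homogeneous under joint rate scaling", {
  set.seed(3)
  v <- exp(stats::runif(13, -1, 1))
  cr <- cascade_rates(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                      v[9], v[10], v[11], v[12], v[13])
  lk <- lump_constants(cr)
  cc <- 7
  cr2 <- cascade_rates(cc * v[1], cc * v[2], cc * v[3], cc * v[4], cc * v[5],
                       cc * v[6], cc * v[7], cc * v[8], cc * v[9], cc * v[10],
                       cc * v[11], cc * v[12], cc * v[13])
  lk2 <- lump_constants(cr2)
  # k3: four activations over three inhibitions -> one net power of c;
  # k4: five over four; k5: six over five
  expect_equal(lk2[["k3"]], cc * lk[["k3"]], tolerance = 1e-12)
  expect_equal(lk2[["k4"]], cc * lk[["k4"]], tolerance = 1e-12)
  expect_equal(lk2[["k5"]], cc * lk[["k5"]], tolerance = 1e-12)
})

test_that("the default rate set reproduces the flow-table lumped constants", {
  cr <- default_cascade_rates()
  lk <- lump_constants(cr)
  expect_equal(lk[["k3"]], 1.5e-5, tolerance = 1e-10)
  expect_equal(lk[["k4"]], 8e-6, tolerance = 1e-10)
  expect_equal(lk[["k5"]], 1e-10, tolerance = 1e-10)
})

test_that("equilibrium map matches hand values and the clamped-thrombin ODE", {
  cr <- cascade_rates(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  eq0 <- equilibrium_map(0, cr)
  expect_true(all(eq0[, c("Va", "VIIIa", "XIa", "IXa", "Xa")] == 0))
  eq1 <- equilibrium_map(1, cr)
  expect_equal(eq1$Va, 1)
  expect_equal(eq1$VIIIa, 1)
  expect_equal(eq1$XIa, 1)
  expect_equal(eq1$IXa, 1)
  expect_equal(eq1$Xa, 2)  # direct route 1 plus complex route 1*1

  # long-time limit of the chain with thrombin clamped at 50 nM
  cr <- default_cascade_rates()
  Tc <- 50
  rhs <- function(t, y, parms) {
    with(as.list(c(y, cr)), list(c(
      khat1 * Tc - h1 * Va,
      khat2 * Tc - h2 * VIIIa,
      khat3 * Tc - h3 * XIa,
      khat4 * XIa - h4 * IXa,
      khat5 * IXa + khat55 * VIIIa * IXa - h5 * Xa)))
  }
  y0 <- c(Va = 0, VIIIa = 0, XIa = 0, IXa = 0, Xa = 0)
  out <- deSolve::ode(y0, c(0, 15 / cr$h1), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  lim <- out[nrow(out), -1]
  ref <- equilibrium_map(Tc, cr)
  for (sp in c("Va", "VIIIa", "XIa", "IXa", "Xa")) {
    expect_lt(abs(lim[[sp]] - ref[[sp]]) / max(ref[[sp]], 1e-12), 0.01)
  }
})

test_that("zero state is invariant and D = 0 reduces to the pure kinetics", {
  cr <- default_cascade_rates(sigma = 0.05)
  tr <- simulate_cascade(cr, rep(0, 26), L = 0.5, h = 0.02, t_end = 20,
                         dt_out = 10)
  expect_true(all(abs(tr$fields) < 1e-10))

  # spatially uniform initial data with no diffusion: every node follows the
  # same ODE, checked against an independent integration
  cr0 <- default_cascade_rates(sigma = 0.05, D = 0)
  T_init <- rep(40, 26)
  tr <- simulate_cascade(cr0, T_init, L = 0.5, h = 0.02, t_end = 30,
                         dt_out = 15)
  rhs <- function(t, y, parms) {
    with(as.list(c(y, cr0)), {
      prod <- (khat6 * Xa + khat66 * Xa * Va) * max(P - T, 0)
      list(c(khat1 * T - h1 * Va, khat2 * T - h2 * VIIIa,
             khat3 * T - h3 * XIa, khat4 * XIa - h4 * IXa,
             khat5 * IXa + khat55 * VIIIa * IXa - h5 * Xa,
             prod - sigma * T))
    })
  }
  y0 <- unlist(equilibrium_map(40, cr0)[1, c("Va", "VIIIa", "XIa", "IXa",
                                             "Xa", "T")])
  ref <- deSolve::ode(y0, c(0, 15, 30), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  for (k in 2:3) {
    for (sp in c("Va", "Xa", "T")) {
      node_vals <- tr$fields[k, , sp]
      expect_lt(diff(range(node_vals)), 1e-6 * max(abs(node_vals), 1))
      expect_lt(abs(node_vals[1] - ref[k, sp]) / max(abs(ref[k, sp]), 1e-9),
                1e-4)
    }
  }
})

test_that("species stay nonnegative and bounded along a propagating front", {
  cr <- default_cascade_rates(sigma = 4.817e-6 * 3400 + 5.6e-3 * 5)
  y <- seq(0, 1, 0.02)
  tr <- simulate_cascade(cr, ifelse(y < 0.3, 1300, 0), L = 1, h = 0.02,
                         t_end = 40, dt_out = 20)
  expect_true(all(tr$fields > -1e-6))
  expect_true(all(tr$fields[, , "T"] <= cr$P * (1 + 1e-6)))
})

test_that("identical models report zero discrepancy and sub-threshold draws no wave", {
  # reduced-vs-reduced: compare the lumped wave against itself
  cr <- default_cascade_rates(sigma = 0.05)
  lk <- lump_constants(cr)
  wp <- wave_params(k1 = 0, k2 = 0, B0 = 0, phi0 = 0, k3 = lk[["k3"]],
                    k4 = lk[["k4"]], k5 = lk[["k5"]], k6 = 0, A0 = 0,
                    a = 1, gamma = 0.05, P0 = cr$P, D = cr$D)
  eq <- find_equilibria(wp, 0)
  y <- seq(0, 1.5, 0.02)
  seed <- ifelse(y < 0.4, eq$T2, 0)
  a <- simulate_wave(wp, L = 1.5, t_end = 60, dt_out = 10, initial = seed)
  b <- simulate_wave(wp, L = 1.5, t_end = 60, dt_out = 10, initial = seed)
  expect_equal(a$T, b$T)

  # a sink too strong for any wave: both tiers report no propagation
  cr_hi <- default_cascade_rates(sigma = 5)
  cmp <- compare_reduction(cr_hi, L = 1, t_end = 30, dt_out = 10)
  expect_true(cmp$no_wave || is.na(cmp$rel_speed_diff))
})
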