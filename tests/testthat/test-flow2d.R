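test_that("Davies resistance matches hand evaluation and its limits", {
  pp <- permeability_params()
  expect_equal(permeability_resistance(0, 0, pp), 0)
  # saturated fibrin, no platelets: (16/alpha^2) 0.7^1.5 (1 + 56*0.343)
  hand <- 16 / (6e-4)^2 * 0.7^1.5 * (1 + 56 * 0.7^3)
  expect_equal(permeability_resistance(7000, 0, pp), hand, tolerance = 1e-12)
  expect_equal(hand, 5.26e8, tolerance = 2e-3)
  # monotone divergence as platelets pack toward phi_max
  phis <- c(0, 200, 380, 399.9)
  r <- permeability_resistance(rep(7000, 4), phis, pp)
  expect_true(all(diff(r) > 0))
  expect_gt(r[4], 1000 * r[1])
  expect_error(permeability_resistance(10, 400, pp), "singular")
})

test_that("inlet pressure is linear in the shear rate", {
  geom <- channel_geometry()
  fl <- flow_params()
  expect_equal(inlet_pressure(0, geom, fl), 0)
  p1 <- inlet_pressure(10, geom, fl)
  expect_equal(inlet_pressure(20, geom, fl), 2 * p1)
  expect_equal(inlet_pressure_cylindrical(10, geom, fl), 2 * p1)
})

test_that("clot-free channel reproduces plane Poiseuille flow", {
  geom <- channel_geometry()
  fl <- flow_params(gamma = 25)
  fs <- solve_channel_flow(geom, fl)
  uexact <- fs$p_in / (2 * fl$mu * geom$L) * geom$y * (geom$H - geom$y)
  mid <- round(geom$nx / 2)
  expect_lt(max(abs(fs$u[mid, ] - uexact)) / max(uexact), 0.01)
  expect_lt(abs(fs$wall_shear - 25) / 25, 0.02)
  expect_lt(fs$div_residual, 1e-8)
  # inflow equals outflow
  Qin <- geom$h * sum(fs$u[1, ])
  Qout <- geom$h * sum(fs$u[geom$nx + 1, ])
  expect_lt(abs(Qin - Qout) / abs(Qin), 1e-6)
  expect_true(all(abs(fs$v) < 1e-8 * max(fs$u)))
})

test_that("uniform overwhelming resistance stalls the flow", {
  geom <- channel_geometry(L = 2, H = 1, patch_start = 0.5, h = 0.04)
  fl <- flow_params(gamma = 25)
  free <- solve_channel_flow(geom, fl)
  blocked <- solve_channel_flow(geom, fl,
                                invKf = matrix(1e10, geom$nx, geom$ny))
  expect_lt(max(abs(blocked$u)), 1e-6 * max(abs(free$u)))
  expect_lt(abs(blocked$flowrate), 1e-6 * abs(free$flowrate))
})

test_that("a resistive band reroutes and throttles the flow", {
  geom <- channel_geometry(L = 2, H = 1, patch_start = 0.5, h = 0.04)
  fl <- flow_params(gamma = 25)
  free <- solve_channel_flow(geom, fl)
  invKf <- matrix(0, geom$nx, geom$ny)
  band <- geom$x > 0.9 & geom$x < 1.1
  invKf[band, seq_len(round(geom$ny / 2))] <- 1e6  # half-height plug
  half <- solve_channel_flow(geom, fl, invKf)
  expect_lt(half$flowrate, free$flowrate)
  expect_gt(half$flowrate, 0.05 * free$flowrate)
  # velocity inside the plug is tiny compared to the open half
  plug_u <- max(abs(half$u[which(band), seq_len(round(geom$ny / 2))]))
  open_u <- max(abs(half$u[which(band), (round(geom$ny / 2) + 1):geom$ny]))
  expect_lt(plug_u, 0.05 * open_u)
  expect_lt(half$div_residual, 1e-8)
})

test_that("patch Robin update saturates, switches off, and solves its implicit equation", {
  geom <- desk_geom()
  Ba <- matrix(0, geom$nx, geom$ny)
  # saturated surface: no further change
  Ba_sat <- Ba; Ba_sat[geom$patch_cols, 1] <- 200
  expect_equal(apply_patch_bc(Ba_sat, 0.005, geom), Ba_sat)
  # alpha1 = 0: identical evolution to a no-patch configuration
  expect_equal(apply_patch_bc(Ba, 0.005, geom, alpha1 = 0), Ba)
  # implicit update against an independent root solve of the backward-Euler
  # equation x = dt/h * alpha1 (B0 - x)/(1 + beta1 (B0 - x)), x = new value
  up <- apply_patch_bc(Ba, 0.005, geom)
  i <- geom$patch_cols[1]
  g <- function(x) x - 0.005 / geom$h * 7.7e4 * (200 - x) /
    (1 + 0.225 * (200 - x))
  ref <- stats::uniroot(g, c(0, 200), tol = 1e-12)$root
  expect_equal(up[i, 1], ref, tolerance = 1e-8)
  # off-patch cells untouched
  expect_true(all(up[-geom$patch_cols, 1] == 0))
  expect_true(all(up[, -1] == 0))
})

test_that("linear Robin boundary layer matches its closed-form steady profile", {
  # 1D-in-y problem: diffusion with linear decay, driven by a linear
  # (beta1 = 0) Robin influx at the wall; the steady state is
  # B(y) = B_w cosh(kappa (H - y)) / cosh(kappa H)
  H <- 0.8; h <- 0.01
  geom <- channel_geometry(L = 3 * h, H = H, patch_start = h / 2,
                           patch_width = 2 * h, h = h)
  D <- 5e-5; decay <- 0.002; B0 <- 200
  alpha1 <- D * sqrt(decay / D)  # balanced Robin: wall value near B0/2
  ny <- geom$ny
  Ba <- rep(0, ny)
  dt <- 0.4 * h^2 / D
  for (step in 1:8000) {
    # cell-centered zero-flux walls: ghost equals the end cell itself
    lap <- (c(Ba[-1], Ba[ny]) - 2 * Ba + c(Ba[1], Ba[-ny])) / h^2
    Ba <- Ba + dt * (D * lap - decay * Ba)
    m <- matrix(rep(Ba, each = geom$nx), geom$nx, ny)
    m <- apply_patch_bc(m, dt, geom, alpha1 = alpha1, beta1 = 0, B0 = B0)
    Ba <- m[geom$patch_cols[1], ]
  }
  kap <- sqrt(decay / D)
  Bw <- alpha1 * B0 / (D * kap * tanh(kap * H) + alpha1)
  yc <- geom$y
  ref <- Bw * cosh(kap * (H - yc)) / cosh(kap * H)
  expect_lt(max(abs(Ba - ref)) / Bw, 0.02)
})
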