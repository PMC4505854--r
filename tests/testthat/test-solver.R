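test_that("Gaussian initial condition has the right peak and half-width", {
  mesh <- boxMesh(c(20, 20, 20), c(10, 10, 10))
  p <- modelParameters(phi_e = 0.389)
  phi0 <- gaussianInitialCondition(mesh, c(10, 10, 10), sigma_mm = 2, params = p)
  # default amplitude 1.1 phi_e at the center vertex
  expect_equal(max(phi0), 1.1 * 0.389, tolerance = 1e-12)
  expect_equal(phi0[which.max(phi0)], 0.4279, tolerance = 1e-4)
  # half amplitude at r = sigma * sqrt(2 ln 2): vertex (10 + 2 sqrt(2 ln 2)) not
  # on the lattice, so check the formula directly at a lattice vertex
  v <- meshVertices(mesh)
  i <- which(v[, 1] == 12 & v[, 2] == 10 & v[, 3] == 10)
  expect_equal(phi0[i], 1.1 * 0.389 * exp(-4 / 8), tolerance = 1e-12)
  expect_warning(gaussianInitialCondition(mesh, c(10, 10, 10), 2,
                                          amplitude = 0.3, params = p),
                 "phi_e")
})

test_that("initial nutrient solves the steady balance", {
  p <- modelParameters(S_n = 1e4, delta_n = 1e3, n_s = 0.07)
  mesh <- boxMesh(c(8, 8, 8), c(4, 4, 4))
  nv <- nrow(meshVertices(mesh))
  D <- isoCellField(mesh, p@D_n)
  # phi0 = 0 with Dirichlet boundary: exactly n_s
  n0 <- initialNutrient(mesh, rep(0, nv), D, p)
  expect_equal(max(abs(n0 - p@n_s)), 0, tolerance = 1e-12 * p@n_s)
  # uniform phi with the no-flux harness: closed-form reaction balance
  nbar <- initialNutrient(mesh, rep(0.5, nv), D, p, no_flux = TRUE)
  expect_equal(unique(round(nbar, 12)), round(1e4 * 0.07 / (1e4 + 500), 12))
  expect_equal(nbar[1], 0.0666667, tolerance = 1e-6)
  # Gaussian lesion: minimum at the core, discrete maximum principle
  pg <- modelParameters(S_n = 1e4, delta_n = 8640, n_s = 0.07)
  meshg <- boxMesh(c(24, 24, 24), c(12, 12, 12))
  phig <- gaussianInitialCondition(meshg, c(12, 12, 12), 2, params = pg)
  ng <- initialNutrient(meshg, phig, isoCellField(meshg, pg@D_n), pg)
  vg <- meshVertices(meshg)
  dmin <- sqrt(sum((vg[which.min(ng), ] - c(12, 12, 12))^2))
  expect_lt(dmin, 2 * sqrt(3) + 1e-12)  # within one cell diameter of the center
  expect_true(all(ng >= 0 & ng <= pg@n_s * (1 + 1e-6)))
})

test_that("the all-healthy state is a fixed point of the stepper", {
  p <- modelParameters(nu_c = 1, k_n = 100)
  mesh <- boxMesh(c(8, 8, 8), c(3, 3, 3))
  nv <- nrow(meshVertices(mesh))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  cfg <- solverConfig(dt = 0.1, t_end = 0.5, output_every = 1L)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0 = rep(0, nv))
  for (s in trajectoryStates(tr)) {
    expect_equal(max(abs(s@phi)), 0)
    expect_equal(max(abs(s@n - p@n_s)), 0, tolerance = 1e-12 * p@n_s)
  }
})

test_that("uniform no-flux runs track the two-ODE reduction at second order", {
  skip_if_not_installed("deSolve")
  p <- modelParameters(nu_c = 1, delta_c = 0.3, S_n = 100, delta_n = 50, k_n = 0)
  mesh <- boxMesh(c(4, 4, 4), c(2, 2, 2))
  e1 <- uniformRunError(mesh, p, 0.2, 0.8 * p@n_s, 0.5, 0.05)
  e2 <- uniformRunError(mesh, p, 0.2, 0.8 * p@n_s, 0.5, 0.025)
  expect_gt(log2(e1 / e2), 1.8)
  # absolute agreement is already tight at dt = 0.05
  expect_lt(e1, 1e-4)
})

test_that("uniform fields stay uniform and single-step matches runSimulation", {
  p <- modelParameters(nu_c = 1, S_n = 100, delta_n = 50, k_n = 0)
  mesh <- boxMesh(c(4, 4, 4), c(2, 2, 2))
  nv <- nrow(meshVertices(mesh))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  cfg <- solverConfig(dt = 0.05, t_end = 0.05, output_every = 1L, no_flux = TRUE)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0 = rep(0.2, nv),
                      n0 = rep(0.8 * p@n_s, nv))
  fs <- finalState(tr)
  expect_equal(diff(range(fs@phi)), 0)
  expect_equal(diff(range(fs@n)), 0)
  st0 <- trajectoryStates(tr)[[1]]
  one <- stepSimulation(st0, cfg, p, D, T_f, mesh)
  expect_equal(one@phi, fs@phi, tolerance = 1e-12)
  expect_equal(one@n, fs@n, tolerance = 1e-12)
})

test_that("cell mass is conserved without proliferation and chemotaxis", {
  p <- modelParameters(nu_c = 0, k_n = 0, M = 2000)
  mesh <- boxMesh(c(20, 20, 20), c(6, 6, 6))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  phi0 <- gaussianInitialCondition(mesh, c(10, 10, 10), 3, params = p)
  cfg <- solverConfig(dt = 0.05, t_end = 0.5, output_every = 100L, no_flux = TRUE)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0 = phi0)
  m0 <- lumpedIntegral(mesh, trajectoryStates(tr)[[1]]@phi)
  m1 <- lumpedIntegral(mesh, finalState(tr)@phi)
  expect_lt(abs(m1 - m0) / m0, 1e-6)
})

test_that("with saturating oxygen the total cell mass grows monotonically", {
  p <- modelParameters(nu_c = 1, delta_n = 0, k_n = 0)
  mesh <- boxMesh(c(20, 20, 20), c(6, 6, 6))
  nv <- nrow(meshVertices(mesh))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  phi0 <- gaussianInitialCondition(mesh, c(10, 10, 10), 3, params = p)
  cfg <- solverConfig(dt = 0.1, t_end = 1, output_every = 2L, no_flux = TRUE)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0 = phi0, n0 = rep(p@n_s, nv))
  masses <- vapply(trajectoryStates(tr), function(s) lumpedIntegral(mesh, s@phi),
                   numeric(1))
  expect_true(all(diff(masses) > 0))
  expect_true(all(finalState(tr)@phi <= 1 + 1e-3))
})

test_that("run bookkeeping: snapshots, t_end = 0, determinism", {
  p <- modelParameters(nu_c = 1, S_n = 100, delta_n = 50)
  mesh <- boxMesh(c(8, 8, 8), c(3, 3, 3))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  phi0 <- gaussianInitialCondition(mesh, c(4, 4, 4), 2, params = p)
  # t_end = 0: single snapshot equal to the initial state
  tr0 <- runSimulation(mesh, D, T_f, p, solverConfig(dt = 0.1, t_end = 0), phi0)
  expect_length(trajectoryStates(tr0), 1L)
  expect_equal(finalState(tr0)@t, 0)
  # doubling output_every roughly halves the intermediate snapshot count
  tr1 <- runSimulation(mesh, D, T_f, p,
                       solverConfig(dt = 0.1, t_end = 0.8, output_every = 1L), phi0)
  tr2 <- runSimulation(mesh, D, T_f, p,
                       solverConfig(dt = 0.1, t_end = 0.8, output_every = 2L), phi0)
  n1 <- length(trajectoryStates(tr1)) - 2L  # intermediate snapshots
  n2 <- length(trajectoryStates(tr2)) - 2L
  expect_lte(abs(n1 - 2L * n2), 2L)
  # bit-identical repetition
  tr1b <- runSimulation(mesh, D, T_f, p,
                        solverConfig(dt = 0.1, t_end = 0.8, output_every = 1L), phi0)
  expect_identical(finalState(tr1)@phi, finalState(tr1b)@phi)
  expect_identical(finalState(tr1)@n, finalState(tr1b)@n)
})

test_that("isotropic inputs with a symmetric seed give axis-symmetric fields", {
  p <- modelParameters(nu_c = 1, S_n = 1e4, delta_n = 8640, k_n = 100, M = 2000)
  mesh <- boxMesh(c(16, 16, 16), c(8, 8, 8))
  D <- isoCellField(mesh, p@D_n)
  T_f <- preferentialDirections(D)
  phi0 <- gaussianInitialCondition(mesh, c(8, 8, 8), 2, params = p)
  cfg <- solverConfig(dt = 0.1, t_end = 1, output_every = 100L)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0)
  fs <- finalState(tr)
  v <- meshVertices(mesh)
  # mirror pairs across the x = 8 plane carry equal phi (the Kuhn
  # triangulation is not mirror-symmetric, so allow discretization tolerance)
  key <- paste(v[, 2], v[, 3], pmin(v[, 1], 16 - v[, 1]))
  grp <- split(fs@phi, key)
  spread <- vapply(grp, function(g) diff(range(g)), numeric(1))
  expect_lt(max(spread), 5e-3)
})

test_that("anisotropic preferential directions elongate the tumor on-axis", {
  p <- modelParameters(nu_c = 1, S_n = 1e4, delta_n = 8640, k_n = 100, M = 2000)
  mesh <- boxMesh(c(24, 24, 24), c(10, 10, 10))
  D <- uniformCellField(mesh, c(p@D_n, 0, 0, 0, 0, 0))
  T_f <- preferentialDirections(D)
  expect_equal(unname(tensorValues(T_f)[1, ]), c(3, 0, 0, 0, 0, 0))
  phi0 <- gaussianInitialCondition(mesh, c(12, 12, 12), 2, params = p)
  cfg <- solverConfig(dt = 0.1, t_end = 2, output_every = 100L)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0)
  ax <- semiAxes(mesh, finalState(tr)@phi, 0.05)
  expect_gt(ax["dx"], ax["dy"])
  expect_gt(ax["dx"], ax["dz"])
})

test_that("nutrient respects its physical bounds throughout stiff runs", {
  p <- modelParameters(nu_c = 1, S_n = 1e4, delta_n = 8640, k_n = 100, M = 2000)
  mesh <- boxMesh(c(16, 16, 16), c(8, 8, 8))
  D <- uniformCellField(mesh, c(p@D_n, 0, 0, 0, 0, 0))
  T_f <- preferentialDirections(D)
  phi0 <- gaussianInitialCondition(mesh, c(8, 8, 8), 2, params = p)
  cfg <- solverConfig(dt = 0.1, t_end = 1, output_every = 1L)
  tr <- runSimulation(mesh, D, T_f, p, cfg, phi0)
  for (s in trajectoryStates(tr)) {
    expect_gte(min(s@n), 0)
    expect_lte(max(s@n), p@n_s * (1 + 1e-6))
  }
})
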