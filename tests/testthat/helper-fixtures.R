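# Shared fixtures: everything is generated in code at test time.

# Uniform cell-space tensor field over a mesh (row = xx, yy, zz, xy, xz, yz).
uniformCellField <- function(mesh, row) {
  nc <- nrow(meshCells(mesh))
  tensorField(matrix(row, nc, 6L, byrow = TRUE))
}

isoCellField <- function(mesh, d = 86.4) uniformCellField(mesh, c(d, d, d, 0, 0, 0))

# Random symmetric positive-definite tensors as an n x 6 component matrix,
# built vectorized as L L^T from a random lower-triangular factor.
randomSPDComponents <- function(n, seed = 1L) {
  set.seed(seed)
  l11 <- runif(n, 0.2, 2); l21 <- rnorm(n); l22 <- runif(n, 0.2, 2)
  l31 <- rnorm(n); l32 <- rnorm(n); l33 <- runif(n, 0.2, 2)
  cbind(
    xx = l11^2,
    yy = l21^2 + l22^2,
    zz = l31^2 + l32^2 + l33^2,
    xy = l21 * l11,
    xz = l31 * l11,
    yz = l31 * l21 + l32 * l22
  )
}

# Random rotation matrix (axis-angle).
randomRotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Lumped-mass integral of a vertex field (for mass-conservation checks).
lumpedIntegral <- function(mesh, field) {
  vols <- cellVolumes(mesh)
  cells <- meshCells(mesh)
  acc <- numeric(nrow(meshVertices(mesh)))
  for (a in 1:4) {
    r <- rowsum(vols / 4, cells[, a])
    acc[as.integer(rownames(r))] <- acc[as.integer(rownames(r))] + r
  }
  sum(acc * field)
}

# The two-ODE reduction of the uniform-field model (oracle via deSolve).
odeOracle <- function(phi0, n0, params, t_end) {
  rhs <- function(t, y, parms) {
    list(c(params@nu_c * y[1] * (y[2] / params@n_s - params@delta_c) * (1 - y[1]),
           params@S_n * (params@n_s - y[2]) - params@delta_n * y[1] * y[2]))
  }
  out <- deSolve::lsoda(c(phi0, n0), c(0, t_end), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  unname(out[2L, 2:3])
}

# Max |phi(T) - oracle| over phi and n for a uniform no-flux run at a given dt.
uniformRunError <- function(mesh, params, phi0, n0, t_end, dt) {
  nv <- nrow(meshVertices(mesh))
  D <- isoCellField(mesh, params@D_n)
  T_f <- preferentialDirections(D)
  cfg <- solverConfig(dt = dt, t_end = t_end, output_every = 100000L,
                      no_flux = TRUE)
  tr <- runSimulation(mesh, D, T_f, params, cfg,
                      phi0 = rep(phi0, nv), n0 = rep(n0, nv))
  fs <- finalState(tr)
  ref <- odeOracle(phi0, n0, params, t_end)
  max(abs(mean(fs@phi) - ref[1]), abs(mean(fs@n) - ref[2]))
}
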