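#' @include fem.R model-core.R tensor-field.R
NULL

#' Construct solver settings
#'
#' Defaults: \code{dt = 0.05} day with automatic halving (up to 3 times) when
#' the Newton iteration fails, Newton relative tolerance \code{1e-8} with at
#' most 20 iterations, saturation guard \code{clip_eta = 1e-6}, snapshots
#' every 10 steps, tumor threshold \code{eps_t = 0.05}.
#'
#' @param dt,t_end,newton_tol,newton_max_iter,clip_eta,output_every,eps_t,seed,no_flux
#'   see [SolverConfig-class].
#' @return a validated [SolverConfig-class].
#' @export
solverConfig <- function(dt = 0.05, t_end = 6, newton_tol = 1e-8,
                         newton_max_iter = 20L, clip_eta = 1e-6,
                         output_every = 10L, eps_t = 0.05, seed = 1L,
                         no_flux = FALSE) {
  new("SolverConfig", dt = dt, t_end = t_end, newton_tol = newton_tol,
      newton_max_iter = as.integer(newton_max_iter), clip_eta = clip_eta,
      output_every = as.integer(output_every), eps_t = eps_t,
      seed = as.integer(seed), no_flux = no_flux)
}

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf("SolverConfig: dt = %g day, t_end = %g day, %s boundary conditions\n",
              object@dt, object@t_end,
              if (object@no_flux) "no-flux (test harness)" else "production (phi = 0, n = n_s)"))
  cat(sprintf("  Newton: tol %g, max %d iterations; clip_eta %g; eps_t %g; output every %d steps\n",
              object@newton_tol, object@newton_max_iter, object@clip_eta,
              object@eps_t, object@output_every))
})

#' Simulation trajectory
#'
#' Snapshots of a run at regular step intervals plus the final time, with
#' the mesh and the settings that produced them and solver diagnostics
#' (Newton iteration counts, saturation-clip events, field-bound violations).
#'
#' @slot states list of [SimulationState-class] snapshots.
#' @slot mesh the [TumorMesh-class] the fields live on.
#' @slot params the [ModelParameters-class] used.
#' @slot config the [SolverConfig-class] used.
#' @slot diagnostics list of per-run counters.
#' @exportClass SimulationTrajectory
setClass("SimulationTrajectory",
  representation(states = "list", mesh = "TumorMesh",
                 params = "ModelParameters", config = "SolverConfig",
                 diagnostics = "list"))

setMethod("show", "SimulationTrajectory", function(object) {
  ts <- vapply(object@states, function(s) s@t, numeric(1))
  cat(sprintf("SimulationTrajectory: %d snapshot(s), t = %g .. %g day\n",
              length(ts), min(ts), max(ts)))
  fin <- object@states[[length(object@states)]]
  cat(sprintf("  final: max phi = %.4f, min n/n_s = %.4f\n",
              max(fin@phi), min(fin@n) / object@params@n_s))
  d <- object@diagnostics
  cat(sprintf("  steps %d, newton iterations %d, clip events %d, dt halvings %d\n",
              d$steps, d$newton_iters, d$clip_events, d$halvings))
})

#' Snapshots of a trajectory
#' @param traj a [SimulationTrajectory-class].
#' @return list of [SimulationState-class] objects.
#' @export
trajectoryStates <- function(traj) {
  stopifnot(is(traj, "SimulationTrajectory"))
  traj@states
}

#' Final state of a trajectory
#' @param traj a [SimulationTrajectory-class].
#' @return the last [SimulationState-class].
#' @export
finalState <- function(traj) {
  stopifnot(is(traj, "SimulationTrajectory"))
  traj@states[[length(traj@states)]]
}

setMethod("show", "SimulationState", function(object) {
  cat(sprintf("SimulationState at t = %g day: %d vertices\n",
              object@t, length(object@phi)))
  cat(sprintf("  phi in [%.4g, %.4g], n in [%.4g, %.4g] mM, sigma in [%.4g, %.4g] Pa\n",
              min(object@phi), max(object@phi), min(object@n), max(object@n),
              min(object@sigma), max(object@sigma)))
})

#' Gaussian initial tumor-cell distribution
#'
#' The initial lesion is a smooth normal profile,
#' \eqn{\phi_0(x) = A \exp(-|x - c|^2 / (2\sigma^2))}, reflecting the diffuse
#' (not sharp-interfaced) host/tumor transition of GBM. The peak should sit
#' slightly above the equilibrium fraction \eqn{\phi_e}; the default
#' amplitude is \code{1.1 * phi_e}.
#'
#' @param mesh a [TumorMesh-class].
#' @param center 3-vector, mm.
#' @param sigma_mm Gaussian width, mm, positive.
#' @param amplitude peak volume fraction in \code{(0, 1)}; values at or below
#'   \code{phi_e} trigger a warning but are honored.
#' @param params a [ModelParameters-class] (for \code{phi_e}).
#' @return numeric vertex vector.
#' @export
gaussianInitialCondition <- function(mesh, center, sigma_mm = 2,
                                     amplitude = NULL,
                                     params = modelParameters()) {
  stopifnot(is(mesh, "TumorMesh"), length(center) == 3L)
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  if (is.null(amplitude)) amplitude <- 1.1 * params@phi_e
  if (amplitude >= 1) stop("amplitude must be below 1")
  if (amplitude <= params@phi_e)
    warning("amplitude does not exceed phi_e; the initial lesion carries no excess pressure")
  v <- mesh@vertices
  d2 <- (v[, 1L] - center[1L])^2 + (v[, 2L] - center[2L])^2 + (v[, 3L] - center[3L])^2
  amplitude * exp(-d2 / (2 * sigma_mm^2))
}

## Proliferation rate and slope without argument policing (solver internals;
## transient undershoot in phi or n must not abort a Newton iteration).
gammaRate <- function(phi, n, params) {
  params@nu_c * phi * (n / params@n_s - params@delta_c) * (1 - phi)
}
gammaRateSlope <- function(phi, n, params) {
  params@nu_c * (n / params@n_s - params@delta_c) * (1 - 2 * phi)
}

#' Initial (steady-state) oxygen field
#'
#' Solves the stationary nutrient balance
#' \eqn{0 = \nabla\cdot(\mathbf{D}\nabla n) + S_n(n_s - n) - \delta_n \phi_0 n}
#' for the given initial cell distribution, with \eqn{n = n_s} on the
#' boundary (or pure natural conditions in the no-flux test harness). The
#' result equals \eqn{n_s} away from the lesion and dips towards the tumor
#' core.
#'
#' @param mesh a [TumorMesh-class].
#' @param phi0 vertex field of initial volume fractions in \code{[0, 1]}.
#' @param D a cell-space diffusion [TensorField-class] (a voxel field is
#'   transferred with [sampleToMesh()]).
#' @param params a [ModelParameters-class].
#' @param no_flux use the natural-boundary harness instead of \eqn{n = n_s}.
#' @return numeric vertex field (mM).
#' @export
initialNutrient <- function(mesh, phi0, D, params, no_flux = FALSE) {
  stopifnot(is(mesh, "TumorMesh"), is(params, "ModelParameters"))
  if (is(D, "TensorField") && D@space == "voxel") D <- sampleToMesh(D, mesh)
  bdry <- if (no_flux) integer(0) else boundaryVertexIndices(mesh)
  ops <- femOperators(mesh, bdry)
  solveSteadyNutrient(ops, phi0, tensorValues(D), params)
}

## Linear-algebra context for one run: the (constant) nutrient stiffness,
## its interior block and interior-to-boundary coupling, plus a cached
## CHOLMOD factorization whose symbolic pattern is reused across steps.
linearContext <- function(ops, Dvals) {
  KD_full <- assembleTensorStiffness(ops, Dvals, drop_bdry = FALSE)
  int <- ops$interior
  ctx <- new.env(parent = emptyenv())
  ctx$KD_full <- KD_full
  ctx$K_int <- KD_full[int, int, drop = FALSE]
  ctx$K_ib <- if (length(ops$bdry)) KD_full[int, ops$bdry, drop = FALSE] else NULL
  ctx$chol <- NULL
  ctx
}

## Solve (scale*K + diag(dvec)) n = rhs on the interior with n = bval on the
## Dirichlet boundary; symmetric positive definite, solved with CHOLMOD
## (numeric update of a cached symbolic factorization).
solveNutrientSystem <- function(ops, ctx, scale, dvec, rhs, bval) {
  int <- ops$interior
  A <- scale * ctx$K_int + Diagonal(x = dvec[int])
  b <- rhs[int]
  if (!is.null(ctx$K_ib)) b <- b - scale * as.numeric(ctx$K_ib %*% rep(bval, length(ops$bdry)))
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  Asym <- Matrix::forceSymmetric(A)
  if (is.null(ctx$chol)) {
    ctx$chol <- Matrix::Cholesky(Asym, LDL = FALSE, super = TRUE)
  } else {
    ctx$chol <- Matrix::update(ctx$chol, Asym)
  }
  x <- as.numeric(Matrix::solve(ctx$chol, b, system = "A"))
  n <- numeric(ops$nv)
  n[int] <- x
  if (length(ops$bdry)) n[ops$bdry] <- bval
  if (any(!is.finite(n))) stop("nutrient solve failed (non-finite solution)")
  n
}

solveSteadyNutrient <- function(ops, phi0, Dvals, params, ctx = NULL) {
  if (is.null(ctx)) ctx <- linearContext(ops, Dvals)
  r <- params@S_n + params@delta_n * pmax(phi0, 0)
  steady <- new.env(parent = emptyenv())   # do not disturb the stepping cache
  steady$K_int <- ctx$K_int
  steady$K_ib <- ctx$K_ib
  steady$chol <- NULL
  solveNutrientSystem(ops, steady, 1, ops$ml * r,
                      ops$ml * params@S_n * params@n_s, params@n_s)
}

## Crank-Nicolson nutrient step with the consumption coefficient frozen at
## phi_eff (a second-order midpoint extrapolation supplied by the caller).
stepNutrient <- function(ops, ctx, n_o, phi_eff, dt, params) {
  r <- params@S_n + params@delta_n * pmax(phi_eff, 0)
  dvec <- ops$ml / dt + 0.5 * ops$ml * r
  rhs <- ops$ml * n_o / dt - 0.5 * as.numeric(ctx$KD_full %*% n_o) -
    0.5 * ops$ml * r * n_o + ops$ml * params@S_n * params@n_s
  solveNutrientSystem(ops, ctx, 0.5, dvec, rhs, params@n_s)
}

## Jacobi-preconditioned BiCGSTAB for the (diagonally dominant) Schur
## complement of the Newton system. Returns NULL on breakdown/stagnation so
## the caller can fall back to a direct solve.
bicgstabSolve <- function(matvec, b, dprec, tol = 1e-9, maxit = 400L) {
  x <- numeric(length(b))
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) return(NULL)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    phat <- p / dprec
    v <- matvec(phat)
    denom <- sum(r0 * v)
    if (abs(denom) < 1e-300) return(NULL)
    alpha <- rho / denom
    s <- r - alpha * v
    if (sqrt(sum(s^2)) <= tol * bnorm) {
      x <- x + alpha * phat
      return(x)
    }
    shat <- s / dprec
    t <- matvec(shat)
    tt <- sum(t * t)
    if (tt < 1e-300) return(NULL)
    omega <- sum(t * s) / tt
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    if (!is.finite(omega) || abs(omega) < 1e-300) return(NULL)
  }
  NULL
}

## Newton solve of the Crank-Nicolson (phi, Sigma) system for one time step.
## Returns list(phi, sigma, iters, clips) or raises an error on breakdown.
solvePhiSigma <- function(ops, phi_o, sigma_o, n_o, n_n, dt, params, config,
                          Tvals, chem_o, KcS_o, gamma_o) {
  nv <- ops$nv
  ml <- ops$ml
  eps2 <- params@eps^2
  eta <- config@clip_eta
  chemDeriv <- if (params@k_n > 0) chemotaxisDerivMatrix(ops, n_n, Tvals, params@k_n) else NULL
  phin <- phi_o
  sigman <- sigma_o
  clips <- 0L
  res0 <- NULL
  mlInv <- 1 / ml
  for (iter in seq_len(config@newton_max_iter + 1L)) {
    phibar <- cellMeans(ops, phin)
    cvec <- sigmaFluxCoefficient(phibar, params, eta)
    Kc_n <- assembleScalarStiffness(ops, cvec, drop_bdry = TRUE)
    phic <- clipPhi(phin, eta)
    clips <- clips + attr(phic, "n_clipped")
    f_n <- params@E * phic^2 * (phic - params@phi_e) / (1 - phic)
    gamma_n <- gammaRate(phin, n_n, params)
    chem_n <- chemotaxisVector(ops, phin, n_n, Tvals, params@k_n, eta)
    Rphi <- ml * (phin - phi_o) / dt +
      0.5 * (as.numeric(Kc_n %*% sigman) + KcS_o) -
      0.5 * ml * (gamma_n + gamma_o) -
      0.5 * (chem_n + chem_o)
    if (length(ops$bdry)) Rphi[ops$bdry] <- phin[ops$bdry]
    Rsig <- ml * sigman - ml * f_n - eps2 * as.numeric(ops$K1 %*% phin)
    res <- sqrt(sum(Rphi^2) + sum(Rsig^2))
    if (!is.finite(res)) stop("Newton iteration diverged (non-finite residual)")
    if (is.null(res0)) res0 <- max(res, 1e-300)
    if (res <= config@newton_tol * res0 || res < 1e-12 * sqrt(nv)) {
      return(list(phi = phin, sigma = sigman, iters = iter - 1L, clips = clips))
    }
    if (iter > config@newton_max_iter) break
    ## Newton system in (dphi, dsigma); the (sigma, sigma) block is the
    ## lumped mass, so dsigma is eliminated exactly and the Schur complement
    ## S = Jpp - Jps ML^-1 Jsp (strongly diagonally dominant: the ML/dt
    ## diagonal) is solved matrix-free with preconditioned BiCGSTAB.
    dgamma <- gammaRateSlope(phin, n_n, params)
    jdiag <- ml / dt - 0.5 * ml * dgamma
    if (length(ops$bdry)) jdiag[ops$bdry] <- 1
    Jpp <- Diagonal(x = jdiag)
    cp <- sigmaFluxCoefficientSlope(phibar, params, eta)
    Jpp <- Jpp + 0.5 * mobilityDerivMatrix(ops, cp, sigman)
    if (!is.null(chemDeriv)) Jpp <- Jpp - 0.5 * chemDeriv
    Jps <- 0.5 * Kc_n
    fp <- bulkPressureSlope(phic, params)
    Jsp <- Diagonal(x = -ml * fp) - eps2 * ops$K1
    matvec <- function(x) {
      as.numeric(Jpp %*% x) - as.numeric(Jps %*% (mlInv * as.numeric(Jsp %*% x)))
    }
    rhs <- -Rphi + as.numeric(Jps %*% (mlInv * Rsig))
    dphi <- bicgstabSolve(matvec, rhs, jdiag, tol = 1e-10)
    if (is.null(dphi)) {
      ## rare fallback: direct solve of the full 2x2 block system
      J <- rbind(cbind(Jpp, Jps), cbind(Jsp, Diagonal(x = ml)))
      du <- as.numeric(solve(J, -c(Rphi, Rsig)))
      dphi <- du[seq_len(nv)]
      dsigma <- du[nv + seq_len(nv)]
    } else {
      dsigma <- -mlInv * (Rsig + as.numeric(Jsp %*% dphi))
    }
    if (any(!is.finite(dphi)) || any(!is.finite(dsigma)))
      stop("Newton iteration diverged (non-finite update)")
    phin <- phin + dphi
    sigman <- sigman + dsigma
  }
  stop(sprintf("Newton did not converge in %d iterations (last relative residual %.3g)",
               config@newton_max_iter, res / res0))
}

## One coupled step from (phi_o, sigma_o, n_o): nutrient first (implicit CN,
## consumption coefficient at the extrapolated midpoint phi_eff), then the
## (phi, Sigma) Newton solve against the new nutrient field. phi_eff = NULL
## requests a predictor-corrector pass (first step, or after dt halving).
stepCoupled <- function(ops, phi_o, sigma_o, n_o, phi_eff, dt, params, config,
                        ctx, Tvals) {
  gamma_o <- gammaRate(phi_o, n_o, params)
  chem_o <- chemotaxisVector(ops, phi_o, n_o, Tvals, params@k_n, config@clip_eta)
  KcS_o <- as.numeric(
    assembleScalarStiffness(ops, sigmaFluxCoefficient(cellMeans(ops, phi_o),
                                                      params, config@clip_eta),
                            drop_bdry = TRUE) %*% sigma_o)
  doPass <- function(pe) {
    n_n <- stepNutrient(ops, ctx, n_o, pe, dt, params)
    ps <- solvePhiSigma(ops, phi_o, sigma_o, n_o, n_n, dt, params, config,
                        Tvals, chem_o, KcS_o, gamma_o)
    c(ps, list(n = n_n))
  }
  if (is.null(phi_eff)) {
    pred <- doPass(phi_o)
    out <- doPass(0.5 * (phi_o + pred$phi))
    out$iters <- out$iters + pred$iters
    out$clips <- out$clips + pred$clips
    out
  } else {
    doPass(phi_eff)
  }
}

#' Advance a simulation state by one time step
#'
#' Applies the Crank-Nicolson scheme once: the oxygen equation is solved
#' implicitly (with the consumption coefficient at a second-order midpoint
#' extrapolation of phi), then the mixed \eqn{(\phi, \Sigma)} system is
#' solved by Newton iteration against the new oxygen field. Intended for
#' fine-grained control; [runSimulation()] amortizes the finite-element
#' setup across steps.
#'
#' @param state a [SimulationState-class].
#' @param config a [SolverConfig-class] (uses \code{dt}, tolerances, and the
#'   boundary-condition harness flag).
#' @param params a [ModelParameters-class].
#' @param D,T_field cell-space [TensorField-class] objects (diffusion /
#'   preferential directions); voxel fields are transferred automatically.
#' @param mesh the [TumorMesh-class] the state lives on.
#' @param phi_prev phi at the start of the previous step (same \code{dt}),
#'   or \code{NULL} to use a predictor-corrector first step.
#' @return a [SimulationState-class] at \code{state@t + config@dt}.
#' @export
stepSimulation <- function(state, config, params, D, T_field, mesh,
                           phi_prev = NULL) {
  stopifnot(is(state, "SimulationState"))
  if (is(D, "TensorField") && D@space == "voxel") D <- sampleToMesh(D, mesh)
  if (is(T_field, "TensorField") && T_field@space == "voxel")
    T_field <- sampleToMesh(T_field, mesh)
  bdry <- if (config@no_flux) integer(0) else boundaryVertexIndices(mesh)
  ops <- femOperators(mesh, bdry)
  ctx <- linearContext(ops, tensorValues(D))
  phi_eff <- if (is.null(phi_prev)) NULL else 1.5 * state@phi - 0.5 * phi_prev
  out <- stepCoupled(ops, state@phi, state@sigma, state@n, phi_eff,
                     config@dt, params, config, ctx, tensorValues(T_field))
  new("SimulationState", phi = out$phi, sigma = out$sigma, n = out$n,
      t = state@t + config@dt)
}

#' Run a full simulation
#'
#' Drives [stepSimulation()]'s scheme from the initial state to
#' \code{config@t_end}, collecting snapshots every \code{config@output_every}
#' steps plus the final state. On Newton failure the offending step is
#' retried with a halved time step (up to three halvings) before giving up.
#' The run is deterministic given identical inputs.
#'
#' @param mesh a [TumorMesh-class].
#' @param D,T_field diffusion / preferential-direction [TensorField-class]
#'   objects (voxel fields are transferred onto the mesh automatically).
#' @param params a [ModelParameters-class].
#' @param config a [SolverConfig-class].
#' @param phi0 initial volume-fraction vertex field (e.g. from
#'   [gaussianInitialCondition()]). In production boundary mode it is forced
#'   to zero on the boundary.
#' @param n0 initial oxygen field; default: the steady state for \code{phi0}.
#' @return a [SimulationTrajectory-class].
#' @examples
#' mesh <- boxMesh(c(20, 20, 20), c(6, 6, 6))
#' p <- modelParameters(nu_c = 1)
#' grid <- phantomGrid(c(8, 8, 8), spacing = 2.5, origin = c(1.25, 1.25, 1.25))
#' D <- isotropicPhantom(grid, D_n = p@D_n)
#' T_iso <- preferentialDirections(D)
#' phi0 <- gaussianInitialCondition(mesh, c(10, 10, 10), sigma_mm = 3, params = p)
#' cfg <- solverConfig(dt = 0.1, t_end = 0.2, output_every = 1L)
#' traj <- runSimulation(mesh, D, T_iso, p, cfg, phi0)
#' traj
#' @export
runSimulation <- function(mesh, D, T_field, params, config, phi0, n0 = NULL) {
  stopifnot(is(mesh, "TumorMesh"), is(params, "ModelParameters"),
            is(config, "SolverConfig"))
  if (is(D, "TensorField") && D@space == "voxel") D <- sampleToMesh(D, mesh)
  if (is(T_field, "TensorField") && T_field@space == "voxel")
    T_field <- sampleToMesh(T_field, mesh)
  Dvals <- tensorValues(D)
  Tvals <- tensorValues(T_field)
  if (nrow(Dvals) != nrow(mesh@cells) || nrow(Tvals) != nrow(mesh@cells))
    stop("tensor fields must provide one tensor per mesh cell")
  bdry <- if (config@no_flux) integer(0) else boundaryVertexIndices(mesh)
  ops <- femOperators(mesh, bdry)
  ctx <- linearContext(ops, Dvals)
  if (length(bdry)) phi0[bdry] <- 0
  if (is.null(n0)) n0 <- solveSteadyNutrient(ops, phi0, Dvals, params, ctx)
  sigma0 <- local({
    phic <- clipPhi(phi0, config@clip_eta)
    params@E * phic^2 * (phic - params@phi_e) / (1 - phic) +
      params@eps^2 * as.numeric(ops$K1 %*% phi0) / ops$ml
  })
  diag_ <- list(steps = 0L, newton_iters = 0L, clip_events = 0L, halvings = 0L,
                phi_bound_violations = 0L, n_bound_violations = 0L)
  phi <- phi0; sigma <- sigma0; n <- n0
  phi_prev <- NULL
  t <- 0
  states <- list(new("SimulationState", phi = phi, sigma = sigma, n = n, t = t))
  stepno <- 0L

  advance <- function(phi, sigma, n, phi_eff, dt, depth) {
    tryCatch(
      stepCoupled(ops, phi, sigma, n, phi_eff, dt, params, config, ctx, Tvals),
      error = function(e) {
        if (depth >= 3L) stop(e)
        diag_$halvings <<- diag_$halvings + 1L
        half1 <- advance(phi, sigma, n, NULL, dt / 2, depth + 1L)
        half2 <- advance(half1$phi, half1$sigma, half1$n, NULL, dt / 2, depth + 1L)
        half2$iters <- half1$iters + half2$iters
        half2$clips <- half1$clips + half2$clips
        half2
      })
  }

  while (t < config@t_end - 1e-12) {
    dt <- min(config@dt, config@t_end - t)
    phi_eff <- if (is.null(phi_prev) || dt != config@dt) NULL
               else 1.5 * phi - 0.5 * phi_prev
    out <- advance(phi, sigma, n, phi_eff, dt, 0L)
    phi_prev <- phi
    phi <- out$phi; sigma <- out$sigma; n <- out$n
    if (any(phi < -1e-2 | phi > 1 + 1e-2))
      stop("phi left [-0.01, 1.01]; reduce dt or refine the mesh")
    t <- t + dt
    stepno <- stepno + 1L
    diag_$steps <- diag_$steps + 1L
    diag_$newton_iters <- diag_$newton_iters + out$iters
    diag_$clip_events <- diag_$clip_events + out$clips
    diag_$phi_bound_violations <- diag_$phi_bound_violations +
      sum(phi < -1e-3 | phi > 1 + 1e-3)
    diag_$n_bound_violations <- diag_$n_bound_violations +
      sum(n < -1e-12 | n > params@n_s * (1 + 1e-6))
    if (stepno %% config@output_every == 0L || t >= config@t_end - 1e-12) {
      states[[length(states) + 1L]] <-
        new("SimulationState", phi = phi, sigma = sigma, n = n, t = t)
    }
  }
  if (diag_$phi_bound_violations > 0L)
    warning(sprintf("phi exceeded [-1e-3, 1+1e-3] at %d vertex-step(s)",
                    diag_$phi_bound_violations))
  new("SimulationTrajectory", states = states, mesh = mesh, params = params,
      config = config, diagnostics = diag_)
}
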