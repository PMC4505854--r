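#' @include gbmsim-package.R
NULL

TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Biological and physical parameters of the mixture model
#'
#' Holds every constant of the tumor-phase and nutrient equations, in the
#' working units (mm, day, mM, Pa). Defaults follow the parameter estimation
#' for human brain / glioblastoma; see [modelParameters()] for the meaning,
#' units and admissible range of each slot.
#'
#' @slot nu_c GBM cell proliferation rate (1/day).
#' @slot delta_c dimensionless hypoxic-death threshold in \code{[0, 1]}.
#' @slot n_s physiological oxygen concentration (mM).
#' @slot k_n chemotactic coefficient (mm^2 mM^-1 day^-1).
#' @slot M interphase friction (mm^-2 Pa day).
#' @slot eps diffuse-interface coefficient; \code{eps^2} multiplies the
#'   Laplacian of the volume fraction so that \code{eps^2 * lap(phi)} carries
#'   pressure units (see [deriveInterfaceCoefficient()]).
#' @slot E Young's modulus of brain matter (Pa).
#' @slot phi_e equilibrium cell volume fraction, in (0, 1).
#' @slot S_n blood-tissue oxygen transfer rate (1/day).
#' @slot delta_n oxygen consumption rate by tumor cells (1/day).
#' @slot D_n scalar oxygen diffusivity for isotropic runs (mm^2/day).
#' @slot chi interstitial fluid pressure scale (Pa).
#' @slot l_n oxygen penetration length (mm).
#' @seealso [modelParameters()]
#' @exportClass ModelParameters
setClass("ModelParameters",
  representation(
    nu_c = "numeric", delta_c = "numeric", n_s = "numeric", k_n = "numeric",
    M = "numeric", eps = "numeric", E = "numeric", phi_e = "numeric",
    S_n = "numeric", delta_n = "numeric", D_n = "numeric", chi = "numeric",
    l_n = "numeric"
  )
)

setValidity("ModelParameters", function(object) {
  msgs <- character()
  scalar <- function(x) length(x) == 1L && is.finite(x)
  for (nm in slotNames(object)) {
    if (!scalar(slot(object, nm))) msgs <- c(msgs, sprintf("'%s' must be a finite scalar", nm))
  }
  if (length(msgs)) return(msgs)
  pos <- c("n_s", "M", "eps", "E", "S_n", "D_n", "chi", "l_n")
  for (nm in pos) {
    if (slot(object, nm) <= 0) msgs <- c(msgs, sprintf("'%s' must be strictly positive", nm))
  }
  ## nu_c, delta_n and k_n admit zero: switching off proliferation, uptake or
  ## chemotaxis is a meaningful limit (conservation and supply-dominated runs)
  for (nm in c("nu_c", "delta_n", "k_n")) {
    if (slot(object, nm) < 0) msgs <- c(msgs, sprintf("'%s' must be non-negative", nm))
  }
  if (object@phi_e <= 0 || object@phi_e >= 1) msgs <- c(msgs, "'phi_e' must lie in (0, 1)")
  if (object@delta_c < 0 || object@delta_c > 1) msgs <- c(msgs, "'delta_c' must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Symmetric 3x3 tensor field over a voxel grid or mesh cells
#'
#' Stores the six independent components (xx, yy, zz, xy, xz, yz) of a
#' symmetric tensor at every location: either at the voxels of a regular
#' axis-aligned grid (\code{space = "voxel"}) or at the cells of a tetrahedral
#' mesh (\code{space = "cell"}). Used both for the oxygen diffusion tensor
#' \eqn{\mathbf{D}} (mm^2/day) and the dimensionless tensor of preferential
#' directions \eqn{\mathbf{T}}.
#'
#' @slot values numeric matrix, one row per location, columns
#'   \code{c("xx","yy","zz","xy","xz","yz")}.
#' @slot space \code{"voxel"} or \code{"cell"}.
#' @slot dim integer grid dimensions (voxel fields; empty for cell fields).
#' @slot spacing voxel edge lengths in mm (voxel fields).
#' @slot origin world coordinate of the center of voxel (1,1,1), mm.
#' @slot mask logical vector, \code{TRUE} where the tensor is valid data;
#'   \code{FALSE} marks background locations that carry the isotropic
#'   fallback (see [preferentialDirections()] and [regularizeTensors()]).
#' @seealso [tensorField()], [isotropicPhantom()], [readTensorVolumes()]
#' @exportClass TensorField
setClass("TensorField",
  representation(
    values = "matrix", space = "character", dim = "integer",
    spacing = "numeric", origin = "numeric", mask = "logical"
  )
)

setValidity("TensorField", function(object) {
  msgs <- character()
  if (ncol(object@values) != 6L || !identical(colnames(object@values), TENSOR_COMPONENTS))
    msgs <- c(msgs, "values must have the six columns xx, yy, zz, xy, xz, yz")
  if (!object@space %in% c("voxel", "cell")) msgs <- c(msgs, "space must be 'voxel' or 'cell'")
  if (object@space == "voxel") {
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msgs <- c(msgs, "voxel fields need a positive 3-vector 'dim'")
    else if (nrow(object@values) != prod(object@dim))
      msgs <- c(msgs, "nrow(values) must equal prod(dim) for voxel fields")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msgs <- c(msgs, "voxel fields need positive spacing (mm)")
    if (length(object@origin) != 3L) msgs <- c(msgs, "voxel fields need a 3-vector origin")
  }
  if (length(object@mask) != nrow(object@values))
    msgs <- c(msgs, "mask must have one entry per location")
  if (length(msgs)) msgs else TRUE
})

#' Tetrahedral simulation domain
#'
#' A conforming tetrahedral mesh: vertex coordinates in mm, a cell table of
#' vertex indices, optional per-cell tissue labels and (for structured box
#' meshes) the generating grid. All cells have strictly positive volume and
#' every interior facet is shared by exactly two cells.
#'
#' @slot vertices numeric matrix n x 3 (mm).
#' @slot cells integer matrix m x 4, 1-based vertex indices.
#' @slot labels integer vector of per-cell tissue labels (length m or 0).
#' @slot grid list with \code{extents}, \code{resolution}, \code{origin} for
#'   meshes produced by [boxMesh()]; empty list otherwise.
#' @seealso [boxMesh()], [refineRegion()], [readMesh()]
#' @exportClass TumorMesh
setClass("TumorMesh",
  representation(vertices = "matrix", cells = "matrix",
                 labels = "integer", grid = "list")
)

setValidity("TumorMesh", function(object) {
  msgs <- character()
  if (ncol(object@vertices) != 3L) msgs <- c(msgs, "vertices must be n x 3")
  if (ncol(object@cells) != 4L) msgs <- c(msgs, "cells must be m x 4")
  if (length(msgs)) return(msgs)
  if (nrow(object@cells) > 0) {
    if (max(object@cells) > nrow(object@vertices) || min(object@cells) < 1L)
      return("cell indices out of range")
    vol <- cellVolumes(object)
    if (any(vol <= 0)) {
      bad <- which(vol <= 0)
      msgs <- c(msgs, sprintf("%d cell(s) with non-positive volume (first: %d)",
                              length(bad), bad[1L]))
    }
    cnt <- facetCounts(object@cells)
    if (any(cnt > 2L)) msgs <- c(msgs, "some facets are shared by more than two cells")
  }
  if (length(object@labels) && length(object@labels) != nrow(object@cells))
    msgs <- c(msgs, "labels must have one entry per cell (or length 0)")
  if (length(msgs)) msgs else TRUE
})

#' Fields of one simulation time point
#'
#' Vertex fields of the coupled system at time \code{t}: tumor volume fraction
#' \code{phi} (dimensionless), excess cell pressure \code{sigma} (Pa) and
#' oxygen concentration \code{n} (mM).
#'
#' @slot phi,sigma,n numeric vertex vectors.
#' @slot t time in days.
#' @exportClass SimulationState
setClass("SimulationState",
  representation(phi = "numeric", sigma = "numeric", n = "numeric", t = "numeric")
)

setValidity("SimulationState", function(object) {
  msgs <- character()
  nv <- length(object@phi)
  if (length(object@sigma) != nv || length(object@n) != nv)
    msgs <- c(msgs, "phi, sigma and n must have equal length")
  if (length(object@t) != 1L || !is.finite(object@t)) msgs <- c(msgs, "t must be a finite scalar")
  if (anyNA(object@phi) || anyNA(object@n)) msgs <- c(msgs, "fields must not contain NA")
  if (length(msgs)) msgs else TRUE
})

#' Numerical settings of the time integrator
#'
#' @slot dt time step (day); halved automatically (up to 3 times) on Newton
#'   failure.
#' @slot t_end final time (day).
#' @slot newton_tol relative residual tolerance of the Newton iteration.
#' @slot newton_max_iter maximum Newton iterations per step.
#' @slot clip_eta saturation guard: constitutive laws are evaluated with phi
#'   clipped to \code{[0, 1 - clip_eta]}.
#' @slot output_every snapshot interval in steps.
#' @slot eps_t tumor threshold for shape metrics, in (0, 1).
#' @slot seed integer seed for any stochastic phantom input.
#' @slot no_flux logical; \code{TRUE} selects the pure natural-boundary test
#'   harness (conservation / ODE-limit studies). Production runs use phi = 0
#'   and n = n_s on the boundary.
#' @seealso [solverConfig()]
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(
    dt = "numeric", t_end = "numeric", newton_tol = "numeric",
    newton_max_iter = "integer", clip_eta = "numeric", output_every = "integer",
    eps_t = "numeric", seed = "integer", no_flux = "logical"
  )
)

setValidity("SolverConfig", function(object) {
  msgs <- character()
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  if (object@t_end < 0) msgs <- c(msgs, "t_end must be non-negative")
  if (object@newton_tol <= 0) msgs <- c(msgs, "newton_tol must be positive")
  if (object@newton_max_iter < 1L) msgs <- c(msgs, "newton_max_iter must be >= 1")
  if (object@clip_eta <= 0 || object@clip_eta >= 0.5) msgs <- c(msgs, "clip_eta must be in (0, 0.5)")
  if (object@output_every < 1L) msgs <- c(msgs, "output_every must be >= 1")
  if (object@eps_t <= 0 || object@eps_t >= 1) msgs <- c(msgs, "eps_t must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Thresholded tumor-region summary
#'
#' Semi-axes of the thresholded tumor region measured along the coordinate
#' axes through its centroid, its volume, the maximum volume fraction and the
#' threshold used.
#'
#' @slot delta_x,delta_y,delta_z semi-axes (mm).
#' @slot volume thresholded region volume (mm^3).
#' @slot phi_max maximum of phi over the mesh.
#' @slot centroid volume-weighted centroid of the region (mm).
#' @slot eps_t threshold the region was computed with.
#' @seealso [tumorShape()], [semiAxes()], [tumorRegion()]
#' @exportClass TumorShape
setClass("TumorShape",
  representation(delta_x = "numeric", delta_y = "numeric", delta_z = "numeric",
                 volume = "numeric", phi_max = "numeric", centroid = "numeric",
                 eps_t = "numeric")
)

setValidity("TumorShape", function(object) {
  msgs <- character()
  if (any(c(object@delta_x, object@delta_y, object@delta_z) < 0))
    msgs <- c(msgs, "semi-axes must be non-negative")
  if (object@volume < 0) msgs <- c(msgs, "volume must be non-negative")
  if (object@phi_max < 0 || object@phi_max > 1 + 1e-3)
    msgs <- c(msgs, "phi_max must lie in [0, 1] (up to overshoot tolerance)")
  if (length(msgs)) msgs else TRUE
})
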