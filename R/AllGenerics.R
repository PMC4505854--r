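#' @include AllClasses.R
NULL

#' Mean diffusivity of a tensor field
#'
#' The mean diffusivity is one third of the tensor trace,
#' \eqn{D_n = \mathrm{tr}(\mathbf{D})/3}, a rotation-invariant scalar measuring
#' the total amount of diffusion at a location regardless of its
#' directionality.
#'
#' @param x a [TensorField-class].
#' @return numeric vector, one value per location (mm^2/day for a diffusion
#'   tensor field).
#' @examples
#' D <- isotropicPhantom(phantomGrid(c(4, 4, 4), spacing = 1), D_n = 86.4)
#' unique(meanDiffusivity(D))
#' @export
setGeneric("meanDiffusivity", function(x) standardGeneric("meanDiffusivity"))

#' Tensor of preferential directions
#'
#' Normalizes a diffusion tensor field by its mean diffusivity,
#' \eqn{T_{ij} = D_{ij} / D_n}, yielding the dimensionless tensor that biases
#' the chemotactic flux along fiber directions. Wherever defined,
#' \eqn{\mathrm{tr}(\mathbf{T}) = 3}; an isotropic tensor maps to the
#' identity. Locations with non-positive mean diffusivity (e.g. image
#' background) are assigned the identity fallback and masked out.
#'
#' @param x a [TensorField-class] holding a diffusion tensor field.
#' @return a dimensionless [TensorField-class] on the same locations; the
#'   \code{mask} slot is \code{FALSE} where the fallback was used.
#' @examples
#' D <- axisAlignedPhantom(phantomGrid(c(2, 2, 2), spacing = 1), D_n = 86.4)
#' tensorValues(preferentialDirections(D))[1, ]
#' @export
setGeneric("preferentialDirections", function(x) standardGeneric("preferentialDirections"))

#' Eigenvalue regularization of a tensor field
#'
#' Measured DTI tensors can carry zero or slightly negative eigenvalues
#' (noise, background). Each tensor is eigendecomposed, eigenvalues are
#' clamped from below to \code{eigen_floor}, and the tensor is reassembled.
#' Tensors already satisfying the floor are returned unchanged bit for bit.
#'
#' @param x a [TensorField-class].
#' @param eigen_floor non-negative lower bound for the eigenvalues.
#' @return a [TensorField-class] with symmetric positive semi-definite
#'   tensors (eigenvalues \code{>= eigen_floor}).
#' @export
setGeneric("regularizeTensors", function(x, eigen_floor = 1e-6) standardGeneric("regularizeTensors"))

#' Transfer a voxel tensor field onto mesh cells
#'
#' Each cell receives the tensor of the voxel containing its barycenter
#' (nearest-voxel assignment, no interpolation), mirroring the voxel-to-
#' tetrahedron transfer used when mapping DTI volumes onto a computational
#' mesh. Cells whose barycenter falls outside the voxel grid receive an
#' isotropic fallback equal to the mean diffusivity averaged over the grid;
#' their number is reported via a warning and the \code{mask} slot.
#'
#' @param x a voxel-space [TensorField-class].
#' @param mesh a [TumorMesh-class] .
#' @return a cell-space [TensorField-class] with one tensor per mesh cell.
#' @export
setGeneric("sampleToMesh", function(x, mesh) standardGeneric("sampleToMesh"))
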