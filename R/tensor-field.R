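#' @include AllGenerics.R
NULL

#' Regular voxel grid geometry for tensor phantoms
#'
#' @param dim integer 3-vector of voxel counts per axis.
#' @param spacing voxel edge length(s), mm (scalar or 3-vector).
#' @param origin world coordinate (mm) of the center of the first voxel;
#'   world position of voxel index \code{(i,j,k)} (0-based) is
#'   \code{origin + c(i,j,k) * spacing}.
#' @return a grid geometry list used by the phantom constructors.
#' @examples
#' phantomGrid(c(16, 16, 16), spacing = 2.5)
#' @export
phantomGrid <- function(dim, spacing = 1, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0), length(origin) == 3L)
  list(dim = dim, spacing = spacing, origin = as.numeric(origin))
}

## World coordinates of all voxel centers, x fastest (R array order).
gridVoxelCenters <- function(grid) {
  ix <- seq_len(grid$dim[1L]) - 1L
  iy <- seq_len(grid$dim[2L]) - 1L
  iz <- seq_len(grid$dim[3L]) - 1L
  cbind(
    rep(grid$origin[1L] + ix * grid$spacing[1L], times = grid$dim[2L] * grid$dim[3L]),
    rep(rep(grid$origin[2L] + iy * grid$spacing[2L], each = grid$dim[1L]), times = grid$dim[3L]),
    rep(grid$origin[3L] + iz * grid$spacing[3L], each = grid$dim[1L] * grid$dim[2L])
  )
}

#' Construct a tensor field from component values
#'
#' @param values n x 6 matrix of components in the order
#'   \code{xx, yy, zz, xy, xz, yz}.
#' @param grid a [phantomGrid()] geometry for voxel fields, or \code{NULL}
#'   for a per-cell field.
#' @param mask logical validity mask (default: all valid).
#' @return a [TensorField-class].
#' @export
tensorField <- function(values, grid = NULL, mask = NULL) {
  values <- as.matrix(values)
  colnames(values) <- TENSOR_COMPONENTS
  if (is.null(mask)) mask <- rep(TRUE, nrow(values))
  if (is.null(grid)) {
    new("TensorField", values = values, space = "cell", dim = integer(0),
        spacing = numeric(0), origin = numeric(0), mask = mask)
  } else {
    new("TensorField", values = values, space = "voxel", dim = grid$dim,
        spacing = grid$spacing, origin = grid$origin, mask = mask)
  }
}

#' Component matrix of a tensor field
#' @param x a [TensorField-class].
#' @return the n x 6 component matrix (columns xx, yy, zz, xy, xz, yz).
#' @export
tensorValues <- function(x) {
  stopifnot(is(x, "TensorField"))
  x@values
}

#' Validity mask of a tensor field
#' @param x a [TensorField-class].
#' @return logical vector; \code{FALSE} marks background/fallback locations.
#' @export
tensorMask <- function(x) {
  stopifnot(is(x, "TensorField"))
  x@mask
}

setMethod("show", "TensorField", function(object) {
  n <- nrow(object@values)
  cat(sprintf("TensorField: %d %s location(s)", n, object@space))
  if (object@space == "voxel")
    cat(sprintf(" [%s grid, spacing %s mm]",
                paste(object@dim, collapse = "x"),
                paste(signif(object@spacing, 4), collapse = "x")))
  cat("\n")
  if (n) {
    md <- meanDiffusivity(object)
    cat(sprintf("  mean diffusivity: %.4g .. %.4g (median %.4g)\n",
                min(md), max(md), stats::median(md)))
  }
  if (!all(object@mask))
    cat(sprintf("  masked (background/fallback) locations: %d\n", sum(!object@mask)))
})

setMethod("meanDiffusivity", "TensorField", function(x) {
  unname((x@values[, "xx"] + x@values[, "yy"] + x@values[, "zz"]) / 3)
})

setMethod("preferentialDirections", "TensorField", function(x) {
  dn <- meanDiffusivity(x)
  ok <- dn > 0
  vals <- x@values
  vals[ok, ] <- vals[ok, , drop = FALSE] / dn[ok]
  if (any(!ok)) {
    ## identity fallback where the tensor carries no diffusion signal
    vals[!ok, ] <- rep(c(1, 1, 1, 0, 0, 0), each = sum(!ok))
  }
  out <- x
  out@values <- vals
  out@mask <- x@mask & ok
  out
})

## Closed-form eigenvalues of symmetric 3x3 tensors, vectorized over rows of
## the 6-column component matrix (trigonometric method for the characteristic
## cubic). Returns an n x 3 matrix, ascending.
symEigenvalues <- function(vals) {
  a11 <- vals[, 1L]; a22 <- vals[, 2L]; a33 <- vals[, 3L]
  a12 <- vals[, 4L]; a13 <- vals[, 5L]; a23 <- vals[, 6L]
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- (b11^2 + b22^2 + b33^2 + 2 * (a12^2 + a13^2 + a23^2)) / 6
  p <- sqrt(pmax(p2, 0))
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / 2 / p^3, 0)
  r <- pmin(pmax(r, -1), 1)
  theta <- acos(r) / 3
  e1 <- q + 2 * p * cos(theta)
  e3 <- q + 2 * p * cos(theta + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e3, e2, e1)
}

setMethod("regularizeTensors", "TensorField", function(x, eigen_floor = 1e-6) {
  if (eigen_floor < 0) stop("eigen_floor must be non-negative")
  vals <- x@values
  if (!all(is.finite(vals))) {
    bad <- which(rowSums(!is.finite(vals)) > 0)
    stop(sprintf("non-finite tensor components at %d location(s), first at index %d",
                 length(bad), bad[1L]))
  }
  ev <- symEigenvalues(vals)
  ## strict comparison: tensors already at/above the floor stay bit-identical
  needs <- ev[, 1L] < eigen_floor
  if (any(needs)) {
    idx <- which(needs)
    for (i in idx) {
      A <- tensorRowToMatrix(vals[i, ])
      ed <- eigen(A, symmetric = TRUE)
      lam <- pmax(ed$values, eigen_floor)
      A2 <- ed$vectors %*% (lam * t(ed$vectors))
      vals[i, ] <- c(A2[1, 1], A2[2, 2], A2[3, 3], A2[1, 2], A2[1, 3], A2[2, 3])
    }
  }
  out <- x
  out@values <- vals
  out
})

tensorRowToMatrix <- function(row) {
  matrix(c(row[1L], row[4L], row[5L],
           row[4L], row[2L], row[6L],
           row[5L], row[6L], row[3L]), 3L, 3L)
}

tensorMatrixToRow <- function(A) {
  c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
}

uniformTensorField <- function(grid, row, mask = NULL) {
  n <- prod(grid$dim)
  tensorField(matrix(row, nrow = n, ncol = 6, byrow = TRUE), grid = grid, mask = mask)
}

#' Isotropic tensor phantom
#'
#' Uniform field \eqn{\mathbf{D} = D_n \mathbf{I}}: the isotropic control
#' used when fiber-structure information is deliberately ignored. Its tensor
#' of preferential directions is the identity everywhere.
#'
#' @param grid a [phantomGrid()].
#' @param D_n scalar diffusivity, mm^2/day (default: the brain estimate 86.4).
#' @return a voxel [TensorField-class].
#' @export
isotropicPhantom <- function(grid, D_n = 86.4) {
  stopifnot(D_n > 0)
  uniformTensorField(grid, c(D_n, D_n, D_n, 0, 0, 0))
}

#' Axis-aligned anisotropic phantom
#'
#' The sensitivity-analysis construction: one diagonal component carries all
#' the diffusivity (\eqn{D_{xx} = D_n}, the other diagonal and all
#' off-diagonal components zero, for \code{axis = "x"}). Its tensor of
#' preferential directions is \code{diag(3, 0, 0)} (cells can only drift
#' along the chosen axis).
#'
#' @param grid a [phantomGrid()].
#' @param D_n diffusivity along the preferred axis, mm^2/day.
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @return a voxel [TensorField-class].
#' @export
axisAlignedPhantom <- function(grid, D_n = 86.4, axis = c("x", "y", "z")) {
  stopifnot(D_n > 0)
  axis <- match.arg(axis)
  row <- c(0, 0, 0, 0, 0, 0)
  row[match(axis, c("x", "y", "z"))] <- D_n
  uniformTensorField(grid, row)
}

#' Curved fiber-bundle phantom
#'
#' A synthetic stand-in for a curved white-matter tract (e.g. the corpus
#' callosum): within \code{bundle_radius} of a polyline centerline the tensor
#' has its principal eigenvector tangent to the centerline with eigenvalues
#' \code{(parallel, perp, perp)}; outside the bundle the field is isotropic at
#' the mean of the three eigenvalues, so the mean diffusivity is uniform.
#'
#' @param grid a [phantomGrid()].
#' @param centerline k x 3 matrix of polyline points (mm), k >= 2, with no
#'   repeated consecutive points.
#' @param bundle_radius bundle radius, mm, positive.
#' @param parallel_diffusivity,perpendicular_diffusivity eigenvalues along /
#'   across the fiber, mm^2/day, with
#'   \code{parallel_diffusivity >= perpendicular_diffusivity > 0}.
#' @return a voxel [TensorField-class]; the \code{mask} marks in-bundle
#'   voxels.
#' @export
fiberBundlePhantom <- function(grid, centerline, bundle_radius,
                               parallel_diffusivity, perpendicular_diffusivity) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3L, nrow(centerline) >= 2L,
            bundle_radius > 0,
            parallel_diffusivity >= perpendicular_diffusivity,
            perpendicular_diffusivity > 0)
  seglen <- sqrt(rowSums((centerline[-1L, , drop = FALSE] -
                          centerline[-nrow(centerline), , drop = FALSE])^2))
  if (any(seglen == 0))
    stop("degenerate centerline: repeated consecutive points")
  pts <- gridVoxelCenters(grid)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_seg <- integer(n)
  best_tang <- matrix(0, n, 3L)
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]; b <- centerline[s + 1L, ]
    ab <- b - a
    tt <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L] +
           (pts[, 3L] - a[3L]) * ab[3L]) / sum(ab^2)
    tt <- pmin(pmax(tt, 0), 1)
    dx <- pts[, 1L] - (a[1L] + tt * ab[1L])
    dy <- pts[, 2L] - (a[2L] + tt * ab[2L])
    dz <- pts[, 3L] - (a[3L] + tt * ab[3L])
    d2 <- dx^2 + dy^2 + dz^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_seg[upd] <- s
      best_tang[upd, ] <- matrix(ab / sqrt(sum(ab^2)), sum(upd), 3L, byrow = TRUE)
    }
  }
  inside <- best_d2 <= bundle_radius^2
  iso <- (parallel_diffusivity + 2 * perpendicular_diffusivity) / 3
  vals <- matrix(rep(c(iso, iso, iso, 0, 0, 0), each = n), n, 6L)
  if (any(inside)) {
    tq <- best_tang[inside, , drop = FALSE]
    dl <- parallel_diffusivity - perpendicular_diffusivity
    vals[inside, 1L] <- perpendicular_diffusivity + dl * tq[, 1L]^2
    vals[inside, 2L] <- perpendicular_diffusivity + dl * tq[, 2L]^2
    vals[inside, 3L] <- perpendicular_diffusivity + dl * tq[, 3L]^2
    vals[inside, 4L] <- dl * tq[, 1L] * tq[, 2L]
    vals[inside, 5L] <- dl * tq[, 1L] * tq[, 3L]
    vals[inside, 6L] <- dl * tq[, 2L] * tq[, 3L]
  }
  tensorField(vals, grid = grid, mask = inside)
}

setMethod("sampleToMesh", signature(x = "TensorField", mesh = "TumorMesh"),
  function(x, mesh) {
    if (x@space != "voxel") stop("sampleToMesh needs a voxel-space field")
    if (nrow(mesh@cells) == 0L) stop("empty mesh")
    bary <- cellBarycenters(mesh)
    ## voxel i covers world interval origin + (i-1 +/- 1/2) * spacing
    idx <- matrix(0L, nrow(bary), 3L)
    for (k in 1:3) {
      idx[, k] <- as.integer(round((bary[, k] - x@origin[k]) / x@spacing[k])) + 1L
    }
    inside <- idx[, 1L] >= 1L & idx[, 1L] <= x@dim[1L] &
      idx[, 2L] >= 1L & idx[, 2L] <= x@dim[2L] &
      idx[, 3L] >= 1L & idx[, 3L] <= x@dim[3L]
    n_out <- sum(!inside)
    lin <- rep(1L, nrow(bary))
    lin[inside] <- idx[inside, 1L] +
      x@dim[1L] * (idx[inside, 2L] - 1L) +
      x@dim[1L] * x@dim[2L] * (idx[inside, 3L] - 1L)
    vals <- x@values[lin, , drop = FALSE]
    mask <- x@mask[lin]
    if (n_out > 0) {
      fallback <- mean(meanDiffusivity(x))
      vals[!inside, ] <- rep(c(fallback, fallback, fallback, 0, 0, 0),
                             each = n_out)
      mask[!inside] <- FALSE
      warning(sprintf("%d mesh cell(s) outside the voxel grid received the isotropic fallback",
                      n_out))
    }
    tensorField(vals, grid = NULL, mask = mask)
  })

#' Read a tensor field from six NIfTI component volumes
#'
#' @param paths character vector of six file paths, one per component, named
#'   or ordered as \code{xx, yy, zz, xy, xz, yz}. All volumes must share grid
#'   dimensions, voxel spacing and origin, and be axis-aligned (general
#'   affines are rejected).
#' @return a voxel [TensorField-class] with geometry from the volume headers.
#' @seealso [writeTensorVolumes()]
#' @export
readTensorVolumes <- function(paths) {
  if (length(paths) != 6L) stop("exactly six component volumes are required")
  if (!is.null(names(paths))) {
    if (!setequal(names(paths), TENSOR_COMPONENTS))
      stop("names(paths) must be xx, yy, zz, xy, xz, yz")
    paths <- paths[TENSOR_COMPONENTS]
  }
  ref <- NULL
  comps <- vector("list", 6L)
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[[i]])
    geo <- niftiGeometry(img, paths[[i]])
    if (is.null(ref)) {
      ref <- geo
    } else if (!isTRUE(all.equal(ref, geo, tolerance = 1e-6))) {
      stop(sprintf("volume '%s' has mismatched grid geometry (dims/spacing/origin)",
                   paths[[i]]))
    }
    comps[[i]] <- as.numeric(img)
  }
  grid <- phantomGrid(ref$dim, spacing = ref$spacing, origin = ref$origin)
  tensorField(do.call(cbind, comps), grid = grid)
}

niftiGeometry <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L) stop(sprintf("volume '%s' is not 3-D", path))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 * max(abs(rot)) || any(diag(rot) <= 0))
    stop(sprintf("volume '%s' has a non-axis-aligned affine; only axis-aligned grids are supported",
                 path))
  list(dim = as.integer(d), spacing = as.numeric(diag(rot)),
       origin = as.numeric(xf[1:3, 4L]))
}

#' Write a voxel tensor field as six NIfTI component volumes
#'
#' @param x a voxel-space [TensorField-class].
#' @param prefix output path prefix; files are written as
#'   \code{<prefix>_<comp>.nii.gz} for each of xx, yy, zz, xy, xz, yz.
#' @return (invisibly) the named vector of file paths.
#' @export
writeTensorVolumes <- function(x, prefix) {
  stopifnot(is(x, "TensorField"))
  if (x@space != "voxel") stop("only voxel-space fields can be written as volumes")
  aff <- rbind(cbind(diag(x@spacing), x@origin), c(0, 0, 0, 1))
  paths <- character(6L)
  names(paths) <- TENSOR_COMPONENTS
  for (i in seq_along(TENSOR_COMPONENTS)) {
    arr <- array(x@values[, i], dim = x@dim)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- x@spacing
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    p <- sprintf("%s_%s.nii.gz", prefix, TENSOR_COMPONENTS[i])
    RNifti::writeNifti(img, p)
    paths[i] <- p
  }
  invisible(paths)
}
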