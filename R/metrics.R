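#' @include mesh.R
NULL

#' Thresholded tumor region
#'
#' The tumor region is the set of cells where the (vertex-interpolated)
#' volume fraction at the barycenter reaches the threshold
#' \eqn{\epsilon_t}: \eqn{\Omega_t = \{x : \phi(x) \ge \epsilon_t\}}.
#'
#' @param mesh a [TumorMesh-class].
#' @param phi vertex field.
#' @param eps_t threshold in (0, 1); default 0.05.
#' @return list with \code{mask} (logical per cell) and \code{volume} (mm^3,
#'   0 for an empty region).
#' @export
tumorRegion <- function(mesh, phi, eps_t = 0.05) {
  stopifnot(is(mesh, "TumorMesh"), length(phi) == nrow(mesh@vertices))
  if (eps_t <= 0 || eps_t >= 1) stop("eps_t must lie in (0, 1)")
  cm <- (phi[mesh@cells[, 1L]] + phi[mesh@cells[, 2L]] +
         phi[mesh@cells[, 3L]] + phi[mesh@cells[, 4L]]) / 4
  mask <- cm >= eps_t
  list(mask = mask, volume = sum(cellVolumes(mesh)[mask]))
}

#' Tumor semi-axes along the coordinate axes
#'
#' Measures the half-extents \eqn{(\Delta x, \Delta y, \Delta z)} of the
#' thresholded tumor region: along each coordinate axis through the region
#' centroid, phi is sampled on a fine line and \eqn{\Delta} is half the
#' distance between the two outermost crossings of \eqn{\phi = \epsilon_t}
#' (linear interpolation between sample points). These are the markers of
#' anisotropic growth: the ratio of the major to the minor semi-axes of the
#' grown tumor ellipsoid.
#'
#' @param mesh a [TumorMesh-class].
#' @param phi vertex field.
#' @param eps_t threshold in (0, 1).
#' @param geom optional precomputed [cellGeometry()] (reused across calls).
#' @return named numeric 3-vector \code{c(dx, dy, dz)} (mm).
#' @export
semiAxes <- function(mesh, phi, eps_t = 0.05, geom = NULL) {
  reg <- tumorRegion(mesh, phi, eps_t)
  if (!any(reg$mask)) stop("empty tumor region: no cell reaches eps_t")
  vols <- cellVolumes(mesh)[reg$mask]
  bary <- cellBarycenters(mesh)[reg$mask, , drop = FALSE]
  centroid <- colSums(bary * vols) / sum(vols)
  if (is.null(geom)) geom <- cellGeometry(mesh)
  hmin <- (6 * min(geom$vol))^(1 / 3)
  bb <- apply(mesh@vertices, 2L, range)
  out <- numeric(3L)
  for (ax in 1:3) {
    ts <- seq(bb[1L, ax], bb[2L, ax], by = hmin / 4)
    pts <- matrix(rep(centroid, each = length(ts)), ncol = 3L)
    pts[, ax] <- ts
    vals <- interpolateAtPoints(mesh, phi, pts, geom = geom)
    inside <- !is.na(vals) & vals >= eps_t
    if (!any(inside)) {
      out[ax] <- 0
      next
    }
    k1 <- which(inside)[1L]
    k2 <- tail(which(inside), 1L)
    t1 <- ts[k1]
    if (k1 > 1L && !is.na(vals[k1 - 1L]) && vals[k1] != vals[k1 - 1L]) {
      t1 <- ts[k1 - 1L] + (eps_t - vals[k1 - 1L]) / (vals[k1] - vals[k1 - 1L]) *
        (ts[k1] - ts[k1 - 1L])
    }
    t2 <- ts[k2]
    if (k2 < length(ts) && !is.na(vals[k2 + 1L]) && vals[k2] != vals[k2 + 1L]) {
      t2 <- ts[k2] + (eps_t - vals[k2]) / (vals[k2 + 1L] - vals[k2]) *
        (ts[k2 + 1L] - ts[k2])
    }
    out[ax] <- (t2 - t1) / 2
  }
  names(out) <- c("dx", "dy", "dz")
  attr(out, "centroid") <- centroid
  out
}

#' Tumor-shape summary of a field
#'
#' @param mesh a [TumorMesh-class].
#' @param phi vertex field.
#' @param eps_t threshold in (0, 1).
#' @return a [TumorShape-class]; for an empty region the semi-axes, volume
#'   and centroid are zero.
#' @export
tumorShape <- function(mesh, phi, eps_t = 0.05) {
  reg <- tumorRegion(mesh, phi, eps_t)
  if (!any(reg$mask)) {
    return(new("TumorShape", delta_x = 0, delta_y = 0, delta_z = 0,
               volume = 0, phi_max = max(max(phi), 0), centroid = c(0, 0, 0),
               eps_t = eps_t))
  }
  ax <- semiAxes(mesh, phi, eps_t)
  new("TumorShape", delta_x = unname(ax[1L]), delta_y = unname(ax[2L]),
      delta_z = unname(ax[3L]), volume = reg$volume,
      phi_max = min(max(phi), 1), centroid = attr(ax, "centroid"),
      eps_t = eps_t)
}

setMethod("show", "TumorShape", function(object) {
  cat(sprintf("TumorShape (eps_t = %g): dx = %.3f, dy = %.3f, dz = %.3f mm\n",
              object@eps_t, object@delta_x, object@delta_y, object@delta_z))
  cat(sprintf("  volume %.3f mm^3, max phi %.4f, centroid (%.2f, %.2f, %.2f) mm\n",
              object@volume, object@phi_max, object@centroid[1L],
              object@centroid[2L], object@centroid[3L]))
})

#' Growth summary between two states
#'
#' The quantities the sensitivity analyses report: the ratio of the maximum
#' volume fraction at the final and initial time \eqn{\phi^M/\phi_0^M}, the
#' final/initial tumor-volume ratio, and the semi-axis ratios
#' \eqn{\Delta x/\Delta y}, \eqn{\Delta x/\Delta z} of the final tumor.
#'
#' @param initial,final [SimulationState-class] objects on the same mesh.
#' @param mesh the [TumorMesh-class].
#' @param eps_t threshold for the tumor region.
#' @return list with \code{phi_max_ratio}, \code{volume_ratio},
#'   \code{dx_over_dy}, \code{dx_over_dz}, and the initial/final
#'   [TumorShape-class] objects.
#' @export
summarizeGrowth <- function(initial, final, mesh, eps_t = 0.05) {
  stopifnot(is(initial, "SimulationState"), is(final, "SimulationState"),
            length(initial@phi) == nrow(mesh@vertices),
            length(final@phi) == nrow(mesh@vertices))
  s0 <- tumorShape(mesh, initial@phi, eps_t)
  s1 <- tumorShape(mesh, final@phi, eps_t)
  list(
    phi_max_ratio = s1@phi_max / s0@phi_max,
    volume_ratio = s1@volume / s0@volume,
    dx_over_dy = s1@delta_x / s1@delta_y,
    dx_over_dz = s1@delta_x / s1@delta_z,
    initial = s0,
    final = s1
  )
}
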