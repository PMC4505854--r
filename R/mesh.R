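#' @include AllClasses.R
NULL

#' Accessors for mesh slots
#' @param mesh a [TumorMesh-class].
#' @return \code{meshVertices}: n x 3 coordinate matrix (mm);
#'   \code{meshCells}: m x 4 index matrix; \code{meshLabels}: integer labels
#'   (length 0 when absent).
#' @export
meshVertices <- function(mesh) {
  stopifnot(is(mesh, "TumorMesh"))
  mesh@vertices
}

#' @rdname meshVertices
#' @export
meshCells <- function(mesh) {
  stopifnot(is(mesh, "TumorMesh"))
  mesh@cells
}

#' @rdname meshVertices
#' @export
meshLabels <- function(mesh) {
  stopifnot(is(mesh, "TumorMesh"))
  mesh@labels
}

setMethod("show", "TumorMesh", function(object) {
  cat(sprintf("TumorMesh: %d vertices, %d tetrahedra\n",
              nrow(object@vertices), nrow(object@cells)))
  bb <- apply(object@vertices, 2L, range)
  cat(sprintf("  bounding box [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  total volume %.6g mm^3\n", sum(cellVolumes(object))))
  if (length(object@labels))
    cat(sprintf("  tissue labels: %s\n",
                paste(names(table(object@labels)), table(object@labels),
                      sep = ":", collapse = ", ")))
})

## Signed volumes * 6 of all cells (positive for correctly oriented cells).
cellSignedVolumes6 <- function(vertices, cells) {
  x1 <- vertices[cells[, 1L], , drop = FALSE]
  e1 <- vertices[cells[, 2L], , drop = FALSE] - x1
  e2 <- vertices[cells[, 3L], , drop = FALSE] - x1
  e3 <- vertices[cells[, 4L], , drop = FALSE] - x1
  e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
    e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
    e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
}

#' Cell volumes and barycenters
#' @param mesh a [TumorMesh-class].
#' @return \code{cellVolumes}: numeric vector (mm^3); \code{cellBarycenters}:
#'   m x 3 matrix (mm).
#' @export
cellVolumes <- function(mesh) {
  cellSignedVolumes6(mesh@vertices, mesh@cells) / 6
}

#' @rdname cellVolumes
#' @export
cellBarycenters <- function(mesh) {
  (mesh@vertices[mesh@cells[, 1L], , drop = FALSE] +
   mesh@vertices[mesh@cells[, 2L], , drop = FALSE] +
   mesh@vertices[mesh@cells[, 3L], , drop = FALSE] +
   mesh@vertices[mesh@cells[, 4L], , drop = FALSE]) / 4
}

## Flip vertex order of negatively oriented cells so volumes are positive.
fixCellOrientation <- function(vertices, cells) {
  s <- cellSignedVolumes6(vertices, cells)
  neg <- s < 0
  if (any(neg)) cells[neg, 3:4] <- cells[neg, c(4L, 3L)]
  cells
}

## Facet census. Keys are built from the sorted vertex triple of each of the
## four facets of every cell; interior facets appear twice, boundary facets
## once.
facetKeys <- function(cells) {
  m <- nrow(cells)
  f <- rbind(cells[, c(1L, 2L, 3L), drop = FALSE],
             cells[, c(1L, 2L, 4L), drop = FALSE],
             cells[, c(1L, 3L, 4L), drop = FALSE],
             cells[, c(2L, 3L, 4L), drop = FALSE])
  lo <- pmin(f[, 1L], f[, 2L], f[, 3L])
  hi <- pmax(f[, 1L], f[, 2L], f[, 3L])
  fs <- cbind(lo, f[, 1L] + f[, 2L] + f[, 3L] - lo - hi, hi)
  nv <- max(cells) + 1
  if (nv^3 < 2^52) {
    key <- (as.numeric(fs[, 1L]) * nv + fs[, 2L]) * nv + fs[, 3L]
  } else {
    key <- paste(fs[, 1L], fs[, 2L], fs[, 3L])
  }
  list(key = key, facets = fs, cell = rep(seq_len(m), times = 4L))
}

facetCounts <- function(cells) {
  if (nrow(cells) == 0L) return(integer(0))
  fk <- facetKeys(cells)
  as.integer(table(fk$key))
}

#' Boundary facets of a mesh
#' @param mesh a [TumorMesh-class].
#' @return integer matrix b x 3 of vertex triples, one row per boundary facet
#'   (facets adjacent to exactly one cell).
#' @export
boundaryFacets <- function(mesh) {
  fk <- facetKeys(mesh@cells)
  tab <- table(fk$key)
  bkeys <- names(tab)[tab == 1L]
  fk$facets[match(bkeys, as.character(fk$key)), , drop = FALSE]
}

boundaryVertexIndices <- function(mesh) {
  sort(unique(as.integer(boundaryFacets(mesh))))
}

newTumorMesh <- function(vertices, cells, labels = integer(0), grid = list()) {
  storage.mode(cells) <- "integer"
  cells <- fixCellOrientation(vertices, cells)
  new("TumorMesh", vertices = vertices, cells = cells,
      labels = as.integer(labels), grid = grid)
}

#' Structured tetrahedral box mesh
#'
#' Tessellates an axis-aligned box into hexahedra, each subdivided into six
#' tetrahedra (Kuhn subdivision, face-consistent across neighboring
#' hexahedra so the mesh is conforming).
#'
#' @param extents box edge lengths per axis, mm (scalar or 3-vector).
#' @param resolution cells per axis (scalar or 3-vector of positive
#'   integers).
#' @param origin coordinates of the box corner (default the world origin).
#' @return a [TumorMesh-class] with \code{prod(resolution + 1)} vertices and
#'   \code{6 * prod(resolution)} tetrahedra; total volume equals
#'   \code{prod(extents)} exactly.
#' @examples
#' m <- boxMesh(c(1, 1, 1), c(1, 1, 1))
#' sum(cellVolumes(m))
#' @export
boxMesh <- function(extents, resolution, origin = c(0, 0, 0)) {
  extents <- rep_len(as.numeric(extents), 3L)
  resolution <- rep_len(as.integer(resolution), 3L)
  if (any(extents <= 0)) stop("extents must be positive")
  if (any(resolution < 1L)) stop("resolution must be at least one cell per axis")
  nx <- resolution[1L]; ny <- resolution[2L]; nz <- resolution[3L]
  h <- extents / resolution
  xs <- origin[1L] + (0:nx) * h[1L]
  ys <- origin[2L] + (0:ny) * h[2L]
  zs <- origin[3L] + (0:nz) * h[3L]
  vertices <- cbind(
    rep(xs, times = (ny + 1L) * (nz + 1L)),
    rep(rep(ys, each = nx + 1L), times = nz + 1L),
    rep(zs, each = (nx + 1L) * (ny + 1L))
  )
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  ii <- rep(0:(nx - 1L), times = ny * nz)
  jj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  kk <- rep(0:(nz - 1L), each = nx * ny)
  corner <- function(di, dj, dk) vid(ii + di, jj + dj, kk + dk)
  ## Kuhn subdivision: six tets along the (0,0,0)-(1,1,1) diagonal, one per
  ## axis permutation
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  ex <- diag(3L)
  cellList <- vector("list", 6L)
  for (p in seq_along(perms)) {
    s <- perms[[p]]
    o1 <- ex[s[1L], ]
    o2 <- ex[s[1L], ] + ex[s[2L], ]
    cellList[[p]] <- cbind(
      corner(0L, 0L, 0L),
      corner(o1[1L], o1[2L], o1[3L]),
      corner(o2[1L], o2[2L], o2[3L]),
      corner(1L, 1L, 1L)
    )
  }
  cells <- do.call(rbind, cellList)
  newTumorMesh(vertices, cells,
               grid = list(extents = extents, resolution = resolution,
                           origin = as.numeric(origin)))
}

## --- red-green local refinement ------------------------------------------

edgeSlotPairs <- cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L))
## edge slots per face; faces (123), (124), (134), (234)
faceEdgeSlots <- rbind(c(1L, 2L, 4L), c(1L, 3L, 5L), c(2L, 3L, 6L), c(4L, 5L, 6L))
oppositeSlotPairs <- rbind(c(1L, 6L), c(2L, 5L), c(3L, 4L))

edgeKey <- function(a, b, nv) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.numeric(lo) * (nv + 1) + hi
}

## Edge keys of all cells, m x 6 (slot order as edgeSlotPairs).
cellEdgeKeys <- function(cells, nv) {
  k <- matrix(0, nrow(cells), 6L)
  for (s in 1:6)
    k[, s] <- edgeKey(cells[, edgeSlotPairs[s, 1L]], cells[, edgeSlotPairs[s, 2L]], nv)
  k
}

#' Locally refine a mesh near a point
#'
#' Cells whose barycenter lies within \code{radius} of \code{center} are
#' subdivided by regular (red, 1-to-8) refinement, \code{levels} times.
#' Hanging nodes on neighboring cells are removed by a conforming green
#' closure (edge bisection, opposite-edge and face patterns; cells whose
#' marked-edge pattern admits no green template are promoted to red). Total
#' volume is preserved exactly and untouched cells keep their vertices.
#'
#' @param mesh a [TumorMesh-class].
#' @param center 3-vector, mm.
#' @param radius positive radius, mm.
#' @param levels number of refinement sweeps (0 returns the mesh unchanged).
#' @return a refined, conforming [TumorMesh-class].
#' @export
refineRegion <- function(mesh, center, radius, levels = 1L) {
  stopifnot(is(mesh, "TumorMesh"), length(center) == 3L)
  if (radius <= 0) stop("radius must be positive")
  levels <- as.integer(levels)
  if (levels < 0L) stop("levels must be non-negative")
  if (levels == 0L) return(mesh)
  bb <- apply(mesh@vertices, 2L, range)
  if (any(center < bb[1L, ] | center > bb[2L, ])) {
    warning("refinement center lies outside the mesh bounding box; returning the mesh unchanged")
    return(mesh)
  }
  for (l in seq_len(levels)) {
    bary <- cellBarycenters(mesh)
    d2 <- (bary[, 1L] - center[1L])^2 + (bary[, 2L] - center[2L])^2 +
      (bary[, 3L] - center[3L])^2
    red <- d2 <= radius^2
    if (!any(red)) break
    mesh <- refineOnce(mesh, red)
  }
  mesh
}

## One red-green sweep: 'red' flags the cells to be regularly subdivided.
refineOnce <- function(mesh, red) {
  cells <- mesh@cells
  vertices <- mesh@vertices
  labels <- mesh@labels
  nv <- nrow(vertices)
  ekeys <- cellEdgeKeys(cells, nv)

  ## closure: promote to red any cell with a face carrying exactly two marked
  ## edges (such faces cannot be split conformingly by a green template)
  repeat {
    markedKeys <- unique(as.vector(ekeys[red, , drop = FALSE]))
    marked <- matrix(ekeys %in% markedKeys, nrow(cells), 6L)
    ## a cell fully surrounded by red neighbors has all 6 edges marked while
    ## every face carries 3: no green template fits, promote it as well
    promote <- !red & rowSums(marked) > 3L
    for (f in 1:4) {
      fc <- rowSums(marked[, faceEdgeSlots[f, ], drop = FALSE])
      promote <- promote | (!red & fc == 2L)
    }
    if (!any(promote)) break
    red <- red | promote
  }

  ## create midpoint vertices for every marked edge
  markedKeys <- unique(as.vector(ekeys[red, , drop = FALSE]))
  if (!length(markedKeys)) return(mesh)
  lo <- floor(markedKeys / (nv + 1))
  hi <- markedKeys - lo * (nv + 1)
  mid <- (vertices[lo, , drop = FALSE] + vertices[hi, , drop = FALSE]) / 2
  midIds <- nv + seq_along(markedKeys)
  vertices <- rbind(vertices, mid)
  midOf <- function(keys) midIds[match(keys, markedKeys)]
  marked <- matrix(ekeys %in% markedKeys, nrow(cells), 6L)
  marked[red, ] <- TRUE
  haveLabels <- length(labels) > 0L

  outCells <- list()
  outLabels <- list()
  emit <- function(newcells, parents) {
    outCells[[length(outCells) + 1L]] <<- newcells
    if (haveLabels) outLabels[[length(outLabels) + 1L]] <<- labels[parents]
  }

  ## untouched cells
  cnt <- rowSums(marked)
  keep <- !red & cnt == 0L
  if (any(keep)) emit(cells[keep, , drop = FALSE], which(keep))

  ## red cells: 4 corner children + octahedron split along the m13-m24
  ## diagonal
  if (any(red)) {
    idx <- which(red)
    v <- cells[idx, , drop = FALSE]
    mm <- matrix(0L, length(idx), 6L)
    for (s in 1:6) mm[, s] <- midOf(ekeys[idx, s])
    ## slots: 1=(12) 2=(13) 3=(14) 4=(23) 5=(24) 6=(34)
    ch <- rbind(
      cbind(v[, 1L], mm[, 1L], mm[, 2L], mm[, 3L]),
      cbind(v[, 2L], mm[, 1L], mm[, 4L], mm[, 5L]),
      cbind(v[, 3L], mm[, 2L], mm[, 4L], mm[, 6L]),
      cbind(v[, 4L], mm[, 3L], mm[, 5L], mm[, 6L]),
      cbind(mm[, 2L], mm[, 5L], mm[, 1L], mm[, 3L]),
      cbind(mm[, 2L], mm[, 5L], mm[, 3L], mm[, 6L]),
      cbind(mm[, 2L], mm[, 5L], mm[, 6L], mm[, 4L]),
      cbind(mm[, 2L], mm[, 5L], mm[, 4L], mm[, 1L])
    )
    emit(ch, rep(idx, times = 8L))
  }

  ## green: single bisected edge
  green1 <- !red & cnt == 1L
  if (any(green1)) {
    for (s in 1:6) {
      sel <- which(green1 & marked[, s])
      if (!length(sel)) next
      a <- edgeSlotPairs[s, 1L]; b <- edgeSlotPairs[s, 2L]
      rest <- setdiff(1:4, c(a, b))
      m <- midOf(ekeys[sel, s])
      ch <- rbind(
        cbind(cells[sel, a], m, cells[sel, rest[1L]], cells[sel, rest[2L]]),
        cbind(m, cells[sel, b], cells[sel, rest[1L]], cells[sel, rest[2L]])
      )
      emit(ch, rep(sel, times = 2L))
    }
  }

  ## green: two opposite bisected edges
  green2 <- !red & cnt == 2L
  if (any(green2)) {
    handled <- rep(FALSE, nrow(cells))
    for (pidx in 1:3) {
      s1 <- oppositeSlotPairs[pidx, 1L]; s2 <- oppositeSlotPairs[pidx, 2L]
      sel <- which(green2 & marked[, s1] & marked[, s2])
      if (!length(sel)) next
      handled[sel] <- TRUE
      a <- edgeSlotPairs[s1, 1L]; b <- edgeSlotPairs[s1, 2L]
      c_ <- edgeSlotPairs[s2, 1L]; d <- edgeSlotPairs[s2, 2L]
      p <- midOf(ekeys[sel, s1]); q <- midOf(ekeys[sel, s2])
      ch <- rbind(
        cbind(cells[sel, a], p, cells[sel, c_], q),
        cbind(cells[sel, a], p, q, cells[sel, d]),
        cbind(p, cells[sel, b], cells[sel, c_], q),
        cbind(p, cells[sel, b], q, cells[sel, d])
      )
      emit(ch, rep(sel, times = 4L))
    }
    if (any(green2 & !handled))
      stop("internal error: two adjacent marked edges survived the closure")
  }

  ## green: one fully marked face
  green3 <- !red & cnt == 3L
  if (any(green3)) {
    faceVerts <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 4L, 3L),
                       c(1L, 3L, 4L, 2L), c(2L, 3L, 4L, 1L))
    handled <- rep(FALSE, nrow(cells))
    for (f in 1:4) {
      sel <- which(green3 &
                   rowSums(marked[, faceEdgeSlots[f, ], drop = FALSE]) == 3L)
      if (!length(sel)) next
      handled[sel] <- TRUE
      a <- faceVerts[f, 1L]; b <- faceVerts[f, 2L]
      c_ <- faceVerts[f, 3L]; d <- faceVerts[f, 4L]
      mab <- midOf(edgeKey(cells[sel, a], cells[sel, b], nv))
      mac <- midOf(edgeKey(cells[sel, a], cells[sel, c_], nv))
      mbc <- midOf(edgeKey(cells[sel, b], cells[sel, c_], nv))
      ch <- rbind(
        cbind(cells[sel, a], mab, mac, cells[sel, d]),
        cbind(cells[sel, b], mab, mbc, cells[sel, d]),
        cbind(cells[sel, c_], mac, mbc, cells[sel, d]),
        cbind(mab, mbc, mac, cells[sel, d])
      )
      emit(ch, rep(sel, times = 4L))
    }
    if (any(green3 & !handled))
      stop("internal error: three marked edges not on a single face")
  }

  if (any(!red & cnt > 3L))
    stop("internal error: unclassifiable marked-edge pattern after closure")

  newCells <- do.call(rbind, outCells)
  newLabels <- if (haveLabels) unlist(outLabels) else integer(0)
  newTumorMesh(vertices, newCells, labels = newLabels)
}

## --- P1 geometry -----------------------------------------------------------

## Per-cell P1 basis data: volumes and the gradients of the four barycentric
## basis functions (constant per cell). Gradients are returned as three
## m x 4 matrices (x, y, z components).
cellGeometry <- function(mesh) {
  vertices <- mesh@vertices
  cells <- mesh@cells
  x1 <- vertices[cells[, 1L], , drop = FALSE]
  e1 <- vertices[cells[, 2L], , drop = FALSE] - x1
  e2 <- vertices[cells[, 3L], , drop = FALSE] - x1
  e3 <- vertices[cells[, 4L], , drop = FALSE] - x1
  cx <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- cx(e2, e3); c31 <- cx(e3, e1); c12 <- cx(e1, e2)
  det <- e1[, 1L] * c23[, 1L] + e1[, 2L] * c23[, 2L] + e1[, 3L] * c23[, 3L]
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  list(
    vol = det / 6,
    gx = cbind(g1[, 1L], g2[, 1L], g3[, 1L], g4[, 1L]),
    gy = cbind(g1[, 2L], g2[, 2L], g3[, 2L], g4[, 2L]),
    gz = cbind(g1[, 3L], g2[, 3L], g3[, 3L], g4[, 3L]),
    x1 = x1
  )
}

## Piecewise-linear interpolation of a vertex field at arbitrary points.
## Points outside the mesh give NA. Brute-force cell location with a
## bounding-box prefilter.
interpolateAtPoints <- function(mesh, field, pts, geom = NULL) {
  pts <- matrix(pts, ncol = 3L)
  if (is.null(geom)) geom <- cellGeometry(mesh)
  cells <- mesh@cells
  v <- mesh@vertices
  lo <- pmin(pmin(v[cells[, 1L], , drop = FALSE], v[cells[, 2L], , drop = FALSE]),
             pmin(v[cells[, 3L], , drop = FALSE], v[cells[, 4L], , drop = FALSE]))
  hi <- pmax(pmax(v[cells[, 1L], , drop = FALSE], v[cells[, 2L], , drop = FALSE]),
             pmax(v[cells[, 3L], , drop = FALSE], v[cells[, 4L], , drop = FALSE]))
  out <- rep(NA_real_, nrow(pts))
  tol <- 1e-9
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    cand <- which(lo[, 1L] <= p[1L] + tol & hi[, 1L] >= p[1L] - tol &
                  lo[, 2L] <= p[2L] + tol & hi[, 2L] >= p[2L] - tol &
                  lo[, 3L] <= p[3L] + tol & hi[, 3L] >= p[3L] - tol)
    for (c in cand) {
      dp <- p - geom$x1[c, ]
      l2 <- geom$gx[c, 2L] * dp[1L] + geom$gy[c, 2L] * dp[2L] + geom$gz[c, 2L] * dp[3L]
      l3 <- geom$gx[c, 3L] * dp[1L] + geom$gy[c, 3L] * dp[2L] + geom$gz[c, 3L] * dp[3L]
      l4 <- geom$gx[c, 4L] * dp[1L] + geom$gy[c, 4L] * dp[2L] + geom$gz[c, 4L] * dp[3L]
      l1 <- 1 - l2 - l3 - l4
      if (min(l1, l2, l3, l4) >= -1e-8) {
        out[i] <- l1 * field[cells[c, 1L]] + l2 * field[cells[c, 2L]] +
          l3 * field[cells[c, 3L]] + l4 * field[cells[c, 4L]]
        break
      }
    }
  }
  out
}
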