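#' @include mesh.R
NULL

## P1 finite-element operators on a tetrahedral mesh.
##
## Everything the time stepper assembles repeatedly is precomputed here:
## cell geometry (volumes, constant basis gradients), the 16 per-cell basis
## gradient dot products, the triplet index arrays of the 4x4 element
## blocks, the lumped mass vector, and the unit stiffness matrix. 'bdry'
## lists vertices carrying essential conditions; their rows are dropped from
## assembled phi-block matrices (the Dirichlet identity is added by the
## caller).
femOperators <- function(mesh, bdry = integer(0)) {
  geom <- cellGeometry(mesh)
  cells <- mesh@cells
  nv <- nrow(mesh@vertices)
  m <- nrow(cells)
  gx <- geom$gx; gy <- geom$gy; gz <- geom$gz
  i16 <- matrix(0L, m, 16L)
  j16 <- matrix(0L, m, 16L)
  dots16 <- matrix(0, m, 16L)
  for (a in 1:4) {
    for (b in 1:4) {
      q <- (a - 1L) * 4L + b
      i16[, q] <- cells[, a]
      j16[, q] <- cells[, b]
      dots16[, q] <- gx[, a] * gx[, b] + gy[, a] * gy[, b] + gz[, a] * gz[, b]
    }
  }
  iVec <- as.vector(i16)
  jVec <- as.vector(j16)
  keep <- !(iVec %in% bdry)
  ml <- accumulateVertex(as.vector(cells), rep(geom$vol / 4, times = 4L), nv)
  ops <- list(mesh = mesh, geom = geom, cells = cells, nv = nv, m = m,
              iVec = iVec, jVec = jVec, keep = keep, dots16 = dots16,
              ml = ml, bdry = bdry, interior = setdiff(seq_len(nv), bdry))
  ops$K1 <- assembleScalarStiffness(ops, rep(1, m), drop_bdry = FALSE)
  ops
}

accumulateVertex <- function(idx, vals, nv) {
  r <- rowsum(vals, idx)
  out <- numeric(nv)
  out[as.integer(rownames(r))] <- r
  out
}

## Stiffness with a piecewise-constant scalar coefficient c:
## K[i,j] = sum_cells vol * c * (grad_i . grad_j)
assembleScalarStiffness <- function(ops, cvec, drop_bdry = TRUE) {
  vals <- ops$dots16 * (ops$geom$vol * cvec)
  v <- as.vector(vals)
  if (drop_bdry && length(ops$bdry)) {
    sparseMatrix(i = ops$iVec[ops$keep], j = ops$jVec[ops$keep],
                 x = v[ops$keep], dims = c(ops$nv, ops$nv))
  } else {
    sparseMatrix(i = ops$iVec, j = ops$jVec, x = v, dims = c(ops$nv, ops$nv))
  }
}

## Stiffness with a per-cell symmetric tensor coefficient A (cell TensorField
## component matrix): K[i,j] = sum_cells vol * grad_i . (A grad_j)
assembleTensorStiffness <- function(ops, tvals, drop_bdry = FALSE) {
  gx <- ops$geom$gx; gy <- ops$geom$gy; gz <- ops$geom$gz
  vol <- ops$geom$vol
  axx <- tvals[, 1L]; ayy <- tvals[, 2L]; azz <- tvals[, 3L]
  axy <- tvals[, 4L]; axz <- tvals[, 5L]; ayz <- tvals[, 6L]
  vals <- matrix(0, ops$m, 16L)
  for (a in 1:4) {
    for (b in 1:4) {
      q <- (a - 1L) * 4L + b
      tbx <- axx * gx[, b] + axy * gy[, b] + axz * gz[, b]
      tby <- axy * gx[, b] + ayy * gy[, b] + ayz * gz[, b]
      tbz <- axz * gx[, b] + ayz * gy[, b] + azz * gz[, b]
      vals[, q] <- vol * (gx[, a] * tbx + gy[, a] * tby + gz[, a] * tbz)
    }
  }
  v <- as.vector(vals)
  if (drop_bdry && length(ops$bdry)) {
    sparseMatrix(i = ops$iVec[ops$keep], j = ops$jVec[ops$keep],
                 x = v[ops$keep], dims = c(ops$nv, ops$nv))
  } else {
    sparseMatrix(i = ops$iVec, j = ops$jVec, x = v, dims = c(ops$nv, ops$nv))
  }
}

## Cell means of a vertex field.
cellMeans <- function(ops, field) {
  (field[ops$cells[, 1L]] + field[ops$cells[, 2L]] +
   field[ops$cells[, 3L]] + field[ops$cells[, 4L]]) / 4
}

## Per-cell gradient (m x 3) of a vertex field.
cellGradients <- function(ops, field) {
  f <- matrix(field[ops$cells], ops$m, 4L)
  cbind(rowSums(ops$geom$gx * f), rowSums(ops$geom$gy * f), rowSums(ops$geom$gz * f))
}

## Assembled chemotaxis vector: V[a] = sum_cells vol * k_n * phibar * (T grad n) . grad_a
## (the term enters the phi residual with a minus sign).
chemotaxisVector <- function(ops, phi, n, tvals, k_n, eta = 1e-6) {
  if (k_n == 0) return(numeric(ops$nv))
  phibar <- pmin(pmax(cellMeans(ops, phi), 0), 1 - eta)
  gn <- cellGradients(ops, n)
  tx <- tvals[, 1L] * gn[, 1L] + tvals[, 4L] * gn[, 2L] + tvals[, 5L] * gn[, 3L]
  ty <- tvals[, 4L] * gn[, 1L] + tvals[, 2L] * gn[, 2L] + tvals[, 6L] * gn[, 3L]
  tz <- tvals[, 5L] * gn[, 1L] + tvals[, 6L] * gn[, 2L] + tvals[, 3L] * gn[, 3L]
  w <- ops$geom$vol * k_n * phibar
  out <- numeric(ops$nv)
  for (a in 1:4) {
    va <- w * (ops$geom$gx[, a] * tx + ops$geom$gy[, a] * ty + ops$geom$gz[, a] * tz)
    out <- out + accumulateVertex(ops$cells[, a], va, ops$nv)
  }
  out
}

## Jacobian of the chemotaxis vector with respect to the nodal phi (the
## coefficient is the cell mean, so d phibar / d phi_j = 1/4 per incident
## vertex). Constant during a Newton solve because n is known.
chemotaxisDerivMatrix <- function(ops, n, tvals, k_n) {
  gn <- cellGradients(ops, n)
  tx <- tvals[, 1L] * gn[, 1L] + tvals[, 4L] * gn[, 2L] + tvals[, 5L] * gn[, 3L]
  ty <- tvals[, 4L] * gn[, 1L] + tvals[, 2L] * gn[, 2L] + tvals[, 6L] * gn[, 3L]
  tz <- tvals[, 5L] * gn[, 1L] + tvals[, 6L] * gn[, 2L] + tvals[, 3L] * gn[, 3L]
  w <- ops$geom$vol * k_n / 4
  vals <- matrix(0, ops$m, 16L)
  for (a in 1:4) {
    va <- w * (ops$geom$gx[, a] * tx + ops$geom$gy[, a] * ty + ops$geom$gz[, a] * tz)
    for (b in 1:4) vals[, (a - 1L) * 4L + b] <- va
  }
  v <- as.vector(vals)
  if (length(ops$bdry)) {
    sparseMatrix(i = ops$iVec[ops$keep], j = ops$jVec[ops$keep],
                 x = v[ops$keep], dims = c(ops$nv, ops$nv))
  } else {
    sparseMatrix(i = ops$iVec, j = ops$jVec, x = v, dims = c(ops$nv, ops$nv))
  }
}

## Jacobian block of the Sigma-flux term with respect to nodal phi:
## d/dphi_j [ sum vol c(phibar) grad Sigma . grad_a ] =
##   vol c'(phibar)/4 (grad Sigma . grad_a)
mobilityDerivMatrix <- function(ops, cprime, sigma) {
  gs <- cellGradients(ops, sigma)
  w <- ops$geom$vol * cprime / 4
  vals <- matrix(0, ops$m, 16L)
  for (a in 1:4) {
    va <- w * (ops$geom$gx[, a] * gs[, 1L] + ops$geom$gy[, a] * gs[, 2L] +
               ops$geom$gz[, a] * gs[, 3L])
    for (b in 1:4) vals[, (a - 1L) * 4L + b] <- va
  }
  v <- as.vector(vals)
  if (length(ops$bdry)) {
    sparseMatrix(i = ops$iVec[ops$keep], j = ops$jVec[ops$keep],
                 x = v[ops$keep], dims = c(ops$nv, ops$nv))
  } else {
    sparseMatrix(i = ops$iVec, j = ops$jVec, x = v, dims = c(ops$nv, ops$nv))
  }
}
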