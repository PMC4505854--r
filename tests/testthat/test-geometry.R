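test_that("box meshes tessellate the exact volume with the expected counts", {
  m <- boxMesh(c(1, 1, 1), c(1, 1, 1))
  expect_equal(nrow(meshVertices(m)), 8L)
  expect_equal(nrow(meshCells(m)), 6L)
  expect_equal(sum(cellVolumes(m)), 1, tolerance = 1e-12)
  m2 <- boxMesh(c(3, 2, 5), c(4, 3, 2))
  expect_equal(nrow(meshVertices(m2)), 5L * 4L * 3L)
  expect_equal(sum(cellVolumes(m2)), 30, tolerance = 1e-10 * 30)
  expect_true(all(cellVolumes(m2) > 0))
  expect_error(boxMesh(c(1, 1, 1), c(0, 1, 1)), "resolution")
  expect_error(boxMesh(c(-1, 1, 1), c(1, 1, 1)), "extents")
})

test_that("subdivision geometry bounds the maximum edge length", {
  m <- boxMesh(c(60, 60, 60), c(32, 32, 32))
  cells <- meshCells(m)
  v <- meshVertices(m)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  maxlen <- 0
  for (k in 1:6) {
    d <- v[cells[, pairs[k, 1]], ] - v[cells[, pairs[k, 2]], ]
    maxlen <- max(maxlen, sqrt(max(rowSums(d^2))))
  }
  expect_lte(maxlen, 60 / 32 * sqrt(3) + 1e-12)
})

test_that("facet census: interior facets shared by 2 cells, boundary by 1", {
  m <- boxMesh(c(2, 2, 2), c(2, 2, 2))
  cnt <- gbmsim:::facetCounts(meshCells(m))
  expect_true(all(cnt %in% 1:2))
  bf <- boundaryFacets(m)
  # brute-force census on the small mesh
  expect_equal(nrow(bf), sum(cnt == 1L))
  # every boundary facet lies on the box surface
  v <- meshVertices(m)
  onSurface <- function(tri) {
    any(vapply(1:3, function(ax) {
      all(abs(v[tri, ax]) < 1e-12) || all(abs(v[tri, ax] - 2) < 1e-12)
    }, logical(1)))
  }
  expect_true(all(apply(bf, 1L, onSurface)))
})

test_that("local refinement is conforming, volume-exact and level-0 safe", {
  m <- boxMesh(c(8, 8, 8), c(4, 4, 4))
  expect_identical(refineRegion(m, c(4, 4, 4), 2, levels = 0L), m)
  # whole-mesh refinement: red 1-to-8
  whole <- refineRegion(m, c(4, 4, 4), radius = 100, levels = 1L)
  expect_equal(nrow(meshCells(whole)), 8L * nrow(meshCells(m)))
  expect_equal(sum(cellVolumes(whole)), 512, tolerance = 1e-10 * 512)
  # local refinement: conforming closure, exact volume, untouched far cells
  loc <- refineRegion(m, c(4, 4, 4), radius = 2, levels = 1L)
  expect_gt(nrow(meshCells(loc)), nrow(meshCells(m)))
  expect_equal(sum(cellVolumes(loc)), 512, tolerance = 1e-10 * 512)
  expect_true(all(gbmsim:::facetCounts(meshCells(loc)) %in% 1:2))
  expect_true(all(cellVolumes(loc) > 0))
  # two levels still conforming and volume-exact
  loc2 <- refineRegion(m, c(4, 4, 4), radius = 2, levels = 2L)
  expect_equal(sum(cellVolumes(loc2)), 512, tolerance = 1e-10 * 512)
  expect_true(all(gbmsim:::facetCounts(meshCells(loc2)) %in% 1:2))
  # center outside the bounding box: warning and no-op
  expect_warning(same <- refineRegion(m, c(50, 50, 50), 2, 1L), "outside")
  expect_identical(same, m)
  # labels are inherited by children
  ml <- new("TumorMesh", vertices = meshVertices(m), cells = meshCells(m),
            labels = rep(c(1L, 2L), length.out = nrow(meshCells(m))),
            grid = list())
  mlr <- refineRegion(ml, c(4, 4, 4), radius = 100, levels = 1L)
  expect_equal(length(meshLabels(mlr)), nrow(meshCells(mlr)))
  expect_equal(sum(cellVolumes(mlr)[meshLabels(mlr) == 1L]),
               sum(cellVolumes(ml)[meshLabels(ml) == 1L]), tolerance = 1e-10)
})

test_that("MSH and VTK files round-trip coordinates, connectivity and labels", {
  m <- boxMesh(c(3, 3, 3), c(2, 2, 2))
  m@labels <- rep(c(1L, 2L, 3L), length.out = nrow(meshCells(m)))
  for (writer in list(writeMeshMSH, writeMeshVTK)) {
    path <- tempfile(fileext = if (identical(writer, writeMeshMSH)) ".msh" else ".vtk")
    writer(m, path)
    back <- readMesh(path)
    expect_equal(meshVertices(back), meshVertices(m), tolerance = 1e-12)
    expect_identical(meshCells(back), meshCells(m))
    expect_identical(meshLabels(back), meshLabels(m))
    unlink(path)
  }
})

test_that("mesh readers reject non-tetrahedral and degenerate cells", {
  # MSH with a pyramid element (type 7)
  msh <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", "5",
           "1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0", "5 0.5 0.5 1",
           "$EndNodes", "$Elements", "1", "1 7 2 1 1 1 2 3 4 5", "$EndElements")
  f <- tempfile(fileext = ".msh")
  writeLines(msh, f)
  expect_error(readMesh(f), "non-tetrahedral")
  # VTK with a hexahedron type
  vtk <- c("# vtk DataFile Version 3.0", "t", "ASCII",
           "DATASET UNSTRUCTURED_GRID", "POINTS 4 double",
           "0 0 0", "1 0 0", "0 1 0", "0 0 1",
           "CELLS 1 5", "4 0 1 2 3", "CELL_TYPES 1", "12")
  f2 <- tempfile(fileext = ".vtk")
  writeLines(vtk, f2)
  expect_error(readMesh(f2), "non-tetrahedral")
  # degenerate (zero-volume) tetrahedron
  msh2 <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", "4",
            "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 1 1 0",
            "$EndNodes", "$Elements", "1", "1 4 2 1 1 1 2 3 4", "$EndElements")
  f3 <- tempfile(fileext = ".msh")
  writeLines(msh2, f3)
  expect_error(readMesh(f3), "degenerate")
  unlink(c(f, f2, f3))
})
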