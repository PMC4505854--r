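test_that("mean diffusivity is the trace third and rotation invariant", {
  mesh <- boxMesh(c(2, 2, 2), c(1, 1, 1))
  f <- uniformCellField(mesh, c(1, 2, 3, 0.1, -0.2, 0.3))
  expect_equal(unique(meanDiffusivity(f)), 2)
  expect_equal(unique(meanDiffusivity(uniformCellField(mesh, c(86.4, 0, 0, 0, 0, 0)))),
               28.8)
  set.seed(42)
  vals <- randomSPDComponents(50, seed = 7L)
  for (k in c(1L, 17L, 50L)) {
    A <- gbmsim:::tensorRowToMatrix(vals[k, ])
    R <- randomRotation()
    Arot <- R %*% A %*% t(R)
    fr <- tensorField(matrix(gbmsim:::tensorMatrixToRow(Arot), 1, 6))
    fo <- tensorField(matrix(vals[k, ], 1, 6))
    expect_equal(meanDiffusivity(fr), meanDiffusivity(fo), tolerance = 1e-12)
  }
})

test_that("preferential directions normalize by mean diffusivity with trace 3", {
  grid <- phantomGrid(c(3, 3, 3), spacing = 1)
  expect_equal(unname(tensorValues(preferentialDirections(isotropicPhantom(grid, 5)))[1, ]),
               c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(tensorValues(preferentialDirections(axisAlignedPhantom(grid, 86.4)))[1, ]),
               c(3, 0, 0, 0, 0, 0))
  vals <- randomSPDComponents(2000, seed = 3L)
  T_f <- preferentialDirections(tensorField(vals))
  tr <- rowSums(tensorValues(T_f)[, 1:3])
  expect_true(all(abs(tr - 3) < 3e-10))
  # D = D_n * T reconstruction
  rec <- tensorValues(T_f) * meanDiffusivity(tensorField(vals))
  expect_equal(max(abs(rec - vals) / pmax(abs(vals), 1e-12)), 0, tolerance = 1e-12)
})

test_that("preferential directions commute with rotations", {
  vals <- randomSPDComponents(20, seed = 11L)
  set.seed(5)
  for (k in 1:5) {
    A <- gbmsim:::tensorRowToMatrix(vals[k, ])
    R <- randomRotation()
    T_then_rot <- R %*% gbmsim:::tensorRowToMatrix(
      tensorValues(preferentialDirections(tensorField(matrix(vals[k, ], 1, 6))))[1, ]) %*% t(R)
    rot_then_T <- gbmsim:::tensorRowToMatrix(
      tensorValues(preferentialDirections(tensorField(
        matrix(gbmsim:::tensorMatrixToRow(R %*% A %*% t(R)), 1, 6))))[1, ])
    expect_equal(T_then_rot, rot_then_T, tolerance = 1e-10)
  }
})

test_that("zero mean diffusivity locations get the masked identity fallback", {
  vals <- rbind(c(2, 1, 0.5, 0, 0, 0), c(0, 0, 0, 0, 0, 0))
  T_f <- preferentialDirections(tensorField(vals))
  expect_equal(unname(tensorValues(T_f)[2, ]), c(1, 1, 1, 0, 0, 0))
  expect_equal(tensorMask(T_f), c(TRUE, FALSE))
})

test_that("eigenvalue regularization clamps from below and is a no-op otherwise", {
  good <- c(1, 2, 3, 0, 0, 0)
  bad <- c(1, -0.1, 0.5, 0, 0, 0)
  f <- tensorField(rbind(good, bad))
  out <- regularizeTensors(f, 1e-6)
  # untouched tensor is bit-identical
  expect_identical(unname(tensorValues(out)[1, ]), good)
  expect_equal(unname(tensorValues(out)[2, ]), c(1, 1e-6, 0.5, 0, 0, 0))
  # zero tensor -> floor * I
  z <- regularizeTensors(tensorField(matrix(0, 1, 6)), 1e-6)
  expect_equal(unname(tensorValues(z)[1, ]), c(1e-6, 1e-6, 1e-6, 0, 0, 0))
  # non-diagonal case against an eigen oracle
  A <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 0.5), 3, 3)  # eigenvalues 3, -1, 0.5
  out2 <- regularizeTensors(tensorField(matrix(gbmsim:::tensorMatrixToRow(A), 1, 6)), 0)
  ed <- eigen(A, symmetric = TRUE)
  Aref <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
  expect_equal(gbmsim:::tensorRowToMatrix(tensorValues(out2)[1, ]), Aref,
               tolerance = 1e-12)
  expect_error(regularizeTensors(tensorField(matrix(c(NA, 1, 1, 0, 0, 0), 1, 6))),
               "non-finite")
  # regularize then normalize gives trace 3 everywhere
  vals <- randomSPDComponents(500, seed = 9L)
  vals[, 1L] <- vals[, 1L] - 0.1  # may push some eigenvalues negative
  T_f <- preferentialDirections(regularizeTensors(tensorField(vals), 1e-9))
  tr <- rowSums(tensorValues(T_f)[, 1:3])
  expect_true(all(abs(tr - 3) < 3e-10))
})

test_that("fiber-bundle phantom aligns its principal axis with the centerline", {
  grid <- phantomGrid(c(20, 20, 5), spacing = 1)
  # straight bundle along x reduces to the axis-aligned diagonal inside
  straight <- fiberBundlePhantom(grid, rbind(c(-5, 10, 2.5), c(30, 10, 2.5)),
                                 bundle_radius = 3, 2, 0.5)
  inside <- tensorMask(straight)
  expect_true(any(inside))
  expect_equal(unname(tensorValues(straight)[which(inside)[1], ]),
               c(2, 0.5, 0.5, 0, 0, 0))
  expect_equal(unname(tensorValues(straight)[which(!inside)[1], ]),
               c(1, 1, 1, 0, 0, 0))
  # equal eigenvalues: isotropic everywhere
  iso <- fiberBundlePhantom(grid, rbind(c(-5, 10, 2.5), c(30, 10, 2.5)), 3, 1, 1)
  expect_true(all(abs(tensorValues(iso)[, 1:3] - 1) < 1e-14))
  expect_true(all(abs(tensorValues(iso)[, 4:6]) < 1e-14))
  # quarter circle: principal eigenvector at the arc midpoint within 1 degree
  ang <- seq(0, pi / 2, length.out = 361L)
  cl <- cbind(10 + 8 * cos(ang), 2 + 8 * sin(ang), rep(2.5, length(ang)))
  arc <- fiberBundlePhantom(grid, cl, bundle_radius = 2, 3, 0.3)
  mid <- c(10 + 8 * cos(pi / 4), 2 + 8 * sin(pi / 4), 2.5)
  idx <- round((mid - c(0, 0, 0)) / 1) + 1L  # origin 0, spacing 1
  lin <- idx[1] + 20 * (idx[2] - 1) + 400 * (idx[3] - 1)
  A <- gbmsim:::tensorRowToMatrix(tensorValues(arc)[lin, ])
  v1 <- eigen(A, symmetric = TRUE)$vectors[, 1]
  tangent <- c(-sin(pi / 4), cos(pi / 4), 0)
  angle <- acos(min(abs(sum(v1 * tangent)), 1)) * 180 / pi
  expect_lt(angle, 1)
  expect_error(fiberBundlePhantom(grid, rbind(c(0, 0, 0), c(0, 0, 0)), 1, 2, 1),
               "degenerate")
})

test_that("voxel fields transfer to mesh cells by barycenter lookup", {
  mesh <- boxMesh(c(10, 10, 10), c(5, 5, 5))
  grid <- phantomGrid(c(5, 5, 5), spacing = 2, origin = c(1, 1, 1))
  # uniform field: every cell identical
  u <- sampleToMesh(isotropicPhantom(grid, 3), mesh)
  expect_true(all(tensorValues(u)[, 1] == 3))
  # two-valued field split at the plane x = 4: brute-force barycenter check
  vals <- tensorValues(isotropicPhantom(grid, 1))
  centers <- gbmsim:::gridVoxelCenters(grid)
  vals[centers[, 1] > 4, 1:3] <- 7
  f2 <- tensorField(vals, grid = grid)
  s2 <- sampleToMesh(f2, mesh)
  bary <- cellBarycenters(mesh)
  expect_equal(unname(tensorValues(s2)[, 1]), ifelse(bary[, 1] > 4, 7, 1))
  # mesh extending outside the grid: fallback + warning
  big <- boxMesh(c(30, 30, 30), c(3, 3, 3), origin = c(-10, -10, -10))
  expect_warning(out <- sampleToMesh(isotropicPhantom(grid, 3), big), "fallback")
  expect_true(any(!tensorMask(out)))
  expect_error(sampleToMesh(isotropicPhantom(grid, 3),
                            new("TumorMesh", vertices = matrix(0, 0, 3),
                                cells = matrix(0L, 0, 4), labels = integer(0),
                                grid = list())),
               "empty mesh")
})

test_that("NIfTI tensor volumes round-trip bit-exactly and validate geometry", {
  grid <- phantomGrid(c(6, 5, 4), spacing = c(2, 2.5, 3), origin = c(1, -2, 0.5))
  vals <- randomSPDComponents(prod(c(6, 5, 4)), seed = 21L)
  f <- tensorField(vals, grid = grid)
  prefix <- file.path(tempdir(), "dti_test")
  paths <- writeTensorVolumes(f, prefix)
  back <- readTensorVolumes(paths)
  expect_identical(unname(tensorValues(back)), unname(tensorValues(f)))
  expect_equal(back@spacing, f@spacing, tolerance = 1e-6)
  expect_equal(back@origin, f@origin, tolerance = 1e-5)
  expect_equal(back@dim, f@dim)
  # constant diagonal volumes assemble d * I
  g2 <- phantomGrid(c(3, 3, 3), spacing = 1)
  p2 <- writeTensorVolumes(isotropicPhantom(g2, 4), file.path(tempdir(), "dti_iso"))
  expect_true(all(tensorValues(readTensorVolumes(p2))[, 1:3] == 4))
  # mismatched shapes are rejected with the offending file named
  p3 <- writeTensorVolumes(isotropicPhantom(phantomGrid(c(4, 3, 3)), 1),
                           file.path(tempdir(), "dti_bad"))
  mixed <- paths
  mixed[["yz"]] <- p3[["yz"]]
  expect_error(readTensorVolumes(mixed), "mismatched")
  expect_error(readTensorVolumes(paths[1:3]), "six")
  unlink(c(paths, p2, p3))
})
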