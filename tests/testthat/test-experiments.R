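smallBase <- function(t_end = 0.4, kind = "axis", model = NULL) {
  if (is.null(model))
    model <- modelParameters(nu_c = 1, S_n = 1e3, delta_n = 1e3, k_n = 100,
                             M = 2000)
  runConfig(
    domain = list(extents = c(16, 16, 16), resolution = c(6, 6, 6)),
    tensors = list(kind = kind, d_n = 86.4, axis = "x"),
    model = model,
    initial = list(center = c(8, 8, 8), sigma_mm = 2),
    solver = solverConfig(dt = 0.1, t_end = t_end, output_every = 100L)
  )
}

test_that("TOML configurations round-trip losslessly", {
  txt <- c("# run configuration",
           "[domain]", 'kind = "box"', "extents = [16.0, 16.0, 16.0]",
           "resolution = [6, 6, 6]",
           "[tensors]", 'kind = "axis"', 'axis = "x"', "d_n = 86.4",
           "[model]", "nu_c = 0.5  # 1/day", "k_n = 1296.0",
           "[solver]", "dt = 0.05", "t_end = 1.5", "no_flux = false",
           "[output]")
  f <- tempfile(fileext = ".toml")
  writeLines(txt, f)
  parsed <- parseTOML(f)
  expect_equal(parsed$model$nu_c, 0.5)
  expect_equal(parsed$model$k_n, 1296)
  expect_identical(parsed$tensors$kind, "axis")
  expect_identical(parsed$solver$no_flux, FALSE)
  expect_equal(parsed$domain$extents, c(16, 16, 16))
  back <- parseTOML(text = writeTOML(parsed))
  expect_equal(back, parsed)
  unlink(f)
})

test_that("run configurations read from TOML and re-serialize stably", {
  cfg <- smallBase()
  f <- tempfile(fileext = ".toml")
  writeRunConfig(cfg, f)
  cfg2 <- readRunConfig(f)
  expect_equal(cfg2@model@nu_c, cfg@model@nu_c)
  expect_equal(cfg2@model@k_n, cfg@model@k_n)
  expect_equal(cfg2@solver@dt, cfg@solver@dt)
  expect_equal(cfg2@domain$extents, cfg@domain$extents)
  expect_identical(cfg2@digest, cfg@digest)  # content digest is reproducible
  unlink(f)
})

test_that("configured runs are deterministic and write a complete manifest", {
  outdir <- file.path(tempdir(), "gbmsim_run_out")
  unlink(outdir, recursive = TRUE)
  cfg <- smallBase()
  cfg@output <- list(dir = outdir, basename = "case")
  cfg@digest <- gbmsim:::configDigest(cfg)
  r1 <- runFromConfig(cfg)
  csv1 <- readLines(file.path(outdir, "case_summary.csv"))
  manifest <- jsonlite::read_json(file.path(outdir, "case_manifest.json"))
  expect_true(file.exists(file.path(outdir, "case_config.toml")))
  expect_true(all(file.exists(unlist(manifest$snapshots))))
  expect_identical(manifest$digest, cfg@digest)
  r2 <- runFromConfig(cfg)
  csv2 <- readLines(file.path(outdir, "case_summary.csv"))
  expect_identical(csv1, csv2)
  expect_identical(finalState(r1$trajectory)@phi, finalState(r2$trajectory)@phi)
  unlink(outdir, recursive = TRUE)
})

test_that("a 1x1 sweep grid reproduces a direct run", {
  base <- smallBase()
  tab <- suppressWarnings(sensitivityMKn(base, 2000, 100))
  expect_equal(nrow(tab), 1L)
  direct <- runFromConfig(base)
  expect_equal(tab$phi_max_ratio, direct$summary$phi_max_ratio, tolerance = 1e-12)
  expect_equal(tab$volume_ratio, direct$summary$volume_ratio, tolerance = 1e-12)
  tab2 <- suppressWarnings(sensitivitySnDeltan(base, 1e3, 1e3))
  expect_equal(tab2$phi_max_ratio, direct$summary$phi_max_ratio, tolerance = 1e-12)
})

test_that("supply-dominated nutrient stays pinned at the physiological level", {
  # delta_n = 0 with large S_n: n/n_s ~ 1 everywhere
  model <- modelParameters(nu_c = 1, S_n = 1e4, delta_n = 0, k_n = 100, M = 2000)
  base <- smallBase(t_end = 0.3, model = model)
  res <- runFromConfig(base)
  expect_gte(res$summary$n_min_rel, 1 - 1e-3)
})

test_that("an isotropic field passed as the anisotropic arm gives a null comparison", {
  base <- smallBase(t_end = 0.3, kind = "isotropic")
  cmp <- compareAnisotropicIsotropic(base)
  expect_equal(cmp$major_axis_anisotropic, cmp$major_axis_isotropic,
               tolerance = 1e-10)
  expect_equal(cmp$volume_difference, 0, tolerance = 1e-10)
  expect_equal(cmp$anisotropic$phi_max_ratio, cmp$isotropic$phi_max_ratio,
               tolerance = 1e-10)
})

test_that("a seed far outside the fiber bundle behaves isotropically", {
  # bundle along x at y = 14, far from the seed at the domain center
  model <- modelParameters(nu_c = 1, S_n = 1e3, delta_n = 1e3, k_n = 100, M = 2000)
  base <- runConfig(
    domain = list(extents = c(16, 16, 16), resolution = c(6, 6, 6)),
    tensors = list(kind = "axis", d_n = 86.4, axis = "x"),
    model = model,
    initial = list(center = c(8, 8, 8), sigma_mm = 2),
    solver = solverConfig(dt = 0.1, t_end = 0.4, output_every = 100L)
  )
  grid <- phantomGrid(c(6, 6, 6), spacing = 16 / 6, origin = rep(16 / 12, 3))
  bundle <- fiberBundlePhantom(grid, rbind(c(-5, 15, 15), c(25, 15, 15)),
                               bundle_radius = 1.5, 86.4, 8.64)
  cmp <- compareAnisotropicIsotropic(base, tensor_field = bundle)
  # outside the bundle the phantom is isotropic at the eigenvalue mean, so the
  # shape ratios match the isotropic control closely
  rat <- function(s) s$final@delta_x / s$final@delta_y
  expect_gt(rat(cmp$anisotropic) / rat(cmp$isotropic), 0.95)
  expect_lt(rat(cmp$anisotropic) / rat(cmp$isotropic), 1.05)
})

test_that("the CLI dispatcher runs configs and writes phantoms", {
  f <- tempfile(fileext = ".toml")
  writeRunConfig(smallBase(t_end = 0.2), f)
  out <- capture.output(status <- gbmsimMain(c("run", "-c", f)))
  expect_true(any(grepl("final tumor", out)))
  prefix <- file.path(tempdir(), "cli_phantom")
  out2 <- capture.output(gbmsimMain(c("phantom", "--kind", "axis", "--dim", "4",
                                      "--spacing", "2", "-o", prefix)))
  expect_true(file.exists(paste0(prefix, "_xx.nii.gz")))
  f2 <- readTensorVolumes(setNames(sprintf("%s_%s.nii.gz", prefix,
                                           c("xx", "yy", "zz", "xy", "xz", "yz")),
                                   c("xx", "yy", "zz", "xy", "xz", "yz")))
  expect_equal(unname(tensorValues(f2)[1, ]), c(86.4, 0, 0, 0, 0, 0))
  unlink(c(f, sprintf("%s_%s.nii.gz", prefix, c("xx","yy","zz","xy","xz","yz"))))
})
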