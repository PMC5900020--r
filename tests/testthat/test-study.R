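test_that("the panel enumerates exactly the twelve representations", {
  cfgs <- enumerate_configurations()
  expect_length(cfgs, 12L)
  first <- cfgs[[1L]]
  expect_equal(first$apd_variant, "normal")
  expect_equal(first$conductivity_mode, "normal_anisotropic")
  expect_equal(first$bz_fiber_mode, "horizontal")
  labels <- vapply(cfgs, bzep:::config_label, "")
  expect_length(unique(labels), 12L)
  apds <- vapply(cfgs, function(cf) cf$apd_variant, "")
  expect_equal(unname(table(apds)[c("normal", "longer", "shorter")]),
               rep(4L, 3L), ignore_attr = TRUE)
})

test_that("invalid conductivity/fiber pairings are rejected", {
  expect_error(bz_configuration("normal", "normal_anisotropic", "random"),
               "random fibers")
  expect_error(bz_configuration("normal", "decreased_isotropic", "random"),
               "random fibers")
  expect_silent(bz_configuration("shorter", "decreased_transverse", "random"))
})

test_that("border-zone properties follow the configured representation", {
  mesh <- suite_mesh02()
  bz <- mesh$region == "border_zone"
  p <- apply_bz_properties(mesh, bz_configuration("shorter",
                                                  "decreased_transverse",
                                                  "horizontal"))
  expect_true(all(p$conductivity$sigma_t[bz] == 0.0069))
  expect_true(all(p$conductivity$sigma_l[bz] == 0.1890))
  expect_true(all(p$conductivity$sigma_l[!bz] == 0.1890))
  expect_true(all(p$conductivity$sigma_t[!bz] == 0.0690))
  expect_equal(p$cell$border_zone$gks_scale, 2.0)
  p2 <- apply_bz_properties(mesh, bz_configuration("longer",
                                                   "decreased_isotropic",
                                                   "horizontal"))
  expect_true(all(p2$conductivity$sigma_l[bz] == 0.0689))
  expect_true(all(p2$conductivity$sigma_t[bz] == 0.0689))
  expect_equal(p2$cell$border_zone$gks_scale, 0.5)
  # normal APD: membrane parameters identical in both regions
  p3 <- apply_bz_properties(mesh, bz_configuration("normal",
                                                   "normal_anisotropic",
                                                   "horizontal"))
  expect_true(all(p3$gks_node == 1))
})

test_that("the smooth conductivity transition ramps linearly inward", {
  mesh <- suite_mesh02()
  cfg <- bz_configuration("normal", "decreased_transverse", "horizontal")
  abrupt <- apply_bz_properties(mesh, cfg)$conductivity
  # zero width is the abrupt field
  expect_identical(apply_smooth_transition(abrupt, mesh, 0), abrupt)
  ramped <- apply_smooth_transition(abrupt, mesh, 2)
  cc <- element_centroids(mesh)
  r <- sqrt((cc[, 1L] - 15)^2 + (cc[, 2L] - 15)^2)
  mid <- which.min(abs(r - 6))          # radial midpoint of the full-BZ ramp
  expected_mid <- (0.0690 + 0.0069) / 2
  tol <- (0.0690 - 0.0069) * mesh$h / 2 * 1.5
  expect_lt(abs(ramped$sigma_t[mid] - expected_mid), tol)
  # monotone within the ramp, continuous at the interface
  inner <- which(r > 5 & r <= 5.2)
  outer <- which(r > 6.8 & r <= 7)
  expect_lt(max(ramped$sigma_t[inner]), min(ramped$sigma_t[outer]))
  expect_error(apply_smooth_transition(abrupt, mesh, 3), "exceeds")
})

test_that("cell-state caching in the study reproduces uncached pacing", {
  a <- pace_to_steady_state(make_variant("shorter_apd"), 500, 5)
  b <- pace_to_steady_state(make_variant("shorter_apd"), 500, 5)
  expect_identical(unclass(a), unclass(b))
})

test_that("a tiny study run is deterministic and seed-isolated", {
  cfg_h <- bz_configuration("normal", "normal_anisotropic", "horizontal",
                            random_seed = 1L, resolution = 0.45)
  cfg_h99 <- cfg_h
  cfg_h99$random_seed <- 99L
  tis <- tissue_params(n_beats = 1, dt = 0.025, stimulus_amplitude = 80,
                       cycle_length = 400)
  s1 <- run_study(list(cfg_h), tissue = tis, cell_n_beats = 3,
                  progress = FALSE)
  s2 <- run_study(list(cfg_h99), tissue = tis, cell_n_beats = 3,
                  progress = FALSE)
  # the wave must actually propagate for the comparison to mean anything
  expect_true(mean(is.finite(s1$results[[1L]]$at$values)) > 0.95)
  # horizontal fibers: the seed must not matter, bitwise
  expect_identical(s1$results[[1L]]$at$values, s2$results[[1L]]$at$values)
  cfg_r <- bz_configuration("normal", "decreased_transverse", "random",
                            random_seed = 1L, resolution = 0.45)
  r1 <- run_study(list(cfg_r), tissue = tis, cell_n_beats = 3,
                  progress = FALSE)
  r1b <- run_study(list(cfg_r), tissue = tis, cell_n_beats = 3,
                   progress = FALSE)
  expect_identical(r1$results[[1L]]$at$values, r1b$results[[1L]]$at$values)
})

test_that("per-configuration failures are collected, not fatal", {
  good <- bz_configuration("normal", "normal_anisotropic", "horizontal",
                           resolution = 0.45)
  bad <- good
  bad$resolution <- 5          # too coarse to resolve the BZ
  st <- run_study(list(good, bad),
                  tissue = tissue_params(n_beats = 1, dt = 0.025,
                                         cycle_length = 400,
                                         stimulus_amplitude = 80),
                  cell_n_beats = 3, progress = FALSE)
  expect_length(st$failures, 1L)
  expect_match(st$results[[st$failures]]$error, "coarse")
  expect_false(inherits(st$results[[1L]], "bz_study_failure"))
})

test_that("study outputs and config files round-trip on disk", {
  dir <- withr::local_tempdir()
  cfg <- bz_configuration("normal", "normal_anisotropic", "horizontal",
                          resolution = 0.45)
  st <- run_study(list(cfg),
                  tissue = tissue_params(n_beats = 1, dt = 0.025,
                                         cycle_length = 400,
                                         stimulus_amplitude = 80),
                  cell_n_beats = 3, output_dir = dir, progress = FALSE)
  files <- list.files(dir)
  expect_true(any(grepl("\\.vtk$", files)))
  expect_true("summary.csv" %in% files)
  expect_true("run_log.txt" %in% files)
  smry <- read.csv(file.path(dir, "summary.csv"))
  expect_true(all(c("configuration", "region", "max_gradient") %in%
                    names(smry)))
  vtk <- readLines(list.files(dir, "\\.vtk$", full.names = TRUE)[1L])
  expect_identical(vtk[1L], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINT_DATA", vtk)))
  # mesh text pair
  mesh <- quiet_sheet()
  np <- file.path(dir, "nodes.txt"); ep <- file.path(dir, "elems.txt")
  write_mesh_text(mesh, np, ep)
  expect_identical(length(readLines(np)), nrow(mesh$nodes))
  expect_identical(length(readLines(ep)), nrow(mesh$elements))
  # run-config JSON round trip
  skip_if_not_installed("jsonlite")
  cfgpath <- file.path(dir, "run.json")
  write_run_config(cfgpath, geometry_config(resolution = 0.3),
                   tissue_params(dt = 0.025))
  rc <- read_run_config(cfgpath)
  expect_equal(rc$geometry$resolution, 0.3)
  expect_equal(rc$tissue$dt, 0.025)
  expect_equal(rc$tissue$cycle_length, 500)
})
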