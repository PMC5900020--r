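test_that("an unstimulated sheet stays at rest", {
  mesh <- quiet_sheet()
  tis <- tissue_params(n_beats = 1, cycle_length = 500,
                       stimulus_amplitude = 0)
  rec <- run_simulation(mesh, conductivity_field(mesh, 0.1890, 0.0690), tis,
                        cell_params(), steady_state("control"))
  v0 <- unclass(steady_state("control"))[["V"]]
  expect_lt(max(abs(rec$V - v0)), 1)
  expect_true(all(is.na(rec$AT)))
})

test_that("a uniformly stimulated pair of triangles reproduces the 0D trace", {
  g <- bzep:::structured_tri_grid(1, 1, 1, 1)
  mesh <- structure(list(nodes = g$nodes, elements = g$elements,
                         region = rep("healthy", 2L),
                         fiber_angle = c(0, 0),
                         stim_nodes = 1:4, h = 1,
                         config = list(sheet_size = c(1, 1),
                                       scar_diameter = 0, bz_thickness = 0,
                                       resolution = 1,
                                       bz_fiber_mode = "horizontal",
                                       random_seed = 0L)),
                    class = "bz_mesh")
  expect_equal(nrow(mesh$elements), 2L)
  st <- steady_state("control")
  amp <- attr(st, "stimulus_amplitude")
  tis <- tissue_params(n_beats = 1, cycle_length = 500,
                       stimulus_amplitude = amp, sample_dt = 0.5,
                       cg_tol = 1e-10)
  rec <- run_simulation(mesh, conductivity_field(mesh, 0.189, 0.069), tis,
                        cell_params(), st)
  cell <- bzep:::cpp_cell_pace(unclass(st), 1, tis$dt, 500, 1L, amp, 2, 0.5, 1L)
  # all nodes identical (uniform problem) up to the diffusion-solve tolerance
  expect_lt(max(apply(rec$V, 2, function(col) diff(range(col)))), 1e-6)
  # ... and equal to the single-cell trace within the lookup-table error,
  # outside the steep upstroke (where a ~0.01 ms table-induced timing shift
  # is amplified by the ~300 mV/ms slope)
  common <- seq_len(min(ncol(rec$V), length(cell$V)))
  dv <- rec$V[1L, common] - cell$V[common]
  steep <- abs(c(0, diff(cell$V[common]))) > 2.5  # > 5 mV/ms at 0.5 ms sampling
  expect_lt(max(abs(dv[!steep])), 1)
  # upstroke timing itself agrees to a small fraction of a millisecond
  t_up_2d <- rec$time[which(rec$V[1L, ] >= -20)[1L]]
  t_up_0d <- cell$time[which(cell$V >= -20)[1L]]
  expect_lt(abs(t_up_2d - t_up_0d), 0.51)
})

test_that("activation respects the mirror symmetry of a symmetric sheet", {
  mesh <- bz_cached("sym_sheet",
                    build_mesh(geometry_config(sheet_size = 10,
                                               scar_diameter = 4,
                                               bz_thickness = 1,
                                               resolution = 0.35)))
  tis <- tissue_params(n_beats = 1, cycle_length = 120,
                       stimulus_amplitude = 80)
  rec <- run_simulation(mesh, conductivity_field(mesh, 0.1890, 0.0690), tis,
                        cell_params(), steady_state("control"),
                        stop_margin = 2)
  at <- rec$AT[, 1L]
  mir <- mirror_index(mesh)
  expect_lt(max(abs(at - at[mir]), na.rm = TRUE), 0.5)
})

test_that("repeated runs of a deterministic configuration are identical", {
  mesh <- quiet_sheet()
  tis <- tissue_params(n_beats = 1, cycle_length = 100,
                       stimulus_amplitude = 80)
  r1 <- run_simulation(mesh, conductivity_field(mesh, 0.19, 0.07), tis,
                       cell_params(), steady_state("control"))
  r2 <- run_simulation(mesh, conductivity_field(mesh, 0.19, 0.07), tis,
                       cell_params(), steady_state("control"))
  expect_identical(r1$AT, r2$AT)
  expect_identical(r1$V, r2$V)
})

test_that("gross instability aborts with a located diagnostic", {
  mesh <- quiet_sheet()
  tis <- tissue_params(n_beats = 1, cycle_length = 50, dt = 5, sample_dt = 5,
                       stimulus_amplitude = 5000, stimulus_duration = 10)
  expect_error(run_simulation(mesh, conductivity_field(mesh, 0.19, 0.07), tis,
                              cell_params(), steady_state("control")),
               "instability")
})

test_that("longitudinal conduction velocity converges under mesh refinement", {
  cv_fine <- strip_cv(0.1890, 0.0690, "longitudinal", resolution = 0.05)
  cv_finer <- strip_cv(0.1890, 0.0690, "longitudinal", resolution = 0.025)
  expect_lt(abs(cv_fine$velocity - cv_finer$velocity) / cv_finer$velocity,
            0.03)
})
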