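synthetic_record <- function() {
  # three nodes: clean AP, never-activating, early-dip-then-AP
  tm <- seq(0, 400, by = 1)
  ap <- function(t_up, t_down) {
    v <- rep(-85, length(tm))
    v[tm >= t_up & tm < t_down] <- 20
    v
  }
  V <- rbind(ap(10, 310),          # crossings at 9.x and 309.x
             rep(-85, length(tm)), # masked
             ap(50, 150))
  dip <- which(tm >= 20 & tm <= 30)
  V[3L, dip] <- -100               # sub-threshold dip before activation
  structure(list(V = V, time = tm, AT = matrix(NA_real_, 3, 1)),
            class = "bz_voltage_record")
}

test_that("threshold crossings are interpolated, masked and ordered", {
  rec <- synthetic_record()
  at <- activation_times(rec, threshold = -20)
  # V jumps -85 -> 20 between t=9 and t=10; -20 crossed at 9 + 65/105
  expect_equal(at$values[1L], 9 + 65 / 105, tolerance = 1e-9)
  expect_true(is.na(at$values[2L]))
  rt <- repolarization_times(rec, threshold = -70)
  expect_equal(rt$values[1L], 309 + 90 / 105, tolerance = 1e-9)
  expect_true(is.na(rt$values[2L]))
  # node 3: the early dip below -70 precedes activation and must not count
  expect_gt(rt$values[3L], at$values[3L])
  expect_gt(rt$values[3L], 149)
})

test_that("a spatially uniform record yields a constant map", {
  rec <- synthetic_record()
  rec$V <- rec$V[c(1L, 1L, 1L), ]
  rt <- repolarization_times(rec)
  expect_equal(max(rt$values) - min(rt$values), 0)
})

test_that("the gradient operator is exact on linear fields and zero on constants", {
  mesh <- quiet_sheet()
  g0 <- repolarization_gradient(mesh, rep(5, nrow(mesh$nodes)))
  expect_lt(max(abs(g0$values)), 1e-10)
  g3 <- repolarization_gradient(mesh, 3 * mesh$nodes[, 1L])
  expect_equal(unname(g3$values), rep(3, nrow(mesh$nodes)), tolerance = 1e-9)
  gxy <- repolarization_gradient(mesh,
                                 3 * mesh$nodes[, 1L] + 4 * mesh$nodes[, 2L])
  expect_equal(unname(gxy$values), rep(5, nrow(mesh$nodes)), tolerance = 1e-9)
})

test_that("masking propagates from nodes to incident elements only", {
  mesh <- quiet_sheet()
  v <- 3 * mesh$nodes[, 1L]
  masked_node <- which.min(rowSums((mesh$nodes - 4)^2))
  v[masked_node] <- NA
  g <- repolarization_gradient(mesh, v)
  el <- mesh$elements
  touches <- el[, 1L] == masked_node | el[, 2L] == masked_node |
    el[, 3L] == masked_node
  expect_true(all(is.na(g$element_values[touches])))
  expect_true(all(is.finite(g$element_values[!touches])))
  expect_true(is.na(g$values[masked_node]))
  far <- which(abs(mesh$nodes[, 1L] - mesh$nodes[masked_node, 1L]) > 1)
  expect_true(all(abs(g$values[far] - 3) < 1e-9))
})

test_that("gradient exceedance areas are exact on a constructed field", {
  mesh <- quiet_sheet()
  A <- element_areas(mesh)
  gmag <- rep(0, nrow(mesh$elements))
  picked <- cumsum(A) <= 10
  gmag[picked] <- 6
  g <- bzep:::new_node_map(rep(0, nrow(mesh$nodes)), "gradient", "ms/mm",
                           element_values = gmag)
  expect_warning(gs <- gradient_summary(g, mesh, thresholds = c(3.2, 5)),
                 "empty")
  glob <- gs[gs$region == "global", ]
  expect_equal(glob$area_gt_3.2, sum(A[picked]), tolerance = 1e-9)
  expect_equal(glob$area_gt_5, sum(A[picked]), tolerance = 1e-9)
  expect_equal(glob$max_gradient, 6)
  # empty-region fallback warns and returns zeros
  expect_warning(gs0 <- gradient_summary(g, mesh, thresholds = 3.2),
                 "empty")
  expect_equal(gs0[gs0$region == "border_zone", "area_gt_3.2"], 0)
})

test_that("exceedance area is non-increasing in the threshold", {
  mesh <- quiet_sheet()
  set.seed(11)
  gmag <- rexp(nrow(mesh$elements), rate = 0.5)
  g <- bzep:::new_node_map(rep(0, nrow(mesh$nodes)), "gradient", "ms/mm",
                           element_values = gmag)
  expect_warning(gs <- gradient_summary(g, mesh, thresholds = c(1, 2, 4, 8)),
                 "empty")
  glob <- gs[gs$region == "global", ]
  areas <- unlist(glob[grep("^area_gt_", names(glob))])
  expect_true(all(diff(areas) <= 0))
})

test_that("tissue repolarization minus activation matches the cellular APD", {
  mesh <- bzep:::strip_mesh(length = 1, width = 1, resolution = 1.2)
  mesh$stim_nodes <- seq_len(nrow(mesh$nodes))
  st <- steady_state("control")
  amp <- attr(st, "stimulus_amplitude")
  tis <- tissue_params(n_beats = 1, cycle_length = 500,
                       stimulus_amplitude = amp, sample_dt = 0.5)
  rec <- run_simulation(mesh, conductivity_field(mesh, 0.189, 0.069), tis,
                        cell_params(), st)
  at <- activation_times(rec)$values
  rt <- repolarization_times(rec)$values
  apd70 <- measure_apd(bz_cached("ap_control",
                                 simulate_ap(cell_params(), st, 500, 1)),
                       threshold = -70)
  expect_lt(abs((rt[1L] - at[1L]) - apd70), 15)
})
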