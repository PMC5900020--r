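test_that("study variants scale gKs as specified", {
  expect_equal(make_variant("control")$gks_scale, 1.0)
  expect_equal(make_variant("longer_apd")$gks_scale, 0.5)
  expect_equal(make_variant("shorter_apd")$gks_scale, 2.0)
  expect_error(make_variant("weird"), "arg")
  expect_error(cell_params(gks_scale = -1))
})

test_that("a relaxed resting state is a fixed point of the integrator", {
  s0 <- cell_initial_state()
  relaxed <- bzep:::cpp_cell_run(unclass(s0), 1, 0.02, 2000, 0, 0, 100)$state
  for (dt in c(0.005, 0.02)) {
    s1 <- step_cell(structure(relaxed, class = "bz_cell_state"), dt,
                    cell_params(), I_stim = 0)
    expect_lt(max(abs(unclass(s1) - relaxed) /
                    pmax(abs(relaxed), 1e-4)), 1e-6)
  }
})

test_that("a threshold stimulus elicits an action potential with overshoot", {
  p <- cell_params()
  th <- bz_cached("cell_threshold", find_threshold(p))
  expect_gt(th, 0)
  tr <- simulate_ap(p, state = cell_initial_state(), cycle_length = 400,
                    n_beats = 1)
  expect_gt(max(tr$V), 10)
  # resting potential in the physiological range for control parameters
  expect_gt(tr$V[1L], -90)
  expect_lt(tr$V[1L], -80)
})

test_that("pacing failure is reported with the failing beat", {
  p <- cell_params(stimulus_amplitude = 0.05)
  expect_error(pace_to_steady_state(p, 500, 2), "beat 1")
})

test_that("zero pre-pacing beats returns the published initial conditions", {
  expect_equal(unclass(pace_to_steady_state(n_beats = 0)),
               unclass(cell_initial_state()))
})

test_that("paced steady state is periodic with bounded gates", {
  st <- steady_state("control")
  tr <- simulate_ap(cell_params(), st, 500, n_beats = 2, record_beats = 2,
                    sample_dt = 0.5)
  b1 <- tr$V[tr$time < 500]
  b2 <- tr$V[tr$time >= 500 & tr$time < 1000]
  expect_lt(max(abs(b1 - b2)), 1)
  for (kind in c("control", "longer_apd", "shorter_apd")) {
    s <- unclass(steady_state(kind))
    gates <- s[c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                 "xr1", "xr2", "xs", "Rbar")]
    expect_true(all(gates >= 0 & gates <= 1))
    conc <- s[c("K_i", "Na_i", "Ca_i", "Ca_ss", "Ca_sr")]
    expect_true(all(conc > 0))
  }
})

test_that("beat-to-beat APD change is below 1 ms after 100 beats", {
  st99 <- bz_cached("steady_control_99",
                    pace_to_steady_state(cell_params(), 500, 99))
  tr99 <- simulate_ap(cell_params(), st99, 500, 1)
  tr100 <- simulate_ap(cell_params(), steady_state("control"), 500, 1)
  expect_lt(abs(measure_apd(tr99) - measure_apd(tr100)), 1)
})

test_that("APD is strictly decreasing in the gKs multiplier", {
  apds <- vapply(c("longer_apd", "control", "shorter_apd"), function(k) {
    measure_apd(bz_cached(paste0("ap_", k),
                          simulate_ap(make_variant(k), steady_state(k), 500, 1)))
  }, 0)
  expect_true(apds[["longer_apd"]] > apds[["control"]])
  expect_true(apds[["control"]] > apds[["shorter_apd"]])
})

test_that("APD measurement handles a rectangular pulse exactly", {
  tr <- list(time = c(0, 0.5, 200, 200.5, 300),
             V = c(-85, 20, 20, -85, -85))
  expect_lt(abs(measure_apd(tr, 0.9) - 200), 0.51)
  expect_error(measure_apd(list(time = c(0, 0.5, 100), V = c(-85, 20, 20))),
               "incomplete repolarization")
})

test_that("earlier repolarization fractions give shorter APDs", {
  tr <- bz_cached("ap_control",
                  simulate_ap(cell_params(), steady_state("control"), 500, 1))
  expect_lt(measure_apd(tr, 0.5), measure_apd(tr, 0.9))
  # the -70 mV convention agrees with APD90 to within a few ms here
  expect_lt(abs(measure_apd(tr, threshold = -70) - measure_apd(tr, 0.9)), 5)
})

test_that("halving dt leaves the trace and APD essentially unchanged", {
  st <- steady_state("control")
  amp <- attr(st, "stimulus_amplitude")
  tr1 <- bzep:::cpp_cell_pace(unclass(st), 1, 0.02, 500, 1L, amp, 2, 0.5, 1L)
  tr2 <- bzep:::cpp_cell_pace(unclass(st), 1, 0.01, 500, 1L, amp, 2, 0.5, 1L)
  expect_lt(max(abs(tr1$V - tr2$V)), 1)
  apd1 <- measure_apd(list(time = tr1$time, V = tr1$V))
  apd2 <- measure_apd(list(time = tr2$time, V = tr2$V))
  expect_lt(abs(apd1 - apd2), 0.5)
})

test_that("non-finite states abort with the offending variable named", {
  s <- cell_initial_state()
  s[["Na_i"]] <- NaN
  expect_error(step_cell(s, 0.02), "Na_i")
})

test_that("steady-state snapshots round-trip through plain text", {
  st <- steady_state("longer_apd")
  path <- withr::local_tempfile(fileext = ".txt")
  write_state_snapshot(st, path)
  st2 <- read_state_snapshot(path)
  expect_equal(unname(unclass(st2)), unname(as.numeric(st)), tolerance = 1e-15)
  expect_identical(names(st2), names(unclass(st)))
  expect_true(any(grepl("gks_scale: 0.5", readLines(path))))
})
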