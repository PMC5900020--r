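#' Membrane-model parameter set
#'
#' Parameters of the ten Tusscher-Panfilov (2006, epicardial) human
#' ventricular membrane model as used here: everything is held at its
#' published value except the slow delayed-rectifier conductance
#' \eqn{g_{Ks}}, which is scaled by \code{gks_scale}.  Halving
#' \eqn{g_{Ks}} prolongs the action potential, doubling it shortens it.
#'
#' @param gks_scale positive multiplier on \eqn{g_{Ks}} (dimensionless).
#' @param Cm membrane capacitance per unit area (uF/cm^2).
#' @param stimulus_amplitude depolarizing transmembrane current density
#'   (uA/cm^2) used when pacing a single cell; \code{NULL} means
#'   "twice the diastolic threshold", found by bisection when first needed.
#' @param stimulus_duration stimulus duration (ms).
#' @param variant label carried along in outputs.
#' @return An object of class \code{bz_cell_params}.
#' @seealso [make_variant()] for the three study variants.
#' @export
cell_params <- function(gks_scale = 1, Cm = 1, stimulus_amplitude = NULL,
                        stimulus_duration = 2, variant = "control") {
  stopifnot(is.numeric(gks_scale), length(gks_scale) == 1L, gks_scale > 0,
            is.numeric(Cm), length(Cm) == 1L, Cm > 0,
            is.numeric(stimulus_duration), stimulus_duration > 0)
  if (!is.null(stimulus_amplitude))
    stopifnot(is.numeric(stimulus_amplitude), stimulus_amplitude > 0)
  structure(list(gks_scale = gks_scale, Cm = Cm,
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_duration = stimulus_duration,
                 model = "ten Tusscher-Panfilov 2006, epicardial",
                 variant = variant),
            class = "bz_cell_params")
}

#' @export
print.bz_cell_params <- function(x, ...) {
  cat("Ventricular membrane parameters (", x$model, ")\n", sep = "")
  cat("  variant:", x$variant, "  gKs scale:", x$gks_scale, "\n")
  cat("  Cm:", x$Cm, "uF/cm^2;  stimulus:",
      if (is.null(x$stimulus_amplitude)) "2x diastolic threshold"
      else paste(x$stimulus_amplitude, "uA/cm^2"),
      "for", x$stimulus_duration, "ms\n")
  invisible(x)
}

#' Border-zone action-potential variants
#'
#' The three membrane variants used throughout the study: \code{control}
#' (unmodified), \code{longer_apd} (\eqn{g_{Ks}} at 50\% of control) and
#' \code{shorter_apd} (\eqn{g_{Ks}} at 200\% of control).
#'
#' @param kind one of \code{"control"}, \code{"longer_apd"},
#'   \code{"shorter_apd"}.
#' @param ... passed on to [cell_params()].
#' @return A \code{bz_cell_params} object.
#' @examples
#' make_variant("longer_apd")$gks_scale  # 0.5
#' @export
make_variant <- function(kind = c("control", "longer_apd", "shorter_apd"), ...) {
  kind <- match.arg(kind)
  scale <- switch(kind, control = 1.0, longer_apd = 0.5, shorter_apd = 2.0)
  cell_params(gks_scale = scale, variant = kind, ...)
}

#' Published resting initial conditions of the membrane model
#'
#' @return Named numeric vector of the 19 state variables (class
#'   \code{bz_cell_state}): membrane potential \code{V} (mV), intracellular
#'   concentrations (mM) and Hodgkin-Huxley gates.
#' @export
cell_initial_state <- function() {
  structure(cpp_cell_init(), class = "bz_cell_state")
}

#' @export
print.bz_cell_state <- function(x, ...) {
  cat("Membrane state: V =", round(unclass(x)[["V"]], 2), "mV,",
      "[Na]_i =", round(unclass(x)[["Na_i"]], 3), "mM,",
      "[K]_i =", round(unclass(x)[["K_i"]], 2), "mM,",
      "[Ca]_i =", signif(unclass(x)[["Ca_i"]], 3), "mM\n")
  invisible(x)
}

#' Advance a single cell by one time step
#'
#' One step of the 0D membrane model: Rush-Larsen exponential update for the
#' gating variables, forward Euler for concentrations and voltage.
#'
#' @param state a \code{bz_cell_state} vector.
#' @param dt time step (ms).
#' @param params a \code{bz_cell_params} object.
#' @param I_stim depolarizing transmembrane current density (uA/cm^2).
#' @return The advanced \code{bz_cell_state}.
#' @export
step_cell <- function(state, dt, params = cell_params(), I_stim = 0) {
  stopifnot(inherits(params, "bz_cell_params"), is.numeric(dt), dt > 0)
  structure(cpp_cell_step(unclass(state), dt, params$gks_scale, I_stim / params$Cm),
            class = "bz_cell_state")
}

#' Diastolic stimulus threshold of a resting cell
#'
#' Finds, by bisection, the smallest rectangular-pulse amplitude that
#' elicits an action potential (an upward crossing of -20 mV within 50 ms)
#' from the supplied resting state.
#'
#' @param params a \code{bz_cell_params} object.
#' @param state resting state to stimulate from.
#' @param dt integration step (ms).
#' @param tol relative bisection tolerance.
#' @return Threshold amplitude (uA/cm^2).
#' @export
find_threshold <- function(params = cell_params(), state = cell_initial_state(),
                           dt = 0.02, tol = 0.02) {
  excites <- function(amp) {
    tr <- cpp_cell_run(unclass(state), params$gks_scale, dt, 50,
                       amp / params$Cm, params$stimulus_duration, 0.5)
    any(tr$V > -20)
  }
  lo <- 0; hi <- 8
  while (!excites(hi)) {
    hi <- hi * 2
    if (hi > 2048) stop("cell inexcitable: no capture up to 2048 uA/cm^2")
  }
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Resolve the pacing stimulus amplitude: explicit value, or 2x threshold.
resolve_stim <- function(params, state, dt) {
  if (!is.null(params$stimulus_amplitude)) return(params$stimulus_amplitude)
  2 * find_threshold(params, state, dt)
}

#' Pace a single cell to steady state
#'
#' Applies `n_beats` stimuli at a fixed cycle length and returns the
#' end-diastolic state, which seeds every node of a tissue simulation.
#' Fails if any paced cycle fails to elicit an action potential.
#'
#' @param params a \code{bz_cell_params} object.
#' @param cycle_length pacing cycle length (ms).
#' @param n_beats number of paced beats; 0 returns the published initial
#'   conditions unchanged.
#' @param dt integration step (ms).
#' @return A \code{bz_cell_state} with attributes \code{cycle_length},
#'   \code{n_beats} and \code{params}.
#' @export
pace_to_steady_state <- function(params = cell_params(), cycle_length = 500,
                                 n_beats = 100, dt = 0.02) {
  stopifnot(inherits(params, "bz_cell_params"), cycle_length > 0, n_beats >= 0)
  state <- cell_initial_state()
  if (n_beats == 0) return(state)
  amp <- resolve_stim(params, state, dt)
  res <- cpp_cell_pace(unclass(state), params$gks_scale, dt, cycle_length,
                       as.integer(n_beats), amp / params$Cm,
                       params$stimulus_duration, 1, 0L)
  if (any(res$captured == 0)) {
    stop("failure to capture 1:1: no action potential on beat ",
         which(res$captured == 0)[1])
  }
  structure(res$state, class = "bz_cell_state", cycle_length = cycle_length,
            n_beats = n_beats, params = params, stimulus_amplitude = amp)
}

#' Simulate a paced action-potential trace
#'
#' Paces a cell from `state` and records the membrane potential of the
#' last `record_beats` cycles.
#'
#' @param params a \code{bz_cell_params} object.
#' @param state starting state (typically from [pace_to_steady_state()]).
#' @param cycle_length pacing cycle length (ms).
#' @param n_beats beats to simulate.
#' @param record_beats how many final beats to record.
#' @param dt integration step (ms).
#' @param sample_dt trace sampling interval (ms).
#' @return An action-potential trace, class \code{bz_ap_trace}: a list with
#'   \code{time} (ms), \code{V} (mV), \code{cycle_length} and the final
#'   \code{state}.
#' @export
simulate_ap <- function(params = cell_params(),
                        state = pace_to_steady_state(params),
                        cycle_length = 500, n_beats = 1, record_beats = n_beats,
                        dt = 0.02, sample_dt = 0.1) {
  amp <- attr(state, "stimulus_amplitude")
  if (is.null(amp)) amp <- resolve_stim(params, state, dt)
  res <- cpp_cell_pace(unclass(state), params$gks_scale, dt, cycle_length,
                       as.integer(n_beats), amp / params$Cm,
                       params$stimulus_duration, sample_dt,
                       as.integer(record_beats))
  if (any(res$captured == 0))
    stop("failure to capture 1:1: no action potential on beat ",
         which(res$captured == 0)[1])
  structure(list(time = res$time, V = res$V, cycle_length = cycle_length,
                 state = structure(res$state, class = "bz_cell_state"),
                 params = params),
            class = "bz_ap_trace")
}

#' @export
print.bz_ap_trace <- function(x, ...) {
  cat("Action-potential trace:", length(x$time), "samples over",
      round(max(x$time)), "ms (CL", x$cycle_length, "ms);",
      "V in [", round(min(x$V), 1), ",", round(max(x$V), 1), "] mV\n")
  invisible(x)
}

#' @export
plot.bz_ap_trace <- function(x, ...) {
  graphics::plot(x$time, x$V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  invisible(x)
}

#' Measure action-potential duration
#'
#' APD measured from the instant of maximum upstroke velocity to the
#' downward crossing of either a repolarization fraction of the amplitude
#' (e.g. APD90: \eqn{V_{peak} - 0.9 (V_{peak} - V_{rest})}) or, if
#' \code{threshold} is given, an absolute voltage (e.g. -70 mV, the tissue
#' repolarization threshold).  Crossings are linearly interpolated between
#' samples.  If the trace holds several beats, the last complete beat is
#' measured.
#'
#' @param trace a \code{bz_ap_trace}, or any list with \code{time} and
#'   \code{V} components.
#' @param repolarization_fraction fraction of the amplitude that must be
#'   lost (in (0,1); 0.9 gives APD90).
#' @param threshold absolute repolarization threshold (mV); overrides
#'   \code{repolarization_fraction} when non-NULL.
#' @return APD in ms.
#' @export
measure_apd <- function(trace, repolarization_fraction = 0.9, threshold = NULL) {
  tm <- trace$time; V <- trace$V
  stopifnot(length(tm) == length(V), length(tm) > 2, !is.unsorted(tm))
  if (is.null(threshold))
    stopifnot(repolarization_fraction > 0, repolarization_fraction < 1)
  # restrict to the last complete beat if the trace holds several
  cl <- trace$cycle_length
  if (!is.null(cl) && max(tm) > cl * 1.5) {
    k0 <- max(tm) - cl
    keep <- tm >= k0 - 1e-9
    tm <- tm[keep] - k0
    V <- V[keep]
  }
  dv <- diff(V) / diff(tm)
  iup <- which.max(dv)
  t_up <- tm[iup + 1L]
  v_rest <- V[1L]
  ipk <- which.max(V)
  v_peak <- V[ipk]
  if (v_peak < -20) stop("trace contains no action potential upstroke")
  v_level <- if (is.null(threshold))
    v_peak - repolarization_fraction * (v_peak - v_rest) else threshold
  after <- seq_along(V) > ipk
  below <- after & V <= v_level
  if (!any(below)) stop("incomplete repolarization: no crossing of ",
                        round(v_level, 2), " mV before trace end")
  i2 <- which(below)[1L]
  i1 <- i2 - 1L
  t_cross <- tm[i1] + (tm[i2] - tm[i1]) * (V[i1] - v_level) / (V[i1] - V[i2])
  t_cross - t_up
}
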