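#' Tissue-level simulation parameters
#'
#' @param beta surface-to-volume ratio (1/um).
#' @param Cm membrane capacitance per unit area (uF/cm^2).
#' @param dt integration step (ms).
#' @param sample_dt output sampling interval of the voltage record (ms).
#' @param stimulus_amplitude transmembrane stimulus current density
#'   (uA/cm^2); \code{NULL} means twice the tissue diastolic threshold,
#'   found by bisection when the simulation is set up.
#' @param stimulus_duration stimulus duration (ms).
#' @param cycle_length pacing cycle length (ms).
#' @param n_beats number of paced beats (maps are taken from the last).
#' @param record_from_beat first beat (1-based) captured in the voltage
#'   record; defaults to the final beat.
#' @param rev_update_every steps between refreshes of the reversal
#'   potentials (they drift with the slow intracellular concentrations).
#' @param cg_tol relative residual tolerance of the conjugate-gradient
#'   diffusion solve.
#' @return Object of class \code{bz_tissue_params}.
#' @export
tissue_params <- function(beta = 0.14, Cm = 1, dt = 0.02, sample_dt = 1,
                          stimulus_amplitude = NULL, stimulus_duration = 2,
                          cycle_length = 500, n_beats = 5,
                          record_from_beat = n_beats, rev_update_every = 25,
                          cg_tol = 1e-6) {
  stopifnot(beta > 0, Cm > 0, dt > 0, sample_dt >= dt, cycle_length > 0,
            n_beats >= 1, stimulus_duration > 0)
  if (!is.null(stimulus_amplitude)) stopifnot(stimulus_amplitude >= 0)
  structure(list(beta = beta, Cm = Cm, dt = dt, sample_dt = sample_dt,
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_duration = stimulus_duration,
                 cycle_length = cycle_length, n_beats = as.integer(n_beats),
                 record_from_beat = as.integer(record_from_beat),
                 rev_update_every = as.integer(rev_update_every),
                 cg_tol = cg_tol),
            class = "bz_tissue_params")
}

# Effective diffusivity tensor entries (mm^2/ms) from bulk conductivity.
# Unit audit: sigma [S/m] = 1e-3 S/mm; beta [1/um] = 1e3 /mm;
# Cm [uF/cm^2] = 1e-8 F/mm^2; D = sigma/(beta Cm) [mm^2/s] = 1e-3 mm^2/ms,
# collapsing to D = 0.1 * sigma/(beta * Cm) in mm^2/ms.
diffusivity <- function(sigma, beta, Cm) 0.1 * sigma / (beta * Cm)

#' Assemble the discrete diffusion operators
#'
#' Linear-triangle finite-element discretization of
#' \eqn{\nabla\cdot(D\nabla V)} with natural (no-flux) boundary conditions;
#' the scar hole's boundary is automatically no-flux, which is what makes
#' the removed core an insulator.  D is the per-element diffusivity tensor
#' \eqn{\sigma/(\beta C_m)} rotated by the fiber angle.
#'
#' @param mesh a \code{bz_mesh}.
#' @param conductivity a \code{bz_conductivity} on the same elements.
#' @param beta surface-to-volume ratio (1/um).
#' @param Cm membrane capacitance (uF/cm^2).
#' @return List with \code{K} (sparse symmetric stiffness, mm^2/ms scale,
#'   rows summing to zero) and \code{M} (lumped mass vector, mm^2).
#' @export
assemble_operators <- function(mesh, conductivity, beta = 0.14, Cm = 1) {
  stopifnot(inherits(mesh, "bz_mesh"), inherits(conductivity, "bz_conductivity"),
            length(conductivity$sigma_l) == nrow(mesh$elements))
  el <- mesh$elements
  x1 <- mesh$nodes[el[, 1L], 1L]; y1 <- mesh$nodes[el[, 1L], 2L]
  x2 <- mesh$nodes[el[, 2L], 1L]; y2 <- mesh$nodes[el[, 2L], 2L]
  x3 <- mesh$nodes[el[, 3L], 1L]; y3 <- mesh$nodes[el[, 3L], 2L]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(abs(det) < 1e-14))
    stop("degenerate (zero-area) triangle: element ",
         which(abs(det) < 1e-14)[1L])
  A <- abs(det) / 2
  # gradients of the three barycentric basis functions
  b1 <- (y2 - y3) / det; c1 <- (x3 - x2) / det
  b2 <- (y3 - y1) / det; c2 <- (x1 - x3) / det
  b3 <- (y1 - y2) / det; c3 <- (x2 - x1) / det
  th <- mesh$fiber_angle
  Dl <- diffusivity(conductivity$sigma_l, beta, Cm)
  Dt <- diffusivity(conductivity$sigma_t, beta, Cm)
  cs <- cos(th); sn <- sin(th)
  Dxx <- Dl * cs * cs + Dt * sn * sn
  Dyy <- Dl * sn * sn + Dt * cs * cs
  Dxy <- (Dl - Dt) * sn * cs
  bmat <- cbind(b1, b2, b3)
  cmat <- cbind(c1, c2, c3)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 1L
  for (a in 1:3) for (b in 1:3) {
    ii[[k]] <- el[, a]
    jj[[k]] <- el[, b]
    xx[[k]] <- A * (Dxx * bmat[, a] * bmat[, b] + Dyy * cmat[, a] * cmat[, b] +
                      Dxy * (bmat[, a] * cmat[, b] + cmat[, a] * bmat[, b]))
    k <- k + 1L
  }
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  M <- as.vector(Matrix::sparseMatrix(i = as.vector(el),
                                      j = rep(1L, 3L * nrow(el)),
                                      x = rep(A / 3, 3L), dims = c(n, 1L)))
  list(K = K, M = M)
}

# Per-node gKs multipliers from per-region membrane parameters.
node_gks <- function(mesh, params_healthy, params_bz) {
  reg <- node_regions(mesh)
  ifelse(reg == "border_zone", params_bz$gks_scale, params_healthy$gks_scale)
}

#' Diastolic stimulus threshold of the tissue
#'
#' Bisects the amplitude of a 2 ms transmembrane current over the stimulus
#' node set until a propagating wave is elicited (capture = activation of
#' tissue more than 5 mm from the stimulus within 60 ms).
#'
#' @param mesh a \code{bz_mesh} with stimulus nodes.
#' @param conductivity a \code{bz_conductivity}.
#' @param params membrane parameters.
#' @param state initial cell state for every node.
#' @param tissue tissue parameters (dt, beta, Cm are used).
#' @param tol relative bisection tolerance.
#' @return Threshold amplitude in uA/cm^2.
#' @export
find_tissue_threshold <- function(mesh, conductivity,
                                  params = cell_params(),
                                  state = cell_initial_state(),
                                  tissue = tissue_params(), tol = 0.05) {
  ops <- assemble_operators(mesh, conductivity, tissue$beta, tissue$Cm)
  L <- mesh$config$sheet_size[1L]
  d <- sqrt((mesh$nodes[, 1L] - L / 2)^2 + mesh$nodes[, 2L]^2)
  far <- d > 5
  if (!any(far)) stop("mesh too small to assess capture")
  Kp <- ops$K@p; Kj <- ops$K@i  # symmetric: CSC slots double as CSR
  excites <- function(amp) {
    stim <- numeric(nrow(mesh$nodes))
    stim[mesh$stim_nodes] <- amp / tissue$Cm
    res <- cpp_monodomain_run(Kp, Kj, ops$K@x, ops$M,
                              rep(params$gks_scale, nrow(mesh$nodes)), stim,
                              unclass(state), tissue$dt, 60, 1L,
                              tissue$stimulus_duration, 60, 1L, -1,
                              tissue$rev_update_every, tissue$cg_tol, 200L,
                              FALSE)
    any(is.finite(res$AT[far, 1L]))
  }
  lo <- 0; hi <- 16
  while (!excites(hi)) {
    hi <- hi * 2
    if (hi > 4096) stop("tissue inexcitable: no capture up to 4096 uA/cm^2")
  }
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Run a monodomain tissue simulation
#'
#' Integrates \eqn{\beta C_m \partial V/\partial t = \nabla\cdot(\sigma
#' \nabla V) - \beta C_m (I_{ion} - I_{stim})} on the mesh by first-order
#' operator splitting: a Rush-Larsen membrane update followed by a
#' backward-Euler diffusion solve (lumped mass, conjugate gradients).
#' Every node starts from the supplied single-cell state; the stimulus-node
#' set is paced \code{tissue$n_beats} times at the configured cycle length.
#'
#' @param mesh a \code{bz_mesh} with stimulus nodes.
#' @param conductivity a \code{bz_conductivity}; or a string naming a
#'   [conductivity_preset()] applied uniformly.
#' @param tissue tissue parameters, see [tissue_params()].
#' @param cell_params_per_node membrane parameters: a single
#'   \code{bz_cell_params} (homogeneous tissue), a list
#'   \code{list(healthy =, border_zone =)} of two parameter sets, or a
#'   numeric per-node vector of gKs multipliers.
#' @param initial_state a \code{bz_cell_state} seeding every node.
#' @param stop_margin if non-negative, stop this many ms after every node
#'   has activated in the current beat (used for strip measurements).
#' @param record logical: keep the sampled voltage record (matrix of
#'   nodes x samples); crossing-based activation/repolarization times per
#'   beat are always tracked at full step resolution.
#' @return Object of class \code{bz_voltage_record}: list with \code{V}
#'   (nodes x samples, mV; empty if \code{record = FALSE}), \code{time}
#'   (ms, zero at the stimulus onset of the first recorded beat),
#'   \code{AT}/\code{RT} (nodes x beats, solver-tracked -20 mV upstroke /
#'   -70 mV repolarization crossing times per beat, ms), diagnostic fields
#'   and the generating configuration.
#' @export
run_simulation <- function(mesh, conductivity, tissue = tissue_params(),
                           cell_params_per_node = cell_params(),
                           initial_state = cell_initial_state(),
                           stop_margin = -1, record = TRUE) {
  stopifnot(inherits(mesh, "bz_mesh"))
  if (is.character(conductivity)) {
    pre <- conductivity_preset(conductivity)
    conductivity <- conductivity_field(mesh, pre[["sigma_l"]], pre[["sigma_t"]])
  }
  n <- nrow(mesh$nodes)
  if (length(mesh$stim_nodes) == 0L) stop("mesh has no stimulus nodes")
  gks <- cell_params_per_node
  if (inherits(gks, "bz_cell_params")) {
    gks <- rep(gks$gks_scale, n)
  } else if (is.list(gks)) {
    stopifnot(all(c("healthy", "border_zone") %in% names(gks)))
    gks <- node_gks(mesh, gks$healthy, gks$border_zone)
  }
  stopifnot(is.numeric(gks), length(gks) == n, all(gks > 0))
  ops <- assemble_operators(mesh, conductivity, tissue$beta, tissue$Cm)
  amp <- tissue$stimulus_amplitude
  if (is.null(amp)) {
    base <- if (inherits(cell_params_per_node, "bz_cell_params"))
      cell_params_per_node else cell_params()
    amp <- 2 * find_tissue_threshold(mesh, conductivity, base, initial_state,
                                     tissue)
  }
  stim <- numeric(n)
  stim[mesh$stim_nodes] <- amp / tissue$Cm
  res <- cpp_monodomain_run(ops$K@p, ops$K@i, ops$K@x, ops$M, gks, stim,
                            unclass(initial_state), tissue$dt,
                            tissue$cycle_length, tissue$n_beats,
                            tissue$stimulus_duration, tissue$sample_dt,
                            if (record) tissue$record_from_beat - 1L
                            else tissue$n_beats,
                            stop_margin, tissue$rev_update_every,
                            tissue$cg_tol, 500L, TRUE)
  structure(list(V = res$V, time = res$time, AT = res$AT, RT = res$RT,
                 n_activated = res$n_activated,
                 stopped_early = res$stopped_early, t_end = res$t_end,
                 cg_mean_iter = res$cg_mean_iter,
                 final_state = res$final_state,
                 stimulus_amplitude = amp, tissue = tissue,
                 n_nodes = n),
            class = "bz_voltage_record")
}

#' @export
print.bz_voltage_record <- function(x, ...) {
  cat("Voltage record:", x$n_nodes, "nodes;",
      if (length(x$V)) paste(ncol(x$V), "samples;") else "no sampled V;",
      ncol(x$AT), "beat(s); activated on final beat:",
      x$n_activated[length(x$n_activated)], "/", x$n_nodes, "\n")
  invisible(x)
}
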