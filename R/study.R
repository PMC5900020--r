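#' A single computational representation of the border zone
#'
#' @param apd_variant BZ action-potential variant: \code{"normal"},
#'   \code{"longer"} or \code{"shorter"} (gKs x1, x0.5, x2).
#' @param conductivity_mode BZ conductivity preset, see
#'   [conductivity_preset()].
#' @param bz_fiber_mode \code{"horizontal"} or \code{"random"}.  Only
#'   \code{decreased_transverse} pairs with random fibers (fiber disarray
#'   is modeled together with interstitial fibrosis); the other presets
#'   pair with horizontal fibers.
#' @param smooth_transition width (mm) of a linear conductivity ramp at the
#'   healthy/BZ interface; 0 = abrupt (the default).
#' @param random_seed seed for random fiber angles.
#' @param resolution mesh resolution (mm).
#' @return Object of class \code{bz_configuration}.
#' @export
bz_configuration <- function(apd_variant = c("normal", "longer", "shorter"),
                             conductivity_mode = c("normal_anisotropic",
                                                   "decreased_transverse",
                                                   "decreased_isotropic"),
                             bz_fiber_mode = c("horizontal", "random"),
                             smooth_transition = 0, random_seed = 1L,
                             resolution = 0.15) {
  apd_variant <- match.arg(apd_variant)
  conductivity_mode <- match.arg(conductivity_mode)
  bz_fiber_mode <- match.arg(bz_fiber_mode)
  if (bz_fiber_mode == "random" && conductivity_mode != "decreased_transverse")
    stop("random fibers pair only with decreased_transverse conductivity")
  stopifnot(smooth_transition >= 0)
  if (smooth_transition > 0 && conductivity_mode != "decreased_transverse")
    stop("the smooth conductivity transition applies to decreased_transverse")
  structure(list(apd_variant = apd_variant,
                 conductivity_mode = conductivity_mode,
                 bz_fiber_mode = bz_fiber_mode,
                 smooth_transition = smooth_transition,
                 random_seed = as.integer(random_seed),
                 resolution = resolution),
            class = "bz_configuration")
}

#' @export
print.bz_configuration <- function(x, ...) {
  cat("BZ representation:", config_label(x), "\n")
  invisible(x)
}

#' @export
format.bz_configuration <- function(x, ...) config_label(x)

config_label <- function(config) {
  lbl <- paste(config$apd_variant, config$conductivity_mode,
               config$bz_fiber_mode, sep = "+")
  if (config$smooth_transition > 0)
    lbl <- paste0(lbl, "+ramp", config$smooth_transition)
  lbl
}

#' Enumerate the twelve border-zone representations
#'
#' Three action-potential rows (normal, longer, shorter APD) times four
#' conductivity/fiber columns (normal anisotropic; decreased transverse
#' with horizontal fibers; decreased transverse with random fibers;
#' decreased isotropic), in row-major order starting from
#' (normal, normal_anisotropic, horizontal).
#'
#' @param random_seed seed used by the random-fiber configurations.
#' @param resolution mesh resolution (mm) recorded in each configuration.
#' @return List of 12 \code{bz_configuration} objects.
#' @export
enumerate_configurations <- function(random_seed = 1L, resolution = 0.15) {
  cols <- list(c("normal_anisotropic", "horizontal"),
               c("decreased_transverse", "horizontal"),
               c("decreased_transverse", "random"),
               c("decreased_isotropic", "horizontal"))
  rows <- c("normal", "longer", "shorter")
  out <- list()
  for (r in rows) for (cc in cols) {
    out[[length(out) + 1L]] <-
      bz_configuration(r, cc[1L], cc[2L], random_seed = random_seed,
                       resolution = resolution)
  }
  out
}

#' Assign border-zone membrane and conductivity properties
#'
#' Healthy elements always carry the normal anisotropic conductivities and
#' control membrane parameters; border-zone elements carry the configured
#' conductivity preset and gKs scaling.  Membrane heterogeneity is
#' per-node (majority label of incident elements).
#'
#' @param mesh a \code{bz_mesh} (fiber angles should already match the
#'   configuration; see [assign_fibers()]).
#' @param config a \code{bz_configuration}.
#' @return List with \code{conductivity} (a \code{bz_conductivity}),
#'   \code{cell} (list of \code{healthy} and \code{border_zone}
#'   \code{bz_cell_params}) and \code{gks_node} (per-node multipliers).
#' @export
apply_bz_properties <- function(mesh, config) {
  stopifnot(inherits(mesh, "bz_mesh"), inherits(config, "bz_configuration"))
  normal <- conductivity_preset("normal_anisotropic")
  bzpre <- conductivity_preset(config$conductivity_mode)
  bz <- mesh$region == "border_zone"
  sl <- ifelse(bz, bzpre[["sigma_l"]], normal[["sigma_l"]])
  st <- ifelse(bz, bzpre[["sigma_t"]], normal[["sigma_t"]])
  cond <- conductivity_field(mesh, sl, st)
  if (config$smooth_transition > 0)
    cond <- apply_smooth_transition(cond, mesh, config$smooth_transition)
  variant <- switch(config$apd_variant, normal = "control",
                    longer = "longer_apd", shorter = "shorter_apd")
  cell <- list(healthy = make_variant("control"),
               border_zone = make_variant(variant))
  list(conductivity = cond, cell = cell,
       gks_node = node_gks(mesh, cell$healthy, cell$border_zone))
}

#' Smooth the conductivity transition at the healthy/BZ interface
#'
#' Ramps the transverse conductivity linearly from its healthy value at
#' the healthy/BZ interface down to the border-zone value over
#' \code{width} mm measured radially inward; the longitudinal conductivity
#' is unchanged.
#'
#' @param conductivity a \code{bz_conductivity} built for the
#'   decreased-transverse representation.
#' @param mesh the \code{bz_mesh} it lives on.
#' @param width ramp width (mm), at most the BZ thickness.
#' @return The modified \code{bz_conductivity}.
#' @export
apply_smooth_transition <- function(conductivity, mesh, width) {
  stopifnot(inherits(conductivity, "bz_conductivity"), width >= 0)
  cfg <- mesh$config
  if (width > cfg$bz_thickness)
    stop("ramp width (", width, " mm) exceeds the BZ thickness (",
         cfg$bz_thickness, " mm)")
  if (width == 0) return(conductivity)
  L <- cfg$sheet_size[1L]
  r_if <- cfg$scar_diameter / 2 + cfg$bz_thickness  # healthy/BZ interface
  cc <- element_centroids(mesh)
  r <- sqrt((cc[, 1L] - L / 2)^2 + (cc[, 2L] - L / 2)^2)
  bz <- mesh$region == "border_zone"
  healthy_t <- conductivity_preset("normal_anisotropic")[["sigma_t"]]
  ramp <- bz & r > (r_if - width) & r <= r_if
  frac <- (r[ramp] - (r_if - width)) / width   # 0 at inner end, 1 at interface
  conductivity$sigma_t[ramp] <- conductivity$sigma_t[ramp] +
    frac * (healthy_t - conductivity$sigma_t[ramp])
  # keep sigma_l >= sigma_t; the ramp cannot exceed the healthy transverse
  conductivity$sigma_l <- pmax(conductivity$sigma_l, conductivity$sigma_t)
  conductivity
}

#' Run the full border-zone representation study
#'
#' For each configuration: pace the needed membrane variants to steady
#' state (cached across configurations), build the sheet with the
#' configured fibers, run the monodomain simulation, and extract
#' activation-time, repolarization-time and repolarization-gradient maps
#' plus the gradient exceedance summary from the final beat.  The tissue
#' stimulus amplitude is twice the diastolic threshold, found once on the
#' normal-conductivity sheet and held identical across configurations.
#'
#' @param configs list of \code{bz_configuration} (default: the 12-member
#'   panel at the given resolution).
#' @param geometry base [geometry_config()]; its resolution and seed are
#'   overridden per configuration.
#' @param tissue [tissue_params()] shared by all runs.
#' @param output_dir if non-NULL, maps (VTK + plain text) and the summary
#'   CSV are written there.
#' @param cell_n_beats pre-pacing beats for the membrane variants.
#' @param keep_records keep each configuration's sampled voltage record
#'   (memory-hungry; off by default).
#' @param progress print per-configuration progress lines.
#' @return Object of class \code{bz_study}: list with \code{results} (one
#'   entry per configuration: maps, summary, diagnostics or error),
#'   \code{summary} (data.frame, one row per configuration x region),
#'   \code{failures} (labels of failed configurations), and shared run
#'   metadata.
#' @export
run_study <- function(configs = enumerate_configurations(),
                      geometry = geometry_config(resolution =
                                                   configs[[1L]]$resolution),
                      tissue = tissue_params(),
                      output_dir = NULL, cell_n_beats = 100,
                      keep_records = FALSE, progress = interactive()) {
  stopifnot(length(configs) >= 1L)
  # cell pre-pacing, cached per distinct variant
  variants <- unique(vapply(configs, function(cf) cf$apd_variant, ""))
  states <- new.env(parent = emptyenv())
  get_state <- function(variant) {
    if (is.null(states[[variant]])) {
      kind <- switch(variant, normal = "control", longer = "longer_apd",
                     shorter = "shorter_apd")
      states[[variant]] <- pace_to_steady_state(
        make_variant(kind), cycle_length = tissue$cycle_length,
        n_beats = cell_n_beats, dt = tissue$dt)
    }
    states[[variant]]
  }
  ctrl_state <- get_state("normal")

  meshes <- new.env(parent = emptyenv())
  get_mesh <- function(res) {
    key <- sprintf("%.6g", res)
    if (is.null(meshes[[key]])) {
      g <- geometry
      g$resolution <- res
      meshes[[key]] <- build_mesh(g)
    }
    meshes[[key]]
  }

  # stimulus amplitude: 2x diastolic threshold on the normal sheet,
  # identical across configurations
  amp <- tissue$stimulus_amplitude
  if (is.null(amp)) {
    m0 <- get_mesh(configs[[1L]]$resolution)
    amp <- 2 * find_tissue_threshold(m0, conductivity_field(
      m0, conductivity_preset("normal_anisotropic")[["sigma_l"]],
      conductivity_preset("normal_anisotropic")[["sigma_t"]]),
      cell_params(), ctrl_state, tissue)
  }
  tissue$stimulus_amplitude <- amp

  results <- list()
  summary_rows <- list()
  labels <- make.unique(vapply(configs, config_label, ""))
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    lbl <- labels[ci]
    if (progress) message("running ", lbl)
    res <- tryCatch({
      mesh <- get_mesh(cf$resolution)
      mesh <- assign_fibers(mesh, cf$bz_fiber_mode, cf$random_seed)
      props <- apply_bz_properties(mesh, cf)
      rec <- run_simulation(mesh, props$conductivity, tissue,
                            props$gks_node, get_state(cf$apd_variant))
      if (rec$n_activated[length(rec$n_activated)] < nrow(mesh$nodes))
        warning("conduction failure: ",
                nrow(mesh$nodes) - rec$n_activated[length(rec$n_activated)],
                " nodes did not activate on the final beat")
      at <- activation_times(rec)
      rt <- repolarization_times(rec)
      gr <- repolarization_gradient(mesh, rt)
      gs <- gradient_summary(gr, mesh)
      gs <- cbind(configuration = lbl, gs)
      out <- list(config = cf, label = lbl, at = at, rt = rt, gradient = gr,
                  summary = gs, bz_cv = bz_macroscopic_cv(mesh, at),
                  beat_AT = rec$AT, beat_RT = rec$RT,
                  n_activated = rec$n_activated,
                  stimulus_amplitude = rec$stimulus_amplitude)
      if (keep_records) out$record <- rec
      out
    }, error = function(e) structure(list(config = cf, label = lbl,
                                          error = conditionMessage(e)),
                                     class = "bz_study_failure"))
    results[[lbl]] <- res
    if (!inherits(res, "bz_study_failure"))
      summary_rows[[lbl]] <- res$summary
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else NULL
  if (!is.null(summary)) rownames(summary) <- NULL
  failures <- names(results)[vapply(results, inherits, TRUE,
                                    "bz_study_failure")]
  study <- structure(list(results = results, summary = summary,
                          failures = failures, tissue = tissue,
                          geometry = geometry,
                          stimulus_amplitude = amp,
                          cell_n_beats = cell_n_beats),
                     class = "bz_study")
  if (!is.null(output_dir)) write_study(study, output_dir,
                                        mesh_env = meshes)
  study
}

# Macroscopic conduction-velocity diagnostic for the BZ: median inverse
# activation-time gradient magnitude over BZ elements (mm/ms = m/s).
bz_macroscopic_cv <- function(mesh, at) {
  g <- repolarization_gradient(mesh, at)
  gbz <- g$element_values[mesh$region == "border_zone"]
  gbz <- gbz[is.finite(gbz) & gbz > 1e-9]
  if (!length(gbz)) return(NA_real_)
  median(1 / gbz)
}

#' @export
print.bz_study <- function(x, ...) {
  ok <- sum(!vapply(x$results, inherits, TRUE, "bz_study_failure"))
  cat("Border-zone study:", length(x$results), "configuration(s),", ok,
      "completed,", length(x$failures), "failed\n")
  if (!is.null(x$summary)) {
    g <- x$summary[x$summary$region == "global", ]
    for (i in seq_len(nrow(g)))
      cat(sprintf("  %-45s max |grad RT| %6.2f ms/mm, area>3.2 %7.2f mm^2\n",
                  g$configuration[i], g$max_gradient[i], g$area_gt_3.2[i]))
  }
  invisible(x)
}
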