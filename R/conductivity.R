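#' Bulk conductivity presets
#'
#' The three monodomain bulk-conductivity settings used for the border
#' zone (healthy tissue always uses \code{normal_anisotropic}):
#' \describe{
#'   \item{normal_anisotropic}{0.1890 / 0.0690 S/m, yielding conduction
#'     velocities of about 0.6 and 0.4 m/s along/across fibers.}
#'   \item{decreased_transverse}{transverse conductivity at 10\% of normal
#'     (0.0069 S/m), modeling interstitial fibrosis (about 0.12 m/s).}
#'   \item{decreased_isotropic}{0.0689 S/m both directions, modeling slow
#'     isotropic conduction (about 0.4 m/s).}
#' }
#'
#' @param mode preset name.
#' @return Named numeric vector \code{c(sigma_l, sigma_t)} in S/m.
#' @export
conductivity_preset <- function(mode = c("normal_anisotropic",
                                         "decreased_transverse",
                                         "decreased_isotropic")) {
  mode <- match.arg(mode)
  switch(mode,
         normal_anisotropic = c(sigma_l = 0.1890, sigma_t = 0.0690),
         decreased_transverse = c(sigma_l = 0.1890, sigma_t = 0.0069),
         decreased_isotropic = c(sigma_l = 0.0689, sigma_t = 0.0689))
}

#' Per-element conductivity field
#'
#' Longitudinal/transverse bulk conductivities per element; together with
#' the mesh's fiber angle \eqn{\theta} each element carries the 2x2 tensor
#' \eqn{R(\theta) \, diag(\sigma_l, \sigma_t) \, R(\theta)^T}.
#'
#' @param mesh a \code{bz_mesh}.
#' @param sigma_l,sigma_t conductivities (S/m), scalars or per-element
#'   vectors; \code{sigma_l >= sigma_t > 0} elementwise.
#' @return Object of class \code{bz_conductivity}: list with per-element
#'   \code{sigma_l}, \code{sigma_t}.
#' @export
conductivity_field <- function(mesh, sigma_l, sigma_t = sigma_l) {
  m <- nrow(mesh$elements)
  sigma_l <- rep_len(sigma_l, m)
  sigma_t <- rep_len(sigma_t, m)
  stopifnot(all(sigma_t > 0), all(sigma_l >= sigma_t))
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t),
            class = "bz_conductivity")
}

#' @export
print.bz_conductivity <- function(x, ...) {
  cat("Conductivity field:", length(x$sigma_l), "elements; sigma_l in [",
      signif(min(x$sigma_l), 3), ",", signif(max(x$sigma_l), 3),
      "] S/m, sigma_t in [", signif(min(x$sigma_t), 3), ",",
      signif(max(x$sigma_t), 3), "] S/m\n")
  invisible(x)
}

# 20 x 1 mm strip used for conduction-velocity measurement; fibers at
# `angle` everywhere, stimulus across one short end (x <= 0.5 mm).
strip_mesh <- function(length = 20, width = 1, resolution = 0.1) {
  h <- resolution * 3 / (2 + sqrt(2))
  nx <- max(4L, as.integer(round(length / h)))
  ny <- max(2L, as.integer(round(width / h)))
  g <- structured_tri_grid(length, width, nx, ny)
  mesh <- structure(list(nodes = g$nodes, elements = g$elements,
                         region = rep("healthy", nrow(g$elements)),
                         fiber_angle = numeric(nrow(g$elements)),
                         stim_nodes = which(g$nodes[, 1L] <= 0.5),
                         h = length / nx,
                         config = list(sheet_size = c(length, width),
                                       scar_diameter = 0, bz_thickness = 0,
                                       resolution = resolution,
                                       bz_fiber_mode = "horizontal",
                                       random_seed = 0L)),
                    class = "bz_mesh")
  mesh
}

#' Measure conduction velocity in a planar-wave strip
#'
#' Simulates a single stimulated wave in a thin strip (default 20 x 1 mm)
#' and fits activation time against distance by least squares over the
#' central half of the strip; the conduction velocity is the inverse slope.
#' For \code{direction = "longitudinal"} fibers lie along the strip so
#' \code{sigma_l} governs propagation; for \code{"transverse"} fibers lie
#' across the strip so \code{sigma_t} governs.
#'
#' @param sigma_l,sigma_t bulk conductivities (S/m).
#' @param direction \code{"longitudinal"} or \code{"transverse"}.
#' @param cell_state steady-state cell state seeding every node (from
#'   [pace_to_steady_state()]); the published resting state by default.
#' @param params membrane parameters.
#' @param tissue tissue parameters ([tissue_params()]); the cycle length is
#'   only an upper bound on the simulated time, the wave is stimulated once.
#' @param resolution strip mesh resolution (mm).
#' @return Object of class \code{bz_cv}: list with \code{velocity} (m/s),
#'   \code{direction}, \code{fit_residual} (RMS, ms), \code{n_nodes}.
#' @export
measure_cv <- function(sigma_l, sigma_t = sigma_l,
                       direction = c("longitudinal", "transverse"),
                       cell_state = cell_initial_state(),
                       params = cell_params(),
                       tissue = tissue_params(n_beats = 1, cycle_length = 400,
                                              stimulus_amplitude = 60),
                       resolution = 0.1) {
  direction <- match.arg(direction)
  stopifnot(sigma_l > 0, sigma_t > 0)
  mesh <- strip_mesh(resolution = resolution)
  mesh$fiber_angle[] <- if (direction == "longitudinal") 0 else pi / 2
  cond <- conductivity_field(mesh, sigma_l, sigma_t)
  rec <- run_simulation(mesh, cond, tissue, params, cell_state,
                        stop_margin = 5, record = FALSE)
  at <- rec$AT[, ncol(rec$AT)]
  x <- mesh$nodes[, 1L]
  if (anyNA(at[x > 19]))
    stop("conduction block: wave did not reach the far end of the strip")
  sel <- x >= 5 & x <= 15
  fit <- lm(at[sel] ~ x[sel])
  slope <- coef(fit)[[2L]]
  structure(list(velocity = 1 / slope, direction = direction,
                 fit_residual = sqrt(mean(fit$residuals^2)),
                 sigma_l = sigma_l, sigma_t = sigma_t,
                 resolution = resolution, n_nodes = nrow(mesh$nodes)),
            class = "bz_cv")
}

#' @export
print.bz_cv <- function(x, ...) {
  cat("Conduction velocity:", signif(x$velocity, 4), "m/s (", x$direction,
      "), RMS fit residual", signif(x$fit_residual, 2), "ms\n")
  invisible(x)
}

#' Calibrate bulk conductivity to a target conduction velocity
#'
#' Fixed-point iteration exploiting the square-root dependence of velocity
#' on conductivity: \eqn{\sigma \leftarrow \sigma (CV_{target}/CV)^2},
#' terminating when the measured velocity is within \code{tolerance} of the
#' target.
#'
#' @param target_cv target conduction velocity (m/s).
#' @param initial_sigma starting conductivity (S/m).
#' @param direction \code{"longitudinal"} or \code{"transverse"}; the
#'   calibrated conductivity is applied isotropically when
#'   \code{isotropic = TRUE} (it governs propagation either way).
#' @param tolerance relative tolerance on the velocity.
#' @param max_iter iteration cap.
#' @param isotropic if TRUE (default) the strip is isotropic at sigma;
#'   otherwise only the direction of propagation carries sigma and the
#'   other direction keeps \code{other_sigma}.
#' @param other_sigma conductivity of the non-measured direction when
#'   \code{isotropic = FALSE}.
#' @param ... passed to [measure_cv()] (cell state, parameters, resolution).
#' @return List with converged \code{sigma} (S/m), achieved \code{cv} and
#'   the iteration \code{log} (data.frame: iteration, sigma, cv).
#' @export
calibrate_conductivity <- function(target_cv, initial_sigma,
                                   direction = c("longitudinal", "transverse"),
                                   tolerance = 0.01, max_iter = 10,
                                   isotropic = TRUE, other_sigma = initial_sigma,
                                   ...) {
  direction <- match.arg(direction)
  stopifnot(target_cv > 0, initial_sigma > 0)
  sigma <- initial_sigma
  log <- data.frame(iteration = integer(), sigma = numeric(), cv = numeric())
  for (it in seq_len(max_iter)) {
    cv <- tryCatch({
      if (isotropic) measure_cv(sigma, sigma, direction, ...)
      else if (direction == "longitudinal")
        measure_cv(sigma, min(sigma, other_sigma), direction, ...)
      else measure_cv(max(sigma, other_sigma), sigma, direction, ...)
    }, error = function(e) e)
    if (inherits(cv, "error")) {
      stop("conduction failure at iteration ", it, " (sigma = ",
           signif(sigma, 4), " S/m): ", conditionMessage(cv),
           "\nIteration log:\n", paste(utils::capture.output(print(log)),
                                       collapse = "\n"))
    }
    log <- rbind(log, data.frame(iteration = it, sigma = sigma,
                                 cv = cv$velocity))
    if (abs(cv$velocity - target_cv) / target_cv < tolerance)
      return(list(sigma = sigma, cv = cv$velocity, log = log))
    sigma <- sigma * (target_cv / cv$velocity)^2
  }
  stop("calibration did not converge in ", max_iter, " iterations.\n",
       paste(utils::capture.output(print(log)), collapse = "\n"))
}
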