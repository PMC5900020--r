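new_node_map <- function(values, what, units, threshold = NA_real_,
                         beat = NA_integer_, element_values = NULL) {
  structure(list(values = values, what = what, units = units,
                 threshold = threshold, beat = beat,
                 element_values = element_values),
            class = "bz_node_map")
}

#' @export
print.bz_node_map <- function(x, ...) {
  def <- sum(is.finite(x$values))
  cat("Node map (", x$what, "): ", def, "/", length(x$values),
      " nodes defined; range [", signif(min(x$values, na.rm = TRUE), 4), ", ",
      signif(max(x$values, na.rm = TRUE), 4), "] ", x$units, "\n", sep = "")
  invisible(x)
}

# final-beat record matrix or error
record_matrix <- function(record) {
  if (!length(record$V))
    stop("voltage record was not sampled (record = FALSE); ",
         "re-run with record = TRUE")
  record
}

#' Activation-time map
#'
#' Time of the first upward crossing of the activation threshold per node,
#' linearly interpolated between samples.  Time zero is the stimulus onset
#' of the first recorded beat; nodes that never cross are masked (NA).
#'
#' @param record a \code{bz_voltage_record} with a sampled voltage record.
#' @param threshold activation threshold (mV).
#' @return A \code{bz_node_map} in ms.
#' @export
activation_times <- function(record, threshold = -20) {
  record <- record_matrix(record)
  at <- cpp_crossing_times(record$V, record$time, threshold, TRUE,
                           numeric(0))
  new_node_map(at, "activation time", "ms", threshold,
               beat = ncol(record$AT))
}

#' Repolarization-time map
#'
#' Time of the first downward crossing of the repolarization threshold
#' after the node's activation (default activation threshold -20 mV);
#' masked where activation or repolarization is absent.
#'
#' @param record a \code{bz_voltage_record} with a sampled voltage record.
#' @param threshold repolarization threshold (mV).
#' @param activation_threshold threshold defining the preceding activation.
#' @return A \code{bz_node_map} in ms.
#' @export
repolarization_times <- function(record, threshold = -70,
                                 activation_threshold = -20) {
  record <- record_matrix(record)
  at <- cpp_crossing_times(record$V, record$time, activation_threshold, TRUE,
                           numeric(0))
  rt <- cpp_crossing_times(record$V, record$time, threshold, FALSE, at)
  new_node_map(rt, "repolarization time", "ms", threshold,
               beat = ncol(record$AT))
}

#' Repolarization-gradient magnitude map
#'
#' The spatial gradient of the repolarization time is constant on each
#' linear triangle; its magnitude is averaged onto nodes weighted by
#' element area.  Elements touching a masked node are masked; a node is
#' masked when all its incident elements are.
#'
#' @param mesh a \code{bz_mesh}.
#' @param rt a repolarization-time \code{bz_node_map} (any nodal scalar
#'   field works).
#' @return A \code{bz_node_map} in ms/mm; per-element magnitudes are kept
#'   in the \code{element_values} field (used for area summaries).
#' @export
repolarization_gradient <- function(mesh, rt) {
  v <- if (inherits(rt, "bz_node_map")) rt$values else rt
  stopifnot(length(v) == nrow(mesh$nodes))
  el <- mesh$elements
  x1 <- mesh$nodes[el[, 1L], 1L]; y1 <- mesh$nodes[el[, 1L], 2L]
  x2 <- mesh$nodes[el[, 2L], 1L]; y2 <- mesh$nodes[el[, 2L], 2L]
  x3 <- mesh$nodes[el[, 3L], 1L]; y3 <- mesh$nodes[el[, 3L], 2L]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  A <- abs(det) / 2
  v1 <- v[el[, 1L]]; v2 <- v[el[, 2L]]; v3 <- v[el[, 3L]]
  gx <- ((y2 - y3) * v1 + (y3 - y1) * v2 + (y1 - y2) * v3) / det
  gy <- ((x3 - x2) * v1 + (x1 - x3) * v2 + (x2 - x1) * v3) / det
  gmag <- sqrt(gx^2 + gy^2)           # NA where any vertex masked
  n <- nrow(mesh$nodes)
  w <- ifelse(is.na(gmag), 0, A)
  gw <- ifelse(is.na(gmag), 0, gmag * A)
  wsum <- tabulate_sum(el, w, n)
  gsum <- tabulate_sum(el, gw, n)
  node <- ifelse(wsum > 0, gsum / wsum, NA_real_)
  new_node_map(node, "repolarization gradient", "ms/mm",
               element_values = gmag)
}

# sum a per-element value onto each of its three nodes
tabulate_sum <- function(el, val, n) {
  as.vector(Matrix::sparseMatrix(i = as.vector(el),
                                 j = rep(1L, 3L * nrow(el)),
                                 x = rep(val, 3L), dims = c(n, 1L)))
}

#' Exceedance summary of a gradient map
#'
#' Maximum gradient magnitude (global and per region) and, for each
#' threshold, the tissue area (mm^2) and area fraction whose gradient
#' exceeds it, computed from the per-element magnitudes.
#'
#' @param grad a gradient \code{bz_node_map} from
#'   [repolarization_gradient()].
#' @param mesh the \code{bz_mesh} the map lives on.
#' @param thresholds gradient thresholds (ms/mm); 3.2 ms/mm is the reported
#'   experimental minimum for unidirectional block, 5 ms/mm the map-scale
#'   reference.
#' @return A data.frame with one row per region (\code{healthy},
#'   \code{border_zone}, \code{global}): \code{max_gradient}, and columns
#'   \code{area_gt_<thr>} / \code{frac_gt_<thr>} per threshold.
#' @export
gradient_summary <- function(grad, mesh, thresholds = c(3.2, 5)) {
  stopifnot(inherits(grad, "bz_node_map"), !is.null(grad$element_values))
  gmag <- grad$element_values
  A <- element_areas(mesh)
  regions <- list(healthy = mesh$region == "healthy",
                  border_zone = mesh$region == "border_zone",
                  global = rep(TRUE, length(gmag)))
  rows <- lapply(names(regions), function(rn) {
    sel <- regions[[rn]] & !is.na(gmag)
    if (!any(regions[[rn]])) {
      warning("region '", rn, "' is empty")
      out <- data.frame(region = rn, max_gradient = 0)
      for (th in thresholds) {
        out[[sprintf("area_gt_%g", th)]] <- 0
        out[[sprintf("frac_gt_%g", th)]] <- 0
      }
      return(out)
    }
    atot <- sum(A[regions[[rn]]])
    out <- data.frame(region = rn,
                      max_gradient = if (any(sel)) max(gmag[sel]) else 0)
    for (th in thresholds) {
      aexc <- sum(A[sel][gmag[sel] > th])
      out[[sprintf("area_gt_%g", th)]] <- aexc
      out[[sprintf("frac_gt_%g", th)]] <- aexc / atot
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
plot.bz_node_map <- function(x, mesh, ...) {
  stopifnot(inherits(mesh, "bz_mesh"))
  pal <- grDevices::hcl.colors(64, "Spectral", rev = TRUE)
  v <- x$values
  col <- pal[cut(v, 64, labels = FALSE)]
  graphics::plot(mesh$nodes[, 1L], mesh$nodes[, 2L], col = col, pch = 15,
                 cex = 0.3, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = paste0(x$what, " (", x$units, ")"), ...)
  invisible(x)
}
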