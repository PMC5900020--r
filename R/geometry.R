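#' Configuration of the idealized scar/border-zone sheet
#'
#' Describes the square 2D tissue sheet with a central circular scar core
#' (removed from the mesh: the scar is an insulator) surrounded by a
#' border-zone (BZ) annulus.  Lengths in mm.
#'
#' @param sheet_size side of the square sheet (mm).
#' @param scar_diameter diameter of the insulating scar core (mm);
#'   0 gives a plain sheet with no hole and no BZ.
#' @param bz_thickness thickness of the BZ annulus (mm).
#' @param resolution target mean edge length of the triangulation (mm).
#' @param bz_fiber_mode fiber orientation in the BZ: \code{"horizontal"}
#'   (aligned with the x axis, like healthy tissue) or \code{"random"}
#'   (independent per-element angles, modeling fiber disarray).
#' @param random_seed seed for random fiber angles.
#' @return An object of class \code{bz_geometry_config}.
#' @export
geometry_config <- function(sheet_size = 30, scar_diameter = 10,
                            bz_thickness = 2, resolution = 0.05,
                            bz_fiber_mode = c("horizontal", "random"),
                            random_seed = 1L) {
  bz_fiber_mode <- match.arg(bz_fiber_mode)
  stopifnot(sheet_size > 0, scar_diameter >= 0, bz_thickness >= 0,
            resolution > 0,
            scar_diameter + 2 * bz_thickness < sheet_size)
  structure(list(sheet_size = sheet_size, scar_diameter = scar_diameter,
                 bz_thickness = bz_thickness, resolution = resolution,
                 bz_fiber_mode = bz_fiber_mode,
                 random_seed = as.integer(random_seed)),
            class = "bz_geometry_config")
}

# Structured criss-cross triangulation of [0,Lx] x [0,Ly] with nx x ny
# cells, each split along a parity-alternating diagonal.  With nx even the
# triangulation is exactly mirror-symmetric about the vertical midline
# (mirroring flips the diagonal, so the parity must flip with it).
structured_tri_grid <- function(Lx, Ly, nx, ny) {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  nodes <- cbind(x = rep(xs, times = ny + 1L), y = rep(ys, each = nx + 1L))
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i  # i: x index, j: y index
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  even <- (i + j) %% 2L == 0L
  # even cells: diagonal a-c; odd cells: diagonal b-d
  t1 <- ifelse(even, a, a); t2 <- ifelse(even, b, b); t3 <- ifelse(even, c, d)
  u1 <- ifelse(even, a, b); u2 <- ifelse(even, c, c); u3 <- ifelse(even, d, d)
  elements <- rbind(cbind(t1, t2, t3), cbind(u1, u2, u3))
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  list(nodes = nodes, elements = elements)
}

#' Build the triangulated scar/border-zone sheet
#'
#' Generates a structured criss-cross triangulation of the square sheet,
#' removes every element whose centroid falls inside the scar core (the
#' hole is real: its boundary becomes a no-flux boundary), labels elements
#' with centroid radius in (scar radius, scar radius + BZ thickness] as
#' border zone, assigns fiber angles (healthy tissue along x; BZ per
#' \code{config$bz_fiber_mode}) and places the stimulus at the center of
#' the bottom edge.
#'
#' @param config a [geometry_config()].
#' @param stimulus_radius radius (mm) of the half-disc stimulus node set on
#'   the bottom edge.
#' @return An object of class \code{bz_mesh}: list with \code{nodes}
#'   (n x 2, mm), \code{elements} (m x 3 node indices), \code{region}
#'   (per element, \code{"healthy"}/\code{"border_zone"}),
#'   \code{fiber_angle} (per element, radians from x axis),
#'   \code{stim_nodes}, and the generating \code{config}.
#' @export
build_mesh <- function(config = geometry_config(), stimulus_radius = 0.5) {
  stopifnot(inherits(config, "bz_geometry_config"))
  L <- config$sheet_size
  # mean edge of the criss-cross pattern is (2 + sqrt(2))/3 * h
  h_target <- config$resolution * 3 / (2 + sqrt(2))
  # Mirroring a cell flips its diagonal, so the parity that selects the
  # diagonal must flip across the midline too: the cell count per side has
  # to be even for the triangulation to be exactly mirror-symmetric.
  n <- max(4L, as.integer(round(L / h_target)))
  if (n %% 2L == 1L) n <- n + 1L
  h <- L / n
  r_scar <- config$scar_diameter / 2
  if (r_scar > 0 && config$bz_thickness / h < 1.5)
    stop("resolution too coarse to resolve the border zone: fewer than ",
         "3 element layers across its thickness")
  g <- structured_tri_grid(L, L, n, n)
  cx <- (g$nodes[g$elements[, 1L], 1L] + g$nodes[g$elements[, 2L], 1L] +
           g$nodes[g$elements[, 3L], 1L]) / 3
  cy <- (g$nodes[g$elements[, 1L], 2L] + g$nodes[g$elements[, 2L], 2L] +
           g$nodes[g$elements[, 3L], 2L]) / 3
  r <- sqrt((cx - L / 2)^2 + (cy - L / 2)^2)
  keep <- r > r_scar
  elements <- g$elements[keep, , drop = FALSE]
  r <- r[keep]
  region <- ifelse(r_scar > 0 & r <= r_scar + config$bz_thickness,
                   "border_zone", "healthy")
  # drop orphaned nodes and renumber
  used <- sort(unique(as.vector(elements)))
  renum <- integer(nrow(g$nodes))
  renum[used] <- seq_along(used)
  elements[] <- renum[elements]
  nodes <- g$nodes[used, , drop = FALSE]
  if (cpp_n_components(elements, nrow(nodes)) != 1L)
    stop("mesh is not a single connected component")
  mesh <- structure(list(nodes = nodes, elements = elements, region = region,
                         fiber_angle = numeric(nrow(elements)),
                         stim_nodes = integer(0), h = h, config = config),
                    class = "bz_mesh")
  mesh <- assign_fibers(mesh, config$bz_fiber_mode, config$random_seed)
  place_stimulus(mesh, stimulus_radius)
}

#' Assign per-element fiber angles
#'
#' Healthy-tissue fibers always lie along the x axis (angle 0).  Border-zone
#' fibers are either also horizontal or drawn independently and uniformly
#' on \eqn{[0, \pi)} from the seeded generator (fiber disarray).
#'
#' @param mesh a \code{bz_mesh}.
#' @param mode \code{"horizontal"} or \code{"random"}.
#' @param seed integer seed used for \code{mode = "random"}.
#' @return The mesh with updated \code{fiber_angle}.
#' @export
assign_fibers <- function(mesh, mode = c("horizontal", "random"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "bz_mesh"))
  ang <- numeric(nrow(mesh$elements))
  if (mode == "random") {
    bz <- mesh$region == "border_zone"
    ang[bz] <- local_runif(sum(bz), seed) * pi
  }
  mesh$fiber_angle <- ang
  mesh$config$bz_fiber_mode <- mode
  mesh$config$random_seed <- as.integer(seed)
  mesh
}

# Uniform draws from a local RNG stream that does not disturb the caller's.
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  runif(n)
}

#' Place the pacing stimulus on the bottom edge
#'
#' Selects all nodes within \code{radius} of the midpoint of the bottom
#' tissue edge (the same site for every simulation of the study).
#'
#' @param mesh a \code{bz_mesh}.
#' @param radius stimulus radius (mm).
#' @return The mesh with \code{stim_nodes} set.
#' @export
place_stimulus <- function(mesh, radius = 0.5) {
  stopifnot(inherits(mesh, "bz_mesh"), radius > 0)
  L <- mesh$config$sheet_size
  d <- sqrt((mesh$nodes[, 1L] - L / 2)^2 + mesh$nodes[, 2L]^2)
  idx <- which(d <= radius)
  if (length(idx) == 0L)
    stop("no nodes within ", radius, " mm of the stimulus site; ",
         "use a larger radius (nodal spacing is ", signif(mesh$h, 3), " mm)")
  mesh$stim_nodes <- idx
  mesh
}

#' Triangle areas of a mesh (mm^2)
#' @param mesh a \code{bz_mesh}.
#' @return Numeric vector, one area per element.
#' @export
element_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$elements[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[mesh$elements[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[mesh$elements[, 3L], , drop = FALSE]
  0.5 * abs((p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
              (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L]))
}

#' Element centroids (mm)
#' @param mesh a \code{bz_mesh}.
#' @return m x 2 matrix of centroid coordinates.
#' @export
element_centroids <- function(mesh) {
  cbind((mesh$nodes[mesh$elements[, 1L], 1L] + mesh$nodes[mesh$elements[, 2L], 1L] +
           mesh$nodes[mesh$elements[, 3L], 1L]) / 3,
        (mesh$nodes[mesh$elements[, 1L], 2L] + mesh$nodes[mesh$elements[, 2L], 2L] +
           mesh$nodes[mesh$elements[, 3L], 2L]) / 3)
}

#' Mean edge length of a mesh (mm)
#' @param mesh a \code{bz_mesh}.
#' @return Mean length over unique edges.
#' @export
mean_edge_length <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, c(1L, 2L)], el[, c(2L, 3L)], el[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  d <- mesh$nodes[e[, 1L], , drop = FALSE] - mesh$nodes[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# Per-node region label by majority of incident elements (ties -> border_zone,
# so cell heterogeneity extends to the interface nodes).
node_regions <- function(mesh) {
  m <- nrow(mesh$elements)
  n <- nrow(mesh$nodes)
  isbz <- as.integer(mesh$region == "border_zone")
  cnt_all <- tabulate(as.vector(mesh$elements), nbins = n)
  cnt_bz <- tabulate(as.vector(mesh$elements)[rep(isbz == 1L, 3L)], nbins = n)
  ifelse(cnt_bz * 2L >= cnt_all, "border_zone", "healthy")
}

#' @export
print.bz_mesh <- function(x, ...) {
  cat("Triangulated sheet:", nrow(x$nodes), "nodes,", nrow(x$elements),
      "elements (", sum(x$region == "border_zone"), "border zone )\n")
  cat("  sheet", x$config$sheet_size, "mm; scar d =", x$config$scar_diameter,
      "mm; BZ", x$config$bz_thickness, "mm; mean edge",
      signif(mean_edge_length(x), 3), "mm\n")
  cat("  BZ fibers:", x$config$bz_fiber_mode, "; stimulus nodes:",
      length(x$stim_nodes), "\n")
  invisible(x)
}

#' @export
plot.bz_mesh <- function(x, value = NULL, ...) {
  cc <- element_centroids(x)
  col <- if (is.null(value)) {
    ifelse(x$region == "border_zone", "steelblue", "pink")
  } else {
    pal <- grDevices::hcl.colors(64, "viridis")
    pal[cut(value, 64, labels = FALSE)]
  }
  graphics::plot(cc[, 1L], cc[, 2L], col = col, pch = 15, cex = 0.3,
                 asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
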