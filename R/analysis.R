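# Field analyses: turn trajectories into regular-grid maps in the
# pipette-centered frame, axis profiles, per-cell force maps,
# gradient-vs-uniform difference profiles and junction-length metrics.
# Maps are linear (triangulation-based) interpolants -- exact at their
# sample sites -- averaged across runs; tabular outputs are tibbles.

#' Regular-grid field map in the pipette-centered analysis frame
#'
#' @param points sample sites (n x 2), analysis-frame um.
#' @param values n x k matrix (k = 1 scalar or 2 vector components).
#' @param spacing grid spacing, um.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the point hull.
#' @param tri optional triangulation of `points` (index triples); computed
#'   by Delaunay when absent.
#' @param origin frame origin (initial pipette position), um.
#' @return an object of class `epi_fieldmap`: grid vectors `x`, `y`, an
#'   array `vals` (nx x ny x k), validity `mask`, `n_runs`, `origin`,
#'   `spacing`.
#' @export
field_map <- function(points, values, spacing = 1, extent = NULL,
                      tri = NULL, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (nrow(points) == 0) stop("field_map(): no sample sites in frame")
  if (is.null(extent))
    extent <- c(min(points[, 1]), max(points[, 1]),
                min(points[, 2]), max(points[, 2]))
  gx <- seq(extent[1], extent[2], by = spacing)
  gy <- seq(extent[3], extent[4], by = spacing)
  flat <- interp_linear(points, values, gx, gy, tri = tri)
  vals <- array(flat, dim = c(length(gx), length(gy), ncol(values)))
  structure(list(x = gx, y = gy, vals = vals,
                 mask = !is.na(vals[, , 1]), n_runs = 1L,
                 origin = origin, spacing = spacing),
            class = "epi_fieldmap")
}

#' @export
print.epi_fieldmap <- function(x, ...) {
  cat(sprintf("<epi_fieldmap> %d x %d grid (%.3g um), %d component(s), n_runs = %d\n",
              length(x$x), length(x$y), x$spacing, dim(x$vals)[3], x$n_runs))
  invisible(x)
}

#' Average field maps across runs
#'
#' Maps must share grids; only grid cells valid in a run enter that run's
#' contribution (averaging commutes with masking). Averaging identical maps
#' is the identity, and the result is order-independent.
#'
#' @param maps list of [field_map()]s on a common grid.
#' @return the averaged `epi_fieldmap` with `n_runs` set.
#' @export
average_field_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  g1 <- maps[[1]]
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$x, g1$x)) || !isTRUE(all.equal(m$y, g1$y)))
      stop("average_field_maps(): grid mismatch")
  k <- dim(g1$vals)[3]
  acc <- array(0, dim = dim(g1$vals))
  cnt <- matrix(0, length(g1$x), length(g1$y))
  for (m in maps) {
    v <- m$vals
    ok <- !is.na(v[, , 1])
    v[is.na(v)] <- 0
    acc <- acc + v
    cnt <- cnt + ok
  }
  for (j in seq_len(k)) {
    slice <- acc[, , j] / cnt
    slice[cnt == 0] <- NA_real_
    acc[, , j] <- slice
  }
  structure(list(x = g1$x, y = g1$y, vals = acc, mask = cnt > 0,
                 n_runs = length(maps), origin = g1$origin,
                 spacing = g1$spacing),
            class = "epi_fieldmap")
}

#' @exportS3Method tibble::as_tibble
as_tibble.epi_fieldmap <- function(x, ...) {
  k <- dim(x$vals)[3]
  xs <- rep(x$x, times = length(x$y))
  ys <- rep(x$y, each = length(x$x))
  out <- tibble::tibble(x = xs, y = ys)
  if (k == 1) {
    out$value <- as.vector(x$vals[, , 1])
  } else {
    out$vx <- as.vector(x$vals[, , 1])
    out$vy <- as.vector(x$vals[, , 2])
    out$magnitude <- sqrt(out$vx^2 + out$vy^2)
  }
  out
}

# map magnitude slice (k=1: the value; k=2: vector magnitude)
map_magnitude <- function(map) {
  if (dim(map$vals)[3] == 1) map$vals[, , 1]
  else sqrt(map$vals[, , 1]^2 + map$vals[, , 2]^2)
}

# ---- displacement and force maps -----------------------------------------

traj_cell_points <- function(traj) {
  tb <- traj$before$tissue; ta <- traj$after$tissue
  c0 <- tissue_centroids(tb)
  c1 <- tissue_centroids(ta)
  list(points = c0, disp = c1 - c0)
}

#' Cell-center displacement map
#'
#' Per-cell centroid displacement (after minus before) assigned at the
#' original centroid, linearly interpolated to a 1-um grid in the
#' pipette-centered frame and averaged across runs.
#'
#' @param trajs one `epi_trajectory` or a list of them (shared frame).
#' @param spacing grid spacing, um.
#' @param extent optional common grid extent (required to average runs of
#'   differing tissue outlines).
#' @return an `epi_fieldmap` with 2 components (ux, uy).
#' @export
cell_displacement_map <- function(trajs, spacing = 1, extent = NULL) {
  if (inherits(trajs, "epi_trajectory")) trajs <- list(trajs)
  if (is.null(extent)) extent <- common_cell_extent(trajs)
  maps <- lapply(trajs, function(tr) {
    cp <- traj_cell_points(tr)
    field_map(cp$points, cp$disp, spacing = spacing, extent = extent)
  })
  average_field_maps(maps)
}

#' Common analysis extent across runs
#'
#' The intersection of the runs' cell-centroid bounding boxes, used as the
#' shared grid for run-averaged maps.
#' @param trajs list of `epi_trajectory` objects.
#' @return `c(xmin, xmax, ymin, ymax)`.
#' @export
common_cell_extent <- function(trajs) {
  exts <- sapply(trajs, function(tr) {
    P <- tissue_centroids(tr$before$tissue)
    c(min(P[, 1]), max(P[, 1]), min(P[, 2]), max(P[, 2]))
  })
  c(max(exts[1, ]), min(exts[2, ]), max(exts[3, ]), min(exts[4, ]))
}

#' Substrate displacement map
#'
#' Point displacements sampled at the lattice points themselves (exact
#' there; the grid interpolation uses the structured lattice triangles),
#' averaged across runs.
#'
#' @inheritParams cell_displacement_map
#' @return an `epi_fieldmap` with 2 components.
#' @export
substrate_displacement_map <- function(trajs, spacing = 1, extent = NULL) {
  if (inherits(trajs, "epi_trajectory")) trajs <- list(trajs)
  if (is.null(extent)) {
    exts <- sapply(trajs, function(tr) tr$after$lattice$extent)
    extent <- c(max(exts[1, ]), min(exts[2, ]), max(exts[3, ]), min(exts[4, ]))
  }
  maps <- lapply(trajs, function(tr) {
    lat <- tr$after$lattice
    field_map(lat$S0, lat$S - lat$S0, spacing = spacing, extent = extent,
              tri = lat$tri)
  })
  average_field_maps(maps)
}

#' Per-cell force-magnitude map
#'
#' Mean per-vertex force magnitude of one component (`fa`, `cort` or
#' `junc`) per cell at the analysis time point, assigned to the original
#' cell centers, interpolated and run-averaged. Units AU.
#'
#' @inheritParams cell_displacement_map
#' @param component `"fa"`, `"cort"` or `"junc"`.
#' @return a scalar `epi_fieldmap`.
#' @export
force_map <- function(trajs, component = c("fa", "cort", "junc"),
                      spacing = 1, extent = NULL) {
  component <- match.arg(component)
  if (inherits(trajs, "epi_trajectory")) trajs <- list(trajs)
  if (is.null(extent)) extent <- common_cell_extent(trajs)
  maps <- lapply(trajs, function(tr) {
    Fc <- tr$breakdown_after[[component]]
    mag <- sqrt(Fc[, 1]^2 + Fc[, 2]^2)
    ts <- tr$before$tissue
    permean <- as.numeric(rowsum(mag, ts$cell) / ts$clen)
    field_map(tissue_centroids(ts), permean, spacing = spacing,
              extent = extent)
  })
  average_field_maps(maps)
}

# ---- profiles -------------------------------------------------------------

#' Axis profile of a field map
#'
#' Samples the map magnitude along the negative y axis (`"parallel"`, the
#' pipette movement direction) or along x at y = 0 (`"perpendicular"`),
#' with a distance-from-origin coordinate. Points outside the valid mask
#' are flagged.
#'
#' @param map an `epi_fieldmap`.
#' @param axis `"parallel"` or `"perpendicular"`.
#' @param step sampling step, um.
#' @return tibble with `distance`, `value`, `valid`.
#' @export
axis_profile <- function(map, axis = c("parallel", "perpendicular"),
                         step = map$spacing) {
  axis <- match.arg(axis)
  o <- map$origin
  if (axis == "parallel") {
    dmax <- o[2] - min(map$y)
    d <- seq(0, max(dmax, 0), by = step)
    px <- rep(o[1], length(d)); py <- o[2] - d
  } else {
    dmax <- max(map$x) - o[1]
    d <- seq(0, max(dmax, 0), by = step)
    px <- o[1] + d; py <- rep(o[2], length(d))
  }
  v <- sample_map(map, px, py)
  tibble::tibble(distance = d, value = v, valid = !is.na(v))
}

# bilinear sampling of the magnitude grid
sample_map <- function(map, px, py) {
  M <- map_magnitude(map)
  ix <- (px - map$x[1]) / map$spacing + 1
  iy <- (py - map$y[1]) / map$spacing + 1
  i0 <- floor(ix); j0 <- floor(iy)
  fx <- ix - i0; fy <- iy - j0
  nx <- length(map$x); ny <- length(map$y)
  ok <- i0 >= 1 & i0 <= nx - 1 & j0 >= 1 & j0 <= ny - 1
  out <- rep(NA_real_, length(px))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- M[cbind(i0k, j0k)]; v10 <- M[cbind(i0k + 1, j0k)]
    v01 <- M[cbind(i0k, j0k + 1)]; v11 <- M[cbind(i0k + 1, j0k + 1)]
    out[ok] <- (1 - fxk) * (1 - fyk) * v00 + fxk * (1 - fyk) * v10 +
      (1 - fxk) * fyk * v01 + fxk * fyk * v11
  }
  out
}

#' First distance at which a monotone profile crosses a threshold
#'
#' Linear interpolation between samples; NA when the profile never crosses.
#'
#' @param profile a tibble from [axis_profile()].
#' @param threshold value to cross (from above).
#' @return the crossing distance, um.
#' @export
profile_crossing <- function(profile, threshold) {
  d <- profile$distance[profile$valid]
  v <- profile$value[profile$valid]
  below <- which(v < threshold)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  d[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) * (d[i] - d[i - 1])
}

#' Difference profile between a gradient run and its uniform control
#'
#' Parallel-axis profile of the gradient-case map minus the uniform-case
#' map, on their shared grid.
#'
#' @param map_gradient,map_uniform `epi_fieldmap`s on identical grids.
#' @return tibble with `distance`, `gradient`, `uniform`, `diff`, `valid`.
#' @export
difference_profile <- function(map_gradient, map_uniform) {
  if (!isTRUE(all.equal(map_gradient$x, map_uniform$x)) ||
      !isTRUE(all.equal(map_gradient$y, map_uniform$y)))
    stop("difference_profile(): grid mismatch")
  pg <- axis_profile(map_gradient, "parallel")
  pu <- axis_profile(map_uniform, "parallel")
  tibble::tibble(distance = pg$distance, gradient = pg$value,
                 uniform = pu$value, diff = pg$value - pu$value,
                 valid = pg$valid & pu$valid)
}

# ---- optogenetic metrics --------------------------------------------------

#' Junction-length and substrate-peak metrics of an optogenetic run
#'
#' The relative junction length L/L0 time series comes with the trajectory;
#' here the substrate displacement between the pre-activation state (t_on)
#' and the end of activation (t_off) is sampled along the line through the
#' activated junction, smoothed with a 3-sample moving average, and the
#' largest local maximum on each side of the junction center is found. The
#' peak statistic is the mean of the two peaks; it is paired with half the
#' junction length change over the activation window.
#'
#' @param traj an `opto_trajectory` from [run_optogenetic()].
#' @param step line sampling step, um.
#' @param half_width half-length of the sampled line, um.
#' @return list with `L_series` (tibble), `L_rel_end`, `dL`, `half_dL`,
#'   `peaks` (left/right), `peak_mean`, `peak_per_half_dL`, `flagged`
#'   (fewer than one peak per side).
#' @export
junction_metrics <- function(traj, step = 1, half_width = 25) {
  lat <- traj$lattice
  disp <- sqrt(rowSums((traj$S_off - traj$S_on)^2))
  s <- seq(-half_width, half_width, by = step)
  px <- traj$junction_center[1] + s * traj$junction_axis[1]
  py <- traj$junction_center[2] + s * traj$junction_axis[2]
  # direct per-point interpolation along the line (no grid detour)
  line <- line_interp(lat, disp, px, py)
  sm <- moving_average3(line)
  LS <- traj$L_series
  on_w <- LS$time >= traj$protocol$t_on - 1e-9 &
    LS$time <= traj$protocol$t_off + 1e-9
  L_on <- LS$L[which(on_w)[1]]
  L_off <- LS$L[rev(which(on_w))[1]]
  dL <- L_on - L_off
  pk <- function(side) {
    idx <- if (side < 0) which(s < 0) else which(s > 0)
    vals <- sm[idx]
    loc <- which(diff(sign(diff(vals))) < 0) + 1   # interior local maxima
    if (!length(loc)) return(NA_real_)
    max(vals[loc])
  }
  peaks <- c(left = pk(-1), right = pk(1))
  flagged <- anyNA(peaks)
  peak_mean <- mean(peaks)
  ok_dL <- is.finite(dL) && dL > 0
  list(L_series = LS, L_rel_end = L_off / traj$L0, dL = dL,
       half_dL = dL / 2, peaks = peaks, peak_mean = peak_mean,
       peak_per_half_dL = if (is.finite(peak_mean) && ok_dL)
         peak_mean / (dL / 2) else NA_real_,
       flagged = flagged || !ok_dL)
}

line_interp <- function(lat, vals, px, py) {
  out <- rep(NA_real_, length(px))
  loc <- locate_in_lattice(cbind(px, py), lat)
  ok <- !is.na(loc$tri[, 1])
  if (any(ok)) {
    tri <- loc$tri[ok, , drop = FALSE]; w <- loc$w[ok, , drop = FALSE]
    out[ok] <- w[, 1] * vals[tri[, 1]] + w[, 2] * vals[tri[, 2]] +
      w[, 3] * vals[tri[, 3]]
  }
  out
}

moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}
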