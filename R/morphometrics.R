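# trilinear (cartesian) / bilinear (axisymmetric) sampling of a cell-centered
# field at physical points; points outside the outermost cell centers clamp
# to the boundary value
interp_field <- function(field, points, grid) {
  h <- grid$spacing
  d <- dim(field)
  if (grid$type == "axisymmetric") {
    orig <- c(0.5 * h, grid$origin[2] + 0.5 * h)
    nd <- 2
  } else {
    orig <- grid$origin + 0.5 * h
    nd <- 3
  }
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    u <- (points[p, 1:nd] - orig) / h
    i0 <- pmin(pmax(floor(u), 0), d[1:nd] - 2)
    w <- pmin(pmax(u - i0, 0), 1)
    acc <- 0
    for (corner in 0:(2^nd - 1)) {
      off <- as.integer(intToBits(corner))[1:nd]
      wt <- prod(ifelse(off == 1, w, 1 - w))
      idx <- i0 + off + 1
      acc <- acc + wt * if (nd == 2) field[idx[1], idx[2]] else
        field[idx[1], idx[2], idx[3]]
    }
    out[p] <- acc
  }
  out
}

# sub-cell isotherm crossing points along grid lines (marching-cubes edge
# vertices), tagged with the component label of their below-level endpoint
isotherm_points <- function(T, level, grid, labels) {
  d <- dim(T); h <- grid$spacing
  nd <- length(d)
  ax <- grid_axes(grid)
  axc <- if (grid$type == "axisymmetric") list(ax$r, ax$z) else ax
  pts <- list()
  for (axis in seq_len(nd)) {
    n <- d[axis]
    if (n < 2) next
    sl <- function(arr, idx) {
      args <- rep(list(quote(expr = )), nd)
      args[[axis]] <- idx
      do.call(`[`, c(list(arr), args, list(drop = FALSE)))
    }
    Ta <- sl(T, 1:(n - 1)); Tb <- sl(T, 2:n)
    La <- sl(labels, 1:(n - 1)); Lb <- sl(labels, 2:n)
    cross <- (Ta <= level & Tb > level) | (Ta > level & Tb <= level)
    if (!any(cross)) next
    frac <- (level - Ta[cross]) / (Tb[cross] - Ta[cross])
    which_idx <- which(cross)
    ij <- arrayInd(which_idx, dim(Ta))
    coord <- matrix(0, length(which_idx), nd)
    for (a in seq_len(nd)) coord[, a] <- axc[[a]][ij[, a]]
    coord[, axis] <- coord[, axis] + frac * h
    lab <- ifelse(Ta[cross] <= level, La[cross], Lb[cross])
    pts[[length(pts) + 1L]] <- cbind(coord, lab)
  }
  if (!length(pts)) return(matrix(0, 0, nd + 1))
  do.call(rbind, pts)
}

# outer-face points of mask cells lying on the domain boundary, so that
# boundary-clipped regions still report the full clipped extent
boundary_points <- function(mask, grid, labels) {
  d <- dim(mask); nd <- length(d); h <- grid$spacing
  ax <- grid_axes(grid)
  axc <- if (grid$type == "axisymmetric") list(ax$r, ax$z) else ax
  pts <- list()
  for (axis in seq_len(nd)) {
    for (side in c(1L, d[axis])) {
      args <- rep(list(quote(expr = )), nd)
      args[[axis]] <- side
      m <- do.call(`[`, c(list(mask), args, list(drop = FALSE)))
      if (!any(m)) next
      lb <- do.call(`[`, c(list(labels), args, list(drop = FALSE)))
      idx <- which(m)
      ij <- arrayInd(idx, dim(m))
      ij[, axis] <- side
      coord <- matrix(0, length(idx), nd)
      for (a in seq_len(nd)) coord[, a] <- axc[[a]][ij[, a]]
      coord[, axis] <- coord[, axis] + (if (side == 1) -h / 2 else h / 2)
      pts[[length(pts) + 1L]] <- cbind(coord, lb[idx])
    }
  }
  if (!length(pts)) return(matrix(0, 0, nd + 1))
  do.call(rbind, pts)
}

#' Extract an isotherm-bounded region from a temperature field
#'
#' The region is the set of cells at or below `level`; its surface is
#' represented by sub-cell crossing points obtained by linear interpolation
#' along grid lines (marching-cubes edge vertices). Connected components use
#' 6-connectivity. The region volume is integrated column-wise with sub-cell
#' linear interpolation (a voxel-count volume is also reported).
#'
#' @param T temperature field (array of the grid's shape), °C.
#' @param level isotherm level, °C (e.g. 0 for the ice-ball boundary).
#' @param grid the [sim_grid()] / [axi_grid()] the field lives on.
#' @return list with `mask`, `labels`, `n_components`, `points` (surface
#'   point matrix, one row per crossing, last column = component label),
#'   `volume_m3`, `volume_voxel_m3`, `boundary_clipped`, `level`.
#' @export
extract_isotherm_region <- function(T, level, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  if (any(!is.finite(T)))
    stop("extract_isotherm_region: non-finite temperature field", call. = FALSE)
  d3 <- if (grid$type == "cartesian") grid$shape else c(grid$shape, 1L)
  mask <- array(T <= level, dim(T))
  lab_raw <- .label_components(as.vector(mask), d3[1], d3[2], d3[3])
  ncomp <- attr(lab_raw, "n_components")
  labels <- array(lab_raw, dim(T))
  pts <- isotherm_points(T, level, grid, labels)
  bpts <- boundary_points(mask, grid, labels)
  clipped <- nrow(bpts) > 0
  vol_vox <- if (length(grid$cell_volume) == 1) {
    sum(mask) * grid$cell_volume
  } else {
    # axisymmetric: per-ring volumes recycled down columns
    sum(array(grid$cell_volume, dim(T))[mask])
  }
  list(mask = mask, labels = labels, n_components = ncomp,
       points = rbind(pts, bpts), volume_m3 = interp_volume(T, level, grid),
       volume_voxel_m3 = vol_vox, boundary_clipped = clipped, level = level)
}

# column-integrated sub-cell volume of {T <= level}
interp_volume <- function(T, level, grid) {
  h <- grid$spacing
  if (grid$type == "cartesian") {
    d <- dim(T)
    n1 <- d[1]
    Ta <- T[1:(n1 - 1), , , drop = FALSE]
    Tb <- T[2:n1, , , drop = FALSE]
    both_below <- Ta <= level & Tb <= level
    one_below <- xor(Ta <= level, Tb <= level)
    frac <- abs(level - ifelse(Ta <= level, Ta, Tb)) /
      pmax(abs(Tb - Ta), 1e-300)
    len <- sum(both_below) * h + sum((frac * one_below)) * h
    # half-cells at the column ends behave as constant-temperature stubs
    len <- len + (sum(T[1, , ] <= level) + sum(T[n1, , ] <= level)) * h / 2
    len * h^2
  } else {
    d <- dim(T)
    nr <- d[1]
    rf <- seq_len(nr) * h     # outer radius of each ring
    rc <- grid$r_centers
    vol <- 0
    Ta <- T[1:(nr - 1), , drop = FALSE]
    Tb <- T[2:nr, , drop = FALSE]
    ra <- matrix(rc[1:(nr - 1)], nr - 1, d[2])
    rb <- matrix(rc[2:nr], nr - 1, d[2])
    both <- Ta <= level & Tb <= level
    vol <- vol + sum((pi * (rb^2 - ra^2) * h)[both])
    onlyA <- Ta <= level & Tb > level
    if (any(onlyA)) {
      rx <- ra + (level - Ta) / (Tb - Ta) * h
      vol <- vol + sum((pi * (rx^2 - ra^2) * h)[onlyA])
    }
    onlyB <- Tb <= level & Ta > level
    if (any(onlyB)) {
      rx <- ra + (level - Ta) / (Tb - Ta) * h
      vol <- vol + sum((pi * (rb^2 - rx^2) * h)[onlyB])
    }
    # inner core [0, r_1] and outer collar [r_c(nr), R]
    vol <- vol + sum(T[1, ] <= level) * pi * rc[1]^2 * h
    vol <- vol + sum(T[nr, ] <= level) * pi * ((nr * h)^2 - rc[nr]^2) * h
    vol
  }
}

#' Caliper extents of an isotherm region
#'
#' Longitudinal extent is the maximum span of the largest connected
#' component along the probe axis; transverse extent is the maximum caliper
#' (support-function) width over all directions perpendicular to the axis.
#' Both are evaluated from the sub-cell interpolated surface points.
#'
#' @param region result of [extract_isotherm_region()].
#' @param probe_axis unit 3-vector; defaults to the insertion axis
#'   (0, 0, 1)/(0, 0, −1) direction.
#' @return list with `longitudinal_m`, `transverse_m`, `component` (label of
#'   the component measured), `boundary_clipped`.
#' @export
measure_axes <- function(region, probe_axis = c(0, 0, 1)) {
  pts <- region$points
  if (!sum(region$mask) || nrow(pts) == 0)
    stop("measure_axes: empty isotherm region", call. = FALSE)
  # largest component by cell count
  tab <- tabulate(region$labels[region$labels > 0])
  comp <- which.max(tab)
  pts <- pts[pts[, ncol(pts)] == comp, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("measure_axes: no surface points for the largest component",
         call. = FALSE)
  if (ncol(pts) == 3) {
    # axisymmetric (r, z, label): swept solid around the axis
    long <- diff(range(pts[, 2]))
    trans <- 2 * max(pts[, 1])
  } else {
    axis <- probe_axis / sqrt(sum(probe_axis^2))
    proj <- pts[, 1:3] %*% axis
    long <- diff(range(proj))
    # perpendicular plane basis
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    uv <- cbind(pts[, 1:3] %*% e1, pts[, 1:3] %*% e2)
    hull <- grDevices::chull(uv)
    hv <- uv[hull, , drop = FALSE]
    trans <- if (nrow(hv) == 1) 0 else max(stats::dist(hv))
  }
  list(longitudinal_m = long, transverse_m = trans, component = comp,
       boundary_clipped = region$boundary_clipped)
}

# point-in-convex-polygon (vertices in hull order); boundary counts as inside
in_convex_polygon <- function(poly, pts, eps = 1e-12) {
  nv <- nrow(poly)
  if (nv < 3) return(rep(FALSE, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  sgn <- 0
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    if (sgn == 0) sgn <- sign(sum(cr))
    inside <- inside & (sgn * cr >= -eps)
  }
  inside
}

#' Warm-zone volume inside the ice-ball hull
#'
#' Volume of cells warmer than `lethal_level` that lie inside the convex
#' hull of the `hull_level` (ice-ball) region. For the parallel-probe
#' geometry the hull is taken slice-wise: in every plane perpendicular to
#' the probe axis the 2-D convex hull of frozen-cell centers is formed and
#' warm cells inside it are counted. Captures both the interstitial pockets
#' of multi-probe arrays and the sub-lethal shell of the ice ball.
#'
#' @param T temperature field, °C.
#' @param grid the grid the field lives on.
#' @param hull_level ice-ball hull isotherm, °C (default 0).
#' @param lethal_level lethal threshold, °C (must be below `hull_level`).
#' @return Warm-zone volume, m^3.
#' @export
warm_zone_volume <- function(T, grid, hull_level = 0, lethal_level = -40) {
  stopifnot(inherits(grid, "sim_grid"))
  if (lethal_level >= hull_level)
    stop("warm_zone_volume: lethal_level must be below hull_level",
         call. = FALSE)
  if (grid$type == "axisymmetric") {
    # hull of a swept region is the disk of its outermost frozen radius
    d <- dim(T)
    rc <- grid$r_centers
    vol <- 0
    Vr <- grid$cell_volume
    for (j in seq_len(d[2])) {
      frozen <- which(T[, j] <= hull_level)
      if (!length(frozen)) next
      rmax <- max(rc[frozen])
      warm <- rc <= rmax & T[, j] > lethal_level
      vol <- vol + sum(Vr[warm])
    }
    return(vol)
  }
  d <- dim(T)
  ax <- grid_axes(grid)
  count <- 0L
  for (k in seq_len(d[3])) {
    sl <- T[, , k]
    fz <- which(sl <= hull_level, arr.ind = TRUE)
    if (nrow(fz) < 3) next
    xy <- cbind(ax[[1]][fz[, 1]], ax[[2]][fz[, 2]])
    hull <- grDevices::chull(xy)
    if (length(hull) < 3) next
    poly <- xy[hull, , drop = FALSE]
    wz <- which(sl > lethal_level, arr.ind = TRUE)
    if (!nrow(wz)) next
    wxy <- cbind(ax[[1]][wz[, 1]], ax[[2]][wz[, 2]])
    count <- count + sum(in_convex_polygon(poly, wxy))
  }
  count * grid$cell_volume
}

#' Connected ice-ball components over time
#'
#' Counts the 6-connected components of the at-or-below-`level` region in
#' each stored snapshot. Merge events are strict decreases of the count.
#'
#' @param trajectory a [run_simulation()] result.
#' @param level isotherm level, °C (default 0).
#' @return data.frame with columns `t`, `components`, `merge_event`.
#' @export
track_merge_events <- function(trajectory, level = 0) {
  stopifnot(inherits(trajectory, "cryo_trajectory"))
  grid <- trajectory$grid
  d3 <- if (grid$type == "cartesian") grid$shape else c(grid$shape, 1L)
  counts <- vapply(trajectory$snapshots, function(s) {
    lab <- .label_components(as.vector(s$T <= level), d3[1], d3[2], d3[3])
    as.integer(attr(lab, "n_components"))
  }, integer(1))
  data.frame(t = trajectory$times, components = counts,
             merge_event = c(FALSE, diff(counts) < 0))
}

#' Mean relative dimensional error between simulated and reference extents
#'
#' @param sim numeric vector of simulated dimensions (any unit).
#' @param ref numeric vector of reference dimensions, same length and unit,
#'   strictly positive.
#' @return Mean of the per-axis absolute relative errors, in percent.
#' @export
#' @examples
#' dimensional_error(c(2.5, 1.2), c(2.6, 1.25))
dimensional_error <- function(sim, ref) {
  if (length(sim) != length(ref))
    stop("dimensional_error: sim and ref must have equal length", call. = FALSE)
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("dimensional_error: reference dimensions must be > 0", call. = FALSE)
  mean(abs(sim - ref) / ref) * 100
}

#' Sample virtual thermocouples from stored snapshots
#'
#' Trilinear interpolation of temperature and damage fraction at fixed
#' points, one row per stored snapshot. For continuous 1 Hz traces pass the
#' points as `monitors` to [run_simulation()] instead; this helper reads
#' back whatever snapshot cadence the trajectory retained.
#'
#' @param trajectory a [run_simulation()] result.
#' @param points matrix/list of (x, y, z) coordinates, m.
#' @return data.frame: `t_s`, then `T<i>_C` and `theta<i>` per point.
#' @export
sample_thermocouples <- function(trajectory, points) {
  stopifnot(inherits(trajectory, "cryo_trajectory"))
  mon <- normalize_monitors(points, trajectory$grid)
  rows <- lapply(trajectory$snapshots, function(s)
    trace_row(s$t, s$T, s$alpha, mon, trajectory$grid))
  do.call(rbind, rows)
}

#' Ice-ball morphometrics table
#'
#' Per-isotherm metrics of a temperature field: caliper extents of the
#' largest connected region, interpolated and voxel volumes, component
#' count, and the warm-zone volume above that isotherm inside the 0 °C hull.
#'
#' @param T temperature field, °C (array of the grid's shape).
#' @param grid the grid the field lives on.
#' @param levels isotherm levels, °C.
#' @param probe_axis axis for the longitudinal direction (cartesian grids).
#' @return data.frame with one row per level.
#' @export
iceball_metrics <- function(T, grid, levels = c(0, -20, -40, -50),
                            probe_axis = c(0, 0, 1)) {
  rows <- lapply(levels, function(lv) {
    reg <- extract_isotherm_region(T, lv, grid)
    if (sum(reg$mask) == 0 || nrow(reg$points) == 0) {
      return(data.frame(level_C = lv, longitudinal_m = 0, transverse_m = 0,
                        volume_m3 = 0, volume_voxel_m3 = 0, components = 0L,
                        warm_zone_m3 = if (lv < 0)
                          warm_zone_volume(T, grid, 0, lv) else NA_real_,
                        boundary_clipped = FALSE))
    }
    axes <- measure_axes(reg, probe_axis)
    data.frame(level_C = lv,
               longitudinal_m = axes$longitudinal_m,
               transverse_m = axes$transverse_m,
               volume_m3 = reg$volume_m3,
               volume_voxel_m3 = reg$volume_voxel_m3,
               components = reg$n_components,
               warm_zone_m3 = if (lv < 0)
                 warm_zone_volume(T, grid, 0, lv) else NA_real_,
               boundary_clipped = reg$boundary_clipped)
  })
  do.call(rbind, rows)
}
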