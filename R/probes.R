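#' Single cryoprobe description
#'
#' A cylindrical probe defined by its entry point on the tissue surface, a
#' unit insertion axis (by convention (0, 0, −1): straight down), insertion
#' depth, the length of the distal actively cooled segment and the shaft
#' radius.
#'
#' @param entry_point 3-vector, m: where the shaft crosses the entry plane.
#' @param axis unit 3-vector: insertion direction.
#' @param insertion_depth m (> 0).
#' @param active_length m; length of the cooled distal segment,
#'   `0 < active_length <= insertion_depth`.
#' @param radius shaft radius, m (`0 < radius < insertion_depth`).
#' @return Object of class `cryo_probe`.
#' @export
probe <- function(entry_point = c(0, 0, 0), axis = c(0, 0, -1),
                  insertion_depth = 0.02, active_length = insertion_depth,
                  radius = 0.85e-3) {
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm == 0) stop("probe: axis must be a nonzero vector", call. = FALSE)
    axis <- axis / nrm
  }
  if (!(active_length > 0 && active_length <= insertion_depth))
    stop("probe: requires 0 < active_length <= insertion_depth", call. = FALSE)
  if (!(radius > 0 && radius < insertion_depth))
    stop("probe: requires 0 < radius < insertion_depth", call. = FALSE)
  structure(list(entry_point = entry_point, axis = axis,
                 insertion_depth = insertion_depth,
                 active_length = active_length, radius = radius),
            class = "cryo_probe")
}

#' Probe temperature load curve
#'
#' Three-segment piecewise-linear model of the probe surface temperature
#' during one freeze–thaw cycle: a linear ramp from `start_C` to the cooling
#' plateau over `ramp_s`, a hold at `plateau_C` until `freeze_s`, then a
#' linear thaw ramp to `thaw_C` over `thaw_s`, after which the temperature is
#' held at `thaw_C`. Continuous in time.
#'
#' @param start_C probe temperature at t = 0, °C.
#' @param plateau_C cooling plateau temperature, °C (< `start_C`).
#' @param ramp_s duration of the initial cooling ramp, s.
#' @param freeze_s end of the freeze phase, s (>= `ramp_s`).
#' @param thaw_C thaw target temperature, °C.
#' @param thaw_s duration of the thaw ramp, s.
#' @return Object of class `load_curve`.
#' @export
#' @examples
#' lc <- load_curve()
#' evaluate_load_curve(lc, c(0, 30, 61, 900))
load_curve <- function(start_C = 25, plateau_C = -150, ramp_s = 60,
                       freeze_s = 900, thaw_C = 20, thaw_s = 300) {
  if (!(plateau_C < start_C))
    stop("load_curve: plateau_C must lie below start_C", call. = FALSE)
  if (ramp_s < 0 || thaw_s < 0 || freeze_s < ramp_s)
    stop("load_curve: requires 0 <= ramp_s <= freeze_s and thaw_s >= 0",
         call. = FALSE)
  structure(list(start_C = start_C, plateau_C = plateau_C, ramp_s = ramp_s,
                 freeze_s = freeze_s, thaw_C = thaw_C, thaw_s = thaw_s),
            class = "load_curve")
}

#' Evaluate a probe load curve
#'
#' @param curve a [load_curve()] object.
#' @param t time, s (>= 0, vectorised).
#' @return Probe surface temperature, °C.
#' @export
evaluate_load_curve <- function(curve, t) {
  stopifnot(inherits(curve, "load_curve"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("evaluate_load_curve: t must be finite and >= 0", call. = FALSE)
  out <- numeric(length(t))
  r <- curve$ramp_s; f <- curve$freeze_s; th <- curve$thaw_s
  seg1 <- t <= r
  out[seg1] <- if (r > 0) {
    curve$start_C + (curve$plateau_C - curve$start_C) * t[seg1] / r
  } else curve$plateau_C
  seg2 <- t > r & t <= f
  out[seg2] <- curve$plateau_C
  seg3 <- t > f & t <= f + th
  out[seg3] <- if (th > 0) {
    curve$plateau_C + (curve$thaw_C - curve$plateau_C) * (t[seg3] - f) / th
  } else curve$thaw_C
  out[t > f + th] <- curve$thaw_C
  out
}

#' Build a probe layout
#'
#' Constructs the standard patterns, all probes parallel and inserted along
#' −z from the entry plane z = 0:
#' \describe{
#'   \item{single}{one probe at the lateral origin;}
#'   \item{five}{a center probe plus four probes at lateral distance
#'     `spacing` along ±x and ±y (annular arrangement);}
#'   \item{seven}{a center probe plus six on a hexagon of circumradius
#'     `spacing` ("plum-blossom");}
#'   \item{nine}{a 3×3 square matrix with nearest-neighbor distance
#'     `spacing`.}
#' }
#'
#' @param pattern one of `"single"`, `"five"`, `"seven"`, `"nine"`.
#' @param spacing probe spacing, m (required for multi-probe patterns;
#'   must exceed twice the probe radius).
#' @param depth insertion depth, m.
#' @param active_length cooled distal segment length, m
#'   (default: whole inserted portion).
#' @param radius probe shaft radius, m.
#' @return Object of class `probe_layout`.
#' @export
#' @examples
#' lay <- make_layout("nine", spacing = 0.01)
#' layout_positions(lay)
make_layout <- function(pattern = c("single", "five", "seven", "nine"),
                        spacing = NULL, depth = 0.02,
                        active_length = depth, radius = 0.85e-3) {
  pattern <- match.arg(pattern)
  if (pattern != "single") {
    if (is.null(spacing) || !is.finite(spacing))
      stop("make_layout: spacing is required for pattern '", pattern, "'",
           call. = FALSE)
    if (spacing <= 2 * radius)
      stop("make_layout: spacing (", spacing,
           " m) must exceed twice the probe radius (2 x ", radius, " m)",
           call. = FALSE)
  }
  xy <- switch(pattern,
    single = matrix(0, 1, 2),
    five = rbind(c(0, 0),
                 c(spacing, 0), c(-spacing, 0),
                 c(0, spacing), c(0, -spacing)),
    seven = rbind(c(0, 0),
                  t(sapply(0:5, function(i) {
                    a <- i * pi / 3
                    spacing * c(cos(a), sin(a))
                  }))),
    nine = as.matrix(expand.grid(x = spacing * (-1:1),
                                 y = spacing * (-1:1)))
  )
  probes <- lapply(seq_len(nrow(xy)), function(i)
    probe(entry_point = c(xy[i, 1], xy[i, 2], 0),
          insertion_depth = depth, active_length = active_length,
          radius = radius))
  probe_layout(pattern = pattern, spacing = if (pattern == "single") NA_real_
               else spacing, probes = probes)
}

#' Assemble a probe layout from explicit probes
#'
#' @param pattern pattern name (`"custom"` for free-form sets).
#' @param spacing nominal spacing, m (NA for single/custom).
#' @param probes list of [probe()] objects.
#' @return Object of class `probe_layout`.
#' @export
probe_layout <- function(pattern, spacing, probes) {
  expected <- c(single = 1L, five = 5L, seven = 7L, nine = 9L)
  if (pattern %in% names(expected) && length(probes) != expected[[pattern]])
    stop("probe_layout: pattern '", pattern, "' requires ",
         expected[[pattern]], " probes", call. = FALSE)
  if (length(probes) > 1) {
    pos <- t(vapply(probes, function(p) p$entry_point[1:2], numeric(2)))
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    rmax <- max(vapply(probes, function(p) p$radius, numeric(1)))
    if (min(d) < 2 * rmax)
      stop("probe_layout: probes overlap (min center distance ", min(d),
           " m < 2 x radius)", call. = FALSE)
  }
  structure(list(pattern = pattern, spacing = spacing, probes = probes),
            class = "probe_layout")
}

#' Lateral probe positions of a layout
#'
#' @param layout a [probe_layout()].
#' @return data.frame with columns `x_cm`, `y_cm`, `z_tip_cm`.
#' @export
layout_positions <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  do.call(rbind, lapply(layout$probes, function(p) {
    tip <- p$entry_point + p$axis * p$insertion_depth
    data.frame(x_cm = p$entry_point[1] * 100, y_cm = p$entry_point[2] * 100,
               z_tip_cm = tip[3] * 100)
  }))
}

#' Rasterize a probe layout onto a simulation grid
#'
#' Classifies grid cells into the actively cooled probe segment (these
#' receive the Dirichlet load-curve temperature) and the remaining shaft
#' cells (treated as thermally insulated). A cell belongs to a probe when its
#' center lies within the probe radius of the axis and within the inserted
#' segment; the active mask covers the distal `active_length` of each probe.
#'
#' @param layout a [probe_layout()].
#' @param grid a [sim_grid()] or [axi_grid()] (axisymmetric grids accept only
#'   a single on-axis probe).
#' @return list with logical arrays `active` and `shaft` (disjoint), each of
#'   the grid's shape.
#' @export
rasterize_layout <- function(layout, grid) {
  stopifnot(inherits(layout, "probe_layout"), inherits(grid, "sim_grid"))
  if (length(layout$probes) == 0) {
    d <- if (grid$type == "cartesian") grid$shape else grid$shape
    empty <- array(FALSE, d)
    return(list(active = empty, shaft = empty))
  }
  co <- grid_coords(grid)
  if (grid$type == "axisymmetric") {
    if (length(layout$probes) != 1)
      stop("rasterize_layout: axisymmetric grids support a single probe",
           call. = FALSE)
    p <- layout$probes[[1]]
    if (any(abs(p$entry_point[1:2]) > 1e-12) ||
        any(abs(p$axis - c(0, 0, -1)) > 1e-9))
      stop("rasterize_layout: axisymmetric probe must be on-axis, vertical",
           call. = FALSE)
    tip_z <- -p$insertion_depth
    inside <- co$r <= p$radius & co$z >= tip_z & co$z <= 0
    active <- inside & co$z <= tip_z + p$active_length
    if (p$insertion_depth > grid$extent[2])
      stop("rasterize_layout: probe extends below the domain", call. = FALSE)
  } else {
    active <- array(FALSE, grid$shape)
    inside <- array(FALSE, grid$shape)
    lo <- grid$origin; hi <- grid$origin + grid$extent
    for (p in layout$probes) {
      e <- p$entry_point
      if (any(abs(p$axis - c(0, 0, -1)) > 1e-9))
        stop("rasterize_layout: only vertical (0,0,-1) probe axes are rasterized",
             call. = FALSE)
      tip_z <- e[3] - p$insertion_depth
      if (e[1] - p$radius < lo[1] || e[1] + p$radius > hi[1] ||
          e[2] - p$radius < lo[2] || e[2] + p$radius > hi[2] ||
          tip_z < lo[3] || e[3] > hi[3] + 1e-12)
        stop("rasterize_layout: probe at (", e[1], ", ", e[2],
             ") lies outside the grid", call. = FALSE)
      r2 <- (co$x - e[1])^2 + (co$y - e[2])^2
      cyl <- r2 <= p$radius^2 & co$z >= tip_z & co$z <= e[3]
      inside <- inside | cyl
      active <- active | (cyl & co$z <= tip_z + p$active_length)
    }
  }
  if (!any(active))
    stop("rasterize_layout: no active cells captured; probe radius ",
         "is too small for the grid spacing", call. = FALSE)
  list(active = active, shaft = inside & !active)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("Probe layout '%s': %d probe(s)%s\n", x$pattern,
              length(x$probes),
              if (is.finite(x$spacing)) sprintf(", spacing %.1f cm",
                                                x$spacing * 100) else ""))
  invisible(x)
}
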