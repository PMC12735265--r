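#' Uniform Cartesian simulation grid
#'
#' Cell-centered uniform grid. The tissue block occupies
#' `origin + [0, shape*spacing]` on each axis; cell centers sit at
#' `origin + (i - 1/2) * spacing`. By convention probes are inserted along
#' −z from the entry plane z = 0, so the default origin places the top face
#' of the domain at z = 0 and centers the lateral extent on x = y = 0.
#'
#' @param spacing isotropic cell size, m (> 0).
#' @param shape integer 3-vector of cell counts (each >= 3).
#' @param origin 3-vector, m: position of the low corner of the domain.
#'   Default centers x/y on 0 and puts the top z-face at 0.
#' @return Object of class `sim_grid`.
#' @export
#' @examples
#' g <- sim_grid(0.002, c(20, 20, 20))
#' g$extent
sim_grid <- function(spacing, shape, origin = NULL) {
  shape <- as.integer(round(shape))
  if (!is.finite(spacing) || spacing <= 0)
    stop("sim_grid: spacing must be > 0", call. = FALSE)
  if (length(shape) != 3 || any(shape < 3))
    stop("sim_grid: shape must be 3 integers, each >= 3", call. = FALSE)
  ext <- shape * spacing
  if (is.null(origin)) origin <- c(-ext[1] / 2, -ext[2] / 2, -ext[3])
  structure(list(type = "cartesian", spacing = spacing, shape = shape,
                 origin = origin, extent = ext,
                 n = prod(shape), cell_volume = spacing^3),
            class = "sim_grid")
}

#' Axisymmetric (r, z) simulation grid
#'
#' Cylindrical-coordinate grid for a single on-axis probe: `nr` radial rings
#' of width `spacing` starting at the axis and `nz` axial cells with the top
#' face at z = 0. Cell volumes and face areas carry the 2*pi*r factors.
#'
#' @param spacing cell size, m, shared by r and z.
#' @param nr,nz radial / axial cell counts (each >= 3).
#' @return Object of class `sim_grid` with `type = "axisymmetric"`.
#' @export
axi_grid <- function(spacing, nr, nz) {
  nr <- as.integer(round(nr)); nz <- as.integer(round(nz))
  if (!is.finite(spacing) || spacing <= 0)
    stop("axi_grid: spacing must be > 0", call. = FALSE)
  if (nr < 3 || nz < 3)
    stop("axi_grid: nr and nz must each be >= 3", call. = FALSE)
  rc <- (seq_len(nr) - 0.5) * spacing
  structure(list(type = "axisymmetric", spacing = spacing,
                 shape = c(nr, nz), origin = c(0, -nz * spacing),
                 extent = c(nr * spacing, nz * spacing),
                 n = nr * nz, r_centers = rc,
                 cell_volume = 2 * pi * rc * spacing^2),
            class = "sim_grid")
}

# cell-center coordinates along each axis
grid_axes <- function(grid) {
  h <- grid$spacing
  if (grid$type == "cartesian") {
    lapply(1:3, function(a)
      grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * h)
  } else {
    list(r = grid$r_centers, z = grid$origin[2] + (seq_len(grid$shape[2]) - 0.5) * h)
  }
}

# full coordinate arrays (same shape as the field) for mask building
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  if (grid$type == "cartesian") {
    s <- grid$shape
    list(x = array(rep(ax[[1]], times = s[2] * s[3]), dim = s),
         y = array(rep(rep(ax[[2]], each = s[1]), times = s[3]), dim = s),
         z = array(rep(ax[[3]], each = s[1] * s[2]), dim = s))
  } else {
    s <- grid$shape
    list(r = array(rep(ax$r, times = s[2]), dim = s),
         z = array(rep(ax$z, each = s[1]), dim = s))
  }
}

#' @export
print.sim_grid <- function(x, ...) {
  if (x$type == "cartesian") {
    cat(sprintf("Cartesian grid: %d x %d x %d cells, h = %g mm, extent %s cm\n",
                x$shape[1], x$shape[2], x$shape[3], x$spacing * 1e3,
                paste(sprintf("%.1f", x$extent * 100), collapse = " x ")))
  } else {
    cat(sprintf("Axisymmetric grid: %d (r) x %d (z) cells, h = %g mm, R = %.1f cm, depth %.1f cm\n",
                x$shape[1], x$shape[2], x$spacing * 1e3,
                x$extent[1] * 100, x$extent[2] * 100))
  }
  invisible(x)
}
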