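#' Packaged default configuration
#'
#' The full default parameter set: the packaged tissue property table, the
#' damage kinetics constants and the single-probe scenario. All user-facing
#' keys carry explicit unit suffixes (`_cm`, `_mm`, `_C`, `_s`); internal
#' computation is strictly SI.
#'
#' @return Nested configuration list (see [load_config()]).
#' @export
default_config <- function() {
  list(
    domain = list(mode = "cartesian", size_cm = c(8, 8, 8),
                  radius_cm = 4, depth_cm = 8, spacing_mm = 1),
    tissue = list(k_u = 0.5, k_f = 2, c_u = 3600, c_f = 1800,
                  rho_u = 1000, rho_f = 998, Q_lf_MJ_m3 = 250,
                  T_mu_C = -1, T_ml_C = -8,
                  w_b_per_s = 5e-4, rho_b = 1000, c_b = 3600,
                  T_b_C = 37, Q_m_W_m3 = 4200),
    damage = list(T_dc_C = -20, t_dc_s = 60, T_nc_C = -50, L_dc_kJ_kg = 250,
                  apply_damage_enthalpy = FALSE),
    layout = list(pattern = "single", spacing_cm = 1),
    probe = list(depth_cm = 2, active_length_cm = 2, radius_mm = 0.85),
    loadcurve = list(start_C = 25, plateau_C = -150, ramp_s = 60,
                     freeze_s = 900, thaw_C = 20, thaw_s = 300),
    solver = list(dt_s = 0.5, end_time_s = 900, initial_C = 37,
                  frozen_shutdown = TRUE, picard_tol_C = 1e-3,
                  lin_tol = 1e-8, snapshot_s = 100, trace_s = 1,
                  method = "implicit"),
    monitors = list()
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref))
      stop("config: unknown key '", here, "'", call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && nm != "monitors") {
      if (!is.list(cfg[[nm]]))
        stop("config: key '", here, "' must be a mapping", call. = FALSE)
      check_known_keys(cfg[[nm]], ref[[nm]], here)
    }
  }
  invisible(TRUE)
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration, merges it over the packaged defaults
#' (Table-of-defaults tissue constants, damage kinetics constants, the
#' single-probe scenario), rejects unknown keys, normalises units to SI and
#' runs the physical-consistency checks of the parameter constructors.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides optional named list merged over the file contents
#'   (same structure as the file).
#' @return Resolved configuration list (class `cryo_config`) with the
#'   original unit-suffixed keys; pass to [build_scenario()] or
#'   [simulate_config()].
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_cfg <- function(base, user) {
    # modifyList merges named mappings only; the monitors key holds an
    # unnamed list of points and is replaced wholesale
    mon <- if ("monitors" %in% names(user)) user$monitors else base$monitors
    out <- utils::modifyList(base, user[setdiff(names(user), "monitors")])
    out$monitors <- mon
    out
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config: file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config: top level must be a mapping",
                             call. = FALSE)
    check_known_keys(user, cfg)
    cfg <- merge_cfg(cfg, user)
  }
  if (!is.null(overrides)) {
    check_known_keys(overrides, cfg)
    cfg <- merge_cfg(cfg, overrides)
  }
  cfg$source <- path
  class(cfg) <- "cryo_config"
  build_scenario(cfg)  # run all validation; discard the objects
  cfg
}

#' Materialize simulation objects from a resolved configuration
#'
#' @param cfg a `cryo_config` list from [load_config()] or [preset()].
#' @return list with `grid`, `layout`, `tissue`, `damage`, `curve`,
#'   `control`, `monitors` (matrix in m, or NULL).
#' @export
build_scenario <- function(cfg) {
  tp <- cfg$tissue
  tissue <- tissue_params(k_u = tp$k_u, k_f = tp$k_f, c_u = tp$c_u,
                          c_f = tp$c_f, rho_u = tp$rho_u, rho_f = tp$rho_f,
                          Q_lf = tp$Q_lf_MJ_m3 * 1e6,
                          T_mu = tp$T_mu_C, T_ml = tp$T_ml_C,
                          w_b = tp$w_b_per_s, rho_b = tp$rho_b, c_b = tp$c_b,
                          T_b = tp$T_b_C, Q_m = tp$Q_m_W_m3)
  dm <- cfg$damage
  damage <- damage_params(T_dc = dm$T_dc_C, t_dc = dm$t_dc_s, T_nc = dm$T_nc_C,
                          L_dc = dm$L_dc_kJ_kg * 1e3,
                          apply_damage_enthalpy = dm$apply_damage_enthalpy)
  h <- cfg$domain$spacing_mm * 1e-3
  if (identical(cfg$domain$mode, "axisymmetric")) {
    grid <- axi_grid(h, nr = round(cfg$domain$radius_cm * 1e-2 / h),
                     nz = round(cfg$domain$depth_cm * 1e-2 / h))
  } else if (identical(cfg$domain$mode, "cartesian")) {
    size <- cfg$domain$size_cm * 1e-2
    grid <- sim_grid(h, shape = round(size / h))
  } else {
    stop("config: domain.mode must be 'cartesian' or 'axisymmetric'",
         call. = FALSE)
  }
  layout <- make_layout(cfg$layout$pattern,
                        spacing = cfg$layout$spacing_cm * 1e-2,
                        depth = cfg$probe$depth_cm * 1e-2,
                        active_length = cfg$probe$active_length_cm * 1e-2,
                        radius = cfg$probe$radius_mm * 1e-3)
  lc <- cfg$loadcurve
  curve <- load_curve(start_C = lc$start_C, plateau_C = lc$plateau_C,
                      ramp_s = lc$ramp_s, freeze_s = lc$freeze_s,
                      thaw_C = lc$thaw_C, thaw_s = lc$thaw_s)
  sv <- cfg$solver
  control <- solver_config(dt = sv$dt_s, end_time = sv$end_time_s,
                           initial_C = sv$initial_C,
                           frozen_shutdown = sv$frozen_shutdown,
                           picard_tol = sv$picard_tol_C, lin_tol = sv$lin_tol,
                           snapshot_interval = sv$snapshot_s,
                           trace_interval = sv$trace_s, method = sv$method)
  monitors <- NULL
  if (length(cfg$monitors)) {
    monitors <- if (is.matrix(cfg$monitors)) cfg$monitors * 1e-2 else
      do.call(rbind, lapply(cfg$monitors, function(p) unlist(p) * 1e-2))
  }
  list(grid = grid, layout = layout, tissue = tissue, damage = damage,
       curve = curve, control = control, monitors = monitors)
}

#' Scenario presets
#'
#' Named configurations of the packaged study scenarios. Phantom presets
#' emulate bench experiments on tissue-mimicking specimens at room
#' temperature (initial 25 °C); the liver preset uses core body temperature
#' (37 °C). All use 2 cm insertion depth, a 900 s freeze and, for
#' multi-probe patterns, 1 cm probe spacing. The single-probe phantom runs
#' on the fast axisymmetric grid; multi-probe presets are fully 3-D. Default
#' monitor points mirror the four-channel thermocouple layout: at the main
#' probe, 5 mm from it, at an auxiliary probe position, and at a distal
#' reference.
#'
#' @param name one of `"phantom-single"`, `"phantom-five"`,
#'   `"phantom-seven"`, `"phantom-nine"`, `"liver-nine"`.
#' @param overrides optional named list merged over the preset.
#' @return A `cryo_config` list (see [load_config()]).
#' @export
#' @examples
#' cfg <- preset("phantom-nine")
#' cfg$layout$pattern
preset <- function(name, overrides = NULL) {
  known <- c("phantom-single", "phantom-five", "phantom-seven",
             "phantom-nine", "liver-nine")
  if (!name %in% known)
    stop("preset: unknown preset '", name, "' (expected one of ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  pattern <- sub("^(phantom|liver)-", "", name)
  initial <- if (grepl("^liver", name)) 37 else 25
  ov <- list(
    domain = if (pattern == "single") {
      list(mode = "axisymmetric", radius_cm = 4, depth_cm = 8,
           spacing_mm = 1)
    } else {
      list(mode = "cartesian", size_cm = c(8, 8, 6.4), spacing_mm = 2)
    },
    layout = list(pattern = pattern, spacing_cm = 1),
    loadcurve = list(start_C = initial),
    solver = list(end_time_s = 900, initial_C = initial),
    monitors = {
      aux <- if (pattern == "single") c(1, 0, -1) else c(1, 0, -1)
      list(c(0, 0, -1), c(0.5, 0, -1), aux, c(3, 0, -1))
    }
  )
  cfg <- utils::modifyList(default_config(),
                           ov[setdiff(names(ov), "monitors")])
  cfg$monitors <- ov$monitors
  cfg$source <- paste0("preset:", name)
  class(cfg) <- "cryo_config"
  if (!is.null(overrides)) {
    check_known_keys(overrides, default_config())
    mon <- if ("monitors" %in% names(overrides)) overrides$monitors else
      cfg$monitors
    cfg <- utils::modifyList(cfg, overrides[setdiff(names(overrides),
                                                    "monitors")])
    cfg$monitors <- mon
    class(cfg) <- "cryo_config"
  }
  build_scenario(cfg)
  cfg
}

#' Run a simulation from a configuration
#'
#' @param cfg a `cryo_config` (from [load_config()] or [preset()]).
#' @param verbose print progress.
#' @return A `cryo_trajectory` (see [run_simulation()]) with the resolved
#'   configuration attached as attribute `config`.
#' @export
simulate_config <- function(cfg, verbose = FALSE) {
  sc <- build_scenario(cfg)
  tr <- run_simulation(sc$grid, sc$layout, tissue = sc$tissue,
                       damage = sc$damage, curve = sc$curve,
                       control = sc$control, monitors = sc$monitors,
                       verbose = verbose)
  attr(tr, "config") <- cfg
  tr
}

# ---- result serialization ----------------------------------------------

#' Write a field snapshot as a legacy VTK structured-points file
#'
#' Cell-centered fields are exported as point data at the cell centers.
#' Axisymmetric fields are written as an (nr, nz, 1) plane.
#'
#' @param snapshot one element of a trajectory's `snapshots` list.
#' @param grid the simulation grid.
#' @param tissue tissue parameters (for the frozen-fraction field).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(snapshot, grid, tissue, path) {
  d <- if (grid$type == "cartesian") grid$shape else c(grid$shape, 1L)
  h <- grid$spacing
  orig <- if (grid$type == "cartesian") grid$origin + h / 2 else
    c(h / 2, grid$origin[2] + h / 2, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cryosim snapshot t=%g s", snapshot$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", orig[1], orig[2],
                       if (grid$type == "cartesian") orig[3] else 0),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d))), con)
  emit <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(vals, format = "g", digits = 7),
                     collapse = " "), con)
  }
  emit("T", as.vector(snapshot$T))
  emit("theta_d", as.vector(pmin(snapshot$alpha, 1)))
  emit("frozen_fraction", frozen_fraction(as.vector(snapshot$T), tissue))
  invisible(path)
}

#' Read back a legacy VTK structured-points snapshot
#'
#' Minimal parser for the files produced by [write_vtk_snapshot()].
#'
#' @param path VTK file path.
#' @return list with `dims`, `origin`, `spacing`, and one array per scalar
#'   field.
#' @export
read_vtk_snapshot <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
    ln[grep("^DIMENSIONS", ln)])), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "",
    ln[grep("^ORIGIN", ln)])), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
    ln[grep("^SPACING", ln)])), "\\s+")[[1]])
  out <- list(dims = dims, origin = origin, spacing = spacing[1])
  sc <- grep("^SCALARS", ln)
  for (s in sc) {
    name <- strsplit(ln[s], "\\s+")[[1]][2]
    vals <- as.numeric(strsplit(trimws(ln[s + 2]), "\\s+")[[1]])
    out[[name]] <- array(vals, dims)
  }
  out
}

#' Write simulation outputs to a directory
#'
#' Emits one VTK snapshot per stored time, the monitor traces and final
#' ice-ball metrics as CSV, and a JSON run manifest containing the fully
#' resolved configuration (sufficient to re-run the scenario
#' deterministically) and the package version.
#'
#' @param trajectory a `cryo_trajectory` from [simulate_config()].
#' @param out_dir output directory (created if missing).
#' @param run_id stem used in file names.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(trajectory, out_dir, run_id = "run") {
  cfg <- attr(trajectory, "config")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("write_outputs: cannot create directory: ", out_dir, call. = FALSE)
  files <- character(0)
  for (i in seq_along(trajectory$snapshots)) {
    s <- trajectory$snapshots[[i]]
    f <- file.path(out_dir, sprintf("%s_t%06.0f.vtk", run_id, s$t))
    write_vtk_snapshot(s, trajectory$grid, trajectory$tissue, f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, paste0(run_id, "_traces.csv"))
  utils::write.csv(trajectory$traces, f, row.names = FALSE)
  files <- c(files, f)
  ax <- if (trajectory$grid$type == "cartesian") c(0, 0, 1) else c(0, 0, 1)
  metrics <- iceball_metrics(trajectory$final$T, trajectory$grid,
                             probe_axis = ax)
  f <- file.path(out_dir, paste0(run_id, "_metrics.csv"))
  utils::write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- list(
    package = "cryosim",
    version = as.character(utils::packageVersion("cryosim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    config_digest = if (!is.null(cfg$source) && !is.null(cfg) &&
                          file.exists(cfg$source %||% ""))
      unname(tools::md5sum(cfg$source)) else NULL,
    outputs = basename(files))
  f <- file.path(out_dir, paste0(run_id, "_manifest.json"))
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- verification suite -------------------------------------------------

#' Run the analytic verification suite
#'
#' Three desk-scale checks of the transient solver against closed forms:
#' a 1-D two-phase freezing run versus the Neumann/Stefan front position,
#' a conduction-free run versus the lumped perfusion relaxation, and the
#' uniform perfusion/metabolism steady state.
#'
#' @param quick logical; use the reduced problem sizes (default).
#' @return list of check results, each with `name`, `value`, `reference`,
#'   `tol`, `pass`; overall flag in attribute `pass`.
#' @export
validate_oracles <- function(quick = TRUE) {
  checks <- list()
  # 1-D Stefan front (sharp-interface tissue: narrow mushy interval)
  h <- if (quick) 1e-3 else 5e-4
  t_end <- if (quick) 300 else 600
  tis <- tissue_params(T_mu = 0, T_ml = -0.2, w_b = 0, Q_m = 0)
  setup <- stefan_setup(-150, 25, 0, tis)
  sol <- solve_stefan_1d(tis, wall_C = -150, initial_C = 25, h = h,
                         t_end = t_end, length_m = 0.08)
  x_num <- sol$front_m
  x_ref <- stefan_front_position(setup, t_end)
  checks$stefan <- list(name = "stefan_front",
                        value = x_num, reference = x_ref, tol = 0.02,
                        pass = abs(x_num - x_ref) / x_ref < 0.02)
  # conduction-free perfusion relaxation
  lum <- solve_lumped_check(t_end = 600, dt = 1)
  checks$lumped <- list(name = "lumped_perfusion",
                        value = lum$num, reference = lum$ref, tol = 0.05,
                        pass = abs(lum$num - lum$ref) < 0.05)
  # uniform steady state T_b + Q_m / (w_b rho_b c_b)
  tp <- tissue_params()
  Tss <- tp$T_b + tp$Q_m / (tp$w_b * tp$rho_b * tp$c_b)
  lum2 <- solve_lumped_check(t_end = 20000, dt = 50, T0 = Tss)
  checks$steady <- list(name = "uniform_steady_state",
                        value = lum2$num, reference = Tss, tol = 0.05,
                        pass = abs(lum2$num - Tss) < 0.05)
  attr(checks, "pass") <- all(vapply(checks, `[[`, logical(1), "pass"))
  checks
}

# 1-D freezing slab driven through the solver's 3-D kernel (pseudo-1D grid);
# returns the interpolated front position at t_end
solve_stefan_1d <- function(tissue, wall_C, initial_C, h, t_end,
                            length_m = 0.08, dt = 0.5) {
  n <- round(length_m / h)
  g <- sim_grid(h, c(n, 3, 3), origin = c(0, 0, -3 * h))
  # the "probe" is the whole first-cell wall layer: emulate with a custom
  # one-cell-thick slab probe via direct mask injection
  masks <- list(active = array(FALSE, c(n, 3, 3)),
                shaft = array(FALSE, c(n, 3, 3)))
  masks$active[1, , ] <- TRUE
  geom <- fv_geometry(g, masks)
  curve <- load_curve(start_C = initial_C, plateau_C = wall_C, ramp_s = 0,
                      freeze_s = t_end + 1, thaw_C = initial_C,
                      thaw_s = 1)
  ctrl <- solver_config(dt = dt, end_time = t_end, initial_C = initial_C,
                        frozen_shutdown = FALSE)
  Tarr <- array(initial_C, c(n, 3, 3))
  Tarr[1, , ] <- wall_C
  t <- 0
  nsteps <- round(t_end / dt)
  for (s in seq_len(nsteps)) {
    st <- step_implicit(Tarr, t, geom, tissue, curve, ctrl)
    Tarr <- st$T
    t <- t + dt
  }
  Tmid <- Tarr[, 2, 2]
  xc <- (seq_len(n) - 0.5) * h - 0.5 * h  # wall layer center at x = 0
  level <- (tissue$T_mu + tissue$T_ml) / 2
  below <- which(Tmid <= level)
  i <- max(below)
  frac <- (level - Tmid[i]) / (Tmid[i + 1] - Tmid[i])
  list(front_m = xc[i] + frac * h, T = Tmid, x = xc)
}

# conduction-free Pennes relaxation on a tiny grid vs the closed form
solve_lumped_check <- function(t_end, dt, T0 = 30) {
  tis <- tissue_params(k_u = 1e-9, k_f = 1e-9)
  g <- sim_grid(1e-3, c(3, 3, 3))
  masks <- list(active = array(FALSE, c(3, 3, 3)),
                shaft = array(FALSE, c(3, 3, 3)))
  geom <- fv_geometry(g, masks)
  curve <- load_curve(start_C = T0, plateau_C = -150, ramp_s = 60,
                      freeze_s = t_end + 1, thaw_C = 20, thaw_s = 10)
  ctrl <- solver_config(dt = dt, end_time = t_end, initial_C = T0,
                        frozen_shutdown = FALSE)
  Tarr <- array(T0, c(3, 3, 3))
  t <- 0
  for (s in seq_len(round(t_end / dt))) {
    st <- step_implicit(Tarr, t, geom, tis, curve, ctrl)
    Tarr <- st$T
    t <- t + dt
  }
  list(num = Tarr[2, 2, 2],
       ref = lumped_perfusion_temperature(t_end, tis, T0))
}
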