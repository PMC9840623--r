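#' Validate acquisition frame timing
#'
#' Computes the derived frame timing quantities and checks that the
#' requested stroboscopic peak-to-peak interval is compatible with placing
#' one pulse at the end of the odd frame and one at the start of the even
#' frame: the interval must be positive and strictly smaller than the total
#' frame time, and must accommodate the pulse durations.
#'
#' @param exposure_ms Camera exposure, ms.
#' @param dead_time_ms Camera dead time, ms.
#' @param dt_ms Optional peak-to-peak interval to validate, ms.
#' @param pulse_405_ms Activation (405 nm) pulse duration, ms.
#' @param pulse_561_ms Excitation (561 nm) pulse duration, ms.
#' @return Object of class `frame_timing`: `exposure_ms`, `dead_time_ms`,
#'   `total_frame_ms`, `frame_rate_hz`, `pulse_405_ms`, `pulse_561_ms`,
#'   `dt_peak_to_peak_ms`.
#' @export
validate_timing <- function(exposure_ms, dead_time_ms, dt_ms = NULL,
                            pulse_405_ms = 1, pulse_561_ms = 0.5) {
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  if (dead_time_ms < 0) stop("dead_time_ms must be >= 0")
  total <- exposure_ms + dead_time_ms
  if (!is.null(dt_ms)) {
    if (dt_ms <= 0) stop("dt_ms must be > 0")
    if (dt_ms >= total)
      stop(sprintf(
        "dt = %g ms is incompatible with a total frame time of %g ms (pairing impossible)",
        dt_ms, total))
    if (dt_ms < pulse_561_ms)
      stop("dt_ms cannot be shorter than the excitation pulse")
  }
  structure(list(exposure_ms = exposure_ms, dead_time_ms = dead_time_ms,
                 total_frame_ms = total, frame_rate_hz = 1000 / total,
                 pulse_405_ms = pulse_405_ms, pulse_561_ms = pulse_561_ms,
                 dt_peak_to_peak_ms = dt_ms),
            class = "frame_timing")
}

#' @export
print.frame_timing <- function(x, ...) {
  cat(sprintf("frame timing: %g ms exposure + %g ms dead time = %g ms (~%.0f Hz)\n",
              x$exposure_ms, x$dead_time_ms, x$total_frame_ms,
              x$frame_rate_hz))
  if (!is.null(x$dt_peak_to_peak_ms))
    cat(sprintf("  peak-to-peak dt = %g ms\n", x$dt_peak_to_peak_ms))
  invisible(x)
}

loc_required_cols <- c("frame", "x_nm", "y_nm", "amplitude", "background",
                       "sigma_x_nm", "sigma_y_nm")

#' Read / write localization tables
#'
#' Delimited-text tables in the standard dialect with header
#' `frame,x_nm,y_nm,amplitude,background,sigma_x_nm,sigma_y_nm,pair_id`.
#' Unknown extra columns are preserved; missing required columns raise a
#' schema error naming them. Round-trips are lossless.
#'
#' @param path File path.
#' @return A `data.table` localization table.
#' @export
read_localizations <- function(path) {
  tb <- data.table::fread(path, na.strings = c("", "NA"))
  miss <- setdiff(loc_required_cols, names(tb))
  if (length(miss))
    stop("localization table is missing required columns: ",
         paste(miss, collapse = ", "))
  if (!"pair_id" %in% names(tb)) tb[, pair_id := NA_character_]
  tb
}

#' @rdname read_localizations
#' @param table Localization table to write.
#' @export
write_localizations <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Nested configuration for the end-to-end pipelines, schema-checked before
#' any stage runs. May be loaded from a YAML file with [read_run_config()].
#'
#' @param mode `"smdm"` or `"spt"`.
#' @param dt_ms Displacement interval: peak-to-peak time (SMdM) or frame
#'   time (SPT), ms.
#' @param seed Root RNG seed.
#' @param r_max_nm SMdM pairing radius, nm.
#' @param n_components Components for the displacement fits.
#' @param segmentation List: `alpha_density`, `min_points`, `max_dim_nm`.
#' @param map List: `grid_nm`, `min_count`.
#' @param drift List: `enabled`, `segment_len_frames`.
#' @param spt List: `link_radius_nm`, `min_len`, `max_len`.
#' @param pole_fraction Fraction of cell length per pole region.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("smdm", "spt"), dt_ms = 1.5, seed = 1L,
                       r_max_nm = 600, n_components = 1,
                       segmentation = list(), map = list(), drift = list(),
                       spt = list(), pole_fraction = 0.2) {
  mode <- match.arg(mode)
  seg <- utils::modifyList(
    list(alpha_density = 2, min_points = 300, max_dim_nm = c(4000, 1500)),
    segmentation)
  mp <- utils::modifyList(list(grid_nm = 50, min_count = 20), map)
  dr <- utils::modifyList(list(enabled = FALSE, segment_len_frames = 2000),
                          drift)
  sp <- utils::modifyList(list(link_radius_nm = 800, min_len = 5,
                               max_len = 30), spt)
  if (dt_ms <= 0) stop("dt_ms must be > 0")
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  if (pole_fraction <= 0 || pole_fraction >= 0.5)
    stop("pole_fraction must lie in (0, 0.5)")
  structure(list(mode = mode, dt_ms = dt_ms, seed = as.integer(seed),
                 r_max_nm = r_max_nm, n_components = n_components,
                 segmentation = seg, map = mp, drift = dr, spt = sp,
                 pole_fraction = pole_fraction, schema_version = 1L),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

fit_or_null <- function(r, dt, r_max, n_components, min_n = 50) {
  if (length(r) < min_n) return(NULL)
  tryCatch(
    fit_displacement_mle(r, n_components = n_components, dt = dt,
                         r_max = r_max, min_n = min_n),
    error = function(e) NULL)
}

fit_summary <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(D = fit$components$D, f = fit$components$f, b = fit$b,
       loglik = fit$loglik, n = fit$n, converged = fit$converged)
}

#' Run the end-to-end SMdM analysis
#'
#' Stages: (optional) drift correction, Voronoi cell segmentation, per-cell
#' alignment, pole/middle region assignment, stroboscopic displacement
#' extraction in the aligned cell frame, displacement MLE fits for the whole
#' cell and each region, and 50 nm diffusivity map reconstruction. Every
#' input row is accounted for: member of an accepted cell, of a rejected
#' cluster, or background.
#'
#' @param table Localization table (or a path readable by
#'   [read_localizations()]).
#' @param config A [run_config()] with `mode = "smdm"`.
#' @param out_dir Optional output directory; when given, the per-cell report
#'   (JSON), summary table (CSV) and diffusivity maps (TIFF) are written.
#' @return A report list: `cells` (per accepted cell: fits, map, region
#'   labels), `rejected` (clusters with reasons), `accounting`, `config`.
#' @export
run_smdm_pipeline <- function(table, config = run_config("smdm"),
                              out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$mode == "smdm")
  if (is.character(table)) table <- read_localizations(table)
  tb <- data.table::as.data.table(table)
  set.seed(config$seed)
  report <- list(schema_version = config$schema_version,
                 config = unclass(config), cells = list(),
                 rejected = list(),
                 accounting = list(n_rows = nrow(tb), assigned = 0L,
                                   rejected_cluster = 0L, background = 0L))
  if (!nrow(tb)) {
    report$accounting$background <- 0L
    return(finish_report(report, out_dir))
  }
  if (isTRUE(config$drift$enabled)) {
    dc <- estimate_and_apply_drift(tb, config$drift$segment_len_frames)
    tb <- dc$table
    report$drift <- dc$drift
  }
  clusters <- segment_cells(tb,
                            alpha_density = config$segmentation$alpha_density,
                            min_points = config$segmentation$min_points,
                            max_dim_nm = config$segmentation$max_dim_nm)
  in_cluster <- integer(0)
  cell_id <- 0L
  for (cl in clusters) {
    if (!cl$accepted) {
      report$rejected[[length(report$rejected) + 1L]] <-
        list(n_points = length(cl$indices), reason = cl$reason)
      report$accounting$rejected_cluster <-
        report$accounting$rejected_cluster + length(cl$indices)
      in_cluster <- c(in_cluster, cl$indices)
      next
    }
    cell_id <- cell_id + 1L
    in_cluster <- c(in_cluster, cl$indices)
    report$accounting$assigned <-
      report$accounting$assigned + length(cl$indices)
    al <- if (is.null(cl$aligned)) align_cell(cl) else cl
    regions <- assign_regions(al, config$pole_fraction)
    # displacements are extracted in the aligned cell frame
    sub <- tb[al$indices]
    cell_tab <- data.table::data.table(
      frame = sub$frame, x_nm = al$aligned[, 1], y_nm = al$aligned[, 2])
    ds <- extract_displacements(cell_tab, dt = config$dt_ms,
                                r_max = config$r_max_nm)
    # region of a displacement = region of its starting position
    reg_of <- region_of_displacement(ds, regions, al)
    fits <- list(
      whole = fit_summary(fit_or_null(ds$r, config$dt_ms, config$r_max_nm,
                                      config$n_components)),
      middle = fit_summary(fit_or_null(ds$r[reg_of == "middle"],
                                       config$dt_ms, config$r_max_nm,
                                       config$n_components)),
      pole_left = fit_summary(fit_or_null(ds$r[reg_of == "pole_left"],
                                          config$dt_ms, config$r_max_nm,
                                          config$n_components)),
      pole_right = fit_summary(fit_or_null(ds$r[reg_of == "pole_right"],
                                           config$dt_ms, config$r_max_nm,
                                           config$n_components)))
    map <- build_diffusion_map(ds, grid_nm = config$map$grid_nm,
                               min_count = config$map$min_count)
    report$cells[[cell_id]] <- list(
      cell = cell_id, n_points = length(cl$indices),
      rotation_angle = al$rotation_angle,
      centroid = as.numeric(al$centroid),
      length_nm = regions$length,
      n_displacements = nrow(ds),
      region_counts = as.list(table(regions$labels)),
      fits = fits, map = map)
  }
  report$accounting$background <- nrow(tb) - length(unique(in_cluster))
  finish_report(report, out_dir)
}

region_of_displacement <- function(ds, regions, al) {
  if (!nrow(ds)) return(character(0))
  x <- ds$x0
  lo <- regions$breaks[1]; hi <- regions$breaks[2]
  ifelse(x < lo, "pole_left", ifelse(x > hi, "pole_right", "middle"))
}

#' Run the end-to-end SPT analysis
#'
#' Links localizations into trajectories and fits the pooled step-size
#' distribution with the untruncated multi-component model.
#'
#' @inheritParams run_smdm_pipeline
#' @param config A [run_config()] with `mode = "spt"`; `dt_ms` is the frame
#'   interval.
#' @return Report list: `n_trajectories`, `n_steps`, `fit`, `trajectories`.
#' @export
run_spt_pipeline <- function(table, config = run_config("spt", dt_ms = 30),
                             out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$mode == "spt")
  if (is.character(table)) table <- read_localizations(table)
  tb <- data.table::as.data.table(table)
  set.seed(config$seed)
  trajs <- link_trajectories(tb, link_radius = config$spt$link_radius_nm,
                             min_len = config$spt$min_len,
                             max_len = config$spt$max_len)
  steps <- trajectory_steps(trajs)
  fit <- if (length(steps) >= 200)
    fit_trajectory_displacements(steps, dt = config$dt_ms,
                                 n_components = config$n_components)
  else NULL
  report <- list(schema_version = config$schema_version,
                 config = unclass(config),
                 n_trajectories = if (nrow(trajs)) length(unique(trajs$traj_id)) else 0L,
                 n_steps = length(steps),
                 note = if (length(steps) < 200)
                   "too few pooled steps for a fit" else NULL,
                 fit = fit_summary(fit),
                 trajectories = trajs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(trajs, file.path(out_dir, "trajectories.csv"))
    jsonlite::write_json(report[setdiff(names(report), "trajectories")],
                         file.path(out_dir, "spt_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

finish_report <- function(report, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    slim <- report
    slim$cells <- lapply(report$cells, function(cc) {
      cc$map <- list(n_valid = sum(cc$map$valid),
                     grid_nm = cc$map$grid_nm)
      cc
    })
    jsonlite::write_json(slim, file.path(out_dir, "smdm_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (length(report$cells)) {
      summ <- data.table::rbindlist(lapply(report$cells, function(cc) {
        data.table::data.table(
          cell = cc$cell, n_points = cc$n_points,
          rotation_angle = cc$rotation_angle,
          n_displacements = cc$n_displacements,
          D_whole = if (!is.null(cc$fits$whole)) cc$fits$whole$D[1] else NA_real_)
      }))
      data.table::fwrite(summ, file.path(out_dir, "cells_summary.csv"))
      for (cc in report$cells)
        if (sum(cc$map$valid))
          write_diffusion_map(cc$map,
                              file.path(out_dir,
                                        sprintf("cell%02d_Dmap.tif", cc$cell)))
    }
  }
  report
}
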