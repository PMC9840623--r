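#' Diffusive population specification
#'
#' Describes one molecular population inside a cell: freely diffusing in the
#' cytoplasmic volume, diffusing laterally on the membrane surface, or an
#' immobile cluster (a fixed point to which all member molecules are pinned,
#' up to localization error).
#'
#' @param compartment One of `"cytoplasm_3d"`, `"membrane_surface"`,
#'   `"immobile_cluster"`.
#' @param D_true Diffusion coefficient in um^2/s (>= 0; ignored and forced to
#'   0 for immobile clusters).
#' @param n_molecules Number of molecules of this population per cell.
#' @param fraction Optional nominal fraction in `[0, 1]`; if omitted it is
#'   derived from `n_molecules` when populations are combined.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(compartment = c("cytoplasm_3d", "membrane_surface",
                                            "immobile_cluster"),
                            D_true, n_molecules, fraction = NA_real_) {
  compartment <- match.arg(compartment)
  if (D_true < 0) stop("D_true must be >= 0")
  if (compartment == "immobile_cluster") D_true <- 0
  if (n_molecules < 0) stop("n_molecules must be >= 0")
  structure(list(compartment = compartment, D_true = D_true,
                 n_molecules = as.integer(n_molecules), fraction = fraction),
            class = "population_spec")
}

#' Acquisition specification for stroboscopic (SMdM) or long-exposure (SPT)
#' imaging
#'
#' In SMdM mode each pair of camera frames carries two excitation pulses, one
#' at the end of the odd frame and one at the start of the following even
#' frame, separated by the peak-to-peak time `dt_ms`. Frames are 1-based;
#' pair k consists of frames (2k - 1, 2k). In SPT mode a single pulse sits at
#' the start of every frame and the sampling interval is the total frame time.
#'
#' @param exposure_ms Camera exposure per frame, ms.
#' @param dead_time_ms Camera dead time between frames, ms.
#' @param dt_ms Peak-to-peak time between the two pulses of a frame pair, ms
#'   (SMdM mode; must be smaller than the total frame time).
#' @param n_frame_pairs Number of stroboscopic frame pairs (SMdM), or number
#'   of frames (SPT).
#' @param loc_sigma_nm Localization error, standard deviation per coordinate,
#'   nm.
#' @param background_rate False localizations per frame per um^2 of the field
#'   of view.
#' @param detection_prob Probability that an emitting molecule is localized
#'   at a given pulse.
#' @param mean_on_frames SPT mode only: mean fluorescent on-time, frames
#'   (geometric lifetime before irreversible bleaching).
#' @param fov_nm Field of view (x, y) in nm. Default 25 x 25 um
#'   (250 x 250 camera pixels of 100 nm).
#' @param mode `"smdm"` or `"spt"`.
#' @param rng_seed Integer seed; identical seeds give bitwise-identical
#'   output tables.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(exposure_ms = 17.08, dead_time_ms = 0.78,
                             dt_ms = 1.5, n_frame_pairs = 1000,
                             loc_sigma_nm = 20, background_rate = 0,
                             detection_prob = 0.7, mean_on_frames = 15,
                             fov_nm = c(25000, 25000),
                             mode = c("smdm", "spt"), rng_seed = 1L) {
  mode <- match.arg(mode)
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  if (dt_ms <= 0) stop("dt_ms must be > 0")
  if (loc_sigma_nm < 0) stop("loc_sigma_nm must be >= 0")
  total <- exposure_ms + dead_time_ms
  if (mode == "smdm" && dt_ms >= total)
    stop("dt_ms must be smaller than the total frame time (pairing impossible)")
  structure(list(exposure_ms = exposure_ms, dead_time_ms = dead_time_ms,
                 dt_ms = dt_ms, n_frame_pairs = as.integer(n_frame_pairs),
                 loc_sigma_nm = loc_sigma_nm,
                 background_rate = background_rate,
                 detection_prob = detection_prob,
                 mean_on_frames = mean_on_frames,
                 fov_nm = as.numeric(fov_nm), mode = mode,
                 rng_seed = as.integer(rng_seed),
                 total_frame_ms = total),
            class = "acquisition_spec")
}

# um^2/s -> nm^2/ms (1 um^2/s = 1e6 nm^2 / 1e3 ms)
D_to_nm2_per_ms <- function(D_um2_s) D_um2_s * 1e3

# --- Brownian steppers (cell-local frame) --------------------------------

# Positions of all molecules at a sequence of sample times. Cytoplasmic
# molecules take Euler-Maruyama substeps (interval/n_sub) with reflecting
# walls; membrane molecules take tangent-plane substeps re-projected onto
# the surface (exact intrinsic update on an open cylinder). Returns an
# n x 3 x (length(intervals) + 1) array; slice t holds the positions after
# the first t - 1 intervals.
sim_path <- function(cell, p0, compartment, D_um2_s, intervals_ms,
                     n_sub = 20L) {
  comp <- match(compartment,
                c("cytoplasm_3d", "membrane_surface", "immobile_cluster")) - 1L
  hc <- sc_half_cyl(cell)
  if (!is.finite(hc)) hc <- 1e15
  out <- .sim_path_cpp(p0, as.numeric(intervals_ms),
                       D_to_nm2_per_ms(D_um2_s), as.integer(n_sub),
                       cell$radius, hc, cell$caps == "none", comp)
  dim(out) <- c(nrow(p0), 3L, length(intervals_ms) + 1L)
  out
}

init_positions <- function(cell, compartment, n) {
  switch(compartment,
         cytoplasm_3d = sc_sample_volume(cell, n),
         membrane_surface = sc_sample_surface(cell, n),
         immobile_cluster = {
           # all molecules of an immobile cluster share one anchor point
           anchor <- sc_sample_volume(cell, 1)
           matrix(rep(anchor, each = n), n, 3)
         })
}

#' Simulate a synthetic single-molecule localization dataset
#'
#' Generates ground-truth Brownian trajectories for every population in every
#' cell, samples positions at the excitation pulse times, projects them
#' orthographically onto the focal plane, perturbs them with isotropic
#' Gaussian localization error, and adds uniform background false
#' localizations. In SMdM mode each frame pair yields two pulses separated by
#' `acq$dt_ms`; in SPT mode one pulse per frame at the frame interval, with
#' molecules appearing at a random frame and bleaching after a geometric
#' on-time.
#'
#' @param cells List of [spherocylinder()] objects; must not overlap.
#' @param populations List of [population_spec()] objects; if explicit
#'   fractions are supplied they must sum to 1.
#' @param acq An [acquisition_spec()].
#' @return A list with elements `table` (the localization table, a
#'   `data.table` with columns `frame, x_nm, y_nm, amplitude, background,
#'   sigma_x_nm, sigma_y_nm, pair_id`) and `truth` (sidecar table keyed by
#'   localization row: `row, molecule, cell, population, compartment,
#'   pulse, true_x_nm, true_y_nm, pair_id`, plus per-molecule population
#'   metadata in `attr(truth, "molecules")`).
#' @export
simulate_dataset <- function(cells, populations, acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (inherits(cells, "spherocylinder")) cells <- list(cells)
  if (inherits(populations, "population_spec")) populations <- list(populations)
  for (cl in cells) stopifnot(inherits(cl, "spherocylinder"))
  if (length(cells) > 1) {
    for (i in seq_along(cells)) for (j in seq_len(i - 1)) {
      if (sc_overlaps(cells[[i]], cells[[j]]))
        stop(sprintf("cells %d and %d overlap", j, i))
    }
  }
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (!all(is.na(fr))) {
    if (any(is.na(fr))) stop("either all or no population fractions must be set")
    if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
  }
  set.seed(acq$rng_seed)
  if (acq$mode == "smdm") sim_smdm(cells, populations, acq)
  else sim_spt(cells, populations, acq)
}

sim_smdm <- function(cells, populations, acq) {
  K <- acq$n_frame_pairs
  gap_ms <- 2 * acq$total_frame_ms - acq$dt_ms
  intervals <- rep(c(acq$dt_ms, gap_ms), K)[seq_len(2L * K - 1L)]
  rows <- list(); truths <- list(); mol0 <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    th <- cell$axis_angle * pi / 180
    for (pi in seq_along(populations)) {
      pop <- populations[[pi]]
      nm <- pop$n_molecules
      if (nm == 0) next
      p0 <- init_positions(cell, pop$compartment, nm)
      P <- sim_path(cell, p0, pop$compartment, pop$D_true, intervals)
      np <- 2L * K
      # orthographic projection + cell pose, all pulses at once
      X <- matrix(P[, 1, ], nm, np); Y <- matrix(P[, 2, ], nm, np)
      WX <- cos(th) * X - sin(th) * Y + cell$center[1]
      WY <- sin(th) * X + cos(th) * Y + cell$center[2]
      det <- matrix(stats::runif(nm * np) < acq$detection_prob, nm, np)
      pulse_of <- rep(1:2, K)
      kpair <- rep(seq_len(K), each = 2)
      genuine <- det[, seq(1, np, 2), drop = FALSE] &
        det[, seq(2, np, 2), drop = FALSE]       # nm x K
      hit <- which(det, arr.ind = TRUE)
      m <- hit[, 1]; j <- hit[, 2]
      k <- kpair[j]
      pid <- ifelse(genuine[cbind(m, k)],
                    paste0(mol0 + m, "_", k), NA_character_)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        frame = j,
        x_nm = WX[cbind(m, j)] + stats::rnorm(length(m), sd = acq$loc_sigma_nm),
        y_nm = WY[cbind(m, j)] + stats::rnorm(length(m), sd = acq$loc_sigma_nm),
        amplitude = 200, background = 10,
        sigma_x_nm = 130, sigma_y_nm = 130, pair_id = pid)
      truths[[length(truths) + 1L]] <- data.table::data.table(
        molecule = mol0 + m, cell = ci, population = pi,
        compartment = pop$compartment, pulse = pulse_of[j],
        true_x_nm = WX[cbind(m, j)], true_y_nm = WY[cbind(m, j)],
        pair_id = pid)
      mol0 <- mol0 + nm
    }
  }
  assemble_dataset(rows, truths, acq, 2L * K)
}

sim_spt <- function(cells, populations, acq) {
  n_frames <- acq$n_frame_pairs
  intervals <- rep(acq$total_frame_ms, n_frames - 1L)
  rows <- list(); truths <- list(); mol0 <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    th <- cell$axis_angle * pi / 180
    for (pi in seq_along(populations)) {
      pop <- populations[[pi]]
      nm <- pop$n_molecules
      if (nm == 0) next
      p0 <- init_positions(cell, pop$compartment, nm)
      P <- sim_path(cell, p0, pop$compartment, pop$D_true, intervals)
      X <- matrix(P[, 1, ], nm, n_frames); Y <- matrix(P[, 2, ], nm, n_frames)
      WX <- cos(th) * X - sin(th) * Y + cell$center[1]
      WY <- sin(th) * X + cos(th) * Y + cell$center[2]
      # activation frame uniform; on-time geometric (mean mean_on_frames),
      # then irreversible bleaching
      f_on <- sample.int(n_frames, nm, replace = TRUE)
      life <- 1L + stats::rgeom(nm, prob = 1 / acq$mean_on_frames)
      f_off <- pmin(f_on + life - 1L, n_frames)
      kk <- matrix(rep(seq_len(n_frames), each = nm), nm, n_frames)
      det <- kk >= f_on & kk <= f_off &
        matrix(stats::runif(nm * n_frames) < acq$detection_prob, nm, n_frames)
      hit <- which(det, arr.ind = TRUE)
      m <- hit[, 1]; j <- hit[, 2]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        frame = j,
        x_nm = WX[cbind(m, j)] + stats::rnorm(length(m), sd = acq$loc_sigma_nm),
        y_nm = WY[cbind(m, j)] + stats::rnorm(length(m), sd = acq$loc_sigma_nm),
        amplitude = 200, background = 10,
        sigma_x_nm = 130, sigma_y_nm = 130, pair_id = NA_character_)
      truths[[length(truths) + 1L]] <- data.table::data.table(
        molecule = mol0 + m, cell = ci, population = pi,
        compartment = pop$compartment, pulse = 1L,
        true_x_nm = WX[cbind(m, j)], true_y_nm = WY[cbind(m, j)],
        pair_id = NA_character_)
      mol0 <- mol0 + nm
    }
  }
  assemble_dataset(rows, truths, acq, n_frames)
}

assemble_dataset <- function(rows, truths, acq, n_frames) {
  tab <- if (length(rows)) data.table::rbindlist(rows) else empty_loc_table()
  tru <- if (length(truths)) data.table::rbindlist(truths) else
    data.table::data.table(molecule = integer(), cell = integer(),
                           population = integer(), compartment = character(),
                           pulse = integer(), true_x_nm = numeric(),
                           true_y_nm = numeric(), pair_id = character())
  # background false localizations, uniform over the field of view
  if (acq$background_rate > 0) {
    area_um2 <- prod(acq$fov_nm) / 1e6
    nbg <- stats::rpois(n_frames, acq$background_rate * area_um2)
    tot <- sum(nbg)
    if (tot > 0) {
      bg <- data.table::data.table(
        frame = rep(seq_len(n_frames), nbg),
        x_nm = stats::runif(tot, 0, acq$fov_nm[1]),
        y_nm = stats::runif(tot, 0, acq$fov_nm[2]),
        amplitude = 200, background = 10,
        sigma_x_nm = 130, sigma_y_nm = 130, pair_id = NA_character_)
      tab <- rbind(tab, bg)
      tru <- rbind(tru, data.table::data.table(
        molecule = NA_integer_, cell = NA_integer_, population = NA_integer_,
        compartment = "background", pulse = NA_integer_,
        true_x_nm = bg$x_nm, true_y_nm = bg$y_nm, pair_id = NA_character_))
    }
  }
  ord <- order(tab$frame, tab$x_nm, tab$y_nm)
  tab <- tab[ord]
  tru <- tru[ord]
  tru[, row := .I]
  data.table::setcolorder(tru, "row")
  structure(list(table = tab[], truth = tru[]), class = "sim_dataset",
            dt_ms = if (acq$mode == "smdm") acq$dt_ms else acq$total_frame_ms)
}

empty_loc_table <- function() {
  data.table::data.table(frame = integer(), x_nm = numeric(),
                         y_nm = numeric(), amplitude = numeric(),
                         background = numeric(), sigma_x_nm = numeric(),
                         sigma_y_nm = numeric(), pair_id = character())
}

#' Ground-truth displacement set of a simulated dataset
#'
#' Builds the displacement set from the simulator's own pairing record
#' (`pair_id`), bypassing the candidate search: one record per genuine
#' molecule pair, localization error included. Background false
#' localizations never contribute.
#'
#' @param dataset Result of [simulate_dataset()] (SMdM mode).
#' @param r_max Truncation radius, nm; records beyond it are dropped
#'   (default `Inf` keeps everything).
#' @return A [displacement_set()].
#' @export
ground_truth_displacements <- function(dataset, r_max = Inf) {
  stopifnot(inherits(dataset, "sim_dataset"))
  tb <- dataset$table[!is.na(pair_id)]
  p1 <- tb[frame %% 2L == 1L]
  p2 <- tb[frame %% 2L == 0L]
  data.table::setkey(p1, pair_id)
  data.table::setkey(p2, pair_id)
  m <- p1[p2, nomatch = NULL]
  rec <- data.table::data.table(
    x0 = m$x_nm, y0 = m$y_nm, x1 = m$i.x_nm, y1 = m$i.y_nm,
    r = sqrt((m$i.x_nm - m$x_nm)^2 + (m$i.y_nm - m$y_nm)^2),
    pair = seq_len(nrow(m)))
  rec <- rec[rec$r <= r_max]
  displacement_set(rec, dt = attr(dataset, "dt_ms"), r_max = r_max)
}

#' Render camera frames from a localization table
#'
#' Each localization is drawn as a pixel-integrated 2D Gaussian of
#' `photons_per_spot` total photons, on a constant camera offset, optionally
#' with Poisson shot noise and Gaussian read noise. Used to exercise the
#' localizer against emitters with known positions.
#'
#' @param table Localization table (needs `frame`, `x_nm`, `y_nm`).
#' @param psf_sigma_nm PSF standard deviation, nm.
#' @param photons_per_spot Total photons per localization.
#' @param pixel_size_nm Camera pixel size, nm (default 100).
#' @param fov_nm Field of view (x, y), nm.
#' @param offset Camera offset, counts.
#' @param read_noise Read noise SD, counts (0 disables).
#' @param shot_noise Apply Poisson noise to the photon signal.
#' @param n_frames Number of frames; default spans the table.
#' @return 3D array `[row, col, frame]` of counts, with attributes
#'   `pixel_size_nm`; class `image_stack`.
#' @export
render_frames <- function(table, psf_sigma_nm = 130, photons_per_spot = 1000,
                          pixel_size_nm = 100, fov_nm = c(25000, 25000),
                          offset = 100, read_noise = 0, shot_noise = FALSE,
                          n_frames = NULL) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  nx <- ceiling(fov_nm[1] / pixel_size_nm)
  ny <- ceiling(fov_nm[2] / pixel_size_nm)
  if (is.null(n_frames))
    n_frames <- if (nrow(table)) max(table$frame) else 1L
  stack <- array(offset, dim = c(ny, nx, n_frames))
  if (nrow(table)) {
    inside <- table$x_nm >= 0 & table$x_nm <= fov_nm[1] &
      table$y_nm >= 0 & table$y_nm <= fov_nm[2]
    if (any(!inside))
      warning(sum(!inside), " emitters outside the field of view were clipped")
    tab <- table[inside & table$frame <= n_frames, ]
    half <- ceiling(4 * psf_sigma_nm / pixel_size_nm)
    for (i in seq_len(nrow(tab))) {
      cx <- tab$x_nm[i] / pixel_size_nm   # in pixel units, origin top-left
      cy <- tab$y_nm[i] / pixel_size_nm
      ix <- max(1, floor(cx) + 1 - half):min(nx, floor(cx) + 1 + half)
      iy <- max(1, floor(cy) + 1 - half):min(ny, floor(cy) + 1 + half)
      s <- psf_sigma_nm / pixel_size_nm
      gx <- stats::pnorm((ix - cx) / s) - stats::pnorm((ix - 1 - cx) / s)
      gy <- stats::pnorm((iy - cy) / s) - stats::pnorm((iy - 1 - cy) / s)
      stack[iy, ix, tab$frame[i]] <-
        stack[iy, ix, tab$frame[i]] + photons_per_spot * outer(gy, gx)
    }
  }
  if (shot_noise) {
    sig <- pmax(stack - offset, 0)
    stack <- offset + array(stats::rpois(length(sig), sig), dim = dim(stack))
  }
  if (read_noise > 0)
    stack <- stack + array(stats::rnorm(length(stack), sd = read_noise),
                           dim = dim(stack))
  structure(stack, pixel_size_nm = pixel_size_nm, class = "image_stack")
}
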