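#' Fit an elliptical 2D Gaussian to a spot image
#'
#' Fits the camera point-spread function model
#' `f(x, y) = B + A exp(-((x - x0)^2 / (2 sigma_x^2) + (y - y0)^2 / (2 sigma_y^2)))`
#' to a small image patch by Levenberg-Marquardt least squares. Because the
#' camera integrates photons over each pixel, the model is evaluated as the
#' pixel-integrated (erf) form of this Gaussian rather than sampled at pixel
#' centres; `A` is the continuous peak amplitude in counts.
#'
#' @param roi Numeric matrix (rows = y), at least 7 x 7 pixels.
#' @param init Optional named list of starting values (`B`, `A`, `x0`, `y0`,
#'   `sigma_x`, `sigma_y`; positions and sigmas in nm relative to the roi's
#'   top-left corner). Defaults come from peak/centroid heuristics.
#' @param pixel_size_nm Pixel size, nm.
#' @param sigma_bounds Allowed sigma range, nm (default `c(40, 400)`).
#' @param min_amplitude Minimum fitted amplitude (counts) for acceptance;
#'   also the floor under the data range below which the roi is rejected as
#'   "no signal".
#' @return Object of class `gauss_spot_fit`: `B`, `A`, `x0`, `y0`
#'   (nm, roi frame), `sigma_x`, `sigma_y`, `rss`, `converged`, `accepted`,
#'   `reason`.
#' @export
fit_gaussian_spot <- function(roi, init = NULL, pixel_size_nm = 100,
                              sigma_bounds = c(40, 400), min_amplitude = 5) {
  roi <- as.matrix(roi)
  ny <- nrow(roi); nx <- ncol(roi)
  if (ny < 7 || nx < 7) stop("roi must be at least 7 x 7 pixels")
  rej <- function(reason) structure(
    list(B = NA_real_, A = NA_real_, x0 = NA_real_, y0 = NA_real_,
         sigma_x = NA_real_, sigma_y = NA_real_, rss = NA_real_,
         converged = FALSE, accepted = FALSE, reason = reason),
    class = "gauss_spot_fit")
  bg0 <- stats::median(c(roi[1, ], roi[ny, ], roi[, 1], roi[, nx]))
  if (max(roi) - bg0 < min_amplitude) return(rej("no signal"))
  if (is.null(init)) {
    pk <- which(roi == max(roi), arr.ind = TRUE)[1, ]
    w <- pmax(roi - bg0, 0)
    xs <- (col(roi) - 0.5) * pixel_size_nm
    ys <- (row(roi) - 0.5) * pixel_size_nm
    init <- list(B = bg0, A = max(roi) - bg0,
                 x0 = sum(w * xs) / sum(w), y0 = sum(w * ys) / sum(w),
                 sigma_x = 1.3 * pixel_size_nm, sigma_y = 1.3 * pixel_size_nm)
  }
  xe <- (0:nx) * pixel_size_nm   # pixel edges
  ye <- (0:ny) * pixel_size_nm
  dat <- data.frame(z = as.vector(roi),
                    i = as.vector(row(roi)), j = as.vector(col(roi)))
  model <- function(B, A, x0, y0, sx, sy, i, j) {
    gx <- (stats::pnorm((xe[j + 1] - x0) / sx) -
             stats::pnorm((xe[j] - x0) / sx)) * sx * sqrt(2 * pi) / pixel_size_nm
    gy <- (stats::pnorm((ye[i + 1] - y0) / sy) -
             stats::pnorm((ye[i] - y0) / sy)) * sy * sqrt(2 * pi) / pixel_size_nm
    B + A * gx * gy
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ model(B, A, x0, y0, sx, sy, i, j), data = dat,
      start = list(B = init$B, A = max(init$A, min_amplitude),
                   x0 = init$x0, y0 = init$y0,
                   sx = init$sigma_x, sy = init$sigma_y),
      lower = c(B = -Inf, A = 0, x0 = 0, y0 = 0,
                sx = sigma_bounds[1], sy = sigma_bounds[1]),
      upper = c(B = Inf, A = Inf, x0 = nx * pixel_size_nm,
                y0 = ny * pixel_size_nm,
                sx = sigma_bounds[2], sy = sigma_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(rej("did not converge"))
  p <- as.list(stats::coef(fit))
  res <- list(B = p$B, A = p$A, x0 = p$x0, y0 = p$y0,
              sigma_x = p$sx, sigma_y = p$sy,
              rss = sum(stats::residuals(fit)^2),
              converged = fit$convInfo$isConv,
              accepted = TRUE, reason = NA_character_)
  tol <- 1e-6
  if (!res$converged) { res$accepted <- FALSE; res$reason <- "did not converge" }
  else if (res$A < min_amplitude) { res$accepted <- FALSE; res$reason <- "no signal" }
  else if (res$x0 <= 0 || res$x0 >= nx * pixel_size_nm ||
           res$y0 <= 0 || res$y0 >= ny * pixel_size_nm) {
    res$accepted <- FALSE; res$reason <- "center outside roi"
  } else if (min(res$sigma_x, res$sigma_y) <= sigma_bounds[1] + tol ||
             max(res$sigma_x, res$sigma_y) >= sigma_bounds[2] - tol) {
    res$accepted <- FALSE; res$reason <- "sigma at bound"
  }
  structure(res, class = "gauss_spot_fit")
}

# separable Gaussian blur with edge replication
gauss_blur <- function(m, sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-h:h, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(mm) {
    top <- mm[rep(1L, h), , drop = FALSE]
    bot <- mm[rep(nrow(mm), h), , drop = FALSE]
    mp <- rbind(top, mm, bot)
    out <- stats::filter(mp, k, sides = 2)
    out[(h + 1):(h + nrow(mm)), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(m))))
}

# candidate peaks: difference-of-Gaussians bandpass, threshold in robust
# noise-SD units, strict 8-neighbour local maxima
detect_peaks <- function(frame, threshold_sd = 4, psf_sigma_px = 1.3) {
  dog <- gauss_blur(frame, psf_sigma_px / 1.5) - gauss_blur(frame, psf_sigma_px * 2)
  noise <- stats::mad(dog, center = stats::median(dog))
  if (noise <= 0) noise <- stats::sd(dog)
  if (!is.finite(noise) || noise <= 0) return(matrix(numeric(), 0, 2))
  ny <- nrow(dog); nx <- ncol(dog)
  core <- dog[2:(ny - 1), 2:(nx - 1)]
  ismax <- core >= stats::median(dog) + threshold_sd * noise
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- dog[2:(ny - 1) + di, 2:(nx - 1) + dj]
    ismax <- ismax & (core > nb | (core == nb & (di > 0 | (di == 0 & dj > 0))))
  }
  idx <- which(ismax, arr.ind = TRUE)
  cbind(idx[, 1] + 1L, idx[, 2] + 1L)   # row, col in the full frame
}

#' Localize single molecules in an image stack
#'
#' Per frame: difference-of-Gaussians band-pass detection with a local-maximum
#' threshold in noise-SD units, rejection of overlapping candidates (peaks
#' closer than `2 * psf_sigma_nm` are both discarded), then per-candidate
#' elliptical Gaussian fitting with [fit_gaussian_spot()]. Positions use the
#' pixel-centre convention: a molecule at the centre of 1-based pixel `i`
#' has coordinate `(i - 0.5) * pixel_size_nm`, origin at the field's
#' top-left corner.
#'
#' @param stack 3D array `[row, col, frame]` (an `image_stack`) or a matrix
#'   for a single frame.
#' @param threshold_sd Detection threshold in noise-SD units (default 4).
#' @param roi_px Fitting roi edge length in pixels, odd, >= 7 (default 9).
#' @param psf_sigma_nm Nominal PSF sigma, nm.
#' @param pixel_size_nm Pixel size, nm.
#' @param sigma_bounds Accepted sigma range for fits, nm. The default brackets
#'   the nominal PSF tightly; fits pushed to the upper bound (e.g. two
#'   unresolvable emitters blurring into one wide spot) are rejected rather
#'   than reported as a midpoint localization.
#' @return Localization table (`data.table`) in the standard dialect.
#' @export
localize_stack <- function(stack, threshold_sd = 4, roi_px = 9,
                           psf_sigma_nm = 130, pixel_size_nm = 100,
                           sigma_bounds = psf_sigma_nm * c(0.6, 1.1)) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (roi_px < 7 || roi_px %% 2 == 0) stop("roi_px must be odd and >= 7")
  half <- (roi_px - 1L) %/% 2L
  psf_px <- psf_sigma_nm / pixel_size_nm
  out <- list()
  for (fr in seq_len(dim(stack)[3])) {
    frame <- stack[, , fr]
    pk <- detect_peaks(frame, threshold_sd, psf_px)
    if (!nrow(pk)) next
    # overlap policy: candidates closer than 2 * psf_sigma are both rejected
    if (nrow(pk) > 1) {
      d <- as.matrix(stats::dist(pk * pixel_size_nm))
      diag(d) <- Inf
      pk <- pk[apply(d, 1, min) >= 2 * psf_sigma_nm, , drop = FALSE]
    }
    if (!nrow(pk)) next
    for (m in seq_len(nrow(pk))) {
      i0 <- pk[m, 1]; j0 <- pk[m, 2]
      if (i0 - half < 1 || i0 + half > nrow(frame) ||
          j0 - half < 1 || j0 + half > ncol(frame)) next
      roi <- frame[(i0 - half):(i0 + half), (j0 - half):(j0 + half)]
      ft <- fit_gaussian_spot(roi, pixel_size_nm = pixel_size_nm,
                              sigma_bounds = sigma_bounds)
      if (!isTRUE(ft$accepted)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        frame = fr,
        x_nm = (j0 - half - 1) * pixel_size_nm + ft$x0,
        y_nm = (i0 - half - 1) * pixel_size_nm + ft$y0,
        amplitude = ft$A, background = ft$B,
        sigma_x_nm = ft$sigma_x, sigma_y_nm = ft$sigma_y,
        pair_id = NA_character_)
    }
  }
  if (length(out)) data.table::rbindlist(out) else empty_loc_table()
}

# --- drift correction ----------------------------------------------------

# 2D histogram of localizations on a fixed grid
drift_histogram <- function(x, y, xlim, ylim, bin) {
  nx <- ceiling(diff(xlim) / bin); ny <- ceiling(diff(ylim) / bin)
  ix <- pmin(pmax(floor((x - xlim[1]) / bin) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - ylim[1]) / bin) + 1L, 1L), ny)
  matrix(tabulate((ix - 1L) * ny + iy, nbins = nx * ny), ny, nx)
}

# pad a histogram to FFT-friendly dimensions (>= 2x to avoid wraparound)
pad_fft <- function(h, py, px) {
  out <- matrix(0, py, px)
  out[seq_len(nrow(h)), seq_len(ncol(h))] <- h
  stats::fft(out)
}

# offset of h2 relative to h1 from the pre-computed FFTs, with parabolic
# sub-bin refinement; returns c(dy, dx) in bins
xcorr_shift <- function(F1, F2, ny, nx) {
  py <- nrow(F1); px <- ncol(F1)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sub <- function(cm, k, n) {
    km <- if (k == 1) n else k - 1
    kp <- if (k == n) 1 else k + 1
    denom <- cm[km] - 2 * cm[k] + cm[kp]
    if (denom >= 0) 0 else 0.5 * (cm[km] - cm[kp]) / denom
  }
  dy <- pk[1] - 1 + sub(cc[, pk[2]], pk[1], py)
  dx <- pk[2] - 1 + sub(cc[pk[1], ], pk[2], px)
  if (dy > py / 2) dy <- dy - py
  if (dx > px / 2) dx <- dx - px
  c(dy, dx)
}

#' Estimate and correct lateral (xy) drift
#'
#' Fiducial-free redundant cross-correlation: the table is cut into temporal
#' segments, each rendered as a super-resolved 2D histogram; all segment
#' pairs are cross-correlated and the per-segment offsets solved by least
#' squares (reference segment fixed at zero), then interpolated
#' piecewise-linearly over frames and subtracted.
#'
#' @param table Localization table.
#' @param segment_len_frames Frames per segment (default 2000).
#' @param bin_nm Histogram bin, nm (default 20).
#' @param min_locs_per_segment Minimum localizations a segment needs; below
#'   this the correction degrades to identity with a warning.
#' @return List with `table` (corrected) and `drift` (`data.frame`: segment,
#'   frame at segment centre, `dx_nm`, `dy_nm`), class `drift_series` on the
#'   latter.
#' @export
estimate_and_apply_drift <- function(table, segment_len_frames = 2000,
                                     bin_nm = 20, min_locs_per_segment = 50,
                                     n_passes = 2) {
  tb <- data.table::as.data.table(table)
  identity_out <- function(msg) {
    warning(msg)
    drift <- data.frame(segment = 1L,
                        frame = stats::median(as.numeric(tb$frame)),
                        dx_nm = 0, dy_nm = 0)
    class(drift) <- c("drift_series", "data.frame")
    list(table = tb, drift = drift)
  }
  if (!nrow(tb)) return(identity_out("empty table: no drift correction"))
  fmax <- max(tb$frame)
  nseg <- ceiling(fmax / segment_len_frames)
  if (nseg < 2)
    return(identity_out("table spans a single segment: no drift correction"))
  seg_of <- pmin((tb$frame - 1L) %/% segment_len_frames + 1L, nseg)
  counts <- tabulate(seg_of, nseg)
  if (any(counts < min_locs_per_segment))
    return(identity_out("too few localizations per segment: identity drift"))
  seg_centers <- (seq_len(nseg) - 0.5) * segment_len_frames
  out <- data.table::copy(tb)
  sx_tot <- numeric(nseg); sy_tot <- numeric(nseg)
  # pass 1 removes the bulk drift; pass 2 re-estimates on the de-streaked
  # coordinates, where the segment histograms are sharp
  for (pass in seq_len(max(1, n_passes))) {
    est <- drift_pass(out, seg_of, nseg, seg_centers, bin_nm)
    sx_tot <- sx_tot + est$sx
    sy_tot <- sy_tot + est$sy
    out[, x_nm := x_nm - est$fx]
    out[, y_nm := y_nm - est$fy]
  }
  drift <- data.frame(segment = seq_len(nseg), frame = seg_centers,
                      dx_nm = sx_tot, dy_nm = sy_tot)
  class(drift) <- c("drift_series", "data.frame")
  list(table = out[], drift = drift)
}

drift_pass <- function(tb, seg_of, nseg, seg_centers, bin_nm) {
  xlim <- range(tb$x_nm); ylim <- range(tb$y_nm)
  ny <- ceiling(diff(ylim) / bin_nm); nx <- ceiling(diff(xlim) / bin_nm)
  py <- stats::nextn(2 * ny, c(2, 3, 5)); px <- stats::nextn(2 * nx, c(2, 3, 5))
  Fs <- lapply(seq_len(nseg), function(s) {
    h <- drift_histogram(tb$x_nm[seg_of == s], tb$y_nm[seg_of == s],
                         xlim, ylim, bin_nm)
    # mild smoothing gives a smooth correlation peak for sub-bin refinement
    pad_fft(gauss_blur(h, 1.5), py, px)
  })
  # redundant pairwise offsets d_ij ~ s_j - s_i (segment lag capped to keep
  # the correlations well-overlapped), least squares with s_1 = 0
  pairs <- utils::combn(nseg, 2)
  pairs <- pairs[, pairs[2, ] - pairs[1, ] <= 6, drop = FALSE]
  A <- matrix(0, ncol(pairs), nseg - 1)
  bx <- numeric(ncol(pairs)); by <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    sh <- xcorr_shift(Fs[[i]], Fs[[j]], ny, nx)  # position of j relative to i
    by[m] <- -sh[1] * bin_nm
    bx[m] <- -sh[2] * bin_nm
    if (i > 1) A[m, i - 1] <- -1
    A[m, j - 1] <- 1
  }
  sx <- c(0, stats::lm.fit(A, bx)$coefficients)
  sy <- c(0, stats::lm.fit(A, by)$coefficients)
  # piecewise-linear between segment centres, linear extrapolation outside
  interp_extrap <- function(v) {
    y <- stats::approx(seg_centers, v, xout = tb$frame, rule = 2)$y
    lo <- tb$frame < seg_centers[1]
    hi <- tb$frame > seg_centers[nseg]
    s1 <- (v[2] - v[1]) / (seg_centers[2] - seg_centers[1])
    s2 <- (v[nseg] - v[nseg - 1]) / (seg_centers[nseg] - seg_centers[nseg - 1])
    y[lo] <- v[1] + s1 * (tb$frame[lo] - seg_centers[1])
    y[hi] <- v[nseg] + s2 * (tb$frame[hi] - seg_centers[nseg])
    y
  }
  list(sx = sx, sy = sy, fx = interp_extrap(sx), fy = interp_extrap(sy))
}
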