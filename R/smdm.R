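#' Construct a displacement set
#'
#' Container for paired-peak displacements: one record per admissible pairing
#' of a localization in the first frame of a stroboscopic pair with a
#' localization in the second frame, within the search radius `r_max`.
#'
#' @param records `data.frame`/`data.table` with columns
#'   `x0, y0, x1, y1, r, pair` (and optionally `region`).
#' @param dt Peak-to-peak interval, ms.
#' @param r_max Pairing radius, nm.
#' @return Object of class `displacement_set` (a `data.table` with
#'   attributes `dt`, `r_max`).
#' @export
displacement_set <- function(records, dt, r_max = 600) {
  dtb <- data.table::as.data.table(records)
  need <- c("x0", "y0", "x1", "y1", "r", "pair")
  miss <- setdiff(need, names(dtb))
  if (length(miss)) stop("missing displacement columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(dtb) && any(dtb$r < 0 | dtb$r > r_max))
    stop("all displacements must satisfy 0 <= r <= r_max")
  data.table::setattr(dtb, "dt", dt)
  data.table::setattr(dtb, "r_max", r_max)
  data.table::setattr(dtb, "class",
                      c("displacement_set", class(dtb)))
  dtb
}

#' Extract displacements from a paired-frame localization table
#'
#' Frames are paired by the stroboscopic parity convention: pair k consists
#' of frames (2k - 1, 2k), with the two excitation pulses separated by `dt`.
#' Every localization in the second frame within `r_max` of a localization
#' in the first frame yields one displacement record (all-candidates policy;
#' false pairings are absorbed by the background term of the fit model).
#' With `pairing = "nearest"` only the mutually nearest admissible candidate
#' is kept, for sensitivity analysis.
#'
#' @param table Localization table with `frame`, `x_nm`, `y_nm`.
#' @param dt Peak-to-peak interval, ms.
#' @param r_max Pairing search radius, nm (default 600).
#' @param pairing `"all"` (default) or `"nearest"`.
#' @return A [displacement_set()]; empty when the table has no valid pairs.
#' @export
extract_displacements <- function(table, dt, r_max = 600,
                                  pairing = c("all", "nearest")) {
  pairing <- match.arg(pairing)
  empty <- data.table::data.table(x0 = numeric(), y0 = numeric(),
                                  x1 = numeric(), y1 = numeric(),
                                  r = numeric(), pair = integer())
  if (!nrow(table)) return(displacement_set(empty, dt, r_max))
  tb <- data.table::as.data.table(table)
  odd <- tb[tb$frame %% 2L == 1L]
  even <- tb[tb$frame %% 2L == 0L]
  if (!nrow(odd) || !nrow(even)) return(displacement_set(empty, dt, r_max))
  odd[, pair := (frame + 1L) %/% 2L]
  even[, pair := frame %/% 2L]
  a <- data.table::data.table(pair = odd$pair, ia = seq_len(nrow(odd)),
                              x0 = odd$x_nm, y0 = odd$y_nm)
  b <- data.table::data.table(pair = even$pair, ib = seq_len(nrow(even)),
                              x1 = even$x_nm, y1 = even$y_nm)
  m <- merge(a, b, by = "pair", allow.cartesian = TRUE)
  if (!nrow(m)) return(displacement_set(empty, dt, r_max))
  m[, r := sqrt((x1 - x0)^2 + (y1 - y0)^2)]
  m <- m[r <= r_max]
  if (nrow(m) && pairing == "nearest") {
    # keep matches that are mutually nearest among admissible candidates
    m[, keep := r == min(r), by = .(pair, ia)]
    m[, keep := keep & r == min(r), by = .(pair, ib)]
    m <- m[keep == TRUE]
  }
  rec <- m[, .(x0, y0, x1, y1, r, pair)]
  displacement_set(rec, dt, r_max)
}

#' Reconstruct a per-cell diffusivity map
#'
#' Bins displacements into square pixels of the aligned cell frame by their
#' starting position and fits each pixel's displacements with the
#' single-component truncated model. The background slope `b` is not
#' identifiable per 50 nm pixel, so it is estimated once at the cell level
#' (or supplied) and held fixed during the per-pixel fits. Pixels with fewer
#' than `min_count` displacements are masked.
#'
#' @param ds A [displacement_set()] from one aligned cell.
#' @param grid_nm Map pixel size, nm (default 50).
#' @param min_count Minimum displacements per valid pixel (default 20).
#' @param b Background slope to hold fixed; `NULL` fits it from the pooled
#'   cell displacements first.
#' @return Object of class `diffusion_map`: list with matrices `D`
#'   (um^2/s, `NA` where masked), `count`, `valid`, plus the grid origin and
#'   pixel size.
#' @export
build_diffusion_map <- function(ds, grid_nm = 50, min_count = 20, b = NULL) {
  stopifnot(inherits(ds, "displacement_set"))
  dt <- attr(ds, "dt"); r_max <- attr(ds, "r_max")
  if (is.null(b)) {
    b <- if (nrow(ds) >= 50)
      fit_displacement_mle(ds, n_components = 1)$b else 0
  }
  if (!nrow(ds)) {
    return(structure(list(D = matrix(NA_real_, 0, 0),
                          count = matrix(0L, 0, 0),
                          valid = matrix(FALSE, 0, 0),
                          origin = c(0, 0), grid_nm = grid_nm,
                          b = b, dt = dt, r_max = r_max),
                     class = "diffusion_map"))
  }
  x0 <- ds$x0; y0 <- ds$y0
  ox <- floor(min(x0) / grid_nm) * grid_nm
  oy <- floor(min(y0) / grid_nm) * grid_nm
  ix <- pmin(floor((x0 - ox) / grid_nm) + 1L,
             ceiling((max(x0) - ox) / grid_nm))
  iy <- pmin(floor((y0 - oy) / grid_nm) + 1L,
             ceiling((max(y0) - oy) / grid_nm))
  nx <- max(ix); ny <- max(iy)
  Dm <- matrix(NA_real_, ny, nx)
  cnt <- matrix(0L, ny, nx)
  fourdt <- 4 * dt
  key <- (ix - 1L) * ny + iy
  split_idx <- split(seq_along(key), key)
  for (cellpix in split_idx) {
    j <- (key[cellpix[1]] - 1L) %/% ny + 1L
    i <- (key[cellpix[1]] - 1L) %% ny + 1L
    cnt[i, j] <- length(cellpix)
    if (length(cellpix) < min_count) next
    r <- ds$r[cellpix]
    Dm[i, j] <- fit_pixel_D(r, dt, r_max, b)
  }
  structure(list(D = Dm, count = cnt, valid = !is.na(Dm),
                 origin = c(ox, oy), grid_nm = grid_nm,
                 b = b, dt = dt, r_max = r_max),
            class = "diffusion_map")
}

# 1D MLE over log D with b held fixed (per-pixel fit)
fit_pixel_D <- function(r, dt, r_max, b) {
  r <- r[r > 0]
  if (!length(r)) return(NA_real_)
  d0 <- max(mean(r^2) / (4 * dt) / 1e3, 1e-6)
  nll <- function(ld) {
    v <- tryCatch(
      -displacement_loglik(r, exp(ld), dt, b = b, r_max = r_max),
      error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  opt <- stats::optimize(nll, interval = log(d0) + c(-7, 7))
  exp(opt$minimum)
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat(sprintf("diffusion map: %d x %d pixels of %g nm, %d valid\n",
              nrow(x$D), ncol(x$D), x$grid_nm, sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  median D = %.3g um^2/s (valid pixels)\n",
                stats::median(x$D[x$valid])))
  invisible(x)
}

#' Write a diffusion map (and its count map) as 32-bit float TIFF
#'
#' Masked pixels are written as NaN.
#'
#' @param map A [build_diffusion_map()] result.
#' @param path Output path for the D map; the count map goes to
#'   `*_counts.tif`.
#' @return Invisibly, the two paths.
#' @export
write_diffusion_map <- function(map, path) {
  d <- map$D
  d[!map$valid] <- NaN
  # values are physical (um^2/s, counts), not [0,1] greyscale; the samples
  # are stored as IEEE 32-bit floats, so the range warning does not apply
  suppressWarnings(
    tiff::writeTIFF(d, path, bits.per.sample = 32L, reduce = FALSE))
  cpath <- sub("\\.tiff?$", "", path)
  cpath <- paste0(cpath, "_counts.tif")
  suppressWarnings(
    tiff::writeTIFF(map$count / 1, cpath, bits.per.sample = 32L))
  invisible(c(path, cpath))
}

#' Super-resolution reconstruction histogram
#'
#' 2D histogram of localizations at `bin_nm` bins — the standard PALM
#' rendering used for presentation next to diffusivity maps.
#'
#' @param table Localization table.
#' @param bin_nm Bin size, nm (default 20).
#' @return Integer matrix of counts (rows = y bins).
#' @export
reconstruct_palm <- function(table, bin_nm = 20) {
  if (!nrow(table)) return(matrix(0L, 0, 0))
  ix <- floor(table$x_nm / bin_nm) + 1L
  iy <- floor(table$y_nm / bin_nm) + 1L
  ix <- ix - min(ix) + 1L; iy <- iy - min(iy) + 1L
  ny <- max(iy); nx <- max(ix)
  matrix(tabulate((ix - 1L) * ny + iy, nbins = nx * ny), ny, nx)
}
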