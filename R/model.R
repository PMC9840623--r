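#' Probability density of single-molecule displacements
#'
#' The step-length density of isotropic 2D Brownian motion observed over a
#' fixed interval dt is the Rayleigh density
#' \deqn{P(r) = \frac{2r}{4D\Delta t} e^{-r^2 / 4D\Delta t}.}
#' Pairing uncertainty from unrelated nearby localizations adds a linear
#' background term \eqn{b\,r}, and the pairing cutoff at `r_max` truncates
#' and renormalizes the density. For `N` diffusive components with fractions
#' `f` the full model is
#' \deqn{P(r) = \frac{\sum_i f_i \frac{2r}{4D_i\Delta t}
#'   e^{-r^2/4D_i\Delta t} + br}{1 - \sum_i f_i e^{-r_{max}^2/4D_i\Delta t}
#'   + \frac{b}{2} r_{max}^2}.}
#' The single-component, background-free and untruncated cases are the
#' obvious specialisations.
#'
#' @param r Displacement distances, nm; all values must lie in `[0, r_max]`.
#' @param D Diffusion coefficients, um^2/s (length N).
#' @param dt Time interval, ms.
#' @param f Component fractions, length N, summing to 1. Default `1`.
#' @param b Background slope, 1/nm^2 (>= 0). Requires finite `r_max` when
#'   positive.
#' @param r_max Truncation radius, nm; `Inf` gives the untruncated model
#'   (only valid with `b = 0`).
#' @return Probability density values, 1/nm.
#' @export
displacement_pdf <- function(r, D, dt, f = 1, b = 0, r_max = 600) {
  if (length(f) != length(D)) stop("f and D must have equal length")
  if (abs(sum(f) - 1) > 1e-8) stop("fractions must sum to 1")
  if (any(D <= 0)) stop("all D must be > 0")
  if (b < 0) stop("b must be >= 0")
  if (!is.finite(r_max) && b > 0)
    stop("background term requires a finite r_max")
  if (any(r < 0 | r > r_max)) stop("r must lie in [0, r_max]")
  fourDdt <- 4 * D_to_nm2_per_ms(D) * dt
  num <- b * r
  for (i in seq_along(D))
    num <- num + f[i] * (2 * r / fourDdt[i]) * exp(-r^2 / fourDdt[i])
  den <- if (is.finite(r_max))
    1 - sum(f * exp(-r_max^2 / fourDdt)) + b / 2 * r_max^2
  else 1
  num / den
}

displacement_loglik <- function(r, D, dt, f = 1, b = 0, r_max = 600) {
  sum(log(displacement_pdf(r, D, dt, f = f, b = b, r_max = r_max)))
}

#' Moment (mean-square-displacement) estimate of the diffusion coefficient
#'
#' For untruncated, background-free 2D Brownian motion the mean square
#' displacement obeys `<r^2> = 4 D dt`, so `mean(r^2) / (4 dt)` is both the
#' moment estimator and the exact maximum-likelihood estimator of the
#' single-component Rayleigh model. Used as a closed-form oracle and as the
#' optimizer initializer.
#'
#' @param ds A [displacement_set()] or a numeric vector of displacements, nm.
#' @param dt Time interval in ms (taken from `ds` when available).
#' @return Diffusion coefficient, um^2/s.
#' @export
closed_form_diffusion <- function(ds, dt = NULL) {
  r <- displacement_r(ds)
  if (is.null(dt)) dt <- attr(ds, "dt")
  if (is.null(dt)) stop("dt is required")
  if (!length(r)) stop("empty displacement set")
  mean(r^2) / (4 * dt) / 1e3   # nm^2/ms -> um^2/s
}

displacement_r <- function(ds) {
  if (inherits(ds, "displacement_set")) ds$r
  else if (is.numeric(ds)) ds
  else stop("expected a displacement_set or a numeric vector")
}

# --- maximum-likelihood fitting ------------------------------------------

# parameter transform: theta = (log D_1..N, stick-breaking logits (N-1),
# log b_scaled) with b = b_scaled / r_max^2 for conditioning
theta_unpack <- function(theta, N, fix_b, r_max) {
  D <- exp(theta[seq_len(N)])
  if (N > 1) {
    z <- stats::plogis(theta[N + seq_len(N - 1)])
    f <- numeric(N); rem <- 1
    for (i in seq_len(N - 1)) { f[i] <- rem * z[i]; rem <- rem - f[i] }
    f[N] <- rem
  } else f <- 1
  b <- if (is.null(fix_b)) exp(theta[length(theta)]) / r_max^2 else fix_b
  list(D = D, f = f, b = b)
}

theta_pack <- function(D, f, b, fix_b, r_max) {
  N <- length(D)
  th <- log(D)
  if (N > 1) {
    z <- numeric(N - 1); rem <- 1
    for (i in seq_len(N - 1)) { z[i] <- f[i] / rem; rem <- rem - f[i] }
    th <- c(th, stats::qlogis(pmin(pmax(z, 1e-6), 1 - 1e-6)))
  }
  if (is.null(fix_b)) th <- c(th, log(max(b, 1e-12) * r_max^2))
  th
}

#' Fit a displacement distribution by maximum likelihood
#'
#' Maximizes the log-likelihood of the truncated multi-component Rayleigh
#' model with background term (see [displacement_pdf()]) over the component
#' diffusion coefficients `D_i`, fractions `f_i` and background slope `b`.
#' Optimization runs on transformed parameters (log D, stick-breaking
#' fractions, log background weight) with a deterministic multistart built
#' from method-of-moments and quantile-split initializers; the best
#' log-likelihood wins, ties broken toward fewer effective components.
#'
#' @param ds A [displacement_set()] or numeric vector of displacements (nm).
#' @param n_components Number of diffusive components (1 to 3).
#' @param dt Interval in ms (taken from `ds` when available).
#' @param r_max Truncation radius, nm (taken from `ds` when available);
#'   `Inf` for the untruncated model.
#' @param fix_b Fix the background slope at this value (e.g. `0`) instead of
#'   fitting it. `NULL` (default) fits `b` freely (finite `r_max` only).
#' @param min_n Minimum number of displacements required (default 50).
#' @return An object of class `smdm_fit`: list with `components`
#'   (data.frame `D`, `f`, sorted by descending D), `b`, `loglik`, `n`,
#'   `n_components`, `dt`, `r_max`, `converged`, `starts` (multistart log).
#' @export
fit_displacement_mle <- function(ds, n_components = 1, dt = NULL,
                                 r_max = NULL, fix_b = NULL, min_n = 50) {
  r <- displacement_r(ds)
  if (is.null(dt)) dt <- attr(ds, "dt")
  if (is.null(r_max)) r_max <- attr(ds, "r_max")
  if (is.null(dt)) stop("dt is required")
  if (is.null(r_max)) r_max <- Inf
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  if (length(r) < min_n)
    stop(sprintf("refusing to fit %d displacements (need >= %d)",
                 length(r), min_n))
  if (!is.finite(r_max) && is.null(fix_b))
    stop("fitting b requires a finite r_max; use fix_b = 0")
  N <- n_components
  r <- r[r > 0]    # r = 0 carries zero density mass in the 2r model

  D_mom <- max(mean(r^2) / (4 * dt) / 1e3, 1e-6)
  starts <- list()
  add_start <- function(D, f, b) {
    starts[[length(starts) + 1L]] <<- list(D = D, f = f, b = b)
  }
  bvals <- if (is.null(fix_b)) c(0.05 / r_max^2, 1e-6 / r_max^2) else fix_b
  if (N == 1) {
    for (b in bvals) { add_start(D_mom, 1, b); add_start(D_mom * 0.3, 1, b) }
  } else {
    # quantile split: partition sorted r into N blocks, one D per block
    qs <- stats::quantile(r, probs = seq(0, 1, length.out = N + 1))
    Dq <- numeric(N)
    for (i in seq_len(N)) {
      blk <- r[r >= qs[i] & r <= qs[i + 1]]
      Dq[i] <- max(mean(blk^2) / (4 * dt) / 1e3, 1e-6)
    }
    Dq <- sort(Dq, decreasing = TRUE)
    for (b in bvals) {
      add_start(Dq, rep(1 / N, N), b)
      add_start(D_mom * 2^seq(0, -2 * (N - 1), length.out = N),
                rep(1 / N, N), b)
      add_start(D_mom * 4^seq(0, -(N - 1)), c(0.7, rep(0.3 / (N - 1), N - 1)), b)
    }
  }

  negll <- function(theta) {
    par <- theta_unpack(theta, N, fix_b, r_max)
    if (any(!is.finite(par$D)) || any(par$D <= 0)) return(1e12)
    ll <- tryCatch(
      displacement_loglik(r, par$D, dt, f = par$f, b = par$b, r_max = r_max),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  best <- NULL; trace <- data.frame()
  for (s in starts) {
    th0 <- theta_pack(s$D, s$f, s$b, fix_b, r_max)
    fit <- tryCatch(
      stats::nlminb(th0, negll,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    trace <- rbind(trace, data.frame(loglik = -fit$objective,
                                     convergence = fit$convergence))
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  par <- theta_unpack(best$par, N, fix_b, r_max)
  ord <- order(par$D, decreasing = TRUE)
  structure(list(
    components = data.frame(D = par$D[ord], f = par$f[ord]),
    b = par$b,
    loglik = -best$objective,
    n = length(r),
    n_components = N,
    dt = dt, r_max = r_max,
    converged = best$convergence == 0,
    starts = trace
  ), class = "smdm_fit")
}

#' @export
print.smdm_fit <- function(x, ...) {
  cat(sprintf("displacement MLE fit: N = %d, n = %d, dt = %g ms, r_max = %g nm\n",
              x$n_components, x$n, x$dt, x$r_max))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  D_%d = %.4g um^2/s   f_%d = %.3f\n",
                i, x$components$D[i], i, x$components$f[i]))
  cat(sprintf("  b = %.3g /nm^2   logLik = %.2f   converged: %s\n",
              x$b, x$loglik, x$converged))
  invisible(x)
}
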