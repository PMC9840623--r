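#' Link localizations into single-particle trajectories
#'
#' Greedy frame-to-frame linking for long-exposure (one pulse per frame)
#' acquisitions. A link between consecutive frames is made only when it is
#' unambiguous in both directions: the localization in frame t has exactly
#' one candidate within `link_radius` in frame t + 1, and that candidate has
#' exactly one candidate in frame t. Any ambiguity terminates the affected
#' trajectories at that frame (pairing-uncertain links are discarded), and a
#' missed frame ends a trajectory (no gap closing). Trajectories shorter
#' than `min_len` or longer than `max_len` frames are dropped, not
#' truncated.
#'
#' @param table Localization table with `frame`, `x_nm`, `y_nm`.
#' @param link_radius Maximum step length, nm (default 800).
#' @param min_len Minimum trajectory length in frames (default 5).
#' @param max_len Maximum trajectory length in frames (default 30).
#' @return A `data.table` with columns `traj_id, frame, x_nm, y_nm`
#'   (class `spt_trajectories`); zero rows when nothing links.
#' @export
link_trajectories <- function(table, link_radius = 800, min_len = 5,
                              max_len = 30) {
  tb <- data.table::as.data.table(table)
  empty <- data.table::data.table(traj_id = integer(), frame = integer(),
                                  x_nm = numeric(), y_nm = numeric())
  data.table::setattr(empty, "class",
                      c("spt_trajectories", class(empty)))
  if (!nrow(tb)) return(empty)
  tb <- tb[order(frame, x_nm, y_nm)]
  n <- nrow(tb)
  succ <- rep(NA_integer_, n)     # row index of the unambiguous successor
  frames <- sort(unique(tb$frame))
  rows_of <- split(seq_len(n), tb$frame)
  for (fi in seq_len(length(frames) - 1)) {
    if (frames[fi + 1] != frames[fi] + 1L) next
    a <- rows_of[[as.character(frames[fi])]]
    b <- rows_of[[as.character(frames[fi + 1])]]
    d <- sqrt(outer(tb$x_nm[a], tb$x_nm[b], "-")^2 +
                outer(tb$y_nm[a], tb$y_nm[b], "-")^2)
    adm <- d <= link_radius
    fwd <- rowSums(adm)           # candidates ahead of each a
    bwd <- colSums(adm)           # candidates behind each b
    for (i in seq_along(a)) {
      if (fwd[i] != 1L) next
      j <- which(adm[i, ])
      if (bwd[j] != 1L) next
      succ[a[i]] <- b[j]
    }
  }
  has_pred <- logical(n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  starts <- which(!has_pred & !is.na(succ))
  out <- list()
  tid <- 0L
  for (s in starts) {
    chain <- s
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    if (length(chain) < min_len || length(chain) > max_len) next
    tid <- tid + 1L
    out[[tid]] <- data.table::data.table(
      traj_id = tid, frame = tb$frame[chain],
      x_nm = tb$x_nm[chain], y_nm = tb$y_nm[chain])
  }
  res <- if (length(out)) data.table::rbindlist(out) else empty
  data.table::setattr(res, "class",
                      unique(c("spt_trajectories", class(res))))
  res
}

#' Pooled step lengths of a trajectory set
#'
#' @param trajs Result of [link_trajectories()].
#' @return Numeric vector of step lengths, nm.
#' @export
trajectory_steps <- function(trajs) {
  if (!nrow(trajs)) return(numeric())
  tb <- data.table::as.data.table(trajs)
  tb[, {
    dx <- diff(x_nm); dy <- diff(y_nm)
    list(r = sqrt(dx^2 + dy^2))
  }, by = traj_id]$r
}

#' Fit pooled trajectory step sizes to the multi-component 2D random-walk
#' model
#'
#' Maximum likelihood on the untruncated mixture-of-Rayleighs density (no
#' background term: ambiguous links are discarded during tracking rather
#' than modelled).
#'
#' @param trajs [link_trajectories()] result (or a numeric vector of step
#'   lengths, nm).
#' @param dt Frame interval (exposure + dead time), ms.
#' @param n_components Number of diffusive components (1 to 3).
#' @param min_steps Minimum pooled steps required (default 200).
#' @return An `smdm_fit` object (see [fit_displacement_mle()]).
#' @export
fit_trajectory_displacements <- function(trajs, dt, n_components = 1,
                                         min_steps = 200) {
  r <- if (is.numeric(trajs)) trajs else trajectory_steps(trajs)
  if (length(r) < min_steps)
    stop(sprintf("refusing to fit %d pooled steps (need >= %d)",
                 length(r), min_steps))
  fit_displacement_mle(r, n_components = n_components, dt = dt,
                       r_max = Inf, fix_b = 0, min_n = min_steps)
}
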