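# Trajectory and count-series analysis: mean square displacement (with
# anomalous-exponent fit) and region enrichment.

#' Mean square displacement of tracked particles
#'
#' MSD(tau) is the mean over particles and all time origins (overlapping
#' windows) of the squared 3-D displacement at lag tau. The anomalous
#' exponent alpha is the least-squares slope of log MSD vs log tau over the
#' fit window, and `slope` the linear-fit slope of MSD vs tau over the same
#' window (equal to 4 D for free planar diffusion).
#'
#' @param traj data.frame with columns time, id, x, y, z; every trajectory
#'   must be sampled at the same uniform interval.
#' @param lags integer lags (in sampling intervals) at which to evaluate the
#'   MSD; default is ~60 log-spaced lags up to a quarter of the shortest
#'   trajectory.
#' @param fit_window numeric length-2 lag-time window (s) for the fits;
#'   default is the second decade of sampled lags, `c(10, 100) * interval`.
#' @return an object of class `msd_curve`: list with `curve` (data.frame
#'   lag, msd, npairs), `alpha`, `slope`, `fit_window`, `n_particles`, and
#'   `degenerate` (TRUE when the MSD is identically zero, e.g. a stationary
#'   particle, in which case alpha is NA).
#' @export
msd <- function(traj, lags = NULL, fit_window = NULL) {
  if (nrow(traj) == 0) stop("empty trajectory")
  ids <- unique(traj$id)
  mats <- list(); h <- NULL
  for (i in ids) {
    tr <- traj[traj$id == i, , drop = FALSE]
    tr <- tr[order(tr$time), , drop = FALSE]
    if (nrow(tr) < 2) next
    dts <- diff(tr$time)
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      stop("uniform sampling interval required")
    if (is.null(h)) h <- dts[1]
    else if (abs(dts[1] - h) > 1e-6 * h)
      stop("all trajectories must share the same sampling interval")
    mats[[length(mats) + 1]] <- cbind(tr$x, tr$y, tr$z)
  }
  if (length(mats) == 0) stop("need at least one trajectory with >= 2 samples")
  nmin <- min(vapply(mats, nrow, integer(1)))
  if (is.null(lags)) {
    lmax <- max(1, floor((nmin - 1) / 4))
    lags <- unique(round(exp(seq(0, log(lmax), length.out = 60))))
  } else {
    lags <- as.integer(lags)
    if (any(lags >= nmin))
      stop("lag exceeds trajectory length")
  }
  vals <- numeric(length(lags)); npairs <- numeric(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]; acc <- 0; cnt <- 0
    for (m in mats) {
      n <- nrow(m)
      if (L >= n) next
      d <- m[(1 + L):n, , drop = FALSE] - m[1:(n - L), , drop = FALSE]
      acc <- acc + sum(d * d)
      cnt <- cnt + (n - L)
    }
    vals[k] <- acc / cnt; npairs[k] <- cnt
  }
  curve <- data.frame(lag = c(0, lags * h), msd = c(0, vals),
                      npairs = c(sum(vapply(mats, nrow, integer(1))), npairs))
  degenerate <- all(vals <= 0)
  if (is.null(fit_window)) fit_window <- c(10, 100) * h
  sel <- curve$lag >= fit_window[1] & curve$lag <= fit_window[2] &
    curve$msd > 0
  alpha <- slope <- NA_real_
  if (!degenerate && sum(sel) >= 2) {
    alpha <- unname(coef(lm(log(curve$msd[sel]) ~ log(curve$lag[sel])))[2])
    slope <- unname(coef(lm(curve$msd[sel] ~ curve$lag[sel]))[2])
  }
  structure(list(curve = curve, alpha = alpha, slope = slope,
                 fit_window = fit_window, n_particles = length(mats),
                 degenerate = degenerate), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD over %d particle(s), %d lags\n", x$n_particles,
              nrow(x$curve) - 1))
  if (x$degenerate) cat("  degenerate: MSD identically zero (alpha undefined)\n")
  else cat(sprintf("  fit window [%.3g, %.3g] s: slope %.4g um^2/s, alpha %.3f\n",
                   x$fit_window[1], x$fit_window[2], x$slope, x$alpha))
  invisible(x)
}

#' Fraction of a species' molecules on a named surface over time
#'
#' Bound complexes can be counted with the species by listing them in
#' `bound_species`; they are counted as on the surface regardless of panel
#' (e.g. scaffold-bound receptors sit at the PSD by construction).
#'
#' @param counts a [sim_counts()]-style data.frame (time, species, surface,
#'   count).
#' @param species species name(s) whose location is being asked about.
#' @param surface surface name.
#' @param bound_species complex species counted as on the surface.
#' @return data.frame (time, fraction).
#' @export
enrichment <- function(counts, species, surface, bound_species = NULL) {
  if (!surface %in% counts$surface) stop(sprintf("unknown surface '%s'", surface))
  times <- sort(unique(counts$time))
  on_sel <- counts$species %in% species & counts$surface == surface
  tot_sel <- counts$species %in% species
  bnd_sel <- counts$species %in% (bound_species %||% character(0))
  agg <- function(sel) {
    v <- tapply(counts$count[sel], factor(counts$time[sel], levels = times),
                sum)
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  num <- agg(on_sel) + agg(bnd_sel)
  den <- agg(tot_sel) + agg(bnd_sel)
  data.frame(time = times, fraction = ifelse(den > 0, num / den, NA_real_))
}

#' Fraction of receptors in the bound state over time
#'
#' @param counts a counts data.frame.
#' @param complex bound-complex species name.
#' @param free free species name(s).
#' @return data.frame (time, fraction).
#' @export
bound_fraction <- function(counts, complex = "AMPAR_Scaffold",
                           free = "AMPAR") {
  times <- sort(unique(counts$time))
  agg <- function(sel) {
    v <- tapply(counts$count[sel], factor(counts$time[sel], levels = times),
                sum)
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  cval <- agg(counts$species == complex)
  fval <- agg(counts$species %in% free)
  den <- cval + fval
  data.frame(time = times, fraction = ifelse(den > 0, cval / den, NA_real_))
}

#' First time a series reaches a threshold
#'
#' @param series data.frame with a time column and a value column.
#' @param threshold value to reach.
#' @param column value column name.
#' @return the earliest time at which the value is >= threshold, or NA.
#' @export
time_to_threshold <- function(series, threshold = 0.9, column = "fraction") {
  hit <- which(series[[column]] >= threshold)
  if (length(hit) == 0) NA_real_ else series$time[hit[1]]
}

#' Time-averaged per-surface molecule counts
#'
#' Averages the recorded counts of a species over all records with
#' `time >= from_time`; used for steady-state occupancy ratios.
#'
#' @param counts a counts data.frame.
#' @param species species name.
#' @param from_time start of the averaging window (s).
#' @return named numeric vector of mean counts per surface.
#' @export
surface_occupancy <- function(counts, species, from_time = 0) {
  sel <- counts$species == species & counts$time >= from_time
  if (!any(sel)) stop("no records in the averaging window")
  tapply(counts$count[sel], counts$surface[sel], mean)
}
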