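# Biased (1/N) autocovariance for lags 0..n_lag via zero-padded FFT;
# identical to the direct sum_{i} dz_i dz_{i+t} / N estimator.
autocovariance_fft <- function(v, n_lag) {
  n <- length(v)
  x <- v - mean(v)
  m <- stats::nextn(2L * n)
  xf <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(xf * Conj(xf), inverse = TRUE)) / m
  ac[seq_len(min(n_lag, n - 1L) + 1L)] / n
}

#' Autocovariance of a restrained time series
#'
#' Computes the biased (1/N) estimator of
#' `C_zz(t) = <dz(0) dz(t)>` with `dz = z - mean(z)`, the integrated
#' autocorrelation time `tau_int = int C_zz dt / C_zz(0)`, and the
#' integration cutoff used: the first non-positive lag of the
#' autocovariance, falling back to the first lag where it drops below
#' 1% of the variance, else the full `max_lag`.
#'
#' @param series A [trajectory_series()].
#' @param max_lag Maximum lag in ps.
#' @return Object of class `acf_result`: `lags` (ps), `acf` (A^2),
#'   `variance`, `tau_int` (ps), `cutoff_lag` (ps).
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(inherits(series, "trajectory_series"))
  v <- series$values
  dt <- series$dt
  n_lag <- floor(max_lag / dt)
  if (length(v) < 10 * n_lag) {
    warning("series shorter than 10 x max_lag; ACF tail will be noisy")
  }
  if (n_lag < 1L) stop("max_lag must be at least one sampling interval")
  if (var(v) == 0) stop("constant series: variance is zero")
  a <- autocovariance_fft(v, n_lag)
  lags <- dt * (seq_along(a) - 1L)
  variance <- a[1]
  # cutoff: first zero crossing, else first drop below 1% of variance
  neg <- which(a <= 0)
  small <- which(a < 0.01 * variance)
  cut_idx <- if (length(neg)) {
    neg[1] - 1L
  } else if (length(small)) {
    small[1] - 1L
  } else {
    length(a)
  }
  cut_idx <- max(cut_idx, 1L)
  integral <- pracma::trapz(lags[1:max(cut_idx, 2L)],
                            a[1:max(cut_idx, 2L)])
  structure(
    list(lags = lags, acf = a, variance = variance,
         tau_int = integral / variance, cutoff_lag = lags[cut_idx],
         integral = integral),
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf(
    "<acf_result> var = %.4g A^2, tau_int = %.4g ps, cutoff = %g ps\n",
    x$variance, x$tau_int, x$cutoff_lag))
  invisible(x)
}

#' Local diffusion coefficient from a restrained trajectory
#'
#' For a harmonically restrained, equilibrated series the local
#' diffusion coefficient is
#' `D = <dz^2>^2 / int_0^cutoff C_zz(t) dt = variance / tau_int`
#' (trapezoidal integration of the autocovariance).
#'
#' @param series A [trajectory_series()].
#' @param max_lag Maximum ACF lag in ps; defaults to a tenth of the
#'   series length.
#' @return D in A^2/ps.
#' @export
estimate_D <- function(series, max_lag = NULL) {
  stopifnot(inherits(series, "trajectory_series"))
  if (is.null(max_lag)) {
    max_lag <- length(series$values) * series$dt / 10
  }
  ac <- autocorrelation(series, max_lag)
  if (ac$cutoff_lag <= series$dt) {
    stop(paste("autocovariance decays within one sampling interval;",
               "sample more frequently or run a longer series"))
  }
  if (ac$integral <= 0) {
    stop("non-positive autocovariance integral; run a longer series")
  }
  ac$variance^2 / ac$integral
}

#' Assemble a D(z) profile from per-window estimates
#'
#' Interpolates log D linearly between window centres (diffusivity
#' varies multiplicatively across the membrane interface, and log-space
#' interpolation preserves positivity), extrapolates as a constant
#' beyond the outermost centres, and combines repeat estimates at one
#' centre by their geometric mean, keeping the spread (sd of log10 D).
#'
#' @param estimates Data frame with columns `center` (A) and `D`
#'   (A^2/ps), one row per independent estimate; repeats allowed.
#' @param target_grid Grid (A) on which to report the profile.
#' @return A [profile()] of D in A^2/ps, with `stderr` holding the
#'   per-point interpolated sd of log10 D where repeats exist, and the
#'   per-centre table in `meta$by_center`.
#' @export
build_D_profile <- function(estimates, target_grid) {
  estimates <- as.data.frame(estimates)
  if (!all(c("center", "D") %in% names(estimates)) ||
      nrow(estimates) == 0L) {
    stop("estimates needs non-empty columns center and D")
  }
  if (any(estimates$D <= 0)) stop("all D estimates must be positive")
  agg <- do.call(rbind, lapply(split(estimates, estimates$center),
    function(d) {
      data.frame(center = d$center[1],
                 D = exp(mean(log(d$D))),
                 spread = if (nrow(d) > 1) sd(log10(d$D)) else 0,
                 n = nrow(d))
    }))
  agg <- agg[order(agg$center), ]
  if (nrow(agg) < 2L) stop("need estimates at >= 2 distinct centers")
  logD <- approx(agg$center, log(agg$D), xout = target_grid,
                 rule = 2)$y
  spread <- approx(agg$center, agg$spread, xout = target_grid,
                   rule = 2)$y
  profile(target_grid, exp(logD), stderr = spread, units = "A^2/ps",
          meta = list(interp = "log-linear", by_center = agg))
}

#' Per-window diffusion coefficients from umbrella runs
#'
#' Convenience driver: runs (or accepts) one restrained series per
#' window and returns the estimates table [build_D_profile()] consumes.
#' The restraints use a common force constant (2.5 kcal/(mol A^2), half
#' convention, by default), independent of the force constants used for
#' the free-energy windows.
#'
#' The default run length (400000 steps of 0.05 ps) gives 20 ns of
#' sampling per window and repeat.
#' @param model A [make_membrane_model()].
#' @param centers Restraint centres (A).
#' @param k Restraint force constant, kcal/(mol A^2), half convention.
#' @param n_steps,dt,stride,seed Passed to [simulate_langevin()];
#'   `seed` is used for the first window and incremented per window.
#' @param n_repeats Independent repeats per centre.
#' @param burn_in Fraction of each series discarded from the front.
#' @return Data frame with columns `center`, `D`, `repeat`.
#' @export
estimate_D_by_window <- function(model, centers, k = 2.5,
                                 n_steps = 400000L, dt = 0.05,
                                 stride = 2L, seed = NULL,
                                 n_repeats = 2L, burn_in = 0.05) {
  rows <- list()
  for (r in seq_len(n_repeats)) {
    for (i in seq_along(centers)) {
      s <- if (is.null(seed)) NULL else seed + (r - 1L) * length(centers) + i
      w <- umbrella_window(centers[i], k, "half")
      traj <- simulate_langevin(model, bias = w, dt = dt,
                                n_steps = n_steps, seed = s,
                                stride = stride)
      v <- traj$values
      v <- v[-seq_len(floor(burn_in * length(v)))]
      traj <- trajectory_series(v, dt = traj$dt, units = traj$units)
      rows[[length(rows) + 1L]] <- data.frame(
        center = centers[i], D = estimate_D(traj), rep = r)
    }
  }
  do.call(rbind, rows)
}
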