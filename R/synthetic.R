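#' Uniformly spaced time series of a scalar observable
#'
#' @param values Numeric observations.
#' @param dt Sampling interval in ps, positive.
#' @param t0 Time of the first sample, ps.
#' @param units Unit label of the observable.
#' @return Object of class `trajectory_series`.
#' @export
trajectory_series <- function(values, dt, t0 = 0, units = "A") {
  values <- as.numeric(values)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!length(values) || any(!is.finite(values))) {
    stop("values must be non-empty and finite")
  }
  structure(list(values = values, dt = dt, t0 = t0, units = units),
            class = "trajectory_series")
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("<trajectory_series> %d samples, dt = %g ps (%g ps total)\n",
              length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' @export
length.trajectory_series <- function(x) length(x$values)

#' Membrane-like 1D model: free energy and diffusivity along z
#'
#' Constructs closed-form G(z) (kcal/mol) and D(z) (A^2/ps) profiles on
#' one membrane leaflet, z in `[0, z_bulk]` with z = 0 the bilayer
#' centre. Presets:
#' \describe{
#'   \item{flat}{G = 0 everywhere.}
#'   \item{square_barrier}{a smoothed step of height `h` (kcal/mol) for
#'     z below the half-width `w`; params `h`, `w`, `smooth` (the
#'     tanh smoothing length, wide enough for the default 0.5 A
#'     histogram bins to resolve the step).}
#'   \item{popc_like}{a central barrier, an interfacial free-energy
#'     minimum near z = 12 A and a headgroup peak near z = 25 A, with G
#'     tending to 0 in bulk water; diffusivity reduced inside the
#'     membrane.}
#'   \item{chol50_like}{free energy monotonically increasing from bulk
#'     toward the bilayer centre (the interfacial minimum is abolished,
#'     as in cholesterol-rich membranes).}
#' }
#' Gaussian components keep the profiles smooth and differentiable.
#'
#' @param preset One of `"flat"`, `"square_barrier"`, `"popc_like"`,
#'   `"chol50_like"`.
#' @param params Named list overriding preset parameters (see Details).
#' @param thermo A [thermo_state()].
#' @param z_bulk Bulk-water edge of the leaflet, Angstrom.
#' @return Object of class `membrane_model` with vectorised functions
#'   `G`, `dG`, `D`, `dD` and fields `z_range`, `thermo`, `preset`.
#' @export
make_membrane_model <- function(preset = c("popc_like", "chol50_like",
                                           "flat", "square_barrier"),
                                params = list(),
                                thermo = thermo_state(300),
                                z_bulk = 37.5) {
  preset <- match.arg(preset)
  p <- switch(preset,
    flat = list(D0 = 0.1),
    square_barrier = list(h = 5, w = 15, smooth = 1.0, D0 = 0.1),
    popc_like = list(
      A0 = 5, s0 = 3,          # central barrier
      A1 = 1.5, z1 = 25, s1 = 3,  # headgroup peak
      A2 = 2.5, z2 = 12, s2 = 3,  # interfacial minimum
      D0 = 0.1, Dmin_frac = 0.3, zD = 15, wD = 4),
    chol50_like = list(h = 8, s = 10, D0 = 0.1, Dmin_frac = 0.3,
                       zD = 15, wD = 4)
  )
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) {
    stop("unknown params for preset '", preset, "': ",
         paste(unknown, collapse = ", "))
  }
  p[names(params)] <- params

  gauss <- function(z, A, z0, s) A * exp(-(z - z0)^2 / (2 * s^2))
  dgauss <- function(z, A, z0, s) -A * (z - z0) / s^2 *
    exp(-(z - z0)^2 / (2 * s^2))

  if (preset == "flat") {
    G <- function(z) rep(0, length(z))
    dG <- function(z) rep(0, length(z))
  } else if (preset == "square_barrier") {
    G <- function(z) p$h / 2 * (1 - tanh((z - p$w) / p$smooth))
    dG <- function(z) -p$h / (2 * p$smooth) / cosh((z - p$w) / p$smooth)^2
  } else if (preset == "popc_like") {
    G <- function(z) gauss(z, p$A0, 0, p$s0) + gauss(z, p$A1, p$z1, p$s1) -
      gauss(z, p$A2, p$z2, p$s2)
    dG <- function(z) dgauss(z, p$A0, 0, p$s0) + dgauss(z, p$A1, p$z1, p$s1) -
      dgauss(z, p$A2, p$z2, p$s2)
  } else { # chol50_like
    G <- function(z) gauss(z, p$h, 0, p$s)
    dG <- function(z) dgauss(z, p$h, 0, p$s)
  }

  if (preset %in% c("popc_like", "chol50_like")) {
    # diffusivity drops smoothly from its bulk value inside the membrane
    Dfun <- function(z) p$D0 * (p$Dmin_frac + (1 - p$Dmin_frac) *
                                  0.5 * (1 + tanh((z - p$zD) / p$wD)))
    dDfun <- function(z) p$D0 * (1 - p$Dmin_frac) /
      (2 * p$wD * cosh((z - p$zD) / p$wD)^2)
  } else {
    Dfun <- function(z) rep(p$D0, length(z))
    dDfun <- function(z) rep(0, length(z))
  }

  structure(
    list(G = G, dG = dG, D = Dfun, dD = dDfun,
         z_range = c(0, z_bulk), thermo = thermo,
         preset = preset, params = p),
    class = "membrane_model"
  )
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> preset '%s' on [%g, %g] A, T = %g K\n",
              x$preset, x$z_range[1], x$z_range[2], x$thermo$temperature))
  invisible(x)
}

#' Membrane model from tabulated profiles
#'
#' Wraps measured or external G(z) and D(z) profiles into a
#' `membrane_model` via monotone-safe spline interpolation, so they can
#' drive the Langevin sampler or the permeability stage.
#'
#' @param G_profile [profile()] of free energy (kcal/mol).
#' @param D_profile [profile()] of diffusivity (A^2/ps), strictly
#'   positive.
#' @param thermo A [thermo_state()].
#' @return A `membrane_model`.
#' @export
model_from_profiles <- function(G_profile, D_profile,
                                thermo = thermo_state(300)) {
  stopifnot(inherits(G_profile, "profile"), inherits(D_profile, "profile"))
  if (any(D_profile$values <= 0)) stop("D must be positive everywhere")
  Gf <- stats::splinefun(G_profile$grid, G_profile$values, method = "natural")
  logDf <- stats::splinefun(D_profile$grid, log(D_profile$values),
                            method = "natural")
  zr <- range(G_profile$grid)
  structure(
    list(G = function(z) Gf(z), dG = function(z) Gf(z, deriv = 1),
         D = function(z) exp(logDf(z)),
         dD = function(z) exp(logDf(z)) * logDf(z, deriv = 1),
         z_range = zr, thermo = thermo, preset = "tabulated",
         params = list()),
    class = "membrane_model"
  )
}

# Tabulate model forces/diffusivity on a fine uniform grid for the C++
# integrator (linear interpolation inside the sampler).
tabulate_model <- function(model, bias = NULL, n_grid = 3751L) {
  zr <- model$z_range
  grid <- seq(zr[1], zr[2], length.out = n_grid)
  list(grid = grid, dG = model$dG(grid), D = model$D(grid),
       dD = model$dD(grid))
}

check_timestep <- function(model, tab, bias, dt) {
  force <- abs(tab$dG)
  keep <- rep(TRUE, length(tab$grid))
  if (!is.null(bias)) {
    force <- force + k_half(bias) * abs(tab$grid - bias$center)
    # a restrained walker only visits ~5 sd around the bias centre
    sd_eq <- sqrt(1 / (model$thermo$beta * k_half(bias)))
    keep <- abs(tab$grid - bias$center) <= 5 * sd_eq
    if (!any(keep)) keep <- rep(TRUE, length(tab$grid))
  }
  max_drift <- max((model$thermo$beta * tab$D * force + abs(tab$dD))[keep])
  if (max_drift * dt > 0.5) {
    warning(sprintf(
      "dt = %g ps gives a maximum drift step of %.3g A; consider a smaller dt",
      dt, max_drift * dt))
  }
}

#' Overdamped Langevin dynamics on a membrane model
#'
#' Integrates the Brownian (position) Langevin equation
#' `dz = [-beta D(z) (G + U_bias)'(z) + D'(z)] dt + sqrt(2 D(z) dt) xi`
#' with the spurious-drift term `D'(z)` required for position-dependent
#' diffusivity, and reflecting boundaries at the edges of the model's z
#' range. The stationary density is proportional to
#' `exp(-beta (G + U_bias))`.
#'
#' @param model A [make_membrane_model()] object.
#' @param bias Optional [umbrella_window()] harmonic restraint.
#' @param dt Integration time step, ps.
#' @param n_steps Number of integration steps.
#' @param seed Optional integer seed.
#' @param z0 Initial position; defaults to the bias centre (or the
#'   mid-range if unbiased), clamped to the z range.
#' @param stride Save every `stride`-th step.
#' @return A [trajectory_series()] with `dt * stride` sampling interval.
#' @export
simulate_langevin <- function(model, bias = NULL, dt = 0.05,
                              n_steps = 10000L, seed = NULL, z0 = NULL,
                              stride = 1L) {
  stopifnot(inherits(model, "membrane_model"))
  if (!is.null(bias)) stopifnot(inherits(bias, "umbrella_window"))
  if (n_steps < stride) stop("n_steps must be at least stride")
  tab <- tabulate_model(model)
  check_timestep(model, tab, bias, dt)
  if (is.null(z0)) {
    z0 <- if (is.null(bias)) mean(model$z_range) else bias$center
  }
  z0 <- min(max(z0, model$z_range[1]), model$z_range[2])
  if (!is.null(seed)) set.seed(seed)
  res <- langevin_cpp(tab$grid, tab$dG, tab$D, tab$dD,
                      model$thermo$beta, dt, as.integer(n_steps), z0,
                      if (is.null(bias)) 0 else bias$center,
                      if (is.null(bias)) 0 else k_half(bias),
                      as.integer(stride))
  if (res$diverged) {
    stop(sprintf("divergent Langevin step (|dz| > 5 A) at dt = %g ps", dt))
  }
  trajectory_series(res$z, dt = dt * stride, units = "A")
}

#' Replica-exchange umbrella sampling on a membrane model
#'
#' Runs one Brownian walker per umbrella window and, every
#' `exchange_interval` steps, attempts Metropolis swaps of the
#' configurations of alternating even/odd neighbouring window pairs with
#' acceptance probability
#' `min(1, exp(-beta [U_i(z_j) + U_j(z_i) - U_i(z_i) - U_j(z_j)]))`.
#'
#' @param model A [make_membrane_model()].
#' @param schedule A [window_schedule()] with at least two windows.
#' @param n_steps Integration steps per window.
#' @param exchange_interval Steps between exchange attempts (>= 1); the
#'   default with `dt = 0.05` ps attempts exchanges every 10 ps.
#' @param dt Time step, ps.
#' @param seed Optional integer seed.
#' @param stride Save every `stride`-th step.
#' @return Object of class `reus_result`: `series` (list of
#'   [trajectory_series()], one per window), `exchange` (data frame of
#'   attempts: time, pair, dU, u, accepted), `acceptance` (per-pair
#'   empirical rates) and the `schedule`.
#' @export
run_reus <- function(model, schedule, n_steps = 20000L,
                     exchange_interval = 200L, dt = 0.05, seed = NULL,
                     stride = 1L) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(schedule, "window_schedule"))
  if (length(schedule) < 2L) stop("run_reus needs at least two windows")
  if (exchange_interval < 1L) stop("exchange_interval must be >= 1")
  tab <- tabulate_model(model)
  centers <- window_centers(schedule)
  kh <- vapply(schedule$windows, k_half, numeric(1))
  z_init <- pmin(pmax(centers, model$z_range[1]), model$z_range[2])
  if (!is.null(seed)) set.seed(seed)
  res <- reus_cpp(tab$grid, tab$dG, tab$D, tab$dD, model$thermo$beta,
                  dt, as.integer(n_steps), as.integer(exchange_interval),
                  centers, kh, z_init, as.integer(stride))
  series <- lapply(seq_along(centers), function(w) {
    trajectory_series(res$z[, w], dt = dt * stride, units = "A")
  })
  names(series) <- sprintf("w%02d", seq_along(centers))
  exchange <- data.frame(
    time = res$attempt_time, pair = res$attempt_pair,
    dU = res$attempt_dU, u = res$attempt_u,
    accepted = as.logical(res$attempt_accepted)
  )
  acceptance <- if (nrow(exchange)) {
    agg <- tapply(exchange$accepted, exchange$pair, mean)
    natt <- tapply(exchange$accepted, exchange$pair, length)
    data.frame(pair = as.integer(names(agg)), rate = as.numeric(agg),
               n_attempts = as.integer(natt))
  } else {
    data.frame(pair = integer(), rate = numeric(), n_attempts = integer())
  }
  structure(
    list(series = series, exchange = exchange, acceptance = acceptance,
         schedule = schedule, dt = dt * stride),
    class = "reus_result"
  )
}

#' @export
print.reus_result <- function(x, ...) {
  cat(sprintf(
    "<reus_result> %d windows x %d samples; mean neighbour acceptance %.3f\n",
    length(x$series), length(x$series[[1]]),
    mean(x$acceptance$rate)))
  invisible(x)
}
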