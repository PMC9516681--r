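#' Boltzmann constant in kcal/(mol K)
#'
#' AMBER-convention value used throughout the package; energies are
#' kcal/mol, lengths Angstrom, times ps.
#' @export
KB_KCAL <- 0.0019872041

#' Thermodynamic state
#'
#' Bundles a temperature with the Boltzmann constant and the derived
#' inverse temperature `beta = 1/(kB*T)` (mol/kcal).
#'
#' @param temperature Temperature in kelvin; must be positive.
#' @return An object of class `thermo_state` with fields `temperature`,
#'   `kB` and `beta`.
#' @examples
#' th <- thermo_state(300)
#' th$beta # about 1.677 mol/kcal
#' @export
thermo_state <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number (kelvin)")
  }
  structure(
    list(temperature = temperature, kB = KB_KCAL,
         beta = 1 / (KB_KCAL * temperature)),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, beta = %.6g mol/kcal\n",
              x$temperature, x$beta))
  invisible(x)
}

#' Profile of a quantity on a strictly increasing grid
#'
#' A `profile` holds values of some observable (free energy, diffusion
#' coefficient, resistance, autocorrelation, ...) on a strictly
#' increasing 1D grid, with optional per-point standard errors.
#'
#' @param grid Strictly increasing numeric grid (Angstrom, or ps for
#'   lag-time profiles).
#' @param values Numeric vector, same length as `grid`. `NA` marks
#'   undefined points (e.g. empty histogram bins).
#' @param stderr Optional non-negative standard errors, same length.
#' @param units Unit label for `values`.
#' @param grid_units Unit label for `grid`.
#' @param meta Optional named list of metadata (conventions, anchors).
#' @return Object of class `profile`.
#' @export
profile <- function(grid, values, stderr = NULL, units = "",
                    grid_units = "A", meta = list()) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values)) {
    stop("grid and values must have equal length")
  }
  if (length(grid) == 0L) stop("empty profile")
  if (any(!is.finite(grid)) || any(diff(grid) <= 0)) {
    stop("grid must be finite and strictly increasing")
  }
  if (!is.null(stderr)) {
    stderr <- as.numeric(stderr)
    if (length(stderr) != length(grid)) {
      stop("stderr must match grid length")
    }
    if (any(stderr < 0, na.rm = TRUE)) stop("stderr must be non-negative")
  }
  structure(
    list(grid = grid, values = values, stderr = stderr,
         units = units, grid_units = grid_units, meta = meta),
    class = "profile"
  )
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile> %d points on [%g, %g] %s; values in %s%s\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)],
              x$grid_units, if (nzchar(x$units)) x$units else "(unitless)",
              if (is.null(x$stderr)) "" else "; has stderr"))
  invisible(x)
}

#' @export
as.data.frame.profile <- function(x, ...) {
  d <- data.frame(grid = x$grid, value = x$values)
  if (!is.null(x$stderr)) d$stderr <- x$stderr
  d
}

#' Umbrella window (harmonic restraint)
#'
#' @param center Restraint center z0 in Angstrom.
#' @param k Force constant in kcal/(mol A^2); must be positive.
#' @param convention Harmonic convention: `"half"` means
#'   U = (k/2)(z - z0)^2, `"full"` means U = k (z - z0)^2.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (!is.finite(center)) stop("center must be finite")
  if (!is.finite(k) || k <= 0) stop("force constant k must be positive")
  structure(list(center = center, k = k, convention = convention),
            class = "umbrella_window")
}

#' Effective half-convention force constant of a window
#'
#' Internally all bias energies are evaluated as U = (k_half/2)(z-z0)^2;
#' a window declared in the full convention (U = k (z-z0)^2) has
#' k_half = 2 k.
#' @param window An `umbrella_window`.
#' @return Numeric half-convention force constant.
#' @export
k_half <- function(window) {
  if (window$convention == "half") window$k else 2 * window$k
}

#' Bias energy of an umbrella window
#'
#' @param window An `umbrella_window`.
#' @param z Positions (Angstrom).
#' @return Energies in kcal/mol.
#' @export
bias_energy <- function(window, z) {
  0.5 * k_half(window) * (z - window$center)^2
}

#' Ordered schedule of umbrella windows
#'
#' @param windows List of `umbrella_window` objects with strictly
#'   increasing, duplicate-free centers.
#' @return Object of class `window_schedule`.
#' @export
window_schedule <- function(windows) {
  if (!length(windows)) stop("schedule needs at least one window")
  ok <- vapply(windows, inherits, logical(1), "umbrella_window")
  if (!all(ok)) stop("all elements must be umbrella_window objects")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (any(diff(centers) <= 0)) {
    stop("window centers must be strictly increasing with no duplicates")
  }
  structure(list(windows = windows), class = "window_schedule")
}

#' @export
length.window_schedule <- function(x) length(x$windows)

#' @export
print.window_schedule <- function(x, ...) {
  cen <- window_centers(x)
  cat(sprintf("<window_schedule> %d windows, centers %g..%g A\n",
              length(cen), min(cen), max(cen)))
  invisible(x)
}

#' @export
as.data.frame.window_schedule <- function(x, ...) {
  data.frame(
    center = window_centers(x),
    k = vapply(x$windows, `[[`, numeric(1), "k"),
    convention = vapply(x$windows, `[[`, character(1), "convention")
  )
}

#' Window centers of a schedule
#' @param schedule A `window_schedule`.
#' @return Numeric vector of centers (Angstrom).
#' @export
window_centers <- function(schedule) {
  vapply(schedule$windows, `[[`, numeric(1), "center")
}

#' Solute-tempering temperature ladder
#'
#' @param rungs Strictly increasing temperatures (kelvin); the first rung
#'   is the system temperature.
#' @return Object of class `temperature_ladder`.
#' @export
temperature_ladder <- function(rungs) {
  rungs <- as.numeric(rungs)
  if (length(rungs) < 1L || any(!is.finite(rungs)) || any(rungs <= 0)) {
    stop("rungs must be positive finite temperatures")
  }
  if (any(diff(rungs) <= 0)) stop("rungs must be strictly increasing")
  structure(list(rungs = rungs), class = "temperature_ladder")
}

#' Default solute-temperature ladder (kelvin)
#'
#' Eight rungs from the system temperature of 300 K up to 980 K, spaced
#' to keep neighbour exchange rates roughly uniform.
#' @return A `temperature_ladder`.
#' @export
default_temperature_ladder <- function() {
  temperature_ladder(c(300, 340, 390, 455, 540, 645, 785, 980))
}

#' Solute-tempering scaling factor
#'
#' In replica exchange with solute tempering the solute's nonbonded and
#' dihedral energies are scaled by `lambda = T_system / T_solute`, so the
#' solute effectively samples at the elevated temperature `T_solute`.
#'
#' @param T_system System (bath) temperature, kelvin.
#' @param T_solute Effective solute temperature, kelvin.
#' @return Dimensionless scaling factor.
#' @examples
#' rest_lambda(300, 2100) # 0.143 to three decimals
#' @export
rest_lambda <- function(T_system, T_solute) {
  if (!is.finite(T_system) || T_system <= 0 ||
      !is.finite(T_solute) || T_solute <= 0) {
    stop("temperatures must be positive")
  }
  T_system / T_solute
}

#' Effective solute temperature implied by a scaling factor
#'
#' Inverse of [rest_lambda()]: `T_solute = T_system / lambda`.
#'
#' @param lambda Dimensionless scaling factor, positive.
#' @param T_system System temperature, kelvin.
#' @return Effective solute temperature in kelvin.
#' @examples
#' effective_temperature(0.143, 300) # about 2100 K
#' @export
effective_temperature <- function(lambda, T_system) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (!is.finite(T_system) || T_system <= 0) {
    stop("T_system must be positive")
  }
  T_system / lambda
}

#' Build an umbrella-window schedule from segment rules
#'
#' Each segment tiles `[z_start, z_end]` with windows every `spacing`
#' Angstrom at force constant `k`. The first segment includes both
#' endpoints; a later segment whose start coincides with the previous
#' segment's end drops that duplicate (the finer segment's window is
#' kept). The default segments place 28 windows: z = 0..6 A at 1.0 A
#' spacing with k = 1.5 kcal/(mol A^2) and z = 6..37.5 A at 1.5 A
#' spacing with k = 0.5 kcal/(mol A^2).
#'
#' @param segments Data frame (or list coercible to one) with columns
#'   `z_start`, `z_end`, `spacing`, `k`.
#' @param convention Harmonic convention for the force constants.
#' @return A `window_schedule`.
#' @examples
#' length(build_window_schedule()) # 28
#' @export
build_window_schedule <- function(segments = default_segments(),
                                  convention = c("half", "full")) {
  convention <- match.arg(convention)
  segments <- as.data.frame(segments)
  need <- c("z_start", "z_end", "spacing", "k")
  if (!all(need %in% names(segments))) {
    stop("segments needs columns z_start, z_end, spacing, k")
  }
  if (nrow(segments) == 0L) stop("no segments given")
  if (any(segments$z_end <= segments$z_start)) {
    stop("each segment must have z_end > z_start")
  }
  if (any(segments$spacing <= 0) || any(segments$k <= 0)) {
    stop("spacing and k must be positive")
  }
  if (nrow(segments) > 1L) {
    if (any(diff(segments$z_start) <= 0) ||
        any(segments$z_start[-1] < segments$z_end[-nrow(segments)] - 1e-9)) {
      stop("segments must be ordered and non-overlapping")
    }
  }
  windows <- list()
  prev_end <- -Inf
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    n_span <- (s$z_end - s$z_start) / s$spacing
    if (abs(n_span - round(n_span)) > 1e-9) {
      stop(sprintf(
        "spacing %g does not evenly tile segment [%g, %g]",
        s$spacing, s$z_start, s$z_end))
    }
    centers <- s$z_start + s$spacing * seq(0L, round(n_span))
    if (is.finite(prev_end) && abs(centers[1] - prev_end) < 1e-9) {
      centers <- centers[-1]  # keep the finer segment's shared window
    }
    for (z0 in centers) {
      windows[[length(windows) + 1L]] <-
        umbrella_window(z0, s$k, convention)
    }
    prev_end <- s$z_end
  }
  window_schedule(windows)
}

#' Default window segments
#'
#' Fine sampling near the bilayer centre (0-6 A, 1.0 A spacing,
#' k = 1.5 kcal/(mol A^2)) and coarser sampling out to bulk water
#' (6-37.5 A, 1.5 A spacing, k = 0.5 kcal/(mol A^2)).
#' @return Data frame of segment rules.
#' @export
default_segments <- function() {
  data.frame(
    z_start = c(0, 6),
    z_end = c(6, 37.5),
    spacing = c(1.0, 1.5),
    k = c(1.5, 0.5)
  )
}

#' Convert a diffusion coefficient from A^2/ps to cm^2/s
#'
#' 1 A^2 = 1e-16 cm^2 and 1 ps = 1e-12 s, so the factor is 1e-4.
#'
#' @param D Diffusion coefficient(s) in A^2/ps; must be non-negative.
#' @return Same values in cm^2/s.
#' @export
diffusion_unit_convert <- function(D) {
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("D must be finite and non-negative")
  }
  D * 1e-4
}
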