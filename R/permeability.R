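#' Local resistance profile of the modified ISDM
#'
#' `R(z) = exp(beta dG(z)) / D(z)` with the free energy referenced to
#' the global PMF minimum (not the bulk value) — the modification that
#' keeps deep interfacial minima from inflating the permeability. Units:
#' ps/A^2.
#'
#' @param pmf [profile()] of G(z), kcal/mol.
#' @param D [profile()] of D(z), A^2/ps, on the identical grid (resample
#'   beforehand, e.g. with [build_D_profile()]).
#' @param thermo A [thermo_state()].
#' @return A [profile()] of R(z) in ps/A^2.
#' @export
resistance_profile <- function(pmf, D, thermo = thermo_state(300)) {
  stopifnot(inherits(pmf, "profile"), inherits(D, "profile"))
  if (length(pmf$grid) != length(D$grid) ||
      any(abs(pmf$grid - D$grid) > 1e-9)) {
    stop("pmf and D must be on a common grid; resample first")
  }
  if (any(!is.finite(D$values)) || any(D$values <= 0)) {
    stop("D must be positive and finite everywhere")
  }
  if (any(!is.finite(pmf$values))) {
    stop("pmf contains undefined values")
  }
  dG <- pmf$values - min(pmf$values)
  profile(pmf$grid, exp(thermo$beta * dG) / D$values, units = "ps/A^2",
          meta = list(reference = "pmf-minimum"))
}

#' Permeability from integrating a resistance profile
#'
#' `P = 1 / int_{z_a}^{z_b} R(z) dz` by trapezoidal quadrature on the
#' profile grid (with linear interpolation at the interval endpoints),
#' converted to cm/s: the integral in ps/A equals 1e-4 s/cm.
#'
#' @param R [profile()] of resistance, ps/A^2.
#' @param z_a,z_b Integration bounds (A), both inside the grid,
#'   distinct; order is irrelevant.
#' @return Permeability in cm/s.
#' @export
permeability_between <- function(R, z_a, z_b) {
  stopifnot(inherits(R, "profile"))
  if (z_a == z_b) stop("degenerate interval: z_a equals z_b")
  lo <- min(z_a, z_b); hi <- max(z_a, z_b)
  g <- R$grid
  if (lo < g[1] - 1e-9 || hi > g[length(g)] + 1e-9) {
    stop("integration bounds fall outside the resistance grid")
  }
  lo <- max(lo, g[1]); hi <- min(hi, g[length(g)])
  inside <- g > lo & g < hi
  x <- c(lo, g[inside], hi)
  y <- approx(g, R$values, xout = x)$y
  r_int <- pracma::trapz(x, y)            # ps/A
  1 / (r_int * 1e-4)                      # cm/s
}

#' Predict membrane permeability from PMF and diffusivity profiles
#'
#' Locates the global PMF minimum z_min (ties broken toward bulk, the
#' more conservative, longer flip path), builds the resistance profile,
#' and integrates it over the two canonical paths: `P_flip` from the
#' bilayer centre (z = 0) to z_min, and `P_out` from z_min to bulk water
#' (z_bulk). When z_min lies beyond 30 A there is no meaningful outward
#' path and `P_out` is undefined. The headline value combines the two
#' by the declared rule (default: the smaller, rate-limiting one); both
#' are always reported, with log10 values in cm/s.
#'
#' @param pmf [profile()] of G(z) spanning `[0, z_bulk]`, kcal/mol.
#' @param D [profile()] of D(z) on the same grid, A^2/ps.
#' @param thermo A [thermo_state()].
#' @param z_bulk Bulk-water coordinate, A (default 37.5).
#' @param z_out_limit z_min beyond this disables P_out (default 30 A).
#' @param combine Headline rule: `"min"` (rate-limiting, default),
#'   `"flip"`, or `"out"`.
#' @param pmf_halves Optional list of two PMF profiles (e.g. from
#'   [halfsplit_error()]) used to attach the sd of log10 P.
#' @return Object of class `permeability_result` with fields `z_min`,
#'   `P_flip`, `P_out` (`NA` when undefined), `headline`, `log10_P_flip`,
#'   `log10_P_out`, `log10_headline`, `stderr_log10` (when halves are
#'   given) and the `combine` rule.
#' @export
predict_permeability <- function(pmf, D, thermo = thermo_state(300),
                                 z_bulk = 37.5, z_out_limit = 30,
                                 combine = c("min", "flip", "out"),
                                 pmf_halves = NULL) {
  combine <- match.arg(combine)
  stopifnot(inherits(pmf, "profile"))
  g <- pmf$grid
  # a histogram PMF lives on bin centres: allow up to one grid step of
  # slack at either edge and integrate over the covered range
  step <- stats::median(diff(g))
  if (g[1] > step + 1e-9 || g[length(g)] < z_bulk - step - 1e-9) {
    stop(sprintf("pmf grid [%g, %g] must cover [0, %g]",
                 g[1], g[length(g)], z_bulk))
  }
  z_lo <- max(0, g[1])
  z_hi <- min(z_bulk, g[length(g)])

  one <- function(p) {
    vmin <- min(p$values)
    ties <- which(p$values <= vmin + 1e-12)
    z_min <- p$grid[max(ties)]  # bulk-most tied minimum
    R <- resistance_profile(p, D, thermo)
    # a minimum at the bilayer centre leaves no flip path to cross
    P_flip <- if (z_min <= z_lo) Inf else
      permeability_between(R, z_lo, z_min)
    P_out <- if (z_min > z_out_limit) NA_real_ else {
      permeability_between(R, z_min, z_hi)
    }
    list(z_min = z_min, P_flip = P_flip, P_out = P_out)
  }

  main <- one(pmf)
  headline <- switch(combine,
    min = if (is.na(main$P_out)) main$P_flip else min(main$P_flip,
                                                      main$P_out),
    flip = main$P_flip,
    out = {
      if (is.na(main$P_out)) stop("P_out is undefined (z_min beyond limit)")
      main$P_out
    })

  stderr_log10 <- NULL
  if (!is.null(pmf_halves)) {
    if (length(pmf_halves) != 2L) stop("pmf_halves must contain two PMFs")
    hl <- lapply(pmf_halves, one)
    lg <- function(f) vapply(hl, function(h) log10(f(h)), numeric(1))
    stderr_log10 <- list(
      P_flip = sd(lg(function(h) h$P_flip)),
      P_out = if (any(vapply(hl, function(h) is.na(h$P_out), logical(1))))
        NA_real_ else sd(lg(function(h) h$P_out))
    )
  }

  structure(
    list(z_min = main$z_min, P_flip = main$P_flip, P_out = main$P_out,
         headline = headline,
         log10_P_flip = log10(main$P_flip),
         log10_P_out = if (is.na(main$P_out)) NA_real_ else
           log10(main$P_out),
         log10_headline = log10(headline),
         stderr_log10 = stderr_log10, combine = combine,
         z_bulk = z_bulk, z_out_limit = z_out_limit),
    class = "permeability_result"
  )
}

#' @export
print.permeability_result <- function(x, ...) {
  cat("<permeability_result>\n")
  cat(sprintf("  z_min      = %.3g A\n", x$z_min))
  cat(sprintf("  P_flip     = %.4g cm/s (log10 = %.3f)\n",
              x$P_flip, x$log10_P_flip))
  if (is.na(x$P_out)) {
    cat(sprintf("  P_out      = undefined (z_min > %g A)\n", x$z_out_limit))
  } else {
    cat(sprintf("  P_out      = %.4g cm/s (log10 = %.3f)\n",
                x$P_out, x$log10_P_out))
  }
  cat(sprintf("  headline   = %.4g cm/s [rule: %s]\n", x$headline,
              x$combine))
  if (!is.null(x$stderr_log10)) {
    cat(sprintf("  sd log10 P_flip (half-split) = %.3g\n",
                x$stderr_log10$P_flip))
  }
  invisible(x)
}

#' Mirror a one-leaflet profile across the bilayer centre
#'
#' The PMF is assumed symmetric across the membrane centre, so a profile
#' computed on one leaflet (grid starting at z = 0) supplements the
#' whole-bilayer profile by mirroring about z = 0 (the shared point is
#' not duplicated). Useful for plotting and for a whole-membrane
#' permeability `P_mem = 1 / int_{-z_bulk}^{z_bulk} R dz`.
#'
#' @param p A [profile()] whose grid starts at 0.
#' @return A [profile()] over `[-z_max, z_max]`.
#' @export
symmetrize <- function(p) {
  stopifnot(inherits(p, "profile"))
  if (p$grid[1] < -1e-9) {
    # already mirrored: idempotent if grid and values are symmetric
    n <- length(p$grid)
    if (all(abs(p$grid + rev(p$grid)) < 1e-9) &&
        all(abs(p$values - rev(p$values)) < 1e-9)) {
      return(p)
    }
    stop("grid must start at z = 0")
  }
  if (abs(p$grid[1]) > 1e-9) stop("grid must start at z = 0")
  n <- length(p$grid)
  grid <- c(-rev(p$grid[-1]), p$grid)
  values <- c(rev(p$values[-1]), p$values)
  stderr <- if (is.null(p$stderr)) NULL else c(rev(p$stderr[-1]), p$stderr)
  profile(grid, values, stderr = stderr, units = p$units,
          grid_units = p$grid_units,
          meta = c(p$meta, list(symmetrized = TRUE)))
}
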