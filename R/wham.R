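#' Default PMF bin edges
#'
#' 0.5 A bins spanning the sampled leaflet.
#' @param z_min,z_max Range, Angstrom.
#' @param width Bin width, Angstrom.
#' @return Numeric vector of bin edges.
#' @export
default_bins <- function(z_min = 0, z_max = 37.5, width = 0.5) {
  seq(z_min, z_max, by = width)
}

# Shared setup: histogram per window + Boltzmann bias factors at bin
# centres. Returns NULL-free list or errors on bad geometry.
wham_setup <- function(schedule, series, bins, thermo, burn_in) {
  stopifnot(inherits(schedule, "window_schedule"))
  if (length(series) != length(schedule)) {
    stop("need one series per window")
  }
  vals <- lapply(series, function(s) {
    v <- if (inherits(s, "trajectory_series")) s$values else as.numeric(s)
    if (burn_in > 0) v <- v[-seq_len(floor(burn_in * length(v)))]
    v
  })
  all_z <- unlist(vals, use.names = FALSE)
  if (min(all_z) < bins[1] || max(all_z) > bins[length(bins)]) {
    stop(sprintf(
      "bin range [%g, %g] does not cover the samples [%g, %g]",
      bins[1], bins[length(bins)], min(all_z), max(all_z)))
  }
  centers <- (bins[-1] + bins[-length(bins)]) / 2
  nb <- length(centers)
  nw <- length(vals)
  H <- matrix(0, nw, nb)
  for (w in seq_len(nw)) {
    idx <- findInterval(vals[[w]], bins, rightmost.closed = TRUE,
                        all.inside = TRUE)
    H[w, ] <- tabulate(idx, nbins = nb)
  }
  # adjacent windows must have overlapping sampled regions
  occ <- H > 0
  for (w in seq_len(nw - 1L)) {
    hi_w <- max(which(occ[w, ]))
    lo_n <- min(which(occ[w + 1L, ]))
    if (lo_n > hi_w + 1L) {
      stop(sprintf(
        "insufficient overlap between windows %d and %d: gap over z = [%g, %g]",
        w, w + 1L, centers[hi_w], centers[lo_n]))
    }
  }
  total <- colSums(H)
  inner <- range(which(total > 0))
  if (any(total[inner[1]:inner[2]] == 0)) {
    empty <- centers[which(total == 0 & seq_along(total) >= inner[1] &
                             seq_along(total) <= inner[2])]
    stop(sprintf("empty interior bins at z = %s; refine sampling or bins",
                 paste(signif(empty, 4), collapse = ", ")))
  }
  # bias Boltzmann factors c[w, b] = exp(-beta U_w(z_b))
  U <- t(vapply(schedule$windows, bias_energy, numeric(nb), z = centers))
  list(vals = vals, H = H, centers = centers,
       C = exp(-thermo$beta * U), N = lengths(vals))
}

# Self-consistent WHAM iteration over window free energies.
wham_iterate <- function(H, C, N, beta, tol, max_iter, f_init = NULL) {
  nw <- nrow(H); nb <- ncol(H)
  h_tot <- colSums(H)
  f <- if (is.null(f_init)) numeric(nw) else as.numeric(f_init)
  if (length(f) != nw) stop("f_init must have one entry per window")
  converged <- FALSE
  iter <- 0L
  kT <- 1 / beta
  for (iter in seq_len(max_iter)) {
    denom <- colSums(N * exp(beta * f) * C)  # length nb
    p <- ifelse(h_tot > 0, h_tot / denom, 0)
    f_new <- -kT * log(C %*% p)[, 1]
    f_new <- f_new - f_new[1]  # gauge: first window at 0
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  denom <- colSums(N * exp(beta * f) * C)
  p <- ifelse(h_tot > 0, h_tot / denom, NA_real_)
  list(f = f, p = p, n_iterations = iter, converged = converged)
}

#' Solve 1D WHAM over umbrella windows
#'
#' Self-consistently unbiases the per-window histograms into a single
#' potential of mean force. Iteration stops when the largest change in
#' any window free energy drops below `tol`; reaching `max_iter` leaves
#' the solution flagged unconverged (never silently).
#'
#' @param schedule A [window_schedule()].
#' @param series List of [trajectory_series()] (or numeric vectors), one
#'   per window.
#' @param bins Bin edges for the PMF histogram; see [default_bins()].
#' @param thermo A [thermo_state()].
#' @param tol Convergence tolerance on window free energies, kcal/mol.
#' @param max_iter Maximum self-consistency iterations.
#' @param burn_in Fraction of each series discarded from the front.
#' @param f_init Optional initial guesses for the window free energies
#'   (kcal/mol); the converged PMF does not depend on them.
#' @param zero Zero convention of the reported PMF: `"min"` (global
#'   minimum at 0) or `"bulk"` (last bin at 0).
#' @return Object of class `wham_solution`: `pmf` ([profile()]),
#'   `window_free_energies`, `n_iterations`, `converged`.
#' @export
solve_wham_1d <- function(schedule, series, bins = default_bins(),
                          thermo = thermo_state(300), tol = 1e-7,
                          max_iter = 100000L, burn_in = 0,
                          f_init = NULL, zero = c("min", "bulk")) {
  zero <- match.arg(zero)
  setup <- wham_setup(schedule, series, bins, thermo, burn_in)
  sol <- wham_iterate(setup$H, setup$C, setup$N, thermo$beta, tol,
                      max_iter, f_init = f_init)
  if (!sol$converged) {
    warning(sprintf("WHAM not converged after %d iterations", max_iter))
  }
  G <- -log(sol$p) / thermo$beta
  keep <- is.finite(G)
  G <- G - if (zero == "min") min(G[keep]) else G[max(which(keep))]
  structure(
    list(
      pmf = profile(setup$centers, G, units = "kcal/mol",
                    meta = list(zero = zero, bin_width = diff(bins)[1])),
      window_free_energies = sol$f,
      n_iterations = sol$n_iterations,
      converged = sol$converged
    ),
    class = "wham_solution"
  )
}

#' @export
print.wham_solution <- function(x, ...) {
  cat(sprintf(
    "<wham_solution> %d bins, %d windows, %d iterations (%s)\n",
    length(x$pmf$grid), length(x$window_free_energies), x$n_iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Bias-reweighted 2D free-energy surface
#'
#' Applies per-frame WHAM weights derived from the 1D bias in z to a 2D
#' histogram over (z, auxiliary observable), e.g. polar surface area,
#' and returns `-kT ln` of the weighted density min-shifted to 0. Empty
#' bins are reported as `NA`, never 0.
#'
#' @param schedule A [window_schedule()].
#' @param z_series,aux_series Frame-aligned per-window series.
#' @param bins_z,bins_aux Bin edges for the two axes.
#' @param thermo A [thermo_state()].
#' @param ... Passed to [solve_wham_1d()] (tol, max_iter, burn_in).
#' @return List of class `pmf2d`: `z` and `aux` bin centres, matrix `G`
#'   (kcal/mol, `NA` where unsampled), and the 1D `wham` solution used
#'   for the weights.
#' @export
pmf_2d_reweight <- function(schedule, z_series, aux_series,
                            bins_z = default_bins(), bins_aux,
                            thermo = thermo_state(300), ...) {
  if (length(z_series) != length(aux_series)) {
    stop("z_series and aux_series must have one entry per window")
  }
  get_vals <- function(s) {
    if (inherits(s, "trajectory_series")) s$values else as.numeric(s)
  }
  zl <- lapply(z_series, get_vals)
  al <- lapply(aux_series, get_vals)
  if (!all(lengths(zl) == lengths(al))) {
    bad <- which(lengths(zl) != lengths(al))[1]
    stop(sprintf("window %d: z series (%d frames) and aux series (%d) differ",
                 bad, lengths(zl)[bad], lengths(al)[bad]))
  }
  sol <- solve_wham_1d(schedule, z_series, bins = bins_z, thermo = thermo,
                       ...)
  f <- sol$window_free_energies
  N <- lengths(zl)
  beta <- thermo$beta
  # per-frame unbiasing weight: 1 / sum_w N_w exp(beta (f_w - U_w(z)))
  z_all <- unlist(zl, use.names = FALSE)
  a_all <- unlist(al, use.names = FALSE)
  Umat <- vapply(seq_along(schedule$windows), function(w) {
    bias_energy(schedule$windows[[w]], z_all)
  }, numeric(length(z_all)))
  wts <- 1 / as.numeric(exp(beta * sweep(-Umat, 2, f, `+`)) %*% N)
  iz <- findInterval(z_all, bins_z, rightmost.closed = TRUE,
                     all.inside = TRUE)
  if (min(a_all) < bins_aux[1] || max(a_all) > bins_aux[length(bins_aux)]) {
    stop("bins_aux does not cover the auxiliary samples")
  }
  ia <- findInterval(a_all, bins_aux, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nbz <- length(bins_z) - 1L
  nba <- length(bins_aux) - 1L
  dens <- matrix(0, nbz, nba)
  for (k in seq_along(z_all)) dens[iz[k], ia[k]] <- dens[iz[k], ia[k]] + wts[k]
  G <- -log(dens) / beta
  G[!is.finite(G)] <- NA_real_
  G <- G - min(G, na.rm = TRUE)
  structure(
    list(z = (bins_z[-1] + bins_z[-length(bins_z)]) / 2,
         aux = (bins_aux[-1] + bins_aux[-length(bins_aux)]) / 2,
         G = G, wham = sol),
    class = "pmf2d"
  )
}

#' Half-split PMF uncertainty
#'
#' Splits every window's series into first and second halves, solves
#' WHAM independently on each, aligns both to the same zero convention,
#' and reports the per-bin standard deviation of the two PMFs together
#' with their mean.
#'
#' @inheritParams solve_wham_1d
#' @return List of class `halfsplit_result`: `pmf` (mean profile with
#'   `stderr`), `first`, `second` (the two `wham_solution`s),
#'   `converged`.
#' @export
halfsplit_error <- function(schedule, series, bins = default_bins(),
                            thermo = thermo_state(300), ...) {
  get_vals <- function(s) {
    if (inherits(s, "trajectory_series")) s$values else as.numeric(s)
  }
  halves <- lapply(1:2, function(h) {
    lapply(series, function(s) {
      v <- get_vals(s)
      n <- length(v)
      if (n < 2L) stop("series too short to split in half")
      if (h == 1L) v[seq_len(n %/% 2)] else v[(n %/% 2 + 1L):n]
    })
  })
  s1 <- solve_wham_1d(schedule, halves[[1]], bins = bins, thermo = thermo,
                      ...)
  s2 <- solve_wham_1d(schedule, halves[[2]], bins = bins, thermo = thermo,
                      ...)
  g1 <- s1$pmf$values
  g2 <- s2$pmf$values
  m <- (g1 + g2) / 2
  sdv <- abs(g1 - g2) / sqrt(2)  # sd of two observations
  structure(
    list(pmf = profile(s1$pmf$grid, m, stderr = sdv, units = "kcal/mol",
                       meta = s1$pmf$meta),
         first = s1, second = s2,
         converged = s1$converged && s2$converged),
    class = "halfsplit_result"
  )
}

#' Mean absolute error between two aligned profiles
#'
#' Both profiles are first shifted to a common reference (their own
#' minimum, or a stated anchor point), then the mean of the absolute
#' pointwise differences is returned. Used to quantify PMF convergence
#' between trajectory halves.
#'
#' @param p1,p2 [profile()] objects on identical grids.
#' @param anchor `"min"` (align each to its minimum), `"bulk"` (align at
#'   the last grid point) or a numeric grid value to anchor at.
#' @return MAE in the profiles' units (kcal/mol for PMFs).
#' @export
mae_between_profiles <- function(p1, p2, anchor = "min") {
  stopifnot(inherits(p1, "profile"), inherits(p2, "profile"))
  if (length(p1$grid) != length(p2$grid) ||
      any(abs(p1$grid - p2$grid) > 1e-9)) {
    stop("profiles must share an identical grid")
  }
  shift <- function(v) {
    if (identical(anchor, "min")) {
      v - min(v, na.rm = TRUE)
    } else if (identical(anchor, "bulk")) {
      v - v[length(v)]
    } else if (is.numeric(anchor)) {
      i <- which.min(abs(p1$grid - anchor))
      v - v[i]
    } else {
      stop("anchor must be 'min', 'bulk' or a numeric grid value")
    }
  }
  mean(abs(shift(p1$values) - shift(p2$values)), na.rm = TRUE)
}
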