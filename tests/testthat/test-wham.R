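test_that("single unbiased window reduces to Boltzmann inversion", {
  # samples straight from exp(-beta G) of a smoothed square barrier
  m <- make_membrane_model("square_barrier", params = list(h = 2, w = 15))
  set.seed(10)
  z_grid <- seq(0.01, 37.49, length.out = 4000)
  wts <- exp(-TH300$beta * m$G(z_grid))
  z <- sample(z_grid, 5e4, replace = TRUE, prob = wts)
  sch <- window_schedule(list(umbrella_window(18, 1e-9, "half")))
  bins <- default_bins(0, 37.5, 1.5)
  sol <- solve_wham_1d(sch, list(z), bins = bins, thermo = TH300)
  expect_true(sol$converged)
  # exact oracle: expected bin mass under the discrete sampling density
  ib <- findInterval(z_grid, bins, rightmost.closed = TRUE,
                     all.inside = TRUE)
  mass <- tapply(wts, ib, sum)
  truth <- -log(as.numeric(mass)) / TH300$beta
  truth <- truth - min(truth)
  expect_lt(max(abs(sol$pmf$values - truth)), 0.1)
})

test_that("duplicating every window and series leaves the PMF unchanged", {
  m <- make_membrane_model("square_barrier")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 2e4, seed = 20, stride = 5)
  sol1 <- solve_wham_1d(sch, r$series, thermo = TH300)
  # duplicate: same centres offset by an epsilon to keep ordering valid
  dup_windows <- list()
  dup_series <- list()
  for (i in seq_along(sch$windows)) {
    w <- sch$windows[[i]]
    dup_windows[[2 * i - 1]] <- w
    dup_windows[[2 * i]] <- umbrella_window(w$center + 1e-7, w$k,
                                            w$convention)
    dup_series[[2 * i - 1]] <- r$series[[i]]
    dup_series[[2 * i]] <- r$series[[i]]
  }
  sol2 <- solve_wham_1d(window_schedule(dup_windows), dup_series,
                        thermo = TH300)
  expect_equal(sol2$pmf$values, sol1$pmf$values, tolerance = 1e-4)
})

test_that("WHAM recovers the square-barrier ground truth", {
  m <- make_membrane_model("square_barrier", params = list(h = 5, w = 15))
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 2e5, exchange_interval = 200, dt = 0.05,
                seed = 12, stride = 5)
  sol <- solve_wham_1d(sch, r$series, thermo = TH300, burn_in = 0.1)
  expect_true(sol$converged)
  truth <- m$G(sol$pmf$grid)
  truth <- truth - min(truth)
  # barrier height: plateau mean minus bulk mean (region averages avoid
  # the noise of referencing a single minimum bin)
  plateau <- sol$pmf$grid <= 10
  bulk <- sol$pmf$grid >= 20
  expect_equal(mean(sol$pmf$values[plateau]) -
                 mean(sol$pmf$values[bulk]), 5, tolerance = 0.2 / 5)
  expect_lt(sqrt(mean((sol$pmf$values - truth)^2)), 0.3)
})

test_that("converged PMF does not depend on the initial free-energy guesses", {
  m <- make_membrane_model("popc_like")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 2e4, seed = 21, stride = 5)
  s0 <- solve_wham_1d(sch, r$series, thermo = TH300)
  s1 <- solve_wham_1d(sch, r$series, thermo = TH300,
                      f_init = rep(3.7, length(sch)))
  s2 <- solve_wham_1d(sch, r$series, thermo = TH300,
                      f_init = seq(0, 2, length.out = length(sch)))
  expect_equal(s1$pmf$values, s0$pmf$values, tolerance = 1e-4)
  expect_equal(s2$pmf$values, s0$pmf$values, tolerance = 1e-4)
})

test_that("PMF is stable under bin-width halving at ample sampling", {
  m <- make_membrane_model("popc_like")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 2e5, seed = 22, stride = 5)
  sA <- solve_wham_1d(sch, r$series, bins = default_bins(0, 37.5, 0.75),
                      thermo = TH300)
  sB <- solve_wham_1d(sch, r$series, bins = default_bins(0, 37.5, 0.375),
                      thermo = TH300)
  # compare on the coarse grid by pooling fine-bin Boltzmann weights
  dens <- exp(-TH300$beta * sB$pmf$values)
  fine_on_coarse <- -log(colMeans(matrix(dens, nrow = 2))) / TH300$beta
  fine_on_coarse <- fine_on_coarse - min(fine_on_coarse)
  expect_lt(max(abs(fine_on_coarse - sA$pmf$values)), 0.25)
})

test_that("non-overlapping histograms raise an informative error", {
  sch <- window_schedule(list(umbrella_window(5, 20, "half"),
                              umbrella_window(30, 20, "half")))
  set.seed(30)
  series <- list(rnorm(2000, 5, 0.15), rnorm(2000, 30, 0.15))
  expect_error(solve_wham_1d(sch, series, thermo = TH300),
               "insufficient overlap")
})

test_that("hitting max_iter flags the solution instead of failing silently", {
  m <- make_membrane_model("popc_like")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 1e4, seed = 23, stride = 5)
  expect_warning(
    sol <- solve_wham_1d(sch, r$series, thermo = TH300, max_iter = 3L),
    "not converged")
  expect_false(sol$converged)
  expect_equal(sol$n_iterations, 3L)
})

test_that("half-split errors behave: zero for identical halves, shrink with data", {
  m <- make_membrane_model("square_barrier")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 4e4, seed = 24, stride = 5)
  # identical halves: duplicate each series back-to-back
  dup <- lapply(r$series, function(s) c(s$values, s$values))
  hs0 <- halfsplit_error(sch, dup, thermo = TH300)
  expect_true(all(hs0$pmf$stderr < 1e-10))
  # real split errors shrink as the run gets longer
  r_long <- run_reus(m, sch, n_steps = 2e5, seed = 24, stride = 5)
  hs_short <- halfsplit_error(sch, r$series, thermo = TH300)
  hs_long <- halfsplit_error(sch, r_long$series, thermo = TH300)
  expect_lt(mean(hs_long$pmf$stderr), mean(hs_short$pmf$stderr))
})

test_that("a drifting window inflates the half-split error where it drifts", {
  m <- make_membrane_model("flat")
  sch <- window_schedule(lapply(seq(10, 20, 2.5),
                                function(c) umbrella_window(c, 1, "half")))
  r <- run_reus(m, sch, n_steps = 1e5, seed = 25, stride = 5)
  series <- lapply(r$series, `[[`, "values")
  drift <- series
  n <- length(drift[[5]])
  drift[[5]] <- drift[[5]] + seq(0, 1.5, length.out = n)  # mean drifts 1.5 A
  bins <- default_bins(5, 27, 0.5)
  hs_ok <- halfsplit_error(sch, series, bins = bins, thermo = TH300)
  hs_bad <- halfsplit_error(sch, drift, bins = bins, thermo = TH300)
  top <- hs_bad$pmf$grid >= 18 & hs_bad$pmf$grid <= 21
  expect_gt(mean(hs_bad$pmf$stderr[top], na.rm = TRUE),
            3 * mean(hs_ok$pmf$stderr[top], na.rm = TRUE))
})

test_that("profile MAE follows the alignment rules", {
  g <- seq(0, 10, by = 0.5)
  v <- sin(g) + 1.2
  p1 <- profile(g, v)
  expect_equal(mae_between_profiles(p1, p1), 0)
  # constant offsets are invisible under min alignment
  p2 <- profile(g, v + 0.5)
  expect_equal(mae_between_profiles(p1, p2), 0)
  # +1 kcal/mol on 10% of bins, anchored at an unperturbed bulk bin
  v3 <- v
  stopifnot(length(g) == 21)
  bump <- c(3, 7)  # ~10% of 21 bins
  v3[bump] <- v3[bump] + 1.0
  p3 <- profile(g, v3)
  expect_equal(mae_between_profiles(p1, p3, anchor = "bulk"),
               length(bump) * 1.0 / length(g))
  expect_error(mae_between_profiles(p1, profile(g[-1], v[-1])),
               "identical grid")
})

test_that("2D reweighting collapses to the 1D PMF on a constant axis", {
  m <- make_membrane_model("popc_like")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 3e4, seed = 26, stride = 5)
  aux <- lapply(r$series, function(s) rep(200, length(s$values)))
  p2 <- pmf_2d_reweight(sch, r$series, aux,
                        bins_aux = seq(150, 250, 25), thermo = TH300)
  # the single occupied aux row carries the 1D PMF
  occ_rows <- which(colSums(!is.na(p2$G)) > 0)
  expect_length(occ_rows, 1L)
  g1 <- p2$wham$pmf$values
  g2 <- p2$G[, occ_rows]
  # per-frame weights vs bin-centre bias factors: small within-bin slack
  expect_lt(max(abs((g2 - min(g2, na.rm = TRUE)) - (g1 - min(g1)))), 0.05)
})

test_that("2D surface separates for an aux independent of z and bias", {
  m <- make_membrane_model("flat")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 3e4, seed = 27, stride = 5)
  set.seed(28)
  aux <- lapply(r$series, function(s) rnorm(length(s$values), 200, 12))
  p2 <- pmf_2d_reweight(sch, r$series, aux,
                        bins_aux = seq(140, 260, 6), thermo = TH300)
  # G(z, s) = G(z) - kT ln p(s) + const: aux profiles identical across z
  rows <- which(p2$z > 5 & p2$z < 32)
  cols <- which(p2$aux > 185 & p2$aux < 215)  # well-sampled aux range
  sub <- p2$G[rows, cols]
  sub <- sub - rowMeans(sub)
  expect_lt(max(apply(sub, 2, sd)), 0.25)
  # and the aux marginal matches the Gaussian free energy shape
  shape <- colMeans(sub)
  theo <- -log(dnorm(p2$aux[cols], 200, 12)) / TH300$beta
  expect_lt(max(abs((shape - mean(shape)) - (theo - mean(theo)))), 0.2)
})

test_that("marginalising the 2D density reproduces the 1D PMF", {
  m <- make_membrane_model("square_barrier")
  sch <- build_window_schedule(convention = "full")
  r <- run_reus(m, sch, n_steps = 5e4, seed = 31, stride = 5)
  set.seed(99)
  aux <- lapply(r$series, function(s) rnorm(length(s$values), 200, 15))
  p2 <- pmf_2d_reweight(sch, r$series, aux,
                        bins_aux = seq(110, 290, 5), thermo = TH300)
  dens2 <- exp(-TH300$beta * p2$G)
  dens2[is.na(dens2)] <- 0
  marg <- -log(rowSums(dens2)) / TH300$beta
  marg <- marg - min(marg)
  g1 <- p2$wham$pmf$values
  expect_lt(max(abs(marg - (g1 - min(g1)))), 0.25)
})

test_that("misaligned z/aux series are rejected", {
  m <- make_membrane_model("flat")
  sch <- window_schedule(list(umbrella_window(10, 1, "half"),
                              umbrella_window(12, 1, "half")))
  r <- run_reus(m, sch, n_steps = 2000, seed = 32)
  aux <- list(rep(1, 2000), rep(1, 1999))
  expect_error(
    pmf_2d_reweight(sch, r$series, aux, bins_aux = 0:2, thermo = TH300),
    "differ")
})
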