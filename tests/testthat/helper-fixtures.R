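# Shared fixtures: built in code, small and deterministic.

TH300 <- thermo_state(300)
KT300 <- KB_KCAL * 300

# Independent all-pairs hydrogen-bond oracle: plain double loop over
# every (donor-H, acceptor) pair, deliberately naive.
oracle_hbonds <- function(frame, d_max = 3.5, angle_min = 135) {
  X <- frame$coords
  hs <- which(frame$role == "donorH")
  acc <- which(frame$role == "acceptor")
  n <- 0L
  for (h in hs) {
    d <- frame$donor_index[h]
    for (a in acc) {
      if (a == d) next
      dist_da <- sqrt(sum((X[d, ] - X[a, ])^2))
      if (dist_da > d_max) next
      v1 <- X[d, ] - X[h, ]
      v2 <- X[a, ] - X[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= angle_min) n <- n + 1L
    }
  }
  n
}

# Random frame with plausible roles for the oracle comparison.
random_hbond_frame <- function(n_atoms = 50, span = 8) {
  coords <- matrix(runif(n_atoms * 3, 0, span), ncol = 3)
  n_units <- n_atoms %/% 3
  role <- rep("other", n_atoms)
  donor_index <- rep(NA_integer_, n_atoms)
  element <- rep("C", n_atoms)
  for (u in seq_len(n_units)) {
    i <- (u - 1) * 3 + 1
    role[i] <- "donor"; element[i] <- "N"
    role[i + 1] <- "donorH"; element[i + 1] <- "H"
    donor_index[i + 1] <- i
    # keep the hydrogen bonded to its donor
    coords[i + 1, ] <- coords[i, ] + runif(3, -0.6, 0.6)
    role[i + 2] <- "acceptor"; element[i + 2] <- "O"
  }
  conformer_frame(coords, element, role, donor_index)
}

# Planar ring of points, optionally tilted about the x axis.
ring_coords <- function(n = 12, radius = 5, tilt_deg = 0) {
  t_ <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- cbind(radius * cos(t_), radius * sin(t_), 0)
  a <- tilt_deg * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  ring %*% t(Rx)
}

# Exact discrete-time OU samples: z_{t+1} = c + phi (z_t - c) + sigma eps
ou_series <- function(n, tau, variance, dt, center = 0) {
  phi <- exp(-dt / tau)
  s <- sqrt(variance * (1 - phi^2))
  z <- numeric(n)
  z[1] <- center + rnorm(1, 0, sqrt(variance))
  for (i in 2:n) z[i] <- center + phi * (z[i - 1] - center) + rnorm(1, 0, s)
  trajectory_series(z, dt = dt)
}
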