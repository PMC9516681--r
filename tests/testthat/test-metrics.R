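test_that("hydrogen-bond counter honours the geometric criterion", {
  # collinear D-H...A at 2.9 A: a textbook hydrogen bond
  mk <- function(da) {
    conformer_frame(
      rbind(c(0, 0, 0), c(1, 0, 0), c(da, 0, 0)),
      element = c("N", "H", "O"),
      role = c("donor", "donorH", "acceptor"),
      donor_index = c(NA, 1L, NA))
  }
  expect_equal(count_hbonds(mk(2.9)), 1L)
  expect_equal(count_hbonds(mk(5.0)), 0L)        # beyond d_max = 3.5
  expect_equal(count_hbonds(mk(2.9), d_max = 2.5), 0L)
  # bent geometry below the angle cutoff does not count
  bent <- conformer_frame(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 2.6, 0)),
    element = c("N", "H", "O"),
    role = c("donor", "donorH", "acceptor"),
    donor_index = c(NA, 1L, NA))
  expect_equal(count_hbonds(bent), 0L)
  expect_equal(count_hbonds(bent, angle_min = 10), 1L)
  no_roles <- conformer_frame(matrix(rnorm(9), 3), rep("C", 3))
  expect_error(count_hbonds(no_roles), "role")
})

test_that("hydrogen-bond counts match the all-pairs oracle on random frames", {
  set.seed(60)
  for (i in 1:300) {
    fr <- random_hbond_frame(n_atoms = sample(20:60, 1))
    expect_identical(count_hbonds(fr), oracle_hbonds(fr))
  }
})

test_that("inter-group mode counts only peptide-water pairs", {
  coords <- rbind(
    c(0, 0, 0), c(1, 0, 0),            # peptide donor + H
    c(2.9, 0, 0),                      # water acceptor (bonded)
    c(20, 0, 0), c(21, 0, 0),          # water donor + H
    c(22.9, 0, 0),                     # peptide acceptor (bonded)
    c(50, 0, 0))                       # peptide acceptor (far)
  fr <- conformer_frame(
    coords,
    element = c("N", "H", "O", "O", "H", "O", "O"),
    role = c("donor", "donorH", "acceptor", "donor", "donorH",
             "acceptor", "acceptor"),
    donor_index = c(NA, 1L, NA, NA, 4L, NA, NA),
    group = c("peptide", "peptide", "water", "water", "water",
              "peptide", "peptide"))
  expect_equal(count_hbonds(fr, mode = "inter",
                            partner = c("peptide", "water")), 1L)
  expect_equal(count_hbonds(fr, mode = "inter",
                            partner = c("water", "peptide")), 1L)
  expect_error(count_hbonds(fr, mode = "inter"), "partner")
})

test_that("profile_by_z recovers generator step rules with half-split errors", {
  set.seed(61)
  z <- runif(4000, 0, 37.5)
  vals <- ifelse(z < 5, 0, ifelse(z > 15, 6, 3))
  p <- profile_by_z(vals, z, bins = default_bins(0, 37.5, 2.5))
  expect_equal(p$values[p$grid < 5], rep(0, sum(p$grid < 5)))
  expect_equal(p$values[p$grid > 15], rep(6, sum(p$grid > 15)))
  expect_true(all(p$stderr[p$grid > 15] == 0))
  # constant observable: flat profile, zero error
  pc <- profile_by_z(rep(4.2, 100), runif(100, 0, 37.5),
                     bins = default_bins(0, 37.5, 7.5))
  expect_true(all(pc$values == 4.2))
  expect_true(all(pc$stderr == 0))
  # bins sampled in only one half are flagged undefined
  p1 <- profile_by_z(c(1, 2), c(1, 30), bins = default_bins(0, 37.5, 15))
  expect_true(any(is.na(p1$stderr)))
  expect_error(profile_by_z(1:3, 1:2), "frame-aligned")
})

test_that("surface areas match sphere closed forms", {
  lone <- conformer_frame(matrix(0, 1, 3), "C")  # r = 1.7
  expect_equal(sasa(lone), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  # two distant atoms are additive
  two <- conformer_frame(rbind(c(0, 0, 0), c(100, 0, 0)), c("C", "N"))
  a <- sasa(two)
  expect_equal(a[1], 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_equal(a[2], 4 * pi * 2.95^2, tolerance = 1e-9)
  # a caged atom loses nearly all accessible surface
  cage_dirs <- sphere_dirs <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
    c(0, 0, -1),
    cbind(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, 1, -1, -1, 1, 1, -1, -1),
          c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  cage <- conformer_frame(rbind(c(0, 0, 0), cage_dirs * 2.2),
                          c("C", rep("S", nrow(cage_dirs))))
  ac <- sasa(cage)
  expect_lt(ac[1], 0.01 * 4 * pi * 3.1^2)
  expect_error(sasa(conformer_frame(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    c("C", "C"))),
               "overlapping")
})

test_that("sphere sampling converges for the isolated sphere", {
  lone <- conformer_frame(matrix(0, 1, 3), "N")
  exact <- 4 * pi * 2.95^2
  expect_equal(sasa(lone, n_sphere_points = 960), exact,
               tolerance = 0.005)
})

test_that("polar surface area sums over N and O atoms only", {
  none <- conformer_frame(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "S"))
  expect_equal(psa(none), 0)
  lone_n <- conformer_frame(matrix(0, 1, 3), "N")
  expect_equal(psa(lone_n), 4 * pi * 2.95^2, tolerance = 1e-9)
  expect_equal(psa(lone_n), 109.36, tolerance = 1e-3)
})

test_that("dihedral PCA recovers a single-angle variance structure", {
  n <- 200
  set.seed(62)
  phi <- matrix(-65, n, 3)
  psi_m <- matrix(120, n, 3)
  omega <- matrix(180 - abs(rnorm(n, 0, 1e-6)), n, 3)
  phi[, 2] <- -65 + rnorm(n, 0, 5)  # all variance in one angle
  ds <- dihedral_series(phi, psi_m, omega)
  pc <- dihedral_pca(ds)
  expect_gt(pc$explained[1], 0.99)
  # leading eigenvectors live in that angle's (sin, cos) coordinates
  idx_sin <- 2  # second phi column in the sin-phi block
  idx_cos <- 3 + 2
  lead <- abs(pc$eigenvectors[, 1])
  expect_gt(lead[idx_sin]^2 + lead[idx_cos]^2, 0.99)
})

test_that("dihedral PCA is an orthonormal, lossless rotation", {
  set.seed(63)
  cs <- generate_conformer_series(
    120, runif(120, 0, 37.5),
    conformer_rules(closed_prob = function(z) rep(0.5, length(z))),
    seed = 64)
  pc <- dihedral_pca(cs$dihedrals)
  V <- pc$eigenvectors
  expect_lt(max(abs(t(V) %*% V - diag(ncol(V)))), 1e-10)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # projections reproduce the centred embedding through the eigenbasis
  rad <- pi / 180
  emb <- cbind(sin(cs$dihedrals$phi * rad), cos(cs$dihedrals$phi * rad),
               sin(cs$dihedrals$psi * rad), cos(cs$dihedrals$psi * rad),
               sin(cs$dihedrals$omega * rad),
               cos(cs$dihedrals$omega * rad))
  centred <- sweep(emb, 2, pc$mean)
  expect_lt(max(abs(pc$projections %*% t(V) - centred)), 1e-8)
  # the mean frame projects to the origin
  expect_lt(max(abs(colMeans(pc$projections))), 1e-10)
  const <- dihedral_series(matrix(10, 5, 2), matrix(20, 5, 2),
                           matrix(30, 5, 2))
  expect_error(dihedral_pca(const), "zero variance")
})

test_that("closed_fraction recovers generator fractions with both classifiers", {
  p_true <- 0.3
  cs <- generate_conformer_series(
    600, runif(600, 0, 37.5),
    conformer_rules(closed_prob = function(z) rep(p_true, length(z))),
    seed = 65)
  # hbond classifier against ground-truth labels: binomial error bound
  frac_hb <- closed_fraction(cs$frames)
  expect_equal(frac_hb, mean(cs$states == "closed"), tolerance = 1e-12)
  expect_equal(frac_hb, p_true, tolerance = 3 * sqrt(p_true * 0.7 / 600))
  # PC-box classifier from the projections agrees on clean templates
  pc <- dihedral_pca(cs$dihedrals)
  proj1 <- pc$projections[, 1]
  mu_c <- mean(proj1[cs$states == "closed"])
  mu_o <- mean(proj1[cs$states == "open"])
  lohi <- sort(c(mu_c - 3 * sd(proj1[cs$states == "closed"]),
                 mu_c + 3 * sd(proj1[cs$states == "closed"])))
  frac_pc <- closed_fraction(pc, classifier = "pc_box", bounds = lohi)
  expect_gt(1 - abs(frac_pc - frac_hb), 0.95)
  # degenerate inputs
  expect_equal(closed_fraction(matrix(2.5, 10, 2), classifier = "pc_box"),
               1.0)
  expect_error(closed_fraction(list(), classifier = "hbond"), "empty")
})

test_that("cis peptide bonds are counted by the |omega| < 90 rule", {
  om <- rbind(c(180, 180, 180), c(0, 180, 180), c(89.9, -89.9, 180),
              c(90.1, -90.1, 90))
  ds <- dihedral_series(matrix(0.1, 4, 3), matrix(0.1, 4, 3), om)
  expect_equal(count_cis_omega(ds), c(0L, 1L, 2L, 0L))
})

test_that("short-axis angle reads tilt from the inertia tensor", {
  expect_equal(short_axis_angle(ring_coords(12, 5, 0)), 0, tolerance = 1e-9)
  expect_equal(short_axis_angle(ring_coords(12, 5, 90)), 90,
               tolerance = 1e-9)
  expect_equal(short_axis_angle(ring_coords(12, 5, 30)), 30,
               tolerance = 1e-6)
  # folding: tilts beyond 90 map back into [0, 90]
  expect_equal(short_axis_angle(ring_coords(12, 5, 150)), 30,
               tolerance = 1e-6)
  # mass weighting shifts the centre but not a rigid ring's axis
  expect_equal(short_axis_angle(ring_coords(12, 5, 30),
                                masses = rep(2, 12)), 30,
               tolerance = 1e-6)
  line <- cbind(seq(0, 10, 1), 0, 0)
  expect_error(short_axis_angle(line), "degenerate")
  expect_error(short_axis_angle(ring_coords(2)), "three atoms")
})

test_that("area per lipid is the lateral box area over the leaflet count", {
  expect_equal(area_per_lipid(c(56.82, 56.82), 51), 63.3, tolerance = 0.01)
  expect_equal(area_per_lipid(c(10, 10), 1), 100)
  expect_equal(area_per_lipid(2 * c(10, 10), 1),
               4 * area_per_lipid(c(10, 10), 1))
  expect_error(area_per_lipid(c(10, 10), 0), "positive")
})
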