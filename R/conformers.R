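# Random 3D rotation matrix from three standard normals (QR of a
# Gaussian matrix, sign-fixed to a proper rotation).
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Template geometry for a two-state cyclic-peptide stand-in
#'
#' Builds a small labelled frame with `n_contacts` donor-H/acceptor
#' units on a carbon scaffold. In the closed state every unit forms a
#' collinear intramolecular hydrogen bond (donor-acceptor distance
#' `contact_distance`), which also buries the polar atoms against each
#' other and lowers the polar surface area. In the open state the
#' acceptors swing `open_separation` Angstrom away: no intramolecular
#' hydrogen bonds and a larger exposed polar surface.
#'
#' @param state `"closed"` or `"open"`.
#' @param n_contacts Number of donor/acceptor units (default 4).
#' @param contact_distance Closed-state donor-acceptor distance, A.
#' @param open_separation Open-state donor-acceptor distance, A.
#' @return A [conformer_frame()] with all atoms in group `"peptide"`.
#' @export
conformer_template <- function(state = c("closed", "open"),
                               n_contacts = 4L, contact_distance = 2.9,
                               open_separation = 8) {
  state <- match.arg(state)
  da <- if (state == "closed") contact_distance else open_separation
  spacing <- 10
  coords <- NULL
  element <- role <- character()
  donor_index <- integer()
  for (i in seq_len(n_contacts)) {
    y <- (i - 1) * spacing
    base <- nrow(coords %||% matrix(numeric(), 0, 3))
    unit <- rbind(
      c(0, y, 0),        # donor N
      c(1.0, y, 0),      # donor H, collinear with the acceptor
      c(da, y, 0),       # acceptor O
      c(-1.4, y, 1.0)    # scaffold C
    )
    coords <- rbind(coords, unit)
    element <- c(element, "N", "H", "O", "C")
    role <- c(role, "donor", "donorH", "acceptor", "other")
    donor_index <- c(donor_index, NA_integer_, base + 1L, NA_integer_,
                     NA_integer_)
  }
  conformer_frame(coords, element, role, donor_index,
                  group = rep("peptide", nrow(coords)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rules for the synthetic conformer generator
#'
#' @param closed_prob Function of z (A) giving the probability that a
#'   frame is in the closed state; default a sigmoid centred at
#'   `z = 7` A (closed conformers dominate inside the membrane).
#' @param dihedral_means Named list with `closed` and `open` entries,
#'   each `c(phi, psi, omega)` degrees.
#' @param angle_sd Circular jitter of the dihedrals, degrees.
#' @param cis_prob Named vector: per-state probability that a residue's
#'   omega flips to cis (near 0 degrees).
#' @param n_residues Residues per frame.
#' @param n_contacts Hydrogen-bond contacts in the closed template.
#' @return List of class `conformer_rules`.
#' @export
conformer_rules <- function(closed_prob = function(z) stats::plogis(-(z - 7) / 1.5),
                            dihedral_means = list(closed = c(-75, 100, 180),
                                                  open = c(-150, 70, 180)),
                            angle_sd = 8, cis_prob = c(closed = 0, open = 0),
                            n_residues = 11L, n_contacts = 4L) {
  p_chk <- closed_prob(seq(0, 40, by = 0.5))
  if (any(p_chk < 0 | p_chk > 1)) {
    stop("closed_prob must map z to probabilities in [0, 1]")
  }
  if (any(cis_prob < 0 | cis_prob > 1)) {
    stop("cis_prob entries must be probabilities in [0, 1]")
  }
  structure(list(closed_prob = closed_prob,
                 dihedral_means = dihedral_means, angle_sd = angle_sd,
                 cis_prob = cis_prob, n_residues = n_residues,
                 n_contacts = n_contacts),
            class = "conformer_rules")
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- a - 360 * floor((a + 180) / 360)
  w[w == -180] <- 180
  w
}

#' Generate a two-state conformer ensemble coupled to z
#'
#' For every frame, draws the closed/open state from
#' `rules$closed_prob(z)`, emits the matching geometry template under a
#' random rigid rotation (rotations leave hydrogen bonds, surface areas
#' and inertia eigenvalues unchanged), and draws backbone dihedrals
#' about the state's means. Ground-truth state labels are kept so the
#' downstream classifiers can be validated.
#'
#' @param n_frames Number of frames; the z series is subsampled evenly
#'   to this length if longer.
#' @param z_series A [trajectory_series()] of the reaction coordinate
#'   (or numeric vector of per-frame z).
#' @param rules A [conformer_rules()].
#' @param seed Optional integer seed.
#' @return Object of class `conformer_series`: `frames` (list of
#'   [conformer_frame()]), `dihedrals` ([dihedral_series()]), `states`
#'   (character labels), `z` (per-frame coordinate).
#' @export
generate_conformer_series <- function(n_frames, z_series,
                                      rules = conformer_rules(),
                                      seed = NULL) {
  stopifnot(inherits(rules, "conformer_rules"))
  z <- if (inherits(z_series, "trajectory_series")) z_series$values else
    as.numeric(z_series)
  if (length(z) < n_frames) stop("z_series shorter than n_frames")
  z <- z[round(seq(1, length(z), length.out = n_frames))]
  if (!is.null(seed)) set.seed(seed)
  templates <- list(
    closed = conformer_template("closed", rules$n_contacts),
    open = conformer_template("open", rules$n_contacts)
  )
  p_closed <- rules$closed_prob(z)
  states <- ifelse(runif(n_frames) < p_closed, "closed", "open")
  frames <- vector("list", n_frames)
  nr <- rules$n_residues
  phi <- psi <- omega <- matrix(NA_real_, n_frames, nr)
  for (f in seq_len(n_frames)) {
    tmpl <- templates[[states[f]]]
    Q <- random_rotation()
    ctr <- colMeans(tmpl$coords)
    coords <- sweep(tmpl$coords, 2, ctr) %*% t(Q)
    frames[[f]] <- conformer_frame(coords, tmpl$element, tmpl$role,
                                   tmpl$donor_index, tmpl$radius,
                                   tmpl$group)
    mu <- rules$dihedral_means[[states[f]]]
    phi[f, ] <- wrap_angle(rnorm(nr, mu[1], rules$angle_sd))
    psi[f, ] <- wrap_angle(rnorm(nr, mu[2], rules$angle_sd))
    om <- rnorm(nr, mu[3], rules$angle_sd)
    flip <- runif(nr) < rules$cis_prob[[states[f]]]
    om[flip] <- rnorm(sum(flip), 0, rules$angle_sd)
    omega[f, ] <- wrap_angle(om)
  }
  structure(
    list(frames = frames,
         dihedrals = dihedral_series(phi, psi, omega),
         states = states, z = z),
    class = "conformer_series"
  )
}

#' @export
print.conformer_series <- function(x, ...) {
  cat(sprintf("<conformer_series> %d frames (%.0f%% closed)\n",
              length(x$frames), 100 * mean(x$states == "closed")))
  invisible(x)
}
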