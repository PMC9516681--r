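#' Default van der Waals radii by element (Angstrom)
#'
#' Bondi-style radii used for surface-area calculations when a frame
#' does not carry explicit radii.
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
}

#' Labelled 3D conformer frame
#'
#' Coordinates plus the per-atom annotation the geometric metrics need:
#' element, hydrogen-bond role (`"donor"` heavy atom, `"donorH"`
#' hydrogen bonded to a donor, `"acceptor"`, `"other"`), the index of
#' the donor each `donorH` belongs to, van der Waals radius, an optional
#' group label (e.g. `"peptide"` / `"water"`) and optional box lengths.
#'
#' @param coords Numeric n x 3 matrix, Angstrom.
#' @param element Character vector of element symbols.
#' @param role Character vector of roles (see above).
#' @param donor_index Integer vector; for `donorH` rows, the row index
#'   of the bonded donor heavy atom, `NA` otherwise.
#' @param radius Optional radii; defaults looked up by element.
#' @param group Optional per-atom group labels.
#' @param box Optional `c(Lx, Ly, Lz)` box, Angstrom.
#' @return Object of class `conformer_frame`.
#' @export
conformer_frame <- function(coords, element, role = NULL,
                            donor_index = NULL, radius = NULL,
                            group = NULL, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (length(element) != n) stop("element must have one entry per atom")
  if (is.null(role)) role <- rep("other", n)
  if (is.null(donor_index)) donor_index <- rep(NA_integer_, n)
  if (length(role) != n || length(donor_index) != n) {
    stop("role and donor_index must have one entry per atom")
  }
  bad <- !role %in% c("donor", "donorH", "acceptor", "other")
  if (any(bad)) stop("unknown roles: ", paste(unique(role[bad]),
                                              collapse = ", "))
  hs <- which(role == "donorH")
  di <- donor_index[hs]
  if (any(is.na(di)) || any(di < 1 | di > n) ||
      any(role[di] != "donor")) {
    stop("every donorH must reference a valid donor heavy atom")
  }
  if (is.null(radius)) {
    radius <- unname(default_vdw_radii()[element])
    if (any(is.na(radius))) {
      stop("no default radius for element(s): ",
           paste(unique(element[is.na(radius)]), collapse = ", "))
    }
  }
  if (any(radius <= 0)) stop("radii must be positive")
  structure(
    list(coords = coords, element = element, role = role,
         donor_index = donor_index, radius = radius,
         group = group, box = box),
    class = "conformer_frame"
  )
}

#' @export
print.conformer_frame <- function(x, ...) {
  cat(sprintf("<conformer_frame> %d atoms (%d donors, %d acceptors)\n",
              nrow(x$coords), sum(x$role == "donor"),
              sum(x$role == "acceptor")))
  invisible(x)
}

#' Count geometric hydrogen bonds in a frame
#'
#' A (donor-H, acceptor) pair forms a hydrogen bond when the donor-heavy
#' to acceptor distance is at most `d_max` and the D-H...A angle at the
#' hydrogen is at least `angle_min`. In `"inter"` mode only pairs whose
#' donor and acceptor belong to different groups count (e.g. peptide vs
#' water); in `"intra"` mode only pairs within `partner` (default all
#' atoms) count.
#'
#' @param frame A [conformer_frame()].
#' @param mode `"inter"` (across groups) or `"intra"` (within a group).
#' @param partner For `"inter"`: character of length 2 naming the two
#'   groups; for `"intra"`: a single group name or `NULL` for all atoms.
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min D-H...A angle cutoff, degrees.
#' @return Integer count.
#' @export
count_hbonds <- function(frame, mode = c("intra", "inter"),
                         partner = NULL, d_max = 3.5, angle_min = 135) {
  stopifnot(inherits(frame, "conformer_frame"))
  mode <- match.arg(mode)
  if (all(frame$role == "other")) stop("frame carries no role assignments")
  hs <- which(frame$role == "donorH")
  acc <- which(frame$role == "acceptor")
  if (!length(hs) || !length(acc)) return(0L)
  if (mode == "inter") {
    if (is.null(frame$group) || is.null(partner) || length(partner) != 2) {
      stop("inter mode needs frame$group and a two-group partner selection")
    }
    keep_h <- frame$group[frame$donor_index[hs]] == partner[1]
    keep_a <- frame$group[acc] == partner[2]
    hs <- hs[keep_h]; acc <- acc[keep_a]
  } else if (!is.null(partner)) {
    hs <- hs[frame$group[frame$donor_index[hs]] == partner]
    acc <- acc[frame$group[acc] == partner]
  }
  if (!length(hs) || !length(acc)) return(0L)
  X <- frame$coords
  don <- frame$donor_index[hs]
  # distances donor-heavy -> acceptor for all (h, a) pairs
  Dd <- sqrt(outer(rowSums(X[don, , drop = FALSE]^2),
                   rowSums(X[acc, , drop = FALSE]^2), `+`) -
               2 * X[don, , drop = FALSE] %*% t(X[acc, , drop = FALSE]))
  cosmin <- cos(angle_min * pi / 180)
  count <- 0L
  for (i in seq_along(hs)) {
    cand <- which(Dd[i, ] <= d_max & acc != don[i])
    if (!length(cand)) next
    h <- X[hs[i], ]
    v1 <- X[don[i], ] - h
    for (a in cand) {
      v2 <- X[acc[a], ] - h
      cosang <- sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2))
      # angle >= angle_min  <=>  cos(angle) <= cos(angle_min)
      if (cosang <= cosmin) count <- count + 1L
    }
  }
  count
}

#' Bin per-frame values along z with half-split errors
#'
#' Per-bin mean of an observable against the reaction coordinate, with
#' the standard deviation of the means computed independently from the
#' first and second halves of the trajectory. Bins without samples are
#' `NA`; bins sampled in only one half get an `NA` stderr.
#'
#' @param values Per-frame observable.
#' @param z Per-frame reaction coordinate, Angstrom.
#' @param bins Bin edges (Angstrom).
#' @return A [profile()] on the bin centres with `stderr`.
#' @export
profile_by_z <- function(values, z, bins = default_bins()) {
  if (length(values) != length(z)) {
    stop("values and z must be frame-aligned")
  }
  centers <- (bins[-1] + bins[-length(bins)]) / 2
  nb <- length(centers)
  idx <- findInterval(z, bins, rightmost.closed = TRUE, all.inside = TRUE)
  idx[z < bins[1] | z > bins[length(bins)]] <- NA
  half <- rep(1:2, c(length(z) %/% 2, length(z) - length(z) %/% 2))
  mean_in <- function(sel) {
    vapply(seq_len(nb), function(b) {
      v <- values[sel & !is.na(idx) & idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  m <- mean_in(rep(TRUE, length(z)))
  m1 <- mean_in(half == 1L)
  m2 <- mean_in(half == 2L)
  sdv <- ifelse(is.na(m1) | is.na(m2), NA_real_, abs(m1 - m2) / sqrt(2))
  profile(centers, m, stderr = sdv, units = "",
          meta = list(split = "first/second half"))
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (numeric sphere sampling)
#'
#' Shrake-Rupley style: each atom's solvent-extended sphere (radius
#' `r + probe_radius`) is sampled with a deterministic golden-spiral
#' point set; the accessible area is the fraction of points not buried
#' inside any neighbour's extended sphere.
#'
#' @param frame A [conformer_frame()] (radii required).
#' @param probe_radius Solvent probe radius, Angstrom (water: 1.4).
#' @param n_sphere_points Sample points per atom; accuracy ~ O(1/n).
#' @return Numeric vector of per-atom accessible areas, A^2.
#' @export
sasa <- function(frame, probe_radius = 1.4, n_sphere_points = 960L) {
  stopifnot(inherits(frame, "conformer_frame"))
  X <- frame$coords
  n <- nrow(X)
  r_ext <- frame$radius + probe_radius
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(X))^2
    if (any(d2[upper.tri(d2)] == 0)) {
      stop("overlapping identical coordinates")
    }
  }
  pts <- sphere_points(n_sphere_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- if (n > 1L) {
      which(d2[i, ] < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    } else integer()
    surf <- sweep(pts * r_ext[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - X[j, 1])^2 + (surf[, 2] - X[j, 2])^2 +
        (surf[, 3] - X[j, 3])^2
      acc <- acc & dj2 > r_ext[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * r_ext[i]^2 * mean(acc)
  }
  areas
}

#' Polar surface area of a frame
#'
#' Solvent-accessible surface area summed over nitrogen and oxygen
#' atoms; a proxy for the exposed polarity of a conformer.
#'
#' @inheritParams sasa
#' @return PSA in A^2.
#' @export
psa <- function(frame, probe_radius = 1.4, n_sphere_points = 960L) {
  a <- sasa(frame, probe_radius, n_sphere_points)
  sum(a[frame$element %in% c("N", "O")])
}

#' Per-frame, per-residue backbone dihedral series
#'
#' @param phi,psi,omega Numeric matrices (frames x residues) of dihedral
#'   angles in degrees, each in (-180, 180].
#' @return Object of class `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, omega) {
  phi <- as.matrix(phi); psi <- as.matrix(psi); omega <- as.matrix(omega)
  if (!all(dim(phi) == dim(psi)) || !all(dim(phi) == dim(omega))) {
    stop("phi, psi, omega must share dimensions (frames x residues)")
  }
  for (m in list(phi, psi, omega)) {
    if (any(!is.finite(m)) || any(m <= -180) || any(m > 180)) {
      stop("angles must be finite and in (-180, 180] degrees")
    }
  }
  structure(list(phi = phi, psi = psi, omega = omega),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %d frames x %d residues\n",
              nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

#' Principal component analysis of backbone dihedrals
#'
#' Embeds every frame as the sine and cosine of each (phi, psi, omega)
#' angle — a 6 x n_residues vector that removes the angular
#' discontinuity — centres the embedding, and eigendecomposes its
#' covariance.
#'
#' @param series A [dihedral_series()].
#' @return Object of class `dihedral_pca`: `mean`, `eigenvectors`
#'   (columns, orthonormal), `eigenvalues` (descending, non-negative),
#'   `projections` (frames x components), `explained` (variance
#'   fractions).
#' @export
dihedral_pca <- function(series) {
  stopifnot(inherits(series, "dihedral_series"))
  if (nrow(series$phi) < 2L) stop("need at least two frames")
  rad <- pi / 180
  emb <- cbind(sin(series$phi * rad), cos(series$phi * rad),
               sin(series$psi * rad), cos(series$psi * rad),
               sin(series$omega * rad), cos(series$omega * rad))
  mu <- colMeans(emb)
  Xc <- sweep(emb, 2, mu)
  if (all(abs(Xc) < 1e-12)) stop("constant embedding: zero variance")
  eig <- eigen(stats::cov(Xc), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(
    list(mean = mu, eigenvectors = eig$vectors, eigenvalues = ev,
         projections = Xc %*% eig$vectors,
         explained = ev / sum(ev)),
    class = "dihedral_pca"
  )
}

#' @export
print.dihedral_pca <- function(x, ...) {
  cat(sprintf("<dihedral_pca> %d components; PC1 explains %.1f%%\n",
              length(x$eigenvalues), 100 * x$explained[1]))
  invisible(x)
}

#' Fraction of frames in the closed conformation
#'
#' Two classifiers are available: a rectangular region in principal
#' component space (dataset-specific: the closed state of a given
#' peptide maps to a known PC window), or a transferable intramolecular
#' hydrogen-bond count threshold.
#'
#' @param x For `classifier = "pc_box"`: a projection matrix or
#'   [dihedral_pca()] object. For `"hbond"`: a list of
#'   [conformer_frame()]s.
#' @param classifier `"hbond"` (default) or `"pc_box"`.
#' @param pc Component used by the PC box.
#' @param bounds `c(lower, upper)` of the PC box.
#' @param min_hbonds Minimum intramolecular hydrogen bonds to call a
#'   frame closed.
#' @param ... Passed to [count_hbonds()] (cutoffs).
#' @return Fraction in `[0, 1]`.
#' @export
closed_fraction <- function(x, classifier = c("hbond", "pc_box"),
                            pc = 1L, bounds = c(2, 3), min_hbonds = 3L,
                            ...) {
  classifier <- match.arg(classifier)
  if (classifier == "pc_box") {
    proj <- if (inherits(x, "dihedral_pca")) x$projections else as.matrix(x)
    if (!nrow(proj)) stop("empty projection set")
    v <- proj[, pc]
    mean(v >= bounds[1] & v <= bounds[2])
  } else {
    if (!length(x)) stop("empty frame set")
    counts <- vapply(x, count_hbonds, integer(1), mode = "intra", ...)
    mean(counts >= min_hbonds)
  }
}

#' Count cis peptide bonds per frame
#'
#' A peptide bond is cis when its omega dihedral satisfies
#' `|omega| < 90` degrees (exactly 90 counts as trans).
#'
#' @param series A [dihedral_series()].
#' @return Integer vector, one count per frame.
#' @export
count_cis_omega <- function(series) {
  stopifnot(inherits(series, "dihedral_series"))
  as.integer(rowSums(abs(series$omega) < 90))
}

#' Angle between the inertial short axis and the z axis
#'
#' Diagonalises the inertia tensor of the frame (unit masses unless
#' given) and returns the angle between the eigenvector of the largest
#' eigenvalue — the short axis of the mass distribution — and the
#' reaction coordinate, folded to `[0, 90]` degrees since the axis sign
#' is arbitrary.
#'
#' @param coords n x 3 coordinate matrix (or a [conformer_frame()]).
#' @param masses Optional per-atom masses; defaults to unit masses.
#' @return Angle in degrees.
#' @export
short_axis_angle <- function(coords, masses = NULL) {
  if (inherits(coords, "conformer_frame")) coords <- coords$coords
  X <- as.matrix(coords)
  if (nrow(X) < 3L) stop("need at least three atoms")
  m <- if (is.null(masses)) rep(1, nrow(X)) else masses
  ctr <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, ctr)
  r2 <- rowSums(Xc^2)
  I <- diag(sum(m * r2), 3) - t(Xc * m) %*% Xc
  eig <- eigen(I, symmetric = TRUE)
  if ((eig$values[1] - eig$values[2]) < 1e-9 * max(eig$values[1], 1)) {
    stop("degenerate inertia tensor: geometry has no unique short axis")
  }
  axis <- eig$vectors[, 1]  # largest eigenvalue
  ang <- acos(min(1, abs(axis[3]))) * 180 / pi
  ang
}

#' Area per lipid from the lateral box
#'
#' @param box_xy `c(Lx, Ly)` lateral box lengths, Angstrom.
#' @param n_lipids_per_leaflet Number of lipids in one leaflet, > 0.
#' @return Area per lipid in A^2.
#' @examples
#' area_per_lipid(c(56.82, 56.82), 51) # about 63.3
#' @export
area_per_lipid <- function(box_xy, n_lipids_per_leaflet) {
  if (length(box_xy) != 2L || any(box_xy <= 0)) {
    stop("box_xy must be two positive lengths")
  }
  if (n_lipids_per_leaflet <= 0) stop("need a positive lipid count")
  box_xy[1] * box_xy[2] / n_lipids_per_leaflet
}
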