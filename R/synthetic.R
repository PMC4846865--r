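# Synthetic ensembles with analytically known statistics. These generators
# define the controlled conditions under which every analysis stage is
# validated: Gaussian positional fluctuations with prescribed amplitudes and
# correlations, diffusion-in-a-cone bond vectors with closed-form order
# parameters, two-state circular dihedral switching, and scripted
# hydrogen-bond geometries.

#' Gaussian positional-fluctuation ensemble
#'
#' Generates frames as \code{template + displacement}, where each residue's
#' displacement is a zero-mean Gaussian 3-vector, independent across frames
#' and Cartesian axes, with per-axis standard deviation \code{sigma[i]} and
#' inter-residue correlation \code{rho[i, j]} (the same correlation on each
#' axis). All atoms of a residue move rigidly together. The implied
#' per-residue RMSF is \code{sigma * sqrt(3)} and the displacement covariance
#' is \code{rho[i,j] * sigma[i] * sigma[j]} per axis.
#'
#' @param template A \code{structure_model} (e.g. from
#'   \code{\link{build_peptide}} or \code{\link{template_from_ca}}).
#' @param sigma Per-residue fluctuation amplitude in Angstrom per axis;
#'   recycled to the residue count. Must be non-negative.
#' @param rho Inter-residue correlation matrix in [-1, 1] (or a scalar applied
#'   to all off-diagonal pairs). The implied covariance must be positive
#'   semi-definite.
#' @param n_frames Number of frames.
#' @param seed Required seed; identical spec and seed give identical frames.
#' @param dt_ps Frame interval metadata.
#' @return An \code{ensemble}.
#' @export
gaussian_ensemble <- function(template, sigma, rho = 0, n_frames, seed,
                              dt_ps = 1) {
  stopifnot(inherits(template, "structure_model"), n_frames >= 1)
  atoms <- template$atoms
  reskey <- paste(atoms$chain, atoms$resno, sep = "|")
  resids <- unique(reskey)
  R <- length(resids)
  sigma <- rep_len(sigma, R)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (length(rho) == 1L) {
    rho <- matrix(rho, R, R) + diag(1 - rho, R)
  }
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == R, ncol(rho) == R)
  if (max(abs(rho - t(rho))) > 1e-9) stop("rho must be symmetric")

  covm <- rho * tcrossprod(sigma)
  ed <- eigen(covm, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values), 1)) {
    stop("implied covariance is not positive semi-definite (min eigenvalue ",
         signif(min(ed$values), 3), ")")
  }
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), R)

  disp <- with_seed(seed, {
    lapply(1:3, function(axis) {
      matrix(rnorm(n_frames * R), n_frames, R) %*% t(A)
    })
  })

  res_of_atom <- match(reskey, resids)
  xyz <- matrix(rep(template$xyz, each = n_frames), nrow = n_frames)
  for (ax in 1:3) {
    cols <- 3L * seq_len(nrow(atoms)) - 3L + ax
    xyz[, cols] <- xyz[, cols] + disp[[ax]][, res_of_atom, drop = FALSE]
  }
  ensemble(template, xyz, dt_ps = dt_ps)
}

#' Bond vectors diffusing in a cone
#'
#' Unit vectors drawn independently and uniformly on the spherical cap of
#' half-angle \code{theta0} about +z. The generalized order parameter of this
#' distribution has the closed form
#' \code{S2 = (cos(theta0) * (1 + cos(theta0)) / 2)^2}.
#'
#' @param theta0 Cone half-angle in degrees, in [0, 180].
#' @param n_frames Number of frames.
#' @param n_residues Number of independent residues (vector columns).
#' @param seed Required seed.
#' @return A \code{vector_trajectory}: array (frames x residues x 3) of unit
#'   vectors with a residue table attribute.
#' @export
cone_vectors <- function(theta0, n_frames, n_residues = 1L, seed) {
  if (theta0 < 0 || theta0 > 180) stop("theta0 must be in [0, 180] degrees")
  cmin <- cos(theta0 * pi / 180)
  arr <- with_seed(seed, {
    u <- runif(n_frames * n_residues, min = cmin, max = 1)   # cos(theta)
    ph <- runif(n_frames * n_residues, min = 0, max = 2 * pi)
    s <- sqrt(pmax(0, 1 - u^2))
    array(c(s * cos(ph), s * sin(ph), u),
          dim = c(n_frames, n_residues, 3))
  })
  .vector_trajectory(arr, data.frame(chain = "A", resno = seq_len(n_residues),
                                     resid = "ALA"))
}

#' Analytic order parameter for diffusion in a cone
#' @param theta0 Cone half-angle in degrees.
#' @return The closed-form S2 of vectors uniform on the cap.
#' @export
cone_s2 <- function(theta0) {
  ct <- cos(theta0 * pi / 180)
  (ct * (1 + ct) / 2)^2
}

#' Two-state circular dihedral switching
#'
#' Per frame, a Bernoulli(\code{p}) draw selects state A or B; the (phi, psi)
#' pair is the state's center plus wrapped-normal jitter, wrapped to
#' (-180, 180].
#'
#' @param center_a,center_b Numeric length-2 (phi, psi) centers in degrees.
#' @param jitter Angular jitter standard deviation (degrees).
#' @param p Probability of state A.
#' @param n_frames Number of frames.
#' @param seed Required seed.
#' @return A \code{dihedral_series} data frame (frame, phi, psi) with a
#'   \code{state} column (TRUE = state A).
#' @export
dihedral_switch <- function(center_a, center_b, jitter, p, n_frames, seed) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  with_seed(seed, {
    in_a <- runif(n_frames) < p
    phi0 <- ifelse(in_a, center_a[1], center_b[1])
    psi0 <- ifelse(in_a, center_a[2], center_b[2])
    phi <- wrap_angle(phi0 + rnorm(n_frames, sd = jitter))
    psi <- wrap_angle(psi0 + rnorm(n_frames, sd = jitter))
    structure(data.frame(frame = seq_len(n_frames), phi = phi, psi = psi,
                         state = in_a),
              class = c("dihedral_series", "data.frame"))
  })
}

#' Scripted hydrogen-bond trajectory
#'
#' Builds a two-group system (donor backbone N-H in chain A, acceptor carbonyl
#' C=O in chain B) whose per-frame geometry realizes a prescribed
#' presence/absence schedule under the detection criterion
#' (donor-acceptor distance <= 3.5 Angstrom and donor-H-acceptor angle >=
#' 120 degrees). Unbonded frames violate exactly one criterion each,
#' alternating between the two (or as given by \code{violation}).
#'
#' @param flags Logical vector: per-frame bonded state to realize.
#' @param bonded_distance,bonded_angle Geometry of bonded frames (defaults
#'   2.9 Angstrom, 165 degrees).
#' @param unbonded_distance Distance used for distance-violating frames
#'   (default 3.8 Angstrom, angle kept compliant).
#' @param unbonded_angle Angle used for angle-violating frames (default
#'   100 degrees, distance kept compliant).
#' @param violation Character vector over unbonded frames: "distance" or
#'   "angle"; recycled. Default alternates.
#' @return A list with \code{ensemble} and the realized \code{flags}.
#' @export
hbond_script <- function(flags, bonded_distance = 2.9, bonded_angle = 165,
                         unbonded_distance = 3.8, unbonded_angle = 100,
                         violation = c("distance", "angle")) {
  stopifnot(is.logical(flags), length(flags) >= 1)
  n_unb <- sum(!flags)
  viol <- rep_len(violation, max(n_unb, 1L))

  donor_n <- c(0, 0, 0)
  donor_h <- c(1, 0, 0)
  donor_ca <- c(-0.48, -1.33, 0)   # antecedent heavy atom on the donor

  # place the acceptor at distance d from N with angle a at H (degrees)
  acceptor_pos <- function(d, a) {
    ar <- a * pi / 180
    w <- c(-cos(ar), sin(ar), 0)
    s <- cos(ar) + sqrt(max(cos(ar)^2 - 1 + d^2, 0))
    donor_h + s * w
  }

  atoms <- data.frame(
    elety = c("N", "H", "CA", "O", "C"),
    resid = c("ALA", "ALA", "ALA", "ALA", "ALA"),
    chain = c("A", "A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L, 1L),
    insert = NA_character_, o = 1, b = 0,
    elesy = c("N", "H", "C", "O", "C"), stringsAsFactors = FALSE)

  xyz <- matrix(0, nrow = length(flags), ncol = 15)
  k <- 0L
  for (f in seq_along(flags)) {
    if (flags[f]) {
      o <- acceptor_pos(bonded_distance, bonded_angle)
    } else {
      k <- k + 1L
      o <- if (viol[k] == "distance") {
        acceptor_pos(unbonded_distance, bonded_angle)
      } else {
        acceptor_pos(bonded_distance, unbonded_angle)
      }
    }
    cc <- o + (o - donor_n) / sqrt(sum((o - donor_n)^2)) * 1.23
    xyz[f, ] <- c(donor_n, donor_h, donor_ca, o, cc)
  }
  topo <- structure_model(atoms, xyz[1, ])
  list(ensemble = ensemble(topo, xyz), flags = flags)
}
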