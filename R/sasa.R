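# Shrake-Rupley solvent-accessible surface area with a deterministic
# Fibonacci-spiral sphere point set, and Ala-X-Ala relative normalization.

# Van der Waals radii (Angstrom) by element; recorded in SASA output.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# n points quasi-uniform on the unit sphere (golden-angle spiral);
# deterministic for a fixed n.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius \code{probe_radius} over the structure: each atom's
#' accessible area is the fraction of \code{points_per_atom} test points on
#' its solvent-exposed sphere (radius vdW + probe) lying outside every
#' neighbor's exposed sphere, times that sphere's area. Atom areas are summed
#' into residues. The point set is a deterministic Fibonacci spiral, so
#' results are exactly reproducible.
#'
#' @param model A \code{structure_model}, or an \code{ensemble} with
#'   \code{frame}.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param points_per_atom Test points per atom (default 240).
#' @param frame Frame index when \code{model} is an ensemble.
#' @param include_h Include hydrogens as area-bearing atoms (default FALSE;
#'   they still occlude nothing when absent from the file).
#' @return A \code{sasa_profile} data frame: \code{chain}, \code{resno},
#'   \code{resid}, \code{sasa} (Angstrom^2) and \code{relative} (NA until
#'   filled), with the radii set and parameters as attributes.
#' @export
sasa <- function(model, probe_radius = 1.4, points_per_atom = 240,
                 frame = 1L, include_h = FALSE) {
  if (inherits(model, "ensemble")) {
    atoms <- model$topology$atoms
    xyz <- model$xyz[frame, ]
  } else {
    stopifnot(inherits(model, "structure_model"))
    atoms <- model$atoms
    xyz <- model$xyz
  }
  keep <- if (include_h) seq_len(nrow(atoms)) else which(atoms$elesy != "H")
  el <- atoms$elesy[keep]
  unknown <- !(el %in% names(.VDW_RADII))
  if (any(unknown)) {
    i <- keep[which(unknown)[1]]
    stop("unknown element '", atoms$elesy[i], "' for atom ", atoms$elety[i],
         " of residue ", atoms$resno[i], " chain ", atoms$chain[i],
         ": no van der Waals radius")
  }
  rad <- .VDW_RADII[el] + probe_radius
  pos <- matrix(xyz[as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))],
                ncol = 3, byrow = TRUE)
  pts <- fibonacci_sphere(points_per_atom)
  n <- length(keep)
  area <- numeric(n)
  maxrad <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    nb <- which(d2 < (rad[i] + maxrad)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < rad[i] + rad[nb]]
    sp <- sweep(pts * rad[i], 2, pos[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, nrow(sp))
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- rowSums(sweep(sp[acc, , drop = FALSE], 2, pos[j, ])^2)
        acc[acc] <- dj2 >= rad[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  reskey <- paste(atoms$chain[keep], atoms$resno[keep], sep = "|")
  resids <- unique(reskey)
  per_res <- vapply(resids, function(k) sum(area[reskey == k]), numeric(1))
  first <- match(resids, reskey)
  structure(data.frame(chain = atoms$chain[keep][first],
                       resno = atoms$resno[keep][first],
                       resid = atoms$resid[keep][first],
                       sasa = as.numeric(per_res), relative = NA_real_,
                       row.names = NULL, stringsAsFactors = FALSE),
            probe_radius = probe_radius, points_per_atom = points_per_atom,
            radii = .VDW_RADII,
            class = c("sasa_profile", "data.frame"))
}

# cache for computed tripeptide reference areas (per probe/points setting)
.sasa_ref_cache <- new.env(parent = emptyenv())

#' Ala-X-Ala reference areas for relative SASA
#'
#' Builds an extended (phi = -120, psi = 120) Ala-X-Ala tripeptide for each
#' requested residue type with \code{\link{build_peptide}}, computes the
#' central residue's SASA, and returns the reference table used for
#' normalization. Only residue types representable by the backbone + CB
#' builder (all types at backbone+CB resolution; side chains beyond CB are
#' not modeled) are supported, which matches the pseudo-residue alphabet of
#' the synthetic ensembles.
#'
#' @param types Character vector of one- or three-letter residue types.
#' @param probe_radius,points_per_atom As in \code{\link{sasa}}.
#' @return Named numeric vector: reference area (Angstrom^2) per three-letter
#'   residue type.
#' @export
ala_x_ala_reference <- function(types = c("ALA", "GLY"), probe_radius = 1.4,
                                points_per_atom = 240) {
  t3 <- toupper(types)
  t3[nchar(t3) == 1] <- bio3d::aa123(t3[nchar(t3) == 1])
  out <- setNames(numeric(length(t3)), t3)
  for (k in seq_along(t3)) {
    key <- paste(t3[k], probe_radius, points_per_atom, sep = "|")
    cached <- .sasa_ref_cache[[key]]
    if (!is.null(cached)) {
      out[k] <- cached
      next
    }
    one <- bio3d::aa321(t3[k])
    if (is.na(one) || one == "X") stop("unknown residue type: ", t3[k])
    tri <- build_peptide(c("A", one, "A"), phi = -120, psi = 120,
                         with_h = FALSE)
    prof <- sasa(tri, probe_radius = probe_radius,
                 points_per_atom = points_per_atom)
    val <- prof$sasa[prof$resno == 2]
    .sasa_ref_cache[[key]] <- val
    out[k] <- val
  }
  out
}

#' Relative solvent accessibility
#'
#' Divides each residue's absolute SASA by the reference area of its residue
#' type (Ala-X-Ala tripeptide normalization). Values may exceed 1 for
#' distorted conformations.
#'
#' @param profile A \code{sasa_profile}.
#' @param reference Named numeric vector (three-letter residue type ->
#'   Angstrom^2); by default computed with \code{\link{ala_x_ala_reference}}
#'   for the residue types present.
#' @return The profile with the \code{relative} column filled.
#' @export
relative_sasa <- function(profile, reference = NULL) {
  stopifnot(inherits(profile, "sasa_profile"))
  if (is.null(reference)) {
    reference <- ala_x_ala_reference(
      unique(profile$resid),
      probe_radius = attr(profile, "probe_radius"),
      points_per_atom = attr(profile, "points_per_atom"))
  }
  miss <- setdiff(unique(profile$resid), names(reference))
  if (length(miss) > 0) {
    stop("no reference area for residue type(s): ",
         paste(miss, collapse = ", "))
  }
  profile$relative <- profile$sasa / as.numeric(reference[profile$resid])
  profile
}
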