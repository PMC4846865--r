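#' Wrap angles to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

# signed dihedral (degrees, IUPAC convention) of four points; each argument is
# a frames x 3 matrix
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else p
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crossm <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- crossm(b1, b2)
  n2 <- crossm(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- crossm(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  -atan2(y, x) * 180 / pi
}

#' Backbone phi/psi time series for one residue
#'
#' phi is the C(i-1)-N-CA-C torsion and psi the N-CA-C-N(i+1) torsion, signed
#' by the IUPAC convention and wrapped to (-180, 180]. A chain-terminal
#' residue yields NA for the angle whose flanking atom does not exist; a
#' missing backbone atom on an interior residue is an error naming the atom.
#'
#' @param ens An \code{ensemble}.
#' @param residue List \code{(chain, resno)}.
#' @return A \code{dihedral_series} data frame: \code{frame}, \code{phi},
#'   \code{psi} (degrees).
#' @export
phi_psi <- function(ens, residue) {
  a <- ens$topology$atoms
  ch <- residue$chain
  in_chain <- a$chain == ch
  res_order <- unique(a$resno[in_chain])
  pos <- match(residue$resno, res_order)
  if (is.na(pos)) stop("residue ", residue$resno, " not found in chain ", ch)

  coord <- function(resno, elety, required_for) {
    i <- which(in_chain & a$resno == resno & a$elety == elety)
    if (length(i) != 1L) {
      stop("missing backbone atom ", elety, " in residue ", resno,
           " chain ", ch, " (needed for ", required_for, ")")
    }
    ens$xyz[, c(3 * i - 2, 3 * i - 1, 3 * i), drop = FALSE]
  }
  nf <- n_frames(ens)
  N <- coord(residue$resno, "N", "phi/psi")
  CA <- coord(residue$resno, "CA", "phi/psi")
  CC <- coord(residue$resno, "C", "phi/psi")

  phi <- rep(NA_real_, nf)
  psi <- rep(NA_real_, nf)
  if (pos > 1L) {
    Cprev <- coord(res_order[pos - 1L], "C", "phi")
    phi <- wrap_angle(dihedral_angle(Cprev, N, CA, CC))
  }
  if (pos < length(res_order)) {
    Nnext <- coord(res_order[pos + 1L], "N", "psi")
    psi <- wrap_angle(dihedral_angle(N, CA, CC, Nnext))
  }
  structure(data.frame(frame = seq_len(nf), phi = phi, psi = psi),
            class = c("dihedral_series", "data.frame"))
}

#' Fraction of sampling inside a phi/psi box
#'
#' Fraction of frames whose wrapped angular distances to the reference
#' satisfy \code{|dphi| <= halfwidth} and \code{|dpsi| <= halfwidth}
#' (inclusive edges; distances are circular, so samples across the +/-180
#' seam count correctly). The percentage is reported to one decimal place.
#'
#' @param series A \code{dihedral_series}.
#' @param ref Numeric length-2 reference (phi0, psi0) in degrees, e.g. the
#'   bound-state angles.
#' @param halfwidth Box half-width in degrees (default 30).
#' @return A \code{box_occupancy} list: \code{ref}, \code{halfwidth},
#'   \code{fraction} (in [0, 1]) and \code{percent} (one decimal).
#' @export
box_occupancy <- function(series, ref, halfwidth = 30) {
  stopifnot(inherits(series, "dihedral_series"), length(ref) == 2)
  phi <- series$phi; psi <- series$psi
  ok <- !is.na(phi) & !is.na(psi)
  if (!any(ok)) stop("no frames with both phi and psi defined")
  inside <- abs(wrap_angle(phi[ok] - ref[1])) <= halfwidth &
    abs(wrap_angle(psi[ok] - ref[2])) <= halfwidth
  frac <- mean(inside)
  structure(list(ref = ref, halfwidth = halfwidth, fraction = frac,
                 percent = round(100 * frac, 1), n_frames = sum(ok)),
            class = "box_occupancy")
}

#' @export
print.box_occupancy <- function(x, ...) {
  cat(sprintf("box_occupancy: %.1f%% of %d frames within +/-%g deg of (%g, %g)\n",
              x$percent, x$n_frames, x$halfwidth, x$ref[1], x$ref[2]))
  invisible(x)
}
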