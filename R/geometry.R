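# Internal-coordinate construction of idealized peptide models. Used by the
# synthetic-ensemble generator, the Ala-X-Ala SASA reference, and constructed
# test geometries.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NERF atom placement: position D with |D-C| = bond, angle(B,C,D) = ang (deg)
# and torsion(A,B,C,D) = tor (deg).
place_atom <- function(a, b, c, bond, ang, tor) {
  th <- ang * pi / 180
  ph <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate (collinear) frame in atom placement")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates (Engh-Huber-like values)
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_n_h = 1.010, b_ca_ha = 1.090,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.5, a_c_n_h = 119.0
)

#' Build an idealized peptide chain from backbone torsions
#'
#' Constructs a poly-peptide with ideal bond lengths and angles and the given
#' backbone torsions. Each residue carries N, CA, C, O plus a CB site (or an
#' HA site for glycine, so order-parameter bond vectors exist for every
#' residue type) and an amide hydrogen H (except the first residue).
#' Side chains beyond CB are not built.
#'
#' @param sequence One-letter amino-acid sequence (string or character
#'   vector).
#' @param phi,psi Backbone torsions in degrees; recycled along the chain.
#'   Defaults give an extended conformation.
#' @param omega Peptide-bond torsion (degrees), default trans (180).
#' @param chain Chain identifier for all residues.
#' @param resno_start First residue author number.
#' @param with_h If \code{FALSE}, amide hydrogens are omitted (crystal-like
#'   heavy-atom model).
#' @return A \code{structure_model}.
#' @export
build_peptide <- function(sequence, phi = -120, psi = 120, omega = 180,
                          chain = "A", resno_start = 1L, with_h = TRUE) {
  seq1 <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    strsplit(sequence, "")[[1]]
  } else as.character(sequence)
  n <- length(seq1)
  stopifnot(n >= 1)
  res3 <- bio3d::aa123(toupper(seq1))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  g <- .BB

  atoms <- list()
  coords <- list()
  add <- function(elety, resno, resid, xyz, elesy = NULL) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = resid, chain = chain, resno = resno,
      insert = NA_character_, o = 1, b = 0,
      elesy = if (is.null(elesy)) substr(elety, 1, 1) else elesy,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }

  N <- CA <- CC <- vector("list", n)
  # first residue laid out in the xy-plane
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  CC[[1]] <- CA[[1]] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], CC[[i - 1]],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                          g$b_n_ca, g$a_c_n_ca, omega[i - 1])
    CC[[i]] <- place_atom(CC[[i - 1]], N[[i]], CA[[i]],
                          g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  for (i in seq_len(n)) {
    rn <- resno_start + i - 1L
    add("N", rn, res3[i], N[[i]])
    if (with_h && i > 1L && res3[i] != "PRO") {
      H <- place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                      g$b_n_h, g$a_c_n_h, omega[i - 1] - 180)
      add("H", rn, res3[i], H)
    }
    add("CA", rn, res3[i], CA[[i]])
    if (res3[i] == "GLY") {
      HA <- place_atom(N[[i]], CC[[i]], CA[[i]],
                       g$b_ca_ha, g$a_n_ca_cb, -122.6)
      add("HA", rn, res3[i], HA)
    } else {
      CB <- place_atom(N[[i]], CC[[i]], CA[[i]],
                       g$b_ca_cb, g$a_n_ca_cb, -122.6)
      add("CB", rn, res3[i], CB)
    }
    add("C", rn, res3[i], CC[[i]])
    # carbonyl O trans to the next amide nitrogen
    O <- place_atom(N[[i]], CA[[i]], CC[[i]],
                    g$b_c_o, g$a_ca_c_o, psi[i] - 180)
    add("O", rn, res3[i], O)
  }
  structure_model(do.call(rbind, atoms), unlist(coords))
}

#' Build a pseudo-residue template from CA positions
#'
#' Places one pseudo-residue at each given CA coordinate, with a CB site (HA
#' for glycine) at a fixed ideal offset so bond vectors exist. Useful for
#' templates whose spatial arrangement matters (e.g. compact clusters) more
#' than their covalent geometry.
#'
#' @param ca Numeric matrix, residues x 3, of CA coordinates (Angstrom).
#' @param sequence One-letter sequence, recycled; default all alanine.
#' @param chain Chain identifier(s), recycled.
#' @param resno Residue numbers; default 1..n.
#' @return A \code{structure_model}.
#' @export
template_from_ca <- function(ca, sequence = "A", chain = "A", resno = NULL) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  seq1 <- rep_len(if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    strsplit(sequence, "")[[1]] else as.character(sequence), n)
  res3 <- bio3d::aa123(toupper(seq1))
  chain <- rep_len(chain, n)
  if (is.null(resno)) resno <- seq_len(n)
  rows <- list(); coords <- list()
  for (i in seq_len(n)) {
    gly <- res3[i] == "GLY"
    site <- if (gly) "HA" else "CB"
    blen <- if (gly) .BB$b_ca_ha else .BB$b_ca_cb
    rows[[length(rows) + 1L]] <- data.frame(
      elety = c("CA", site), resid = res3[i], chain = chain[i],
      resno = resno[i], insert = NA_character_, o = 1, b = 0,
      elesy = c("C", if (gly) "H" else "C"), stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- c(ca[i, ], ca[i, ] + c(0, 0, blen))
  }
  structure_model(do.call(rbind, rows), unlist(coords))
}
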