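#' Superpose ensemble frames onto a reference
#'
#' Each frame is replaced by its optimal rigid-body (rotation plus translation,
#' reflections excluded) least-squares fit of the mask atoms onto the
#' reference coordinates, i.e. the Kabsch solution, so the mask RMSD of every
#' frame is minimal over all rigid placements. The rotation is applied to all
#' atoms of the frame, not only the mask.
#'
#' @param ens An \code{ensemble}.
#' @param mask A \code{selection_mask} with at least 3 non-collinear atoms.
#' @param reference Reference coordinates: either a frame index into
#'   \code{ens}, or a numeric vector of length \code{3 * natoms} (full
#'   topology), or of length \code{3 * length(mask)} (mask atoms only).
#'   Default: frame 1.
#' @return The superposed \code{ensemble}.
#' @export
superpose <- function(ens, mask, reference = 1L) {
  stopifnot(inherits(ens, "ensemble"), inherits(mask, "selection_mask"))
  cidx <- mask_xyz_idx(mask)
  if (length(mask) < 3) stop("superposition mask needs at least 3 atoms")

  ref <- .reference_coords(ens, cidx, reference)
  refm <- matrix(ref, ncol = 3, byrow = TRUE)
  # degenerate (collinear) masks have a rank-deficient centered coordinate
  # matrix and no unique rotation
  if (qr(sweep(refm, 2, colMeans(refm)))$rank < 2 ||
      .is_collinear(refm)) {
    stop("superposition mask is degenerate (collinear reference atoms)")
  }

  out <- ens$xyz
  for (f in seq_len(nrow(out))) {
    out[f, ] <- .kabsch_apply(out[f, ], cidx, ref)
  }
  ens$xyz <- out
  ens
}

.reference_coords <- function(ens, cidx, reference) {
  if (length(reference) == 1L && is.numeric(reference)) {
    return(ens$xyz[as.integer(reference), cidx])
  }
  if (length(reference) == ncol(ens$xyz)) return(reference[cidx])
  if (length(reference) == length(cidx)) return(as.numeric(reference))
  stop("reference must be a frame index, full-topology coordinates, ",
       "or mask-sized coordinates")
}

.is_collinear <- function(m, tol = 1e-8) {
  mc <- sweep(m, 2, colMeans(m))
  s <- svd(mc, nu = 0, nv = 0)$d
  length(s) < 2 || s[2] < tol * max(s[1], 1)
}

# Kabsch fit of frame's mask atoms onto ref (mask-sized coordinate vector);
# returns the transformed full frame.
.kabsch_apply <- function(frame, cidx, ref) {
  X <- matrix(frame[cidx], ncol = 3, byrow = TRUE)   # mobile mask
  Y <- matrix(ref, ncol = 3, byrow = TRUE)           # fixed mask
  xc <- colMeans(X); yc <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xc), sweep(Y, 2, yc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))                              # reflection guard
  R <- s$v %*% D %*% t(s$u)
  allm <- matrix(frame, ncol = 3, byrow = TRUE)
  moved <- sweep(sweep(allm, 2, xc) %*% t(R), 2, yc, `+`)
  as.numeric(t(moved))
}

#' Mask RMSD of each frame against reference coordinates
#'
#' @param ens An \code{ensemble}.
#' @param mask A \code{selection_mask}.
#' @param reference As in \code{\link{superpose}}; default frame 1.
#' @param fit If \code{TRUE}, superpose each frame on the mask before
#'   measuring (RMSD after optimal fit); if \code{FALSE}, measure in place.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
frame_rmsd <- function(ens, mask, reference = 1L, fit = FALSE) {
  cidx <- mask_xyz_idx(mask)
  ref <- .reference_coords(ens, cidx, reference)
  if (fit) ens <- superpose(ens, mask, reference)
  apply(ens$xyz[, cidx, drop = FALSE], 1, function(v) {
    sqrt(mean(rowSums((matrix(v, ncol = 3, byrow = TRUE) -
                         matrix(ref, ncol = 3, byrow = TRUE))^2)))
  })
}
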