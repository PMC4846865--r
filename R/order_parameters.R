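# Generalized order parameters from bond-vector trajectories: the iRED
# (isotropic reorientational eigenmode dynamics) estimator and a direct
# second-rank tensor estimator used as its internal cross-check.

.vector_trajectory <- function(arr, residues) {
  nrm <- sqrt(arr[, , 1]^2 + arr[, , 2]^2 + arr[, , 3]^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    arr <- arr / array(rep(nrm, 3), dim = dim(arr))
  }
  structure(arr, residues = residues, class = "vector_trajectory")
}

#' Extract Ca-Cb (or Ca-Ha for glycine) bond-vector trajectories
#'
#' For each selected residue, builds the normalized per-frame vector from the
#' alpha carbon to the beta carbon, or to the alpha hydrogen (HA) for glycine.
#' A glycine without an HA-type hydrogen is an error, never a silent skip.
#'
#' @param ens An \code{ensemble}.
#' @param residues Data frame (chain, resno) of residues to use, a
#'   \code{loop_definition}, or \code{NULL} for every residue that has a CA.
#' @return A \code{vector_trajectory}: array (frames x residues x 3) of unit
#'   vectors, with the residue table as an attribute.
#' @export
extract_vectors <- function(ens, residues = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  a <- ens$topology$atoms
  if (inherits(residues, "loop_definition")) {
    residues <- data.frame(chain = residues$chain, resno = residues$resno)
  }
  if (is.null(residues)) {
    ca <- a[a$elety == "CA", ]
    residues <- unique(data.frame(chain = ca$chain, resno = ca$resno))
  }
  M <- nrow(residues)
  F <- n_frames(ens)
  arr <- array(NA_real_, dim = c(F, M, 3))
  resid_out <- character(M)
  for (k in seq_len(M)) {
    rows <- a$chain == residues$chain[k] & a$resno == residues$resno[k]
    resid_out[k] <- a$resid[rows][1]
    i_ca <- which(rows & a$elety == "CA")
    if (length(i_ca) != 1L) {
      stop("residue ", residues$resno[k], " chain ", residues$chain[k],
           ": no unique CA atom")
    }
    gly <- a$resid[i_ca] == "GLY"
    partner <- if (gly) c("HA", "HA2", "HA1") else "CB"
    i_p <- which(rows & a$elety %in% partner)[1]
    if (is.na(i_p)) {
      stop("residue ", a$resid[i_ca], " ", residues$resno[k], " chain ",
           residues$chain[k], ": missing ",
           if (gly) "alpha hydrogen (HA)" else "CB", " atom")
    }
    v <- ens$xyz[, c(3 * i_p - 2, 3 * i_p - 1, 3 * i_p), drop = FALSE] -
      ens$xyz[, c(3 * i_ca - 2, 3 * i_ca - 1, 3 * i_ca), drop = FALSE]
    arr[, k, ] <- v / sqrt(rowSums(v^2))
  }
  .vector_trajectory(arr, data.frame(residues, resid = resid_out))
}

# M x M matrix of <P2(u_i . u_j)> averaged over frames, P2(x) = (3x^2 - 1)/2.
# <(u_i.u_j)^2> = sum_{a,b} <u_ia u_ib u_ja u_jb>, computed with 9 crossprods.
ired_matrix <- function(vt) {
  F <- dim(vt)[1]; M <- dim(vt)[2]
  S <- matrix(0, M, M)
  for (a in 1:3) {
    for (b in 1:3) {
      Xab <- vt[, , a] * vt[, , b]
      if (is.null(dim(Xab))) Xab <- matrix(Xab, nrow = F)
      S <- S + crossprod(Xab) / F
    }
  }
  (3 * S - 1) / 2
}

#' iRED generalized order parameters
#'
#' Forms the matrix of ensemble-averaged second Legendre polynomials of the
#' inter-vector angles, \code{<P2(u_i . u_j)>}, diagonalizes it, and computes
#' per-residue order parameters as
#' \code{S2_i = 1 - sum_m lambda_m e_mi^2} over all but the \code{n_excluded}
#' largest-eigenvalue (reorientational/global) modes. Eigenvalues are sorted
#' descending; degenerate eigenvectors are given a deterministic sign (first
#' nonzero component positive). Tiny negative S2 from round-off
#' (> -1e-6) is clamped to 0.
#'
#' @param vt A \code{vector_trajectory}.
#' @param n_excluded Number of largest-eigenvalue modes treated as global
#'   reorientation and excluded from the sum (default 5, the standard iRED
#'   separation).
#' @return An \code{order_parameter_set}: list with \code{profile} (data frame
#'   residue, s2, method), \code{eigenvalues} (descending), \code{eigenvectors}
#'   and \code{n_excluded}.
#' @export
ired_order_parameters <- function(vt, n_excluded = 5L) {
  stopifnot(inherits(vt, "vector_trajectory"))
  M <- dim(vt)[2]
  if (M < 2 || dim(vt)[1] < 2) stop("need >= 2 residues and >= 2 frames")
  if (n_excluded >= M) {
    stop("n_excluded (", n_excluded, ") must be smaller than the number of ",
         "residues (", M, ")")
  }
  P <- ired_matrix(vt)
  ed <- eigen((P + t(P)) / 2, symmetric = TRUE)
  vec <- ed$vectors
  for (m in seq_len(M)) {   # deterministic sign convention
    nz <- which(abs(vec[, m]) > 1e-12)[1]
    if (!is.na(nz) && vec[nz, m] < 0) vec[, m] <- -vec[, m]
  }
  keep <- seq(n_excluded + 1L, M)       # internal (small-lambda) modes
  s2 <- 1 - colSums(ed$values[keep] * t(vec[, keep, drop = FALSE]^2))
  s2[s2 < 0 & s2 > -1e-6] <- 0
  s2 <- pmin(s2, 1 + 1e-9)
  res <- attr(vt, "residues")
  structure(list(
    profile = data.frame(res, s2 = s2, method = "ired",
                         n_excluded = n_excluded),
    eigenvalues = ed$values, eigenvectors = vec, n_excluded = n_excluded),
    class = "order_parameter_set")
}

#' Direct second-rank order parameters
#'
#' Per-residue estimator from the time-averaged second-moment tensor:
#' \code{S2 = (3 * sum_ab <u_a u_b>^2 - 1) / 2}. Serves as an independent
#' cross-check of the iRED estimator for motions without collective modes.
#'
#' @param vt A \code{vector_trajectory}.
#' @return An \code{order_parameter_set} with S2 only.
#' @export
direct_order_parameters <- function(vt) {
  stopifnot(inherits(vt, "vector_trajectory"))
  M <- dim(vt)[2]
  s2 <- vapply(seq_len(M), function(i) {
    U <- vt[, i, ]
    Q <- crossprod(U) / nrow(U)       # <u_a u_b>, 3x3
    (3 * sum(Q^2) - 1) / 2
  }, numeric(1))
  res <- attr(vt, "residues")
  structure(list(profile = data.frame(res, s2 = s2, method = "direct",
                                      n_excluded = NA_integer_),
                 eigenvalues = NULL, eigenvectors = NULL,
                 n_excluded = NA_integer_),
            class = "order_parameter_set")
}

#' @export
print.order_parameter_set <- function(x, ...) {
  cat("order_parameter_set (", x$profile$method[1], "): ",
      nrow(x$profile), " residues, mean S2 = ",
      round(mean(x$profile$s2), 4), "\n", sep = "")
  invisible(x)
}
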