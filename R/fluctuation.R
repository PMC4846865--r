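#' Per-atom root-mean-square fluctuations
#'
#' RMSF of each mask atom about its ensemble-mean position:
#' \code{RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)}, with the mean taken over
#' all frames. The ensemble should be superposed first; RMSF is then invariant
#' under any further global rigid motion applied to every frame.
#'
#' @param ens A superposed \code{ensemble}.
#' @param mask A \code{selection_mask} (typically alpha carbons).
#' @return A \code{fluctuation_profile} data frame: \code{chain},
#'   \code{resno}, \code{resid}, \code{elety}, \code{rmsf} (Angstrom) and
#'   \code{b} (equivalent B-factor, NA until filled).
#' @export
rmsf <- function(ens, mask) {
  stopifnot(inherits(ens, "ensemble"), inherits(mask, "selection_mask"))
  if (n_frames(ens) == 1L) {
    warning("single-frame ensemble: RMSF is identically zero")
  }
  X <- ens$xyz[, mask_xyz_idx(mask), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  msd_axis <- colMeans(Xc^2)                      # per coordinate column
  msd <- msd_axis[c(TRUE, FALSE, FALSE)] + msd_axis[c(FALSE, TRUE, FALSE)] +
    msd_axis[c(FALSE, FALSE, TRUE)]
  refs <- attr(mask, "refs")
  structure(data.frame(refs[, c("chain", "resno", "resid", "elety")],
                       rmsf = sqrt(msd), b = NA_real_, row.names = NULL),
            class = c("fluctuation_profile", "data.frame"))
}

#' Interconvert RMSF and isotropic B-factors
#'
#' Uses the crystallographic relation \code{B = (8 pi^2 / 3) * RMSF^2}
#' (Angstrom^2), a strict monotone bijection on RMSF >= 0; the two functions
#' are exact inverses.
#'
#' @param profile A \code{fluctuation_profile} (or numeric vector of RMSF /
#'   B-factor values).
#' @return The profile with the \code{b} (resp. \code{rmsf}) column filled, or
#'   a numeric vector if a vector was given.
#' @export
bfactor_from_rmsf <- function(profile) {
  k <- 8 * pi^2 / 3
  if (is.numeric(profile)) return(k * profile^2)
  stopifnot(inherits(profile, "fluctuation_profile"))
  profile$b <- k * profile$rmsf^2
  profile
}

#' @rdname bfactor_from_rmsf
#' @export
rmsf_from_bfactor <- function(profile) {
  k <- 8 * pi^2 / 3
  if (is.numeric(profile)) return(sqrt(profile / k))
  stopifnot(inherits(profile, "fluctuation_profile"))
  profile$rmsf <- sqrt(profile$b / k)
  profile
}

.resolve_atom <- function(ens, at, default_elety = "CA") {
  if (inherits(at, "selection_mask")) return(as.integer(at)[1])
  if (is.numeric(at) && length(at) == 1L) return(as.integer(at))
  a <- ens$topology$atoms
  elety <- if (!is.null(at$elety)) at$elety else default_elety
  i <- which(a$chain == at$chain & a$resno == at$resno & a$elety == elety)
  if (length(i) != 1L) {
    stop("atom ", elety, " of residue ", at$resno, " chain ", at$chain,
         " resolves to ", length(i), " atoms")
  }
  i
}

#' Inter-atomic distance time series with running average
#'
#' Per-frame Euclidean distance between two atoms, smoothed by a centered
#' running mean whose window is truncated at the series edges (so the smoothed
#' series has the same length as the raw one).
#'
#' @param ens An \code{ensemble}.
#' @param atomA,atomB Atom references: a list \code{(chain, resno, elety)}, a
#'   single-atom \code{selection_mask}, or an atom index.
#' @param window Running-average window in frames (default 1 = no smoothing).
#' @return A \code{distance_series}: data frame \code{frame},
#'   \code{distance}, \code{smoothed} with the window size as an attribute.
#' @export
distance_series <- function(ens, atomA, atomB, window = 1L) {
  ia <- .resolve_atom(ens, atomA)
  ib <- .resolve_atom(ens, atomB)
  dx <- ens$xyz[, 3 * ia - 2] - ens$xyz[, 3 * ib - 2]
  dy <- ens$xyz[, 3 * ia - 1] - ens$xyz[, 3 * ib - 1]
  dz <- ens$xyz[, 3 * ia] - ens$xyz[, 3 * ib]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  window <- as.integer(window)
  if (window > length(d)) {
    warning("window (", window, ") exceeds series length (", length(d),
            "); smoothed series is the global mean")
    sm <- rep(mean(d), length(d))
  } else if (window <= 1L) {
    sm <- d
  } else {
    sm <- as.numeric(zoo::rollapply(zoo::zoo(d), width = window, FUN = mean,
                                    align = "center", partial = TRUE))
  }
  structure(data.frame(frame = seq_along(d), distance = d, smoothed = sm),
            window = window,
            class = c("distance_series", "data.frame"))
}

#' Binding-groove width series
#'
#' Distance between marker residues on the two helices flanking a binding
#' groove (e.g. Tyr59 on the MHC alpha-1 helix and Arg170 on the alpha-2
#' helix), measured between their alpha carbons by default, plus its ensemble
#' mean.
#'
#' @param ens An \code{ensemble} (may hold a single crystallographic frame).
#' @param res1,res2 Lists \code{(chain, resno)} identifying the two residues.
#' @param elety Measurement atom name, default \code{"CA"}.
#' @param window Running-average window (frames).
#' @return A \code{distance_series} with an extra \code{mean} attribute.
#' @export
groove_width <- function(ens, res1, res2, elety = "CA", window = 1L) {
  ds <- distance_series(ens,
                        c(res1, list(elety = elety)),
                        c(res2, list(elety = elety)), window = window)
  attr(ds, "mean") <- mean(ds$distance)
  ds
}

#' Snapshot-to-snapshot RMSD matrix with block averages
#'
#' Takes snapshots (frames at a fixed stride) from one or more labeled
#' ensembles, superposes every snapshot pair on the mask, and records the
#' pairwise alpha-carbon RMSD. Block averages summarize each (simulation,
#' simulation) pair: off-diagonal blocks average all cross pairs, diagonal
#' blocks the distinct within-simulation pairs.
#'
#' @param ensembles Named list of \code{ensemble} objects.
#' @param refs Data frame (chain, resno, elety) defining the mask, resolved
#'   against each ensemble; or a \code{selection_mask} if a single ensemble is
#'   given.
#' @param stride Snapshot stride in frames (default 1 = every frame).
#' @return A \code{snapshot_rmsd_matrix}: list with \code{matrix} (symmetric,
#'   zero diagonal), \code{labels} (simulation, frame) and \code{blocks}
#'   (simulation x simulation block means).
#' @export
snapshot_rmsd_matrix <- function(ensembles, refs, stride = 1L) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(sim1 = ensembles)
  if (is.null(names(ensembles))) {
    names(ensembles) <- paste0("sim", seq_along(ensembles))
  }
  snaps <- list(); labels <- list()
  for (nm in names(ensembles)) {
    e <- ensembles[[nm]]
    m <- if (inherits(refs, "selection_mask")) refs
         else selection_mask(e, refs = refs)
    fr <- seq(1L, n_frames(e), by = as.integer(stride))
    cidx <- mask_xyz_idx(m)
    for (f in fr) {
      snaps[[length(snaps) + 1L]] <- e$xyz[f, cidx]
      labels[[length(labels) + 1L]] <- data.frame(sim = nm, frame = f)
    }
  }
  labels <- do.call(rbind, labels)
  S <- length(snaps)
  M <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j <= i) next
      M[i, j] <- M[j, i] <- .pair_rmsd(snaps[[i]], snaps[[j]])
    }
  }
  sims <- unique(labels$sim)
  B <- matrix(NA_real_, length(sims), length(sims),
              dimnames = list(sims, sims))
  for (a in seq_along(sims)) {
    for (b in seq_along(sims)) {
      ia <- which(labels$sim == sims[a]); ib <- which(labels$sim == sims[b])
      sub <- M[ia, ib, drop = FALSE]
      B[a, b] <- if (a == b) {
        if (length(ia) < 2) 0 else mean(sub[upper.tri(sub)])
      } else mean(sub)
    }
  }
  structure(list(matrix = M, labels = labels, blocks = B),
            class = "snapshot_rmsd_matrix")
}

# optimal-fit RMSD between two mask-coordinate vectors
.pair_rmsd <- function(x, y) {
  X <- matrix(x, ncol = 3, byrow = TRUE)
  Y <- matrix(y, ncol = 3, byrow = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
}

#' @export
print.snapshot_rmsd_matrix <- function(x, ...) {
  cat("snapshot_rmsd_matrix:", nrow(x$matrix), "snapshots from",
      nrow(x$blocks), "simulation(s)\nblock averages (Angstrom):\n")
  print(round(x$blocks, 3))
  invisible(x)
}
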