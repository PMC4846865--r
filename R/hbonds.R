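# Geometric hydrogen-bond analysis: detection on single frames, occupancy
# across ensembles, and interloop counting on crystallographic models.
# Criterion: donor-acceptor heavy-atom distance <= 3.5 Angstrom AND
# donor-H-acceptor angle >= 120 degrees.

# Donor/acceptor chemistry for standard amino acids. Backbone N donates
# (except proline) and backbone O (and OXT) accepts; side-chain groups as
# listed. The detection criterion itself is purely geometric.
.HB_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = character(0),
  ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1")
.HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

.hb_atom_indices <- function(atoms, rows, role) {
  tab <- if (role == "donor") .HB_DONORS else .HB_ACCEPTORS
  idx <- integer(0)
  for (i in rows) {
    names_ok <- tab$backbone
    sc <- tab[[atoms$resid[i]]]
    if (!is.null(sc)) names_ok <- c(names_ok, sc)
    if (role == "donor" && atoms$resid[i] == "PRO") {
      names_ok <- setdiff(names_ok, "N")
    }
    if (atoms$elety[i] %in% names_ok) idx <- c(idx, i)
  }
  idx
}

.frame_coords <- function(xyz_frame, i) {
  matrix(xyz_frame[as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))],
         ncol = 3, byrow = TRUE)
}

.angle_deg <- function(a, b, c) {
  # angle at b
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds between two atom groups in one frame
#'
#' A bond is recorded when the donor-acceptor heavy-atom distance is at most
#' \code{dist_cutoff} and the donor-H-acceptor angle is at least
#' \code{angle_min} for some hydrogen covalently attached to the donor
#' (identified by a <= 1.25 Angstrom H-donor distance within the donor's
#' residue). For structures without hydrogens (e.g. crystallographic models),
#' \code{no_h_fallback = TRUE} replaces the angle test by an
#' antecedent-donor-acceptor angle proxy >= \code{fallback_angle_min}; the
#' output flags this mode.
#'
#' @param model A \code{structure_model}, or an \code{ensemble} with
#'   \code{frame} selecting the frame.
#' @param groupA,groupB Logical or integer atom row selectors, or lists
#'   \code{(chain = ..., resno = ...)}; donors and acceptors are searched in
#'   both directions between the groups.
#' @param frame Frame index when \code{model} is an ensemble.
#' @param dist_cutoff Donor-acceptor distance cutoff (Angstrom), default 3.5.
#' @param angle_min Minimum donor-H-acceptor angle (degrees), default 120.
#' @param no_h_fallback Enable the hydrogen-free approximation (default
#'   FALSE). Donors without hydrogens are otherwise skipped with a warning.
#' @param warn_no_h Emit the skipped-donor warning (default TRUE; ensemble
#'   scans warn on the first frame only).
#' @param fallback_angle_min Antecedent-donor-acceptor angle floor used in
#'   fallback mode (degrees), default 90.
#' @return Data frame of detected bonds: donor/acceptor chain, resno, resid,
#'   elety, distance, angle, and a \code{fallback} flag.
#' @export
detect_hbonds <- function(model, groupA, groupB, frame = 1L,
                          dist_cutoff = 3.5, angle_min = 120,
                          no_h_fallback = FALSE, fallback_angle_min = 90,
                          warn_no_h = TRUE) {
  if (inherits(model, "ensemble")) {
    atoms <- model$topology$atoms
    xyz <- model$xyz[frame, ]
  } else {
    atoms <- model$atoms
    xyz <- model$xyz
  }
  rowsA <- .resolve_group(atoms, groupA)
  rowsB <- .resolve_group(atoms, groupB)

  out <- list()
  for (dir in 1:2) {
    don_rows <- if (dir == 1) rowsA else rowsB
    acc_rows <- if (dir == 1) rowsB else rowsA
    don <- .hb_atom_indices(atoms, don_rows, "donor")
    acc <- .hb_atom_indices(atoms, acc_rows, "acceptor")
    if (length(don) == 0 || length(acc) == 0) next
    acc_xyz <- .frame_coords(xyz, acc)
    for (d in don) {
      dpos <- .frame_coords(xyz, d)[1, ]
      hyd <- .attached_hydrogens(atoms, xyz, d)
      if (length(hyd) == 0 && !no_h_fallback) {
        if (warn_no_h) {
          warning("donor ", atoms$elety[d], " of residue ", atoms$resno[d],
                  " chain ", atoms$chain[d],
                  " has no attached hydrogen; skipped (no_h_fallback = FALSE)")
        }
        next
      }
      dd <- sqrt(rowSums(sweep(acc_xyz, 2, dpos)^2))
      # cutoffs are inclusive; epsilon guards exact-boundary geometries
      for (k in which(dd <= dist_cutoff + 1e-9)) {
        apos <- acc_xyz[k, ]
        if (length(hyd) > 0) {
          angs <- vapply(hyd, function(h) {
            .angle_deg(dpos, .frame_coords(xyz, h)[1, ], apos)
          }, numeric(1))
          ang <- max(angs)
          ok <- ang >= angle_min - 1e-9
          fb <- FALSE
        } else {
          ante <- .donor_antecedent(atoms, xyz, d)
          if (is.na(ante)) next
          ang <- .angle_deg(.frame_coords(xyz, ante)[1, ], dpos, apos)
          ok <- ang >= fallback_angle_min
          fb <- TRUE
        }
        if (ok) {
          a_i <- acc[k]
          out[[length(out) + 1L]] <- data.frame(
            donor_chain = atoms$chain[d], donor_resno = atoms$resno[d],
            donor_resid = atoms$resid[d], donor_elety = atoms$elety[d],
            acceptor_chain = atoms$chain[a_i], acceptor_resno = atoms$resno[a_i],
            acceptor_resid = atoms$resid[a_i], acceptor_elety = atoms$elety[a_i],
            distance = dd[k], angle = ang, fallback = fb,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_elety = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resid = character(0),
                      acceptor_elety = character(0),
                      distance = numeric(0), angle = numeric(0),
                      fallback = logical(0)))
  }
  unique(do.call(rbind, out))
}

.resolve_group <- function(atoms, group) {
  if (is.logical(group)) return(which(group))
  if (is.numeric(group)) return(as.integer(group))
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(group$chain)) sel <- sel & atoms$chain %in% group$chain
  if (!is.null(group$resno)) sel <- sel & atoms$resno %in% group$resno
  which(sel)
}

.attached_hydrogens <- function(atoms, xyz, donor) {
  same_res <- which(atoms$chain == atoms$chain[donor] &
                      atoms$resno == atoms$resno[donor] &
                      atoms$elesy == "H")
  if (length(same_res) == 0) return(integer(0))
  dpos <- .frame_coords(xyz, donor)[1, ]
  hpos <- .frame_coords(xyz, same_res)
  same_res[sqrt(rowSums(sweep(hpos, 2, dpos)^2)) <= 1.25]
}

.donor_antecedent <- function(atoms, xyz, donor) {
  same_res <- which(atoms$chain == atoms$chain[donor] &
                      atoms$resno == atoms$resno[donor] &
                      atoms$elesy != "H")
  same_res <- setdiff(same_res, donor)
  if (length(same_res) == 0) return(NA_integer_)
  dpos <- .frame_coords(xyz, donor)[1, ]
  dd <- sqrt(rowSums(sweep(.frame_coords(xyz, same_res), 2, dpos)^2))
  cand <- same_res[dd <= 1.8]
  if (length(cand) == 0) return(NA_integer_)
  cand[which.min(dd[dd <= 1.8])]
}

#' Hydrogen-bond occupancy map across an ensemble
#'
#' Detects hydrogen bonds between two groups in every frame and reports, per
#' residue pair, the occupancy (percent of frames) of the most persistent
#' donor/acceptor atom combination, along with summary statistics over the
#' pairs above an occupancy floor. If a crystallographic model is supplied,
#' pairs bonded in the crystal frame are flagged.
#'
#' @param ens An \code{ensemble}.
#' @param groupA,groupB Group selectors as in \code{\link{detect_hbonds}}.
#' @param crystal Optional \code{structure_model} for crystallographic flags
#'   (detected with \code{no_h_fallback = TRUE}).
#' @param occupancy_floor Percent floor for a pair to enter the summary
#'   (default 10); recorded in the output.
#' @param ... Passed to \code{\link{detect_hbonds}}.
#' @return An \code{occupancy_map}: data frame (residue pair, occupancy
#'   percent, crystal flag) with summary attributes \code{n_bonds},
#'   \code{mean_occupancy} and \code{occupancy_floor}.
#' @export
occupancy_map <- function(ens, groupA, groupB, crystal = NULL,
                          occupancy_floor = 10, ...) {
  stopifnot(inherits(ens, "ensemble"))
  nf <- n_frames(ens)
  tally <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    b <- detect_hbonds(ens, groupA, groupB, frame = f, warn_no_h = f == 1L,
                       ...)
    if (nrow(b) == 0) next
    combo <- paste(b$donor_chain, b$donor_resno, b$donor_elety,
                   b$acceptor_chain, b$acceptor_resno, b$acceptor_elety,
                   sep = "|")
    for (k in seq_along(combo)) {
      cur <- tally[[combo[k]]]
      tally[[combo[k]]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  combos <- ls(tally)
  if (length(combos) == 0) {
    map <- data.frame(resA_chain = character(0), resA_resno = integer(0),
                      resB_chain = character(0), resB_resno = integer(0),
                      occupancy = numeric(0), crystal = logical(0))
    return(structure(map, n_bonds = 0L, mean_occupancy = NA_real_,
                     occupancy_floor = occupancy_floor,
                     class = c("occupancy_map", "data.frame")))
  }
  parts <- do.call(rbind, strsplit(combos, "|", fixed = TRUE))
  occ <- 100 * vapply(combos, function(k) tally[[k]], integer(1)) / nf
  # residue pair key is orientation-free: (groupA residue, groupB residue)
  atomsA <- .resolve_group(ens$topology$atoms, groupA)
  a_res <- unique(paste(ens$topology$atoms$chain[atomsA],
                        ens$topology$atoms$resno[atomsA]))
  don_key <- paste(parts[, 1], parts[, 2])
  resA <- ifelse(don_key %in% a_res, don_key, paste(parts[, 4], parts[, 5]))
  resB <- ifelse(don_key %in% a_res, paste(parts[, 4], parts[, 5]), don_key)
  pair <- paste(resA, resB, sep = " ~ ")
  best <- tapply(occ, pair, max)
  pr <- do.call(rbind, strsplit(names(best), " ~ ", fixed = TRUE))
  ra <- do.call(rbind, strsplit(pr[, 1], " ", fixed = TRUE))
  rb <- do.call(rbind, strsplit(pr[, 2], " ", fixed = TRUE))
  map <- data.frame(resA_chain = ra[, 1], resA_resno = as.integer(ra[, 2]),
                    resB_chain = rb[, 1], resB_resno = as.integer(rb[, 2]),
                    occupancy = as.numeric(best), crystal = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(crystal)) {
    cb <- detect_hbonds(crystal, groupA, groupB, no_h_fallback = TRUE, ...)
    if (nrow(cb) > 0) {
      ck <- unique(paste(
        ifelse(paste(cb$donor_chain, cb$donor_resno) %in% a_res,
               paste(cb$donor_chain, cb$donor_resno),
               paste(cb$acceptor_chain, cb$acceptor_resno)),
        ifelse(paste(cb$donor_chain, cb$donor_resno) %in% a_res,
               paste(cb$acceptor_chain, cb$acceptor_resno),
               paste(cb$donor_chain, cb$donor_resno)), sep = " ~ "))
      map$crystal <- paste(paste(map$resA_chain, map$resA_resno),
                           paste(map$resB_chain, map$resB_resno),
                           sep = " ~ ") %in% ck
    }
  }
  map <- map[order(map$resA_chain, map$resA_resno, map$resB_chain,
                   map$resB_resno), ]
  rownames(map) <- NULL
  above <- map$occupancy >= occupancy_floor
  structure(map, n_bonds = sum(above),
            mean_occupancy = if (any(above)) mean(map$occupancy[above])
                             else NA_real_,
            occupancy_floor = occupancy_floor,
            class = c("occupancy_map", "data.frame"))
}

#' Count hydrogen bonds between different loops of one structure
#'
#' Detects hydrogen bonds (same geometric criterion) between residues that
#' belong to two different loops and returns the count plus a per-bond
#' partner-loop breakdown. Crystallographic heavy-atom models are supported
#' through the hydrogen-free fallback.
#'
#' @param model A \code{structure_model}.
#' @param loops List of \code{loop_definition} objects.
#' @param no_h_fallback Default TRUE (crystal models usually lack hydrogens).
#' @param ... Passed to \code{\link{detect_hbonds}}.
#' @return List with \code{count} and \code{bonds} (data frame with
#'   \code{loopA}, \code{loopB} columns appended).
#' @export
interloop_hbonds <- function(model, loops, no_h_fallback = TRUE, ...) {
  stopifnot(inherits(model, "structure_model"))
  loop_of <- function(chain, resno) {
    for (lp in loops) {
      if (lp$chain == chain && resno %in% lp$resno) return(lp$name)
    }
    NA_character_
  }
  out <- list()
  for (i in seq_along(loops)) {
    for (j in seq_along(loops)) {
      if (j <= i) next
      b <- detect_hbonds(model,
                         groupA = list(chain = loops[[i]]$chain,
                                       resno = loops[[i]]$resno),
                         groupB = list(chain = loops[[j]]$chain,
                                       resno = loops[[j]]$resno),
                         no_h_fallback = no_h_fallback, ...)
      if (nrow(b) == 0) next
      b$loopA <- loops[[i]]$name
      b$loopB <- loops[[j]]$name
      out[[length(out) + 1L]] <- b
    }
  }
  bonds <- if (length(out) > 0) do.call(rbind, out) else NULL
  if (!is.null(bonds)) {
    # one bond per residue pair across loops
    key <- paste(bonds$loopA, bonds$donor_resno, bonds$acceptor_resno,
                 bonds$loopB)
    bonds <- bonds[!duplicated(key), ]
    rownames(bonds) <- NULL
  }
  list(count = if (is.null(bonds)) 0L else nrow(bonds), bonds = bonds)
}
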