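#' Read a single structure from a PDB file
#'
#' Parses a PDB file and returns its topology (atoms, residues, chains,
#' occupancies and isotropic B-factors) together with the coordinates of the
#' first MODEL. Alternate locations are reduced to a single conformer by
#' keeping the highest-occupancy altloc (ties broken by altloc letter order),
#' so downstream analyses always see one coordinate triple per atom.
#'
#' @param path Path to a PDB file with at least one coordinate block.
#' @return An object of class \code{structure_model}: a list with
#'   \item{atoms}{data frame with one row per atom (\code{elety}, \code{resid},
#'     \code{chain}, \code{resno}, \code{insert}, \code{o}, \code{b},
#'     \code{elesy})}
#'   \item{xyz}{numeric vector of first-frame coordinates, length
#'     \code{3 * natoms}, in Angstrom}
#' @export
read_structure <- function(path) {
  ens <- read_ensemble(path)
  structure_model(ens$topology$atoms, ens$xyz[1, ])
}

#' Read a multi-model PDB file as a coordinate ensemble
#'
#' Every MODEL in the file becomes one frame; all models must share the same
#' atom count (and therefore atom order, which PDB convention fixes within a
#' model). Frames are returned in MODEL order.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param dt_ps Optional frame interval in picoseconds, stored as metadata.
#' @return An object of class \code{ensemble}: a list with
#'   \item{topology}{\code{structure_model} taken from the first model}
#'   \item{xyz}{numeric matrix, frames x (3 * natoms), Angstrom}
#'   \item{dt_ps}{frame interval metadata (possibly \code{NA})}
#' @export
read_ensemble <- function(path, dt_ps = NA_real_) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  n_atom_lines <- sum(rec %in% c("ATOM  ", "HETATM"))
  if (n_atom_lines == 0L) {
    stop("parse error: no ATOM/HETATM coordinate records in '", path, "'")
  }
  .check_model_atom_counts(lines, rec)

  known <- c("ATOM  ", "HETATM", "MODEL ", "ENDMDL", "END   ", "END",
             "TER   ", "TER", "HEADER", "TITLE ", "REMARK", "CRYST1",
             "SEQRES", "HELIX ", "SHEET ", "CONECT", "MASTER", "ANISOU",
             "EXPDTA", "COMPND", "SOURCE", "AUTHOR", "JRNL  ", "REVDAT",
             "DBREF ", "SEQADV", "HET   ", "HETNAM", "FORMUL", "SSBOND",
             "LINK  ", "SITE  ", "ORIGX1", "ORIGX2", "ORIGX3", "SCALE1",
             "SCALE2", "SCALE3", "MODRES", "CAVEAT", "OBSLTE", "SPRSDE",
             "KEYWDS", "HETSYN", "CISPEP")
  unknown <- setdiff(unique(trimws(rec[nzchar(trimws(rec))])), trimws(known))
  if (length(unknown) > 0) {
    warning("skipping unknown PDB record type(s): ",
            paste(unknown, collapse = ", "))
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)

  keep <- .select_altloc(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  xyz <- xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
             drop = FALSE]
  rownames(atoms) <- NULL

  .check_unique_atom_names(atoms)

  topo <- structure_model(atoms, xyz[1, ])
  structure(list(topology = topo, xyz = unname(xyz), dt_ps = dt_ps),
            class = "ensemble")
}

# Atom counts must agree across MODEL blocks; error names the first offender.
.check_model_atom_counts <- function(lines, rec) {
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) <= 1L) return(invisible(NULL))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  counts <- mapply(function(s, e) {
    sum(rec[s:e] %in% c("ATOM  ", "HETATM"))
  }, model_starts, model_ends[seq_along(model_starts)])
  model_no <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 14)))
  model_no[is.na(model_no)] <- seq_along(model_starts)[is.na(model_no)]
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop("atom count mismatch in multi-model PDB: MODEL ", model_no[bad],
         " has ", counts[bad], " atoms but MODEL ", model_no[1], " has ",
         counts[1])
  }
  invisible(NULL)
}

# Keep highest-occupancy altloc per (chain, resno, insert, elety);
# ties broken by altloc letter order. Returns kept row indices.
.select_altloc <- function(atoms) {
  alt <- atoms$alt
  if (is.null(alt)) return(seq_len(nrow(atoms)))
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(seq_len(nrow(atoms)))
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$elety, sep = "|")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    best <- idx[occ[idx] == max(occ[idx])]
    best[order(alt[best])][1]
  }), use.names = FALSE)
  sort(keep)
}

.check_unique_atom_names <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$elety, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    parts <- strsplit(d, "|", fixed = TRUE)[[1]]
    stop("duplicate atom name '", parts[4], "' in residue ", parts[2],
         " of chain ", parts[1])
  }
  invisible(NULL)
}

#' Construct a structure model from an atom table and coordinates
#'
#' @param atoms Data frame with columns \code{elety}, \code{resid},
#'   \code{chain}, \code{resno} and optionally \code{insert}, \code{o},
#'   \code{b}, \code{elesy}.
#' @param xyz Numeric vector of length \code{3 * nrow(atoms)}.
#' @return A \code{structure_model}.
#' @export
structure_model <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), length(xyz) == 3 * nrow(atoms))
  need <- c("elety", "resid", "chain", "resno")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- NA_character_
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- .guess_element(atoms$elety)
  structure(list(atoms = atoms, xyz = as.numeric(xyz)),
            class = "structure_model")
}

.guess_element <- function(elety) {
  # PDB convention: element is the first alphabetic character for standard
  # amino-acid atom names (two-letter metals do not occur in our scope)
  sub("^[0-9]*([A-Za-z]).*$", "\\1", elety)
}

#' Build an ensemble from a topology and a frame matrix
#'
#' @param topology A \code{structure_model}.
#' @param xyz Frames x (3 * natoms) numeric matrix.
#' @param dt_ps Frame interval (ps), metadata only.
#' @return An \code{ensemble}.
#' @export
ensemble <- function(topology, xyz, dt_ps = NA_real_) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology$atoms)) {
    stop("frame width ", ncol(xyz), " does not match topology with ",
         nrow(topology$atoms), " atoms")
  }
  if (nrow(xyz) < 1) stop("an ensemble needs at least one frame")
  structure(list(topology = topology, xyz = unname(as.matrix(xyz)),
                 dt_ps = dt_ps), class = "ensemble")
}

#' Number of frames in an ensemble
#' @param x An \code{ensemble}.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  nrow(x$xyz)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals); reading the
#' file back therefore round-trips coordinates to 1e-3 Angstrom.
#'
#' @param ens An \code{ensemble}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  a <- ens$topology$atoms
  bio3d::write.pdb(file = path, xyz = ens$xyz,
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(is.na(a$insert), "", a$insert),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$insert))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", n_frames(x), "frame(s) x", nrow(x$topology$atoms),
      "atoms", if (!is.na(x$dt_ps)) paste0("(", x$dt_ps, " ps/frame)"), "\n")
  invisible(x)
}
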