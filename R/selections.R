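#' Resolve an ordered atom selection against a topology
#'
#' A selection mask is an ordered list of (chain, residue number, atom name)
#' references. Order of the references is preserved in the returned mask.
#'
#' @param model A \code{structure_model} (or an \code{ensemble}, whose
#'   topology is used).
#' @param chain Character vector of chain identifiers. If \code{NULL}, all
#'   chains are searched.
#' @param resno Integer vector of residue author numbers. If \code{NULL}, all
#'   residues in the selected chains.
#' @param elety Atom name(s) to select, default \code{"CA"}. \code{NULL}
#'   selects all atoms of the matched residues.
#' @param refs Alternatively, a data frame with columns \code{chain},
#'   \code{resno}, \code{elety} giving explicit ordered references; overrides
#'   the other selectors.
#' @return An object of class \code{selection_mask}: integer atom indices into
#'   the topology, with a \code{refs} attribute recording the references.
#' @export
selection_mask <- function(model, chain = NULL, resno = NULL, elety = "CA",
                           refs = NULL) {
  atoms <- .topology_atoms(model)
  if (!is.null(refs)) {
    stopifnot(all(c("chain", "resno", "elety") %in% names(refs)))
    key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "|")
    want <- paste(refs$chain, refs$resno, refs$elety, sep = "|")
    idx <- match(want, key)
    if (anyNA(idx)) {
      stop("selection does not resolve: ", want[which(is.na(idx))[1]])
    }
    return(.new_mask(idx, atoms))
  }
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) sel <- sel & atoms$chain %in% chain
  if (!is.null(resno)) sel <- sel & atoms$resno %in% resno
  if (!is.null(elety)) sel <- sel & atoms$elety %in% elety
  idx <- which(sel)
  if (length(idx) == 0) stop("selection resolves to zero atoms")
  .new_mask(idx, atoms)
}

.new_mask <- function(idx, atoms) {
  structure(as.integer(idx),
            refs = atoms[idx, c("chain", "resno", "elety", "resid")],
            class = "selection_mask")
}

.topology_atoms <- function(model) {
  if (inherits(model, "ensemble")) model <- model$topology
  stopifnot(inherits(model, "structure_model"))
  model$atoms
}

# xyz column indices (x,y,z interleaved) for a mask
mask_xyz_idx <- function(mask) {
  i <- as.integer(mask)
  as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))
}

#' One-letter amino-acid sequence of a chain
#'
#' Reads residues in chain order from the topology's CA atoms and converts
#' three-letter codes to one-letter codes.
#'
#' @param model A \code{structure_model} or \code{ensemble}.
#' @param chain Chain identifier.
#' @return Character scalar, the chain's one-letter sequence.
#' @export
chain_sequence <- function(model, chain) {
  atoms <- .topology_atoms(model)
  ca <- atoms[atoms$chain == chain & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("chain '", chain, "' has no CA atoms")
  paste(bio3d::aa321(ca$resid), collapse = "")
}

#' Resolve named loop definitions from sequence motifs
#'
#' Each loop is specified by a name, a chain and a one-letter sequence motif
#' (for example a CDR loop sequence). The motif must occur exactly once in the
#' chain; the resolved loop records the matching contiguous residue range.
#' Resolution is deterministic and independent of the order in which loops are
#' given.
#'
#' @param model A \code{structure_model} or \code{ensemble}.
#' @param loop_specs Data frame with columns \code{name}, \code{chain},
#'   \code{sequence}.
#' @return A list of \code{loop_definition} objects (name, chain, resno range,
#'   sequence), one per spec row, in spec order.
#' @export
resolve_loops <- function(model, loop_specs) {
  stopifnot(is.data.frame(loop_specs),
            all(c("name", "chain", "sequence") %in% names(loop_specs)))
  atoms <- .topology_atoms(model)
  lapply(seq_len(nrow(loop_specs)), function(i) {
    nm <- loop_specs$name[i]
    ch <- loop_specs$chain[i]
    sq <- toupper(loop_specs$sequence[i])
    chain_seq <- chain_sequence(model, ch)
    hits <- gregexpr(sq, chain_seq, fixed = TRUE)[[1]]
    n_hits <- if (hits[1] == -1L) 0L else length(hits)
    if (n_hits != 1L) {
      stop("loop '", nm, "': sequence ", sq, " matches chain ", ch, " ",
           n_hits, " times (expected exactly 1)")
    }
    ca <- atoms[atoms$chain == ch & atoms$elety == "CA", , drop = FALSE]
    rows <- seq(hits[1], length.out = nchar(sq))
    loop_definition(name = nm, chain = ch, resno = ca$resno[rows],
                    sequence = sq)
  })
}

#' Construct a loop definition
#'
#' @param name Loop name (e.g. \code{"CDR3b"}).
#' @param chain Chain identifier.
#' @param resno Integer vector of member residue author numbers, in order.
#' @param sequence One-letter sequence; must have the same length as
#'   \code{resno}.
#' @return A \code{loop_definition}.
#' @export
loop_definition <- function(name, chain, resno, sequence) {
  if (nchar(sequence) != length(resno)) {
    stop("loop '", name, "': sequence length ", nchar(sequence),
         " != residue range length ", length(resno))
  }
  structure(list(name = name, chain = chain, resno = as.integer(resno),
                 sequence = sequence), class = "loop_definition")
}

#' @export
print.loop_definition <- function(x, ...) {
  cat(sprintf("loop %s (chain %s): residues %d-%d, %s (%d aa)\n", x$name,
              x$chain, min(x$resno), max(x$resno), x$sequence,
              length(x$resno)))
  invisible(x)
}

#' @export
length.loop_definition <- function(x) length(x$resno)
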