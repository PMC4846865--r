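# Motional correlation analyses: dynamic cross-correlation (DCCM), linear
# mutual information (LMI), the distance/LMI edge-filter protocol, and
# Girvan-Newman community detection.

.correlation_matrix <- function(mat, kind, residues, dist = NULL) {
  labs <- paste0(residues$chain, residues$resno)
  dimnames(mat) <- list(labs, labs)
  if (!is.null(dist)) dimnames(dist) <- dimnames(mat)
  structure(list(matrix = mat, kind = kind, residues = residues, dist = dist),
            class = "correlation_matrix")
}

# centered per-axis coordinate matrices for a mask: list of 3 (frames x M)
.centered_axes <- function(ens, mask) {
  X <- ens$xyz[, mask_xyz_idx(mask), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  lapply(1:3, function(ax) Xc[, seq(ax, ncol(Xc), by = 3), drop = FALSE])
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of atomic displacement vectors about their ensemble
#' means: \code{C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)}, in
#' [-1, 1] with +1 full correlation and -1 full anti-correlation. Residues
#' with zero displacement variance yield missing (NA) entries rather than 0.
#'
#' @param ens A superposed \code{ensemble}.
#' @param mask A \code{selection_mask} (typically alpha carbons).
#' @return A \code{correlation_matrix} of kind \code{"dccm"}.
#' @export
dccm <- function(ens, mask) {
  ax <- .centered_axes(ens, mask)
  nf <- nrow(ax[[1]])
  num <- Reduce(`+`, lapply(ax, function(x) crossprod(x) / nf))
  v <- diag(num)
  zero <- v < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance residue(s): correlation entries ",
            "reported as missing")
  }
  den <- sqrt(outer(v, v))
  C <- num / den
  C[zero, ] <- NA_real_
  C[, zero] <- NA_real_
  C <- pmin(pmax(C, -1), 1)
  diag(C)[!zero] <- 1
  .correlation_matrix(C, "dccm", attr(mask, "refs"))
}

#' Average correlation between residue groups (loop pairs)
#'
#' Unweighted mean of matrix entries over all (i in loop A, j in loop B)
#' pairs; for A = B, only distinct off-diagonal pairs are averaged.
#'
#' @param cm A \code{correlation_matrix}.
#' @param loops List of \code{loop_definition} objects.
#' @return Numeric loops x loops matrix of block means.
#' @export
loop_pair_average <- function(cm, loops) {
  stopifnot(inherits(cm, "correlation_matrix"))
  refs <- cm$residues
  idx <- lapply(loops, function(lp) {
    i <- which(refs$chain == lp$chain & refs$resno %in% lp$resno)
    if (length(i) != length(lp$resno)) {
      stop("loop '", lp$name, "' is not fully covered by the matrix")
    }
    i
  })
  nm <- vapply(loops, function(lp) lp$name, character(1))
  out <- matrix(NA_real_, length(loops), length(loops),
                dimnames = list(nm, nm))
  for (a in seq_along(loops)) {
    for (b in seq_along(loops)) {
      sub <- cm$matrix[idx[[a]], idx[[b]], drop = FALSE]
      out[a, b] <- if (a == b) {
        mean(sub[upper.tri(sub)], na.rm = TRUE)
      } else mean(sub, na.rm = TRUE)
    }
  }
  out
}

#' Linear mutual information matrix
#'
#' Gaussian-model mutual information between the 3D displacements of residue
#' pairs, in nats:
#' \code{LMI_ij = (ln det S_i + ln det S_j - ln det S_ij) / 2}, where
#' \code{S_i} are the marginal 3x3 displacement covariances and \code{S_ij}
#' the joint 6x6 covariance. The diagonal (self-information, divergent) is
#' reported as \code{Inf} and excluded from edge filtering. A singular joint
#' covariance for a pair (perfectly coupled motion) is reported as \code{Inf}
#' with a warning; a zero-variance residue gives missing entries. A companion
#' matrix of ensemble-mean inter-residue distances is attached for the
#' distance filter.
#'
#' @param ens A superposed \code{ensemble}.
#' @param mask A \code{selection_mask} (typically alpha carbons).
#' @return A \code{correlation_matrix} of kind \code{"lmi"} with a
#'   \code{dist} companion matrix (Angstrom).
#' @export
lmi <- function(ens, mask) {
  X <- ens$xyz[, mask_xyz_idx(mask), drop = FALSE]
  nf <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nf                 # 3M x 3M displacement covariance
  M <- length(mask)
  L <- matrix(Inf, M, M)
  n_singular <- 0L
  logdet3 <- numeric(M)
  degenerate <- logical(M)
  for (i in seq_len(M)) {
    ii <- (3 * i - 2):(3 * i)
    d <- det(S[ii, ii])
    degenerate[i] <- !is.finite(d) || d <= 0
    logdet3[i] <- if (degenerate[i]) NA_real_ else log(d)
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance residue(s): LMI entries ",
            "reported as missing")
  }
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      if (degenerate[i] || degenerate[j]) {
        L[i, j] <- L[j, i] <- NA_real_
        next
      }
      ij <- c((3 * i - 2):(3 * i), (3 * j - 2):(3 * j))
      dj <- det(S[ij, ij])
      if (!is.finite(dj) || dj <= exp(logdet3[i] + logdet3[j]) * 1e-12) {
        n_singular <- n_singular + 1L
        L[i, j] <- L[j, i] <- Inf      # divergent MI: perfectly coupled pair
      } else {
        L[i, j] <- L[j, i] <- (logdet3[i] + logdet3[j] - log(dj)) / 2
      }
    }
  }
  if (n_singular > 0) {
    warning(n_singular, " residue pair(s) with singular joint covariance: ",
            "LMI reported as Inf (perfect coupling)")
  }
  # companion mean-distance matrix over frames
  D <- matrix(0, M, M)
  xs <- lapply(1:3, function(ax) X[, seq(ax, ncol(X), by = 3), drop = FALSE])
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      D[i, j] <- D[j, i] <- mean(sqrt(
        (xs[[1]][, i] - xs[[1]][, j])^2 +
          (xs[[2]][, i] - xs[[2]][, j])^2 +
          (xs[[3]][, i] - xs[[3]][, j])^2))
    }
  }
  .correlation_matrix(L, "lmi", attr(mask, "refs"), dist = D)
}

#' Closed-form LMI of a bivariate per-axis correlation
#'
#' For two residues with unit per-axis variances and per-axis correlation
#' \code{r} (independent axes), the Gaussian mutual information is
#' \code{-(3/2) * ln(1 - r^2)} nats.
#'
#' @param r Per-axis correlation coefficient.
#' @return LMI in nats.
#' @export
lmi_gaussian <- function(r) -1.5 * log(1 - r^2)

#' Build the filtered dynamic network and select the distance cutoff
#'
#' Keeps edges whose mutual information is at least \code{lmi_min} and whose
#' ensemble-mean distance does not exceed a candidate cutoff; scans cutoffs
#' over \code{dist_range} at a fixed step, runs community detection at each,
#' and returns the graph and partition for the cutoff that minimizes the
#' number of communities. Cutoffs tied on community count resolve to the
#' larger cutoff.
#'
#' @param lmi_cm A \code{correlation_matrix} of kind \code{"lmi"} with a
#'   distance companion.
#' @param lmi_min Mutual-information edge threshold (nats), default 0.4.
#' @param dist_range Inclusive distance-cutoff scan range (Angstrom), default
#'   \code{c(8, 10)}.
#' @param step Scan step (Angstrom), default 0.5.
#' @return List with \code{graph} (igraph), \code{partition}
#'   (\code{community_partition}), \code{cutoff} (selected, Angstrom) and
#'   \code{scan} (data frame cutoff, n_communities, n_edges).
#' @export
build_network <- function(lmi_cm, lmi_min = 0.4, dist_range = c(8, 10),
                          step = 0.5) {
  stopifnot(inherits(lmi_cm, "correlation_matrix"), lmi_cm$kind == "lmi",
            !is.null(lmi_cm$dist))
  L <- lmi_cm$matrix
  D <- lmi_cm$dist
  diag(L) <- NA_real_                      # self-information never an edge
  cutoffs <- seq(dist_range[1], dist_range[2], by = step)
  results <- vector("list", length(cutoffs))
  n_comm <- n_edge <- integer(length(cutoffs))
  for (k in seq_along(cutoffs)) {
    keep <- !is.na(L) & L >= lmi_min & D <= cutoffs[k]
    n_edge[k] <- sum(keep) / 2
    if (n_edge[k] == 0) {
      n_comm[k] <- NA_integer_
      next
    }
    adj <- (keep | t(keep)) * 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    part <- girvan_newman(g)
    n_comm[k] <- part$n_communities
    results[[k]] <- list(graph = g, partition = part)
  }
  if (all(is.na(n_comm))) {
    stop("no edges survive the LMI >= ", lmi_min,
         " filter at any distance cutoff in [", dist_range[1], ", ",
         dist_range[2], "] Angstrom")
  }
  best_count <- min(n_comm, na.rm = TRUE)
  sel <- max(which(!is.na(n_comm) & n_comm == best_count))  # tie -> larger
  list(graph = results[[sel]]$graph, partition = results[[sel]]$partition,
       cutoff = cutoffs[sel],
       scan = data.frame(cutoff = cutoffs, n_communities = n_comm,
                         n_edges = n_edge))
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness (ties broken by
#' lexicographic order of the edge's endpoint names, for determinism) and
#' keeps, over the whole removal sequence, the connected-component partition
#' of maximum Newman-Girvan modularity evaluated on the original graph.
#' Edges are unweighted: the mutual-information filter decides edge presence,
#' not strength.
#'
#' @param g An igraph undirected graph (node names preserved).
#' @return A \code{community_partition}: list with \code{membership} (named
#'   integer vector), \code{sizes}, \code{n_communities}, \code{modularity}
#'   and \code{edge_weights} (inter-community retained-edge counts).
#' @export
girvan_newman <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  if (igraph::ecount(g) == 0) {
    warning("graph has no edges: every node is its own community")
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    return(.community_partition(g, memb, modularity = NA_real_))
  }
  h <- g
  best_memb <- igraph::components(h)$membership
  best_q <- igraph::modularity(g, best_memb)
  while (igraph::ecount(h) > 0) {
    eb <- igraph::edge_betweenness(h, directed = FALSE)
    cand <- which(eb >= max(eb) - 1e-9)
    if (length(cand) > 1) {
      ends <- igraph::ends(h, igraph::E(h)[cand], names = TRUE)
      key <- apply(ends, 1, function(r) paste(sort(r), collapse = "\r"))
      cand <- cand[order(key)[1]]
    }
    h <- igraph::delete_edges(h, igraph::E(h)[cand[1]])
    memb <- igraph::components(h)$membership
    q <- igraph::modularity(g, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  .community_partition(g, best_memb, best_q)
}

.community_partition <- function(g, membership, modularity) {
  memb <- as.integer(membership)
  names(memb) <- names(membership)
  k <- max(memb)
  ew <- matrix(0, k, k)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  if (nrow(ends) > 0) {
    ca <- memb[ends[, 1]]; cb <- memb[ends[, 2]]
    for (e in seq_len(nrow(ends))) {
      ew[ca[e], cb[e]] <- ew[ca[e], cb[e]] + 1
      if (ca[e] != cb[e]) ew[cb[e], ca[e]] <- ew[cb[e], ca[e]] + 1
    }
  }
  structure(list(membership = memb, sizes = as.integer(table(memb)),
                 n_communities = k, modularity = modularity,
                 edge_weights = ew),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities, sizes",
      paste(x$sizes, collapse = "/"),
      if (!is.na(x$modularity)) paste0("(Q = ", round(x$modularity, 3), ")"),
      "\n")
  invisible(x)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix (", x$kind, "): ", nrow(x$matrix), " residues\n",
      sep = "")
  invisible(x)
}
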