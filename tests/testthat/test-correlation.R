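test_that("DCCM reaches +/-1 for coupled pairs and ~0 for independence", {
  tpl <- build_peptide("AA")
  mask_names <- selection_mask(tpl, elety = "CA")

  # identical displacements: +1; opposite displacements: -1
  ca <- which(tpl$atoms$elety == "CA")
  n <- 200
  set.seed(1)
  d <- matrix(rnorm(n * 3), n, 3)
  mk <- function(sgn) {
    xyz <- matrix(rep(tpl$xyz, each = n), nrow = n)
    for (ax in 1:3) {
      xyz[, 3 * ca[1] - 3 + ax] <- xyz[, 3 * ca[1] - 3 + ax] + d[, ax]
      xyz[, 3 * ca[2] - 3 + ax] <- xyz[, 3 * ca[2] - 3 + ax] + sgn * d[, ax]
    }
    ensemble(tpl, xyz)
  }
  cp <- dccm(mk(+1), selection_mask(tpl, elety = "CA"))
  cm <- dccm(mk(-1), selection_mask(tpl, elety = "CA"))
  expect_equal(cp$matrix[1, 2], 1, tolerance = 1e-12)
  expect_equal(cm$matrix[1, 2], -1, tolerance = 1e-12)
  expect_equal(diag(cp$matrix), c(A1 = 1, A2 = 1))

  # independent residues: |C| below the sampling bound at 2e4 frames
  tpl5 <- build_peptide("AAAAA")
  ens <- gaussian_ensemble(tpl5, 1, 0, 20000, seed = 3)
  C <- dccm(ens, selection_mask(ens, elety = "CA"))$matrix
  expect_lt(max(abs(C[upper.tri(C)])), 0.03)

  # zero-variance residue: missing entries, not zero
  tplz <- build_peptide("AAA")
  ez <- gaussian_ensemble(tplz, c(1, 0, 1), 0, 100, seed = 4)
  expect_warning(Cz <- dccm(ez, selection_mask(ez, elety = "CA"))$matrix,
                 "zero-variance")
  expect_true(is.na(Cz[1, 2]) && is.na(Cz[2, 3]))
  expect_false(is.na(Cz[1, 3]))

  # symmetry and range
  expect_equal(C, t(C))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("DCCM agrees with the bio3d reference implementation", {
  tpl <- build_peptide("ASRGYK")
  rho <- diag(1, 6); rho[2, 5] <- rho[5, 2] <- 0.7
  ens <- gaussian_ensemble(tpl, 0.8, rho, 500, seed = 6)
  mask <- selection_mask(ens, elety = "CA")
  mine <- dccm(ens, mask)$matrix
  ref <- unclass(bio3d::dccm(ens$xyz[, loopdyn:::mask_xyz_idx(mask)]))
  dimnames(ref) <- dimnames(mine)
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("loop-pair averages recover planted block means", {
  # hand computation: 2x2 rectangle {0.2, 0.4, 0.6, 0.8} -> 0.5
  tpl <- build_peptide("AAAA")
  ens <- gaussian_ensemble(tpl, 1, 0, 10, seed = 1)
  cmx <- dccm(ens, selection_mask(ens, elety = "CA"))
  cmx$matrix[1:2, 3:4] <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  cmx$matrix[3:4, 1:2] <- t(cmx$matrix[1:2, 3:4])
  loops <- list(loop_definition("L1", "A", 1:2, "AA"),
                loop_definition("L2", "A", 3:4, "AA"))
  lpa <- loop_pair_average(cmx, loops)
  expect_equal(lpa["L1", "L2"], 0.5)
  expect_equal(lpa["L2", "L1"], 0.5)
  # constant rectangle
  cmx$matrix[1:2, 3:4] <- 0.42
  expect_equal(loop_pair_average(cmx, loops)["L1", "L2"], 0.42)

  # planted block covariance: mean +0.42 between two loops, within 0.02
  tab <- data.frame(name = c("CDR3a", "CDR3b"), chain = c("A", "A"),
                    sequence = c("AVNFGGGKLI", "ASSLSFGTEAF"))
  ch <- build_peptide(paste0("TS", tab$sequence[1], "TS", tab$sequence[2],
                             "TS"))
  loops2 <- resolve_loops(ch, tab)
  reskey <- unique(paste(ch$atoms$chain, ch$atoms$resno))
  nres <- length(reskey)
  rho <- diag(1, nres)
  ia <- match(paste("A", loops2[[1]]$resno), reskey)
  ib <- match(paste("A", loops2[[2]]$resno), reskey)
  rho[ia, ia] <- 0.6; rho[ib, ib] <- 0.6
  rho[ia, ib] <- 0.42; rho[ib, ia] <- 0.42
  diag(rho) <- 1
  ens2 <- gaussian_ensemble(ch, 1, rho, 20000, seed = 9)
  cm2 <- dccm(ens2, selection_mask(ens2, elety = "CA"))
  expect_equal(loop_pair_average(cm2, loops2)["CDR3a", "CDR3b"], 0.42,
               tolerance = 0.02 / 0.42)
})

test_that("LMI matches the bivariate Gaussian closed form", {
  tpl <- build_peptide("AA")
  for (r in c(0.2, 0.5, 0.8)) {
    rho <- matrix(c(1, r, r, 1), 2, 2)
    ens <- gaussian_ensemble(tpl, 1, rho, 50000, seed = round(100 * r))
    L <- lmi(ens, selection_mask(ens, elety = "CA"))
    expect_lt(abs(L$matrix[1, 2] - lmi_gaussian(r)), 0.03)
  }

  # independence: LMI near zero
  tpl3 <- build_peptide("AAA")
  e0 <- gaussian_ensemble(tpl3, 1, 0, 50000, seed = 12)
  L0 <- lmi(e0, selection_mask(e0, elety = "CA"))
  off <- L0$matrix[upper.tri(L0$matrix)]
  expect_lt(max(abs(off)), 0.01)

  # perfect coupling: divergent, flagged as Inf with a warning
  e1 <- gaussian_ensemble(tpl, 1, matrix(1, 2, 2), 500, seed = 13)
  expect_warning(L1 <- lmi(e1, selection_mask(e1, elety = "CA")),
                 "singular|perfect")
  expect_true(is.infinite(L1$matrix[1, 2]))

  # symmetry; diagonal excluded (Inf sentinel); distance companion present
  expect_equal(L0$matrix, t(L0$matrix))
  expect_true(all(is.infinite(diag(L0$matrix))))
  ca_idx <- which(tpl3$atoms$elety == "CA")
  ca_xyz <- matrix(tpl3$xyz, ncol = 3, byrow = TRUE)[ca_idx, ]
  d12 <- sqrt(sum((ca_xyz[1, ] - ca_xyz[2, ])^2))
  expect_equal(L0$dist[1, 2], d12, tolerance = 0.15)
})

test_that("network building scans cutoffs and applies the tie rule", {
  sys <- two_block_system(n_frames = 4000, seed = 11)
  L <- lmi(sys$ens, sys$mask)
  net <- build_network(L)

  # brute-force oracle over the same cutoffs
  counts <- vapply(seq(8, 10, by = 0.5), function(cut) {
    keep <- is.finite(L$matrix) & L$matrix >= 0.4 & L$dist <= cut
    diag(keep) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(keep * 1, mode = "undirected")
    girvan_newman(g)$n_communities
  }, integer(1))
  expect_equal(net$scan$n_communities, counts)
  best <- min(counts)
  expect_equal(net$cutoff, seq(8, 10, by = 0.5)[max(which(counts == best))])

  # every cutoff yields 2 communities -> tie resolves to 10
  expect_true(all(counts == 2))
  expect_equal(net$cutoff, 10)

  # planted two-block partition recovered exactly
  memb <- net$partition$membership
  expect_equal(net$partition$n_communities, 2L)
  expect_true(all(memb[1:6] == memb[1]) && all(memb[7:12] == memb[7]) &&
                memb[1] != memb[7])

  # all LMI below threshold: empty graph at every cutoff is an error
  L2 <- L
  L2$matrix[] <- 0.1
  expect_error(build_network(L2), "no edges")
})

test_that("Girvan-Newman maximizes modularity deterministically", {
  # two 5-cliques joined by one bridge: communities are the cliques
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  p <- girvan_newman(g)
  expect_equal(p$n_communities, 2L)
  expect_equal(as.integer(p$sizes), c(5L, 5L))
  # bridge is the single inter-community edge
  expect_equal(p$edge_weights[1, 2], 1)

  # agrees with igraph's reference edge-betweenness clustering
  ref <- igraph::cluster_edge_betweenness(g)
  expect_equal(unname(p$membership), unname(igraph::membership(ref)))

  # a single clique stays one community
  expect_equal(girvan_newman(igraph::make_full_graph(6))$n_communities, 1L)

  # disconnected components are never merged
  g2 <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  expect_gte(girvan_newman(g2)$n_communities, 2L)

  # edgeless graph: every node its own community, with warning
  expect_warning(p0 <- girvan_newman(igraph::make_empty_graph(3,
                                                              directed = FALSE)),
                 "no edges")
  expect_equal(p0$n_communities, 3L)

  # determinism on a symmetric tie-rich graph
  ring <- igraph::make_ring(6)
  expect_identical(girvan_newman(ring)$membership,
                   girvan_newman(ring)$membership)
})
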