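test_that("RMSF matches hand computations and closed forms", {
  tpl <- build_peptide("AAAA")
  mask <- selection_mask(tpl, elety = "CA")

  # rigid ensemble: zero everywhere
  rigid <- ensemble(tpl, rbind(tpl$xyz, tpl$xyz, tpl$xyz))
  expect_equal(rmsf(rigid, mask)$rmsf, rep(0, 4))

  # two-frame, one atom displaced 2 A in +x: deviations +/-1 A -> RMSF 1
  fr2 <- rbind(tpl$xyz, tpl$xyz)
  i_ca2 <- which(tpl$atoms$elety == "CA")[2]
  fr2[2, 3 * i_ca2 - 2] <- fr2[2, 3 * i_ca2 - 2] + 2
  prof <- rmsf(ensemble(tpl, fr2), mask)
  expect_equal(prof$rmsf, c(0, 1, 0, 0))

  # Gaussian sigma = 1: RMSF = sqrt(3) within 2% at 2e4 frames
  ens <- gaussian_ensemble(tpl, sigma = 1, rho = 0, n_frames = 20000,
                           seed = 21)
  expect_equal(mean(rmsf(ens, mask)$rmsf), sqrt(3), tolerance = 0.02)

  # single frame: zero with a warning
  expect_warning(p1 <- rmsf(ensemble(tpl, matrix(tpl$xyz, 1)), mask),
                 "single-frame")
  expect_equal(p1$rmsf, rep(0, 4))

  # invariance under a global rigid motion applied after superposition
  moved <- apply_rigid_motion(ens, seed = 2)
  expect_equal(rmsf(moved, mask)$rmsf, rmsf(ens, mask)$rmsf,
               tolerance = 1e-9)
})

test_that("B-factor conversion is the exact (8 pi^2 / 3) bijection", {
  expect_equal(bfactor_from_rmsf(1), 8 * pi^2 / 3)
  expect_equal(bfactor_from_rmsf(0), 0)
  x <- c(0, 0.3, 1.7, 5)
  expect_equal(rmsf_from_bfactor(bfactor_from_rmsf(x)), x,
               tolerance = 1e-14)
  # monotone on RMSF >= 0
  expect_true(all(diff(bfactor_from_rmsf(seq(0, 4, by = 0.1))) > 0))

  tpl <- build_peptide("AAA")
  ens <- gaussian_ensemble(tpl, 0.5, 0, 100, seed = 1)
  prof <- bfactor_from_rmsf(rmsf(ens, selection_mask(ens, elety = "CA")))
  expect_equal(rmsf_from_bfactor(prof)$rmsf, prof$rmsf, tolerance = 1e-14)
})

test_that("distance series and running averages follow the edge rules", {
  tpl <- template_from_ca(rbind(c(0, 0, 0), c(13, 0, 0)))
  ens <- ensemble(tpl, matrix(rep(tpl$xyz, 5), nrow = 5, byrow = TRUE))
  a1 <- list(chain = "A", resno = 1, elety = "CA")
  a2 <- list(chain = "A", resno = 2, elety = "CA")
  ds <- distance_series(ens, a1, a2)
  expect_equal(ds$distance, rep(13, 5))

  # alternating 10/12 with window 2: interior smoothed values are 11
  xyz <- t(sapply(1:6, function(f) {
    v <- tpl$xyz
    v[3 * 3 - 2] <- if (f %% 2 == 1) 10 else 12   # CA of residue 2 is atom 3
    v
  }))
  ds2 <- distance_series(ensemble(tpl, xyz), a1, a2, window = 2)
  expect_equal(ds2$distance, rep(c(10, 12), 3))
  expect_equal(ds2$smoothed[2:5], rep(11, 4))

  # window larger than the series: global mean with warning
  expect_warning(ds3 <- distance_series(ensemble(tpl, xyz), a1, a2,
                                        window = 10), "exceeds")
  expect_equal(ds3$smoothed, rep(11, 6))
})

test_that("groove width reports the series and its mean", {
  tpl <- template_from_ca(rbind(c(0, 0, 0), c(13, 0, 0)))
  xyz <- t(sapply(1:10, function(f) {
    v <- tpl$xyz
    v[7] <- if (f <= 5) 13 else 15
    v
  }))
  gw <- groove_width(ensemble(tpl, xyz), list(chain = "A", resno = 1),
                     list(chain = "A", resno = 2))
  expect_equal(attr(gw, "mean"), 14)

  # single crystallographic frame gives a length-1 series
  g1 <- groove_width(ensemble(tpl, matrix(tpl$xyz, 1)),
                     list(chain = "A", resno = 1),
                     list(chain = "A", resno = 2))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$distance, 13)
})

test_that("snapshot RMSD matrix matches a brute-force oracle", {
  tpl <- build_peptide("ASRGY")
  refs <- data.frame(chain = "A",
                     resno = sort(unique(tpl$atoms$resno)), elety = "CA")

  # identical frames: all-zero matrix
  e0 <- ensemble(tpl, rbind(tpl$xyz, tpl$xyz, tpl$xyz))
  m0 <- snapshot_rmsd_matrix(list(a = e0), refs)
  expect_equal(max(abs(m0$matrix)), 0, tolerance = 1e-8)

  # rigid-body motions of one structure: superposition removes everything
  e1 <- ensemble(tpl, rbind(tpl$xyz, tpl$xyz))
  e2 <- apply_rigid_motion(e1, seed = 4)
  m1 <- snapshot_rmsd_matrix(list(a = e1, b = e2), refs)
  expect_equal(max(abs(m1$matrix)), 0, tolerance = 1e-7)

  # block averages equal a brute-force all-pairs computation
  ga <- gaussian_ensemble(tpl, 0.8, 0, 2, seed = 5)
  gb <- gaussian_ensemble(tpl, 0.8, 0, 2, seed = 6)
  mm <- snapshot_rmsd_matrix(list(a = ga, b = gb), refs)
  mask <- selection_mask(ga, refs = refs)
  cidx <- loopdyn:::mask_xyz_idx(mask)
  snaps <- rbind(ga$xyz[, cidx], gb$xyz[, cidx])
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) brute[i, j] <- loopdyn:::.pair_rmsd(snaps[i, ], snaps[j, ])
  }
  expect_equal(mm$matrix, brute, tolerance = 1e-10)
  expect_equal(mm$blocks["a", "b"], mean(brute[1:2, 3:4]))
  expect_equal(mm$blocks["a", "a"], brute[1, 2])

  # stride selects every k-th frame
  g4 <- gaussian_ensemble(tpl, 0.5, 0, 4, seed = 7)
  ms <- snapshot_rmsd_matrix(list(a = g4), refs, stride = 2)
  expect_equal(nrow(ms$matrix), 2L)
  expect_equal(ms$labels$frame, c(1L, 3L))
})

test_that("per-loop RMSF maxima rank loops as their planted amplitudes", {
  tab <- cdr_loop_table("A6")[cdr_loop_table("A6")$chain == "A", ]
  ch <- build_peptide(paste0("TS", paste(tab$sequence, collapse = "TS"),
                             "TS"))
  loops <- resolve_loops(ch, tab)
  reskey <- unique(paste(ch$atoms$chain, ch$atoms$resno))
  sigma <- rep(0.2, length(reskey))
  planted <- c(CDR1a = 0.5, CDR2a = 2.0, CDR3a = 1.0)
  for (lp in loops) {
    sigma[match(paste(lp$chain, lp$resno), reskey)] <- planted[lp$name]
  }
  ens <- gaussian_ensemble(ch, sigma, 0, 3000, seed = 31)
  prof <- rmsf(ens, selection_mask(ens, elety = "CA"))
  loop_max <- vapply(loops, function(lp) {
    max(prof$rmsf[prof$chain == lp$chain & prof$resno %in% lp$resno])
  }, numeric(1))
  expect_equal(order(loop_max), order(planted))
})
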