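# place an acceptor at a chosen donor-acceptor distance and D-H-A angle,
# independent of the generator under test
donor_acceptor_frame <- function(d, ang) {
  ar <- ang * pi / 180
  w <- c(-cos(ar), sin(ar), 0)
  s <- cos(ar) + sqrt(max(cos(ar)^2 - 1 + d^2, 0))
  o <- c(1, 0, 0) + s * w
  atoms <- data.frame(
    elety = c("N", "H", "CA", "O", "C"),
    resid = "ALA", chain = c("A", "A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L, 1L), insert = NA_character_, o = 1, b = 0,
    elesy = c("N", "H", "C", "O", "C"), stringsAsFactors = FALSE)
  structure_model(atoms, c(0, 0, 0, 1, 0, 0, -0.48, -1.33, 0, o,
                           o + c(0, 0, 1.23)))
}

test_that("detection decisions match the 3.5 A / 120 deg rule at boundaries", {
  cases <- expand.grid(d = c(3.4, 3.5, 3.6), ang = c(119, 120, 160))
  for (k in seq_len(nrow(cases))) {
    d <- cases$d[k]; ang <- cases$ang[k]
    m <- donor_acceptor_frame(d, ang)
    got <- nrow(detect_hbonds(m, list(chain = "A"), list(chain = "B")))
    expect_equal(got, as.integer(d <= 3.5 && ang >= 120),
                 info = sprintf("d=%.1f ang=%d", d, ang))
  }
})

test_that("detection is per-frame stateless and rigid-motion invariant", {
  hs <- hbond_script(c(TRUE, FALSE, TRUE, FALSE))
  ga <- list(chain = "A"); gb <- list(chain = "B")
  per_frame <- vapply(1:4, function(f) {
    nrow(detect_hbonds(hs$ensemble, ga, gb, frame = f))
  }, integer(1))
  expect_equal(per_frame, c(1L, 0L, 1L, 0L))

  # frame order does not matter
  rev_ens <- hs$ensemble
  rev_ens$xyz <- rev_ens$xyz[4:1, ]
  expect_equal(vapply(1:4, function(f) {
    nrow(detect_hbonds(rev_ens, ga, gb, frame = f))
  }, integer(1)), rev(per_frame))

  # global rigid motion leaves decisions unchanged
  moved <- apply_rigid_motion(hs$ensemble, seed = 5)
  expect_equal(vapply(1:4, function(f) {
    nrow(detect_hbonds(moved, ga, gb, frame = f))
  }, integer(1)), per_frame)
})

test_that("occupancy equals the scripted fraction exactly", {
  hs <- hbond_script(rep(c(TRUE, FALSE), 50))
  om <- occupancy_map(hs$ensemble, list(chain = "A"), list(chain = "B"))
  expect_equal(nrow(om), 1L)
  expect_equal(om$occupancy, 50)

  # 37/100 scripted
  hs2 <- hbond_script(c(rep(TRUE, 37), rep(FALSE, 63)))
  om2 <- occupancy_map(hs2$ensemble, list(chain = "A"), list(chain = "B"))
  expect_equal(om2$occupancy, 37)

  # no bonds anywhere: empty map
  hs0 <- hbond_script(rep(FALSE, 10))
  om0 <- occupancy_map(hs0$ensemble, list(chain = "A"), list(chain = "B"))
  expect_equal(nrow(om0), 0L)
  expect_equal(attr(om0, "n_bonds"), 0L)
})

test_that("occupancy summaries count bonds above the floor", {
  # two bonded pairs at 80% and 20%: count 2, mean 50% (floor 10)
  mk <- function(shift_y, flags) {
    hs <- hbond_script(flags)
    e <- hs$ensemble
    e$topology$atoms$resno <- e$topology$atoms$resno +
      c(0, 0, 0, shift_y, shift_y)
    e
  }
  e1 <- mk(0L, c(rep(TRUE, 8), rep(FALSE, 2)))
  e2 <- mk(1L, c(rep(TRUE, 2), rep(FALSE, 8)))
  # merge the two donor/acceptor systems into one ensemble, offset in space
  a2 <- e2$topology$atoms
  xyz2 <- e2$xyz + 50
  topo <- structure_model(rbind(e1$topology$atoms, a2),
                          c(e1$xyz[1, ], xyz2[1, ]))
  ens <- ensemble(topo, cbind(e1$xyz, xyz2))
  om <- occupancy_map(ens, list(chain = "A"), list(chain = "B"))
  expect_equal(sort(om$occupancy), c(20, 80))
  expect_equal(attr(om, "n_bonds"), 2L)
  expect_equal(attr(om, "mean_occupancy"), 50)
  expect_equal(attr(om, "occupancy_floor"), 10)

  # raising the floor above 20% drops the weak bond from the summary
  om25 <- occupancy_map(ens, list(chain = "A"), list(chain = "B"),
                        occupancy_floor = 25)
  expect_equal(attr(om25, "n_bonds"), 1L)
  expect_equal(attr(om25, "mean_occupancy"), 80)
})

test_that("crystallographic flags mark bonds present in the crystal frame", {
  hs <- hbond_script(rep(c(TRUE, FALSE), 10))
  crystal <- donor_acceptor_frame(2.9, 165)
  crystal$atoms <- crystal$atoms[crystal$atoms$elety != "H", ]
  crystal$xyz <- donor_acceptor_frame(2.9, 165)$xyz[
    rep(donor_acceptor_frame(2.9, 165)$atoms$elety != "H", each = 3)]
  om <- occupancy_map(hs$ensemble, list(chain = "A"), list(chain = "B"),
                      crystal = crystal)
  expect_true(om$crystal[1])

  far <- donor_acceptor_frame(4.5, 165)
  om2 <- occupancy_map(hs$ensemble, list(chain = "A"), list(chain = "B"),
                       crystal = far)
  expect_false(om2$crystal[1])
})

test_that("interloop bonds are counted with the partner-loop breakdown", {
  # two-loop toy: loop1 residue donates to loop3 acceptors
  m <- donor_acceptor_frame(2.9, 165)
  m$atoms$chain <- "A"
  m$atoms$resno <- c(1L, 1L, 1L, 5L, 5L)
  loops <- list(loop_definition("CDR1", "A", 1, "A"),
                loop_definition("CDR3", "A", 5, "A"))
  il <- interloop_hbonds(m, loops)
  expect_equal(il$count, 1L)
  expect_equal(il$bonds$loopA, "CDR1")
  expect_equal(il$bonds$loopB, "CDR3")

  # acceptor moved out of range: count 0
  far <- donor_acceptor_frame(3.8, 165)
  far$atoms$chain <- "A"
  far$atoms$resno <- c(1L, 1L, 1L, 5L, 5L)
  expect_equal(interloop_hbonds(far, loops)$count, 0L)

  # all bonds to one loop: breakdown names that loop on every bond
  base <- donor_acceptor_frame(2.9, 165)
  mk_pair <- function(resno_d, resno_a, offset) {
    mm <- base
    mm$atoms$chain <- "A"
    mm$atoms$resno <- c(rep(resno_d, 3), rep(resno_a, 2))
    mm$xyz <- mm$xyz + offset
    mm
  }
  big <- loopdyn:::combine_models(list(mk_pair(1L, 20L, 0),
                                       mk_pair(5L, 21L, 50),
                                       mk_pair(9L, 22L, 100)))
  loops3 <- list(loop_definition("CDR1", "A", 1, "A"),
                 loop_definition("CDR2", "A", 5, "A"),
                 loop_definition("CDR3a", "A", 9, "A"),
                 loop_definition("CDR3b", "A", 20:22, "AAA"))
  il3 <- interloop_hbonds(big, loops3)
  expect_equal(il3$count, 3L)
  expect_true(all(il3$bonds$loopB == "CDR3b"))
})
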