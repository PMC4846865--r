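test_that("single-sphere SASA matches the analytic area", {
  m <- structure_model(data.frame(elety = "CA", resid = "ALA", chain = "A",
                                  resno = 1, elesy = "C"), c(0, 0, 0))
  # carbon: 4 pi (1.7 + 1.4)^2
  expect_equal(sasa(m)$sasa, 4 * pi * 3.1^2, tolerance = 0.015)

  # custom radius via element: sulfur 1.8 -> 4 pi (1.8 + 1.4)^2
  ms <- structure_model(data.frame(elety = "SG", resid = "CYS", chain = "A",
                                   resno = 1, elesy = "S"), c(0, 0, 0))
  expect_equal(sasa(ms)$sasa, 4 * pi * 3.2^2, tolerance = 0.015)

  # doubling the point set changes the result by < 1%
  s240 <- sasa(m, points_per_atom = 240)$sasa
  s480 <- sasa(m, points_per_atom = 480)$sasa
  expect_lt(abs(s480 - s240) / s240, 0.01)

  # unknown element is an error naming the atom
  mx <- structure_model(data.frame(elety = "FE", resid = "HEM", chain = "A",
                                   resno = 1, elesy = "Fe"), c(0, 0, 0))
  expect_error(sasa(mx), "unknown element")
})

test_that("occlusion, additivity and rigid-motion invariance hold", {
  # atom caged by 6 tightly packed large atoms: zero accessible area
  cage <- rbind(c(2.8, 0, 0), c(-2.8, 0, 0), c(0, 2.8, 0), c(0, -2.8, 0),
                c(0, 0, 2.8), c(0, 0, -2.8))
  atoms <- data.frame(elety = c("C", rep("S", 6)),
                      resid = c("ALA", rep("CYS", 6)), chain = "A",
                      resno = 1:7, elesy = c("C", rep("S", 6)))
  m <- structure_model(atoms, c(0, 0, 0, as.numeric(t(cage))))
  expect_equal(sasa(m)$sasa[1], 0)

  # two far-apart identical atoms: each the isolated value
  m2 <- structure_model(data.frame(elety = c("CA", "CA"),
                                   resid = "ALA", chain = "A", resno = 1:2,
                                   elesy = "C"),
                        c(0, 0, 0, 100, 0, 0))
  s2 <- sasa(m2)$sasa
  expect_equal(s2[1], s2[2])
  expect_equal(s2[1], 4 * pi * 3.1^2, tolerance = 0.015)

  # rigid-motion invariance on a peptide
  tri <- build_peptide("AGA", with_h = FALSE)
  e <- ensemble(tri, rbind(tri$xyz, tri$xyz))
  moved <- apply_rigid_motion(e, seed = 8)
  s_ref <- sasa(tri)$sasa
  s_mov <- sasa(moved$topology, frame = 1)$sasa
  # the sphere-point set is fixed in space, so rotation changes which test
  # points are occluded: invariance holds to the ~1% discretization level
  s_mov2 <- sasa(structure_model(tri$atoms, moved$xyz[1, ]))$sasa
  expect_equal(s_mov2, s_ref, tolerance = 0.02)
})

test_that("relative SASA normalizes by Ala-X-Ala references", {
  refs <- ala_x_ala_reference(c("ALA", "GLY"))
  expect_true(all(refs > 0))

  # the central residue of the reference tripeptide itself scores 1.0
  tri <- build_peptide("AAA", with_h = FALSE)
  prof <- relative_sasa(sasa(tri), reference = refs)
  expect_equal(prof$relative[prof$resno == 2], 1.0, tolerance = 1e-9)

  # zero absolute area gives zero relative
  prof0 <- sasa(tri)
  prof0$sasa[2] <- 0
  expect_equal(relative_sasa(prof0, refs)$relative[2], 0)

  # missing reference entry errors with the residue type
  profx <- sasa(build_peptide("ASA", with_h = FALSE))
  expect_error(relative_sasa(profx, refs), "SER")
})

test_that("OLS recovers planted coefficients and reports Pearson R", {
  set.seed(77)
  n <- 60
  rsasa <- runif(n, 0, 1)
  bf <- runif(n, 5, 80)
  y <- 0.009 * rsasa + 0.012 * bf + 0.5
  fit <- fit_rmsf_model(y, bf, rsasa)
  expect_equal(fit$a, 0.009, tolerance = 1e-10)
  expect_equal(fit$b, 0.012, tolerance = 1e-10)
  expect_equal(fit$c, 0.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  # residual orthogonality to predictors and constant (machine precision)
  resid <- y + rnorm(n, sd = 0.05) # noisy copy
  fit2 <- fit_rmsf_model(resid, bf, rsasa)
  r2 <- resid - fit2$fitted
  expect_lt(abs(sum(r2)), 1e-9)
  expect_lt(abs(sum(r2 * rsasa)), 1e-9)
  expect_lt(abs(sum(r2 * bf)), 1e-9)

  # constant observations: R undefined with warning
  expect_warning(fc <- fit_rmsf_model(rep(1, n), bf, rsasa), "zero variance")
  expect_true(is.na(fc$r))

  # collinear predictors are rejected with the condition number
  expect_error(fit_rmsf_model(y, 2 * rsasa + 1, rsasa), "condition number")

  expect_error(fit_rmsf_model(y[1:3], bf[1:3], rsasa[1:3]), "at least 4")
})

test_that("noisy replicates recover coefficients within 3 SE", {
  n <- 200
  hits <- 0L
  n_rep <- 120
  for (k in seq_len(n_rep)) {
    set.seed(1000 + k)
    rsasa <- runif(n, 0, 1)
    bf <- runif(n, 5, 80)
    y <- 0.009 * rsasa + 0.012 * bf + 0.5 + rnorm(n, sd = 0.05)
    fit <- fit_rmsf_model(y, bf, rsasa)
    se <- summary(fit$fit)$coefficients[, "Std. Error"]
    ok <- abs(fit$c - 0.5) <= 3 * se["(Intercept)"] &&
      abs(fit$a - 0.009) <= 3 * se["relative_sasa"] &&
      abs(fit$b - 0.012) <= 3 * se["bfactors"]
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("pearson_r behaves on exact and independent inputs", {
  x <- rnorm(100)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(5)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(pearson_r(a, b)), 0.03)
  expect_warning(r0 <- pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0))
})
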