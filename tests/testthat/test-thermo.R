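# Enthalpy-based BDE assembly, Boltzmann averaging, connectivity and
# statistical QC screens.

test_that("BDE assembly is the radical-sum minus parent enthalpy", {
  expect_identical(bde_from_enthalpies(0, 0, 0), 0)
  expect_equal(bde_from_enthalpies(20, 52.1, 52.1), 84.2)
  expect_identical(bde_from_enthalpies(10, 30, 50),
                   bde_from_enthalpies(10, 50, 30))  # fragment order
  # linear in each argument
  expect_equal(bde_from_enthalpies(10, 30 + 5, 50),
               bde_from_enthalpies(10, 30, 50) + 5)
})

test_that("Boltzmann averaging matches the closed form and its limits", {
  # two levels at 0 and RT: <H> = RT * e^-1 / (1 + e^-1)
  RT <- bdegnn::R_KCAL * 298.15
  got <- boltzmann_enthalpy(c(0, RT), T_K = 298.15)
  expect_equal(got$h_mean, RT * exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(got$first_conformer_gap, got$h_mean)
  # single conformer: gap is zero
  expect_identical(boltzmann_enthalpy(5)$first_conformer_gap, 0)
  # equal enthalpies: average equals the common value
  expect_equal(boltzmann_enthalpy(rep(3.2, 7))$h_mean, 3.2)
  # bounded between min and max; T limits
  h <- c(1.3, 0.2, 2.7, 0.9)
  bm <- boltzmann_enthalpy(h)$h_mean
  expect_true(bm >= min(h) && bm <= max(h))
  expect_equal(boltzmann_enthalpy(h, T_K = 1e-9)$h_mean, min(h))
  expect_equal(boltzmann_enthalpy(h, T_K = 1e12)$h_mean, mean(h),
               tolerance = 1e-6)
  expect_error(boltzmann_enthalpy(numeric(0)), "empty")
})

test_that("connectivity check applies the covalent-radius rule", {
  # H2 at 0.74 A: threshold 0.31 + 0.31 + 0.4 = 1.02
  ok <- check_connectivity(c("H", "H"),
                           rbind(c(0, 0, 0), c(0.74, 0, 0)),
                           cbind(1L, 2L))
  expect_true(ok$ok)
  expect_equal(ok$report$threshold, 1.02)
  bad <- check_connectivity(c("H", "H"),
                            rbind(c(0, 0, 0), c(1.5, 0, 0)),
                            cbind(1L, 2L))
  expect_false(bad$ok)
  # no expected bonds: trivially intact
  expect_true(check_connectivity("C", rbind(c(0, 0, 0)),
                                 matrix(integer(0), 0, 2))$ok)
  expect_error(check_connectivity(c("Si", "H"),
                                  rbind(c(0, 0, 0), c(1, 0, 0)),
                                  cbind(1L, 2L)), "Si")
})

test_that("XYZ reader round-trips a geometry", {
  path <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water-like", "O 0.0 0.0 0.0",
               "H 0.96 0.0 0.0", "H -0.24 0.93 0.0"), path)
  g <- read_xyz(path)
  expect_identical(g$symbols, c("O", "H", "H"))
  expect_equal(g$coords[2, 1], 0.96)
  cc <- check_connectivity(g$symbols, g$coords, rbind(c(1L, 2L), c(1L, 3L)))
  expect_true(cc$ok)
})

test_that("composition outlier screen flags exactly the planted outlier", {
  set.seed(31)
  n <- 200
  comp <- data.frame(nC = sample(1:6, n, TRUE), nH = sample(1:12, n, TRUE),
                     nN = sample(0:2, n, TRUE), nO = sample(0:2, n, TRUE))
  # enthalpies exactly linear in composition plus small jitter
  h <- -5 + 3 * comp$nC - 1.5 * comp$nH + 7 * comp$nN + 2 * comp$nO +
    rnorm(n, 0, 0.05)
  rec <- cbind(data.frame(smiles = paste0("m", 1:n), h_kcal_mol = h), comp)
  clean <- formula_outlier_screen(rec)
  expect_false(any(clean$flagged))
  # perturb one record by 10x the IQR of the clean residuals
  iqr <- stats::IQR(clean$residual)
  rec$h_kcal_mol[17] <- rec$h_kcal_mol[17] + 10 * max(iqr, 0.05)
  scr <- formula_outlier_screen(rec)
  expect_identical(which(scr$flagged), 17L)
  # determinism and order invariance of the flag set
  scr2 <- formula_outlier_screen(rec[sample(n), ])
  expect_setequal(scr2$smiles[scr2$flagged], "m17")
  expect_error(formula_outlier_screen(rec[1:4, ]), "at least 5")
  same <- rec[1:8, ]; same[, c("nC", "nH", "nN", "nO")] <- 1L
  expect_error(formula_outlier_screen(same), "degenerate")
})

test_that("composition counts are derived from SMILES when absent", {
  rec <- data.frame(smiles = c("C", "CC", "CCC", "CCO", "CN", "CO"),
                    h_kcal_mol = c(1, 2, 3, 2.5, 1.8, 1.6))
  scr <- formula_outlier_screen(rec)
  expect_identical(scr$nC, c(1L, 2L, 3L, 2L, 1L, 1L))
  expect_identical(scr$nO, c(0L, 0L, 0L, 1L, 0L, 1L))
})

test_that("qc filter requires all four convergence flags", {
  all4 <- c("ok_termination", "no_imaginary_freq", "connectivity_ok",
            "stable_wavefunction")
  expect_true(qc_filter(all4)$pass)
  r <- qc_filter(setdiff(all4, "no_imaginary_freq"))
  expect_false(r$pass)
  expect_identical(r$reasons, "imaginary frequency")
  r2 <- qc_filter(setdiff(all4, "connectivity_ok"))
  expect_identical(r2$reasons, "decomposed")
  expect_false(qc_filter(character(0))$pass)
})
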