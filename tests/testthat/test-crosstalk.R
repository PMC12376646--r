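test_that("MID similarity is the normalized Manhattan score over labeled channels", {
  sp <- lookup_species("FFA(16:0)")
  m <- rand_mid(sp)
  expect_equal(mid_similarity(m, m), 1)

  a <- ffa_mid(sp, c(0.5, 0.5, rep(0, 15)))
  b <- ffa_mid(sp, c(0.5, 0, 0.5, rep(0, 14)))
  expect_equal(mid_similarity(a, b), 0.5) # labeled fractions differ by 1 total

  # tissue M1 0.2 vs serum 0.4, tissue M2 0.1 vs serum 0
  t1 <- ffa_mid(sp, c(0.7, 0.2, 0.1, rep(0, 14)))
  s1 <- ffa_mid(sp, c(0.6, 0.4, 0, rep(0, 14)))
  expect_equal(mid_similarity(t1, s1), 1 / 1.3)

  expect_error(mid_similarity(m, rand_mid(lookup_species("FFA(18:0)"))),
               "species")
})

test_that("MID similarity is symmetric and bounded in (0, 1]", {
  set.seed(61)
  sp <- lookup_species("FFA(18:1)")
  for (k in 1:50) {
    a <- rand_mid(sp)
    b <- rand_mid(sp)
    s <- mid_similarity(a, b)
    expect_equal(s, mid_similarity(b, a))
    expect_gt(s, 0)
    expect_lte(s, 1)
  }
})

test_that("donor screen combines labeling-extent and similarity criteria", {
  sp <- lookup_species("FFA(16:0)")
  serum <- lapply(1:4, function(i) ffa_mid(sp, c(0.7, 0.1, 0.2, rep(0, 14))))
  # equilibrium: same LE and near-identical MID
  donor <- lapply(1:4, function(i) ffa_mid(sp, c(0.7, 0.11, 0.19, rep(0, 14))))
  res <- donor_screen(donor, serum, tissue = "liver")
  expect_equal(res$verdict, "donor-consistent")
  # much lower labeling extent: fails criterion 1
  weak <- lapply(1:4, function(i) ffa_mid(sp, c(0.97, 0.01, 0.02, rep(0, 14))))
  expect_equal(donor_screen(weak, serum)$verdict, "not-donor-consistent")
  # dissimilar MID at equal LE: fails criterion 2
  shifted <- lapply(1:4, function(i) ffa_mid(sp, c(0.7, rep(0, 13), 0.1, 0.2, 0)))
  expect_equal(donor_screen(shifted, serum)$verdict, "not-donor-consistent")
  expect_error(donor_screen(donor[1], serum), "replicates")
})

test_that("palmitate deconvolution recovers the composition on noiseless data", {
  sp <- lookup_species("FFA(16:0)")
  x_true <- acetyl_labeling(0.6, 0.1, 0.3)
  Dn <- denovo_mid(x_true, 8)[-1]
  Dn <- Dn / sum(Dn)
  U <- denovo_mid(acetyl_labeling(0.8, 0.02, 0.18), 8)[-1]
  U <- U / sum(U)
  serum <- ffa_mid(sp, c(1 - 0.3, 0.3 * U))
  for (truth in list(c(0.4, 0.6), c(1, 0))) {
    lab <- 0.35 * (truth[1] * Dn + truth[2] * U)
    obs <- ffa_mid(sp, c(1 - sum(lab), lab))
    fit <- deconvolve_16_0(obs, serum)
    expect_true(fit$converged)
    expect_lt(abs(fit$composition["synthesis"] - truth[1]), 1e-3)
    expect_lt(abs(fit$composition["uptake"] - truth[2]), 1e-3)
  }
})

test_that("deconvolution flags degenerate inputs", {
  sp <- lookup_species("FFA(16:0)")
  x <- acetyl_labeling(0.7, 0.05, 0.25)
  D <- denovo_mid(x, 8)
  Dn <- D[-1] / sum(D[-1])
  # serum pattern identical to the synthesis pattern: non-identifiable
  serum_same <- ffa_mid(sp, c(1 - 0.3, 0.3 * Dn))
  lab <- 0.3 * Dn
  obs <- ffa_mid(sp, c(1 - sum(lab), lab))
  fit <- deconvolve_16_0(obs, serum_same)
  expect_true(fit$non_identifiable)
  # unlabeled tissue: flagged, no fit
  m0 <- ffa_mid(sp, c(1, rep(0, 16)))
  fit0 <- deconvolve_16_0(m0, serum_same)
  expect_true(is.na(fit0$alpha))
  expect_match(fit0$reason, "unlabeled")
})

test_that("stearate deconvolution recovers composition from the palmitate fit", {
  sp18 <- lookup_species("FFA(18:0)")
  x16 <- acetyl_labeling(0.6, 0.1, 0.3)
  d16 <- denovo_mid(x16, 8)
  E <- elongate_mid(d16, x16)
  En <- E[-1] / sum(E[-1])
  U <- elongate_mid(denovo_mid(acetyl_labeling(0.85, 0.02, 0.13), 8),
                    acetyl_labeling(0.85, 0.02, 0.13))
  U <- U[-1] / sum(U[-1])
  serum18 <- ffa_mid(sp18, c(1 - 0.2, 0.2 * U))
  for (truth in list(c(0.7, 0.3), c(0, 1))) {
    lab <- 0.25 * (truth[1] * En + truth[2] * U)
    obs <- ffa_mid(sp18, c(1 - sum(lab), lab))
    fit <- deconvolve_18_0(obs, serum18, x16, d16)
    expect_lt(abs(fit$composition["uptake"] - truth[2]), 1e-3)
  }
  # fully unlabeled model: flagged
  unlabeled <- ffa_mid(sp18, c(1, rep(0, 18)))
  fit_u <- deconvolve_18_0(unlabeled, unlabeled, acetyl_labeling(1, 0, 0),
                           c(1, rep(0, 16)))
  expect_true(is.na(fit_u$alpha))
})

test_that("deconvolution forward model conserves labeled mass", {
  set.seed(62)
  for (k in 1:20) {
    x <- rand_acetyl()
    alpha <- stats::runif(1)
    beta <- stats::runif(1, 0, 1 - 0)
    Dn <- denovo_mid(x, 8)[-1]
    Dn <- Dn / sum(Dn)
    U <- rand_simplex(16)
    expect_equal(sum(alpha * Dn + beta * U), alpha + beta, tolerance = 1e-12)
  }
})

test_that("permutation test is calibrated on edge cases and reproducible", {
  sp <- lookup_species("FFA(16:0)")
  same <- lapply(1:4, function(i) ffa_mid(sp, c(0.7, 0.1, 0.2, rep(0, 14))))
  expect_equal(permutation_test_mid(same, same, n_perm = 99, seed = 1)$p_value, 1)

  set.seed(63)
  a <- lapply(1:6, function(i) {
    l <- 0.30 + stats::runif(1, -0.01, 0.01)
    ffa_mid(sp, c(1 - l, l, rep(0, 15)))
  })
  b <- lapply(1:6, function(i) {
    l <- 0.05 + stats::runif(1, -0.01, 0.01)
    ffa_mid(sp, c(1 - l, rep(0, 15), l))
  })
  res <- permutation_test_mid(a, b, n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 1000)
  # bit-for-bit reproducibility under a fixed seed
  res2 <- permutation_test_mid(a, b, n_perm = 999, seed = 2)
  expect_identical(res, res2)
  expect_error(permutation_test_mid(a, b, n_perm = 0), "n_perm")
})

test_that("labeled-fraction matrix rows are tissue compositions summing to 1", {
  tbl <- tibble::tibble(
    tissue = c("liver", "liver", "liver", "liver", "cortex", "cortex"),
    species = c("FFA(16:0)", "FFA(16:0)", "FFA(16:1)", "FFA(16:1)",
                "FFA(16:0)", "FFA(16:1)"),
    labeled_intensity = c(250, 350, 90, 110, 50, 0))
  m <- labeled_fraction_matrix(tbl)
  expect_equal(m["liver", "FFA(16:0)"], 0.75)
  expect_equal(m["liver", "FFA(16:1)"], 0.25)
  expect_equal(unname(m["cortex", ]), c(1, 0)) # single labeled species
  expect_equal(unname(rowSums(m)), c(1, 1))
  # zero-intensity tissue flagged as missing
  tbl0 <- dplyr::bind_rows(tbl, tibble::tibble(
    tissue = "muscle", species = "FFA(16:0)", labeled_intensity = 0))
  m0 <- labeled_fraction_matrix(tbl0)
  expect_true(all(is.na(m0["muscle", ])))
})
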