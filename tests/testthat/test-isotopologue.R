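test_that("normalize_mid divides by total intensity and rejects empty vectors", {
  sp <- lookup_species("FFA(16:0)")
  v <- iso_vector(sp, c(700, 0, 300, rep(0, 14)))
  m <- normalize_mid(v)
  expect_equal(m$fractions[1], 0.7)
  expect_equal(m$fractions[3], 0.3)
  expect_equal(sum(m$fractions), 1)

  one <- iso_vector(sp, c(1, rep(0, 16)))
  expect_equal(normalize_mid(one)$fractions[1], 1)

  zero <- iso_vector(sp, rep(0, 17))
  expect_error(normalize_mid(zero), "missing measurement")
})

test_that("normalized MIDs sum to 1 for random intensity vectors", {
  set.seed(41)
  sp <- lookup_species("FFA(18:0)")
  for (k in 1:50) {
    v <- iso_vector(sp, stats::rgamma(19, shape = 0.5) * 1e5)
    expect_lt(abs(sum(normalize_mid(v)$fractions) - 1), 1e-9)
  }
})

test_that("natural-abundance correction recovers a pure unlabeled pattern", {
  sp <- lookup_species("FFA(16:0)")
  p13 <- 0.0107
  raw <- convolve_natural_abundance(
    iso_vector(sp, c(1e6, rep(0, 16)), corrected = TRUE), p13)
  # sanity on the forward pattern itself: M1/M0 = C p/(1-p)
  expect_equal(raw$intensities[2] / raw$intensities[1],
               16 * p13 / (1 - p13), tolerance = 1e-12)
  corr <- correct_natural_abundance(raw, p13)
  expect_equal(corr$intensities[1], 1e6, tolerance = 1e-9)
  expect_lt(max(abs(corr$intensities[-1])), 1e-6)
})

test_that("convolve-then-correct round trip recovers random labeled MIDs", {
  set.seed(42)
  for (spn in c("FFA(14:0)", "FFA(16:0)", "FFA(20:4)", "FFA(24:1)")) {
    sp <- lookup_species(spn)
    for (k in 1:10) {
      fr <- rand_simplex(sp$carbons + 1L)
      raw <- convolve_natural_abundance(
        iso_vector(sp, 1e6 * fr, corrected = TRUE))
      rec <- correct_natural_abundance(raw)
      expect_lt(max(abs(rec$intensities / sum(rec$intensities) - fr)), 1e-6)
    }
  }
})

test_that("correction with p13 = 0 is the identity and re-correction refused", {
  sp <- lookup_species("FFA(16:0)")
  v <- iso_vector(sp, c(500, 200, rep(10, 15)))
  out <- correct_natural_abundance(v, p13 = 0)
  expect_equal(out$intensities, v$intensities)
  expect_true(out$corrected)
  expect_error(correct_natural_abundance(out), "already")
})

test_that("labeled intensity weights isotopologues by labeled-carbon count", {
  sp <- lookup_species("FFA(16:0)")
  v <- iso_vector(sp, c(rep(0, 2), 500, rep(0, 14)), corrected = TRUE)
  expect_equal(labeled_intensity(v), 1000)
  m0 <- iso_vector(sp, c(123, rep(0, 16)), corrected = TRUE)
  expect_equal(labeled_intensity(m0), 0)

  set.seed(7)
  ints <- stats::runif(17) * 1e4
  vr <- iso_vector(sp, ints, corrected = TRUE)
  expect_equal(labeled_intensity(vr), sum((0:16) * ints))

  expect_error(labeled_intensity(iso_vector(sp, ints, corrected = FALSE)),
               "corrected")
})

test_that("labeling extent and enrichment follow their closed forms", {
  sp <- lookup_species("FFA(16:0)")
  m <- ffa_mid(sp, c(0.7, rep(0.3 / 16, 16)))
  expect_equal(labeling_extent(m), 0.3)
  expect_equal(labeling_extent(ffa_mid(sp, c(1, rep(0, 16)))), 0)

  m5050 <- ffa_mid(sp, c(0.5, rep(0, 15), 0.5))
  expect_equal(c13_enrichment(m5050), 0.5)
  m2 <- ffa_mid(sp, c(0.5, 0, 0.5, rep(0, 14)))
  expect_equal(c13_enrichment(m2), 0.0625)
})

test_that("enrichment never exceeds labeling extent, and the intensity identity holds", {
  set.seed(43)
  sp <- lookup_species("FFA(18:1)")
  for (k in 1:100) {
    m <- rand_mid(sp)
    expect_lte(c13_enrichment(m), labeling_extent(m) + 1e-12)
  }
  # labeled_intensity = total * C * enrichment(normalized)
  for (k in 1:20) {
    ints <- stats::rgamma(19, 0.7) * 1e5
    v <- iso_vector(sp, ints, corrected = TRUE)
    lhs <- labeled_intensity(v)
    rhs <- sum(ints) * sp$carbons * c13_enrichment(normalize_mid(v))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("labeling detection applies strict thresholds across samples", {
  sp <- lookup_species("FFA(16:0)")
  mk <- function(l2) ffa_mid(sp, c(1 - l2, 0, l2, rep(0, 14)))
  # 0.006 in 4 of 6 samples: qualifies
  mids <- c(lapply(1:4, function(i) mk(0.006)), lapply(1:2, function(i) mk(0)))
  expect_true(is_labeled_ffa(mids))
  # all fractions at 0.004: below the floor
  expect_false(is_labeled_ffa(lapply(1:6, function(i) mk(0.004))))
  # exactly at 0.005 everywhere: strict inequality fails
  expect_false(is_labeled_ffa(lapply(1:6, function(i) mk(0.005))))
  # exactly 50% of samples qualifying is not "more than 50%"
  half <- c(lapply(1:3, function(i) mk(0.01)), lapply(1:3, function(i) mk(0)))
  expect_false(is_labeled_ffa(half))
  expect_error(is_labeled_ffa(list()), "at least one")
})

test_that("adding a strongly labeled sample never flips detection off", {
  set.seed(44)
  sp <- lookup_species("FFA(16:0)")
  for (k in 1:20) {
    mids <- lapply(1:5, function(i) rand_mid(sp))
    before <- is_labeled_ffa(mids)
    # an unambiguous qualifier: every labeled channel above the floor
    strong <- ffa_mid(sp, c(0.2, rep(0.8 / 16, 16)))
    after <- is_labeled_ffa(c(mids, list(strong)))
    if (before) expect_true(after)
  }
})
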