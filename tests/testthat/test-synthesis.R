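test_that("de novo MID matches hand values at simplex corners", {
  expect_equal(denovo_mid(acetyl_labeling(1, 0, 0), 8),
               c(1, rep(0, 16)))
  expect_equal(denovo_mid(acetyl_labeling(0, 0, 1), 8),
               c(rep(0, 16), 1))
  d <- denovo_mid(acetyl_labeling(0.5, 0, 0.5), 8)
  expect_equal(d[3], 8 * 0.5^8) # one fully labeled unit among eight
  expect_error(denovo_mid(acetyl_labeling(0.5, 0, 0.5), 0), "n_units")
})

test_that("de novo MID equals exhaustive enumeration over unit assignments", {
  set.seed(51)
  for (k in 1:25) {
    x <- rand_simplex(3)
    n <- sample(2:6, 1)
    expect_lt(max(abs(denovo_mid(acetyl_labeling(x[1], x[2], x[3]), n) -
                        enumerate_denovo(x[1], x[2], x[3], n))), 1e-12)
  }
})

test_that("de novo and route MIDs are valid distributions for random simplexes", {
  set.seed(52)
  rt <- default_route_table()
  for (k in 1:30) {
    a <- rand_acetyl()
    d <- denovo_mid(a, sample(1:12, 1))
    expect_true(all(d >= 0))
    expect_lt(abs(sum(d) - 1), 1e-12)
  }
  for (spn in rt$species) {
    m <- route_mid(spn, rand_acetyl())
    expect_s3_class(m, "ffa_mid")
    expect_lt(abs(sum(m$fractions) - 1), 1e-9)
  }
})

test_that("elongation is convolution with the acetyl unit", {
  set.seed(53)
  pre <- rand_simplex(17)
  a <- rand_acetyl()
  e <- elongate_mid(pre, a)
  # independent direct-summation oracle
  oracle <- vapply(0:(length(pre) + 1), function(i) {
    get0 <- function(j) if (j >= 0 && j < length(pre)) pre[j + 1] else 0
    get0(i) * a$x0 + get0(i - 1) * a$x1 + get0(i - 2) * a$x2
  }, numeric(1))
  expect_lt(max(abs(e - oracle)), 1e-12)

  expect_equal(elongate_mid(pre, acetyl_labeling(1, 0, 0))[1:17], pre)
  expect_equal(elongate_mid(pre, acetyl_labeling(0, 0, 1))[3:19], pre)
})

test_that("one elongation of an 8-unit chain equals 9-unit de novo assembly", {
  set.seed(54)
  for (k in 1:10) {
    a <- rand_acetyl()
    expect_lt(max(abs(elongate_mid(denovo_mid(a, 8), a) - denovo_mid(a, 9))),
              1e-12)
  }
})

test_that("route MIDs respect desaturation, elongation and essential precursors", {
  a <- rand_acetyl()
  # desaturation preserves the precursor mass pattern
  expect_equal(route_mid("FFA(16:1)", a)$fractions,
               route_mid("FFA(16:0)", a)$fractions)
  # 8 de novo units + 1 elongation, all fully labeled
  m18 <- route_mid("FFA(18:0)", acetyl_labeling(0, 0, 1))
  expect_equal(m18$fractions[19], 1)
  # essential elongation: unlabeled C18 precursor + 1 labeled unit
  m204 <- route_mid("FFA(20:4)", acetyl_labeling(0, 0, 1))
  expect_equal(which(m204$fractions > 0) - 1, 2)
  m204b <- route_mid("FFA(20:4)", acetyl_labeling(0.5, 0, 0.5))
  expect_equal(which(m204b$fractions > 0) - 1, c(0, 2))
})

test_that("synthesis fraction is recovered exactly on noiseless forward models", {
  sp <- lookup_species("FFA(16:0)")
  x <- acetyl_labeling(0.5, 0.1, 0.4)
  e0 <- c(1, rep(0, 16))
  for (g in c(0.1, 0.3, 0.7)) {
    obs <- ffa_mid(sp, (1 - g) * e0 + g * route_mid(sp, x)$fractions)
    fit <- fit_synthesis_fraction(obs)
    expect_true(fit$converged)
    expect_lt(abs(fit$g - g), 1e-3)
  }
  # elongation-route species recover too
  sp18 <- lookup_species("FFA(18:0)")
  obs18 <- ffa_mid(sp18, 0.75 * c(1, rep(0, 18)) +
                     0.25 * route_mid(sp18, x)$fractions)
  fit18 <- fit_synthesis_fraction(obs18)
  expect_lt(abs(fit18$g - 0.25), 1e-3)
})

test_that("degenerate observed MIDs pin g to the boundary", {
  sp <- lookup_species("FFA(16:0)")
  pure_m0 <- ffa_mid(sp, c(1, rep(0, 16)))
  fit0 <- fit_synthesis_fraction(pure_m0)
  expect_equal(fit0$g, 0)
  expect_true(fit0$pinned)

  x <- acetyl_labeling(0.6, 0.05, 0.35)
  fit1 <- fit_synthesis_fraction(route_mid("FFA(16:0)", x))
  expect_lt(abs(fit1$g - 1), 1e-3)
})

test_that("pool-size factors are a min-max rescale with monotone ordering", {
  f <- pool_size_factors(c(liver = 10, lung = 55, BAT = 100), "FFA(16:0)")
  expect_equal(f$factor, c(0, 0.5, 1))
  expect_warning(pool_size_factors(c(a = 5, b = 5)), "equal")
  expect_error(pool_size_factors(c(a = -1, b = 2)), "non-negative")
  set.seed(55)
  totals <- stats::setNames(stats::runif(8) * 1e6, paste0("t", 1:8))
  f <- pool_size_factors(totals)
  expect_equal(order(f$factor), order(totals[f$tissue]))
  expect_equal(range(f$factor), c(0, 1))
})

test_that("pseudo rate is the product of g and the pool-size factor", {
  sp <- lookup_species("FFA(16:0)")
  x <- acetyl_labeling(0.6, 0.05, 0.35)
  obs <- ffa_mid(sp, 0.6 * c(1, rep(0, 16)) + 0.4 * route_mid(sp, x)$fractions)
  fit <- fit_synthesis_fraction(obs)
  expect_equal(pseudo_rate(fit, 0.5), fit$g * 0.5)
  expect_equal(pseudo_rate(fit, 0), 0)
  psf <- pool_size_factors(c(liver = 1, lung = 3), "FFA(18:0)")
  expect_error(pseudo_rate(fit, psf[1, ]), "FFA\\(18:0\\)")
  # monotone in both arguments
  expect_lte(pseudo_rate(fit, 0.3), pseudo_rate(fit, 0.6))
})
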