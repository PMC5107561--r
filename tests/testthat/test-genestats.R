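test_that("the F2 marker counts reproduce the published segregation test", {
  res <- chi_square_ratio(c(95, 201, 114), c(1, 2, 1))
  expect_equal(res$statistic, 1.917, tolerance = 0.001 / 1.917)
  expect_equal(res$df, 2L)
  expect_gt(res$p_value, 0.05)
})

test_that("chi-square ratio test handles exact fits and hand-computed cases", {
  exact <- chi_square_ratio(c(25, 50, 25), c(1, 2, 1))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)

  hand <- chi_square_ratio(c(10, 0), c(1, 1))
  expect_equal(hand$statistic, 10)      # (10-5)^2/5 + (0-5)^2/5
  expect_equal(hand$df, 1L)

  # invariant under rescaling of the ratio weights
  a <- chi_square_ratio(c(95, 201, 114), c(1, 2, 1))
  b <- chi_square_ratio(c(95, 201, 114), c(17, 34, 17))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  expect_error(chi_square_ratio(c(1, 2), c(1, 1, 1)), "equal length")
})

test_that("chi-square tail matches a numerical-integration oracle to 1e-6", {
  for (df in 1:3)
    for (x in c(0.1, 0.5, 1, 1.917, 5, 10, 25, 50)) {
      p <- stats::pchisq(x, df, lower.tail = FALSE)
      expect_lt(abs(p - chisq_tail_integral(x, df)), 1e-6)
    }
  # and through the public interface at the published statistic
  res <- chi_square_ratio(c(95, 201, 114), c(1, 2, 1))
  expect_lt(abs(res$p_value - chisq_tail_integral(res$statistic, 2)), 1e-6)
})

test_that("genotype predicts the published fraction of phenotypes", {
  pheno <- data.frame(
    genotype = c("hom_recessive", "het", "hom_dominant"),
    n_resistant = c(26, 0, 0),
    n_bolting = c(69, 201, 114))
  acc <- prediction_accuracy(pheno)
  expect_equal(acc, 341 / 410)
  expect_equal(round(100 * acc), 83)

  # fully penetrant table predicts perfectly
  perfect <- data.frame(genotype = c("hom_recessive", "het", "hom_dominant"),
                        n_resistant = c(95, 0, 0),
                        n_bolting = c(0, 201, 114))
  expect_equal(prediction_accuracy(perfect), 1)

  # consistency check against class totals
  expect_error(
    prediction_accuracy(pheno, counts = c(hom_recessive = 90, het = 201,
                                          hom_dominant = 114)),
    "inconsistent")
})

test_that("accuracy is maximal at full penetrance for fixed margins", {
  # exhaustive enumeration over small tables with fixed class totals
  totals <- c(hom_recessive = 6L, het = 4L, hom_dominant = 5L)
  best <- prediction_accuracy(data.frame(
    genotype = names(totals), n_resistant = c(6, 0, 0), n_bolting = c(0, 4, 5)))
  for (r_hom in 0:6) for (r_het in 0:4) for (r_dom in 0:5) {
    acc <- prediction_accuracy(data.frame(
      genotype = names(totals),
      n_resistant = c(r_hom, r_het, r_dom),
      n_bolting = totals - c(r_hom, r_het, r_dom)))
    expect_lte(acc, best)
  }
})

test_that("penetrance estimate and its exact CI match the published fractions", {
  pe <- penetrance_estimate(26, 95)
  expect_equal(pe$estimate, 26 / 95)
  expect_equal(round(100 * (1 - pe$estimate), 1), 72.6)

  # Clopper-Pearson bounds vs direct binomial-tail root finding
  cp <- clopper_pearson_bruteforce(26, 95)
  expect_lt(abs(pe$ci_low - cp[1]), 1e-6)
  expect_lt(abs(pe$ci_high - cp[2]), 1e-6)

  zero <- penetrance_estimate(0, 50)
  expect_equal(zero$estimate, 0)
  expect_equal(zero$ci_low, 0)
  expect_error(penetrance_estimate(10, 5), "n_resistant")
})

test_that("penetrance CI covers the truth at the nominal level", {
  set.seed(401)
  p <- 26 / 95
  covered <- replicate(500, {
    x <- rbinom(1, 95, p)
    ci <- penetrance_estimate(x, 95)
    ci$ci_low <= p && p <= ci$ci_high
  })
  # exact intervals are conservative; Monte-Carlo SE ~ 0.01
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("family bolting-rate summaries use unweighted means and n-1 sd", {
  fam <- data.frame(family_id = c("a", "b", "c"),
                    parent_genotype = "hom_recessive",
                    n_bolting = c(0L, 5L, 10L), n_total = 10L)
  expect_warning(out <- family_rates(fam), "omitted")
  expect_equal(out$mean_rate, 0.5)
  expect_equal(out$sd_rate, 0.5)
  expect_equal(out$n_families, 3L)

  single <- data.frame(family_id = "a", parent_genotype = "het",
                       n_bolting = 5L, n_total = 10L)
  expect_warning(s <- family_rates(single))
  expect_equal(s$mean_rate, 0.5)
  expect_true(is.na(s$sd_rate))
})

test_that("simulated F3 family rates order by parent genotype", {
  set.seed(402)
  ok <- replicate(20, {
    fam <- simulate_f3_families(
      rep(c("hom_recessive", "het", "hom_dominant"), each = 40),
      family_sizes = sample(6:31, 120, replace = TRUE))
    out <- suppressWarnings(family_rates(fam))
    m <- setNames(out$mean_rate, out$parent_genotype)
    m["hom_recessive"] < m["het"] && m["het"] <= m["hom_dominant"]
  })
  expect_gte(sum(ok), 19)
})

test_that("pairwise rate comparisons use Pearson 2x2 tests with adjustment", {
  same <- compare_rates(data.frame(group = c("a", "b"),
                                   n_bolting = c(10L, 10L),
                                   n_total = c(20L, 20L)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_adj, 1)

  extreme <- compare_rates(data.frame(group = c("a", "b"),
                                      n_bolting = c(20L, 0L),
                                      n_total = c(20L, 20L)))
  expect_equal(extreme$statistic, 40)   # hand-computed Pearson statistic

  three <- compare_rates(data.frame(group = c("a", "b", "c"),
                                    n_bolting = c(18L, 10L, 2L),
                                    n_total = c(20L, 20L, 20L)))
  expect_equal(nrow(three), 3L)
  expect_true(all(three$p_adj >= three$p_raw))

  holm <- compare_rates(data.frame(group = c("a", "b", "c"),
                                   n_bolting = c(18L, 10L, 2L),
                                   n_total = 20L), adjust = "holm")
  bonf <- compare_rates(data.frame(group = c("a", "b", "c"),
                                   n_bolting = c(18L, 10L, 2L),
                                   n_total = 20L), adjust = "bonferroni")
  expect_true(all(holm$p_adj <= bonf$p_adj + 1e-12))
})
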