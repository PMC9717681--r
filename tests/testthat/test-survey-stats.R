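test_that("taylor variance matches the hand-computed 2x2 design", {
  ds <- make_fixture("tiny_handcheck")
  p <- ds$persons
  z <- c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2, -0.3, 0.15)
  # PSU totals: (0.1-0.2), (0.3+0.05) | (-0.1+0.2), (-0.3+0.15)
  Z <- c(-0.1, 0.35, 0.1, -0.15)
  hand <- 2 * sum((Z[1:2] - mean(Z[1:2]))^2) +
    2 * sum((Z[3:4] - mean(Z[3:4]))^2)
  expect_equal(taylor_variance(z, p$vstratum, p$vpsu), hand)
})

test_that("equal PSU totals give zero variance", {
  strata <- rep(c("a", "b"), each = 4)
  psu <- c(1, 1, 2, 2, 3, 3, 4, 4)
  z <- rep(c(1, 2), 4)  # every PSU totals 3
  expect_equal(taylor_variance(z, strata, psu), 0)
})

test_that("one-PSU-per-person SRS reduces to the textbook estimator", {
  set.seed(8)
  z <- rnorm(40)
  v <- taylor_variance(z, strata = rep(1, 40), psu = 1:40)
  expect_equal(v, (40 / 39) * sum((z - mean(z))^2))
})

test_that("single-PSU strata error by name unless collapsed", {
  z <- c(1, 2, 3, 4)
  expect_error(taylor_variance(z, c("s1", "s1", "s2", "s3"),
                               c(1, 2, 3, 4)),
               "s2")
  v <- taylor_variance(z, c("s1", "s1", "s2", "s3"), c(1, 2, 3, 4),
                       collapse_single = TRUE)
  expect_gt(v, 0)
})

test_that("proportion estimate and SE match the tiny hand check", {
  ds <- make_fixture("tiny_handcheck")
  y <- as.numeric(bitwAnd(ds$persons$cond, 1L) == 1L)
  est <- estimate_proportion(y, ds)
  expect_equal(est$estimate, 0.8)
  # hand-linearized: z_i = w_i (y_i - .8)/20, PSU totals per stratum
  z <- ds$persons$weight * (y - 0.8) / 20
  Zhj <- tapply(z, ds$persons$vpsu, sum)
  v <- 2 * sum((Zhj[1:2] - mean(Zhj[1:2]))^2) +
    2 * sum((Zhj[3:4] - mean(Zhj[3:4]))^2)
  expect_equal(est$se, sqrt(v))
  expect_identical(est$df, 2L)
  # all-ones indicator is estimated without uncertainty
  est1 <- estimate_proportion(rep(1, 8), ds)
  expect_equal(est1$estimate, 1)
  expect_equal(est1$se, 0)
})

test_that("lift is one at the empirical independence point", {
  # construct 4 persons where p_AB = p_A * p_B exactly (both 1/2, joint 1/4)
  p <- make_fixture("tiny_handcheck")$persons[1:4, ]
  p$weight <- rep(1, 4)
  p$cond <- c(3L, 1L, 2L, 0L)  # AB, A, B, none
  ds <- survey_dataset(p, condition_catalog(), 1L)
  est <- estimate_lift(c(1L, 2L), ds)
  expect_equal(est$estimate, 1)
})

test_that("lift matches the hand-computed ratio on the tiny fixture", {
  ds <- make_fixture("tiny_handcheck")
  est <- estimate_lift(c(1L, 2L), ds)
  # p_AB = 14/20, p_A = 16/20, p_B = 16/20
  expect_equal(est$estimate, (14 / 20) / ((16 / 20) * (16 / 20)))
  expect_true(est$lo <= est$estimate && est$estimate <= est$hi)
  expect_error(estimate_lift(1L, ds), "size >= 2")
  # zero-prevalence condition: undefined lift
  expect_error(estimate_lift(c(1L, 20L), ds), "undefined")
})

test_that("domain mean matches hand computation and full-sample proportion", {
  ds <- make_fixture("tiny_handcheck")
  p <- ds$persons
  dom <- p$cond_count >= 2  # persons 3,4,7,8, weights 3,4,3,4
  est <- domain_mean(p$total_exp, dom, ds)
  expect_equal(est$estimate,
               sum(c(3, 4, 3, 4) * c(500, 4000, 2500, 9000)) / 14)
  # agreement with estimate_proportion when the domain is everyone
  y <- as.numeric(p$poor_health)
  a <- estimate_proportion(y, ds)
  b <- domain_mean(y, rep(TRUE, 8), ds)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$se, b$se)
  # constant value over the full domain has zero SE
  cst <- domain_mean(rep(5, 8), rep(TRUE, 8), ds)
  expect_equal(cst$estimate, 5)
  expect_equal(cst$se, 0)
  # empty domain yields a missing-estimate marker, not an error
  empty <- domain_mean(p$total_exp, rep(FALSE, 8), ds)
  expect_true(is.na(empty$estimate))
  expect_identical(attr(empty, "note"), "empty domain")
})

test_that("weighted quantiles use the lower no-interpolation rule", {
  expect_equal(weighted_quantile(1:5, rep(1, 5), 0.5), 3)
  expect_equal(weighted_quantile(c(0, 10), c(1, 9), 0.5), 10)
  expect_equal(weighted_quantile(c(0, 10), c(9, 1), 0.5), 0)
  # q25 <= q75 on random inputs
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(50); w <- runif(50)
    qs <- weighted_quantile(v, w, c(0.25, 0.75))
    expect_lte(qs[1], qs[2])
  }
  expect_error(weighted_quantile(1:3, rep(0, 3), 0.5), "positive-weight")
})

test_that("estimates are invariant to rescaling the weights", {
  ds <- rand_dataset(n = 200L, k = 4L, seed = 13L)
  ds2 <- ds
  ds2$persons$weight <- ds$persons$weight * 1000
  ds2$persons$analysis_weight <- ds$persons$analysis_weight * 1000
  y <- as.numeric(bitwAnd(ds$persons$cond, 1L) == 1L)
  a <- estimate_proportion(y, ds); b <- estimate_proportion(y, ds2)
  expect_equal(a$estimate, b$estimate); expect_equal(a$se, b$se)
  la <- estimate_lift(c(1L, 2L), ds); lb <- estimate_lift(c(1L, 2L), ds2)
  expect_equal(la$estimate, lb$estimate)
  expect_equal(c(la$lo, la$hi), c(lb$lo, lb$hi))
  ma <- domain_mean(ds$persons$total_exp, y, ds)
  mb <- domain_mean(ds2$persons$total_exp, y, ds2)
  expect_equal(ma$estimate, mb$estimate); expect_equal(ma$se, mb$se)
  qa <- weighted_quantile(ds$persons$total_exp, ds$persons$weight, 0.5)
  qb <- weighted_quantile(ds2$persons$total_exp, ds2$persons$weight, 0.5)
  expect_equal(qa, qb)
  # totals scale by the constant
  ta <- estimate_total(y, ds); tb <- estimate_total(y, ds2)
  expect_equal(tb$estimate, 1000 * ta$estimate)
  expect_equal(tb$se, 1000 * ta$se)
})

test_that("weighted total times prevalence identity holds exactly", {
  ds <- rand_dataset(n = 150L, k = 4L, seed = 17L)
  y <- as.numeric(bitwAnd(ds$persons$cond, 3L) == 3L)
  tot <- estimate_total(y, ds)
  prop <- estimate_proportion(y, ds)
  W <- sum(ds$persons$analysis_weight)
  expect_equal(tot$estimate, prop$estimate * W)
})
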