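# hand-constructed estimates frame: conditions 1,2,3 with a triad, its
# three dyads and the three singles; `stat` chosen per scenario
make_est <- function(triad_stat, dyad_stats = c(100, 110, 120),
                     single_stats = c(80, 85, 90)) {
  masks <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  data.frame(
    items = vapply(masks, mask_to_label, "", catalog = condition_catalog()),
    mask = masks,
    size = c(1L, 1L, 1L, 2L, 2L, 2L, 3L),
    weighted_N = c(50, 40, 30, 20, 15, 10, 5) * 1e6,
    prev_pct = c(25, 20, 15, 10, 7, 5, 2),
    mean_exp = c(single_stats, dyad_stats, triad_stat),
    poor_health_pct = c(single_stats, dyad_stats, triad_stat) / 10)
}

test_that("zero improvement over the best dyad drops the triad", {
  est <- make_est(triad_stat = 120)  # equals max dyad
  dec <- min_improvement_filter(est, "mean_exp", tau = 0.10)
  triad <- dec[dec$size == 3, ]
  expect_false(triad$retained)
  expect_equal(triad$improvement, 0)
  expect_identical(triad$best_parent,
                   mask_to_label(6L, condition_catalog()))
})

test_that("a 20% improvement over every parent is retained at tau 0.10", {
  est <- make_est(triad_stat = 1.2 * 120)
  dec <- min_improvement_filter(est, "mean_exp", tau = 0.10)
  expect_true(dec$retained[dec$size == 3])
  expect_equal(dec$improvement[dec$size == 3], 0.2)
  # but not at tau 0.25
  dec2 <- min_improvement_filter(est, "mean_exp", tau = 0.25)
  expect_false(dec2$retained[dec2$size == 3])
})

test_that("dyads are compared against their single conditions", {
  est <- make_est(triad_stat = 150)
  dec <- min_improvement_filter(est, "mean_exp", tau = 0.10)
  # dyad {1,2} stat 100 vs singles 80 and 85: 100/85 - 1 = 17.6% >= 10%
  d12 <- dec[dec$mask == 3L, ]
  expect_true(d12$retained)
  expect_equal(d12$improvement, 100 / 85 - 1)
  # raise tau so 17.6% no longer suffices
  dec2 <- min_improvement_filter(est, "mean_exp", tau = 0.20)
  expect_false(dec2$retained[dec2$mask == 3L])
})

test_that("the retained set is monotone non-increasing in tau", {
  set.seed(33)
  ds <- rand_dataset(n = 300L, k = 6L, seed = 33L)
  rec <- mine_frequent_itemsets(ds, 0.01, 0)
  est <- itemset_estimates(ds, rec[, setdiff(names(rec), "in_result")])
  prev <- NULL
  for (tau in c(0, 0.05, 0.10, 0.25, 0.5, 2, 1e6)) {
    dec <- min_improvement_filter(est, "mean_exp", tau)
    kept <- dec$mask[dec$retained]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # at enormous tau only itemsets without any measured parent remain
  expect_true(all(is.na(dec$improvement[dec$retained])))
})

test_that("filtering is idempotent and never alters estimates", {
  est <- make_est(triad_stat = 150)
  before <- est
  dec1 <- min_improvement_filter(est, "mean_exp", 0.10)
  dec2 <- min_improvement_filter(est, "mean_exp", 0.10)
  expect_identical(dec1, dec2)
  expect_identical(est, before)
})

test_that("a missing parent statistic is skipped with a warning", {
  est <- make_est(triad_stat = 150)
  est$mean_exp[est$mask == 6L] <- NA
  expect_warning(dec <- min_improvement_filter(est, "mean_exp", 0.10),
                 "parent")
  expect_true(dec$retained[dec$size == 3])  # 150 beats 100,110 by >10%
})

test_that("top-k union flags overlap correctly", {
  est <- make_est(triad_stat = 150)
  # identical rankings: cost and health stats are proportional
  dc <- min_improvement_filter(est, "mean_exp", 0)
  dh <- min_improvement_filter(est, "poor_health_pct", 0)
  u <- top_k_union(dc, dh, est, k = 2L)
  expect_true(all(u$both))
  expect_identical(nrow(u), 2L)
  # results sorted by prevalence, descending
  expect_true(all(diff(u$prev_pct) <= 0))

  # disjoint rankings: reverse the health statistic
  est2 <- est
  est2$poor_health_pct <- rev(est2$poor_health_pct)
  dh2 <- min_improvement_filter(est2, "poor_health_pct", 0)
  u2 <- suppressMessages(top_k_union(dc, dh2, est2, k = 2L))
  expect_true(!any(u2$both) || nrow(u2) < 4L)
})

test_that("sex-subgroup domain estimates match a physical subset run", {
  ds <- rand_dataset(n = 500L, k = 5L, seed = 55L)
  top <- sex_subgroup_pipeline(ds, "female", min_support = 0.02,
                               min_weighted = 0, top = 10L)
  sub <- ds
  sub$persons <- ds$persons[ds$persons$sex == "female", ]
  rec <- mine_frequent_itemsets(sub, 0.02, 0)
  est <- itemset_estimates(sub, rec[rec$in_result,
                                    setdiff(names(rec), "in_result")])
  est <- est[match(top$mask, est$mask), ]
  expect_equal(top$prev_pct, est$prev_pct)
  expect_equal(top$weighted_N, est$weighted_N)
  expect_equal(top$mean_exp, est$mean_exp)
  expect_equal(top$poor_health_pct, est$poor_health_pct)

  only_f <- ds
  only_f$persons <- ds$persons[ds$persons$sex == "female", ]
  expect_error(sex_subgroup_pipeline(only_f, "male"), "male")
})

test_that("condition exclusion clears bits and empties accordingly", {
  ds <- rand_dataset(n = 300L, k = 5L, seed = 77L)
  expect_identical(exclude_conditions_variant(ds, character(0)), ds)
  no_htn <- exclude_conditions_variant(ds, "hypertension")
  rec <- mine_frequent_itemsets(no_htn, 0.01, 0)
  expect_false(any(bitwAnd(rec$mask[rec$n > 0], 1L) == 1L &
                     rec$n[rec$n > 0] > 0))
  expect_true(all(bitwAnd(no_htn$persons$cond, 1L) == 0L))
  all20 <- exclude_conditions_variant(ds, default_conditions())
  expect_identical(sum(mine_frequent_itemsets(all20, 0, 0)$in_result), 0L)
  expect_error(exclude_conditions_variant(ds, "gout"), "unknown")
})
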