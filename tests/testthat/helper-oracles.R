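# shared fixtures and independent oracles for the test suite

# random small survey dataset: k active conditions, 3 strata x 2 PSUs,
# unequal weights; conditions drawn independently with random marginals
rand_dataset <- function(n = 300L, k = 6L, seed = 1L) {
  set.seed(seed)
  stratum <- sample(3L, n, replace = TRUE)
  psu <- stratum * 10L + sample(2L, n, replace = TRUE)
  probs <- runif(k, 0.05, 0.5)
  mask <- rep(0L, n)
  for (c in seq_len(k))
    mask <- bitwOr(mask, bitwShiftL(1L, c - 1L) *
                     as.integer(runif(n) < probs[c]))
  persons <- data.frame(
    person_id = seq_len(n), year = 2019L, stratum = stratum, psu = psu,
    weight = rlnorm(n, 8, 0.5), age = runif(n, 18, 85),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race5 = sample(race5_levels(), n, replace = TRUE),
    srh = sample(1:5, n, replace = TRUE),
    total_exp = rlnorm(n, 7, 1), oop_exp = rlnorm(n, 5, 1),
    cond = mask, stringsAsFactors = FALSE)
  survey_dataset(persons, condition_catalog(), 1L)
}

# exhaustive subset enumeration: every itemset observed in at least one
# person, with unweighted and weighted support; the independent oracle for
# the Apriori miner
brute_force_mine <- function(dataset, min_support = 0, min_weighted = 0) {
  p <- dataset$persons
  items <- which(vapply(1:20, function(c)
    any(bitwAnd(p$cond, bitwShiftL(1L, c - 1L)) != 0L), logical(1)))
  out <- list()
  for (size in seq_along(items)) {
    for (combo in utils::combn(items, size, simplify = FALSE)) {
      m <- itemset_mask(combo)
      inX <- bitwAnd(p$cond, m) == m
      nX <- sum(inX)
      if (nX < 1L || nX / nrow(p) < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        mask = m, size = size, n = nX,
        weighted_N = sum(p$analysis_weight[inX]))
    }
  }
  res <- do.call(rbind, out)
  res[res$size >= 2L & res$weighted_N >= min_weighted, , drop = FALSE]
}

# generator configuration with exactly two active conditions; with
# slopes = 0 and frailty_sd = 0 the conditions are truly independent
two_condition_config <- function(p1 = 0.3, p2 = 0.2, frailty_sd = 0,
                                 n_strata = 50L, persons_per_psu = 200L,
                                 truth_draws = 1e3) {
  generator_config(
    n_strata = n_strata, psus_per_stratum = 2L,
    persons_per_psu = persons_per_psu,
    target_population_total = 249221000, pooled_years = 4L,
    cond_base = c(qlogis(p1), qlogis(p2), rep(-30, 18)),
    cond_slope = rep(0, 20), frailty_sd = frailty_sd,
    truth_draws = truth_draws, truth_combos = list(c(1L, 2L)))
}
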