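#' Configuration for the synthetic survey generator
#'
#' Builds the parameter list for \code{\link{generate_population}}, which
#' emulates the structure of a national household expenditure survey: a
#' stratified design with (by default) two PSUs per stratum and unequal
#' person weights; 20 chronic-condition indicators whose treated prevalence
#' rises with age and which are positively dependent through one shared
#' Gaussian frailty; right-skewed (log-normal) medical expenditures growing
#' with condition count; and a 5-level self-rated health item whose
#' fair/poor probability follows a logistic model in condition count,
#' designated conditions, and age.
#'
#' Defaults emulate the pooled 2016-2019 U.S. adult population: a target of
#' 249,221,000 adults, four pooled years, age mixture 18-39/40-64/65+ close
#' to the population age structure, and per-condition baselines giving
#' treated marginal prevalences from roughly 26% (hypertension) down to 1%
#' (epilepsy).  The shared frailty SD of 0.8 makes every pairwise lift
#' exceed 1, the qualitative signature of multimorbidity clustering.
#'
#' @param n_strata Number of variance strata.
#' @param psus_per_stratum PSUs sampled per stratum (>= 2, the minimum for
#'   Taylor variance).
#' @param persons_per_psu Respondents per PSU.
#' @param target_population_total Calibration total for the annualized
#'   weights (persons).
#' @param pooled_years Number of pooled survey years (base weights sum to
#'   \code{pooled_years * target_population_total}).
#' @param age_mix Mixture weights for the 18-39 / 40-64 / 65-85 age bands.
#' @param cond_base Baseline log-odds per condition at age 50 (length 20).
#' @param cond_slope Per-year log-odds age slope per condition (length 20).
#' @param frailty_sd SD of the shared person-level frailty (>= 0);
#'   0 plus zero age slopes gives exact independence between conditions.
#' @param exp_intercept,exp_increment,exp_sd Log-normal total-expenditure
#'   model: log(total) ~ Normal(intercept + increment * count, sd).
#' @param oop_shape1,oop_shape2 Beta parameters of the out-of-pocket share.
#' @param ph_intercept,ph_count_coef Poor-health logistic model: intercept
#'   and per-condition-count coefficient.
#' @param ph_cond_coef Named numeric of extra log-odds for designated
#'   conditions (names from the catalog roster).
#' @param ph_combo Integer vector of condition indices forming a designated
#'   exposure combination, or NULL; \code{ph_combo_coef} is its log-odds
#'   effect (the designed exposure log-OR for recovery studies).
#' @param ph_combo_coef Log-odds effect of holding all of \code{ph_combo}.
#' @param ph_age_coef Per-year log-odds age effect on poor health.
#' @param female_prob,race_probs Demographic mixture (race over
#'   \code{race5_levels()}).
#' @param weight_heterogeneity SD of the log-normal weight perturbation.
#' @param truth_draws Monte-Carlo draws for the ground-truth record.
#' @param truth_combos List of integer index vectors whose true prevalence
#'   and lift are recorded in the truth record.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_strata = 50L,
                             psus_per_stratum = 2L,
                             persons_per_psu = 200L,
                             target_population_total = 249221000,
                             pooled_years = 4L,
                             age_mix = c(0.3795, 0.4117, 0.2088),
                             cond_base = default_cond_base(),
                             cond_slope = default_cond_slope(),
                             frailty_sd = 0.8,
                             exp_intercept = 5.9,
                             exp_increment = 0.55,
                             exp_sd = 1.3,
                             oop_shape1 = 2, oop_shape2 = 9,
                             ph_intercept = -3.3,
                             ph_count_coef = 0.55,
                             ph_cond_coef = c("heart failure" = 0.7,
                                              "dementia" = 0.8),
                             ph_combo = NULL,
                             ph_combo_coef = 0,
                             ph_age_coef = 0,
                             female_prob = 0.517,
                             race_probs = c(0.628, 0.163, 0.118, 0.061, 0.030),
                             weight_heterogeneity = 0.3,
                             truth_draws = 1e6,
                             truth_combos = list(c(1L, 2L), c(5L, 6L))) {
  cfg <- as.list(environment())
  stopifnot(cfg$psus_per_stratum >= 2L, cfg$n_strata >= 1L,
            cfg$persons_per_psu >= 1L,
            length(cfg$age_mix) == 3L, all(cfg$age_mix > 0),
            length(cfg$cond_base) == 20L, length(cfg$cond_slope) == 20L,
            cfg$frailty_sd >= 0, cfg$exp_sd >= 0,
            cfg$weight_heterogeneity >= 0,
            cfg$female_prob > 0, cfg$female_prob < 1,
            length(cfg$race_probs) == 5L, all(cfg$race_probs > 0),
            cfg$pooled_years >= 1L)
  cfg$age_mix <- cfg$age_mix / sum(cfg$age_mix)
  cfg$race_probs <- cfg$race_probs / sum(cfg$race_probs)
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
default_cond_base <- function() {
  # baseline log-odds at age 50, calibrated (by Monte-Carlo root finding
  # under the default age mixture, age slopes and frailty SD 0.8) so the
  # marginal treated prevalences land on realistic values: 26% hypertension,
  # 21% hyperlipidemia, ... down to 0.8% dementia and 1% epilepsy
  c(-1.284, -1.641, -2.671, -2.632, -3.282, -4.812, -2.703, -2.250,
    -2.921, -2.717, -3.340, -1.942, -3.491, -4.501, -4.523, -6.186,
    -4.202, -4.330, -4.906, -3.802)
}

#' @rdname generator_config
#' @export
default_cond_slope <- function() {
  c(0.055, 0.055, 0.045, 0.060, 0.065, 0.070, 0.015, 0.025, 0.030, 0.020,
    0.035, 0.000, 0.050, 0.050, 0.020, 0.090, 0.060, 0.055, 0.000, -0.010)
}

# draw ages from the three-band mixture, uniform within band
draw_ages <- function(n, mix) {
  band <- sample.int(3L, n, replace = TRUE, prob = mix)
  lo <- c(18, 40, 65)[band]
  hi <- c(39.999, 64.999, 85)[band]
  lo + stats::runif(n) * (hi - lo)
}

# per-person condition probabilities for a subset of conditions;
# rows = persons, cols = conditions in `which_c`
cond_probs <- function(age, frailty, cfg, which_c = 1:20) {
  eta <- outer(age - 50, cfg$cond_slope[which_c]) +
    matrix(cfg$cond_base[which_c], length(age), length(which_c), byrow = TRUE)
  if (cfg$frailty_sd > 0) eta <- eta + cfg$frailty_sd * frailty
  stats::plogis(eta)
}

#' Generate a synthetic survey population with known truth
#'
#' Draws a complete \code{survey_dataset} from the generative model of
#' \code{\link{generator_config}} together with a ground-truth record for
#' parameter-recovery testing.  Deterministic given the seed.
#'
#' Weights: each stratum receives a population share (drawn once from the
#' seeded stream), person weights start at share * target / n_h, are
#' perturbed log-normally by the heterogeneity factor, and are then
#' ratio-calibrated so base weights sum exactly to
#' \code{pooled_years * target_population_total} — hence annualized weights
#' sum exactly to the target.
#'
#' The truth record is computed by Monte-Carlo integration over the age and
#' frailty distributions on a separate seed stream.  Because conditions are
#' independent given (age, frailty), true joint prevalences are expectations
#' of products of conditional probabilities — no binary draws are needed —
#' making \code{truth_draws = 1e6} cheap.  With zero frailty and zero age
#' slopes the true lift of any combination is exactly 1.
#'
#' @param config A \code{generator_config}.
#' @param seed Integer seed; every source of randomness flows from it.
#' @return A list with elements \code{dataset} (a \code{survey_dataset}) and
#'   \code{truth} (list: \code{marginal} length-20 numeric,
#'   \code{combos} data.frame with items/true_prev/true_lift,
#'   \code{true_or} = exp(ph_combo_coef) or NA).
#' @export
generate_population <- function(config = generator_config(), seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  S <- cfg$n_strata; P <- cfg$psus_per_stratum; m <- cfg$persons_per_psu
  n <- S * P * m
  stratum <- rep(seq_len(S), each = P * m)
  # globally unique PSU ids (stratum * 100 + within-stratum index)
  psu <- stratum * 100L + rep(rep(seq_len(P), each = m), times = S)

  share <- stats::rgamma(S, shape = 5); share <- share / sum(share)
  w <- (share[stratum] * cfg$target_population_total) / (P * m)
  if (cfg$weight_heterogeneity > 0)
    w <- w * exp(stats::rnorm(n, 0, cfg$weight_heterogeneity))
  w <- w * (cfg$pooled_years * cfg$target_population_total) / sum(w)

  age <- draw_ages(n, cfg$age_mix)
  sex <- ifelse(stats::runif(n) < cfg$female_prob, "female", "male")
  race5 <- sample(race5_levels(), n, replace = TRUE, prob = cfg$race_probs)
  frailty <- if (cfg$frailty_sd > 0) stats::rnorm(n) else numeric(n)

  # skip conditions that cannot occur (baseline pushed to -Inf in fixtures)
  active <- which(cfg$cond_base > -20)
  mask <- rep(0L, n)
  if (length(active)) {
    pr <- cond_probs(age, frailty, cfg, active)
    for (k in seq_along(active)) {
      hit <- stats::runif(n) < pr[, k]
      mask <- bitwOr(mask, bitwShiftL(1L, active[k] - 1L) * as.integer(hit))
    }
  }
  count <- bit_count(mask)

  total_exp <- exp(stats::rnorm(n, cfg$exp_intercept +
                                  cfg$exp_increment * count, cfg$exp_sd))
  oop_exp <- total_exp * stats::rbeta(n, cfg$oop_shape1, cfg$oop_shape2)

  eta <- cfg$ph_intercept + cfg$ph_count_coef * count +
    cfg$ph_age_coef * (age - 50)
  if (length(cfg$ph_cond_coef)) {
    ci <- match(names(cfg$ph_cond_coef), default_conditions())
    if (anyNA(ci)) stop("unknown condition name in ph_cond_coef")
    for (k in seq_along(ci)) {
      b <- bitwShiftL(1L, ci[k] - 1L)
      eta <- eta + cfg$ph_cond_coef[[k]] * (bitwAnd(mask, b) != 0L)
    }
  }
  if (!is.null(cfg$ph_combo) && cfg$ph_combo_coef != 0) {
    cm <- itemset_mask(cfg$ph_combo)
    eta <- eta + cfg$ph_combo_coef * (bitwAnd(mask, cm) == cm)
  }
  poor <- stats::runif(n) < stats::plogis(eta)
  srh <- integer(n)
  srh[poor] <- ifelse(stats::runif(sum(poor)) < 0.72, 4L, 5L)
  srh[!poor] <- sample(1:3, sum(!poor), replace = TRUE,
                       prob = c(0.32, 0.40, 0.28))

  persons <- data.frame(
    person_id = seq_len(n), year = 2019L, stratum = stratum, psu = psu,
    weight = w, age = age, sex = sex, race5 = race5, srh = srh,
    total_exp = total_exp, oop_exp = oop_exp, cond = mask,
    stringsAsFactors = FALSE)
  ds <- survey_dataset(persons, condition_catalog(), cfg$pooled_years)

  truth <- compute_truth(cfg, seed)
  list(dataset = ds, truth = truth)
}

# ground truth by Monte-Carlo integration on a separate seed stream
compute_truth <- function(cfg, seed) {
  set.seed(seed + 1000003L)
  M <- as.integer(cfg$truth_draws)
  age <- draw_ages(M, cfg$age_mix)
  frailty <- if (cfg$frailty_sd > 0) stats::rnorm(M) else numeric(M)
  need <- sort(unique(c(unlist(cfg$truth_combos), which(cfg$cond_base > -20))))
  pr <- cond_probs(age, frailty, cfg, need)
  marginal <- rep(0, 20)
  marginal[need] <- colMeans(pr)
  combos <- do.call(rbind, lapply(cfg$truth_combos, function(it) {
    cols <- match(it, need)
    joint <- mean(Reduce(`*`, lapply(cols, function(j) pr[, j])))
    data.frame(items = paste(it, collapse = "|"),
               true_prev = joint,
               true_lift = joint / prod(marginal[it]))
  }))
  independent <- cfg$frailty_sd == 0 && all(cfg$cond_slope[need] == 0)
  if (independent && nrow(combos)) combos$true_lift <- 1
  list(marginal = marginal, combos = combos,
       true_or = if (!is.null(cfg$ph_combo)) exp(cfg$ph_combo_coef)
                 else NA_real_)
}

#' Frozen test fixtures
#'
#' Three named datasets used throughout the test suite.
#' \describe{
#'   \item{tiny_handcheck}{8 persons, 2 strata x 2 PSUs, weights
#'     1,2,3,4,1,2,3,4, three active conditions — every estimate can be
#'     verified by hand.}
#'   \item{small_mining}{200 persons, 5 active conditions — small enough for
#'     exhaustive subset enumeration to cross-check the miner.}
#'   \item{regression_bench}{50,000 persons with a designated three-condition
#'     exposure whose designed poor-health odds ratio is 6.9; the poor-health
#'     model is linear in age with no count effect, so the adjusted logistic
#'     fit is correctly specified and must recover the designed log-OR.}
#' }
#'
#' @param name One of "tiny_handcheck", "small_mining", "regression_bench".
#' @param seed Seed for the generated fixtures (the tiny fixture is fully
#'   hard-coded and ignores it); vary it to obtain independent replicates of
#'   the same design.
#' @return A \code{survey_dataset}; for generated fixtures the truth record
#'   is attached as attribute \code{truth}.
#' @export
make_fixture <- function(name = c("tiny_handcheck", "small_mining",
                                  "regression_bench"), seed = 20260101L) {
  name <- match.arg(name)
  if (name == "tiny_handcheck") {
    # conditions 1 (hypertension), 2 (hyperlipidemia), 3 (diabetes)
    # masks: 1=A, 2=B, 4=C, 3=AB, 7=ABC
    persons <- data.frame(
      person_id = 1:8,
      year = 2019L,
      stratum = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
      psu = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
      weight = c(1, 2, 3, 4, 1, 2, 3, 4),
      age = c(25, 40, 55, 70, 30, 45, 60, 80),
      sex = rep(c("male", "female"), 4),
      race5 = c("NH-white", "NH-white", "Hispanic", "NH-black",
                "NH-Asian", "other/multiple", "NH-white", "NH-white"),
      srh = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 5L),
      total_exp = c(100, 200, 500, 4000, 150, 700, 2500, 9000),
      oop_exp = c(10, 25, 60, 500, 20, 90, 300, 1100),
      cond = c(0L, 1L, 3L, 7L, 0L, 2L, 3L, 7L),
      stringsAsFactors = FALSE)
    return(survey_dataset(persons, condition_catalog(), 1L))
  }
  if (name == "small_mining") {
    cfg <- generator_config(
      n_strata = 5L, psus_per_stratum = 2L, persons_per_psu = 20L,
      target_population_total = 1e6, pooled_years = 1L,
      cond_base = c(stats::qlogis(c(0.45, 0.40, 0.30, 0.25, 0.20)),
                    rep(-30, 15)),
      cond_slope = rep(0, 20), frailty_sd = 0.8,
      truth_draws = 1e4, truth_combos = list(c(1L, 2L)))
    out <- generate_population(cfg, seed)
    ds <- out$dataset
    attr(ds, "truth") <- out$truth
    return(ds)
  }
  # regression_bench
  cfg <- regression_bench_config()
  out <- generate_population(cfg, seed)
  ds <- out$dataset
  attr(ds, "truth") <- out$truth
  ds
}

#' @rdname make_fixture
#' @export
regression_bench_config <- function() {
  generator_config(
    n_strata = 50L, psus_per_stratum = 2L, persons_per_psu = 500L,
    target_population_total = 249221000, pooled_years = 4L,
    cond_base = c(stats::qlogis(c(0.26, 0.21, 0.10)), rep(-30, 17)),
    cond_slope = c(0.05, 0.05, 0.04, rep(0, 17)),
    frailty_sd = 0.6,
    ph_intercept = -2.6, ph_count_coef = 0,
    ph_cond_coef = numeric(0),
    ph_combo = c(1L, 2L, 3L), ph_combo_coef = log(6.9),
    ph_age_coef = 0.02,
    truth_draws = 1e5, truth_combos = list(c(1L, 2L, 3L)))
}
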