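#' Design-based estimates for each mined combination
#'
#' For every support record produced by \code{\link{mine_frequent_itemsets}}
#' this computes the full set of Taylor-linearized estimates: weighted
#' prevalence (%), weighted number of persons, lift (size >= 2 only), mean
#' total and out-of-pocket expenditures over the combination's domain,
#' median and IQR of total expenditures (reported without CIs), and the
#' percent reporting poor health, each with t-based 95% confidence limits.
#'
#' @param dataset A \code{survey_dataset}.
#' @param records data.frame of support records (from the miner or
#'   \code{\link{weighted_support}}).
#' @param level Confidence level.
#' @param domain Optional logical vector restricting all estimates to a
#'   subpopulation (domain estimation; the design stays whole).
#' @return data.frame, one row per record, with flattened estimate columns
#'   (\code{prev_pct}, \code{prev_lo}, \code{prev_hi}, \code{weighted_N},
#'   \code{N_lo}, \code{N_hi}, \code{lift}, \code{lift_lo}, \code{lift_hi},
#'   \code{mean_exp[...]}, \code{mean_oop[...]}, \code{median_exp},
#'   \code{q25_exp}, \code{q75_exp}, \code{poor_health_pct[...]}).
#' @export
itemset_estimates <- function(dataset, records, level = 0.95,
                              domain = NULL) {
  p <- dataset$persons
  w <- p$analysis_weight
  d <- if (is.null(domain)) rep(TRUE, nrow(p)) else as.logical(domain)
  if (!any(d)) stop("empty estimation domain")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    m <- records$mask[i]
    inX <- bitwAnd(p$cond, m) == m
    dom <- inX & d
    prev <- domain_mean(as.numeric(inX), d, dataset, level)
    tot <- estimate_total(as.numeric(dom), dataset, level)
    lift <- if (records$size[i] >= 2L) {
      tryCatch(estimate_lift(m, dataset, level,
                             domain = if (is.null(domain)) NULL else d),
               error = function(e) NULL)
    } else NULL
    me <- domain_mean(p$total_exp, dom, dataset, level)
    mo <- domain_mean(p$oop_exp, dom, dataset, level)
    ph <- domain_mean(as.numeric(p$poor_health), dom, dataset, level)
    qs <- if (any(dom)) weighted_quantile(p$total_exp[dom], w[dom],
                                          c(0.25, 0.5, 0.75))
          else rep(NA_real_, 3)
    data.frame(
      prev_pct = 100 * prev$estimate, prev_se = 100 * prev$se,
      prev_lo = 100 * max(prev$lo, 0), prev_hi = 100 * min(prev$hi, 1),
      weighted_N = tot$estimate, N_se = tot$se,
      N_lo = tot$lo, N_hi = tot$hi,
      lift = if (is.null(lift)) NA_real_ else lift$estimate,
      lift_lo = if (is.null(lift)) NA_real_ else lift$lo,
      lift_hi = if (is.null(lift)) NA_real_ else lift$hi,
      mean_exp = me$estimate, mean_exp_lo = me$lo, mean_exp_hi = me$hi,
      mean_oop = mo$estimate, mean_oop_lo = mo$lo, mean_oop_hi = mo$hi,
      q25_exp = qs[1], median_exp = qs[2], q75_exp = qs[3],
      poor_health_pct = 100 * ph$estimate,
      poor_health_lo = 100 * max(ph$lo, 0),
      poor_health_hi = 100 * min(ph$hi, 1))
  })
  cbind(records, do.call(rbind, rows))
}
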