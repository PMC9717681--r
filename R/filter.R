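#' Minimum-improvement filter for redundant combinations
#'
#' Prunes combinations that add little burden information over a more
#' parsimonious combination.  A combination X of size k is retained for an
#' outcome only when its outcome statistic exceeds that of \emph{every}
#' immediate sub-combination of size k-1 by at least the relative margin
#' \code{tau} (default 10%); dyads are compared against their two single
#' conditions.  "More parsimonious" means fewer conditions — whose holders
#' form a superset population of X's holders.  Improvement is one-sided:
#' only a higher burden counts, since the filter feeds rankings of the
#' highest-cost and worst-health combinations.  Comparison uses point
#' estimates only.
#'
#' Filtering never alters an estimate — it only decides membership — and is
#' idempotent; raising \code{tau} can only shrink the retained set.
#'
#' @param estimates data.frame from \code{\link{itemset_estimates}}
#'   containing all needed sub-combinations (the miner keeps size-1 rows for
#'   exactly this purpose).
#' @param outcome "mean_exp" or "poor_health_pct".
#' @param tau Minimum relative improvement (0.10 = 10%).
#' @return data.frame of decisions for every size >= 2 row of
#'   \code{estimates}: items, mask, size, outcome, stat, retained,
#'   best_parent (label of the highest-statistic parent found),
#'   improvement (relative to the best parent).
#' @export
min_improvement_filter <- function(estimates,
                                   outcome = c("mean_exp",
                                               "poor_health_pct"),
                                   tau = 0.10) {
  outcome <- match.arg(outcome)
  stopifnot(tau >= 0, outcome %in% names(estimates))
  stat <- stats::setNames(estimates[[outcome]],
                          as.character(estimates$mask))
  label <- stats::setNames(estimates$items, as.character(estimates$mask))
  cand <- estimates[estimates$size >= 2L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    m <- cand$mask[i]
    items <- mask_to_items(m)
    parents <- vapply(items, function(drop_i)
      bitwAnd(m, bitwNot(bitwShiftL(1L, drop_i - 1L))), integer(1))
    ps <- stat[as.character(parents)]
    missing_p <- is.na(ps)
    if (any(missing_p))
      warning("outcome statistic missing for parent(s) of ",
              cand$items[i], "; parent skipped", call. = FALSE)
    ps <- ps[!missing_p]
    if (!length(ps)) {
      best <- NA_character_; imp <- NA_real_; keep <- TRUE
    } else {
      b <- which.max(ps)
      best <- label[[names(ps)[b]]]
      imp <- (cand[[outcome]][i] - ps[[b]]) / ps[[b]]
      keep <- all(cand[[outcome]][i] >= (1 + tau) * ps)
    }
    data.frame(items = cand$items[i], mask = m, size = cand$size[i],
               outcome = outcome, stat = cand[[outcome]][i],
               retained = keep, best_parent = best, improvement = imp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Union of the top-k burden rankings
#'
#' Takes the retained combinations for the cost outcome and for the
#' poor-health outcome, ranks each list by its own statistic, and returns
#' the union of the two top-k lists with flags \code{cost_top},
#' \code{health_top} and \code{both}.  The report is sorted by prevalence,
#' descending, with ties broken by larger weighted total then label.
#'
#' @param decisions_cost,decisions_health Decision frames from
#'   \code{\link{min_improvement_filter}} for the two outcomes.
#' @param estimates The estimates frame the decisions refer to.
#' @param k Ranking depth (default 20).
#' @return data.frame: the union rows of \code{estimates} plus the flags.
#' @export
top_k_union <- function(decisions_cost, decisions_health, estimates,
                        k = 20L) {
  pick_top <- function(dec, col) {
    keep <- estimates$mask %in% dec$mask[dec$retained]
    e <- estimates[keep & !is.na(estimates[[col]]), , drop = FALSE]
    if (nrow(e) < k)
      message("fewer than ", k, " retained combinations for ", col,
              " (", nrow(e), ")")
    e <- e[order(-e[[col]], -e$weighted_N, e$items), , drop = FALSE]
    utils::head(e$mask, k)
  }
  top_cost <- pick_top(decisions_cost, "mean_exp")
  top_health <- pick_top(decisions_health, "poor_health_pct")
  u <- union(top_cost, top_health)
  out <- estimates[match(u, estimates$mask), , drop = FALSE]
  out$cost_top <- out$mask %in% top_cost
  out$health_top <- out$mask %in% top_health
  out$both <- out$cost_top & out$health_top
  out <- out[order(-out$prev_pct, -out$weighted_N, out$items), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sex-subgroup mining and estimation
#'
#' Re-runs mine-then-estimate restricted to one sex as a domain analysis:
#' support thresholds apply within the subgroup, weights are kept, and
#' non-members are excluded from numerators and domain denominators while
#' the full design stays in place for variance estimation.  Point estimates
#' are identical to a run on the physically subset file; standard errors
#' can differ when subsetting would empty out PSUs.
#'
#' @param dataset A \code{survey_dataset}.
#' @param sex "male" or "female".
#' @param min_support,min_weighted Mining thresholds applied within the
#'   subgroup (unweighted support is computed over subgroup members).
#' @param top Number of top-prevalence combinations to return.
#' @param level Confidence level.
#' @return data.frame of estimates for the subgroup's top combinations,
#'   sorted by prevalence descending.
#' @export
sex_subgroup_pipeline <- function(dataset, sex = c("male", "female"),
                                  min_support = 0.0020,
                                  min_weighted = 1e6, top = 10L,
                                  level = 0.95) {
  sex <- match.arg(sex)
  d <- dataset$persons$sex == sex
  if (!any(d)) stop("no persons in the ", sex, " subgroup")
  sub <- dataset
  sub$persons <- dataset$persons[d, , drop = FALSE]
  rec <- mine_frequent_itemsets(sub, min_support, min_weighted)
  rec <- rec[rec$in_result, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  est <- itemset_estimates(dataset, rec[, setdiff(names(rec), "in_result")],
                           level = level, domain = d)
  est <- est[order(-est$prev_pct, -est$weighted_N, est$items), ,
             drop = FALSE]
  utils::head(est, top)
}

#' Variant dataset with conditions removed
#'
#' Clears the named condition bits everywhere (for sensitivity analyses such
#' as re-running the pipeline without hypertension and hyperlipidemia, whose
#' combinations otherwise dominate the rankings).  The catalog is annotated
#' with the excluded names.
#'
#' @param dataset A \code{survey_dataset}.
#' @param drop Character vector of condition names to clear (may be empty).
#' @return The modified \code{survey_dataset}.
#' @export
exclude_conditions_variant <- function(dataset, drop = character(0)) {
  if (!length(drop)) return(dataset)
  idx <- match(drop, dataset$catalog$categories)
  if (anyNA(idx))
    stop("unknown condition name(s): ",
         paste(drop[is.na(idx)], collapse = ", "))
  keep_mask <- 1048575L
  for (i in idx)
    keep_mask <- bitwAnd(keep_mask, bitwNot(bitwShiftL(1L, i - 1L)))
  dataset$persons$cond <- bitwAnd(dataset$persons$cond, keep_mask)
  dataset$persons$cond_count <- bit_count(dataset$persons$cond)
  attr(dataset$catalog, "excluded") <- drop
  dataset
}
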