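#' Weighted support of one condition combination
#'
#' A person supports an itemset when their condition vector contains
#' \emph{all} of its items — "at least", not "exactly": someone treated for
#' hypertension, hyperlipidemia and diabetes counts toward the
#' hypertension+diabetes dyad.  Returns both the unweighted count/support
#' and the analysis-weighted total and prevalence.
#'
#' @param items Integer vector of condition indices (or a bitmask).
#' @param dataset A \code{survey_dataset}.
#' @return One-row data.frame: \code{items} (label), \code{mask},
#'   \code{size}, \code{n}, \code{support}, \code{weighted_N},
#'   \code{prevalence}.
#' @export
weighted_support <- function(items, dataset) {
  if (length(items) == 1L && items > 20L) items <- mask_to_items(items)
  mask <- itemset_mask(items)
  support_records(mask, dataset)
}

# vectorised support counting over many candidate masks
support_records <- function(masks, dataset) {
  p <- dataset$persons
  w <- p$analysis_weight
  W <- sum(w)
  n <- nrow(p)
  out <- lapply(masks, function(m) {
    inX <- bitwAnd(p$cond, m) == m
    c(n = sum(inX), wN = sum(w[inX]))
  })
  out <- do.call(rbind, out)
  data.frame(
    items = vapply(masks, mask_to_label, "", catalog = dataset$catalog),
    mask = as.integer(masks),
    size = bit_count(as.integer(masks)),
    n = as.integer(out[, "n"]),
    support = out[, "n"] / n,
    weighted_N = out[, "wN"],
    prevalence = out[, "wN"] / W,
    stringsAsFactors = FALSE)
}

#' Mine all frequent condition combinations (weighted Apriori)
#'
#' Level-wise Apriori search over the 2^20 = 1,048,576 possible condition
#' subsets, mirroring the study's two-stage thresholding: an initial pass
#' keeps itemsets whose \emph{unweighted} support reaches
#' \code{min_support} (default 0.20%), then combinations whose
#' survey-weighted point estimate falls below \code{min_weighted} persons
#' (default one million) are dropped.  Candidate generation joins frequent
#' size-k sets sharing a (k-1)-prefix and prunes by downward closure on the
#' unweighted criterion; since weighted totals are equally anti-monotone the
#' staging is equivalent to filtering on both, but it reproduces the
#' "initial pass" semantics.
#'
#' Size-1 records are always computed and returned (they are the marginals
#' needed for lift and for the minimum-improvement filter) but flagged with
#' \code{in_result = FALSE}; the mined result proper is the size >= 2 rows
#' with \code{in_result = TRUE}.  Combinations observed in no person are
#' never visited, so \code{min_support = 0} enumerates exactly the
#' combinations present in the data rather than the full 2^20 lattice.
#'
#' @param dataset A \code{survey_dataset}.
#' @param min_support Minimum unweighted support fraction (initial pass).
#' @param min_weighted Minimum weighted total (persons) after weighting.
#' @param max_size Largest itemset size searched (20 = unbounded).
#' @return data.frame of support records sorted by (size, weighted_N
#'   descending, label) with the added logical column \code{in_result}.
#' @seealso \code{\link{weighted_support}}, \code{\link{itemset_space_size}}
#' @export
mine_frequent_itemsets <- function(dataset, min_support = 0.0020,
                                   min_weighted = 1e6, max_size = 20L) {
  stopifnot(min_support >= 0, min_weighted >= 0, max_size >= 1L)
  p <- dataset$persons
  n <- nrow(p)
  singles <- support_records(as.list(bitwShiftL(1L, 0:19)), dataset)
  singles$in_result <- FALSE
  res <- list(singles)
  frequent <- singles$mask[singles$support >= min_support & singles$n >= 1L]
  k <- 1L
  while (length(frequent) >= 2L && k < max_size) {
    cand <- apriori_join(frequent, k)
    if (!length(cand)) break
    rec <- support_records(cand, dataset)
    keep <- rec$support >= min_support & rec$n >= 1L
    rec <- rec[keep, , drop = FALSE]
    if (!nrow(rec)) break
    rec$in_result <- rec$weighted_N >= min_weighted
    res[[length(res) + 1L]] <- rec
    frequent <- rec$mask
    k <- k + 1L
  }
  out <- do.call(rbind, res)
  # deterministic order: size, then larger weighted totals, then label
  out <- out[order(out$size, -out$weighted_N, out$items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# join frequent k-sets sharing a (k-1)-prefix, prune by downward closure
apriori_join <- function(freq_masks, k) {
  sets <- lapply(freq_masks, mask_to_items)
  keys <- vapply(sets, function(s)
    paste(s[-length(s)], collapse = ","), "")
  freq_env <- new.env(hash = TRUE, size = length(freq_masks) * 2L)
  for (m in freq_masks) assign(as.character(m), TRUE, envir = freq_env)
  cand <- integer(0)
  for (grp in split(seq_along(sets), keys)) {
    if (length(grp) < 2L) next
    lasts <- vapply(grp, function(i) sets[[i]][k], integer(1))
    o <- order(lasts)
    grp <- grp[o]
    for (a in seq_len(length(grp) - 1L)) {
      for (b in (a + 1L):length(grp)) {
        m <- bitwOr(freq_masks[grp[a]], freq_masks[grp[b]])
        items <- mask_to_items(m)
        ok <- all(vapply(items, function(drop_i) {
          sub <- bitwAnd(m, bitwNot(bitwShiftL(1L, drop_i - 1L)))
          exists(as.character(sub), envir = freq_env)
        }, logical(1)))
        if (ok) cand <- c(cand, m)
      }
    }
  }
  unique(cand)
}

#' Size of the itemset search space
#'
#' Number of condition subsets (including the empty set) over n items:
#' 2^n.  For the 20-condition roster this is 1,048,576.
#'
#' @param n_items Number of items.
#' @return A double (2^n overflows integer at n >= 31).
#' @export
itemset_space_size <- function(n_items = 20L) 2^n_items

#' Weighted condition-count bands by population group
#'
#' The characteristics table: for each demographic group (total, age bands,
#' sex, race/ethnicity, self-rated poor health) the weighted share of
#' persons with 0, 1+, 2+, 3+ and 4+ treated conditions.  Bands are
#' cumulative, so 2+ always contains 3+.
#'
#' @param dataset A \code{survey_dataset}.
#' @return data.frame with columns group, level, n (unweighted),
#'   weighted_N, and pct_0, pct_1plus .. pct_4plus (row percentages).
#' @export
condition_count_bands <- function(dataset) {
  p <- dataset$persons
  groups <- list(
    total = rep("all", nrow(p)),
    age = cut(p$age, c(18, 40, 65, Inf), right = FALSE,
              labels = c("18-39", "40-64", "65+")),
    sex = as.character(p$sex),
    race = as.character(p$race5),
    poor_health = ifelse(p$poor_health, "poor self-rated health", NA))
  rows <- list()
  for (g in names(groups)) {
    lev <- groups[[g]]
    for (l in unique(stats::na.omit(as.character(lev)))) {
      d <- !is.na(lev) & lev == l
      w <- p$analysis_weight[d]
      W <- sum(w)
      cc <- p$cond_count[d]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, level = l, n = sum(d), weighted_N = W,
        pct_0 = 100 * sum(w[cc == 0]) / W,
        pct_1plus = 100 * sum(w[cc >= 1]) / W,
        pct_2plus = 100 * sum(w[cc >= 2]) / W,
        pct_3plus = 100 * sum(w[cc >= 3]) / W,
        pct_4plus = 100 * sum(w[cc >= 4]) / W,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
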