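#' Taylor-series linearization variance
#'
#' The workhorse of all design-based standard errors.  Per-person influence
#' (linearized) values are summed to PSU totals within variance strata; the
#' variance estimate is the with-replacement first-stage form
#' \deqn{\widehat{Var} = \sum_h \frac{n_h}{n_h - 1} \sum_j (Z_{hj} - \bar Z_h)^2,}
#' where \eqn{Z_{hj}} is the total of the influence values in PSU j of
#' stratum h and \eqn{n_h} the number of sampled PSUs in stratum h.  No
#' finite-population correction is applied, matching the convention for
#' public-use files that suppress first-stage sampling fractions.
#'
#' A stratum containing a single PSU contributes no between-PSU spread and
#' makes the estimator undefined; by default this raises an error naming the
#' stratum.  With \code{collapse_single = TRUE} all single-PSU strata are
#' merged into one synthetic stratum before computing.
#'
#' @param z Numeric vector of per-person influence values.
#' @param strata Stratum identifier per person.
#' @param psu PSU identifier per person (unique across strata).
#' @param collapse_single Merge single-PSU strata instead of erroring.
#' @return The variance estimate (a scalar >= 0).
#' @seealso \code{\link{estimate_proportion}}, \code{\link{estimate_lift}}
#' @export
taylor_variance <- function(z, strata, psu, collapse_single = FALSE) {
  drop(taylor_vcov(cbind(z), strata, psu, collapse_single))
}

# matrix version: returns the p x p covariance of a vector-valued total,
# used directly by the sandwich estimator of the survey logistic fit
taylor_vcov <- function(Z, strata, psu, collapse_single = FALSE) {
  Z <- as.matrix(Z)
  strata <- as.character(strata)
  psu <- as.character(psu)
  stopifnot(nrow(Z) == length(strata), nrow(Z) == length(psu))
  npsu <- tapply(psu, strata, function(x) length(unique(x)))
  single <- names(npsu)[npsu == 1L]
  if (length(single)) {
    if (!collapse_single)
      stop("stratum with a single PSU: ", paste(single, collapse = ", "),
           " (set collapse_single = TRUE to merge such strata)")
    if (length(single) == 1L && length(npsu) == 1L)
      stop("cannot collapse: the design has a single PSU overall")
    strata[strata %in% single] <- ".collapsed"
    npsu <- tapply(psu, strata, function(x) length(unique(x)))
    if (npsu[".collapsed"] == 1L)
      stop("cannot collapse: only one single-PSU stratum present")
  }
  # PSU totals of each influence column (PSU ids are unique across strata)
  tot <- rowsum(Z, psu, reorder = FALSE)
  h_of <- strata[match(rownames(tot), psu)]
  hf <- factor(h_of)
  nh <- tabulate(hf)
  p <- ncol(Z)
  if (p == 1L) {
    # vectorised scalar path
    means <- rowsum(tot[, 1], hf, reorder = TRUE)[, 1] / nh
    dev2 <- rowsum((tot[, 1] - means[as.integer(hf)])^2, hf,
                   reorder = TRUE)[, 1]
    return(matrix(sum(nh / (nh - 1) * dev2), 1, 1))
  }
  V <- matrix(0, p, p)
  for (h in levels(hf)) {
    Zh <- tot[h_of == h, , drop = FALSE]
    k <- nrow(Zh)
    D <- sweep(Zh, 2L, colMeans(Zh))
    V <- V + (k / (k - 1)) * crossprod(D)
  }
  V
}

#' Design degrees of freedom
#'
#' Number of PSUs minus number of strata; governs the t quantile used for
#' confidence intervals.
#'
#' @param dataset A \code{survey_dataset}.
#' @return Integer degrees of freedom.
#' @export
design_df <- function(dataset) {
  p <- dataset$persons
  length(unique(p$vpsu)) - length(unique(p$vstratum))
}

# construct a linearized-estimate record; CIs are t-based with design df,
# built on the log scale when log_se is supplied (ratio-type estimands)
new_svy_est <- function(estimate, se, df, type, level = 0.95,
                        log_se = NULL, clip = NULL) {
  a <- 1 - (1 - level) / 2
  tq <- if (df > 0) stats::qt(a, df) else stats::qnorm(a)
  if (!is.null(log_se)) {
    lo <- exp(log(estimate) - tq * log_se)
    hi <- exp(log(estimate) + tq * log_se)
    se <- estimate * log_se  # delta-method SE on the natural scale
  } else {
    lo <- estimate - tq * se
    hi <- estimate + tq * se
  }
  if (!is.null(clip)) {
    lo <- max(lo, clip[1]); hi <- min(hi, clip[2])
  }
  structure(list(estimate = estimate, se = se, lo = lo, hi = hi,
                 df = df, type = type, level = level),
            class = "svy_est")
}

#' @export
print.svy_est <- function(x, ...) {
  cat(sprintf("%s: %.6g (SE %.4g, %g%% CI %.6g to %.6g, df %d)\n",
              x$type, x$estimate, x$se, 100 * x$level, x$lo, x$hi, x$df))
  invisible(x)
}

#' Design-based proportion
#'
#' Weighted proportion \eqn{\hat p = \sum w_i y_i / \sum w_i} with Taylor
#' linearized SE (influence \eqn{z_i = w_i (y_i - \hat p)/\sum w}) and a
#' t-based CI truncated to [0, 1].
#'
#' @param y Numeric or logical 0/1 indicator, one per person.
#' @param dataset A \code{survey_dataset}.
#' @param level Confidence level.
#' @return A \code{svy_est} of type "proportion".
#' @export
estimate_proportion <- function(y, dataset, level = 0.95) {
  p <- dataset$persons
  w <- p$analysis_weight
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(p), all(y %in% c(0, 1)))
  W <- sum(w)
  if (W <= 0) stop("zero total weight")
  phat <- sum(w * y) / W
  z <- w * (y - phat) / W
  v <- taylor_variance(z, p$vstratum, p$vpsu)
  new_svy_est(phat, sqrt(v), design_df(dataset), "proportion",
              level, clip = c(0, 1))
}

#' Design-based total
#'
#' Weighted total \eqn{\hat N = \sum w_i y_i} (persons) with linearized SE
#' (influence \eqn{z_i = w_i y_i}).
#'
#' @inheritParams estimate_proportion
#' @return A \code{svy_est} of type "total".
#' @export
estimate_total <- function(y, dataset, level = 0.95) {
  p <- dataset$persons
  w <- p$analysis_weight
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(p))
  tot <- sum(w * y)
  v <- taylor_variance(w * y, p$vstratum, p$vpsu)
  new_svy_est(tot, sqrt(v), design_df(dataset), "total", level,
              clip = c(0, Inf))
}

#' Observed-to-expected prevalence ratio (lift)
#'
#' For a combination X of two or more conditions, lift is the observed
#' weighted prevalence of holding all conditions in X divided by the product
#' of the single-condition prevalences — the prevalence expected were the
#' conditions independent.  Lift 1 means co-occurrence at chance level;
#' lift > 1 means the conditions cluster.
#'
#' The SE is obtained by linearizing \eqn{\log L}: per-person influence
#' \deqn{z_i = \frac{w_i}{\sum w}\Big[\frac{1\{i \supseteq X\} - \hat p_X}{\hat p_X}
#'   - \sum_{c \in X} \frac{1\{i \ni c\} - \hat p_c}{\hat p_c}\Big]}
#' feeds \code{\link{taylor_variance}}; the CI is computed on the log scale
#' and exponentiated, which yields the asymmetric intervals typical of
#' ratio estimands.
#'
#' @param items Integer vector of condition indices (length >= 2) or an
#'   itemset bitmask.
#' @param dataset A \code{survey_dataset}.
#' @param level Confidence level.
#' @param domain Optional logical vector restricting the estimand to a
#'   subpopulation; prevalences become domain proportions and the influence
#'   values use the domain-ratio linearization.
#' @return A \code{svy_est} of type "lift".
#' @export
estimate_lift <- function(items, dataset, level = 0.95, domain = NULL) {
  if (length(items) == 1L) items <- mask_to_items(items)
  if (length(items) < 2L) stop("lift requires an itemset of size >= 2")
  p <- dataset$persons
  w <- p$analysis_weight
  if (!is.null(domain)) w <- w * as.numeric(domain)
  W <- sum(w)
  mask <- itemset_mask(items)
  inX <- as.numeric(bitwAnd(p$cond, mask) == mask)
  pX <- sum(w * inX) / W
  singles <- lapply(items, function(c)
    as.numeric(bitwAnd(p$cond, bitwShiftL(1L, c - 1L)) != 0L))
  pc <- vapply(singles, function(y) sum(w * y) / W, numeric(1))
  if (pX <= 0 || any(pc <= 0))
    stop("lift undefined: a marginal or joint prevalence is zero")
  L <- pX / prod(pc)
  z <- (inX - pX) / pX
  for (k in seq_along(items)) z <- z - (singles[[k]] - pc[k]) / pc[k]
  z <- w * z / W
  v <- taylor_variance(z, p$vstratum, p$vpsu)
  new_svy_est(L, NA_real_, design_df(dataset), "lift", level,
              log_se = sqrt(v))
}

#' Design-based domain (subpopulation) mean
#'
#' Ratio estimator \eqn{\hat R = \sum w_i d_i v_i / \sum w_i d_i} of the mean
#' of \code{values} over the domain flagged by \code{domain}, with the
#' ratio-linearized influence \eqn{z_i = w_i d_i (v_i - \hat R)/\sum w d}.
#' Used for per-combination mean expenditures and poor-health percentages.
#' Non-domain persons stay in the dataset so the design (strata/PSUs) is
#' intact — the correct handling of subpopulations in complex surveys.
#'
#' @param values Numeric vector, one per person (ignored off-domain).
#' @param domain Logical/0-1 vector flagging domain membership.
#' @param dataset A \code{survey_dataset}.
#' @param level Confidence level.
#' @return A \code{svy_est} of type "mean", or one with NA fields (and a
#'   \code{note} attribute) when the domain is empty.
#' @export
domain_mean <- function(values, domain, dataset, level = 0.95) {
  p <- dataset$persons
  w <- p$analysis_weight
  d <- as.numeric(domain)
  stopifnot(length(values) == nrow(p), length(d) == nrow(p))
  Wd <- sum(w * d)
  if (Wd <= 0) {
    est <- new_svy_est(NA_real_, NA_real_, design_df(dataset), "mean", level)
    attr(est, "note") <- "empty domain"
    return(est)
  }
  v <- ifelse(d > 0, values, 0)
  R <- sum(w * d * v) / Wd
  z <- w * d * (v - R) / Wd
  vv <- taylor_variance(z, p$vstratum, p$vpsu)
  new_svy_est(R, sqrt(vv), design_df(dataset), "mean", level)
}

#' Weighted quantile
#'
#' Lower weighted quantile without interpolation: the smallest observed value
#' whose cumulative weight fraction reaches q.  Deterministic and invariant
#' to rescaling the weights; an interpolated variant is available via
#' \code{type = "interpolate"}.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, some positive.
#' @param q Quantile(s) in (0, 1).
#' @param type "lower" (default) or "interpolate".
#' @return Numeric vector of the same length as q.
#' @export
#' @examples
#' weighted_quantile(c(0, 10), c(1, 9), 0.5)   # 10
weighted_quantile <- function(values, weights, q, type = c("lower",
                                                           "interpolate")) {
  type <- match.arg(type)
  stopifnot(length(values) == length(weights), all(q > 0), all(q < 1))
  keep <- !is.na(values) & weights > 0
  values <- values[keep]; weights <- weights[keep]
  if (!length(values)) stop("no positive-weight values")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(q, function(qq) {
    if (type == "lower") {
      v[which(cw >= qq - 1e-12)[1]]
    } else {
      stats::approx(c(0, cw), c(v[1], v), xout = qq, rule = 2, ties = "ordered")$y
    }
  }, numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median_iqr <- function(values, weights) {
  qs <- weighted_quantile(values, weights, c(0.25, 0.5, 0.75))
  c(q25 = qs[1], median = qs[2], q75 = qs[3])
}
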