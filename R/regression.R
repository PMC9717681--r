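#' Natural cubic spline basis for age
#'
#' Builds the age adjustment basis: a natural cubic spline (linear beyond
#' the boundary knots) with interior knots placed at equally spaced
#' \emph{weighted} quantiles of age.  \code{df} counts the age parameters
#' including the model intercept, so the basis has \code{df - 1} columns and
#' \code{df - 2} interior knots; \code{df = 2} has no interior knot and
#' spans exactly the linear-in-age model.
#'
#' @param age Numeric vector of ages (years).
#' @param df Age degrees of freedom including intercept (>= 2; default 4).
#' @param weights Optional sampling weights for the knot quantiles.
#' @param knots,boundary Optional explicit interior/boundary knots, for
#'   reproducing a basis on new data.
#' @return Matrix with \code{df - 1} columns and attributes \code{knots}
#'   and \code{boundary}.
#' @export
spline_basis <- function(age, df = 4L, weights = NULL, knots = NULL,
                         boundary = NULL) {
  stopifnot(df >= 2L)
  if (length(unique(age)) < 2L)
    stop("degenerate age distribution: all ages equal")
  if (is.null(weights)) weights <- rep(1, length(age))
  if (is.null(boundary)) boundary <- range(age)
  if (is.null(knots)) {
    m <- df - 2L
    knots <- if (m > 0L)
      unique(weighted_quantile(age, weights, seq_len(m) / (m + 1L),
                               type = "interpolate"))
    else numeric(0)
  }
  B <- if (length(knots))
    splines::ns(age, knots = knots, Boundary.knots = boundary)
  else
    splines::ns(age, df = 1L, Boundary.knots = boundary)
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  B
}

#' Model specification for the adjusted odds-ratio fit
#'
#' The exposure is the indicator of holding \emph{all} conditions of an
#' itemset; adjustment covariates are the age spline
#' (\code{\link{spline_basis}}), race/ethnicity one-hot with non-Hispanic
#' white as the reference, and sex with male as the reference.
#'
#' @param exposure Integer vector of condition indices (or a bitmask).
#' @param spline_df Age degrees of freedom including intercept.
#' @return A list of class \code{model_spec}.
#' @export
model_spec <- function(exposure, spline_df = 4L) {
  if (length(exposure) == 1L && exposure > 20L)
    exposure <- mask_to_items(exposure)
  structure(list(exposure = as.integer(exposure),
                 spline_df = as.integer(spline_df)),
            class = "model_spec")
}

# design matrix: intercept | exposure | ns(age) | race dummies | female
build_design <- function(dataset, spec) {
  p <- dataset$persons
  mask <- itemset_mask(spec$exposure)
  expo <- as.numeric(bitwAnd(p$cond, mask) == mask)
  B <- spline_basis(p$age, spec$spline_df, weights = p$analysis_weight)
  race <- stats::model.matrix(~ race5, data = p)[, -1, drop = FALSE]
  female <- as.numeric(p$sex == "female")
  X <- cbind(`(Intercept)` = 1, exposure = expo, B, race,
             sexfemale = female)
  colnames(X)[2 + seq_len(ncol(B))] <- paste0("age_ns", seq_len(ncol(B)))
  X
}

#' Survey-weighted logistic regression of poor health
#'
#' Fits the design-based logistic model by iteratively reweighted least
#' squares: the coefficient vector solves the weighted score equation
#' \eqn{\sum_i w_i x_i (y_i - \mathrm{expit}(x_i'\beta)) = 0}.  The
#' covariance is the linearized sandwich \eqn{A^{-1} B A^{-1}} with
#' \eqn{A = \sum_i w_i \mu_i (1-\mu_i) x_i x_i'} and \eqn{B} the
#' Taylor-series (stratum/PSU) covariance of the per-person score
#' contributions \eqn{w_i x_i (y_i - \mu_i)}.  Confidence limits use the t
#' distribution with design degrees of freedom (PSUs minus strata).
#'
#' Convergence: relative deviance change below 1e-8 or 25 iterations;
#' separation is flagged when any coefficient magnitude exceeds 15.
#'
#' @param dataset A \code{survey_dataset}.
#' @param spec A \code{\link{model_spec}} (or an itemset, converted with the
#'   default spline df).
#' @param level Confidence level for the odds-ratio interval.
#' @return Object of class \code{svy_logit}: coefficients, sandwich
#'   \code{vcov}, exposure \code{or}/\code{or_lo}/\code{or_hi}, \code{n},
#'   \code{df}, \code{iterations}, \code{score_norm}, \code{converged}.
#' @export
fit_survey_logistic <- function(dataset, spec, level = 0.95) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  p <- dataset$persons
  y <- as.numeric(p$poor_health)
  w <- p$analysis_weight
  # scale-free weights: normalizing changes neither beta nor the sandwich
  w <- w / mean(w)
  X <- build_design(dataset, spec)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("outcome has no cases or no non-cases")
  if (qr(crossprod(X * sqrt(w)))$rank < ncol(X))
    stop("singular design matrix (rank deficiency; degenerate exposure?)")

  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    Wd <- w * mu * (1 - mu)
    zr <- eta + (y - mu) / (mu * (1 - mu))
    fit <- tryCatch(solve(crossprod(X, Wd * X), crossprod(X, Wd * zr)),
                    error = function(e) NULL)
    if (is.null(fit)) stop("singular weighted information matrix")
    beta <- drop(fit)
    if (max(abs(beta)) > 15)
      stop("non-convergence: separation suspected (|beta| > 15)")
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev_old) + 0.1) < 1e-8) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    if (iter >= 25L) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  A <- crossprod(X, (w * mu * (1 - mu)) * X)
  U <- X * (w * (y - mu))
  B <- taylor_vcov(U, p$vstratum, p$vpsu)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  df <- design_df(dataset)
  se <- sqrt(diag(V))
  tq <- stats::qt(1 - (1 - level) / 2, df)
  b_exp <- beta[2]
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = V, se = stats::setNames(se, colnames(X)),
    or = exp(b_exp),
    or_lo = exp(b_exp - tq * se[2]),
    or_hi = exp(b_exp + tq * se[2]),
    n = nrow(X), df = df, level = level,
    iterations = iter,
    score_norm = sqrt(sum(colSums(U)^2)),
    converged = converged,
    exposure = spec$exposure), class = "svy_logit")
}

#' @export
print.svy_logit <- function(x, ...) {
  cat(sprintf(
    "Survey logistic fit (n = %d, design df = %d, %d IRLS iterations)\n",
    x$n, x$df, x$iterations))
  cat(sprintf("  exposure {%s}: adjusted OR %.2f (%g%% CI %.2f-%.2f)\n",
              paste(x$exposure, collapse = ","), x$or, 100 * x$level,
              x$or_lo, x$or_hi))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Batch adjusted odds ratios
#'
#' One survey-weighted logistic fit per combination; rows come back in input
#' order and a fit that fails (separation, rank deficiency, degenerate
#' exposure) is reported as a row with NA estimates and the error message,
#' never silently dropped.
#'
#' @param dataset A \code{survey_dataset}.
#' @param itemsets List of integer index vectors, or a mined/filtered
#'   data.frame with a \code{mask} column.
#' @param spline_df Age degrees of freedom including intercept.
#' @param level Confidence level.
#' @return data.frame: items, aOR, aOR_lo, aOR_hi, converged, error.
#' @export
batch_adjusted_or <- function(dataset, itemsets, spline_df = 4L,
                              level = 0.95) {
  if (is.data.frame(itemsets))
    itemsets <- lapply(itemsets$mask, mask_to_items)
  rows <- lapply(itemsets, function(it) {
    lab <- mask_to_label(itemset_mask(it), dataset$catalog)
    fit <- tryCatch(
      fit_survey_logistic(dataset, model_spec(it, spline_df), level),
      error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(items = lab, aOR = NA_real_, aOR_lo = NA_real_,
                 aOR_hi = NA_real_, converged = FALSE,
                 error = conditionMessage(fit), stringsAsFactors = FALSE)
    else
      data.frame(items = lab, aOR = fit$or, aOR_lo = fit$or_lo,
                 aOR_hi = fit$or_hi, converged = fit$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
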