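#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one list, optionally
#' seeded from a YAML file (\code{\link{read_pipeline_config}}).  When
#' \code{input} is NULL the synthetic generator supplies the microdata.
#'
#' @param input Path to microdata (delimited text) or NULL to simulate.
#' @param condition_file,map_file Optional long-format condition file and
#'   ICD-10 mapping TSV for the ingest path.
#' @param pooled_years Annualization divisor for ingested data.
#' @param generator A \code{\link{generator_config}} for simulated input.
#' @param min_support Unweighted support threshold of the initial pass.
#' @param min_weighted Weighted person threshold after weighting.
#' @param tau Minimum-improvement margin for the redundancy filter.
#' @param spline_df Age degrees of freedom including intercept.
#' @param level Confidence level.
#' @param k_top Depth of the burden rankings.
#' @param exclude Condition names to clear before analysis (variant runs).
#' @param sex_subgroups Run the by-sex secondary analysis.
#' @param seed Seed for simulated input.
#' @param outdir Output directory for the report bundle.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, condition_file = NULL,
                            map_file = NULL, pooled_years = 4L,
                            generator = generator_config(),
                            min_support = 0.0020, min_weighted = 1e6,
                            tau = 0.10, spline_df = 4L, level = 0.95,
                            k_top = 20L, exclude = character(0),
                            sex_subgroups = TRUE, seed = 1L,
                            outdir = tempfile("svymine_run_")) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_support >= 0, cfg$min_weighted >= 0, cfg$tau >= 0,
            cfg$level > 0, cfg$level < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override the defaults above (the
#'   \code{generator} key may itself be a mapping of
#'   \code{\link{generator_config}} arguments).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$generator))
    raw$generator <- do.call(generator_config, raw$generator)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation) -> mining -> design-based estimation
#' -> redundancy filtering -> survey-weighted logistic regression ->
#' report assembly, writing every table as CSV plus a JSON run manifest
#' (inputs, thresholds, row counts per stage, seed) into
#' \code{config$outdir}.  Deterministic: identical config and inputs give
#' byte-identical outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with all in-memory results (dataset, records,
#'   estimates, decisions, top table, odds ratios, table1, manifest).
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(thresholds = list(min_support = config$min_support,
                                     min_weighted = config$min_weighted,
                                     tau = config$tau),
                   spline_df = config$spline_df, level = config$level,
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("svymine")))

  # -- ingest -----------------------------------------------------------
  if (is.null(config$input)) {
    sim <- generate_population(config$generator, config$seed)
    dataset <- sim$dataset
    manifest$input <- "synthetic"
    manifest$truth_combos <- sim$truth$combos$items
  } else {
    catalog <- if (!is.null(config$map_file))
      read_condition_map(config$map_file) else condition_catalog()
    dataset <- read_survey_data(config$input, catalog,
                                config$pooled_years,
                                condition_file = config$condition_file)
    manifest$input <- config$input
  }
  manifest$n_persons <- nrow(dataset$persons)
  manifest$n_excluded_missing <- attr(dataset, "n_excluded")
  if (length(config$exclude)) {
    dataset <- exclude_conditions_variant(dataset, config$exclude)
    manifest$excluded_conditions <- config$exclude
  }
  dataset <- annualize_weights(dataset)
  manifest$population_total <- sum(dataset$persons$analysis_weight)

  # -- mine -------------------------------------------------------------
  records <- mine_frequent_itemsets(dataset, config$min_support,
                                    config$min_weighted)
  manifest$n_itemsets_mined <- sum(records$in_result)
  by_size <- table(records$size[records$in_result])
  manifest$itemsets_by_size <- as.list(stats::setNames(
    as.integer(by_size), paste0("size_", names(by_size))))

  # -- estimate ---------------------------------------------------------
  estimates <- itemset_estimates(
    dataset, records[, setdiff(names(records), "in_result")],
    level = config$level)
  estimates$in_result <- records$in_result

  # -- filter -----------------------------------------------------------
  dec_cost <- min_improvement_filter(
    estimates[estimates$in_result | estimates$size == 1L, ],
    "mean_exp", config$tau)
  dec_health <- min_improvement_filter(
    estimates[estimates$in_result | estimates$size == 1L, ],
    "poor_health_pct", config$tau)
  top_tab <- top_k_union(dec_cost, dec_health, estimates, config$k_top)
  manifest$n_retained_cost <- sum(dec_cost$retained)
  manifest$n_retained_health <- sum(dec_health$retained)
  manifest$n_top_union <- nrow(top_tab)
  manifest$n_top_both <- sum(top_tab$both)

  # -- regress ----------------------------------------------------------
  ors <- if (nrow(top_tab))
    batch_adjusted_or(dataset, top_tab, config$spline_df, config$level)
  else NULL
  manifest$n_or_fits <- if (is.null(ors)) 0L else nrow(ors)

  # -- report -----------------------------------------------------------
  t1 <- table1_report(dataset)
  subgroups <- NULL
  if (isTRUE(config$sex_subgroups)) {
    subgroups <- lapply(c(male = "male", female = "female"), function(s)
      tryCatch(sex_subgroup_pipeline(dataset, s, config$min_support,
                                     config$min_weighted),
               error = function(e) NULL))
  }

  wr <- function(x, f) if (!is.null(x) && nrow(x))
    utils::write.csv(x, file.path(config$outdir, f), row.names = FALSE)
  wr(records, "itemsets.csv")
  wr(estimates, "estimates.csv")
  wr(dec_cost, "filter_cost.csv")
  wr(dec_health, "filter_health.csv")
  wr(top_tab, "top_burden.csv")
  wr(ors, "odds_ratios.csv")
  wr(t1$bands, "table1_bands.csv")
  wr(t1$expenditures, "table1_expenditures.csv")
  if (!is.null(subgroups)) {
    wr(subgroups$male, "top10_male.csv")
    wr(subgroups$female, "top10_female.csv")
  }
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, records = records,
                 estimates = estimates, decisions_cost = dec_cost,
                 decisions_health = dec_health, top = top_tab, ors = ors,
                 table1 = t1, subgroups = subgroups, manifest = manifest))
}

#' Population characteristics table
#'
#' The Table-1 style report: weighted condition-count bands (0, 1+, 2+, 3+,
#' 4+) by demographic group via \code{\link{condition_count_bands}}, plus
#' weighted median (IQR) total and out-of-pocket expenditures by band over
#' the whole population.
#'
#' @param dataset A \code{survey_dataset}.
#' @return List of two data.frames: \code{bands} and \code{expenditures}.
#' @export
table1_report <- function(dataset) {
  p <- dataset$persons
  bands <- condition_count_bands(dataset)
  # cumulative bands: "2+" summarizes everyone with >= 2 conditions
  exp_rows <- lapply(0:4, function(b) {
    d <- if (b == 0) p$cond_count == 0 else p$cond_count >= b
    w <- p$analysis_weight[d]
    qt <- weighted_quantile(p$total_exp[d], w, c(0.25, 0.5, 0.75))
    qo <- weighted_quantile(p$oop_exp[d], w, c(0.25, 0.5, 0.75))
    data.frame(band = if (b == 0) "0" else paste0(b, "+"),
               median_exp = qt[2], q25_exp = qt[1], q75_exp = qt[3],
               median_oop = qo[2], q25_oop = qo[1], q75_oop = qo[3])
  })
  list(bands = bands, expenditures = do.call(rbind, exp_rows))
}

#' Display rounding helpers
#'
#' Formats estimates at the precision used in reporting: percentages to one
#' decimal, dollar amounts to whole dollars, lifts and odds ratios to one
#' decimal, population counts in millions to one decimal.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
fmt_pct <- function(x) sprintf("%.1f%%", x)
#' @rdname fmt_pct
#' @export
fmt_usd <- function(x) sprintf("$%s", formatC(round(x), big.mark = ",",
                                              format = "d"))
#' @rdname fmt_pct
#' @export
fmt_ratio <- function(x) sprintf("%.1f", x)
#' @rdname fmt_pct
#' @export
fmt_millions <- function(x) sprintf("%.1f million", x / 1e6)
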