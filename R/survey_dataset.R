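#' Assemble a survey dataset
#'
#' The central container: one row per respondent-year with complex-survey
#' design metadata (variance stratum, PSU, person weight), demographics,
#' a packed 20-bit chronic-condition vector, and the outcomes (self-rated
#' health, total and out-of-pocket medical expenditures).  Mining treats each
#' person as a transaction and each condition as an item.
#'
#' Persons with missing self-rated health or expenditures are excluded at
#' assembly with a message (the count is kept in attribute
#' \code{n_excluded}).  Weights of zero are allowed; negative weights are not.
#'
#' @param persons data.frame with columns \code{person_id}, \code{year},
#'   \code{stratum}, \code{psu}, \code{weight} (base person weight),
#'   \code{age} (years, >= 18), \code{sex} ("male"/"female"), \code{race5}
#'   (one of \code{race5_levels()}), \code{srh} (integer 1-5),
#'   \code{total_exp}, \code{oop_exp} (USD, >= 0), and \code{cond}
#'   (integer 20-bit condition mask).
#' @param catalog A \code{condition_catalog}.
#' @param pooled_years Integer k >= 1; the number of pooled survey years.
#'   Analysis weights are base weights divided by k (see
#'   \code{\link{annualize_weights}}).
#' @param nest When TRUE, PSU labels are interpreted as nested within strata
#'   and relabelled stratum-by-stratum (the convention of public-use files
#'   that recycle PSU labels 1, 2, ... in every stratum).  When FALSE
#'   (default) a PSU label appearing under two strata of the same year is a
#'   design violation.
#' @return An object of class \code{survey_dataset}.
#' @seealso \code{\link{validate_dataset}}, \code{\link{read_survey_data}}
#' @export
survey_dataset <- function(persons, catalog = condition_catalog(),
                           pooled_years = 1L, nest = FALSE) {
  req <- c("person_id", "year", "stratum", "psu", "weight", "age", "sex",
           "race5", "srh", "total_exp", "oop_exp", "cond")
  miss <- setdiff(req, names(persons))
  if (length(miss)) stop("persons is missing column(s): ",
                         paste(miss, collapse = ", "))
  pooled_years <- as.integer(pooled_years)
  if (is.na(pooled_years) || pooled_years < 1L)
    stop("pooled_years must be an integer >= 1")

  drop <- is.na(persons$srh) | is.na(persons$total_exp) | is.na(persons$oop_exp)
  if (any(drop)) {
    message(sum(drop), " person(s) excluded for missing self-rated health ",
            "or expenditures")
    persons <- persons[!drop, , drop = FALSE]
  }
  if (nrow(persons) == 0L) stop("dataset is empty after exclusions")

  if (nest)
    persons$psu <- paste(persons$stratum, persons$psu, sep = ".")
  persons$sex <- factor(as.character(persons$sex), levels = c("male", "female"))
  persons$race5 <- factor(as.character(persons$race5), levels = race5_levels())
  persons$srh <- as.integer(persons$srh)
  persons$cond <- as.integer(persons$cond)
  persons$poor_health <- dichotomize_health(persons$srh)
  persons$cond_count <- bit_count(persons$cond)
  # variance strata are (year, stratum) pairs so pooled years never share PSUs
  persons$vstratum <- paste(persons$year, persons$stratum, sep = ":")
  persons$vpsu <- paste(persons$vstratum, persons$psu, sep = ":")
  persons$analysis_weight <- persons$weight / pooled_years
  rownames(persons) <- NULL

  obj <- structure(list(persons = persons, catalog = catalog,
                        pooled_years = pooled_years),
                   class = "survey_dataset",
                   n_excluded = sum(drop))
  viol <- validate_dataset(obj)
  if (length(viol)) stop("invalid survey dataset:\n  ",
                         paste(viol, collapse = "\n  "))
  obj
}

#' Race/ethnicity levels
#'
#' The five-level race/ethnicity classification used for adjustment and
#' reporting; the first level, non-Hispanic white, is the regression
#' reference (the largest group in the target population).
#'
#' @return Character vector of 5 levels.
#' @export
race5_levels <- function() {
  c("NH-white", "Hispanic", "NH-black", "NH-Asian", "other/multiple")
}

#' @export
print.survey_dataset <- function(x, ...) {
  p <- x$persons
  cat("Survey dataset:", nrow(p), "persons,",
      length(unique(p$vstratum)), "strata,",
      length(unique(p$vpsu)), "PSUs\n")
  cat(sprintf("  pooled years: %d; annualized population: %.0f\n",
              x$pooled_years, sum(p$analysis_weight)))
  cat(sprintf("  multimorbidity (2+ conditions): %.1f%% weighted\n",
              100 * sum(p$analysis_weight * (p$cond_count >= 2)) /
                sum(p$analysis_weight)))
  invisible(x)
}

#' Validate a survey dataset
#'
#' Checks the container invariants and returns a character vector of
#' violations (empty when the dataset is well-formed).  This is a reporting
#' operation: it never modifies the data.
#'
#' Checked: non-negative weights; ages >= 18; srh in 1..5 with
#' \code{poor_health} equal to \code{srh \%in\% c(4, 5)}; non-negative
#' expenditures; condition masks within 20 bits; every PSU identifier
#' belonging to exactly one stratum; pooled_years >= 1.
#'
#' @param dataset A \code{survey_dataset}.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_dataset <- function(dataset) {
  p <- dataset$persons
  v <- character(0)
  if (nrow(p) == 0L) return("dataset has no persons")
  if (any(p$weight < 0, na.rm = TRUE)) v <- c(v, "negative person weights")
  if (any(p$age < 18, na.rm = TRUE)) v <- c(v, "ages below 18")
  bad_srh <- !(p$srh %in% 1:5)
  if (any(bad_srh)) v <- c(v, sprintf("%d srh values outside 1..5",
                                      sum(bad_srh)))
  if (!identical(as.logical(p$poor_health), p$srh %in% c(4L, 5L)))
    v <- c(v, "poor_health inconsistent with srh dichotomization")
  if (any(p$total_exp < 0 | p$oop_exp < 0, na.rm = TRUE))
    v <- c(v, "negative expenditures")
  if (any(p$cond < 0L | p$cond > 1048575L))
    v <- c(v, "condition masks outside 20-bit range")
  if (anyNA(p$sex)) v <- c(v, "unrecognized sex values")
  if (anyNA(p$race5)) v <- c(v, "unrecognized race/ethnicity values")
  # each raw PSU label may recur across strata only via the vpsu nesting;
  # check the *raw* ids: a psu id seen under two strata of the same year
  # indicates a design error
  key <- unique(p[, c("year", "stratum", "psu")])
  dup <- duplicated(key[, c("year", "psu")])
  if (any(dup)) {
    bad <- key[dup, ]
    v <- c(v, sprintf("PSU '%s' (year %s) appears in more than one stratum",
                      bad$psu[1], bad$year[1]))
  }
  if (dataset$pooled_years < 1L) v <- c(v, "pooled_years below 1")
  v
}

#' Dichotomize self-rated health
#'
#' Five-level self-rated health (1 excellent, 2 very good, 3 good, 4 fair,
#' 5 poor) is collapsed to the poor-health outcome: fair or poor counts as
#' poor perceived health.
#'
#' @param srh Integer vector with values in 1..5 (NA allowed; propagated).
#' @return Logical vector, TRUE iff srh is 4 or 5.
#' @export
#' @examples
#' dichotomize_health(c(1, 3, 4, 5))
dichotomize_health <- function(srh) {
  srh <- as.integer(srh)
  bad <- !is.na(srh) & !(srh %in% 1:5)
  if (any(bad))
    stop("self-rated health outside 1..5 at position(s) ",
         paste(which(bad), collapse = ", "))
  srh %in% c(4L, 5L) & !is.na(srh)
}

#' Adjust expenditures for inflation
#'
#' Multiplies an amount by the deflator that converts its survey year to
#' base-year (2019) dollars.  Total and out-of-pocket expenditures use
#' different price series (health PCE index and medical-care CPI
#' respectively); both are supplied as data, never computed here.  A
#' deflator table with every entry 1 is the identity, which is the default
#' for synthetic runs.
#'
#' @param amount Numeric vector of non-negative dollar amounts.
#' @param year Integer vector of survey years (recycled).
#' @param index_table Named numeric vector, year -> deflator to 2019 dollars;
#'   must satisfy \code{index_table["2019"] == 1} when 2019 is present.
#' @return Numeric vector in 2019 dollars.
#' @export
#' @examples
#' adjust_inflation(100, 2016, c("2016" = 1.05, "2019" = 1))
adjust_inflation <- function(amount, year, index_table) {
  if (any(amount < 0, na.rm = TRUE)) stop("negative expenditure amount")
  defl <- index_table[as.character(year)]
  if (anyNA(defl))
    stop("no deflator for year(s): ",
         paste(unique(year[is.na(defl)]), collapse = ", "))
  if ("2019" %in% names(index_table) &&
      abs(index_table[["2019"]] - 1) > 1e-12)
    stop("deflator for the 2019 base year must be 1")
  unname(amount * defl)
}

#' Annualize pooled survey weights
#'
#' Divides every base person weight by the number of pooled survey years so
#' that the weighted total estimates the single-year population rather than
#' person-years.  Pooling four years of a survey and dividing weights by four
#' is the standard convention for annualized national estimates.
#'
#' @param dataset A \code{survey_dataset} with \code{pooled_years} set.
#' @return The dataset with refreshed \code{analysis_weight}.
#' @export
annualize_weights <- function(dataset) {
  k <- dataset$pooled_years
  if (is.na(k) || k < 1L) stop("pooled_years must be >= 1")
  dataset$persons$analysis_weight <- dataset$persons$weight / k
  dataset
}

#' Read and write survey microdata
#'
#' The canonical on-disk format is a delimited text file with one row per
#' person, design and outcome columns as in \code{\link{survey_dataset}}, and
#' the 20 condition indicators as 0/1 columns \code{cond_1} .. \code{cond_20}
#' (ordered as the catalog).  Numeric fields are written with full precision
#' so a write/read round trip is bit-exact.
#'
#' Alternatively conditions may arrive as a long-format file of
#' \code{(person_id, icd10_3)} rows plus an ICD-10 mapping
#' (\code{\link{read_condition_map}}); codes that map to no category are
#' tallied and reported via a message.
#'
#' @param path File path.
#' @param catalog A \code{condition_catalog}.
#' @param pooled_years Passed to \code{\link{survey_dataset}}.
#' @param condition_file Optional path to a long-format condition file; when
#'   given, \code{cond_*} columns in the microdata are ignored.
#' @param sep Field separator ("," default).
#' @return \code{read_survey_data}: a \code{survey_dataset};
#'   \code{write_survey_data}: the path, invisibly.
#' @export
read_survey_data <- function(path, catalog = condition_catalog(),
                             pooled_years = 1L, condition_file = NULL,
                             sep = ",") {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!is.null(condition_file)) {
    long <- utils::read.table(condition_file, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE)
    if (!all(c("person_id", "icd10_3") %in% names(long)))
      stop("condition file needs columns person_id and icd10_3")
    masks <- rep(0L, nrow(tab))
    n_unmapped <- 0L
    split_codes <- split(long$icd10_3, long$person_id)
    pos <- match(names(split_codes), as.character(tab$person_id))
    for (i in seq_along(split_codes)) {
      if (is.na(pos[i])) next
      m <- map_icd_to_conditions(split_codes[[i]], catalog)
      n_unmapped <- n_unmapped + attr(m, "n_unmapped")
      masks[pos[i]] <- as.integer(m)
    }
    if (n_unmapped > 0L)
      message(n_unmapped, " condition code(s) mapped to no category")
    tab$cond <- masks
  } else if (!"cond" %in% names(tab)) {
    flag_cols <- paste0("cond_", 1:20)
    if (!all(flag_cols %in% names(tab)))
      stop("microdata must carry cond_1..cond_20 indicator columns, ",
           "a packed 'cond' column, or a long-format condition file")
    mask <- rep(0L, nrow(tab))
    for (c in 1:20)
      mask <- bitwOr(mask, bitwShiftL(as.integer(tab[[flag_cols[c]]] != 0),
                                      c - 1L))
    tab$cond <- mask
  }
  survey_dataset(tab, catalog, pooled_years)
}

#' @rdname read_survey_data
#' @param dataset A \code{survey_dataset} to serialize.
#' @export
write_survey_data <- function(dataset, path, sep = ",") {
  p <- dataset$persons
  out <- p[, c("person_id", "year", "stratum", "psu", "weight", "age",
               "sex", "race5", "srh", "total_exp", "oop_exp")]
  for (c in 1:20)
    out[[paste0("cond_", c)]] <-
      as.integer(bitwAnd(p$cond, bitwShiftL(1L, c - 1L)) != 0L)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
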