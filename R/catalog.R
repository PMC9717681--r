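#' The 20-category chronic-condition roster
#'
#' Returns the default ordered roster of 20 chronic-condition categories used
#' throughout the package.  The roster follows the primary-care multimorbidity
#' classification of Fortin and colleagues: conditions selected for relevance
#' to primary care, impact on patients, and prevalence among primary-care
#' users.  The order fixes the bit position of each condition in the packed
#' condition vector (bit 1 = first category).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' default_conditions()
default_conditions <- function() {
  c("hypertension", "hyperlipidemia", "diabetes", "arthritis",
    "cardiovascular disease", "heart failure", "asthma/COPD",
    "musculoskeletal disorder", "thyroid disorder", "stomach problem",
    "urinary problem", "anxiety/depression", "cancer", "kidney disease",
    "liver disease", "dementia", "osteoporosis", "stroke/TIA",
    "epilepsy", "substance use")
}

#' Construct a condition catalog
#'
#' A condition catalog holds the ordered roster of exactly 20 condition
#' categories plus a mapping from 3-character ICD-10-CM categories to roster
#' indices.  The roster is configurable but must contain exactly 20 unique
#' names; downstream code packs condition indicators into 20-bit integers.
#'
#' @param categories Character vector of exactly 20 unique condition names.
#' @param code_map Named integer vector mapping 3-character ICD-10-CM category
#'   strings (e.g. \code{"I10"}) to indices in \code{categories}, or a
#'   data.frame with columns \code{icd10_3} and \code{category_name}.  May be
#'   empty when microdata already carry condition flags.
#' @return An object of class \code{condition_catalog}.
#' @export
condition_catalog <- function(categories = default_conditions(),
                              code_map = integer(0)) {
  categories <- as.character(categories)
  if (length(categories) != 20L)
    stop("a condition catalog must contain exactly 20 categories, got ",
         length(categories))
  if (anyDuplicated(categories))
    stop("condition category names must be unique")
  if (is.data.frame(code_map)) {
    if (!all(c("icd10_3", "category_name") %in% names(code_map)))
      stop("code_map data.frame needs columns 'icd10_3' and 'category_name'")
    idx <- match(code_map$category_name, categories)
    if (anyNA(idx))
      stop("unknown category name(s) in code map: ",
           paste(unique(code_map$category_name[is.na(idx)]), collapse = ", "))
    code_map <- stats::setNames(idx, toupper(code_map$icd10_3))
  }
  code_map <- as.integer(code_map) |> stats::setNames(names(code_map))
  if (length(code_map) &&
      (any(code_map < 1L) || any(code_map > 20L) || anyNA(code_map)))
    stop("every mapped code must point to a category index in 1..20")
  structure(list(categories = categories, code_map = code_map),
            class = "condition_catalog")
}

#' @export
print.condition_catalog <- function(x, ...) {
  cat("Condition catalog: 20 categories,",
      length(x$code_map), "mapped ICD-10 codes\n")
  cat(paste(sprintf("%2d %s", 1:20, x$categories), collapse = "\n"), "\n")
  invisible(x)
}

#' Read an ICD-10 to condition-category mapping from TSV
#'
#' Reads a two-column tab-separated file (\code{icd10_3}, \code{category_name})
#' and builds a catalog.  The package ships a best-effort mapping in
#' \code{system.file("extdata", "icd10_condition_map.tsv", package = "svymine")}
#' approximating the Fortin 20-condition classification at the 3-character
#' ICD-10-CM level; the map is data, not code, and can be swapped for a
#' site-specific version.
#'
#' @param path Path to the TSV file.
#' @param categories Roster to map into; defaults to
#'   \code{default_conditions()}.
#' @return A \code{condition_catalog}.
#' @export
read_condition_map <- function(path, categories = default_conditions()) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  condition_catalog(categories, tab)
}

#' Map ICD-10-CM category codes to a 20-bit condition vector
#'
#' Sets bit \code{c} when any supplied code maps to category \code{c}.
#' Unmapped (but well-formed) codes are ignored and tallied; duplicate codes
#' have set semantics, so the operation is idempotent and order-invariant.
#'
#' @param codes Character vector of 3-character ICD-10-CM categories
#'   (one uppercase letter followed by two alphanumerics).  Longer codes are
#'   truncated to 3 characters before lookup, matching public-use files that
#'   release only 3-digit codes.
#' @param catalog A \code{condition_catalog} with a non-trivial code map.
#' @return Integer bitmask (bit i-1 set for category i) with attribute
#'   \code{n_unmapped}, the count of well-formed codes absent from the map.
#' @export
#' @examples
#' cat20 <- condition_catalog(code_map = c(I10 = 1L, E78 = 2L, E11 = 3L))
#' map_icd_to_conditions(c("E11", "E11", "I10"), cat20)
map_icd_to_conditions <- function(codes, catalog) {
  stopifnot(inherits(catalog, "condition_catalog"))
  codes <- toupper(substr(as.character(codes), 1L, 3L))
  bad <- !grepl("^[A-Z][A-Z0-9]{2}$", codes)
  if (any(bad))
    stop("malformed ICD-10 code(s) at position(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(codes[bad], collapse = ", "))
  idx <- catalog$code_map[codes]
  n_unmapped <- sum(is.na(idx) & !duplicated(codes))
  idx <- unique(idx[!is.na(idx)])
  mask <- 0L
  for (i in idx) mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
  structure(mask, n_unmapped = n_unmapped)
}

#' Convert between itemsets and bitmasks
#'
#' Internal helpers exposed because reports and tests refer to itemsets both
#' ways.  \code{itemset_mask} packs sorted condition indices into an integer;
#' \code{mask_to_items} unpacks.
#'
#' @param items Integer vector of condition indices in 1..20.
#' @return \code{itemset_mask}: an integer; \code{mask_to_items}: a sorted
#'   integer vector.
#' @export
itemset_mask <- function(items) {
  items <- as.integer(items)
  if (length(items) == 0L) stop("itemset must be non-empty")
  if (anyDuplicated(items) || any(items < 1L) || any(items > 20L))
    stop("itemset indices must be unique and in 1..20")
  mask <- 0L
  for (i in items) mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
  mask
}

#' @rdname itemset_mask
#' @param mask Integer bitmask.
#' @export
mask_to_items <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:19)) != 0L)
}

#' @rdname itemset_mask
#' @param catalog A \code{condition_catalog} supplying names.
#' @param sep Separator used between condition names.
#' @export
mask_to_label <- function(mask, catalog, sep = "|") {
  paste(catalog$categories[mask_to_items(mask)], collapse = sep)
}

# popcount over packed 20-bit condition vectors, vectorised
bit_count <- function(masks) {
  n <- integer(length(masks))
  for (b in 0:19) n <- n + (bitwAnd(masks, bitwShiftL(1L, b)) != 0L)
  n
}
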