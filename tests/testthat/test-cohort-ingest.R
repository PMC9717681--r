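test_that("ICD-10 codes map to condition bits with set semantics", {
  cat20 <- condition_catalog(code_map = c(I10 = 1L, E78 = 2L, E11 = 3L))

  m <- map_icd_to_conditions("I10", cat20)
  expect_identical(mask_to_items(m), 1L)
  expect_identical(attr(m, "n_unmapped"), 0L)

  m <- map_icd_to_conditions("Z99", cat20)
  expect_identical(as.integer(m), 0L)
  expect_identical(attr(m, "n_unmapped"), 1L)

  m <- map_icd_to_conditions(c("E11", "E11", "I10"), cat20)
  expect_identical(mask_to_items(m), c(1L, 3L))

  # idempotent and order-invariant
  m1 <- map_icd_to_conditions(c("I10", "E78", "E11"), cat20)
  m2 <- map_icd_to_conditions(c("E11", "I10", "E78", "I10"), cat20)
  expect_identical(as.integer(m1), as.integer(m2))

  expect_error(map_icd_to_conditions("1X", cat20), "malformed")
  # 4+ character codes are truncated to the 3-character category
  expect_identical(mask_to_items(map_icd_to_conditions("E11.9", cat20)), 3L)
})

test_that("the shipped ICD-10 map loads and covers all 20 categories", {
  path <- system.file("extdata", "icd10_condition_map.tsv",
                      package = "svymine")
  cat20 <- read_condition_map(path)
  expect_s3_class(cat20, "condition_catalog")
  expect_length(unique(cat20$code_map), 20L)
  expect_identical(mask_to_items(map_icd_to_conditions("I10", cat20)), 1L)
  expect_identical(mask_to_items(map_icd_to_conditions("J44", cat20)), 7L)
})

test_that("catalog invariants are enforced", {
  expect_error(condition_catalog(letters[1:19]), "exactly 20")
  expect_error(condition_catalog(rep("x", 20)), "unique")
  expect_error(condition_catalog(code_map = c(I10 = 25L)), "1..20")
})

test_that("self-rated health dichotomizes at fair-or-poor", {
  expect_false(dichotomize_health(3L))
  expect_true(dichotomize_health(4L))
  expect_false(dichotomize_health(1L))
  expect_identical(dichotomize_health(c(1, 4, 5, 2)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(dichotomize_health(6L), "1..5")
  expect_error(dichotomize_health(0L), "1..5")
})

test_that("inflation adjustment multiplies by the year deflator", {
  tab <- c("2016" = 1.05, "2017" = 1.03, "2019" = 1)
  expect_equal(adjust_inflation(100, 2019, tab), 100)
  expect_equal(adjust_inflation(100, 2016, tab), 105)
  expect_equal(adjust_inflation(0, 2017, tab), 0)
  expect_equal(adjust_inflation(c(100, 200), c(2016, 2017), tab),
               c(105, 206))
  expect_error(adjust_inflation(100, 2015, tab), "2015")
  expect_error(adjust_inflation(-5, 2019, tab), "negative")
})

test_that("weight annualization divides by pooled years exactly", {
  ds <- make_fixture("tiny_handcheck")
  ds$pooled_years <- 4L
  ds <- annualize_weights(ds)
  expect_identical(ds$persons$analysis_weight, ds$persons$weight / 4)
  expect_identical(sum(ds$persons$analysis_weight),
                   sum(ds$persons$weight) / 4)
  ds$pooled_years <- 1L
  ds <- annualize_weights(ds)
  expect_identical(ds$persons$analysis_weight, ds$persons$weight)
})

test_that("assembly excludes missing-outcome persons and validates design", {
  ds <- make_fixture("tiny_handcheck")
  expect_length(validate_dataset(ds), 0L)

  p <- ds$persons[, !(names(ds$persons) %in%
                        c("poor_health", "cond_count", "vstratum", "vpsu",
                          "analysis_weight"))]
  p$srh[3] <- NA
  expect_message(ds2 <- survey_dataset(p, ds$catalog, 1L), "1 person")
  expect_identical(nrow(ds2$persons), 7L)
  expect_identical(attr(ds2, "n_excluded"), 1L)

  # PSU label shared by two strata is a design violation unless nested
  p2 <- ds$persons
  p2$psu[5:6] <- 1L  # psu 1 now under stratum 1 and stratum 2
  ds$persons <- p2
  expect_match(paste(validate_dataset(ds), collapse = ";"),
               "more than one stratum")
  p3 <- make_fixture("tiny_handcheck")$persons
  p3$psu <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  ds3 <- survey_dataset(p3, condition_catalog(), 1L, nest = TRUE)
  expect_length(validate_dataset(ds3), 0L)
  expect_length(unique(ds3$persons$vpsu), 4L)
})

test_that("the canonical delimited format round-trips bit-exactly", {
  ds <- rand_dataset(n = 120L, k = 5L, seed = 42L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_data(ds, path)
  ds2 <- read_survey_data(path, ds$catalog, ds$pooled_years)
  for (col in c("weight", "age", "total_exp", "oop_exp", "cond", "srh",
                "stratum", "psu", "analysis_weight")) {
    expect_identical(ds2$persons[[col]], ds$persons[[col]], label = col)
  }
  expect_identical(as.character(ds2$persons$sex),
                   as.character(ds$persons$sex))
})

test_that("long-format condition files attach through the ICD map", {
  ds <- make_fixture("tiny_handcheck")
  base <- withr::local_tempfile(fileext = ".csv")
  write_survey_data(ds, base)
  condf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(person_id = c(2L, 4L, 4L, 4L, 6L),
                       icd10_3 = c("I10", "I10", "E78", "E11", "E78")),
            condf, row.names = FALSE)
  cat20 <- read_condition_map(system.file("extdata",
                                          "icd10_condition_map.tsv",
                                          package = "svymine"))
  ds2 <- read_survey_data(base, cat20, 1L, condition_file = condf)
  expect_identical(ds2$persons$cond,
                   c(0L, 1L, 0L, 7L, 0L, 2L, 0L, 0L))
})
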