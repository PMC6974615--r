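zero_config <- function(seed = 1) {
  generator_config(seed = seed, n_groups = 0, n_subtypes = 0, n_cancer = 0,
                   n_infectious = 0, n_poisoning = 0, n_nonpoint = 0,
                   n_unknown = 0, n_not_documented = 0, n_numeric = 0,
                   n_class_only = 0, n_case_report = 0, n_family_report = 0,
                   n_above_threshold = 0, n_usa_above_threshold = 0)
}

test_that("all-zero configuration yields an empty dataset and manifest", {
  d <- generate_epidemiology(zero_config())
  expect_equal(nrow(d$entities), 0)
  expect_equal(nrow(d$annotations), 0)
  expect_equal(nrow(d$manifest$dispositions), 0)
  expect_equal(d$manifest$bounds$min_per_100k, 0)
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  d1 <- generate_epidemiology(generator_config(seed = 99))
  d2 <- generate_epidemiology(generator_config(seed = 99))
  expect_identical(d1$entities, d2$entities)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$manifest$dispositions, d2$manifest$dispositions)
  d3 <- generate_epidemiology(generator_config(seed = 100))
  expect_false(identical(d1$annotations, d3$annotations))
})

test_that("generated counts match the configuration exactly", {
  cfg <- generator_config(seed = 4, n_groups = 5, n_subtypes = 7,
                          n_cancer = 3, n_infectious = 2, n_poisoning = 1,
                          n_nonpoint = 4, n_unknown = 2, n_not_documented = 3,
                          n_numeric = 6, n_class_only = 5, n_case_report = 8,
                          n_family_report = 2, n_above_threshold = 3,
                          n_usa_above_threshold = 2)
  d <- generate_epidemiology(cfg)
  disp <- d$manifest$dispositions
  expect_equal(nrow(d$entities), 53)
  expect_equal(sum(d$entities$level == "group"), 5)
  expect_equal(sum(d$entities$level == "subtype"), 7)
  expect_equal(sum(disp$disposition == "excluded_group_or_subtype"), 12)
  expect_equal(sum(disp$disposition == "excluded_incidence_domain"), 6)
  expect_equal(sum(disp$disposition == "excluded_nonpoint_indicator"), 4)
  expect_equal(sum(disp$disposition == "excluded_unknown_or_undocumented"), 5)
  expect_equal(sum(disp$disposition == "excluded_above_threshold"), 3)
  expect_equal(sum(disp$disposition == "excluded_no_eligible_geography"), 2)
  expect_equal(sum(disp$disposition == "included_numeric"), 6)
  expect_equal(sum(disp$disposition == "included_class"), 5)
  expect_equal(sum(disp$disposition == "included_case_report"), 8)
  expect_equal(sum(disp$disposition == "included_family_report"), 2)
})

test_that("manifest dispositions partition the generated entity set", {
  for (seed in c(1, 17, 23)) {
    d <- generate_epidemiology(generator_config(seed = seed))
    disp <- d$manifest$dispositions
    expect_setequal(disp$entity_id, d$entities$entity_id)
    expect_false(any(duplicated(disp$entity_id)))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_numeric = -1), "nonnegative")
  expect_error(generator_config(numeric_class_weights = c(lt_1_per_1M = 0.5)),
               "sum to 1")
  expect_error(generator_config(geography_profile = c(mars = 1)), "named")
  expect_error(published_scale_config(0), "positive")
  expect_error(published_scale_config(-2), "positive")
})

test_that("scaled configurations reproduce the reference composition", {
  cfg1 <- published_scale_config(1)
  included <- cfg1$n_numeric + cfg1$n_class_only + cfg1$n_case_report +
    cfg1$n_family_report
  expect_equal(included, 3585)
  expect_equal(cfg1$n_case_report, 2496)
  expect_equal(cfg1$n_family_report, 344)
  expect_equal(cfg1$n_cancer + cfg1$n_infectious + cfg1$n_poisoning, 868)

  cfg10 <- published_scale_config(1 / 10)
  included10 <- cfg10$n_numeric + cfg10$n_class_only + cfg10$n_case_report +
    cfg10$n_family_report
  expect_gte(included10, 358)
  expect_lte(included10, 359)
})

test_that("tenth-scale manifest group shares stay within a point of the reference", {
  d <- generate_epidemiology(published_scale_config(1 / 10, seed = 8))
  disp <- d$manifest$dispositions
  inc <- disp[grepl("^included", disp$disposition), ]
  share <- function(mask) sum(mask) / nrow(inc) * 100
  expect_lt(abs(share(inc$disposition %in%
                        c("included_numeric", "included_class")) - 20.8), 1)
  expect_lt(abs(share(inc$disposition == "included_case_report") - 69.6), 1)
  expect_lt(abs(share(inc$disposition == "included_family_report") - 9.6), 1)
})

test_that("case and family totals target the reference totals in expectation", {
  # at tenth scale the targets are 8,568 cases and 341.8 family reports;
  # geometric totals over 250 / 34 disorders have sd ~ 7% / 24% of the mean
  totals <- vapply(1:5, function(s) {
    m <- generate_epidemiology(published_scale_config(1 / 10, seed = s))$manifest
    c(m$total_cases, m$total_families)
  }, numeric(2))
  expect_lt(abs(mean(totals[1, ]) / 8568 - 1), 0.15)
  expect_lt(abs(mean(totals[2, ]) / 341.8 - 1), 0.35)
})

test_that("largest-remainder apportionment preserves scaled totals", {
  x <- c(a = 3, b = 3, c = 4)
  expect_equal(largest_remainder(x, 1), c(3L, 3L, 4L), ignore_attr = TRUE)
  y <- largest_remainder(c(745, 2496, 344), 1 / 10)
  expect_equal(sum(y), 359) # round_half_up(358.5)
  set.seed(41)
  for (i in 1:20) {
    v <- runif(5, 0, 100)
    s <- runif(1, 0.05, 2)
    out <- largest_remainder(v, s)
    expect_equal(sum(out), round_half_up(sum(v) * s))
    expect_true(all(out >= floor(v * s)))
  }
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(c(1.25, 1.15, 9.595, 20.78), 1),
               c(1.3, 1.2, 9.6, 20.8))
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(358.5), 359)
})
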