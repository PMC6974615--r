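test_that("a single numeric disorder yields one fully-loaded stratum", {
  led <- run_selection(ent(1), ann_num(1, 2))
  st <- stratify(led)
  expect_equal(nrow(st), 4)
  row <- st[st$class_label == "from_1_to_9_per_100k", ]
  expect_equal(row$n_diseases, 1L)
  expect_equal(row$share_diseases, 100)
  expect_equal(row$min_per_100k, 2)
  expect_equal(st$n_diseases[st$class_label != "from_1_to_9_per_100k"],
               rep(0L, 3))
})

test_that("strata conserve disease counts and bound components", {
  d <- generate_epidemiology(published_scale_config(1 / 20, seed = 2))
  led <- run_selection(d$entities, d$annotations)
  b <- cumulative_bounds(led)
  st <- stratify(led, b)
  expect_equal(sum(st$n_diseases),
               sum(grepl("^included", led$disposition)))
  expect_equal(sum(st$min_per_100k), b$min_per_100k)
  expect_equal(sum(st$max_per_100k), b$max_per_100k)
  # per-class counts equal the generator manifest exactly
  m <- d$manifest$per_class_counts
  expect_equal(st$n_diseases, m$n_diseases[match(st$class_label,
                                                 m$class_label)])
  # excluding the indirect component shrinks only the rarest class row
  st0 <- stratify(led, b, include_indirect = FALSE)
  expect_equal(sum(st0$min_per_100k) + b$indirect_per_100k, b$min_per_100k)
  expect_equal(st0$min_per_100k[-1], st$min_per_100k[-1])
})

test_that("the two most common classes dominate the patient burden", {
  # full published composition: the 1-9/100,000 and 1-5/10,000 classes carry
  # almost all of the patient burden despite holding few of the diseases
  d <- generate_epidemiology(published_scale_config(1, seed = 5))
  led <- run_selection(d$entities, d$annotations)
  st <- stratify(led)
  top <- st$class_label %in% c("from_1_to_9_per_100k", "from_1_to_5_per_10k")
  expect_lt(sum(st$share_diseases[top]), 15)
  expect_gt(sum(st$share_min[top]), 98)
  expect_gt(sum(st$share_max[top]), 98)
})

test_that("definition coverage is monotone and complete at the EU threshold", {
  d <- generate_epidemiology(published_scale_config(1 / 10, seed = 7))
  led <- run_selection(d$entities, d$annotations)
  cov <- definition_coverage(led, c(0.5, 5, 10, 50, 80))
  expect_true(all(diff(cov$share_diseases) >= 0))
  expect_true(all(diff(cov$share_burden_min) >= 0))
  expect_equal(cov$share_diseases[cov$threshold_per_100k == 50], 100)
  # a threshold at the 1-9/100,000 class boundary already covers the vast
  # majority of diseases, while dropping the most common class loses most
  # of the patients
  expect_gte(cov$share_diseases[cov$threshold_per_100k == 10], 90.5)
  expect_lt(cov$share_burden_max[cov$threshold_per_100k == 10], 40)
})

test_that("count-form definitions convert through the reference population", {
  us <- national_definition("USA", absolute_count = 200000,
                            reference_population = 232558140)
  expect_equal(round_half_up(us$threshold_per_100k, 0), 86)
  defs <- default_national_definitions()
  expect_equal(round_half_up(
    defs$threshold_per_100k[defs$name == "USA (2017 population)"], 1), 61.4)
  expect_error(national_definition("x"), "exactly one")
  expect_error(national_definition("x", threshold_per_100k = -5), "positive")
})

test_that("descriptive statistics summarise onset, genetic share, inheritance", {
  e <- disorder_entities(
    1:6,
    level = c(rep("disorder", 5), "group"),
    onset = c("pediatric", "pediatric", "adult pediatric", "adult", "", ""),
    genetic = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    inheritance = c("autosomal_dominant", "autosomal_dominant x_linked",
                    "", "", "", ""))
  d <- descriptive_stats(e)
  expect_equal(d$n_disorders, 5) # the group row is ignored
  expect_equal(d$onset$n_documented, 4)
  dist <- d$onset$distribution
  expect_equal(dist$n[dist$category == "pediatric_only"], 2L)
  expect_equal(dist$share[dist$category == "pediatric_only"], 50)
  expect_equal(d$genetic$n_genetic, 3)
  expect_equal(d$genetic$share, 60)
  inh <- d$inheritance
  expect_equal(inh$n[inh$tag == "autosomal_dominant"], 2L)
  expect_equal(inh$n[inh$tag == "x_linked"], 1L)
})

test_that("onset shares reproduce the published rounding convention", {
  expect_equal(round_half_up(3510 / 5018 * 100, 1), 69.9)
  e <- disorder_entities(1:3) # no onset documented anywhere
  d <- descriptive_stats(e)
  expect_true(d$onset$undefined)
  expect_equal(d$onset$n_documented, 0)
})

test_that("generator composition is recovered exactly from the entities", {
  d <- generate_epidemiology(published_scale_config(1 / 10, seed = 3))
  stats <- descriptive_stats(d$entities)
  comp <- d$manifest$composition
  expect_equal(stats$n_disorders, comp$n_disorder_level)
  expect_equal(stats$onset$n_documented, comp$n_onset_documented)
  dist <- stats$onset$distribution
  expect_equal(dist$n[dist$category == "pediatric_only"],
               comp$n_onset_pediatric_only)
  expect_equal(dist$n[dist$category == "mixed"], comp$n_onset_both)
  expect_equal(stats$genetic$n_genetic, comp$n_genetic)
  expect_equal(stats$inheritance$n, comp$inheritance_counts$n)
})

test_that("reports are deterministic and carry the computed bounds", {
  d <- generate_epidemiology(generator_config(seed = 14))
  led <- run_selection(d$entities, d$annotations)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- render_report(led, dir1, entities = d$entities)
  p2 <- render_report(led, dir2, entities = d$entities)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = f)
  }
  b <- cumulative_bounds(led)
  narrative <- readLines(p1[["narrative"]])
  expect_true(any(grepl(sprintf("%.1f - %.1f per 100,000",
                                round_half_up(b$min_per_100k, 1),
                                round_half_up(b$max_per_100k, 1)),
                        narrative, fixed = TRUE)))
  js <- jsonlite::read_json(p1[["summary"]])
  expect_equal(js$min_per_100k, round_half_up(b$min_per_100k, 1))
  expect_equal(js$total_cases, b$total_cases)
  # empty ledger still renders a valid report
  led0 <- run_selection(disorder_entities(integer()),
                        epidemiology_annotations(integer()))
  p0 <- render_report(led0, withr::local_tempdir())
  expect_true(all(file.exists(p0)))
})

test_that("autoplot methods return ggplot objects", {
  d <- generate_epidemiology(generator_config(seed = 16))
  led <- run_selection(d$entities, d$annotations)
  expect_s3_class(autoplot(stratify(led)), "ggplot")
  expect_s3_class(autoplot(cumulative_bounds(led)), "ggplot")
})
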