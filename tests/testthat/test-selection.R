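test_that("entity-level filter keeps only disorders", {
  e <- disorder_entities(1:3, level = c("disorder", "group", "subtype"))
  out <- filter_entity_level(e)
  expect_equal(out$kept$entity_id, 1L)
  expect_equal(out$excluded$disposition, rep("excluded_group_or_subtype", 2))

  all_groups <- filter_entity_level(disorder_entities(1:2, level = "group"))
  expect_equal(nrow(all_groups$kept), 0)
})

test_that("incidence-described domains are excluded, genetic disorders kept", {
  e <- disorder_entities(1:4,
                         cancer = c(TRUE, FALSE, FALSE, FALSE),
                         infectious_disease = c(FALSE, TRUE, FALSE, FALSE),
                         poisoning = c(FALSE, FALSE, TRUE, FALSE),
                         genetic = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_incidence_domains(e)
  expect_equal(out$kept$entity_id, 4L)
  expect_equal(out$excluded$disposition, rep("excluded_incidence_domain", 3))
})

test_that("geographic preference picks worldwide over europe over usa", {
  a <- dplyr::bind_rows(
    ann_num(1, 2.0, "France"),
    ann_cls(1, "from_1_to_9_per_100k", "Worldwide"))
  got <- select_preferred_annotation(1, a)
  expect_equal(got$geography, "worldwide")
  expect_equal(got$value_kind, "class")
  expect_equal(got$class_label, "from_1_to_9_per_100k")

  b <- dplyr::bind_rows(ann_num(2, 3, "United States"),
                        ann_num(2, 7, "Iceland"))
  got <- select_preferred_annotation(2, b)
  expect_equal(got$geography, "europe")
  expect_equal(got$numeric_value, 7)
})

test_that("a lone USA figure is eligible only under the rarity threshold", {
  over <- select_preferred_annotation(1, ann_num(1, 80, "United States"))
  expect_equal(over$disposition, "excluded_no_eligible_geography")
  under <- select_preferred_annotation(1, ann_num(1, 30, "United States"))
  expect_equal(under$disposition, "chosen")
  expect_equal(under$numeric_value, 30)
  # class-form USA records are judged by the class minimum boundary
  cls_ok <- select_preferred_annotation(1,
    ann_cls(1, "from_1_to_5_per_10k", "United States"))
  expect_equal(cls_ok$disposition, "chosen")
  cls_over <- select_preferred_annotation(1,
    ann_cls(1, "from_6_to_9_per_10k", "United States"))
  expect_equal(cls_over$disposition, "excluded_no_eligible_geography")
})

test_that("case-report-only disorders are retained in the rarest class", {
  got <- select_preferred_annotation(1, ann_cnt(1, 3L))
  expect_equal(got$disposition, "included_case_report")
  expect_equal(got$class_label, "lt_1_per_1M")
  expect_equal(got$count_value, 3L)
  fam <- select_preferred_annotation(2, ann_cnt(2, 5L, "family_report"))
  expect_equal(fam$disposition, "included_family_report")
})

test_that("within a tier numerics outrank classes and tier means are used", {
  a <- dplyr::bind_rows(
    ann_num(1, 2, "France"), ann_num(1, 4, "Germany"),
    ann_cls(1, "from_1_to_5_per_10k", "Italy"))
  got <- select_preferred_annotation(1, a)
  expect_equal(got$value_kind, "numeric")
  expect_equal(got$numeric_value, 3) # mean of 2 and 4
  # class-only ties: most frequent class, then the lower class
  b <- dplyr::bind_rows(
    ann_cls(2, "from_1_to_9_per_100k", "France"),
    ann_cls(2, "from_1_to_9_per_100k", "Spain"),
    ann_cls(2, "from_1_to_5_per_10k", "Italy"))
  expect_equal(select_preferred_annotation(2, b)$class_label,
               "from_1_to_9_per_100k")
  c2 <- dplyr::bind_rows(
    ann_cls(3, "from_1_to_9_per_1M", "France"),
    ann_cls(3, "from_1_to_9_per_100k", "Spain"))
  expect_equal(select_preferred_annotation(3, c2)$class_label,
               "from_1_to_9_per_1M")
})

test_that("the rarity threshold excludes strictly above 50 per 100,000", {
  chosen <- dplyr::bind_rows(
    select_preferred_annotation(1, ann_num(1, 50)),
    select_preferred_annotation(2, ann_num(2, 50.1)),
    select_preferred_annotation(3, ann_cls(3, "from_6_to_9_per_10k")),
    select_preferred_annotation(4, ann_cls(4, "gt_1_per_1k")))
  out <- filter_rarity_threshold(chosen)
  expect_equal(out$kept$entity_id, 1L)
  expect_equal(out$excluded$entity_id, 2:4)
  expect_equal(unique(out$excluded$disposition), "excluded_above_threshold")
})

test_that("the worked six-entity example resolves as documented", {
  e <- dplyr::bind_rows(
    ent(1, level = "group"),
    ent(2, cancer = TRUE),
    ent(3), # annual incidence only
    ent(4), # USA figure above threshold
    ent(5), # worldwide numeric
    ent(6)) # case reports only
  a <- dplyr::bind_rows(
    ann_num(1, 5, "Worldwide"),
    ann_num(2, 1, "Worldwide", indicator = "annual_incidence"),
    ann_num(3, 2, "Worldwide", indicator = "annual_incidence"),
    ann_num(4, 80, "United States"),
    ann_num(5, 2.5, "Worldwide"),
    ann_cnt(6, 4L))
  led <- run_selection(e, a)
  expect_equal(led$disposition,
               c("excluded_group_or_subtype", "excluded_incidence_domain",
                 "excluded_nonpoint_indicator",
                 "excluded_no_eligible_geography", "included_numeric",
                 "included_case_report"))
  expect_equal(sum(grepl("^included", led$disposition)), 2)
})

test_that("selection is a partition, order-independent, and idempotent", {
  withr::local_seed(202)
  for (rep in 1:10) {
    d <- random_dataset(sample(5:20, 1))
    led <- run_selection(d$entities, d$annotations)
    # partition
    expect_setequal(led$entity_id, d$entities$entity_id)
    expect_false(any(duplicated(led$entity_id)))
    # order-independence
    perm_a <- d$annotations
    if (nrow(perm_a) > 0) perm_a <- perm_a[sample(nrow(perm_a)), ]
    perm <- run_selection(d$entities[sample(nrow(d$entities)), ], perm_a)
    expect_equal(perm, led)
    # idempotence on the included subset
    inc <- led$entity_id[grepl("^included", led$disposition)]
    if (length(inc) > 0) {
      led2 <- run_selection(
        d$entities[d$entities$entity_id %in% inc, ],
        d$annotations[d$annotations$entity_id %in% inc, ])
      expect_equal(led2$disposition,
                   led$disposition[match(led2$entity_id, led$entity_id)])
    }
  }
})

test_that("adding a worldwide annotation never excludes an included disorder", {
  withr::local_seed(303)
  for (rep in 1:10) {
    d <- random_dataset(10)
    led <- run_selection(d$entities, d$annotations)
    inc <- led$entity_id[grepl("^included", led$disposition)]
    if (length(inc) == 0) next
    id <- inc[1]
    extra <- ann_num(id, runif(1, 0.05, 45), "Worldwide")
    led2 <- run_selection(d$entities,
                          dplyr::bind_rows(d$annotations, extra))
    expect_true(grepl("^included",
                      led2$disposition[led2$entity_id == id]))
  }
})

test_that("selection matches the brute-force oracle on random small datasets", {
  withr::local_seed(404)
  for (rep in 1:40) {
    d <- random_dataset(sample(2:20, 1))
    led <- run_selection(d$entities, d$annotations)
    ora <- oracle_selection(d$entities, d$annotations)
    expect_equal(led$disposition, ora$disposition,
                 info = sprintf("rep %d", rep))
    num <- led$disposition == "included_numeric"
    expect_equal(led$numeric_value[num], ora$numeric_value[num])
    cls <- led$disposition == "included_class"
    expect_equal(led$class_label[cls], ora$class_label[cls])
  }
})

test_that("pipeline dispositions equal the generator manifest", {
  for (seed in c(3, 12)) {
    d <- generate_epidemiology(generator_config(seed = seed))
    led <- run_selection(d$entities, d$annotations)
    m <- dplyr::arrange(d$manifest$dispositions, entity_id)
    expect_equal(led$disposition, m$disposition)
    expect_equal(led$evidence_group, m$evidence_group)
  }
})

test_that("disposition summary counts every bucket", {
  d <- generate_epidemiology(generator_config(seed = 6))
  led <- run_selection(d$entities, d$annotations)
  s <- summarise_dispositions(led)
  expect_equal(nrow(s), 10)
  expect_equal(sum(s$n_entities), nrow(d$entities))
})
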