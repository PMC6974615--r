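# reference composition used by published_scale_config(); the included groups
# (numeric/class/case/family) reproduce the published snapshot composition,
# the contaminant counts are the package's fixed emulation of the rest of the
# file (see the methods vignette for the derivation)
published_composition <- function() {
  c(groups = 200, subtypes = 300,
    cancer = 684, infectious = 159, poisoning = 25,
    nonpoint = 600, unknown = 560, not_documented = 559,
    numeric = 372, class_only = 373,
    case_report = 2496, family_report = 344)
}

# per-class composition of the 745 numeric-or-class disorders, derived from
# the published per-class disease counts
published_class_weights <- function() {
  c(lt_1_per_1M = 189, from_1_to_9_per_1M = 166,
    from_1_to_9_per_100k = 241, from_1_to_5_per_10k = 149) / 745
}

#' Synthetic-data generator configuration
#'
#' Defines the composition of a synthetic epidemiology knowledge file: how
#' many contaminating records of each kind (groups, subtypes,
#' incidence-domain disorders, non-point indicators, unknown and
#' not-documented entries, above-threshold disorders, USA-only
#' above-threshold disorders) and how many includable disorders of each
#' evidence group (numeric value, class only, case reports, family reports),
#' together with the sampling distributions. All randomness is driven by a
#' single seeded stream, recorded in the manifest.
#'
#' @param seed Integer seed for the dataset's random stream.
#' @param n_groups,n_subtypes Number of group / subtype contaminant entities.
#' @param n_cancer,n_infectious,n_poisoning Incidence-domain disorders.
#' @param n_nonpoint Disorders annotated only with birth prevalence,
#'   lifetime prevalence or annual incidence.
#' @param n_unknown,n_not_documented Disorders whose point prevalence is
#'   recorded as unknown / not yet documented.
#' @param n_numeric Disorders with a numeric point-prevalence value.
#' @param n_class_only Disorders with a prevalence class only.
#' @param n_case_report,n_family_report Disorders known only from case /
#'   family reports.
#' @param n_above_threshold Disorders whose chosen evidence exceeds the
#'   rarity threshold (to be excluded).
#' @param n_usa_above_threshold Disorders whose only figure is a USA figure
#'   above the threshold (no eligible geography).
#' @param numeric_class_weights,class_only_weights Named probabilities over
#'   the four includable classes; default from the published composition.
#' @param case_count_mean,family_count_mean Mean of the 1-shifted geometric
#'   distribution of per-disorder case / family counts; defaults match the
#'   published totals (85,680 cases over 2,496 disorders; 3,418 families
#'   over 344).
#' @param geography_profile Named probabilities of geographic annotation
#'   patterns for included disorders: `worldwide`, `europe`, `usa` (single
#'   record) and `worldwide_europe`, `europe_usa` (preferred record plus a
#'   decoy in a lower-preference tier).
#' @param p_other_decoy Probability of an extra other-geography decoy record
#'   on an included disorder.
#' @param p_genetic Probability that a disorder-level entity is genetic.
#' @param p_onset Probability that age of onset is documented.
#' @param onset_weights Named probabilities over `pediatric`, `both`,
#'   `adult` given onset is documented.
#' @param p_inherit_one,p_inherit_multi Probability that a genetic disorder
#'   carries exactly one / more than one inheritance tag.
#' @param inheritance_weights Named sampling weights over inheritance tags.
#' @param population Population figure for the manifest's indirect estimate.
#' @return A validated `generator_config` list.
#' @seealso [published_scale_config()], [generate_epidemiology()]
#' @export
generator_config <- function(seed = 1L,
                             n_groups = 3, n_subtypes = 4,
                             n_cancer = 4, n_infectious = 2, n_poisoning = 1,
                             n_nonpoint = 4,
                             n_unknown = 3, n_not_documented = 3,
                             n_numeric = 8, n_class_only = 8,
                             n_case_report = 10, n_family_report = 4,
                             n_above_threshold = 2,
                             n_usa_above_threshold = 2,
                             numeric_class_weights = published_class_weights(),
                             class_only_weights = published_class_weights(),
                             case_count_mean = 85680 / 2496,
                             family_count_mean = 3418 / 344,
                             geography_profile = c(worldwide = 0.35,
                                                   europe = 0.35,
                                                   usa = 0.10,
                                                   worldwide_europe = 0.12,
                                                   europe_usa = 0.08),
                             p_other_decoy = 0.1,
                             p_genetic = 0.719,
                             p_onset = 0.813,
                             onset_weights = c(pediatric = 0.699,
                                               both = 0.182, adult = 0.119),
                             p_inherit_one = 0.724,
                             p_inherit_multi = 0.073,
                             inheritance_weights = c(
                               autosomal_dominant = 0.30,
                               autosomal_recessive = 0.30,
                               x_linked = 0.10, mitochondrial = 0.03,
                               chromosomal = 0.10,
                               multigenic_multifactorial = 0.07,
                               unknown = 0.07, not_applicable = 0.03),
                             population = world_population_2017()) {
  cfg <- list(seed = as.integer(seed),
              n_groups = n_groups, n_subtypes = n_subtypes,
              n_cancer = n_cancer, n_infectious = n_infectious,
              n_poisoning = n_poisoning, n_nonpoint = n_nonpoint,
              n_unknown = n_unknown, n_not_documented = n_not_documented,
              n_numeric = n_numeric, n_class_only = n_class_only,
              n_case_report = n_case_report,
              n_family_report = n_family_report,
              n_above_threshold = n_above_threshold,
              n_usa_above_threshold = n_usa_above_threshold,
              numeric_class_weights = numeric_class_weights,
              class_only_weights = class_only_weights,
              case_count_mean = case_count_mean,
              family_count_mean = family_count_mean,
              geography_profile = geography_profile,
              p_other_decoy = p_other_decoy,
              p_genetic = p_genetic, p_onset = p_onset,
              onset_weights = onset_weights,
              p_inherit_one = p_inherit_one,
              p_inherit_multi = p_inherit_multi,
              inheritance_weights = inheritance_weights,
              population = population)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  count_fields <- grep("^n_", names(cfg), value = TRUE)
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 ||
        v != floor(v)) {
      abort(sprintf("generator config: %s must be a nonnegative integer", f))
    }
  }
  check_weights <- function(w, name, vocab) {
    if (is.null(names(w)) || length(setdiff(names(w), vocab)) > 0) {
      abort(sprintf("generator config: %s must be named among %s",
                    name, paste(vocab, collapse = ", ")))
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
      abort(sprintf("generator config: %s must be nonnegative and sum to 1",
                    name))
    }
  }
  check_weights(cfg$numeric_class_weights, "numeric_class_weights",
                includable_classes())
  check_weights(cfg$class_only_weights, "class_only_weights",
                includable_classes())
  check_weights(cfg$geography_profile, "geography_profile",
                c("worldwide", "europe", "usa", "worldwide_europe",
                  "europe_usa"))
  check_weights(cfg$onset_weights, "onset_weights",
                c("pediatric", "both", "adult"))
  if (cfg$case_count_mean < 1 || cfg$family_count_mean < 1) {
    abort("generator config: count means must be >= 1")
  }
  if (cfg$p_inherit_one + cfg$p_inherit_multi > 1) {
    abort("generator config: inheritance tag probabilities exceed 1")
  }
  invisible(cfg)
}

#' Generator configuration emulating the published composition at scale
#'
#' Returns a [generator_config()] whose expected composition equals the
#' published file composition multiplied by `scale`, with counts rounded to
#' integers by the largest-remainder method so the grand total is preserved.
#' At scale 1 the included disorders number 372 + 373 + 2496 + 344 = 3585.
#' The snapshot's arithmetic implies no above-threshold exclusions, so those
#' contaminant counts are zero here (the generic [generator_config()]
#' default exercises them).
#'
#' @param scale Positive scaling factor (e.g. `1/10` for a tenth-scale
#'   dataset).
#' @param seed Integer seed.
#' @return A `generator_config`.
#' @examples
#' cfg <- published_scale_config(1 / 10)
#' cfg$n_case_report # about a tenth of 2,496
#' @export
published_scale_config <- function(scale = 1, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    abort("scale must be a single positive number")
  }
  base <- published_composition()
  n <- largest_remainder(base, scale)
  names(n) <- names(base)
  generator_config(
    seed = seed,
    n_groups = n[["groups"]], n_subtypes = n[["subtypes"]],
    n_cancer = n[["cancer"]], n_infectious = n[["infectious"]],
    n_poisoning = n[["poisoning"]], n_nonpoint = n[["nonpoint"]],
    n_unknown = n[["unknown"]], n_not_documented = n[["not_documented"]],
    n_numeric = n[["numeric"]], n_class_only = n[["class_only"]],
    n_case_report = n[["case_report"]],
    n_family_report = n[["family_report"]],
    n_above_threshold = 0, n_usa_above_threshold = 0
  )
}

# 1-shifted geometric counts with a given mean, capped to keep totals finite
draw_counts <- function(n, mean) {
  if (n == 0) return(integer())
  pmin(1L + rgeom(n, 1 / mean), 100000L)
}

# log-uniform draw within a class interval (open enough at boundaries that
# class assignment of the drawn value recovers the drawn class)
draw_numeric_in_class <- function(class_label) {
  lo <- c(lt_1_per_1M = 0.01, from_1_to_9_per_1M = 0.1,
          from_1_to_9_per_100k = 1, from_1_to_5_per_10k = 10)[class_label]
  hi <- c(lt_1_per_1M = 0.0999, from_1_to_9_per_1M = 0.9,
          from_1_to_9_per_100k = 9, from_1_to_5_per_10k = 50)[class_label]
  exp(runif(length(class_label), log(lo), log(hi)))
}

europe_labels <- function() {
  c("Europe", "France", "Germany", "Italy", "Spain", "United Kingdom",
    "Iceland", "Turkey")
}
other_labels <- function() c("Japan", "China", "Brazil", "Australia")

#' Generate a synthetic epidemiology knowledge file
#'
#' Produces a seeded synthetic dataset with the statistical structure of a
#' real epidemiology knowledge file — includable disorders described by
#' numeric values, prevalence classes, or case/family reports, mixed with
#' every contaminant the selection cascade must remove — together with a
#' ground-truth manifest. The manifest's dispositions, per-class counts,
#' case/family totals and cumulative bounds are computed by direct
#' construction while generating, never by running the selection or
#' aggregation code, so they serve as an independent oracle for
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return A list with `entities`, `annotations` and `manifest`. The
#'   manifest holds `seed`, `dispositions` (tibble: `entity_id`,
#'   `disposition`, `evidence_group`, `class_label`, `numeric_value`,
#'   `count_value`), `per_class_counts`, `total_cases`, `total_families`,
#'   `bounds` (components and min/max per 100,000), and `composition`
#'   (onset/genetic/inheritance counts among disorder-level entities).
#' @examples
#' d <- generate_epidemiology(generator_config(seed = 42))
#' nrow(d$entities)
#' d$manifest$bounds$min_per_100k
#' @export
generate_epidemiology <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  rows_e <- list()  # entity rows
  rows_a <- list()  # annotation rows
  rows_m <- list()  # manifest disposition rows
  next_id <- 0L
  new_ids <- function(n) {
    ids <- next_id + seq_len(n)
    next_id <<- next_id + n
    as.integer(ids)
  }

  add_entities <- function(ids, level, cancer = FALSE, infectious = FALSE,
                           poisoning = FALSE, prefix = "Synthetic disorder") {
    if (length(ids) == 0) return()
    rows_e[[length(rows_e) + 1]] <<- tibble(
      entity_id = ids, name = sprintf("%s %05d", prefix, ids),
      level = level, cancer = cancer, infectious_disease = infectious,
      poisoning = poisoning, genetic = FALSE, onset = "", inheritance = "")
  }
  add_ann <- function(entity_id, indicator, value_kind,
                      numeric_value = NA_real_, class_label = NA_character_,
                      count_value = NA_integer_, geography_raw = "Worldwide",
                      geography = NULL) {
    if (length(entity_id) == 0) return()
    if (is.null(geography)) {
      geography <- normalize_geography(geography_raw, quiet = TRUE)
    }
    rows_a[[length(rows_a) + 1]] <<- tibble(
      entity_id = as.integer(entity_id), indicator = indicator,
      value_kind = value_kind, numeric_value = as.numeric(numeric_value),
      class_label = as.character(class_label),
      count_value = as.integer(count_value),
      geography_raw = geography_raw, geography = geography)
  }
  add_manifest <- function(ids, disposition, evidence_group = NA_character_,
                           class_label = NA_character_,
                           numeric_value = NA_real_,
                           count_value = NA_integer_) {
    if (length(ids) == 0) return()
    rows_m[[length(rows_m) + 1]] <<- tibble(
      entity_id = as.integer(ids), disposition = disposition,
      evidence_group = evidence_group, class_label = class_label,
      numeric_value = as.numeric(numeric_value),
      count_value = as.integer(count_value))
  }

  # --- contaminants -------------------------------------------------------
  ids <- new_ids(cfg$n_groups)
  add_entities(ids, "group", prefix = "Synthetic group")
  with_decoy <- ids[runif(length(ids)) < 0.7]
  add_ann(with_decoy, "point_prevalence", "numeric",
          numeric_value = exp(runif(length(with_decoy), log(0.01), log(50))))
  add_manifest(ids, "excluded_group_or_subtype")

  ids <- new_ids(cfg$n_subtypes)
  add_entities(ids, "subtype", prefix = "Synthetic subtype")
  with_decoy <- ids[runif(length(ids)) < 0.7]
  add_ann(with_decoy, "point_prevalence", "numeric",
          numeric_value = exp(runif(length(with_decoy), log(0.01), log(50))))
  add_manifest(ids, "excluded_group_or_subtype")

  for (dom in c("cancer", "infectious", "poisoning")) {
    n <- cfg[[paste0("n_", dom)]]
    ids <- new_ids(n)
    add_entities(ids, "disorder", cancer = dom == "cancer",
                 infectious = dom == "infectious",
                 poisoning = dom == "poisoning")
    add_ann(ids, "annual_incidence", "numeric",
            numeric_value = exp(runif(n, log(0.01), log(20))))
    add_manifest(ids, "excluded_incidence_domain")
  }

  ids <- new_ids(cfg$n_nonpoint)
  add_entities(ids, "disorder")
  if (length(ids) > 0) {
    add_ann(ids,
            sample(c("birth_prevalence", "lifetime_prevalence",
                     "annual_incidence"), length(ids), replace = TRUE),
            "numeric",
            numeric_value = exp(runif(length(ids), log(0.01), log(50))))
  }
  add_manifest(ids, "excluded_nonpoint_indicator")

  ids <- new_ids(cfg$n_unknown)
  add_entities(ids, "disorder")
  add_ann(ids, "point_prevalence", "unknown")
  add_manifest(ids, "excluded_unknown_or_undocumented")

  ids <- new_ids(cfg$n_not_documented)
  add_entities(ids, "disorder")
  add_ann(ids, "point_prevalence", "not_documented")
  add_manifest(ids, "excluded_unknown_or_undocumented")

  ids <- new_ids(cfg$n_above_threshold)
  add_entities(ids, "disorder")
  if (length(ids) > 0) {
    geo <- sample(c("Worldwide", "Europe"), length(ids), replace = TRUE)
    as_class <- runif(length(ids)) < 0.5
    add_ann(ids[!as_class], "point_prevalence", "numeric",
            numeric_value = runif(sum(!as_class), 55, 300),
            geography_raw = geo[!as_class])
    add_ann(ids[as_class], "point_prevalence", "class",
            class_label = sample(c("from_6_to_9_per_10k", "gt_1_per_1k"),
                                 sum(as_class), replace = TRUE),
            geography_raw = geo[as_class])
  }
  add_manifest(ids, "excluded_above_threshold")

  ids <- new_ids(cfg$n_usa_above_threshold)
  add_entities(ids, "disorder")
  add_ann(ids, "point_prevalence", "numeric",
          numeric_value = runif(length(ids), 55, 300),
          geography_raw = rep("United States", length(ids)))
  add_manifest(ids, "excluded_no_eligible_geography")

  # --- included disorders -------------------------------------------------
  place_geography <- function(ids, kind, value = NULL, class_label = NULL) {
    # one annotation in the chosen (preferred) tier plus decoys in strictly
    # lower-preference tiers so geography preference is actually exercised
    if (length(ids) == 0) return()
    pattern <- sample(names(cfg$geography_profile), length(ids),
                      replace = TRUE, prob = cfg$geography_profile)
    chosen_tier <- c(worldwide = "worldwide", europe = "europe", usa = "usa",
                     worldwide_europe = "worldwide", europe_usa = "europe")[pattern]
    raw_for <- function(tier) {
      out <- character(length(tier))
      out[tier == "worldwide"] <- "Worldwide"
      out[tier == "usa"] <- "United States"
      n_eu <- sum(tier == "europe")
      out[tier == "europe"] <- sample(europe_labels(), n_eu, replace = TRUE)
      out
    }
    if (kind == "numeric") {
      add_ann(ids, "point_prevalence", "numeric", numeric_value = value,
              geography_raw = raw_for(chosen_tier))
    } else {
      add_ann(ids, "point_prevalence", "class", class_label = class_label,
              geography_raw = raw_for(chosen_tier))
    }
    decoy_tier <- c(worldwide = NA, europe = NA, usa = NA,
                    worldwide_europe = "europe", europe_usa = "usa")[pattern]
    has_decoy <- !is.na(decoy_tier)
    if (any(has_decoy)) {
      d_ids <- ids[has_decoy]
      d_tier <- decoy_tier[has_decoy]
      d_numeric <- runif(length(d_ids)) < 0.5
      add_ann(d_ids[d_numeric], "point_prevalence", "numeric",
              numeric_value = exp(runif(sum(d_numeric), log(0.01), log(50))),
              geography_raw = raw_for(d_tier[d_numeric]))
      add_ann(d_ids[!d_numeric], "point_prevalence", "class",
              class_label = sample(includable_classes(), sum(!d_numeric),
                                   replace = TRUE),
              geography_raw = raw_for(d_tier[!d_numeric]))
    }
    other <- ids[runif(length(ids)) < cfg$p_other_decoy]
    if (length(other) > 0) {
      add_ann(other, "point_prevalence", "numeric",
              numeric_value = exp(runif(length(other), log(0.01), log(50))),
              geography_raw = sample(other_labels(), length(other),
                                     replace = TRUE))
    }
    invisible(chosen_tier)
  }

  ids_num <- new_ids(cfg$n_numeric)
  add_entities(ids_num, "disorder")
  num_class <- character()
  num_value <- numeric()
  if (length(ids_num) > 0) {
    num_class <- sample(names(cfg$numeric_class_weights), length(ids_num),
                        replace = TRUE, prob = cfg$numeric_class_weights)
    num_value <- draw_numeric_in_class(num_class)
    place_geography(ids_num, "numeric", value = num_value)
  }
  add_manifest(ids_num, "included_numeric", "numeric",
               class_label = num_class, numeric_value = num_value)

  ids_cls <- new_ids(cfg$n_class_only)
  add_entities(ids_cls, "disorder")
  cls_class <- character()
  if (length(ids_cls) > 0) {
    cls_class <- sample(names(cfg$class_only_weights), length(ids_cls),
                        replace = TRUE, prob = cfg$class_only_weights)
    place_geography(ids_cls, "class", class_label = cls_class)
  }
  add_manifest(ids_cls, "included_class", "class", class_label = cls_class)

  ids_case <- new_ids(cfg$n_case_report)
  add_entities(ids_case, "disorder")
  case_counts <- draw_counts(cfg$n_case_report, cfg$case_count_mean)
  add_ann(ids_case, "case_report", "count", count_value = case_counts)
  add_manifest(ids_case, "included_case_report", "case",
               class_label = "lt_1_per_1M", count_value = case_counts)

  ids_fam <- new_ids(cfg$n_family_report)
  add_entities(ids_fam, "disorder")
  fam_counts <- draw_counts(cfg$n_family_report, cfg$family_count_mean)
  add_ann(ids_fam, "family_report", "count", count_value = fam_counts)
  add_manifest(ids_fam, "included_family_report", "family",
               class_label = "lt_1_per_1M", count_value = fam_counts)

  # --- entity attributes (onset / genetic / inheritance) ------------------
  entities <- if (length(rows_e) > 0) bind_rows(rows_e) else
    disorder_entities(integer())
  is_dis <- entities$level == "disorder"
  n_dis <- sum(is_dis)
  if (n_dis > 0) {
    genetic <- runif(n_dis) < cfg$p_genetic
    entities$genetic[is_dis] <- genetic
    documented <- runif(n_dis) < cfg$p_onset
    onset_kind <- rep(NA_character_, n_dis)
    onset_kind[documented] <- sample(names(cfg$onset_weights),
                                     sum(documented), replace = TRUE,
                                     prob = cfg$onset_weights)
    entities$onset[is_dis] <- dplyr::case_when(
      is.na(onset_kind) ~ "",
      onset_kind == "pediatric" ~ "pediatric",
      onset_kind == "adult" ~ "adult",
      TRUE ~ "adult pediatric")
    n_tags <- rep(0L, n_dis)
    u <- runif(n_dis)
    n_tags[genetic & u < cfg$p_inherit_one] <- 1L
    n_tags[genetic & u >= cfg$p_inherit_one &
             u < cfg$p_inherit_one + cfg$p_inherit_multi] <- 2L
    w <- cfg$inheritance_weights
    tags <- vapply(n_tags, function(k) {
      if (k == 0) "" else join_tokens(sample(names(w), k, prob = w))
    }, character(1))
    entities$inheritance[is_dis] <- tags
  }

  annotations <- if (length(rows_a) > 0) bind_rows(rows_a) else
    epidemiology_annotations(integer())
  validate_entities(entities)
  validate_annotations(annotations)

  manifest <- build_manifest(cfg, entities,
                             if (length(rows_m) > 0) bind_rows(rows_m) else
                               empty_manifest_dispositions())
  list(entities = entities, annotations = annotations, manifest = manifest)
}

empty_manifest_dispositions <- function() {
  tibble(entity_id = integer(), disposition = character(),
         evidence_group = character(), class_label = character(),
         numeric_value = numeric(), count_value = integer())
}

# expected pipeline outputs, computed by construction from the planned roster
build_manifest <- function(cfg, entities, disp) {
  disp <- arrange(disp, .data$entity_id)
  total_cases <- sum(disp$count_value[disp$disposition ==
                                        "included_case_report"], na.rm = TRUE)
  total_families <- sum(disp$count_value[disp$disposition ==
                                           "included_family_report"],
                        na.rm = TRUE)
  ind <- indirect_prevalence(total_cases, total_families, cfg$population)
  numeric_sum <- sum(disp$numeric_value[disp$disposition ==
                                          "included_numeric"], na.rm = TRUE)
  cls_lab <- disp$class_label[disp$disposition == "included_class"]
  cb <- if (length(cls_lab) > 0) class_bounds(cls_lab) else
    tibble(min_per_100k = numeric(), max_per_100k = numeric())
  inc <- filter(disp, .data$disposition %in% included_dispositions())
  per_class <- inc |>
    count(class_label = factor(.data$class_label,
                               levels = includable_classes()),
          .drop = FALSE, name = "n_diseases") |>
    mutate(class_label = as.character(.data$class_label))

  is_dis <- entities$level == "disorder"
  onset <- entities$onset[is_dis]
  composition <- list(
    n_disorder_level = sum(is_dis),
    n_onset_documented = sum(onset != ""),
    n_onset_pediatric_only = sum(onset == "pediatric"),
    n_onset_both = sum(onset == "adult pediatric"),
    n_onset_adult_only = sum(onset == "adult"),
    n_genetic = sum(entities$genetic[is_dis]),
    inheritance_counts = {
      toks <- unlist(split_tokens(entities$inheritance[is_dis &
                                                         entities$genetic]))
      tibble(tag = factor(toks, levels = inheritance_tags())) |>
        count(.data$tag, .drop = FALSE, name = "n") |>
        mutate(tag = as.character(.data$tag))
    }
  )

  list(
    seed = cfg$seed,
    config = cfg,
    dispositions = disp,
    per_class_counts = per_class,
    total_cases = total_cases,
    total_families = total_families,
    bounds = list(
      numeric_sum = numeric_sum,
      class_min_sum = sum(cb$min_per_100k),
      class_max_sum = sum(cb$max_per_100k),
      indirect_per_100k = ind,
      min_per_100k = numeric_sum + sum(cb$min_per_100k) + ind,
      max_per_100k = numeric_sum + sum(cb$max_per_100k) + ind
    ),
    composition = composition
  )
}
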