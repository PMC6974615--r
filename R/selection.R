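# disposition vocabulary of the selection ledger
dispositions <- function() {
  c("excluded_group_or_subtype", "excluded_incidence_domain",
    "excluded_nonpoint_indicator", "excluded_unknown_or_undocumented",
    "excluded_no_eligible_geography", "excluded_above_threshold",
    "included_numeric", "included_class", "included_case_report",
    "included_family_report")
}

included_dispositions <- function() {
  c("included_numeric", "included_class", "included_case_report",
    "included_family_report")
}

empty_ledger <- function() {
  tibble(entity_id = integer(), disposition = character(),
         geography = character(), value_kind = character(),
         numeric_value = numeric(), class_label = character(),
         count_value = integer(), evidence_group = character())
}

#' Keep only disorder-level entities
#'
#' Groups of disorders and disorder subtypes describe the same patients as
#' their member/parent disorders, so counting them alongside disorders would
#' double-count; only the disorder level is analysed.
#'
#' @param entities Entity tibble.
#' @return A list with `kept` (disorder-level entities) and `excluded`
#'   (ledger rows with disposition `excluded_group_or_subtype`).
#' @export
filter_entity_level <- function(entities) {
  validate_entities(entities)
  keep <- entities$level == "disorder"
  list(kept = entities[keep, ],
       excluded = ledger_rows(entities$entity_id[!keep],
                              "excluded_group_or_subtype"))
}

#' Exclude incidence-described medical domains
#'
#' Rare cancers, infectious diseases and poisonings with an acute or
#' subacute course are described by annual incidence rather than point
#' prevalence and are excluded from the prevalence analysis.
#'
#' @param entities Disorder-level entity tibble.
#' @return A list with `kept` and `excluded` (disposition
#'   `excluded_incidence_domain`).
#' @export
filter_incidence_domains <- function(entities) {
  validate_entities(entities)
  drop <- entities$cancer | entities$infectious_disease | entities$poisoning
  list(kept = entities[!drop, ],
       excluded = ledger_rows(entities$entity_id[drop],
                              "excluded_incidence_domain"))
}

ledger_rows <- function(entity_id, disposition, geography = NA_character_,
                        value_kind = NA_character_, numeric_value = NA_real_,
                        class_label = NA_character_, count_value = NA_integer_,
                        evidence_group = NA_character_) {
  tibble(entity_id = as.integer(entity_id), disposition = disposition,
         geography = geography, value_kind = value_kind,
         numeric_value = as.numeric(numeric_value),
         class_label = class_label, count_value = as.integer(count_value),
         evidence_group = evidence_group)
}

# Resolve the preferred point-prevalence evidence for each entity present in
# `annotations` (pre rarity-threshold). Returns one row per entity with either
# a chosen annotation summary (disposition "chosen") or an exclusion reason.
resolve_entities <- function(annotations) {
  validate_annotations(annotations)
  ids <- unique(annotations$entity_id)
  if (length(ids) == 0) return(empty_ledger())
  tiers <- c("worldwide", "europe", "usa")
  cls <- prevalence_classes()

  pp <- filter(annotations, .data$indicator == "point_prevalence",
               .data$value_kind %in% c("numeric", "class"),
               .data$geography %in% tiers)
  tier_num <- pp |>
    filter(.data$value_kind == "numeric") |>
    group_by(.data$entity_id, .data$geography) |>
    summarise(mean_num = mean(.data$numeric_value), n_num = n(),
              .groups = "drop")
  tier_cls <- pp |>
    filter(.data$value_kind == "class") |>
    count(.data$entity_id, .data$geography, .data$class_label) |>
    mutate(class_order = match(.data$class_label, cls$class_label)) |>
    group_by(.data$entity_id, .data$geography) |>
    arrange(dplyr::desc(.data$n), .data$class_order, .by_group = TRUE) |>
    summarise(best_class = .data$class_label[1], .groups = "drop")

  tier_summary <- dplyr::full_join(tier_num, tier_cls,
                                   by = c("entity_id", "geography")) |>
    mutate(
      tier = match(.data$geography, tiers),
      class_min = cls$min_per_100k[match(.data$best_class, cls$class_label)],
      # a USA figure is usable only when it does not exceed the European
      # rarity threshold; numeric records outrank class-only, so the test
      # applies to the tier mean when numerics exist, else to the class
      # minimum boundary (conservative reading of "did not exceed")
      eligible = .data$tier < 3 |
        (!is.na(.data$mean_num) &
           .data$mean_num <= rarity_threshold_per_100k()) |
        (is.na(.data$mean_num) &
           .data$class_min <= rarity_threshold_per_100k())
    )

  chosen <- tier_summary |>
    filter(.data$eligible) |>
    group_by(.data$entity_id) |>
    arrange(.data$tier, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(
      value_kind = ifelse(!is.na(.data$mean_num), "numeric", "class"),
      numeric_value = .data$mean_num,
      class_label = ifelse(!is.na(.data$mean_num), NA_character_,
                           .data$best_class)
    ) |>
    select("entity_id", "geography", "value_kind", "numeric_value",
           "class_label")

  counts <- annotations |>
    filter(.data$indicator %in% c("case_report", "family_report"),
           .data$value_kind == "count") |>
    group_by(.data$entity_id) |>
    summarise(
      case_tot = sum(.data$count_value[.data$indicator == "case_report"]),
      fam_tot = sum(.data$count_value[.data$indicator == "family_report"]),
      .groups = "drop")

  evidence <- annotations |>
    group_by(.data$entity_id) |>
    summarise(
      has_pp_value = any(.data$indicator == "point_prevalence" &
                           .data$value_kind %in% c("numeric", "class")),
      has_unknown = any(.data$value_kind %in% c("unknown", "not_documented")),
      .groups = "drop")

  out <- tibble(entity_id = sort(ids)) |>
    left_join(chosen, by = "entity_id") |>
    left_join(counts, by = "entity_id") |>
    left_join(evidence, by = "entity_id") |>
    mutate(
      case_tot = dplyr::coalesce(.data$case_tot, 0L),
      fam_tot = dplyr::coalesce(.data$fam_tot, 0L),
      disposition = case_when(
        !is.na(.data$value_kind) ~ "chosen",
        .data$case_tot > 0 ~ "included_case_report",
        .data$fam_tot > 0 ~ "included_family_report",
        .data$has_pp_value ~ "excluded_no_eligible_geography",
        .data$has_unknown ~ "excluded_unknown_or_undocumented",
        TRUE ~ "excluded_nonpoint_indicator"
      ),
      # diseases known only from case or family reports are assumed to sit
      # in the rarest class, <1/1,000,000
      class_label = ifelse(
        .data$disposition %in% c("included_case_report",
                                 "included_family_report"),
        "lt_1_per_1M", .data$class_label),
      value_kind = ifelse(
        .data$disposition %in% c("included_case_report",
                                 "included_family_report"),
        "count", .data$value_kind),
      count_value = dplyr::case_when(
        .data$disposition == "included_case_report" ~ .data$case_tot,
        .data$disposition == "included_family_report" ~ .data$fam_tot,
        TRUE ~ NA_integer_
      )
    ) |>
    select("entity_id", "disposition", "geography", "value_kind",
           "numeric_value", "class_label", "count_value") |>
    mutate(evidence_group = NA_character_)
  out
}

#' Select the preferred annotation for one entity
#'
#' Applies the geographic preference rule to a single entity's annotations:
#' among usable point-prevalence records, worldwide evidence is preferred,
#' then European, then a USA figure provided it does not exceed the European
#' rarity threshold of 5/10,000. Within a geography tier, numeric records
#' outrank class-only records (the tier mean of the numeric values is used);
#' among class-only records the most frequent class wins, ties going to the
#' lower class. Entities with no usable point prevalence but with case or
#' family reports are retained as count evidence in the rarest class.
#' Note the rarity threshold itself is applied afterwards, by
#' [filter_rarity_threshold()].
#'
#' @param entity_id The entity to resolve.
#' @param annotations Annotation tibble (may contain other entities; only
#'   rows for `entity_id` are used).
#' @return A one-row tibble with the chosen evidence (`disposition`
#'   `"chosen"`, `"included_case_report"` or `"included_family_report"`) or
#'   an exclusion reason.
#' @examples
#' ann <- epidemiology_annotations(
#'   c(1, 1), "point_prevalence", c("numeric", "class"),
#'   numeric_value = c(2, NA), class_label = c(NA, "from_1_to_9_per_100k"),
#'   geography_raw = c("France", "Worldwide"))
#' select_preferred_annotation(1, ann) # the worldwide class record wins
#' @export
select_preferred_annotation <- function(entity_id, annotations) {
  stopifnot(length(entity_id) == 1)
  sub <- filter(annotations, .data$entity_id == !!as.integer(entity_id))
  if (nrow(sub) == 0) {
    return(ledger_rows(entity_id, "excluded_unknown_or_undocumented"))
  }
  resolve_entities(sub)
}

#' Apply the European rarity threshold
#'
#' Removes chosen evidence whose prevalence exceeds 5/10,000 (50 per
#' 100,000): numeric means strictly above 50, and the two class ranges that
#' lie entirely above the threshold. A mean of exactly 50 is kept — the rule
#' excludes only disorders *exceeding* the threshold.
#'
#' @param chosen Tibble of resolved evidence (columns `value_kind`,
#'   `numeric_value`, `class_label`; see [select_preferred_annotation()]).
#' @return A list with `kept` and `excluded` rows (the latter re-dispositioned
#'   `excluded_above_threshold`).
#' @export
filter_rarity_threshold <- function(chosen) {
  assert_columns(chosen, c("value_kind", "numeric_value", "class_label"),
                 "chosen evidence")
  over <- (chosen$value_kind == "numeric" &
             chosen$numeric_value > rarity_threshold_per_100k()) |
    (chosen$value_kind == "class" &
       !chosen$class_label %in% includable_classes())
  over[is.na(over)] <- FALSE
  excluded <- chosen[over, ]
  if (nrow(excluded) > 0) {
    excluded$disposition <- "excluded_above_threshold"
  }
  list(kept = chosen[!over, ], excluded = excluded)
}

#' Run the full selection cascade
#'
#' Partitions every input entity into exactly one disposition bucket by
#' applying, in order: the entity-level filter (disorders only), the
#' medical-domain filter (cancers, infectious diseases, poisonings out), the
#' geographic preference rule, and the rarity threshold. The result is a
#' selection ledger holding, for each included disorder, the single piece of
#' evidence that feeds the cumulative estimate: a numeric mean, a prevalence
#' class, or a case/family count.
#'
#' @param entities Entity tibble.
#' @param annotations Annotation tibble.
#' @return The selection ledger: one row per input entity with columns
#'   `entity_id`, `disposition`, `geography`, `value_kind`, `numeric_value`,
#'   `class_label`, `count_value`, `evidence_group` (`"numeric"`, `"class"`,
#'   `"case"`, `"family"` or `NA` for exclusions).
#' @examples
#' ents <- disorder_entities(1:2, level = c("disorder", "group"))
#' ann <- epidemiology_annotations(1, numeric_value = 2)
#' run_selection(ents, ann)
#' @export
run_selection <- function(entities, annotations) {
  validate_entities(entities)
  validate_annotations(annotations)
  if (nrow(entities) == 0) return(empty_ledger())

  lvl <- filter_entity_level(entities)
  dom <- filter_incidence_domains(lvl$kept)
  keep_ids <- dom$kept$entity_id

  ann <- filter(annotations, .data$entity_id %in% keep_ids)
  res <- resolve_entities(ann)
  # entities with no annotations at all: nothing documented
  silent <- setdiff(keep_ids, res$entity_id)
  res <- bind_rows(res, ledger_rows(silent, "excluded_unknown_or_undocumented"))

  thr <- filter_rarity_threshold(res[res$disposition == "chosen", ])
  kept <- thr$kept
  is_num <- kept$value_kind == "numeric"
  kept$disposition <- as.character(
    ifelse(is_num, "included_numeric", "included_class"))
  # numeric means are assigned a class for stratified reporting
  kept$class_label[is_num] <- assign_class(kept$numeric_value[is_num])

  ledger <- bind_rows(
    lvl$excluded, dom$excluded,
    res[!res$disposition %in% "chosen" , ],
    thr$excluded, kept
  ) |>
    mutate(evidence_group = case_when(
      .data$disposition == "included_numeric" ~ "numeric",
      .data$disposition == "included_class" ~ "class",
      .data$disposition == "included_case_report" ~ "case",
      .data$disposition == "included_family_report" ~ "family",
      TRUE ~ NA_character_
    )) |>
    arrange(.data$entity_id)
  stopifnot(identical(sort(ledger$entity_id), sort(entities$entity_id)))
  ledger
}

#' Count ledger dispositions
#'
#' @param ledger A selection ledger from [run_selection()].
#' @return A tibble of disposition counts in cascade order.
#' @export
summarise_dispositions <- function(ledger) {
  assert_columns(ledger, c("entity_id", "disposition"), "ledger")
  ledger |>
    count(disposition = factor(.data$disposition, levels = dispositions()),
          .drop = FALSE, name = "n_entities") |>
    mutate(disposition = as.character(.data$disposition))
}
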