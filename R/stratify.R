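#' Stratify the cumulative estimate by prevalence class
#'
#' Repeats the boundary calculation within each of the four includable
#' prevalence classes: disorders with a numeric value contribute their mean
#' to both bounds of their assigned class, class-only disorders contribute
#' their class boundaries, and case/family-report disorders are counted in
#' the rarest class (<1/1,000,000) with their burden carried by the indirect
#' component (attached to that class row when `include_indirect = TRUE`,
#' reported separately otherwise). The per-class rows sum exactly to the
#' overall bounds.
#'
#' @param ledger Selection ledger from [run_selection()].
#' @param bounds Optional precomputed [cumulative_bounds()] result; computed
#'   from the ledger when omitted.
#' @param population,cases_per_family Passed to [cumulative_bounds()] when
#'   `bounds` is omitted.
#' @param include_indirect Whether the indirect component is carried on the
#'   <1/1,000,000 row (default) or left out of the per-class burden columns.
#' @return A tibble of class `rd_strata`: one row per includable class with
#'   `n_diseases`, `share_diseases` (percent, unrounded),
#'   `min_per_100k`, `max_per_100k`, `share_min`, `share_max` (percent of
#'   each overall bound). Attributes `indirect_per_100k`,
#'   `include_indirect`, `total_min`, `total_max` record the decomposition.
#' @examples
#' ents <- disorder_entities(1)
#' ann <- epidemiology_annotations(1, numeric_value = 2)
#' stratify(run_selection(ents, ann))
#' @export
stratify <- function(ledger, bounds = NULL,
                     population = world_population_2017(),
                     cases_per_family = 1, include_indirect = TRUE) {
  if (is.null(bounds)) {
    bounds <- cumulative_bounds(ledger, population, cases_per_family)
  }
  inc <- filter(ledger, .data$disposition %in% included_dispositions())
  cls <- prevalence_classes()
  rows <- lapply(includable_classes(), function(cl) {
    sub <- filter(inc, .data$class_label == cl)
    num <- filter(sub, .data$disposition == "included_numeric")
    conly <- filter(sub, .data$disposition == "included_class")
    b <- class_bounds(cl)
    tibble(
      class_label = cl,
      n_diseases = nrow(sub),
      min_per_100k = sum(num$numeric_value) + nrow(conly) * b$min_per_100k,
      max_per_100k = sum(num$numeric_value) + nrow(conly) * b$max_per_100k
    )
  })
  out <- bind_rows(rows)
  ind <- bounds$indirect_per_100k %||% 0
  if (include_indirect) {
    i <- out$class_label == "lt_1_per_1M"
    out$min_per_100k[i] <- out$min_per_100k[i] + ind
    out$max_per_100k[i] <- out$max_per_100k[i] + ind
  }
  total_min <- sum(out$min_per_100k)
  total_max <- sum(out$max_per_100k)
  out <- out |>
    mutate(
      share_diseases = if (nrow(inc) > 0) .data$n_diseases / nrow(inc) * 100
                       else NA_real_,
      share_min = if (total_min > 0) .data$min_per_100k / total_min * 100
                  else NA_real_,
      share_max = if (total_max > 0) .data$max_per_100k / total_max * 100
                  else NA_real_
    ) |>
    select("class_label", "n_diseases", "share_diseases", "min_per_100k",
           "max_per_100k", "share_min", "share_max")
  structure(out,
            class = c("rd_strata", class(out)),
            indirect_per_100k = ind,
            include_indirect = include_indirect,
            total_min = total_min, total_max = total_max)
}

#' Coverage of a national rare-disease definition
#'
#' Evaluates which share of the included diseases, and of the minimum and
#' maximum patient burden, falls inside a national definition expressed as a
#' point-prevalence threshold. A disease counts as covered only if its whole
#' plausible range is below the threshold: numeric diseases by their mean,
#' class-only and case/family diseases by their class maximum boundary. The
#' burden of case/family diseases (the indirect component) is attributed to
#' the rarest class and is covered whenever that class is.
#'
#' @param ledger Selection ledger.
#' @param definitions One or more definitions: a numeric vector of
#'   thresholds per 100,000 or a tibble from [national_definition()] /
#'   [default_national_definitions()].
#' @param population,cases_per_family Passed to [cumulative_bounds()].
#' @return A tibble with one row per definition: `name`,
#'   `threshold_per_100k`, `n_covered`, `share_diseases`,
#'   `share_burden_min`, `share_burden_max` (percents, unrounded).
#' @examples
#' ents <- disorder_entities(1)
#' ann <- epidemiology_annotations(1, numeric_value = 2)
#' definition_coverage(run_selection(ents, ann), 50)
#' @export
definition_coverage <- function(ledger, definitions = default_national_definitions(),
                                population = world_population_2017(),
                                cases_per_family = 1) {
  if (is.numeric(definitions)) {
    definitions <- tibble(name = sprintf("%g per 100,000", definitions),
                          threshold_per_100k = as.numeric(definitions),
                          form = "prevalence")
  }
  assert_columns(definitions, c("name", "threshold_per_100k"), "definitions")
  if (any(definitions$threshold_per_100k <= 0)) {
    abort("definition thresholds must be positive")
  }
  bounds <- cumulative_bounds(ledger, population, cases_per_family)
  inc <- filter(ledger, .data$disposition %in% included_dispositions())
  cls <- prevalence_classes()
  cls_max <- cls$max_per_100k[match(inc$class_label, cls$class_label)]
  # per-disease contribution to each bound (indirect handled separately)
  contrib_min <- ifelse(inc$disposition == "included_numeric",
                        inc$numeric_value,
                 ifelse(inc$disposition == "included_class",
                        cls$min_per_100k[match(inc$class_label,
                                               cls$class_label)], 0))
  contrib_max <- ifelse(inc$disposition == "included_numeric",
                        inc$numeric_value,
                 ifelse(inc$disposition == "included_class", cls_max, 0))
  measure <- ifelse(inc$disposition == "included_numeric",
                    inc$numeric_value, cls_max)
  ind <- bounds$indirect_per_100k
  total_min <- bounds$min_per_100k
  total_max <- bounds$max_per_100k
  out <- lapply(seq_len(nrow(definitions)), function(i) {
    thr <- definitions$threshold_per_100k[i]
    covered <- measure <= thr
    ind_covered <- cls$max_per_100k[cls$class_label == "lt_1_per_1M"] <= thr
    tibble(
      name = definitions$name[i],
      threshold_per_100k = thr,
      n_covered = sum(covered),
      share_diseases = if (nrow(inc) > 0) sum(covered) / nrow(inc) * 100
                       else NA_real_,
      share_burden_min = if (total_min > 0)
        (sum(contrib_min[covered]) + ind * ind_covered) / total_min * 100
        else NA_real_,
      share_burden_max = if (total_max > 0)
        (sum(contrib_max[covered]) + ind * ind_covered) / total_max * 100
        else NA_real_
    )
  })
  bind_rows(out)
}
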