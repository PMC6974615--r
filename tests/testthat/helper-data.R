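# Shorthand builders for one-off entities/annotations in tests.

ent <- function(id, level = "disorder", ...) {
  disorder_entities(id, level = level, ...)
}

ann_num <- function(id, value, geo = "Worldwide", indicator = "point_prevalence") {
  epidemiology_annotations(id, indicator, "numeric", numeric_value = value,
                           geography_raw = geo)
}

ann_cls <- function(id, class, geo = "Worldwide") {
  epidemiology_annotations(id, "point_prevalence", "class",
                           class_label = class, geography_raw = geo)
}

ann_cnt <- function(id, count, indicator = "case_report", geo = "Worldwide") {
  epidemiology_annotations(id, indicator, "count", count_value = count,
                           geography_raw = geo)
}

ann_none <- function(id, kind = "unknown") {
  epidemiology_annotations(id, "point_prevalence", kind)
}

# Random small dataset for oracle-equivalence checks: arbitrary mixture of
# levels, domain flags, indicators, kinds, geographies (including 'other'),
# magnitudes straddling the rarity threshold, and case/family counts.
random_dataset <- function(n_entities = 12) {
  levels <- sample(c("disorder", "group", "subtype"), n_entities,
                   replace = TRUE, prob = c(0.7, 0.15, 0.15))
  flags <- matrix(runif(n_entities * 3) < 0.08, ncol = 3)
  entities <- disorder_entities(
    seq_len(n_entities), level = levels,
    cancer = flags[, 1], infectious_disease = flags[, 2],
    poisoning = flags[, 3], genetic = runif(n_entities) < 0.5)
  geos <- c("Worldwide", "France", "Iceland", "United States", "Japan")
  rows <- list()
  for (id in seq_len(n_entities)) {
    for (k in seq_len(sample(0:4, 1))) {
      indicator <- sample(c("point_prevalence", "birth_prevalence",
                            "lifetime_prevalence", "annual_incidence",
                            "case_report", "family_report"), 1,
                          prob = c(0.55, 0.08, 0.07, 0.1, 0.12, 0.08))
      geo <- sample(geos, 1)
      if (indicator %in% c("case_report", "family_report")) {
        rows[[length(rows) + 1]] <- ann_cnt(id, sample(1:80, 1), indicator, geo)
      } else if (indicator != "point_prevalence") {
        rows[[length(rows) + 1]] <- ann_num(id, runif(1, 0.01, 200),
                                            geo, indicator)
      } else {
        kind <- sample(c("numeric", "class", "unknown", "not_documented"), 1,
                       prob = c(0.45, 0.3, 0.15, 0.1))
        if (kind == "numeric") {
          rows[[length(rows) + 1]] <- ann_num(id, runif(1, 0.01, 120), geo)
        } else if (kind == "class") {
          rows[[length(rows) + 1]] <-
            ann_cls(id, sample(prevalence_classes()$class_label, 1), geo)
        } else {
          rows[[length(rows) + 1]] <- epidemiology_annotations(
            id, "point_prevalence", kind, geography_raw = geo)
        }
      }
    }
  }
  annotations <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    epidemiology_annotations(integer())
  list(entities = entities, annotations = annotations)
}
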