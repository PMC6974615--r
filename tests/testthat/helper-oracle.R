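# Brute-force reference implementation of the selection rules and the bound
# summation, written as literal per-entity enumeration. Kept deliberately
# independent of the package internals (its own class table, its own loops)
# so it can serve as an oracle on small datasets.

oracle_class_table <- function() {
  data.frame(
    label = c("lt_1_per_1M", "from_1_to_9_per_1M", "from_1_to_9_per_100k",
              "from_1_to_5_per_10k", "from_6_to_9_per_10k", "gt_1_per_1k"),
    lo = c(0.1, 0.1, 1, 10, 60, 100),
    hi = c(0.1, 0.9, 9, 50, 90, Inf),
    stringsAsFactors = FALSE)
}

oracle_selection <- function(entities, annotations) {
  ct <- oracle_class_table()
  out <- list()
  for (i in seq_len(nrow(entities))) {
    e <- entities[i, ]
    a <- annotations[annotations$entity_id == e$entity_id, , drop = FALSE]
    row <- list(entity_id = e$entity_id, disposition = NA_character_,
                value_kind = NA_character_, numeric_value = NA_real_,
                class_label = NA_character_, count_value = NA_integer_)
    if (e$level != "disorder") {
      row$disposition <- "excluded_group_or_subtype"
    } else if (e$cancer || e$infectious_disease || e$poisoning) {
      row$disposition <- "excluded_incidence_domain"
    } else {
      chosen <- NULL
      for (tier in c("worldwide", "europe", "usa")) {
        pp <- a[a$indicator == "point_prevalence" &
                  a$value_kind %in% c("numeric", "class") &
                  a$geography == tier, , drop = FALSE]
        if (nrow(pp) == 0) next
        nums <- pp[pp$value_kind == "numeric", , drop = FALSE]
        if (nrow(nums) > 0) {
          kind <- "numeric"; v <- mean(nums$numeric_value); cl <- NA
        } else {
          tab <- table(pp$class_label)
          best <- names(tab)[tab == max(tab)]
          best <- best[order(match(best, ct$label))][1]
          kind <- "class"; v <- NA; cl <- best
        }
        if (tier == "usa") {
          ok <- if (kind == "numeric") v <= 50 else
            ct$lo[ct$label == cl] <= 50
          if (!ok) next
        }
        chosen <- list(kind = kind, v = v, cl = cl)
        break
      }
      cases <- sum(a$count_value[a$indicator == "case_report" &
                                   a$value_kind == "count"])
      fams <- sum(a$count_value[a$indicator == "family_report" &
                                  a$value_kind == "count"])
      if (!is.null(chosen)) {
        over <- if (chosen$kind == "numeric") chosen$v > 50 else
          chosen$cl %in% c("from_6_to_9_per_10k", "gt_1_per_1k")
        if (over) {
          row$disposition <- "excluded_above_threshold"
        } else if (chosen$kind == "numeric") {
          row$disposition <- "included_numeric"
          row$value_kind <- "numeric"
          row$numeric_value <- chosen$v
        } else {
          row$disposition <- "included_class"
          row$value_kind <- "class"
          row$class_label <- chosen$cl
        }
      } else if (cases > 0) {
        row$disposition <- "included_case_report"
        row$value_kind <- "count"
        row$class_label <- "lt_1_per_1M"
        row$count_value <- as.integer(cases)
      } else if (fams > 0) {
        row$disposition <- "included_family_report"
        row$value_kind <- "count"
        row$class_label <- "lt_1_per_1M"
        row$count_value <- as.integer(fams)
      } else if (any(a$indicator == "point_prevalence" &
                       a$value_kind %in% c("numeric", "class"))) {
        row$disposition <- "excluded_no_eligible_geography"
      } else if (nrow(a) == 0 ||
                   any(a$value_kind %in% c("unknown", "not_documented"))) {
        row$disposition <- "excluded_unknown_or_undocumented"
      } else {
        row$disposition <- "excluded_nonpoint_indicator"
      }
    }
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$entity_id), , drop = FALSE]
}

oracle_bounds <- function(oracle_ledger, population_size = 7.55e9,
                          cases_per_family = 1) {
  ct <- oracle_class_table()
  lo <- 0; hi <- 0; cases <- 0; fams <- 0
  for (i in seq_len(nrow(oracle_ledger))) {
    r <- oracle_ledger[i, ]
    if (r$disposition == "included_numeric") {
      lo <- lo + r$numeric_value
      hi <- hi + r$numeric_value
    } else if (r$disposition == "included_class") {
      lo <- lo + ct$lo[ct$label == r$class_label]
      hi <- hi + ct$hi[ct$label == r$class_label]
    } else if (r$disposition == "included_case_report") {
      cases <- cases + r$count_value
    } else if (r$disposition == "included_family_report") {
      fams <- fams + r$count_value
    }
  }
  ind <- (cases + cases_per_family * fams) / population_size * 1e5
  c(min = lo + ind, max = hi + ind)
}
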