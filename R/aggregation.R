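#' Indirect point prevalence from case and family reports
#'
#' Diseases known only from published case or family reports are too poorly
#' characterised for a per-disease prevalence, but collectively they have a
#' well-defined lower-bound burden: the sum of all reported cases and
#' families divided by the reference population. A family contributes
#' `cases_per_family` cases (1 by default; 10 in the published sensitivity
#' setting).
#'
#' @param total_cases Total number of reported cases.
#' @param total_families Total number of reported families.
#' @param population Reference population (number of persons, or a one-row
#'   tibble from [population_figure()]). Defaults to the worldwide 2017
#'   population.
#' @param cases_per_family Cases attributed to each reported family
#'   (integer >= 1).
#' @return The indirect point prevalence in cases per 100,000, unrounded.
#'   Round with [round_half_up()] at report time.
#' @examples
#' # the reported totals: 85,680 cases and 3,418 families worldwide
#' round_half_up(indirect_prevalence(85680, 3418), 1)      # 1.2
#' round_half_up(indirect_prevalence(85680, 3418,
#'                                   cases_per_family = 10), 1) # 1.6
#' @export
indirect_prevalence <- function(total_cases, total_families,
                                population = world_population_2017(),
                                cases_per_family = 1) {
  if (total_cases < 0 || total_families < 0) {
    abort("case and family totals must be nonnegative")
  }
  if (cases_per_family < 1) abort("cases_per_family must be >= 1")
  size <- pop_size(population)
  (total_cases + cases_per_family * total_families) / size * 1e5
}

#' Assemble a bound estimate from group components
#'
#' A cumulative point-prevalence estimate is a pair of per-100,000 bounds,
#' each the exact sum of per-evidence-group contributions: disorders with a
#' numeric value contribute their mean to both bounds; class-only disorders
#' contribute their class minimum to the minimum bound and class maximum to
#' the maximum bound; case/family-report disorders contribute the single
#' indirect estimate to both. This constructor performs the summation given
#' a component table — use [cumulative_bounds()] to derive the components
#' from a selection ledger.
#'
#' @param components Tibble with columns `group` (character),
#'   `min_per_100k`, `max_per_100k`, and optionally `n_diseases`.
#' @param population Population figure the estimate refers to (kept for
#'   extrapolation; optional).
#' @param cases_per_family Multiplier recorded for provenance.
#' @return An object of class `bound_estimate` with elements `components`,
#'   `min_per_100k`, `max_per_100k`, `population`, `cases_per_family`.
#' @examples
#' bound_estimate(tibble::tibble(
#'   group = c("point_prevalence", "indirect"),
#'   min_per_100k = c(3481.1, 1.2), max_per_100k = c(5909.1, 1.2)))
#' @export
bound_estimate <- function(components, population = world_population_2017(),
                           cases_per_family = 1) {
  assert_columns(components, c("group", "min_per_100k", "max_per_100k"),
                 "component table")
  if (!"n_diseases" %in% names(components)) {
    components$n_diseases <- NA_integer_
  }
  if (any(components$min_per_100k > components$max_per_100k)) {
    abort("component minimum exceeds its maximum")
  }
  if (any(components$min_per_100k < 0)) {
    abort("components must be nonnegative")
  }
  structure(
    list(components = as_tibble(components),
         min_per_100k = sum(components$min_per_100k),
         max_per_100k = sum(components$max_per_100k),
         population = population,
         cases_per_family = cases_per_family),
    class = "bound_estimate")
}

#' Cumulative point-prevalence bounds from a selection ledger
#'
#' Sums the three evidence groups of the selection ledger into minimum and
#' maximum cumulative point-prevalence boundaries: numeric means (both
#' bounds), class minima/maxima (respective bounds), and the indirect
#' estimate derived from the ledger's case and family totals (both bounds).
#' Arithmetic is exact; rounding happens only at report time.
#'
#' @param ledger Selection ledger from [run_selection()].
#' @param population Reference population for the indirect estimate.
#' @param cases_per_family Cases attributed to each reported family.
#' @return A [bound_estimate()] whose components are the three groups, with
#'   `total_cases`, `total_families` and `indirect_per_100k` attached.
#' @examples
#' ents <- disorder_entities(1)
#' ann <- epidemiology_annotations(1, numeric_value = 2)
#' cumulative_bounds(run_selection(ents, ann))
#' @export
cumulative_bounds <- function(ledger, population = world_population_2017(),
                              cases_per_family = 1) {
  assert_columns(ledger, c("entity_id", "disposition", "value_kind",
                           "numeric_value", "class_label", "count_value",
                           "evidence_group"), "ledger")
  num <- filter(ledger, .data$disposition == "included_numeric")
  cls <- filter(ledger, .data$disposition == "included_class")
  cas <- filter(ledger, .data$disposition == "included_case_report")
  fam <- filter(ledger, .data$disposition == "included_family_report")

  s_num <- sum(num$numeric_value)
  cb <- if (nrow(cls) > 0) class_bounds(cls$class_label) else
    tibble(min_per_100k = numeric(), max_per_100k = numeric())
  total_cases <- sum(cas$count_value)
  total_families <- sum(fam$count_value)
  ind <- indirect_prevalence(total_cases, total_families, population,
                             cases_per_family)

  components <- tibble(
    group = c("numeric_value", "class_only", "indirect"),
    n_diseases = c(nrow(num), nrow(cls), nrow(cas) + nrow(fam)),
    min_per_100k = c(s_num, sum(cb$min_per_100k), ind),
    max_per_100k = c(s_num, sum(cb$max_per_100k), ind)
  )
  out <- bound_estimate(components, population, cases_per_family)
  out$total_cases <- total_cases
  out$total_families <- total_families
  out$indirect_per_100k <- ind
  out
}

#' Extrapolate a per-100,000 bound to affected persons
#'
#' Converts cumulative prevalence bounds to absolute numbers of affected
#' people in a reference population. Linear in the population size.
#'
#' @param bound_per_100k Numeric vector of prevalence bounds per 100,000.
#' @param population Reference population.
#' @return A tibble with columns `per_100k`, `persons` (exact), and
#'   `millions` (rounded half-up to one decimal).
#' @examples
#' extrapolate_persons(c(3482.3, 5910.3), world_population_2017())
#' @export
extrapolate_persons <- function(bound_per_100k,
                                population = world_population_2017()) {
  if (any(bound_per_100k < 0)) abort("bounds must be nonnegative")
  size <- pop_size(population)
  persons <- bound_per_100k / 1e5 * size
  tibble(per_100k = bound_per_100k,
         persons = persons,
         millions = round_half_up(persons / 1e6, 1))
}

#' @export
print.bound_estimate <- function(x, ...) {
  cat("Cumulative point-prevalence estimate\n")
  cat(sprintf("  bounds: %.1f - %.1f per 100,000 (%.1f%% - %.1f%%)\n",
              round_half_up(x$min_per_100k, 1),
              round_half_up(x$max_per_100k, 1),
              round_half_up(x$min_per_100k / 1000, 1),
              round_half_up(x$max_per_100k / 1000, 1)))
  if (!is.null(x$indirect_per_100k)) {
    cat(sprintf("  indirect component: %.1f per 100,000 (%d cases, %d families, %d case(s)/family)\n",
                round_half_up(x$indirect_per_100k, 1), x$total_cases,
                x$total_families, as.integer(x$cases_per_family)))
  }
  cat("  components:\n")
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("    %-14s %s%9.1f - %9.1f per 100,000\n", comp$group[i],
                ifelse(is.na(comp$n_diseases[i]), "",
                       sprintf("n=%5d ", comp$n_diseases[i])),
                comp$min_per_100k[i], comp$max_per_100k[i]))
  }
  invisible(x)
}

#' Tidy a bound estimate
#'
#' @param x A `bound_estimate`.
#' @param ... Unused.
#' @return The component table: one row per evidence group with its
#'   contribution to each bound.
#' @method tidy bound_estimate
#' @export
tidy.bound_estimate <- function(x, ...) {
  x$components
}

#' One-row summary of a bound estimate
#'
#' @param x A `bound_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the bounds (exact and rounded), the
#'   indirect component, case/family totals and the extrapolated person
#'   counts for the estimate's population.
#' @method glance bound_estimate
#' @export
glance.bound_estimate <- function(x, ...) {
  ext <- extrapolate_persons(c(x$min_per_100k, x$max_per_100k), x$population)
  tibble(
    min_per_100k = x$min_per_100k,
    max_per_100k = x$max_per_100k,
    min_per_100k_rounded = round_half_up(x$min_per_100k, 1),
    max_per_100k_rounded = round_half_up(x$max_per_100k, 1),
    indirect_per_100k = x$indirect_per_100k %||% NA_real_,
    total_cases = x$total_cases %||% NA_integer_,
    total_families = x$total_families %||% NA_integer_,
    cases_per_family = x$cases_per_family,
    persons_min_millions = ext$millions[1],
    persons_max_millions = ext$millions[2]
  )
}
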