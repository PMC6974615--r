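#' Evidence-group summary table
#'
#' The headline derivation table: for each evidence group (case reports,
#' family reports, their pooled indirect estimate, disorders with a
#' point-prevalence figure or class) the number of diseases, the percent
#' share of all included diseases (rounded half-up to one decimal, matching
#' the reporting convention), the reported case totals and the per-100,000
#' estimates, with a closing total row carrying the cumulative bounds.
#'
#' @param ledger Selection ledger.
#' @param population,cases_per_family Passed to [cumulative_bounds()].
#' @return A tibble with columns `group`, `n_diseases`, `share_pct`,
#'   `n_cases`, `min_per_100k`, `max_per_100k` (the per-100,000 columns
#'   rounded half-up to one decimal).
#' @export
summarise_evidence_groups <- function(ledger,
                                      population = world_population_2017(),
                                      cases_per_family = 1) {
  b <- cumulative_bounds(ledger, population, cases_per_family)
  n_case <- sum(ledger$disposition == "included_case_report")
  n_fam <- sum(ledger$disposition == "included_family_report")
  n_num <- sum(ledger$disposition == "included_numeric")
  n_cls <- sum(ledger$disposition == "included_class")
  n_inc <- n_case + n_fam + n_num + n_cls
  share <- function(n) if (n_inc > 0) round_half_up(n / n_inc * 100, 1)
                       else NA_real_
  pp_min <- b$components$min_per_100k[1] + b$components$min_per_100k[2]
  pp_max <- b$components$max_per_100k[1] + b$components$max_per_100k[2]
  tibble(
    group = c("case_reports", "family_reports", "indirect_point_prevalence",
              "point_prevalence", "total"),
    n_diseases = c(n_case, n_fam, n_case + n_fam, n_num + n_cls, n_inc),
    share_pct = c(share(n_case), share(n_fam), share(n_case + n_fam),
                  share(n_num + n_cls), share(n_inc)),
    n_cases = c(b$total_cases, b$total_families,
                b$total_cases + b$cases_per_family * b$total_families,
                NA_integer_, NA_integer_),
    min_per_100k = round_half_up(
      c(NA, NA, b$indirect_per_100k, pp_min, b$min_per_100k), 1),
    max_per_100k = round_half_up(
      c(NA, NA, b$indirect_per_100k, pp_max, b$max_per_100k), 1)
  )
}

#' Write the full analysis report
#'
#' Emits the deterministic report bundle for a completed analysis: the
#' evidence-group derivation table, the per-class stratification table, the
#' national-definition coverage table (all TSV with header rows), a JSON
#' summary, and a plain-text narrative with the rounded headline numbers.
#' Identical inputs yield byte-identical files.
#'
#' @param ledger Selection ledger.
#' @param dir Output directory (created if needed).
#' @param population,cases_per_family Passed to the aggregation stage.
#' @param definitions National definitions to evaluate (see
#'   [default_national_definitions()]).
#' @param entities Optional entity tibble; when given, descriptive onset /
#'   genetic statistics are added to the summary and narrative.
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(ledger, dir,
                          population = world_population_2017(),
                          cases_per_family = 1,
                          definitions = default_national_definitions(),
                          entities = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bounds <- cumulative_bounds(ledger, population, cases_per_family)
  strata <- stratify(ledger, bounds)
  groups <- summarise_evidence_groups(ledger, population, cases_per_family)
  coverage <- definition_coverage(ledger, definitions, population,
                                  cases_per_family)
  ext <- extrapolate_persons(c(bounds$min_per_100k, bounds$max_per_100k),
                             population)

  paths <- c(
    evidence_groups = file.path(dir, "evidence_groups.tsv"),
    strata = file.path(dir, "strata.tsv"),
    definitions = file.path(dir, "definitions.tsv"),
    summary = file.path(dir, "summary.json"),
    narrative = file.path(dir, "narrative.txt")
  )
  readr::write_tsv(groups, paths[["evidence_groups"]])
  strata_out <- as_tibble(strata) |>
    mutate(across(c("share_diseases", "min_per_100k", "max_per_100k",
                    "share_min", "share_max"),
                  \(x) round_half_up(x, 1)))
  readr::write_tsv(strata_out, paths[["strata"]])
  cov_out <- coverage |>
    mutate(across(c("threshold_per_100k", "share_diseases",
                    "share_burden_min", "share_burden_max"),
                  \(x) round_half_up(x, 1)))
  readr::write_tsv(cov_out, paths[["definitions"]])

  summary <- list(
    included_counts = as.list(setNames(groups$n_diseases, groups$group)),
    total_cases = bounds$total_cases,
    total_families = bounds$total_families,
    cases_per_family = cases_per_family,
    indirect_per_100k = round_half_up(bounds$indirect_per_100k, 1),
    min_per_100k = round_half_up(bounds$min_per_100k, 1),
    max_per_100k = round_half_up(bounds$max_per_100k, 1),
    population = list(region = population$region, year = population$year,
                      size = population$size),
    persons_millions = list(min = ext$millions[1], max = ext$millions[2])
  )
  if (!is.null(entities)) {
    d <- descriptive_stats(entities)
    summary$descriptives <- list(
      n_disorders = d$n_disorders,
      onset_documented_pct = round_half_up(d$onset$share_documented, 1),
      genetic_pct = round_half_up(d$genetic$share, 1)
    )
  }
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  lines <- c(
    "Cumulative point prevalence of rare diseases",
    "============================================",
    sprintf("Included diseases: %d (numeric or class: %d; case reports: %d; family reports: %d)",
            groups$n_diseases[5], groups$n_diseases[4],
            groups$n_diseases[1], groups$n_diseases[2]),
    sprintf("Reported cases: %d; reported families: %d (%d case(s) per family)",
            bounds$total_cases, bounds$total_families,
            as.integer(cases_per_family)),
    sprintf("Indirect point prevalence: %.1f per 100,000",
            round_half_up(bounds$indirect_per_100k, 1)),
    sprintf("Cumulative point prevalence bounds: %.1f - %.1f per 100,000 (%.1f%% - %.1f%%)",
            round_half_up(bounds$min_per_100k, 1),
            round_half_up(bounds$max_per_100k, 1),
            round_half_up(bounds$min_per_100k / 1000, 1),
            round_half_up(bounds$max_per_100k / 1000, 1)),
    sprintf("Affected persons (population %s, %s): %.1f - %.1f million",
            format(population$size, big.mark = ","),
            ifelse(is.na(population$year), "year n/a", population$year),
            ext$millions[1], ext$millions[2])
  )
  writeLines(lines, paths[["narrative"]], useBytes = TRUE)
  invisible(paths)
}
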