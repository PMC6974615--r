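#' Population figure
#'
#' A reference population used either as the denominator of the indirect
#' point-prevalence estimate or as the basis for extrapolating per-100,000
#' bounds to numbers of affected persons.
#'
#' @param size Positive integer number of persons.
#' @param region One of `"worldwide"`, `"eu"`, `"usa"`, `"custom"`.
#' @param year Calendar year of the figure.
#' @return A one-row tibble with columns `region`, `year`, `size`.
#' @examples
#' population_figure(7550000000, "worldwide", 2017)
#' @export
population_figure <- function(size, region = "custom", year = NA_integer_) {
  if (!is.numeric(size) || length(size) != 1 || is.na(size) || size <= 0) {
    abort("population size must be a single positive number")
  }
  region <- match.arg(region, c("worldwide", "eu", "usa", "custom"))
  tibble(region = region, year = as.integer(year), size = as.numeric(size))
}

#' Packaged reference populations
#'
#' Reads the population-figures config shipped with the package (worldwide
#' 2017, EU 2017, USA 1983 and 2017). Pass a path to use a different config.
#'
#' @param path Optional path to a YAML file of `region`/`year`/`size` records.
#' @return A tibble of population figures.
#' @export
default_populations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "populations.yml",
                                package = "raremetrics", mustWork = TRUE)
  recs <- yaml::read_yaml(path)
  out <- bind_rows(lapply(recs, function(r) {
    population_figure(r$size, r$region, r$year)
  }))
  if (anyDuplicated(out[c("region", "year")]) > 0) {
    abort("duplicate region/year pair in population config")
  }
  out
}

#' Worldwide 2017 population
#'
#' Convenience accessor for the 7.55 billion worldwide 2017 figure used as
#' the default denominator throughout the package.
#'
#' @return A one-row population tibble.
#' @export
world_population_2017 <- function() {
  population_figure(7.55e9, "worldwide", 2017)
}

pop_size <- function(population) {
  if (is.data.frame(population)) {
    if (nrow(population) != 1) abort("population must be a single figure")
    population <- population$size
  }
  if (!is.numeric(population) || length(population) != 1 ||
      is.na(population) || population <= 0) {
    abort("population size must be a single positive number")
  }
  as.numeric(population)
}

#' National rare-disease definition
#'
#' National definitions of "rare disease" come in two forms: a prevalence
#' threshold (e.g. the EU's 50 per 100,000) or an absolute affected-person
#' count relative to the national population (e.g. the USA's fewer than
#' 200,000 persons). Count-form definitions are converted to a per-100,000
#' threshold using the supplied reference population, which is why such
#' definitions become more restrictive as the population grows.
#'
#' @param name Definition name (free text).
#' @param threshold_per_100k Prevalence-form threshold, per 100,000.
#' @param absolute_count Count-form threshold in persons.
#' @param reference_population Population the count refers to (number or
#'   one-row population tibble). Required with `absolute_count`.
#' @return A one-row tibble with columns `name`, `threshold_per_100k`,
#'   `form` (`"prevalence"` or `"count"`).
#' @examples
#' national_definition("EU", threshold_per_100k = 50)
#' national_definition("USA 1983", absolute_count = 200000,
#'                     reference_population = 232558140)
#' @export
national_definition <- function(name, threshold_per_100k = NULL,
                                absolute_count = NULL,
                                reference_population = NULL) {
  has_prev <- !is.null(threshold_per_100k)
  has_count <- !is.null(absolute_count)
  if (has_prev == has_count) {
    abort("supply exactly one of threshold_per_100k or absolute_count")
  }
  if (has_prev) {
    if (threshold_per_100k <= 0) abort("threshold_per_100k must be positive")
    return(tibble(name = name,
                  threshold_per_100k = as.numeric(threshold_per_100k),
                  form = "prevalence"))
  }
  if (is.null(reference_population)) {
    abort("count-form definitions need a reference_population")
  }
  if (absolute_count <= 0) abort("absolute_count must be positive")
  thr <- absolute_count / pop_size(reference_population) * 1e5
  tibble(name = name, threshold_per_100k = thr, form = "count")
}

#' Packaged national definitions
#'
#' A small default set of national rare-disease definitions spanning the
#' published 5-80 per 100,000 range: the EU prevalence threshold and the
#' US count-form definition converted at its 1983 and 2017 reference
#' populations, plus the published extremes.
#'
#' @return A tibble of definitions (see [national_definition()]).
#' @export
default_national_definitions <- function() {
  pops <- default_populations()
  us1983 <- pops$size[pops$region == "usa" & pops$year == 1983]
  us2017 <- pops$size[pops$region == "usa" & pops$year == 2017]
  bind_rows(
    national_definition("Lowest published", threshold_per_100k = 5),
    national_definition("EU", threshold_per_100k = 50),
    national_definition("USA (1983 population)", absolute_count = 200000,
                        reference_population = us1983),
    national_definition("USA (2017 population)", absolute_count = 200000,
                        reference_population = us2017),
    national_definition("Highest published", threshold_per_100k = 80)
  )
}
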