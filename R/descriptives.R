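#' Descriptive statistics of the disease catalogue
#'
#' Summarises the disorder-level entities: how many have a documented age of
#' onset and its split into exclusively pediatric, mixed, and exclusively
#' adult onset; the share classified as genetic; and the distribution of
#' inheritance tags among genetic disorders (a disorder may carry several
#' tags, so inheritance counts can exceed the number of disorders).
#'
#' @param entities Entity tibble; only `level == "disorder"` rows are used.
#' @return A list of class `rd_descriptives` with elements `n_disorders`,
#'   `onset` (list: `n_documented`, `share_documented`, `distribution`
#'   tibble with percent shares among documented disorders, `NA` and flagged
#'   `undefined = TRUE` when nothing is documented), `genetic` (list:
#'   `n_genetic`, `share`), `inheritance` (tibble of tag counts and shares
#'   among genetic disorders). Shares are percents, unrounded.
#' @examples
#' e <- disorder_entities(1:4, onset = c("pediatric", "adult pediatric",
#'                                       "", "adult"),
#'                        genetic = c(TRUE, TRUE, FALSE, FALSE))
#' descriptive_stats(e)
#' @export
descriptive_stats <- function(entities) {
  validate_entities(entities)
  dis <- filter(entities, .data$level == "disorder")
  n <- nrow(dis)
  documented <- dis$onset != ""
  n_doc <- sum(documented)
  onset_cat <- dplyr::case_when(
    dis$onset == "pediatric" ~ "pediatric_only",
    dis$onset == "adult" ~ "adult_only",
    documented ~ "mixed",
    TRUE ~ NA_character_
  )
  dist <- tibble(category = factor(onset_cat[documented],
                                   levels = c("pediatric_only", "mixed",
                                              "adult_only"))) |>
    count(.data$category, .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category),
           share = if (n_doc > 0) .data$n / n_doc * 100 else NA_real_)
  genetic <- dis$genetic
  toks <- unlist(split_tokens(dis$inheritance[genetic]))
  inh <- tibble(tag = factor(toks, levels = inheritance_tags())) |>
    count(.data$tag, .drop = FALSE, name = "n") |>
    mutate(tag = as.character(.data$tag),
           share = if (sum(genetic) > 0) .data$n / sum(genetic) * 100
                   else NA_real_)
  structure(
    list(
      n_disorders = n,
      onset = list(
        n_documented = n_doc,
        share_documented = if (n > 0) n_doc / n * 100 else NA_real_,
        distribution = dist,
        undefined = n_doc == 0
      ),
      genetic = list(
        n_genetic = sum(genetic),
        share = if (n > 0) sum(genetic) / n * 100 else NA_real_
      ),
      inheritance = inh
    ),
    class = "rd_descriptives")
}

#' @export
print.rd_descriptives <- function(x, ...) {
  cat(sprintf("Disorder-level entities: %d\n", x$n_disorders))
  if (x$onset$undefined) {
    cat("Age of onset: not documented for any disorder\n")
  } else {
    cat(sprintf("Age of onset documented: %d (%.1f%%)\n",
                x$onset$n_documented,
                round_half_up(x$onset$share_documented, 1)))
    d <- x$onset$distribution
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %-15s %5d (%.1f%%)\n", d$category[i], d$n[i],
                  round_half_up(d$share[i], 1)))
    }
  }
  cat(sprintf("Genetic: %d (%.1f%%)\n", x$genetic$n_genetic,
              round_half_up(x$genetic$share, 1)))
  invisible(x)
}
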