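# cache for one-shot logging of unknown labels within a session
the <- new.env(parent = emptyenv())
the$seen_unknown <- character()

#' Default geography normalisation table
#'
#' Reads the mapping shipped with the package (a YAML file listing, for each
#' analysis region, the raw area labels that belong to it). The mapping is a
#' plain config file rather than hard-coded so that region membership (for
#' example future EU membership changes) can be edited without touching code.
#'
#' @param path Path to a YAML mapping file; defaults to the packaged table.
#' @return A named list with character vectors `worldwide`, `europe`, `usa`.
#' @export
default_geography_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "geography.yml",
                                package = "raremetrics", mustWork = TRUE)
  mapping <- yaml::read_yaml(path)
  needed <- c("worldwide", "europe", "usa")
  assert_columns(mapping, needed, "geography mapping")
  mapping[needed]
}

#' Normalise raw geographic area labels
#'
#' Collapses free-text area labels into the four analysis regions used by the
#' geographic preference rule: `worldwide`, `europe` (EU member states plus
#' Russia, Turkey and Iceland), `usa`, and `other` for everything else.
#' Matching is case-insensitive and idempotent (already-normalised labels map
#' to themselves). Unknown labels are reported once per distinct label per
#' session via a warning, then mapped to `other`.
#'
#' @param raw_label Character vector of raw area labels.
#' @param mapping Mapping list as returned by [default_geography_mapping()].
#' @param quiet If `TRUE`, suppress the unknown-label warning.
#' @return Character vector, same length, with values in
#'   `c("worldwide", "europe", "usa", "other")`.
#' @examples
#' normalize_geography(c("Worldwide", "Iceland", "Japan"))
#' @export
normalize_geography <- function(raw_label,
                                mapping = default_geography_mapping(),
                                quiet = FALSE) {
  key <- tolower(trimws(raw_label))
  lookup <- c(
    setNames(rep("worldwide", length(mapping$worldwide) + 1),
             c("worldwide", tolower(mapping$worldwide))),
    setNames(rep("europe", length(mapping$europe) + 1),
             c("europe", tolower(mapping$europe))),
    setNames(rep("usa", length(mapping$usa) + 1),
             c("usa", tolower(mapping$usa))),
    other = "other"
  )
  out <- unname(lookup[key])
  unknown <- unique(raw_label[is.na(out) & !is.na(raw_label)])
  if (length(unknown) > 0 && !quiet) {
    new <- setdiff(unknown, the$seen_unknown)
    if (length(new) > 0) {
      the$seen_unknown <- c(the$seen_unknown, new)
      warn(sprintf("unrecognised geographic label(s) mapped to 'other': %s",
                   paste(new, collapse = ", ")))
    }
  }
  out[is.na(out)] <- "other"
  out
}
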