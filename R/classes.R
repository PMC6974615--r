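#' Predefined prevalence classes
#'
#' The six predefined point-prevalence ranges used by the knowledge base,
#' with their minimum and maximum boundary values expressed in cases per
#' 100,000 persons. The rarest class (<1/1,000,000) is degenerate by
#' convention: both boundaries are set to 1 per 1,000,000 (0.1 per 100,000).
#' The two most common classes (6-9/10,000 and >1/1,000) lie above the
#' European rarity threshold of 5/10,000 and are excluded from cumulative
#' prevalence analysis by [filter_rarity_threshold()].
#'
#' @return A tibble with columns `class_label`, `min_per_100k`,
#'   `max_per_100k`, `includable` (logical: below the rarity threshold) and
#'   `pretty` (display label), ordered from rarest to most common.
#' @examples
#' prevalence_classes()
#' @export
prevalence_classes <- function() {
  tibble(
    class_label = c("lt_1_per_1M", "from_1_to_9_per_1M",
                    "from_1_to_9_per_100k", "from_1_to_5_per_10k",
                    "from_6_to_9_per_10k", "gt_1_per_1k"),
    min_per_100k = c(0.1, 0.1, 1, 10, 60, 100),
    max_per_100k = c(0.1, 0.9, 9, 50, 90, Inf),
    includable = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    pretty = c("<1 / 1 000 000", "1-9 / 1 000 000", "1-9 / 100 000",
               "1-5 / 10 000", "6-9 / 10 000", ">1 / 1 000")
  )
}

# cached label vectors
class_labels <- function() prevalence_classes()$class_label
includable_classes <- function() {
  cl <- prevalence_classes()
  cl$class_label[cl$includable]
}

#' European rarity threshold in cases per 100,000
#'
#' A disease is rare in Europe if its point prevalence does not exceed
#' 5 per 10,000, i.e. 50 per 100,000. Diseases whose mean prevalence
#' exceeds this threshold are excluded from the cumulative estimate.
#'
#' @return The scalar 50 (cases per 100,000).
#' @export
rarity_threshold_per_100k <- function() 50

#' Boundary values of a prevalence class
#'
#' Returns the minimum and maximum boundary values (per 100,000) assigned to
#' diseases known only by a prevalence class: the class minimum feeds the
#' minimum cumulative bound and the class maximum the maximum bound. Only
#' the four classes at or below the rarity threshold are accepted.
#'
#' @param class_label Character vector of class labels (see
#'   [prevalence_classes()]).
#' @return A tibble with columns `class_label`, `min_per_100k`,
#'   `max_per_100k`, one row per input element.
#' @examples
#' class_bounds("from_1_to_9_per_100k") # 1 and 9 per 100,000
#' class_bounds("lt_1_per_1M")          # both boundaries 0.1 per 100,000
#' @export
class_bounds <- function(class_label) {
  cl <- prevalence_classes()
  bad <- setdiff(class_label, cl$class_label)
  if (length(bad) > 0) {
    abort(sprintf("unknown prevalence class label(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  not_ok <- setdiff(class_label, includable_classes())
  if (length(not_ok) > 0) {
    abort(sprintf(
      "class(es) above the rarity threshold have no analysis bounds: %s",
      paste(unique(not_ok), collapse = ", ")))
  }
  idx <- match(class_label, cl$class_label)
  tibble(class_label = class_label,
         min_per_100k = cl$min_per_100k[idx],
         max_per_100k = cl$max_per_100k[idx])
}

#' Assign a prevalence class to a numeric mean prevalence
#'
#' Maps a mean point prevalence (per 100,000) to one of the four includable
#' prevalence classes. Intervals are half-open on the right — \[0, 0.1) is
#' <1/1,000,000, \[0.1, 1) is 1-9/1,000,000, \[1, 10) is 1-9/100,000 — with
#' the topmost includable class closed at the rarity threshold, \[10, 50\],
#' so that every mean in \[0, 50\] maps to exactly one class. Values above
#' the threshold are a contract violation: they must have been removed by
#' [filter_rarity_threshold()] beforehand.
#'
#' @param mean_per_100k Numeric vector of mean point prevalences, per
#'   100,000, each in \[0, 50\].
#' @return Character vector of class labels.
#' @examples
#' assign_class(c(0.05, 0.1, 1, 9.99, 10, 50))
#' @export
assign_class <- function(mean_per_100k) {
  if (any(is.na(mean_per_100k)) || any(mean_per_100k < 0)) {
    abort("mean_per_100k must be nonnegative and non-missing")
  }
  if (any(mean_per_100k > rarity_threshold_per_100k())) {
    abort("mean prevalence exceeds the rarity threshold of 50 per 100,000; such disorders must be excluded before class assignment")
  }
  cut_points <- c(0, 0.1, 1, 10)
  labels <- includable_classes()
  labels[findInterval(mean_per_100k, cut_points)]
}
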