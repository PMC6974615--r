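# enum vocabularies of the knowledge-file dialect
entity_levels <- function() c("group", "disorder", "subtype")
indicator_types <- function() {
  c("point_prevalence", "birth_prevalence", "lifetime_prevalence",
    "annual_incidence", "case_report", "family_report")
}
value_kinds <- function() c("numeric", "class", "count", "unknown", "not_documented")
domain_flags <- function() c("cancer", "infectious_disease", "poisoning", "genetic")
onset_tags <- function() c("pediatric", "adult")
inheritance_tags <- function() {
  c("autosomal_dominant", "autosomal_recessive", "x_linked", "mitochondrial",
    "chromosomal", "multigenic_multifactorial", "unknown", "not_applicable")
}
geography_regions <- function() c("worldwide", "europe", "usa", "other")

#' Construct disorder entities
#'
#' Builds a catalogue tibble of clinical entities, one row per entity. An
#' entity is either a unique clinical disorder, a group of disorders, or a
#' disorder subtype; only the disorder level enters the prevalence analysis
#' (groups and subtypes would double-count the same patients). Medical-domain
#' flags, age-of-onset tags and inheritance tags are carried as entity
#' attributes supplied by the classification source.
#'
#' @param entity_id Integer vector of unique positive identifiers
#'   (ORPHAcode-like).
#' @param name Character vector of entity names.
#' @param level `"group"`, `"disorder"` or `"subtype"`.
#' @param cancer,infectious_disease,poisoning,genetic Logical medical-domain
#'   flags.
#' @param onset Space-separated onset tags among `"pediatric"`, `"adult"`;
#'   `""` when age of onset is not documented.
#' @param inheritance Space-separated inheritance tags (see
#'   `inheritance_tags`); `""` when none are annotated.
#' @return A validated entity tibble.
#' @examples
#' disorder_entities(1:2, c("A", "B"), level = c("disorder", "group"))
#' @export
disorder_entities <- function(entity_id, name = paste("Entity", entity_id),
                              level = "disorder", cancer = FALSE,
                              infectious_disease = FALSE, poisoning = FALSE,
                              genetic = FALSE, onset = "", inheritance = "") {
  out <- tibble(
    entity_id = as.integer(entity_id),
    name = as.character(name),
    level = level,
    cancer = cancer,
    infectious_disease = infectious_disease,
    poisoning = poisoning,
    genetic = genetic,
    onset = onset,
    inheritance = inheritance
  )
  validate_entities(out)
  out
}

#' Construct epidemiology annotations
#'
#' Builds an annotation tibble, one row per evidence record. Each record
#' carries an epidemiological indicator, the kind of value recorded, exactly
#' one of a numeric magnitude (cases per 100,000), a prevalence class label,
#' or a reported case/family count, and a geographic area (raw label plus
#' normalised region).
#'
#' @param entity_id Integer vector referencing [disorder_entities()] rows.
#' @param indicator Indicator type (see `indicator_types`).
#' @param value_kind One of `"numeric"`, `"class"`, `"count"`, `"unknown"`,
#'   `"not_documented"`.
#' @param numeric_value Point prevalence per 100,000 (only for
#'   `value_kind = "numeric"`).
#' @param class_label Prevalence class label (only for `value_kind = "class"`).
#' @param count_value Number of reported cases or families (only for
#'   `value_kind = "count"`).
#' @param geography_raw Raw free-text area label.
#' @param geography Normalised region; computed from `geography_raw` with
#'   [normalize_geography()] when omitted.
#' @return A validated annotation tibble.
#' @examples
#' epidemiology_annotations(1, "point_prevalence", "numeric",
#'                          numeric_value = 2, geography_raw = "Worldwide")
#' @export
epidemiology_annotations <- function(entity_id, indicator = "point_prevalence",
                                     value_kind = "numeric",
                                     numeric_value = NA_real_,
                                     class_label = NA_character_,
                                     count_value = NA_integer_,
                                     geography_raw = "Worldwide",
                                     geography = NULL) {
  if (is.null(geography)) geography <- normalize_geography(geography_raw, quiet = TRUE)
  out <- tibble(
    entity_id = as.integer(entity_id),
    indicator = indicator,
    value_kind = value_kind,
    numeric_value = as.numeric(numeric_value),
    class_label = as.character(class_label),
    count_value = as.integer(count_value),
    geography_raw = as.character(geography_raw),
    geography = geography
  )
  validate_annotations(out)
  out
}

#' Validate an entity table
#'
#' Checks column presence, identifier uniqueness and positivity, the entity
#' level enum, and the onset/inheritance tag vocabularies. Called by all
#' readers and constructors; exported so user-assembled tables can be checked.
#'
#' @param entities Entity tibble.
#' @return `entities`, invisibly, on success; otherwise an error.
#' @export
validate_entities <- function(entities) {
  assert_columns(entities, c("entity_id", "name", "level", "cancer",
                             "infectious_disease", "poisoning", "genetic",
                             "onset", "inheritance"), "entity table")
  if (nrow(entities) == 0) return(invisible(entities))
  if (anyNA(entities$entity_id) || any(entities$entity_id <= 0)) {
    abort("entity_id must be a positive integer")
  }
  dup <- entities$entity_id[duplicated(entities$entity_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated entity_id: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- !entities$level %in% entity_levels()
  if (any(bad)) {
    abort(sprintf("entity %d has unknown level token '%s'",
                  entities$entity_id[bad][1], entities$level[bad][1]))
  }
  for (col in c("cancer", "infectious_disease", "poisoning", "genetic")) {
    if (!is.logical(entities[[col]]) || anyNA(entities[[col]])) {
      abort(sprintf("domain flag '%s' must be TRUE/FALSE", col))
    }
  }
  check_tokens(entities, "onset", onset_tags())
  check_tokens(entities, "inheritance", inheritance_tags())
  invisible(entities)
}

check_tokens <- function(entities, col, vocab) {
  toks <- split_tokens(entities[[col]])
  bad <- vapply(toks, function(v) length(setdiff(v, vocab)) > 0, logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("entity %d has unknown %s token '%s'",
                  entities$entity_id[i], col,
                  setdiff(toks[[i]], vocab)[1]))
  }
}

#' Validate an annotation table
#'
#' Enforces the evidence-record contract: known indicator and value-kind
#' tokens, exactly one payload (numeric value, class label, or count)
#' matching the value kind, nonnegative magnitudes, known class labels, and
#' a normalised geography region.
#'
#' @param annotations Annotation tibble.
#' @return `annotations`, invisibly, on success; otherwise an error.
#' @export
validate_annotations <- function(annotations) {
  assert_columns(annotations, c("entity_id", "indicator", "value_kind",
                                "numeric_value", "class_label", "count_value",
                                "geography_raw", "geography"),
                 "annotation table")
  if (nrow(annotations) == 0) return(invisible(annotations))
  fail <- function(i, msg, token) {
    abort(sprintf("annotation for entity %d: %s '%s'",
                  annotations$entity_id[i], msg, token))
  }
  bad <- !annotations$indicator %in% indicator_types()
  if (any(bad)) fail(which(bad)[1], "unknown indicator token",
                     annotations$indicator[bad][1])
  bad <- !annotations$value_kind %in% value_kinds()
  if (any(bad)) fail(which(bad)[1], "unknown value_kind token",
                     annotations$value_kind[bad][1])
  bad <- !annotations$geography %in% geography_regions()
  if (any(bad)) fail(which(bad)[1], "unknown geography token",
                     annotations$geography[bad][1])
  has <- cbind(numeric = !is.na(annotations$numeric_value),
               class = !is.na(annotations$class_label),
               count = !is.na(annotations$count_value))
  expected <- cbind(numeric = annotations$value_kind == "numeric",
                    class = annotations$value_kind == "class",
                    count = annotations$value_kind == "count")
  mism <- which(rowSums(has != expected) > 0)
  if (length(mism) > 0) {
    abort(sprintf(
      "annotation for entity %d: payload does not match value_kind '%s' (exactly one of numeric_value/class_label/count_value must be set, matching the kind)",
      annotations$entity_id[mism[1]], annotations$value_kind[mism[1]]))
  }
  if (any(annotations$numeric_value < 0, na.rm = TRUE)) {
    abort("numeric_value must be nonnegative")
  }
  if (any(annotations$count_value < 0, na.rm = TRUE)) {
    abort("count_value must be nonnegative")
  }
  bad_class <- setdiff(annotations$class_label[!is.na(annotations$class_label)],
                       class_labels())
  if (length(bad_class) > 0) {
    i <- which(annotations$class_label %in% bad_class)[1]
    fail(i, "unknown class token", bad_class[1])
  }
  invisible(annotations)
}

# canonical row order guaranteeing byte-identical serialisation of
# permutation-equivalent datasets
canonical_entities <- function(entities) {
  arrange(entities, .data$entity_id)
}

canonical_annotations <- function(annotations) {
  arrange(annotations, .data$entity_id, .data$indicator, .data$value_kind,
          .data$class_label, .data$numeric_value, .data$count_value,
          .data$geography, .data$geography_raw)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write an epidemiology knowledge file
#'
#' Serialises an entity and annotation table to the package's XML dialect
#' (schema shipped as `extdata/epidemiology.xsd`). Output is canonical:
#' entities are sorted by identifier and annotations by a full deterministic
#' key, so two permutations of the same data produce byte-identical files
#' and [read_epidemiology_file()] round-trips exactly.
#'
#' @param entities Entity tibble (see [disorder_entities()]).
#' @param annotations Annotation tibble (see [epidemiology_annotations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epidemiology_file <- function(entities, annotations, path) {
  validate_entities(entities)
  validate_annotations(annotations)
  orphan <- setdiff(annotations$entity_id, entities$entity_id)
  if (length(orphan) > 0) {
    abort(sprintf("annotation references unknown entity_id: %s",
                  paste(unique(orphan), collapse = ", ")))
  }
  e <- canonical_entities(entities)
  a <- canonical_annotations(annotations)
  ent_xml <- if (nrow(e) == 0) character() else sprintf(
    paste0("    <Disorder id=\"%d\">\n",
           "      <Name>%s</Name>\n",
           "      <Level>%s</Level>\n",
           "      <DomainFlags>%s</DomainFlags>\n",
           "      <OnsetTags>%s</OnsetTags>\n",
           "      <InheritanceTags>%s</InheritanceTags>\n",
           "    </Disorder>"),
    e$entity_id, xml_escape(e$name), e$level,
    mapply(function(c1, c2, c3, c4) {
      join_tokens(c("cancer", "infectious_disease", "poisoning",
                    "genetic")[c(c1, c2, c3, c4)])
    }, e$cancer, e$infectious_disease, e$poisoning, e$genetic),
    e$onset, e$inheritance)
  payload <- character(nrow(a))
  if (nrow(a) > 0) {
    payload <- dplyr::case_when(
      a$value_kind == "numeric" ~
        sprintf("      <ValuePer100k>%s</ValuePer100k>\n",
                format_number(a$numeric_value)),
      a$value_kind == "class" ~
        sprintf("      <Class>%s</Class>\n", a$class_label),
      a$value_kind == "count" ~
        sprintf("      <Count>%d</Count>\n", a$count_value),
      TRUE ~ ""
    )
  }
  ann_xml <- if (nrow(a) == 0) character() else sprintf(
    paste0("    <Prevalence disorder=\"%d\">\n",
           "      <Indicator>%s</Indicator>\n",
           "      <ValueKind>%s</ValueKind>\n",
           "%s",
           "      <Geography area=\"%s\">%s</Geography>\n",
           "    </Prevalence>"),
    a$entity_id, a$indicator, a$value_kind, payload,
    xml_escape(a$geography_raw), a$geography)
  doc <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<EpidemiologyData version=\"1.0\">",
    sprintf("  <DisorderList count=\"%d\">", nrow(e)),
    ent_xml,
    "  </DisorderList>",
    sprintf("  <PrevalenceList count=\"%d\">", nrow(a)),
    ann_xml,
    "  </PrevalenceList>",
    "</EpidemiologyData>"
  )
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Read an epidemiology knowledge file
#'
#' Parses a knowledge file in the package's XML dialect into the entity and
#' annotation tables consumed by the selection stage. Every element is
#' returned exactly once, in canonical order; raw geographic labels are
#' preserved alongside the normalised region stored in the file. Malformed
#' XML raises a parse error naming the offending line; unknown enum tokens
#' and duplicated identifiers raise validation errors naming the entity.
#'
#' @param path Path to the XML file.
#' @param xsd Optional path to an XSD schema to validate against first
#'   (defaults to none; the packaged schema is in
#'   `system.file("extdata", "epidemiology.xsd", package = "raremetrics")`).
#' @return A list with elements `entities` and `annotations`.
#' @export
read_epidemiology_file <- function(path, xsd = NULL) {
  doc <- xml2::read_xml(path)
  if (!is.null(xsd)) {
    ok <- xml2::xml_validate(doc, xml2::read_xml(xsd))
    if (!ok) {
      abort(paste0("schema validation failed: ",
                   paste(attr(ok, "errors"), collapse = "; ")))
    }
  }
  dis <- xml2::xml_find_all(doc, "/EpidemiologyData/DisorderList/Disorder")
  txt <- function(nodes, xpath) {
    xml2::xml_text(xml2::xml_find_first(nodes, xpath))
  }
  if (length(dis) == 0) {
    entities <- disorder_entities(integer())
  } else {
    flags <- split_tokens(txt(dis, "DomainFlags"))
    has_flag <- function(f) vapply(flags, function(v) f %in% v, logical(1))
    entities <- tibble(
      entity_id = as.integer(xml2::xml_attr(dis, "id")),
      name = txt(dis, "Name"),
      level = txt(dis, "Level"),
      cancer = has_flag("cancer"),
      infectious_disease = has_flag("infectious_disease"),
      poisoning = has_flag("poisoning"),
      genetic = has_flag("genetic"),
      onset = txt(dis, "OnsetTags"),
      inheritance = txt(dis, "InheritanceTags")
    )
    validate_entities(entities)
  }
  prev <- xml2::xml_find_all(doc, "/EpidemiologyData/PrevalenceList/Prevalence")
  if (length(prev) == 0) {
    annotations <- epidemiology_annotations(integer())
  } else {
    geo_nodes <- xml2::xml_find_first(prev, "Geography")
    annotations <- tibble(
      entity_id = as.integer(xml2::xml_attr(prev, "disorder")),
      indicator = txt(prev, "Indicator"),
      value_kind = txt(prev, "ValueKind"),
      numeric_value = as.numeric(txt(prev, "ValuePer100k")),
      class_label = txt(prev, "Class"),
      count_value = as.integer(txt(prev, "Count")),
      geography_raw = xml2::xml_attr(geo_nodes, "area"),
      geography = xml2::xml_text(geo_nodes)
    )
    validate_annotations(annotations)
  }
  orphan <- setdiff(annotations$entity_id, entities$entity_id)
  if (length(orphan) > 0) {
    abort(sprintf("annotation references unknown entity_id: %s",
                  paste(unique(orphan), collapse = ", ")))
  }
  list(entities = canonical_entities(entities),
       annotations = canonical_annotations(annotations))
}

#' Export the flat annotation table
#'
#' Joins annotations to their entities and writes (or returns) the flat
#' per-record table used for spreadsheet inspection.
#'
#' @param entities Entity tibble.
#' @param annotations Annotation tibble.
#' @param path Optional TSV output path; when `NULL` the tibble is returned
#'   only.
#' @return The flat tibble with columns `entity_id`, `level`, `indicator`,
#'   `value_kind`, `value`, `class`, `geography_raw`, `geography_norm`.
#' @export
export_annotation_table <- function(entities, annotations, path = NULL) {
  validate_entities(entities)
  validate_annotations(annotations)
  flat <- canonical_annotations(annotations) |>
    left_join(select(entities, "entity_id", "level"), by = "entity_id") |>
    mutate(value = dplyr::coalesce(.data$numeric_value,
                                   as.numeric(.data$count_value))) |>
    select("entity_id", "level", "indicator", "value_kind", "value",
           class = "class_label", "geography_raw",
           geography_norm = "geography")
  if (!is.null(path)) readr::write_tsv(flat, path)
  flat
}
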