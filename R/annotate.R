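#' Default functional category keyword map
#'
#' The four screening categories with case-insensitive keyword/regex
#' patterns matched against cluster descriptions and KOG classes. The
#' defaults are seeded from gene families typical of each category
#' (carbon metabolism including hydrocarbon and carbohydrate turnover,
#' light reactions including pigment turnover, signaling, and inorganic
#' ion transport); they are a reproducible, auditable stand-in for
#' manual curation and can be replaced via YAML
#' (see [read_category_map()]).
#'
#' @return Named list of character vectors of regex patterns, with class
#'   `crmarray_category_map`.
#' @export
default_category_map <- function() {
  category_map(list(
    carbon_metabolism = c(
      "carbonic anhydrase", "bisphosphatase", "carboxylase", "carboxykinase",
      "dehydrogenase", "glycolysis", "gluconeogenesis", "pentose phosphate",
      "glucan", "glucose", "fructose", "malate", "pyruvate", "citrate",
      "isocitrate lyase", "malate synthase", "acyl-coa", "thiolase",
      "rubisco", "phosphoenolpyruvate"
    ),
    light_reactions = c(
      "chlorophyll", "fucoxanthin", "photosystem", "light-harvesting",
      "xanthin", "xanthophyll", "carotenoid", "epoxidase", "de-epoxidase",
      "plastocyanin", "ferredoxin", "porphyrinogen", "phytoene", "rhodopsin"
    ),
    signaling = c(
      "kinase", "phosphatase 2", "calmodulin", "cyclase", "g-protein",
      "gtpase", "signal transduction", "receptor", "14-3-3",
      "cyclic nucleotide"
    ),
    ion_fluxes = c(
      "antiporter", "symporter", "ion channel", "atpase", "transporter",
      "translocator", "aquaporin", "bicarbonate", "hco3", "v-type",
      "exchanger"
    )
  ))
}

#' Construct and validate a category map
#'
#' @param x Named list: category name -> non-empty character vector of
#'   lower-case keyword/regex patterns. Categories must be exactly
#'   `carbon_metabolism`, `light_reactions`, `signaling`, `ion_fluxes`.
#' @return The validated map with class `crmarray_category_map`.
#' @export
category_map <- function(x) {
  expected <- c("carbon_metabolism", "light_reactions", "signaling",
                "ion_fluxes")
  if (!setequal(names(x), expected)) {
    abort(sprintf("category map must define exactly: %s",
                  paste(expected, collapse = ", ")),
          class = "crmarray_config_error")
  }
  lens <- vapply(x, length, integer(1))
  if (any(lens == 0)) {
    abort("every category needs at least one keyword",
          class = "crmarray_config_error")
  }
  structure(x[expected], class = "crmarray_category_map")
}

#' Read a category map from YAML
#' @param path YAML file mapping the four category names to keyword
#'   lists.
#' @return A validated `crmarray_category_map`.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "crmarray_io_error")
  }
  raw <- yaml::read_yaml(path)
  category_map(lapply(raw, as.character))
}

#' Apply e-value filters to an annotation table
#'
#' Removes model hits whose e-value is strictly greater than
#' `cfg$evalue_blast` (the hit and its e-value are blanked; a surviving
#' second model is promoted to first place so the ordering invariant is
#' kept). When the table carries a `b2g_evalue` column, descriptions
#' whose e-value is strictly greater than `cfg$evalue_b2g` are blanked
#' too. Clusters with no surviving evidence are marked
#' `annotated = FALSE` but never dropped.
#'
#' @param ann Annotation tibble from [read_annotation_table()].
#' @param cfg A [pipeline_config()].
#' @return The filtered tibble with an added logical `annotated` column.
#' @export
filter_annotations <- function(ann, cfg = pipeline_config()) {
  drop1 <- !is.na(ann$evalue_1) & ann$evalue_1 > cfg$evalue_blast
  drop2 <- !is.na(ann$evalue_2) & ann$evalue_2 > cfg$evalue_blast
  ann$model_1[drop1] <- NA_character_
  ann$evalue_1[drop1] <- NA_real_
  ann$model_2[drop2] <- NA_character_
  ann$evalue_2[drop2] <- NA_real_
  promote <- is.na(ann$model_1) & !is.na(ann$model_2)
  ann$model_1[promote] <- ann$model_2[promote]
  ann$evalue_1[promote] <- ann$evalue_2[promote]
  ann$model_2[promote] <- NA_character_
  ann$evalue_2[promote] <- NA_real_
  if ("b2g_evalue" %in% names(ann)) {
    dropd <- !is.na(ann$b2g_evalue) & ann$b2g_evalue > cfg$evalue_b2g
    ann$description[dropd] <- NA_character_
    ann$b2g_evalue[dropd] <- NA_real_
  }
  ann$annotated <- !is.na(ann$model_1) | !is.na(ann$description) |
    (!is.na(ann$kog_class) & nzchar(ann$kog_class))
  ann
}

#' Assign functional categories by keyword matching
#'
#' A cluster is tagged with a category when any of the category's
#' patterns matches its description or KOG class (case-insensitive
#' regex). Multi-label assignment is allowed; each (cluster, category)
#' pair appears at most once. Deterministic for a fixed map.
#'
#' @param ann Filtered annotation tibble (see [filter_annotations()]).
#' @param map A `crmarray_category_map`.
#' @return Tibble with columns `cluster_id`, `category` (long format,
#'   zero rows for untagged clusters).
#' @export
assign_categories <- function(ann, map = default_category_map()) {
  if (!inherits(map, "crmarray_category_map")) map <- category_map(map)
  text <- paste(
    ifelse(is.na(ann$description), "", ann$description),
    ifelse(is.na(ann$kog_class), "", ann$kog_class)
  )
  out <- list()
  for (cat in names(map)) {
    pattern <- paste0("(", paste(map[[cat]], collapse = ")|("), ")")
    hits <- grepl(pattern, text, ignore.case = TRUE, perl = TRUE) &
      nzchar(trimws(text))
    if (any(hits)) {
      out[[cat]] <- tibble::tibble(cluster_id = ann$cluster_id[hits],
                                   category = cat)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(cluster_id = character(), category = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Category counts per gene set
#'
#' For each directed gene set and category, counts tagged members split
#' by direction, plus the per-set total of members assigned to at least
#' one category. A multi-label cluster counts once per category but once
#' in the categorized total.
#'
#' @param sets Named list of [directed_gene_set()]s (or a single set).
#' @param tags Tibble from [assign_categories()].
#' @return A list: `counts` - tibble (set_label, category, up, down) -
#'   and `categorized_total` - tibble (set_label, n_categorized,
#'   set_size).
#' @export
category_counts <- function(sets, tags) {
  if (inherits(sets, "directed_gene_set")) {
    sets <- setNames(list(sets), sets$label)
  }
  cats <- c("carbon_metabolism", "light_reactions", "signaling",
            "ion_fluxes")
  counts <- list()
  totals <- list()
  for (nm in names(sets)) {
    members <- sets[[nm]]$members
    tagged <- dplyr::inner_join(members, tags, by = "cluster_id")
    per_cat <- lapply(cats, function(cat) {
      sub <- tagged[tagged$category == cat, ]
      tibble::tibble(set_label = nm, category = cat,
                     up = sum(sub$direction == "up"),
                     down = sum(sub$direction == "down"))
    })
    counts[[nm]] <- dplyr::bind_rows(per_cat)
    totals[[nm]] <- tibble::tibble(
      set_label = nm,
      n_categorized = length(unique(tagged$cluster_id)),
      set_size = nrow(members)
    )
  }
  list(counts = dplyr::bind_rows(counts),
       categorized_total = dplyr::bind_rows(totals))
}

#' Write a category map to YAML
#' @param map A `crmarray_category_map`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_category_map <- function(map, path) {
  yaml::write_yaml(lapply(unclass(map), as.list), path)
  invisible(path)
}
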