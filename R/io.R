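#' Read a long-format probe intensity table
#'
#' One row per probe per array, with the two channel intensities of the
#' common-reference hybridization. Rows with non-positive intensities or
#' `qc_ok = FALSE` are retained but flagged (`qc_ok` forced to `FALSE`);
#' downstream stages decide exclusion.
#'
#' @param path Path to a TSV with columns `array_id`, `probe_id`,
#'   `cluster_id`, `is_control`, `sample_intensity`,
#'   `reference_intensity`, `qc_ok`.
#' @return A tibble of probe records, one per input row.
#' @seealso [write_probe_table()], [simulate_experiment()]
#' @export
read_probe_table <- function(path) {
  required <- c("array_id", "probe_id", "cluster_id", "is_control",
                "sample_intensity", "reference_intensity", "qc_ok")
  probes <- .read_tsv_checked(path, required, col_types = readr::cols(
    array_id = readr::col_character(),
    probe_id = readr::col_character(),
    cluster_id = readr::col_character(),
    is_control = readr::col_logical(),
    sample_intensity = readr::col_double(),
    reference_intensity = readr::col_double(),
    qc_ok = readr::col_logical()
  ))
  validate_probe_table(probes)
}

#' Validate an in-memory probe table
#'
#' Enforces the probe-table invariants: unique (array, probe) rows, a
#' single cluster per probe, and at most 3 probes per non-control
#' cluster. Rows with non-positive intensities are flagged
#' `qc_ok = FALSE` rather than dropped.
#'
#' @param probes Tibble with the probe-table columns.
#' @return The validated (possibly re-flagged) tibble.
#' @export
validate_probe_table <- function(probes) {
  dup <- duplicated(probes[c("array_id", "probe_id")])
  if (any(dup)) {
    abort(sprintf("duplicate (array_id, probe_id) rows, e.g. (%s, %s)",
                  probes$array_id[dup][1], probes$probe_id[dup][1]),
          class = "crmarray_integrity_error")
  }
  map <- dplyr::distinct(probes, .data$probe_id, .data$cluster_id)
  multi <- map$probe_id[duplicated(map$probe_id)]
  if (length(multi) > 0) {
    abort(sprintf("probe %s maps to more than one cluster_id", multi[1]),
          class = "crmarray_integrity_error")
  }
  noncontrol <- dplyr::distinct(probes[!probes$is_control, ],
                                .data$probe_id, .data$cluster_id)
  per_cluster <- dplyr::count(noncontrol, .data$cluster_id)
  if (any(per_cluster$n > 3)) {
    bad <- per_cluster$cluster_id[per_cluster$n > 3][1]
    abort(sprintf("non-control cluster %s has more than 3 probes", bad),
          class = "crmarray_integrity_error")
  }
  bad_intensity <- !(probes$sample_intensity > 0 &
                       probes$reference_intensity > 0) |
    is.na(probes$sample_intensity) | is.na(probes$reference_intensity)
  probes$qc_ok <- probes$qc_ok & !bad_intensity
  probes
}

#' Write a probe table
#' @param probes Probe tibble as returned by [read_probe_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path)
  invisible(path)
}

#' Read an experiment design table
#'
#' Validates the 2 stage x 2 pCO2 x 2 light factorial design with up to
#' 3 biological replicates per cell. Cells with fewer than 3 replicates
#' are reported in the `incomplete_cells` attribute, not treated as an
#' error.
#'
#' @param path TSV with columns `array_id`, `stage`, `pco2_pa`,
#'   `light_umol`, `replicate`, `sample_dye`.
#' @return A validated design tibble with attribute `incomplete_cells`.
#' @export
read_design <- function(path) {
  required <- c("array_id", "stage", "pco2_pa", "light_umol", "replicate",
                "sample_dye")
  design <- .read_tsv_checked(path, required, col_types = readr::cols(
    array_id = readr::col_character(),
    stage = readr::col_character(),
    pco2_pa = readr::col_double(),
    light_umol = readr::col_double(),
    replicate = readr::col_integer(),
    sample_dye = readr::col_character()
  ))
  validate_design(design)
}

#' Validate an in-memory design table
#' @param design Tibble with the design columns.
#' @return The design with attribute `incomplete_cells` (tibble of
#'   (stage, pco2_pa, light_umol) cells having fewer than 3 replicates).
#' @export
validate_design <- function(design) {
  .check_enum(design$stage, c("diploid", "haploid"), "stage")
  .check_enum(design$pco2_pa, c(38.5, 101.3), "pco2_pa")
  .check_enum(design$light_umol, c(50, 300), "light_umol")
  .check_enum(design$sample_dye, c("cy3", "cy5"), "sample_dye")
  if (any(!design$replicate %in% 1:3)) {
    abort("replicate must be 1, 2 or 3", class = "crmarray_format_error")
  }
  key <- design[c("stage", "pco2_pa", "light_umol", "replicate")]
  if (any(duplicated(key))) {
    abort("duplicate (stage, pco2_pa, light_umol, replicate) combination",
          class = "crmarray_integrity_error")
  }
  if (any(duplicated(design$array_id))) {
    abort("duplicate array_id in design", class = "crmarray_integrity_error")
  }
  cells <- dplyr::count(design, .data$stage, .data$pco2_pa, .data$light_umol)
  full <- tidyr::expand_grid(stage = c("diploid", "haploid"),
                             pco2_pa = c(38.5, 101.3),
                             light_umol = c(50, 300))
  cells <- dplyr::left_join(full, cells,
                            by = c("stage", "pco2_pa", "light_umol"))
  cells$n[is.na(cells$n)] <- 0L
  incomplete <- cells[cells$n < 3, ]
  attr(design, "incomplete_cells") <- incomplete
  design
}

#' Write a design table
#' @param design Design tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' Read a cluster annotation table
#'
#' One row per transcript cluster: the two best aligning (but different)
#' transcript models with their e-values, a KOG class, and a free-text
#' description. Empty fields (`"."` or blank) are parsed as absent. No
#' e-value filtering happens here; see [filter_annotations()]. An
#' optional `b2g_evalue` column carries the alignment e-value backing
#' the description.
#'
#' @param path TSV with columns `cluster_id`, `model_1`, `evalue_1`,
#'   `model_2`, `evalue_2`, `kog_class`, `description` (and optionally
#'   `b2g_evalue`).
#' @return A tibble of annotation records.
#' @export
read_annotation_table <- function(path) {
  required <- c("cluster_id", "model_1", "evalue_1", "model_2", "evalue_2",
                "kog_class", "description")
  first <- readr::read_tsv(path, n_max = 0, show_col_types = FALSE)
  has_b2g <- "b2g_evalue" %in% names(first)
  types <- readr::cols(
    cluster_id = readr::col_character(),
    model_1 = readr::col_character(),
    evalue_1 = readr::col_character(),
    model_2 = readr::col_character(),
    evalue_2 = readr::col_character(),
    kog_class = readr::col_character(),
    description = readr::col_character()
  )
  ann <- .read_tsv_checked(path, required, col_types = types, na = ".")
  for (col in c("evalue_1", "evalue_2", if (has_b2g) "b2g_evalue")) {
    raw <- ann[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(parsed)
    if (any(bad)) {
      abort(sprintf("malformed e-value in column %s, row %d: %s",
                    col, which(bad)[1], raw[bad][1]),
            class = "crmarray_format_error")
    }
    ann[[col]] <- parsed
  }
  same <- !is.na(ann$model_1) & !is.na(ann$model_2) &
    ann$model_1 == ann$model_2
  if (any(same)) {
    abort(sprintf("model_1 equals model_2 for cluster %s",
                  ann$cluster_id[same][1]),
          class = "crmarray_integrity_error")
  }
  misordered <- !is.na(ann$evalue_1) & !is.na(ann$evalue_2) &
    ann$evalue_1 > ann$evalue_2
  if (any(misordered)) {
    warn(sprintf("%d annotation rows have evalue_1 > evalue_2 (e.g. cluster %s)",
                 sum(misordered), ann$cluster_id[misordered][1]),
         class = "crmarray_integrity_warning")
  }
  ann
}

#' Write an annotation table
#' @param ann Annotation tibble.
#' @param path Output TSV path; absent values are written as `"."`.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  readr::write_tsv(ann, path, na = ".")
  invisible(path)
}

#' Write an annotated gene list
#'
#' One row per (cluster, contrast) call, merged with its annotation and
#' category tags, sorted by `cluster_id` then `contrast` for
#' deterministic output. Absent values are written as `"."`.
#'
#' @param calls Cluster-call tibble from [collapse_all()].
#' @param path Output TSV path.
#' @param annotation Optional annotation tibble (joined on
#'   `cluster_id`).
#' @param categories Optional tibble of (cluster_id, category) tags from
#'   [assign_categories()]; tags are collapsed into a comma-separated
#'   `categories` column.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(calls, path, annotation = NULL,
                            categories = NULL) {
  out <- calls
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out, annotation, by = "cluster_id")
  }
  if (!is.null(categories) && nrow(categories) > 0) {
    tags <- dplyr::summarise(
      dplyr::group_by(categories, .data$cluster_id),
      categories = paste(sort(unique(.data$category)), collapse = ","),
      .groups = "drop"
    )
    out <- dplyr::left_join(out, tags, by = "cluster_id")
  } else {
    out$categories <- NA_character_
  }
  out <- dplyr::arrange(out, .data$cluster_id, .data$contrast)
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read back a gene list written by [write_gene_list()]
#' @param path TSV path.
#' @return A tibble.
#' @export
read_gene_list <- function(path) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE)
}

.read_tsv_checked <- function(path, required, col_types, na = c("", "NA")) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "crmarray_io_error")
  }
  header <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "crmarray_format_error")
  }
  readr::read_tsv(path, col_types = col_types, na = na,
                  show_col_types = FALSE)
}

.check_enum <- function(x, allowed, name) {
  bad <- !x %in% allowed
  if (any(bad)) {
    abort(sprintf("invalid %s value: %s (allowed: %s)", name,
                  x[bad][1], paste(allowed, collapse = ", ")),
          class = "crmarray_format_error")
  }
  invisible(TRUE)
}
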