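#' Construct a directed gene set
#'
#' A named set of (cluster, direction) pairs for one contrast: the unit
#' of the Venn-partition algebra.
#'
#' @param members Tibble or data frame with columns `cluster_id` and
#'   `direction` (`"up"` or `"down"`, one row per cluster).
#' @param label Human-readable set label.
#' @param stage Stage the set belongs to (`"diploid"`, `"haploid"`, or
#'   `"cross-stage"`).
#' @param contrast Contrast label, free-form for derived sets.
#' @return An object of class `directed_gene_set`.
#' @export
directed_gene_set <- function(members, label = "", stage = NA_character_,
                              contrast = NA_character_) {
  members <- tibble::as_tibble(members)[c("cluster_id", "direction")]
  if (any(duplicated(members$cluster_id))) {
    abort("directed gene set members must be unique by cluster_id",
          class = "crmarray_integrity_error")
  }
  if (!all(members$direction %in% c("up", "down"))) {
    abort("directions must be 'up' or 'down'",
          class = "crmarray_integrity_error")
  }
  structure(list(label = label, stage = stage, contrast = contrast,
                 members = members),
            class = "directed_gene_set")
}

#' @export
print.directed_gene_set <- function(x, ...) {
  cat(sprintf("<directed_gene_set> %s [%s, %s]: %d members (%d up, %d down)\n",
              x$label, x$stage, x$contrast, nrow(x$members),
              sum(x$members$direction == "up"),
              sum(x$members$direction == "down")))
  invisible(x)
}

#' @export
length.directed_gene_set <- function(x) nrow(x$members)

#' Up/down/total counts of a directed gene set
#' @param set A [directed_gene_set()].
#' @return Named list with `total`, `up`, `down`.
#' @export
set_counts <- function(set) {
  list(total = nrow(set$members),
       up = sum(set$members$direction == "up"),
       down = sum(set$members$direction == "down"))
}

#' Build a directed gene set from cluster calls
#'
#' Members are the clusters with status `regulated` for the given stage
#' and contrast; excluded and unregulated clusters never enter a set.
#'
#' @param calls Cluster-call tibble from [collapse_all()].
#' @param stage Stage to select.
#' @param contrast Contrast to select.
#' @param label Set label (defaults to `"stage contrast"`).
#' @return A [directed_gene_set()].
#' @export
build_set <- function(calls, stage, contrast, label = NULL) {
  sel <- calls[calls$stage == stage & calls$contrast == contrast &
                 calls$status == "regulated", ]
  directed_gene_set(
    tibble::tibble(cluster_id = sel$cluster_id, direction = sel$direction),
    label = label %||% paste(stage, contrast),
    stage = stage, contrast = contrast
  )
}

#' Venn partition of two directed gene sets
#'
#' Partitions by cluster identity: `core` is the identity intersection,
#' `only_first` / `only_second` the identity set differences. The core
#' inherits the first parent's directions; members whose directions
#' disagree between the parents stay in the core but are listed in
#' `discordant`. Cardinalities therefore obey
#' `|only_first| + |core| = |first|` and
#' `|only_second| + |core| = |second|` exactly.
#'
#' @param first,second [directed_gene_set()] objects.
#' @param label Label prefix for the derived sets.
#' @return A list of class `venn_partition`: `core`, `only_first`,
#'   `only_second` (directed gene sets) and `discordant` (character
#'   vector of cluster ids).
#' @export
intersect_core <- function(first, second, label = NULL) {
  label <- label %||% paste0(first$label, " / ", second$label)
  a <- first$members
  b <- second$members
  shared <- intersect(a$cluster_id, b$cluster_id)
  core_members <- a[a$cluster_id %in% shared, ]
  dir_b <- b$direction[match(core_members$cluster_id, b$cluster_id)]
  discordant <- core_members$cluster_id[core_members$direction != dir_b]
  mk <- function(members, what) {
    directed_gene_set(members, label = paste0(label, " [", what, "]"),
                      stage = first$stage, contrast = "derived")
  }
  structure(
    list(
      core = mk(core_members, "core"),
      only_first = mk(a[!a$cluster_id %in% shared, ], "only_first"),
      only_second = mk(b[!b$cluster_id %in% shared, ], "only_second"),
      discordant = discordant
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> core %d | only_first %d | only_second %d | discordant %d\n",
              length(x$core), length(x$only_first), length(x$only_second),
              length(x$discordant)))
  invisible(x)
}

#' Stage-independent overlap of two core responses
#'
#' Overlaps the per-stage core responses across stages. The identity
#' intersection is computed as in [intersect_core()]; genes reacting
#' uniformly in both stages are those with concordant direction, so the
#' result carries an extra `uniform` set with the discordant members
#' removed.
#'
#' @param core_first,core_second The two stages' core
#'   [directed_gene_set()]s.
#' @return A `venn_partition` with an additional `uniform` element.
#' @export
stage_independent_overlap <- function(core_first, core_second) {
  part <- intersect_core(core_first, core_second,
                         label = "stage-independent overlap")
  keep <- !part$core$members$cluster_id %in% part$discordant
  part$uniform <- directed_gene_set(
    part$core$members[keep, ],
    label = "stage-independent overlap [uniform]",
    stage = "cross-stage", contrast = "derived"
  )
  part
}

#' Full Venn count report
#'
#' Builds the eight primary sets (2 stages x 4 contrasts), the per-stage
#' OA core responses and light-specific differences, and the cross-stage
#' overlap of the OA cores, and reports `total`/`up`/`down` for each,
#' with partition cardinalities. Set labels A-F follow the factorial
#' layout: A = diploid OA response at high light, B = diploid OA at low
#' light, C = A intersect B; D, E, F analogous for the haploid stage.
#'
#' @param calls Cluster-call tibble from [collapse_all()].
#' @return A nested list (JSON-ready): `sets` (per primary set), `oa`
#'   (per-stage partitions and the cross-stage overlap). Every reported
#'   set satisfies `up + down = total`.
#' @export
venn_counts <- function(calls) {
  sets <- list()
  for (stage in c("diploid", "haploid")) {
    for (ct in contrast_labels()) {
      sets[[paste(stage, ct, sep = ":")]] <- build_set(calls, stage, ct)
    }
  }
  A <- sets[["diploid:co2_at_highlight"]]
  B <- sets[["diploid:co2_at_lowlight"]]
  D <- sets[["haploid:co2_at_highlight"]]
  E <- sets[["haploid:co2_at_lowlight"]]
  dip <- intersect_core(A, B, label = "C = A & B")
  hap <- intersect_core(D, E, label = "F = D & E")
  cross <- stage_independent_overlap(dip$core, hap$core)

  part_counts <- function(p) {
    out <- list(
      core = set_counts(p$core),
      only_first = set_counts(p$only_first),
      only_second = set_counts(p$only_second),
      discordant = length(p$discordant)
    )
    if (!is.null(p$uniform)) out$uniform <- set_counts(p$uniform)
    out
  }
  list(
    sets = lapply(sets, set_counts),
    oa = list(
      diploid = part_counts(dip),
      haploid = part_counts(hap),
      stage_independent = part_counts(cross)
    )
  )
}

#' Write gene-set members to TSV files
#' @param sets Named list of [directed_gene_set()]s.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_gene_sets <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sets))
  for (i in seq_along(sets)) {
    nm <- gsub("[^A-Za-z0-9_.-]", "_", names(sets)[i])
    paths[i] <- file.path(dir, paste0(nm, ".tsv"))
    members <- dplyr::arrange(sets[[i]]$members, .data$cluster_id)
    readr::write_tsv(members, paths[i])
  }
  invisible(paths)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
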