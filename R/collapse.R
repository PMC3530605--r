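#' Collapse one cluster's probe calls into a cluster-level call
#'
#' Applies the probe-set consistency rules, in order of precedence:
#'
#' 1. significant probes in both directions -> `excluded_divergent`
#'    (the probe set is dropped as a whole);
#' 2. exactly one significant probe among >= 2 testable probes ->
#'    `excluded_single_probe`;
#' 3. at least `min_concordant_probes` concordant significant probes ->
#'    `regulated`, with the shared direction, the hit-probe count, and
#'    the averaged fold change (geometric mean over hit probes, i.e.
#'    arithmetic mean of their absolute log2 fold changes, signed by the
#'    direction);
#' 4. no significant probe -> `not_regulated`;
#' 5. otherwise (fewer than 2 testable probes) -> `untestable`.
#'
#' Untestable probes count as not significant; divergence therefore
#' always wins over concordance (e.g. calls up/up/down are excluded).
#'
#' @param calls Probe-call tibble for a single cluster and contrast
#'   (1-3 rows; see [probe_calls()]).
#' @param cfg A [pipeline_config()].
#' @return One-row tibble: `cluster_id`, `stage`, `contrast`, `status`,
#'   `direction`, `n_hit_probes`, `mean_fold_change`.
#' @examples
#' calls <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3"), cluster_id = "c1",
#'   stage = "diploid", contrast = "co2_at_lowlight",
#'   p_value = c(0.01, 0.02, 0.5), log2fc = c(1, 1.2, 0.1),
#'   call = c("up", "up", "not_significant"), testable = TRUE
#' )
#' collapse_cluster(calls, pipeline_config())
#' @export
collapse_cluster <- function(calls, cfg = pipeline_config()) {
  if (length(unique(calls$cluster_id)) != 1 ||
      length(unique(calls$contrast)) != 1) {
    abort("collapse_cluster expects calls for exactly one cluster and contrast",
          class = "crmarray_integrity_error")
  }
  collapse_all(calls, cfg)$calls
}

#' Collapse all probe calls into cluster-level calls
#'
#' Vectorized application of the rules of [collapse_cluster()] to every
#' (cluster, stage, contrast) probe set, plus an exclusion tally.
#'
#' @param probe_calls Probe-call tibble (any number of clusters,
#'   stages, contrasts).
#' @param cfg A [pipeline_config()].
#' @return A list: `calls` - tibble with one row per (cluster, stage,
#'   contrast) - and `tally` - counts per status per (stage, contrast).
#' @export
collapse_all <- function(probe_calls, cfg = pipeline_config()) {
  pc <- probe_calls
  pc$testable <- if ("testable" %in% names(pc)) pc$testable else !is.na(pc$p_value)
  hit <- pc$call %in% c("up", "down")
  pc$abs_l2fc_hit <- ifelse(hit, abs(pc$log2fc), NA_real_)
  g <- dplyr::group_by(pc, .data$cluster_id, .data$stage, .data$contrast)
  agg <- dplyr::summarise(
    g,
    n_probes = dplyr::n(),
    n_testable = sum(.data$testable),
    n_up = sum(.data$call == "up"),
    n_down = sum(.data$call == "down"),
    mean_abs_l2fc = mean(.data$abs_l2fc_hit, na.rm = TRUE),
    .groups = "drop"
  )
  n_sig <- agg$n_up + agg$n_down
  status <- dplyr::case_when(
    agg$n_up >= 1 & agg$n_down >= 1 ~ "excluded_divergent",
    n_sig == 1 & agg$n_testable >= 2 ~ "excluded_single_probe",
    n_sig >= cfg$min_concordant_probes ~ "regulated",
    n_sig == 0 & agg$n_testable >= 1 ~ "not_regulated",
    TRUE ~ "untestable"
  )
  regulated <- status == "regulated"
  direction <- ifelse(regulated & agg$n_up > 0, "up",
                      ifelse(regulated & agg$n_down > 0, "down", "none"))
  mfc <- ifelse(regulated,
                ifelse(direction == "up", 1, -1) * 2^agg$mean_abs_l2fc,
                NA_real_)
  calls <- tibble::tibble(
    cluster_id = agg$cluster_id,
    stage = agg$stage,
    contrast = agg$contrast,
    status = status,
    direction = direction,
    n_hit_probes = as.integer(n_sig),
    mean_fold_change = mfc
  )
  calls <- dplyr::arrange(calls, .data$stage, .data$contrast,
                          .data$cluster_id)
  tally <- dplyr::count(
    dplyr::group_by(calls, .data$stage, .data$contrast),
    .data$status, name = "n"
  )
  list(calls = calls, tally = tally)
}
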