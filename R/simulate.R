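#' Simulate a common-reference two-color factorial experiment
#'
#' Generates 24 arrays (2 stages x 2 pCO2 x 2 light x 3 biological
#' replicates), each hybridizing one sample against a pooled common
#' reference, with 3 probes per transcript cluster. Planted structure:
#'
#' * cluster baseline log2 intensities from a truncated normal
#'   (+/- 2.5 sd), shared by sample and reference channels;
#' * per-stage treatment cell means built from planted pCO2 effects
#'   (at low and/or high light) and light effects (see [sim_config()]);
#' * stage-specific expression: clusters expressed in only one stage
#'   read near-background in the other (the pooled reference still
#'   carries their signal), and those probes carry `qc_ok = FALSE`,
#'   mirroring a feature-extraction "not above background" flag;
#' * biological replicate noise shared by a cluster's 3 probes, plus
#'   independent per-probe, per-channel noise;
#' * an intensity-dependent dye bias added to the sample channel's log2
#'   intensity as `amplitude * s(A)` for a smooth sinusoid `s`;
#' * anomalies: a divergent probe responds with inverted effect sign,
#'   a dead probe reads background-level noise;
#' * spike-in control probes at fixed log-ratios {-2, -1, 0, 1, 2}.
#'
#' The same seed yields bit-identical output.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements `probes` (probe-record tibble, one row
#'   per probe per array), `design` (sample metadata tibble), and
#'   `truth` (planted ground truth, one row per cluster).
#' @examples
#' sim <- simulate_experiment(sim_config(n_clusters = 50, seed = 3))
#' nrow(sim$design)  # 24 arrays
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "crmarray_sim_config"))
  set.seed(cfg$seed)

  n <- cfg$n_clusters
  cluster_id <- sprintf("GJ%05d", seq_len(n))

  ## --- stage-specific expression ------------------------------------
  n_dip_only <- round(n * cfg$fraction_diploid_only)
  n_hap_only <- round(n * cfg$fraction_haploid_only)
  shuffled <- sample(cluster_id)
  dip_only <- shuffled[seq_len(n_dip_only)]
  hap_only <- shuffled[n_dip_only + seq_len(n_hap_only)]
  expressed_in_stage <- rep("both", n)
  names(expressed_in_stage) <- cluster_id
  expressed_in_stage[dip_only] <- "diploid_only"
  expressed_in_stage[hap_only] <- "haploid_only"

  ## --- planted effects ----------------------------------------------
  # Pools are disjoint; each is drawn fraction_stage_shared from the
  # both-expressed clusters and the remainder from single-stage ones.
  pool_both <- cluster_id[expressed_in_stage == "both"]
  pool_single <- c(dip_only, hap_only)
  take <- function(avail_both, avail_single, n_total) {
    n_shared <- round(n_total * cfg$fraction_stage_shared)
    n_shared <- min(n_shared, length(avail_both))
    n_single <- min(n_total - n_shared, length(avail_single))
    list(
      both = if (n_shared > 0) avail_both[seq_len(n_shared)] else character(),
      single = if (n_single > 0) avail_single[seq_len(n_single)] else character()
    )
  }
  avail_both <- sample(pool_both)
  avail_single <- sample(pool_single)
  assign_pool <- function(frac) {
    sel <- take(avail_both, avail_single, round(n * frac))
    avail_both <<- setdiff(avail_both, sel$both)
    avail_single <<- setdiff(avail_single, sel$single)
    c(sel$both, sel$single)
  }
  core_oa <- assign_pool(cfg$fraction_core_oa)
  ll_spec <- assign_pool(cfg$fraction_ll_specific)
  hl_spec <- assign_pool(cfg$fraction_hl_specific)
  light_core <- assign_pool(cfg$fraction_light)

  draw_effect <- function(k) {
    mag <- rnorm(k, cfg$effect_log2_mean, cfg$effect_log2_sd)
    mag <- pmax(mag, 0)
    mag * sample(c(-1, 1), k, replace = TRUE)
  }
  co2_effect_ll <- co2_effect_hl <- light_effect_380 <-
    setNames(numeric(n), cluster_id)
  e_core <- draw_effect(length(core_oa))
  co2_effect_ll[core_oa] <- e_core
  co2_effect_hl[core_oa] <- e_core
  co2_effect_ll[ll_spec] <- draw_effect(length(ll_spec))
  co2_effect_hl[hl_spec] <- draw_effect(length(hl_spec))
  light_effect_380[light_core] <- draw_effect(length(light_core))
  # Only three cell-mean offsets are free; the light effect at high pCO2
  # is implied by the additive cell-means construction.
  light_effect_1000 <- light_effect_380 + co2_effect_hl - co2_effect_ll

  divergent_probe <- runif(n) < cfg$anomaly_rate_divergent
  dead_probe <- runif(n) < cfg$anomaly_rate_dead
  # each anomaly hits one distinct probe: divergent -> probe 1, dead -> probe 3
  truth <- tibble::tibble(
    cluster_id = cluster_id,
    expressed_in_stage = unname(expressed_in_stage),
    co2_effect_ll = unname(co2_effect_ll),
    co2_effect_hl = unname(co2_effect_hl),
    light_effect_380 = unname(light_effect_380),
    light_effect_1000 = unname(light_effect_1000),
    divergent_probe = divergent_probe,
    dead_probe = dead_probe
  )

  ## --- design --------------------------------------------------------
  design <- tidyr::expand_grid(
    stage = c("diploid", "haploid"),
    pco2_pa = c(38.5, 101.3),
    light_umol = c(50, 300),
    replicate = 1:3
  )
  design$array_id <- sprintf(
    "A_%s_%s_%s_r%d",
    substr(design$stage, 1, 3),
    ifelse(design$pco2_pa == 101.3, "HC", "LC"),
    ifelse(design$light_umol == 300, "HL", "LL"),
    design$replicate
  )
  design$sample_dye <- "cy5"  # no dye swap in the emulated design
  design <- design[c("array_id", "stage", "pco2_pa", "light_umol",
                     "replicate", "sample_dye")]

  ## --- intensities ----------------------------------------------------
  baseline <- cfg$baseline_log2_mean +
    cfg$baseline_log2_sd * .rtnorm(n, 2.5)
  names(baseline) <- cluster_id

  # cell-mean offset per cluster x group (log2): LC_LL is the baseline cell
  cell_offset <- cbind(
    LC_LL = numeric(n),
    HC_LL = unname(co2_effect_ll),
    LC_HL = unname(light_effect_380),
    HC_HL = unname(light_effect_380 + co2_effect_hl)
  )
  rownames(cell_offset) <- cluster_id

  n_arrays <- nrow(design)
  probes_per_cluster <- 3L
  probe_id <- paste0(rep(cluster_id, each = probes_per_cluster), "_p",
                     rep(seq_len(probes_per_cluster), n))
  probe_index <- rep(seq_len(probes_per_cluster), n)
  probe_cluster <- rep(cluster_id, each = probes_per_cluster)
  n_probes <- length(probe_id)

  # replicate (biological) noise: one draw per cluster x stage x group x rep
  # shared by the cluster's 3 probes
  bio <- array(rnorm(n * 8 * 3, 0, cfg$bio_noise_sd), dim = c(n, 8, 3))

  s_shape <- .dye_bias_fun(cfg)

  group_cols <- .group_key(design$pco2_pa, design$light_umol)
  stage_idx <- ifelse(design$stage == "diploid", 0L, 4L)
  group_num <- match(group_cols, c("LC_LL", "HC_LL", "LC_HL", "HC_HL"))

  probe_rows <- vector("list", n_arrays)
  for (a in seq_len(n_arrays)) {
    st <- design$stage[a]
    grp <- group_cols[a]
    rep_i <- design$replicate[a]

    expressed <- switch(st,
      diploid = expressed_in_stage != "haploid_only",
      haploid = expressed_in_stage != "diploid_only"
    )
    mu_sample_cluster <- ifelse(
      expressed,
      baseline + cell_offset[, grp] +
        bio[cbind(seq_len(n), stage_idx[a] + group_num[a], rep_i)],
      cfg$background_log2
    )
    mu_sample <- mu_sample_cluster[probe_cluster]
    # divergent probe (probe 1): effect sign inverted in expressing stage
    div <- divergent_probe[match(probe_cluster, cluster_id)] &
      probe_index == 1L & expressed[probe_cluster]
    if (any(div)) {
      mu_sample[div] <- mu_sample[div] - 2 * cell_offset[probe_cluster[div], grp]
    }
    log2_ref <- baseline[probe_cluster] +
      rnorm(n_probes, 0, cfg$probe_noise_sd)
    log2_sample <- mu_sample + rnorm(n_probes, 0, cfg$probe_noise_sd)
    # dead probe (probe 3): both channels background-level noise
    dead <- dead_probe[match(probe_cluster, cluster_id)] & probe_index == 3L
    if (any(dead)) {
      log2_sample[dead] <- cfg$background_log2 +
        rnorm(sum(dead), 0, max(cfg$probe_noise_sd, 0.5))
      log2_ref[dead] <- cfg$background_log2 +
        rnorm(sum(dead), 0, max(cfg$probe_noise_sd, 0.5))
    }
    # intensity-dependent dye bias on the sample channel
    A0 <- (log2_sample + log2_ref) / 2
    log2_sample <- log2_sample + cfg$dye_bias_amplitude * s_shape(A0)

    probe_rows[[a]] <- tibble::tibble(
      array_id = design$array_id[a],
      probe_id = probe_id,
      cluster_id = probe_cluster,
      is_control = FALSE,
      sample_intensity = unname(2^log2_sample),
      reference_intensity = unname(2^log2_ref),
      # sample channel at array background, as a scanner QC would flag it
      qc_ok = unname(expressed[probe_cluster])
    )
  }
  probes <- dplyr::bind_rows(probe_rows)

  ## --- spike-ins ------------------------------------------------------
  if (cfg$n_spikein > 0) {
    levels <- c(-2, -1, 0, 1, 2)
    spike_m <- levels[(seq_len(cfg$n_spikein) - 1L) %% 5L + 1L]
    # spread over the central 5-95% of the baseline intensity range
    qs <- seq(0.05, 0.95, length.out = cfg$n_spikein)
    spike_base <- cfg$baseline_log2_mean +
      cfg$baseline_log2_sd * qnorm(qs)
    spike_id <- sprintf("SPIKE%03d", seq_len(cfg$n_spikein))
    spikes <- vector("list", n_arrays)
    for (a in seq_len(n_arrays)) {
      ls <- spike_base + spike_m / 2 +
        rnorm(cfg$n_spikein, 0, cfg$probe_noise_sd)
      lr <- spike_base - spike_m / 2 +
        rnorm(cfg$n_spikein, 0, cfg$probe_noise_sd)
      A0 <- (ls + lr) / 2
      ls <- ls + cfg$dye_bias_amplitude * s_shape(A0)
      spikes[[a]] <- tibble::tibble(
        array_id = design$array_id[a],
        probe_id = paste0(spike_id, "_p1"),
        cluster_id = spike_id,
        is_control = TRUE,
        sample_intensity = 2^ls,
        reference_intensity = 2^lr,
        qc_ok = TRUE
      )
    }
    probes <- dplyr::bind_rows(probes, dplyr::bind_rows(spikes))
    spike_truth <- tibble::tibble(
      cluster_id = spike_id,
      planted_log_ratio = spike_m
    )
    attr(truth, "spikein") <- spike_truth
  }

  list(probes = probes, design = design, truth = truth)
}

#' Expected directed gene sets from planted truth
#'
#' The recovery oracle: for each stage and contrast, the clusters whose
#' planted effect magnitude reaches the fold-change threshold and which
#' are expressed in that stage, with the planted direction.
#'
#' @param truth Truth tibble from [simulate_experiment()].
#' @param cfg A [pipeline_config()]; only `fc_threshold` is used.
#' @return A named list (one element per `stage:contrast`) of directed
#'   gene sets (see [directed_gene_set()]).
#' @export
truth_to_expected_sets <- function(truth, cfg = pipeline_config()) {
  thr <- log2(cfg$fc_threshold)
  effect_col <- c(
    co2_at_lowlight = "co2_effect_ll",
    co2_at_highlight = "co2_effect_hl",
    light_at_lowco2 = "light_effect_380",
    light_at_highco2 = "light_effect_1000"
  )
  out <- list()
  for (stage in c("diploid", "haploid")) {
    silent <- if (stage == "diploid") "haploid_only" else "diploid_only"
    expressed <- truth$expressed_in_stage != silent
    for (ct in names(effect_col)) {
      eff <- truth[[effect_col[ct]]]
      keep <- expressed & abs(eff) >= thr
      members <- tibble::tibble(
        cluster_id = truth$cluster_id[keep],
        direction = ifelse(eff[keep] > 0, "up", "down")
      )
      out[[paste(stage, ct, sep = ":")]] <- directed_gene_set(
        members, label = paste("expected", stage, ct),
        stage = stage, contrast = ct
      )
    }
  }
  out
}

#' Write a truth table
#' @param truth Truth tibble from [simulate_experiment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

# truncated standard normal via inverse-CDF, bounded at +/- k sd
.rtnorm <- function(n, k) {
  qnorm(runif(n, pnorm(-k), pnorm(k)))
}

.dye_bias_fun <- function(cfg) {
  if (cfg$dye_bias_shape == "sine") {
    function(A) sin(A)
  } else {
    lo <- cfg$baseline_log2_mean - 3 * cfg$baseline_log2_sd
    width <- 6 * cfg$baseline_log2_sd
    function(A) sin(2 * pi * (A - lo) / width)
  }
}
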