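#' Analysis pipeline configuration
#'
#' Bundles the thresholds applied downstream of normalization. The
#' defaults are the screening thresholds used throughout: per-probe
#' significance at `alpha = 0.05`, a 1.5-fold expression-change filter,
#' and at least 2 concordant significant probes (of up to 3) for a
#' cluster-level call. Annotation e-value cutoffs exclude alignments
#' with e-value strictly greater than the cutoff.
#'
#' @param alpha Per-probe significance level in (0, 1).
#' @param fc_threshold Minimum fold change (linear scale, >= 1) for a
#'   probe to count as a hit.
#' @param min_concordant_probes Minimum number of concordant significant
#'   probes for a regulated cluster call.
#' @param loess_span LOWESS span (fraction of probes in the local
#'   window) for dye-bias correction, in (0, 1].
#' @param loess_iterations Number of robustifying iterations of the
#'   LOWESS fit (>= 0).
#' @param posthoc Pairwise contrast method after the one-way ANOVA:
#'   Fisher's LSD (default) or Tukey HSD.
#' @param evalue_blast Alignments with e-value strictly greater than
#'   this are dropped from the annotation model fields.
#' @param evalue_b2g Free-text descriptions whose alignment e-value is
#'   strictly greater than this are dropped (only applied when the
#'   annotation table carries a `b2g_evalue` column).
#' @param seed Integer seed recorded for provenance and used by
#'   [run_pipeline()] when it simulates input.
#'
#' @return A list of class `crmarray_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$fc_threshold
#' @export
pipeline_config <- function(alpha = 0.05,
                            fc_threshold = 1.5,
                            min_concordant_probes = 2L,
                            loess_span = 0.4,
                            loess_iterations = 3L,
                            posthoc = c("lsd", "tukey"),
                            evalue_blast = 1e-5,
                            evalue_b2g = 1e-6,
                            seed = 1L) {
  posthoc <- match.arg(posthoc)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
    is.numeric(fc_threshold), fc_threshold >= 1,
    min_concordant_probes >= 1,
    loess_span > 0, loess_span <= 1,
    loess_iterations >= 0,
    evalue_blast > 0, evalue_b2g > 0
  )
  structure(
    list(
      alpha = alpha,
      fc_threshold = fc_threshold,
      min_concordant_probes = as.integer(min_concordant_probes),
      loess_span = loess_span,
      loess_iterations = as.integer(loess_iterations),
      posthoc = posthoc,
      evalue_blast = evalue_blast,
      evalue_b2g = evalue_b2g,
      seed = as.integer(seed)
    ),
    class = "crmarray_config"
  )
}

#' Synthetic experiment configuration
#'
#' Parameters of the synthetic two-color common-reference experiment:
#' 2 life-cycle stages x 2 pCO2 levels (38.5 vs 101.3 Pa) x 2 light
#' intensities (50 vs 300 umol photons m-2 s-1), biological triplicates,
#' and 3 probes per transcript cluster. Cluster baselines are drawn on
#' the log2 scale from a truncated normal (bounded at +/- 2.5 sd,
#' mirroring a scanner's finite dynamic range); intensities are
#' log-normal around them.
#'
#' Differential expression is planted as cell-mean offsets for the four
#' treatment groups of a stage. `fraction_core_oa` clusters respond to
#' pCO2 under both light levels, `fraction_ll_specific` /
#' `fraction_hl_specific` under only one, and `fraction_light` respond
#' to light under both pCO2 levels. A `fraction_stage_shared` share of
#' each responsive pool is drawn from clusters expressed in both stages
#' (so the response is visible in both); the rest is split between
#' clusters expressed in only one stage. Since the four per-stage cell
#' means have three free offsets, the light effect at high pCO2 is the
#' implied combination `light_effect_380 + co2_effect_hl -
#' co2_effect_ll`; condition-specific responses therefore appear as
#' genuine interactions, as they do on real arrays.
#'
#' @param n_clusters Number of non-control transcript clusters.
#' @param fraction_core_oa Fraction of clusters with a pCO2 effect at
#'   both light levels.
#' @param fraction_ll_specific,fraction_hl_specific Fractions with a
#'   pCO2 effect only under low / only under high light.
#' @param fraction_light Fraction with a light effect at both pCO2
#'   levels.
#' @param fraction_stage_shared Share of each responsive pool drawn from
#'   clusters expressed in both stages.
#' @param fraction_diploid_only,fraction_haploid_only Fractions of
#'   clusters expressed in only one stage (near-background in the
#'   other).
#' @param effect_log2_mean,effect_log2_sd Mean and sd of planted
#'   absolute log2 effect sizes (signs are +/- with equal probability).
#' @param probe_noise_sd Per-channel, per-probe log2 noise sd.
#' @param bio_noise_sd Biological replicate log2 noise sd, drawn once
#'   per (cluster, replicate) and shared by the cluster's 3 probes.
#' @param baseline_log2_mean,baseline_log2_sd Location and scale of the
#'   cluster baseline log2 intensity (truncated at +/- 2.5 sd).
#' @param background_log2 Log2 intensity of unexpressed material (used
#'   for stage-specific clusters in their silent stage and for dead
#'   probes).
#' @param dye_bias_amplitude Amplitude of the intensity-dependent dye
#'   bias added to the sample channel's log2 intensity.
#' @param dye_bias_shape `"smooth"` (default) is one sinusoid period
#'   across the baseline +/- 3 sd range; `"sine"` is `sin(A)`.
#' @param anomaly_rate_divergent Probability that one of a cluster's 3
#'   probes responds with inverted effect sign.
#' @param anomaly_rate_dead Probability that one probe reads
#'   signal-free noise at background level.
#' @param n_spikein Number of spike-in control probes; planted
#'   log-ratios cycle through {-2, -1, 0, 1, 2} and baselines are spread
#'   over the central intensity range.
#' @param seed Integer seed; identical configurations produce
#'   bit-identical output.
#'
#' @return A list of class `crmarray_sim_config`.
#' @examples
#' cfg <- sim_config(n_clusters = 200, seed = 7)
#' @export
sim_config <- function(n_clusters = 2000L,
                       fraction_core_oa = 0.05,
                       fraction_ll_specific = 0.025,
                       fraction_hl_specific = 0.02,
                       fraction_light = 0.05,
                       fraction_stage_shared = 0.4,
                       fraction_diploid_only = 0.1,
                       fraction_haploid_only = 0.1,
                       effect_log2_mean = 1.5,
                       effect_log2_sd = 0.4,
                       probe_noise_sd = 0.2,
                       bio_noise_sd = 0.1,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       background_log2 = 5,
                       dye_bias_amplitude = 0.3,
                       dye_bias_shape = c("smooth", "sine"),
                       anomaly_rate_divergent = 0.01,
                       anomaly_rate_dead = 0.01,
                       n_spikein = 50L,
                       seed = 1L) {
  dye_bias_shape <- match.arg(dye_bias_shape)
  fracs <- c(fraction_core_oa, fraction_ll_specific, fraction_hl_specific,
             fraction_light)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1) {
    abort("differential-expression fractions must lie in [0, 1] and sum to <= 1",
          class = "crmarray_config_error")
  }
  if (fraction_stage_shared < 0 || fraction_stage_shared > 1 ||
      fraction_diploid_only < 0 || fraction_haploid_only < 0 ||
      fraction_diploid_only + fraction_haploid_only > 1) {
    abort("stage-expression fractions must lie in [0, 1] and sum to <= 1",
          class = "crmarray_config_error")
  }
  if (anomaly_rate_divergent < 0 || anomaly_rate_divergent >= 1 ||
      anomaly_rate_dead < 0 || anomaly_rate_dead >= 1) {
    abort("anomaly rates must lie in [0, 1)", class = "crmarray_config_error")
  }
  stopifnot(n_clusters >= 1, probe_noise_sd >= 0, bio_noise_sd >= 0,
            baseline_log2_sd > 0, effect_log2_sd >= 0, n_spikein >= 0)
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      fraction_core_oa = fraction_core_oa,
      fraction_ll_specific = fraction_ll_specific,
      fraction_hl_specific = fraction_hl_specific,
      fraction_light = fraction_light,
      fraction_stage_shared = fraction_stage_shared,
      fraction_diploid_only = fraction_diploid_only,
      fraction_haploid_only = fraction_haploid_only,
      effect_log2_mean = effect_log2_mean,
      effect_log2_sd = effect_log2_sd,
      probe_noise_sd = probe_noise_sd,
      bio_noise_sd = bio_noise_sd,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      background_log2 = background_log2,
      dye_bias_amplitude = dye_bias_amplitude,
      dye_bias_shape = dye_bias_shape,
      anomaly_rate_divergent = anomaly_rate_divergent,
      anomaly_rate_dead = anomaly_rate_dead,
      n_spikein = as.integer(n_spikein),
      seed = as.integer(seed)
    ),
    class = "crmarray_sim_config"
  )
}

# Fixed contrast vocabulary: first group minus second group on log2 scale,
# so "up" always means up in the treatment (high pCO2, or high light).
.contrasts <- list(
  co2_at_lowlight  = list(g1 = "HC_LL", g2 = "LC_LL"),
  co2_at_highlight = list(g1 = "HC_HL", g2 = "LC_HL"),
  light_at_lowco2  = list(g1 = "LC_HL", g2 = "LC_LL"),
  light_at_highco2 = list(g1 = "HC_HL", g2 = "HC_LL")
)

#' Contrast vocabulary
#'
#' The four within-stage treatment contrasts. Each is the difference of
#' two of the four (pCO2 x light) group means; the first-named group is
#' the treatment (high pCO2 or high light), so positive log-ratios mean
#' up-regulation under the treatment.
#'
#' @return Character vector of contrast labels.
#' @export
contrast_labels <- function() names(.contrasts)

# Group key from design columns: LC/HC = 38.5/101.3 Pa, LL/HL = 50/300.
.group_key <- function(pco2_pa, light_umol) {
  paste0(ifelse(pco2_pa == 101.3, "HC", "LC"),
         "_",
         ifelse(light_umol == 300, "HL", "LL"))
}
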