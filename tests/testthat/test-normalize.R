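test_that("MA transformation matches its closed form", {
  p <- tibble::tibble(
    array_id = "a1", probe_id = c("p1", "p2"), cluster_id = c("c1", "c2"),
    is_control = FALSE,
    sample_intensity = c(200, 100), reference_intensity = c(100, 100),
    qc_ok = TRUE
  )
  ma <- ma_transform(p)
  expect_equal(ma$M, c(1, 0))
  expect_equal(ma$A, c(0.5 * log2(20000), 0.5 * log2(10000)))
})

test_that("QC-failed probes are skipped and counted", {
  p <- toy_probe_table()
  p$qc_ok[3] <- FALSE
  ma <- ma_transform(p)
  expect_equal(nrow(ma), 5)
  expect_equal(attr(ma, "skipped"), 1)
  expect_false("c2" %in% ma$cluster_id[ma$array_id == "a1"])
})

test_that("LOWESS correction flattens a planted sinusoidal dye bias", {
  cfg <- sim_config(
    n_clusters = 1200,
    fraction_core_oa = 0, fraction_ll_specific = 0,
    fraction_hl_specific = 0, fraction_light = 0,
    fraction_diploid_only = 0, fraction_haploid_only = 0,
    probe_noise_sd = 0, bio_noise_sd = 0,
    dye_bias_amplitude = 0.5, dye_bias_shape = "sine",
    anomaly_rate_divergent = 0, anomaly_rate_dead = 0,
    n_spikein = 20, seed = 31
  )
  sim <- simulate_experiment(cfg)
  one_array <- sim$probes[sim$probes$array_id == sim$design$array_id[1], ]
  ma <- ma_transform(one_array)
  # before correction the bias is plainly visible
  expect_gt(median(abs(ma$M[!ma$is_control])), 0.2)
  corrected <- lowess_correct(ma, span = 0.4, iterations = 3)
  expect_lt(median(abs(corrected$M[!corrected$is_control])), 0.05)
  # spike-ins are corrected by the fit they did not influence
  planted <- attr(sim$truth, "spikein")
  sp <- corrected[corrected$is_control, ]
  err <- sp$M - planted$planted_log_ratio[match(sp$cluster_id,
                                                planted$cluster_id)]
  expect_lt(max(abs(err)), 0.1)
})

test_that("correction is near-identity when there is no bias", {
  set.seed(8)
  n <- 1500
  ma <- tibble::tibble(
    array_id = "a1", probe_id = paste0("p", 1:n),
    cluster_id = paste0("c", 1:n), is_control = FALSE,
    A = 10 + 1.5 * qnorm(runif(n, pnorm(-2.5), pnorm(2.5))),
    M = rnorm(n, 0, 0.05)
  )
  corrected <- lowess_correct(ma)
  expect_lt(max(abs(corrected$M - ma$M)), 0.02)
})

test_that("correction is idempotent to tolerance and never touches A", {
  # bias-free: re-correction is near-null everywhere
  sim0 <- simulate_experiment(sim_config(n_clusters = 2000,
                                         fraction_diploid_only = 0,
                                         fraction_haploid_only = 0,
                                         anomaly_rate_dead = 0,
                                         anomaly_rate_divergent = 0,
                                         dye_bias_amplitude = 0,
                                         seed = 13))
  ma0 <- ma_transform(sim0$probes, sim0$design)
  a1 <- ma0[ma0$array_id == sim0$design$array_id[2], ]
  once0 <- lowess_correct(a1)
  twice0 <- lowess_correct(once0)
  expect_lt(max(abs(twice0$M - once0$M)), 0.02)
  expect_identical(once0$A, a1$A)

  # with planted bias: idempotent over the density-supported A range;
  # the outer 2% tails are variance-limited for any local fit
  sim <- simulate_experiment(sim_config(n_clusters = 2000,
                                        fraction_diploid_only = 0,
                                        fraction_haploid_only = 0,
                                        anomaly_rate_dead = 0,
                                        anomaly_rate_divergent = 0,
                                        seed = 13))
  ma <- ma_transform(sim$probes, sim$design)
  ma1 <- ma[ma$array_id == sim$design$array_id[5], ]
  once <- lowess_correct(ma1)
  twice <- lowess_correct(once)
  d <- abs(twice$M - once$M)
  interior <- ma1$A > quantile(ma1$A, 0.02) & ma1$A < quantile(ma1$A, 0.98)
  expect_lt(max(d[interior]), 0.02)
  expect_lt(max(d), 0.05)
  expect_identical(once$A, ma1$A)
})

test_that("corrected arrays are flat: refitting M on A stays within 0.05", {
  sim <- simulate_experiment(sim_config(n_clusters = 2000,
                                        fraction_diploid_only = 0,
                                        fraction_haploid_only = 0,
                                        anomaly_rate_dead = 0,
                                        anomaly_rate_divergent = 0,
                                        seed = 29))
  ma <- ma_transform(sim$probes, sim$design)
  for (a in sim$design$array_id[c(3, 17)]) {
    m1 <- lowess_correct(ma[ma$array_id == a, ])
    refit <- limma::loessFit(m1$M[!m1$is_control], m1$A[!m1$is_control],
                             span = 0.4, iterations = 3)$fitted
    expect_lt(max(abs(refit)), 0.05)
  }
})

test_that("too few probes on an array is a normalization error", {
  ma <- ma_transform(toy_probe_table())
  expect_error(lowess_correct(ma), class = "crmarray_normalization_error")
})

test_that("contrast ratios exploit the common reference", {
  design <- full_design()
  dip <- design[design$stage == "diploid", ]
  m_of <- function(group) switch(group, HC_LL = 1, LC_LL = -1, 0)
  grp <- ifelse(dip$pco2_pa == 101.3, "HC", "LC")
  grp <- paste0(grp, "_", ifelse(dip$light_umol == 300, "HL", "LL"))
  ratios <- tibble::tibble(
    array_id = rep(dip$array_id, each = 1),
    probe_id = "p1", cluster_id = "c1", is_control = FALSE,
    M = vapply(grp, m_of, numeric(1)), A = 10
  )
  cr <- contrast_ratios(ratios, design, "diploid", "co2_at_lowlight")
  expect_equal(cr$log2fc, 2)  # mean(1,1,1) - mean(-1,-1,-1)
  expect_false(cr$unbalanced)

  same <- ratios
  same$M <- 0.5
  cr0 <- contrast_ratios(same, design, "diploid", "co2_at_lowlight")
  expect_equal(cr0$log2fc, 0)

  # one missing replicate in group 1 -> sizes 2 and 3, flagged
  drop <- ratios[!(ratios$array_id == dip$array_id[grp == "HC_LL"][1]), ]
  cr1 <- contrast_ratios(drop, design, "diploid", "co2_at_lowlight")
  expect_true(cr1$unbalanced)
  expect_equal(lengths(cr1$m_g1), 2)
  expect_equal(lengths(cr1$m_g2), 3)
})

test_that("group means cancel the reference exactly in noise-free data", {
  cfg <- sim_config(n_clusters = 150, probe_noise_sd = 0, bio_noise_sd = 0,
                    dye_bias_amplitude = 0, anomaly_rate_divergent = 0,
                    anomaly_rate_dead = 0, n_spikein = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  ma <- ma_transform(sim$probes, sim$design)
  cr <- contrast_ratios(ma, sim$design, "diploid", "co2_at_lowlight")
  per_cluster <- tapply(cr$log2fc, cr$cluster_id, mean)
  planted <- sim$truth$co2_effect_ll
  names(planted) <- sim$truth$cluster_id
  expressed <- sim$truth$expressed_in_stage != "haploid_only"
  keep <- names(per_cluster) %in% sim$truth$cluster_id[expressed &
                                                         !sim$truth$divergent_probe &
                                                         !sim$truth$dead_probe]
  expect_equal(as.vector(per_cluster[keep]),
               unname(planted[names(per_cluster)[keep]]),
               tolerance = 1e-12)
})
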