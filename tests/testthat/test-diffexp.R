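test_that("LSD pairwise p-values match the pooled-sd t-test oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- paste0("g", seq_len(k))
    values <- lapply(groups, function(g) rnorm(sample(2:4, 1), sd = runif(1, 0.5, 2)))
    names(values) <- groups
    y <- matrix(unlist(values), nrow = 1)
    glab <- rep(groups, lengths(values))
    res <- probe_anova(y, glab)
    expect_equal(res$omnibus_p, oracle_lsd(values)$omnibus,
                 tolerance = 1e-10)
    for (pair in utils::combn(groups, 2, simplify = FALSE)) {
      mine <- res$pairwise[[paste0(pair[1], "-", pair[2])]]$p
      expect_equal(mine, unname(oracle_lsd_p(values, pair[1], pair[2])),
                   tolerance = 1e-10)
    }
  }
})

test_that("a strong single-group shift is detected against quiet groups", {
  values <- list(
    g1 = c(-0.05, 0.08, -0.03),
    g2 = c(2.02, 1.95, 2.10),
    g3 = c(0.04, -0.06, 0.01),
    g4 = c(-0.08, 0.03, 0.06)
  )
  y <- matrix(unlist(values), nrow = 1)
  res <- probe_anova(y, rep(names(values), lengths(values)))
  p <- res$pairwise[["g1-g2"]]$p
  expect_lt(p, 0.001)
  expect_equal(p, unname(oracle_lsd_p(values, "g1", "g2")),
               tolerance = 1e-10)
})

test_that("two-group LSD equals the classical pooled t-test", {
  a <- c(1.0, 1.1, 0.9)
  b <- c(-1.0, -0.9, -1.1)
  res <- probe_anova(matrix(c(a, b), nrow = 1),
                     rep(c("a", "b"), each = 3))
  classic <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$pairwise[["a-b"]]$p, classic$p.value, tolerance = 1e-12)
  expect_equal(res$pairwise[["a-b"]]$diff, 2, tolerance = 1e-12)
})

test_that("identical groups give p = 1 and no calls", {
  jitter <- c(1e-9, -2e-9, 3e-9)  # same values in every group
  y <- matrix(rep(jitter, 4), nrow = 1)
  res <- probe_anova(y, rep(paste0("g", 1:4), each = 3))
  for (pw in res$pairwise) {
    expect_equal(pw$p, 1, tolerance = 1e-6)
  }
  expect_equal(call_probe(res$pairwise[[1]]$p, res$pairwise[[1]]$diff),
               "not_significant")
})

test_that("calls apply both thresholds conjunctively with inclusive bounds", {
  cfg <- pipeline_config()
  expect_equal(call_probe(0.01, 0.8, cfg), "up")       # fold 1.74
  expect_equal(call_probe(0.01, 0.5, cfg), "not_significant")  # fold 1.41
  expect_equal(call_probe(0.2, 2.0, cfg), "not_significant")   # fails alpha
  expect_equal(call_probe(0.01, -0.9, cfg), "down")
  expect_equal(call_probe(0.05, log2(1.5), cfg), "up")  # both boundaries
  expect_equal(call_probe(NA_real_, 3, cfg), "not_significant")
})

test_that("growing the effect never loses a call (monotonicity)", {
  set.seed(7)
  base <- rnorm(3, 0, 0.1)
  shifted <- rnorm(3, 0, 0.1)
  cfg <- pipeline_config()
  previous_called <- FALSE
  for (delta in seq(0, 3, by = 0.25)) {
    y <- matrix(c(shifted + delta, base), nrow = 1)
    res <- probe_anova(y, rep(c("g1", "g2"), each = 3))
    pw <- res$pairwise[["g1-g2"]]
    called <- call_probe(pw$p, pw$diff, cfg) == "up"
    if (previous_called) expect_true(called)
    previous_called <- called
  }
})

test_that("negating all values swaps directions and preserves p-values", {
  sim <- simulate_experiment(sim_config(n_clusters = 120, seed = 23))
  ma <- ma_transform(sim$probes, sim$design)
  pc <- probe_calls(ma, sim$design, "diploid", "co2_at_lowlight")
  neg <- ma
  neg$M <- -neg$M
  pc_neg <- probe_calls(neg, sim$design, "diploid", "co2_at_lowlight")
  expect_equal(pc_neg$p_value, pc$p_value, tolerance = 1e-12)
  expect_equal(pc_neg$log2fc, -pc$log2fc, tolerance = 1e-12)
  expect_equal(pc_neg$call[pc$call == "up"],
               rep("down", sum(pc$call == "up")))
  expect_equal(pc_neg$call[pc$call == "down"],
               rep("up", sum(pc$call == "down")))
})

test_that("probes with missing replicates are flagged untestable", {
  sim <- simulate_experiment(sim_config(n_clusters = 40, seed = 3))
  ma <- ma_transform(sim$probes, sim$design)
  # drop 2 of 3 replicates of one group for one probe
  victim <- ma$probe_id[1]
  drop_arrays <- sim$design$array_id[sim$design$stage == "diploid" &
                                       sim$design$pco2_pa == 101.3 &
                                       sim$design$light_umol == 50][1:2]
  ma_cut <- ma[!(ma$probe_id == victim & ma$array_id %in% drop_arrays), ]
  pc <- probe_calls(ma_cut, sim$design, "diploid", "co2_at_lowlight")
  row <- pc[pc$probe_id == victim, ]
  expect_false(row$testable)
  expect_true(is.na(row$p_value))
  expect_equal(row$call, "not_significant")
  expect_equal(attr(pc, "n_untestable"), 1L)
})

test_that("Tukey HSD is available and not smaller than LSD", {
  set.seed(11)
  y <- matrix(rnorm(12), nrow = 1)
  g <- rep(paste0("g", 1:4), each = 3)
  lsd <- probe_anova(y, g, posthoc = "lsd")
  tuk <- probe_anova(y, g, posthoc = "tukey")
  for (nm in names(lsd$pairwise)) {
    expect_gte(tuk$pairwise[[nm]]$p, lsd$pairwise[[nm]]$p)
  }
})
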