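#' Per-probe one-way ANOVA with pairwise contrasts
#'
#' Fits, independently for every row of `m`, a one-way fixed-effects
#' ANOVA across the treatment groups given by `groups`, and computes
#' pairwise contrast p-values from the pooled residual mean square:
#' Fisher's LSD t statistics on group-mean differences (default), or
#' Tukey HSD via the studentized range. Rows are probes; columns are
#' arrays. Missing values are allowed and reduce the per-group counts.
#'
#' A probe is untestable for a pair when either group has fewer than 2
#' non-missing values or the pooled residual degrees of freedom are
#' zero; its p-values are `NA`.
#'
#' @param m Numeric matrix of M values, probes x arrays.
#' @param groups Factor or character vector of length `ncol(m)` giving
#'   each array's treatment group (>= 2 groups).
#' @param pairs List of character pairs `c(g1, g2)` for which pairwise
#'   p-values are wanted; defaults to all group pairs.
#' @param posthoc `"lsd"` (default) or `"tukey"`.
#' @return A list: `omnibus_p` (length-nrow vector of F-test p-values),
#'   `group_means` (probes x groups), `mse`, `df_resid`, `n` (probes x
#'   groups counts), and `pairwise` - a named list per pair with
#'   elements `diff` (mean g1 - mean g2) and `p`.
#' @examples
#' m <- rbind(c(0, 0.1, -0.1, 2, 2.1, 1.9))
#' probe_anova(m, c("a", "a", "a", "b", "b", "b"))$pairwise[["b-a"]]$p
#' @export
probe_anova <- function(m, groups, pairs = NULL,
                        posthoc = c("lsd", "tukey")) {
  posthoc <- match.arg(posthoc)
  m <- as.matrix(m)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  glev <- unique(groups)
  k_all <- length(glev)
  if (k_all < 2) {
    abort("probe_anova needs at least 2 groups",
          class = "crmarray_stat_error")
  }
  present <- !is.na(m)
  # per-group counts and means
  ind <- vapply(glev, function(g) as.numeric(groups == g),
                numeric(length(groups)))
  n_g <- present %*% ind                       # probes x groups
  m0 <- m
  m0[!present] <- 0
  sum_g <- m0 %*% ind
  mean_g <- sum_g / n_g                        # NaN where n_g == 0
  # within-group sum of squares: sum(x^2) - sum(n_g * mean_g^2)
  ss_tot_g <- (m0^2) %*% ind
  ss_within <- rowSums(ss_tot_g - n_g * ifelse(n_g > 0, mean_g, 0)^2)
  n_tot <- rowSums(n_g)
  k_eff <- rowSums(n_g > 0)
  df_resid <- n_tot - k_eff
  mse <- ifelse(df_resid > 0, ss_within / df_resid, NA_real_)
  # between-group SS against the grand mean of non-missing values
  grand <- rowSums(sum_g) / n_tot
  ss_between <- rowSums(n_g * (ifelse(n_g > 0, mean_g, grand) - grand)^2)
  df_between <- k_eff - 1
  f_stat <- (ss_between / df_between) / mse
  omnibus_p <- ifelse(df_between > 0 & df_resid > 0 & mse > 0,
                      pf(f_stat, df_between, df_resid, lower.tail = FALSE),
                      NA_real_)
  omnibus_p[!is.na(mse) & mse == 0 & ss_between > 0] <- 0

  if (is.null(pairs)) {
    pairs <- utils::combn(glev, 2, simplify = FALSE)
  }
  pairwise <- list()
  for (pr in pairs) {
    g1 <- pr[1]; g2 <- pr[2]
    i1 <- match(g1, glev); i2 <- match(g2, glev)
    d <- mean_g[, i1] - mean_g[, i2]
    n1 <- n_g[, i1]; n2 <- n_g[, i2]
    testable <- n1 >= 2 & n2 >= 2 & df_resid > 0 & !is.na(mse) & mse > 0
    p <- rep(NA_real_, nrow(m))
    if (posthoc == "lsd") {
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      tt <- d / se
      p[testable] <- 2 * pt(-abs(tt[testable]), df_resid[testable])
    } else {
      q <- abs(d) / sqrt(mse / 2 * (1 / n1 + 1 / n2))
      p[testable] <- stats::ptukey(q[testable], nmeans = k_eff[testable],
                                   df = df_resid[testable],
                                   lower.tail = FALSE)
    }
    # zero residual variance with a non-zero difference: call it exact
    degenerate <- n1 >= 2 & n2 >= 2 & df_resid > 0 & !is.na(mse) & mse == 0
    p[degenerate] <- ifelse(d[degenerate] == 0, 1, 0)
    pairwise[[paste0(g1, "-", g2)]] <- list(diff = unname(d), p = p)
  }
  list(omnibus_p = unname(omnibus_p), group_means = mean_g, mse = unname(mse),
       df_resid = unname(df_resid), n = n_g, pairwise = pairwise)
}

#' Threshold a probe's statistics into a directional call
#'
#' Applies the two screening thresholds conjunctively: a probe is called
#' `up` when `p_value <= alpha` and `log2fc >= log2(fc_threshold)`,
#' `down` when `p_value <= alpha` and `log2fc <= -log2(fc_threshold)`,
#' and `not_significant` otherwise (including untestable probes with
#' `NA` p-values).
#'
#' @param p_value Numeric vector of p-values.
#' @param log2fc Numeric vector of log2 fold changes.
#' @param cfg A [pipeline_config()].
#' @return Character vector of calls.
#' @examples
#' call_probe(c(0.01, 0.01, 0.2), c(0.8, 0.5, 2), pipeline_config())
#' @export
call_probe <- function(p_value, log2fc, cfg = pipeline_config()) {
  thr <- log2(cfg$fc_threshold)
  call <- rep("not_significant", length(p_value))
  sig <- !is.na(p_value) & p_value <= cfg$alpha
  call[sig & log2fc >= thr] <- "up"
  call[sig & log2fc <= -thr] <- "down"
  call
}

#' Per-probe calls for one stage and contrast
#'
#' Runs the one-way ANOVA across the four (pCO2 x light) treatment
#' groups of the given stage and extracts the requested pairwise
#' contrast (Fisher's LSD from the pooled residual mean square by
#' default). The log2 fold change is the difference of group-mean M
#' values, which under the common-reference design equals the
#' treatment-vs-treatment log-ratio. Both thresholds of `cfg` are then
#' applied per probe.
#'
#' No across-probe multiple-testing correction is applied by default,
#' matching the screening design; set `adjust = "BH"` for
#' Benjamini-Hochberg on the contrast p-values.
#'
#' @param ratios Normalized MA tibble (see [normalize_arrays()]).
#' @param design Design tibble.
#' @param stage `"diploid"` or `"haploid"`.
#' @param contrast One of [contrast_labels()].
#' @param cfg A [pipeline_config()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble with one row per non-control probe: `probe_id`,
#'   `cluster_id`, `stage`, `contrast`, `p_value`, `log2fc`, `call`,
#'   `testable`; attribute `n_untestable` counts probes lacking
#'   replicates.
#' @export
probe_calls <- function(ratios, design, stage,
                        contrast = contrast_labels(),
                        cfg = pipeline_config(),
                        adjust = c("none", "BH")) {
  contrast <- match.arg(contrast)
  adjust <- match.arg(adjust)
  spec <- .contrasts[[contrast]]
  d <- design[design$stage == stage, ]
  if (nrow(d) == 0) {
    abort(sprintf("no arrays for stage %s", stage),
          class = "crmarray_contrast_error")
  }
  d$group <- .group_key(d$pco2_pa, d$light_umol)
  if (!spec$g1 %in% d$group || !spec$g2 %in% d$group) {
    abort(sprintf("contrast %s in stage %s: a group has no replicates",
                  contrast, stage),
          class = "crmarray_contrast_error")
  }
  r <- ratios[!ratios$is_control & ratios$array_id %in% d$array_id, ]
  wide <- tidyr::pivot_wider(
    r[c("probe_id", "cluster_id", "array_id", "M")],
    names_from = "array_id", values_from = "M"
  )
  array_cols <- setdiff(names(wide), c("probe_id", "cluster_id"))
  m <- as.matrix(wide[array_cols])
  groups <- d$group[match(array_cols, d$array_id)]
  res <- probe_anova(m, groups, pairs = list(c(spec$g1, spec$g2)),
                     posthoc = cfg$posthoc)
  pw <- res$pairwise[[paste0(spec$g1, "-", spec$g2)]]
  p <- pw$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    probe_id = wide$probe_id,
    cluster_id = wide$cluster_id,
    stage = stage,
    contrast = contrast,
    p_value = p,
    log2fc = pw$diff,
    call = call_probe(p, pw$diff, cfg),
    testable = !is.na(p)
  )
  attr(out, "n_untestable") <- sum(!out$testable)
  out
}
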