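# Independent oracles used across the suite. These deliberately take a
# different route than the package implementation.

# Fisher's LSD oracle: pooled-sd pairwise t-tests (stats::pairwise.t.test)
# and the omnibus F from anova(lm(...)).
oracle_lsd <- function(values_by_group) {
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  lengths(values_by_group)),
              levels = names(values_by_group))
  ptt <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                                pool.sd = TRUE)
  omnibus <- stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
  list(pairwise = ptt$p.value, omnibus = omnibus)
}

oracle_lsd_p <- function(values_by_group, g1, g2) {
  pm <- oracle_lsd(values_by_group)$pairwise
  p <- if (g1 %in% rownames(pm) && g2 %in% colnames(pm)) pm[g1, g2] else NA
  if (is.na(p) && g2 %in% rownames(pm) && g1 %in% colnames(pm)) {
    p <- pm[g2, g1]
  }
  p
}

# Hand-written collapse decision table: expected status for every probe
# call pattern (order-free). Directions: u = up, d = down, n = not
# significant. A pattern's expected status was reasoned out case by case
# from the consistency rules and is frozen here as a lookup, keyed by
# sorted pattern.
collapse_oracle <- local({
  tab <- c(
    # 3-probe patterns (multisets over {u, d, n})
    "uuu" = "regulated_up",
    "uud" = "excluded_divergent",
    "uun" = "regulated_up",
    "udd" = "excluded_divergent",
    "udn" = "excluded_divergent",
    "unn" = "excluded_single_probe",
    "ddd" = "regulated_down",
    "ddn" = "regulated_down",
    "dnn" = "excluded_single_probe",
    "nnn" = "not_regulated",
    # 2-probe patterns
    "uu" = "regulated_up",
    "ud" = "excluded_divergent",
    "un" = "excluded_single_probe",
    "dd" = "regulated_down",
    "dn" = "excluded_single_probe",
    "nn" = "not_regulated",
    # 1-probe patterns
    "u" = "untestable",
    "d" = "untestable",
    "n" = "not_regulated"
  )
  norm <- vapply(names(tab), function(k) {
    paste(sort(strsplit(k, "")[[1]]), collapse = "")
  }, character(1))
  function(pattern) {
    key <- paste(sort(strsplit(pattern, "")[[1]]), collapse = "")
    unname(tab[which(norm == key)[1]])
  }
})

# All ordered probe-call patterns of a given length over u/d/n.
all_patterns <- function(len) {
  alphabet <- c("u", "d", "n")
  grids <- do.call(expand.grid,
                   c(rep(list(alphabet), len), stringsAsFactors = FALSE))
  apply(grids, 1, paste, collapse = "")
}

# Build a probe-call tibble from a pattern string like "uud".
calls_from_pattern <- function(pattern, l2fc_up = 1, l2fc_down = -1) {
  codes <- strsplit(pattern, "")[[1]]
  tibble::tibble(
    probe_id = paste0("p", seq_along(codes)),
    cluster_id = "c1",
    stage = "diploid",
    contrast = "co2_at_lowlight",
    p_value = ifelse(codes == "n", 0.5, 0.01),
    log2fc = ifelse(codes == "u", l2fc_up,
                    ifelse(codes == "d", l2fc_down, 0.05)),
    call = c(u = "up", d = "down", n = "not_significant")[codes],
    testable = TRUE
  )
}

expected_from_oracle <- function(status) {
  switch(status,
         regulated_up = list(status = "regulated", direction = "up"),
         regulated_down = list(status = "regulated", direction = "down"),
         list(status = status, direction = "none"))
}
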