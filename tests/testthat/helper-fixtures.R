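# Small in-code fixtures.

toy_probe_table <- function() {
  tibble::tibble(
    array_id = rep(c("a1", "a2"), each = 3),
    probe_id = rep(c("c1_p1", "c1_p2", "c2_p1"), 2),
    cluster_id = rep(c("c1", "c1", "c2"), 2),
    is_control = FALSE,
    sample_intensity = c(200, 150, 300, 100, 120, 90),
    reference_intensity = c(100, 100, 100, 100, 100, 100),
    qc_ok = TRUE
  )
}

full_design <- function() {
  d <- tidyr::expand_grid(
    stage = c("diploid", "haploid"),
    pco2_pa = c(38.5, 101.3),
    light_umol = c(50, 300),
    replicate = 1:3
  )
  d$array_id <- sprintf("arr%02d", seq_len(nrow(d)))
  d$sample_dye <- "cy5"
  d[c("array_id", "stage", "pco2_pa", "light_umol", "replicate",
      "sample_dye")]
}

toy_annotation <- function() {
  tibble::tibble(
    cluster_id = c("c1", "c2", "c3", "c4", "c5"),
    model_1 = c("m1", "m3", NA, "m7", "m9"),
    evalue_1 = c(1e-8, 1e-4, NA, 1e-20, 1e-6),
    model_2 = c("m2", NA, NA, "m8", NA),
    evalue_2 = c(1e-6, NA, NA, 1e-10, NA),
    kog_class = c("KOG1234", NA, NA, "KOG9", NA),
    description = c(
      "fucoxanthin-chlorophyll a/c binding protein",
      "Ca2+/H+ antiporter",
      NA,
      "serine/threonine kinase",
      "malate dehydrogenase"
    )
  )
}

# Directed set built from an id prefix and up/down counts.
dgs_counts <- function(prefix, n_up, n_down, offset = 0, label = prefix,
                       stage = "diploid") {
  n <- n_up + n_down
  directed_gene_set(
    tibble::tibble(
      cluster_id = sprintf("%s%06d", prefix, offset + seq_len(n)),
      direction = rep(c("up", "down"), c(n_up, n_down))
    ),
    label = label, stage = stage, contrast = "co2"
  )
}
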