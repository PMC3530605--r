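test_that("probe tables round-trip through TSV with clusters grouped", {
  probes <- toy_probe_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(probes, path)
  back <- read_probe_table(path)
  expect_equal(as.data.frame(back), as.data.frame(probes))
  expect_equal(nrow(back), 6)
  expect_setequal(unique(back$cluster_id), c("c1", "c2"))
  expect_equal(sum(back$cluster_id == "c1"), 4)
})

test_that("non-positive intensities are flagged, not dropped", {
  probes <- toy_probe_table()
  probes$reference_intensity[2] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(probes, path)
  back <- read_probe_table(path)
  expect_equal(nrow(back), 6)
  expect_false(back$qc_ok[2])
  expect_true(all(back$qc_ok[-2]))
})

test_that("probe-table integrity violations are errors naming the culprit", {
  probes <- toy_probe_table()
  probes$cluster_id[4] <- "c9"  # c1_p1 now maps to two clusters
  expect_error(validate_probe_table(probes),
               class = "crmarray_integrity_error")

  dup <- toy_probe_table()
  dup$probe_id[2] <- "c1_p1"
  dup$cluster_id[2] <- "c1"
  expect_error(validate_probe_table(dup),
               class = "crmarray_integrity_error")

  crowded <- toy_probe_table()[1:3, ]
  crowded$probe_id <- paste0("c1_p", 1:3)
  crowded$cluster_id <- "c1"
  extra <- crowded[1, ]
  extra$probe_id <- "c1_p4"
  expect_error(validate_probe_table(dplyr::bind_rows(crowded, extra)),
               class = "crmarray_integrity_error")
})

test_that("missing probe-table columns raise a format error naming them", {
  probes <- toy_probe_table()
  probes$qc_ok <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(probes, path)
  expect_error(read_probe_table(path), "qc_ok",
               class = "crmarray_format_error")
})

test_that("a complete design validates with no incomplete cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(full_design(), path)
  d <- read_design(path)
  expect_equal(nrow(d), 24)
  expect_equal(nrow(attr(d, "incomplete_cells")), 0)
})

test_that("a missing replicate is reported, not fatal", {
  d <- full_design()[-1, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, path)
  back <- read_design(path)
  inc <- attr(back, "incomplete_cells")
  expect_equal(nrow(inc), 1)
  expect_equal(inc$stage, "diploid")
  expect_equal(inc$n, 2L)
})

test_that("design enum and uniqueness violations are errors", {
  d <- full_design()
  d$pco2_pa[1] <- 500
  expect_error(validate_design(d), "pco2_pa",
               class = "crmarray_format_error")

  d2 <- full_design()
  d2$replicate[2] <- 1L
  expect_error(validate_design(d2), class = "crmarray_integrity_error")
})

test_that("annotation tables parse absent fields and flag misordered e-values", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_true(is.na(back$model_1[3]))
  expect_true(all(is.na(back[3, -1])))

  misordered <- ann
  misordered$evalue_1[1] <- 1e-4
  misordered$evalue_2[1] <- 1e-9
  write_annotation_table(misordered, path)
  expect_warning(read_annotation_table(path),
                 class = "crmarray_integrity_warning")
})

test_that("malformed e-values raise a format error with the row number", {
  lines <- c(
    "cluster_id\tmodel_1\tevalue_1\tmodel_2\tevalue_2\tkog_class\tdescription",
    "c1\tm1\tnot-a-number\t.\t.\t.\t."
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path)
  expect_error(read_annotation_table(path), "row 1",
               class = "crmarray_format_error")
})

test_that("gene lists are written sorted, with '.' for absent, and round-trip", {
  calls <- tibble::tibble(
    cluster_id = c("c2", "c1"),
    stage = "diploid",
    contrast = "co2_at_lowlight",
    status = "regulated",
    direction = c("down", "up"),
    n_hit_probes = c(3L, 2L),
    mean_fold_change = c(-1.8, 2.25)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(calls, path, annotation = toy_annotation(),
                  categories = tibble::tibble(cluster_id = "c1",
                                              category = "light_reactions"))
  back <- read_gene_list(path)
  expect_equal(back$cluster_id, c("c1", "c2"))
  expect_equal(back$mean_fold_change, c(2.25, -1.8))
  expect_equal(back$categories, c("light_reactions", NA))
  raw <- readLines(path)
  expect_true(grepl("\t\\.\t", raw[3]))  # absent fields written as '.'
})

test_that("an empty gene list yields a header-only file", {
  calls <- tibble::tibble(
    cluster_id = character(), stage = character(), contrast = character(),
    status = character(), direction = character(),
    n_hit_probes = integer(), mean_fold_change = numeric()
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(calls, path)
  expect_equal(length(readLines(path)), 1)
})
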