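test_that("an empty cohort is empty everywhere", {
  co <- simulate_cohort(sim_config(n_patients = 0))
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$segments), 0)
  expect_equal(nrow(co$samples), 0)
  expect_equal(nrow(co$fish), 0)
  expect_equal(nrow(co$truth$volumes), 0)
})

test_that("degenerate configuration ranges are rejected", {
  expect_error(sim_config(purity_range = c(0.9, 0.3)), "degenerate range")
  expect_error(sim_config(clones_per_tumor = c(3, 2)), "degenerate range")
  expect_error(sim_config(n_genes = 10, planted_gene_id = "G0042"),
               "planted_gene_id")
})

test_that("the same seed reproduces byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(small_config(seed = 1), out_dir = d1)
  simulate_cohort(small_config(seed = 1), out_dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  # and a different seed changes at least the variant calls
  d3 <- withr::local_tempdir()
  simulate_cohort(small_config(seed = 2), out_dir = d3)
  v <- grep("\\.vcf$", f1, value = TRUE)[1]
  expect_false(identical(unname(tools::md5sum(file.path(d1, v))),
                         unname(tools::md5sum(file.path(d3, v)))))
})

test_that("response classification follows the pathologic definitions", {
  expect_equal(classify_response(0, NA, any_tumor = FALSE, involution = FALSE),
               "CR")
  expect_equal(classify_response(0.15, 6, TRUE, TRUE), "MRD")
  expect_equal(classify_response(0.2, 6, TRUE, TRUE), "MRD") # boundary in
  # above 0.2 cc: never MRD, involution splits PR/NR
  expect_equal(classify_response(0.25, 6, TRUE, TRUE), "PR")
  expect_equal(classify_response(0.25, 6, TRUE, FALSE), "NR")
  # high-grade element blocks MRD
  expect_equal(classify_response(0.1, 7, TRUE, FALSE), "NR")
  expect_error(classify_response(-1, 6, TRUE, TRUE), ">= 0")
})

test_that("mean clone VAF converges to the purity/copy-number expectation", {
  co <- simulate_cohort(sim_config(n_patients = 2, mean_depth = 10000,
                                   n_snvs_per_patient = 300, n_genes = 50,
                                   planted_gene_id = "G0005",
                                   n_fish_cells = 50, seed = 5))
  v <- dplyr::inner_join(co$variants, co$truth$snv_clones,
                         by = c("chrom", "pos"))
  v <- dplyr::inner_join(v, co$samples[, c("sample", "patient", "purity",
                                           "timepoint", "preservation")],
                         by = c("sample", "patient"))
  v <- dplyr::filter(v, .data$timepoint == "BX", .data$preservation == "FF")
  v <- dplyr::inner_join(v, co$truth$clone_ccfs, by = c("patient", "clone"))
  agg <- v |>
    dplyr::group_by(.data$patient, .data$clone) |>
    dplyr::summarise(mean_vaf = mean(.data$vaf),
                     expected = mean(.data$purity * .data$ccf_pre /
                                       (.data$purity * 2 +
                                          2 * (1 - .data$purity))),
                     n = dplyr::n(), .groups = "drop")
  agg <- dplyr::filter(agg, .data$n >= 30)
  expect_true(all(abs(agg$mean_vaf - agg$expected) < 0.01))
})

test_that("deep-deletion prevalence anticorrelates with residual volume", {
  neg <- vapply(1:30, function(s) {
    co <- simulate_cohort(sim_config(n_patients = 12, n_snvs_per_patient = 10,
                                     n_genes = 50, planted_gene_id = "G0005",
                                     n_fish_cells = 50, seed = s))
    tr <- dplyr::inner_join(co$truth$prevalence, co$truth$volumes,
                            by = "patient")
    cor(tr$prevalence_pre, tr$residual_volume_cc, method = "spearman") < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("planted expression fold change is realized at cohort scale", {
  lfc <- vapply(1:10, function(s) {
    sim <- withr::with_seed(s, simulate_expression(n_genes = 500, n1 = 6,
                                                   n2 = 7, n_de = 25,
                                                   logfc = 2,
                                                   dispersion = 0.1))
    de <- de_test(sim$counts, sim$groups)
    mean(de$logFC[de$gene %in% rownames(sim$counts)[sim$is_de]])
  }, numeric(1))
  expect_true(all(abs(lfc - 2) < 0.5))
})

test_that("responders carry the planted loss before treatment only", {
  co <- simulate_cohort(small_config(seed = 4))
  planted <- co$truth$planted_loss$patient[co$truth$planted_loss$planted]
  gm <- co$gene_model[co$gene_model$gene == co$truth$planted_gene, ]
  covering <- dplyr::filter(co$segments, .data$chrom == gm$chrom,
                            .data$start <= gm$start, .data$end >= gm$end,
                            .data$minor_cn == 0)
  hit <- dplyr::inner_join(covering, co$samples[, c("sample", "patient",
                                                    "timepoint")],
                           by = "sample")
  expect_setequal(unique(hit$patient[hit$timepoint == "BX"]), planted)
  expect_false(any(hit$timepoint == "TX" & hit$patient %in% planted &
                     hit$cn_fraction > 0.1))
})

test_that("written cohorts read back into the same analysis inputs", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_config(seed = 6), out_dir = dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$variants), nrow(co$variants))
  expect_equal(dim(back$counts), dim(co$counts))
  expect_equal(sort(back$samples$sample), sort(co$samples$sample))
  expect_equal(nrow(back$segments), nrow(co$segments))
  expect_equal(back$gene_model$gene, co$gene_model$gene)
})
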