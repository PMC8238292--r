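test_that("CCF estimates match the purity/copy-number transform on a grid", {
  grid <- expand.grid(purity = c(0.2, 0.4, 0.6, 0.8, 1.0),
                      cnt = c(1L, 2L, 3L, 4L),
                      m = c(1L, 2L),
                      vaf = c(0.05, 0.1, 0.2, 0.4))
  grid <- grid[grid$m <= grid$cnt, ]
  depth <- 1000L
  variants <- tibble::tibble(
    chrom = "chr1", pos = seq_len(nrow(grid)), ref = "A", alt = "T",
    alt_count = as.integer(round(grid$vaf * depth)),
    ref_count = depth - as.integer(round(grid$vaf * depth)),
    depth = depth, vaf = grid$vaf,
    major_cn = as.integer(pmax(grid$m, grid$cnt - 1L)),
    minor_cn = 0L, total_cn = as.integer(grid$cnt),
    in_segment = TRUE,
    sample = paste0("S", seq_len(nrow(grid))))
  samples <- tibble::tibble(sample = variants$sample, purity = grid$purity)
  est <- estimate_ccfs(variants, samples)
  expected_m <- pmin(pmax(round(grid$vaf *
    (grid$purity * grid$cnt + 2 * (1 - grid$purity)) / grid$purity), 1),
    variants$major_cn)
  expected <- pmin(oracle_ccf(grid$vaf, grid$purity, grid$cnt, expected_m), 1.5)
  expect_equal(est$m, as.integer(expected_m))
  expect_equal(est$ccf, expected, tolerance = 1e-9)
})

test_that("clonal heterozygous limit and edge cases behave", {
  v <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
                      alt_count = c(50L, 15L, 0L), ref_count = c(50L, 85L, 100L),
                      depth = 100L, vaf = c(0.5, 0.15, 0),
                      major_cn = 1L, minor_cn = 1L, total_cn = 2L,
                      in_segment = TRUE, sample = c("A", "B", "C"))
  s <- tibble::tibble(sample = c("A", "B", "C"), purity = c(1, 0.6, 0.4))
  est <- estimate_ccfs(v, s)
  expect_equal(est$ccf[1], 1.0)            # purity 1, CNt 2, VAF 0.5
  expect_equal(est$ccf[2], 0.15 * 2 / 0.6) # = 0.5
  expect_equal(est$ccf[3], 0)              # VAF 0 -> CCF 0 at any purity
})

test_that("CCF is scale-consistent: doubled counts, same estimate, tighter CI", {
  base <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "C", alt = "A",
                         alt_count = 30L, ref_count = 70L, depth = 100L,
                         vaf = 0.3, major_cn = 1L, minor_cn = 1L,
                         total_cn = 2L, in_segment = TRUE, sample = "A")
  doubled <- dplyr::mutate(base, alt_count = 60L, ref_count = 140L,
                           depth = 200L)
  s <- tibble::tibble(sample = "A", purity = 0.7)
  e1 <- estimate_ccfs(base, s)
  e2 <- estimate_ccfs(doubled, s)
  expect_equal(e1$ccf, e2$ccf, tolerance = 1e-12)
  expect_lt(e2$ccf_high - e2$ccf_low, e1$ccf_high - e1$ccf_low)
})

test_that("VCF round-trip preserves allelic depths and VAFs", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_config(seed = 3), out_dir = dir)
  s <- co$samples$sample[1]
  back <- read_vcf_variants(file.path(dir, paste0(s, ".vcf")))
  orig <- dplyr::arrange(co$variants[co$variants$sample == s, ],
                         .data$chrom, .data$pos)
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$alt_count, orig$alt_count)
  expect_equal(back$ref_count, orig$ref_count)
  expect_equal(back$vaf, orig$vaf)
})

test_that("an empty VCF body reads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"),
             path)
  v <- suppressWarnings(read_vcf_variants(path))
  expect_equal(nrow(v), 0)
})

test_that("malformed segment tables are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample = "A", chrom = "chr1",
                                  start = c(0, 500), end = c(100, 400),
                                  major_cn = 1L, minor_cn = 1L,
                                  cn_fraction = 1), path)
  expect_error(read_segments(path), "start >= end.*line 3")
})

test_that("segment classes follow the subclonality thresholds", {
  samples <- tibble::tibble(sample = c("A", "B"), patient = "P1", ploidy = 2,
                            purity_clear = TRUE)
  seg <- tibble::tibble(
    sample = c("A", "A", "A", "A"),
    chrom = "chr1",
    start = c(0, 1000, 2000, 3000), end = c(500, 1500, 2500, 3500),
    major_cn = c(1L, 1L, 1L, 2L), minor_cn = c(0L, 0L, 0L, 2L),
    cn_fraction = c(0.5, 0.95, 0.05, 0.5))
  cl <- classify_segments(seg, samples)
  expect_equal(cl$class[1], "subclonal")  # loss, 0.1 < 0.5 < 0.9
  expect_equal(cl$class[2], "clonal")     # >= 0.9
  expect_equal(cl$class[3], "absent")     # <= 0.1, no support elsewhere
  expect_true(cl$high_amp[4] == FALSE && cl$total_cn[4] == 4)
})

test_that("a low-fraction loss is rescued by support in another sample", {
  samples <- tibble::tibble(sample = c("A", "B"), patient = "P1", ploidy = 2,
                            purity_clear = TRUE)
  seg <- tibble::tibble(
    sample = c("A", "B"),
    chrom = "chr1", start = 0, end = 500,
    major_cn = 1L, minor_cn = 0L,
    cn_fraction = c(0.05, 0.3))
  cl <- classify_segments(seg, samples)
  expect_equal(cl$class[cl$sample == "A"], "rescued-subclonal")
  expect_equal(cl$class[cl$sample == "B"], "subclonal")
})

test_that("classification ignores row order and which sample comes first", {
  samples <- tibble::tibble(sample = c("A", "B"), patient = "P1", ploidy = 2,
                            purity_clear = TRUE)
  seg <- tibble::tibble(
    sample = c("A", "B", "A"),
    chrom = "chr1", start = c(0, 0, 1000), end = c(500, 500, 1500),
    major_cn = 1L, minor_cn = 0L,
    cn_fraction = c(0.05, 0.3, 0.6))
  cl1 <- classify_segments(seg, samples)
  cl2 <- classify_segments(seg[c(3, 2, 1), ], samples)
  key <- function(x) dplyr::arrange(x, .data$sample, .data$start)$class
  expect_equal(key(cl1), key(cl2))
})

test_that("samples with unclear purity are excluded", {
  samples <- tibble::tibble(sample = "A", patient = "P1", ploidy = 2,
                            purity_clear = FALSE)
  seg <- tibble::tibble(sample = "A", chrom = "chr1", start = 0, end = 500,
                        major_cn = 1L, minor_cn = 0L, cn_fraction = 0.5)
  expect_equal(classify_segments(seg, samples)$class, "excluded")
})

test_that("FFPE transition test handles degenerate and forced cases", {
  mk_variants <- function(fracs_ff, fracs_ffpe, n_per = 40) {
    out <- list()
    for (i in seq_along(fracs_ff)) {
      for (kind in c("FF", "FFPE")) {
        frac <- if (kind == "FF") fracs_ff[i] else fracs_ffpe[i]
        n_tr <- round(frac * n_per)
        out[[paste(i, kind)]] <- tibble::tibble(
          chrom = "chr1", pos = seq_len(n_per),
          ref = c(rep("C", n_tr), rep("A", n_per - n_tr)),
          alt = c(rep("T", n_tr), rep("G", n_per - n_tr)),
          ref_count = 95L, alt_count = 5L, depth = 100L, vaf = 0.05,
          sample = sprintf("P%d_%s", i, kind))
      }
    }
    dplyr::bind_rows(out)
  }
  mk_samples <- function(k) tibble::tibble(
    sample = c(sprintf("P%d_FF", 1:k), sprintf("P%d_FFPE", 1:k)),
    patient = rep(sprintf("P%d", 1:k), 2),
    preservation = rep(c("FF", "FFPE"), each = k),
    timepoint = "BX")

  # identical fractions in all pairs -> p = 1 by convention
  v <- mk_variants(rep(0.2, 4), rep(0.2, 4))
  res <- ffpe_transition_test(v, mk_samples(4), vaf_bins = c(0.01, 0.10))
  expect_equal(res$p, 1)

  # FFPE uniformly above FF across 8 pairs (with spread) -> rejection
  set.seed(1)
  ff <- runif(8, 0.1, 0.2)
  v <- mk_variants(ff, ff + 0.3)
  res <- ffpe_transition_test(v, mk_samples(8), vaf_bins = c(0.01, 0.10))
  expect_lt(res$p, 0.05)
  expect_gt(res$mean_diff, 0.25)
})

test_that("pairs without variants in a bin are dropped with a warning", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "C", alt = "T",
    ref_count = c(95L, 95L, 80L, 80L), alt_count = c(5L, 5L, 20L, 20L),
    depth = 100L, vaf = c(0.05, 0.05, 0.2, 0.2),
    sample = c("P1_FF", "P1_FFPE", "P2_FF", "P2_FFPE"))
  s <- tibble::tibble(sample = v$sample, patient = rep(c("P1", "P2"), each = 2),
                      preservation = rep(c("FF", "FFPE"), 2), timepoint = "BX")
  # only one pair has variants in the low bin -> < 2 pairs after dropping
  expect_warning(
    expect_error(ffpe_transition_test(v, s, vaf_bins = c(0.01, 0.10)),
                 ">= 2 matched"),
    "dropped")
})
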