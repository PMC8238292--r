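test_that("every cell lands in exactly one state", {
  cells <- tibble::tibble(sample = "S", cell_id = as.character(1:6),
                          target_signals = c(0L, 0L, 1L, 2L, 3L, 5L),
                          centromere_signals = c(2L, 0L, 2L, 2L, 1L, 0L))
  cl <- classify_cells(cells)
  expect_equal(cl$state, c("deep_deletion", "qc_fail", "single_loss",
                           "two_plus", "two_plus", "qc_fail"))
  expect_false(anyNA(cl$state))
})

test_that("prevalence fractions partition passing cells with valid CIs", {
  cells <- tibble::tibble(sample = "S", cell_id = as.character(1:500),
                          target_signals = rep(2L, 500),
                          centromere_signals = 2L)
  pv <- fish_prevalence(cells)
  expect_equal(pv$frac_deep_deletion, 0)
  expect_equal(pv$frac_two_plus, 1)
  expect_equal(pv$frac_deep_deletion + pv$frac_single_loss +
                 pv$frac_two_plus, 1)
  expect_false(pv$low_confidence)
  expect_true(pv$frac_two_plus_low <= 1 & pv$frac_two_plus_high >= 1)
})

test_that("too few cells is flagged low-confidence", {
  cells <- tibble::tibble(sample = "S", cell_id = as.character(1:10),
                          target_signals = 2L, centromere_signals = 2L)
  expect_true(fish_prevalence(cells)$low_confidence)
})

test_that("prevalence is invariant to cell order and table duplication", {
  set.seed(12)
  cells <- tibble::tibble(sample = "S", cell_id = sprintf("c%03d", 1:200),
                          target_signals = sample(0:3, 200, replace = TRUE),
                          centromere_signals = sample(1:3, 200, replace = TRUE))
  p1 <- fish_prevalence(cells)
  p2 <- fish_prevalence(cells[sample(200), ])
  dup <- dplyr::mutate(cells, cell_id = paste0(.data$cell_id, "_dup"))
  p3 <- fish_prevalence(dplyr::bind_rows(cells, dup))
  expect_equal(p1$frac_deep_deletion, p2$frac_deep_deletion)
  expect_equal(p1$frac_deep_deletion, p3$frac_deep_deletion)
  expect_equal(p1$frac_single_loss, p3$frac_single_loss)
})

test_that("Wilson interval covers a planted 20% deep-deletion prevalence", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 500
    deep <- rbinom(1, n, 0.2)
    cells <- tibble::tibble(sample = "S", cell_id = as.character(1:n),
                            target_signals = rep(c(0L, 2L),
                                                 c(deep, n - deep)),
                            centromere_signals = 2L)
    pv <- fish_prevalence(cells)
    pv$frac_deep_deletion_low <= 0.2 && 0.2 <= pv$frac_deep_deletion_high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("perfectly anti-monotone vectors give rho = -1 with small exact p", {
  prev <- tibble::tibble(sample = sprintf("S%d", 1:5),
                         frac_deep_deletion = c(0.05, 0.1, 0.2, 0.25, 0.3),
                         frac_two_plus = c(0.9, 0.8, 0.7, 0.6, 0.5))
  samples <- tibble::tibble(sample = prev$sample,
                            patient = sprintf("P%d", 1:5),
                            residual_volume_cc = c(5, 4, 3, 2, 1))
  rc <- response_correlation(prev, samples)
  dd <- rc[rc$state == "frac_deep_deletion", ]
  expect_equal(dd$rho, -1)
  expect_equal(dd$p, 2 / factorial(5)) # two-sided exact permutation p
  expect_equal(rc$rho[rc$state == "frac_two_plus"], 1)
})

test_that("exact permutation p agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:5) {
    x <- runif(7); y <- runif(7)
    ours <- neoclone:::spearman_test(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("constant prevalence is flagged undefined", {
  prev <- tibble::tibble(sample = sprintf("S%d", 1:5),
                         frac_deep_deletion = 0.2,
                         frac_two_plus = seq(0.5, 0.9, 0.1))
  samples <- tibble::tibble(sample = prev$sample,
                            patient = sprintf("P%d", 1:5),
                            residual_volume_cc = 1:5)
  rc <- response_correlation(prev, samples)
  expect_false(rc$defined[rc$state == "frac_deep_deletion"])
  expect_true(is.na(rc$rho[rc$state == "frac_deep_deletion"]))
})

test_that("too few patients is an error", {
  prev <- tibble::tibble(sample = sprintf("S%d", 1:3),
                         frac_deep_deletion = c(0.1, 0.2, 0.3))
  samples <- tibble::tibble(sample = prev$sample, patient = prev$sample,
                            residual_volume_cc = 3:1)
  expect_error(response_correlation(prev, samples, "frac_deep_deletion"),
               ">= 4 patients")
})

test_that("pre/post deltas are zero for identical summaries and detect depletion", {
  mk_cells <- function(id, frac_deep, n = 500) {
    deep <- round(frac_deep * n)
    tibble::tibble(sample = id, cell_id = as.character(1:n),
                   target_signals = rep(c(0L, 2L), c(deep, n - deep)),
                   centromere_signals = 2L)
  }
  pre <- fish_prevalence(mk_cells("pre", 0.3))
  same <- fish_prevalence(mk_cells("post", 0.3))
  d0 <- pre_post_change(pre, same)
  expect_equal(d0$delta, rep(0, 3))

  post <- fish_prevalence(mk_cells("post", 0.05)) # planted 0.25 depletion
  d1 <- pre_post_change(pre, post)
  dd <- d1[d1$state == "deep_deletion", ]
  expect_lt(dd$delta, 0)
  expect_lt(dd$delta_high, 0) # CI excludes zero

  low <- fish_prevalence(mk_cells("tiny", 0.3, n = 10))
  expect_error(pre_post_change(low, post), "minimum-cell")
  expect_error(pre_post_change(NULL, post), "exactly one")
})
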