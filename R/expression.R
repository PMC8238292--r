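#' Coerce a counts table to a genes-by-samples integer matrix
#'
#' Accepts a matrix with gene rownames or a data frame whose first column
#' (or a column named `gene`) carries gene ids.
#'
#' @param counts Matrix or data frame of non-negative counts.
#' @return Numeric matrix with gene rownames.
#' @export
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    gene_col <- if ("gene" %in% names(counts)) "gene" else names(counts)[1]
    genes <- counts[[gene_col]]
    m <- as.matrix(counts[setdiff(names(counts), gene_col)])
    rownames(m) <- genes
    counts <- m
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in count matrix", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  storage.mode(counts) <- "double"
  counts
}

# median-of-ratios size factors (geometric-mean reference, positive genes only)
size_factors <- function(m) {
  lg <- log(m)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg, na.rm = FALSE) # geometric mean over samples, NA if any 0
  use <- is.finite(ref)
  if (!any(use)) return(rep(1, ncol(m)))
  apply(m[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - ref[use]))
  })
}

#' Log2 counts-per-million with median-of-ratios normalization
#'
#' Counts are first divided by median-of-ratios size factors, then
#' transformed as `log2((count + 0.5) / (library_size + 1) * 1e6)`. The
#' library size is the mean corrected library size, common to all
#' samples: after size-factor correction the samples share one scale, and
#' dividing each sample by its own corrected total would re-introduce the
#' composition bias (a block of genuinely up-regulated genes inflating
#' one group's totals and deflating every other gene there) that the
#' size factors exist to remove.
#'
#' @param counts Genes-by-samples counts (matrix or data frame).
#' @return Matrix of log2 CPM values, same dimensions.
#' @export
log_cpm <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(colSums(m) == 0)) stop("zero library size", call. = FALSE)
  sf <- size_factors(m)
  m <- sweep(m, 2, sf, "/")
  lib <- mean(colSums(m))
  log2((m + 0.5) / (lib + 1) * 1e6)
}

#' Per-gene differential expression by Welch t-test on log-CPM
#'
#' Genes are first filtered for expression (CPM > 1 in at least half of
#' the smaller group); filtered genes are excluded from testing and from
#' the Benjamini-Hochberg denominator. The log fold change is the
#' difference of group means of log2 CPM (treated minus control).
#'
#' @param counts Genes-by-samples counts.
#' @param groups Factor/character vector over samples with exactly two
#'   levels; the *second* level (alphabetically, or factor level 2) is
#'   treated and the first is control.
#' @param min_cpm,min_frac Expression filter: CPM above `min_cpm` in at
#'   least `min_frac` of the smaller group's size.
#' @return Tibble with `gene`, `logFC`, `logCPM`, `p`, `fdr`, ordered by
#'   `p`. Only tested genes appear.
#' @export
de_test <- function(counts, groups, min_cpm = 1, min_frac = 0.5) {
  m <- as_count_matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels",
                                 call. = FALSE)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group",
                                   call. = FALSE)
  lc <- log_cpm(m)
  cpm <- 2^lc
  n_small <- min(table(groups))
  keep <- rowSums(cpm > min_cpm) >= ceiling(min_frac * n_small)
  lc <- lc[keep, , drop = FALSE]
  ctrl <- lc[, groups == levels(groups)[1], drop = FALSE]
  trt <- lc[, groups == levels(groups)[2], drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(trt)
  v1 <- apply(ctrl, 1, stats::var); v2 <- apply(trt, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1 # no variance, no evidence
  out <- tibble::tibble(gene = rownames(lc),
                        logFC = unname(m2 - m1),
                        logCPM = unname(rowMeans(lc)),
                        p = unname(p),
                        fdr = unname(stats::p.adjust(p, method = "BH")))
  dplyr::arrange(out, .data$p)
}

#' Filter differential-expression results to candidate genes
#'
#' Keeps genes passing all three strict thresholds: log fold change above
#' `lfc_min`, FDR below `fdr_max`, and average log2 CPM above `lcpm_min`.
#'
#' @param de Tibble from [de_test()].
#' @param lfc_min,fdr_max,lcpm_min Thresholds (strict inequalities).
#' @return Filtered tibble.
#' @export
filter_candidates <- function(de, lfc_min = 1, fdr_max = 0.05, lcpm_min = 3) {
  stopifnot(is.finite(lfc_min), is.finite(fdr_max))
  dplyr::filter(de, .data$logFC > lfc_min, .data$fdr < fdr_max,
                .data$logCPM > lcpm_min)
}

#' Variance fractions of principal components of log-CPM
#'
#' Centered PCA of samples in log-CPM space. For a constant matrix all
#' fractions are zero (with a warning) rather than undefined.
#'
#' @param counts Genes-by-samples counts.
#' @return Tibble with `component` and `var_fraction` (ordered, summing
#'   to 1 when total variance is positive).
#' @export
pca_variance <- function(counts) {
  lc <- log_cpm(counts)
  if (ncol(lc) < 2) stop("need >= 2 samples", call. = FALSE)
  x <- t(lc)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  total <- sum(v)
  if (total == 0) {
    warning("constant matrix: zero variance in all components", call. = FALSE)
    frac <- rep(0, length(v))
  } else {
    frac <- v / total
  }
  tibble::tibble(component = seq_along(frac), var_fraction = frac)
}

#' Splice-junction ratio of a variant to its canonical isoform
#'
#' The ratio of reads supporting the variant-specific junction to reads
#' supporting the canonical junction (e.g. AR-V7 cryptic exon junction vs
#' the full-length receptor's exon junction), with a Wilson binomial
#' confidence interval on the proportion
#' `variant / (variant + canonical)`. With zero canonical reads the ratio
#' is undefined and flagged.
#'
#' @param variant_reads,canonical_reads Non-negative read counts
#'   (vectorized).
#' @param conf_level Confidence level.
#' @return Tibble with `variant_reads`, `canonical_reads`, `ratio`,
#'   `prop`, `prop_low`, `prop_high`, `defined`.
#' @export
junction_ratio <- function(variant_reads, canonical_reads,
                           conf_level = 0.95) {
  stopifnot(all(variant_reads >= 0), all(canonical_reads >= 0))
  total <- variant_reads + canonical_reads
  defined <- canonical_reads > 0
  ratio <- ifelse(defined, variant_reads / canonical_reads, NA_real_)
  ci <- wilson_ci(variant_reads, pmax(total, 1), conf_level)
  tibble::tibble(variant_reads = variant_reads,
                 canonical_reads = canonical_reads,
                 ratio = ratio,
                 prop = ifelse(total > 0, variant_reads / total, NA_real_),
                 prop_low = ifelse(total > 0, ci$lower, NA_real_),
                 prop_high = ifelse(total > 0, ci$upper, NA_real_),
                 defined = defined)
}

#' Per-gene log fold changes for a signature gene list
#'
#' Convenience extraction of DE log fold changes for a user-supplied
#' signature (e.g. EMT or stemness markers); genes absent from the tested
#' universe are reported with missing values.
#'
#' @param de Tibble from [de_test()].
#' @param genes Character vector of gene ids.
#' @return Tibble with one row per requested gene.
#' @export
signature_logfc <- function(de, genes) {
  dplyr::left_join(tibble::tibble(gene = genes), de, by = "gene")
}
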