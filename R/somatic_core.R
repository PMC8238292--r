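#' Read somatic SNVs from a VCF file
#'
#' Parses a VCF v4.2 file carrying a single tumor sample with `AD`
#' (ref,alt allelic depths) and `DP` FORMAT fields, as written by
#' [simulate_cohort()] or any caller emitting those fields.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param sample_id Sample identifier to attach; defaults to the VCF's
#'   genotype column name.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `sample`, and derived `depth` and `vaf`
#'   (`NA` when depth is zero).
#' @export
read_vcf_variants <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          ref_count = integer(), alt_count = integer(),
                          sample = character(), depth = integer(),
                          vaf = double()))
  }
  if (ncol(v@gt) < 2) stop("VCF has no genotype column: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (all(is.na(ad))) stop("VCF lacks AD FORMAT field: ", path, call. = FALSE)
  if (all(is.na(dp))) stop("VCF lacks DP FORMAT field: ", path, call. = FALSE)
  counts <- stringr::str_split_fixed(ad[, 1], ",", 2)
  out <- tibble::tibble(
    chrom = v@fix[, "CHROM"],
    pos = as.integer(v@fix[, "POS"]),
    ref = v@fix[, "REF"],
    alt = v@fix[, "ALT"],
    ref_count = as.integer(counts[, 1]),
    alt_count = as.integer(counts[, 2]),
    sample = sample_id
  )
  if (anyNA(out$ref_count) || anyNA(out$alt_count)) {
    bad <- which(is.na(out$ref_count) | is.na(out$alt_count))[1]
    stop("malformed AD field at record ", bad, " of ", path, call. = FALSE)
  }
  add_vaf(out)
}

add_vaf <- function(variants) {
  dplyr::mutate(variants,
                depth = .data$ref_count + .data$alt_count,
                vaf = dplyr::if_else(.data$depth > 0,
                                     .data$alt_count / .data$depth,
                                     NA_real_))
}

#' Read an allele-specific copy-number segment table
#'
#' Expects a tab-separated file with header
#' `sample, chrom, start, end, major_cn, minor_cn, cn_fraction`; intervals
#' are 0-based half-open. `cn_fraction` is the fraction of tumor cells
#' bearing the aberration (Battenberg-style subclonal output).
#'
#' @param path Path to the TSV.
#' @return A tibble of segments with derived `total_cn` and `loh`
#'   (`minor_cn == 0`).
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment table not found: ", path, call. = FALSE)
  seg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           major_cn = readr::col_integer(),
                           minor_cn = readr::col_integer(),
                           cn_fraction = readr::col_double()))
  validate_segments(seg, path)
  dplyr::mutate(seg, total_cn = .data$major_cn + .data$minor_cn,
                loh = .data$minor_cn == 0)
}

validate_segments <- function(seg, what = "segment table") {
  bad <- which(seg$start >= seg$end)
  if (length(bad)) {
    stop("invalid segment (start >= end) at line ", bad[1] + 1, " of ", what,
         call. = FALSE)
  }
  if (any(seg$major_cn < 0 | seg$minor_cn < 0)) {
    stop("negative copy numbers in ", what, call. = FALSE)
  }
  if (any(seg$cn_fraction < 0 | seg$cn_fraction > 1)) {
    stop("cn_fraction outside [0, 1] in ", what, call. = FALSE)
  }
  invisible(TRUE)
}

#' Read the clinical sample sheet
#'
#' @param path CSV with columns `patient, sample, timepoint, preservation,
#'   purity, ploidy, purity_clear, residual_volume_cc, response`.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("patient", "sample", "timepoint", "preservation", "purity",
              "ploidy", "purity_clear", "residual_volume_cc", "response")
  missing <- setdiff(needed, names(sheet))
  if (length(missing)) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(sheet$purity > 0 & sheet$purity <= 1))
  sheet
}

#' Read all somatic inputs for a cohort
#'
#' @param vcf_paths Named character vector of VCF paths; names are sample
#'   ids (unnamed paths take the VCF's own genotype column name).
#' @param segments_path Segment TSV covering all samples.
#' @param sheet_path Clinical sample sheet CSV.
#' @return A list with `variants` (all samples stacked, annotated with the
#'   overlapping segment via [annotate_variants()]), `segments`, `samples`.
#' @export
read_somatic_inputs <- function(vcf_paths, segments_path, sheet_path) {
  ids <- names(vcf_paths)
  variants <- purrr::map2_dfr(vcf_paths,
                              ids %||% rep(list(NULL), length(vcf_paths)),
                              function(p, id) read_vcf_variants(p, id))
  segments <- read_segments(segments_path)
  samples <- read_sample_sheet(sheet_path)
  list(variants = annotate_variants(variants, segments),
       segments = segments, samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate variants with their overlapping copy-number segment
#'
#' Each variant is matched to the segment of the same sample whose
#' half-open interval contains its (1-based) position. Variants outside
#' any segment keep `NA` copy-number columns and are flagged.
#'
#' @param variants Tibble as returned by [read_vcf_variants()].
#' @param segments Tibble as returned by [read_segments()].
#' @return `variants` with `major_cn`, `minor_cn`, `total_cn`,
#'   `cn_fraction` and logical `in_segment` appended.
#' @export
annotate_variants <- function(variants, segments) {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, major_cn = integer(), minor_cn = integer(),
                         total_cn = integer(), cn_fraction = double(),
                         in_segment = logical()))
  }
  vg <- GenomicRanges::GRanges(
    paste(variants$sample, variants$chrom, sep = "!"),
    IRanges::IRanges(variants$pos, width = 1))
  sg <- GenomicRanges::GRanges(
    paste(segments$sample, segments$chrom, sep = "!"),
    IRanges::IRanges(segments$start + 1, segments$end))
  hit <- GenomicRanges::findOverlaps(vg, sg, select = "first")
  dplyr::mutate(variants,
                major_cn = segments$major_cn[hit],
                minor_cn = segments$minor_cn[hit],
                total_cn = segments$major_cn[hit] + segments$minor_cn[hit],
                cn_fraction = segments$cn_fraction[hit],
                in_segment = !is.na(hit))
}

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' Applies the standard purity/copy-number transformation. With tumor
#' purity \eqn{\rho}, local tumor total copy number \eqn{C_t} and mutation
#' multiplicity \eqn{m}, the expected VAF of a mutation present in a
#' fraction \eqn{\phi} of tumor cells is
#' \deqn{E[\mathrm{VAF}] = \frac{\rho\, m\, \phi}{\rho C_t + 2(1-\rho)}.}
#' The multiplicity is estimated by rounding the inverted map at
#' \eqn{\phi = 1} and clipping to `[1, major_cn]`, then
#' \deqn{\hat\phi = \mathrm{VAF}\,\frac{\rho C_t + 2(1-\rho)}{\rho\, m}.}
#' A Wilson binomial confidence interval on the VAF is propagated through
#' the same linear map. Estimates are clipped to `[0, 1.5]` and values
#' above 1 flagged (`ccf_gt1`).
#'
#' @param variants Annotated variant tibble (needs `alt_count`, `depth`,
#'   `major_cn`, `total_cn`; see [annotate_variants()]).
#' @param samples Sample sheet tibble carrying `sample` and `purity`.
#' @param conf_level Confidence level of the interval.
#' @return Input tibble with `m`, `ccf`, `ccf_low`, `ccf_high`, `ccf_gt1`
#'   appended. Variants with zero depth or no overlapping segment get `NA`.
#' @export
estimate_ccfs <- function(variants, samples, conf_level = 0.95) {
  v <- dplyr::left_join(variants,
                        dplyr::distinct(samples[, c("sample", "purity")]),
                        by = "sample")
  if (any(v$purity <= 0, na.rm = TRUE)) stop("purity must be > 0", call. = FALSE)
  if (any(v$total_cn == 0 & v$purity >= 1, na.rm = TRUE)) {
    stop("CCF undefined: zero tumor copy number at full purity", call. = FALSE)
  }
  denom2 <- v$purity * v$total_cn + 2 * (1 - v$purity) # expected total copies
  m <- pmin(pmax(round(v$vaf * denom2 / v$purity), 1), pmax(v$major_cn, 1))
  ci <- wilson_ci(v$alt_count, v$depth, conf_level)
  scale <- denom2 / (v$purity * m)
  clip <- function(x) pmin(pmax(x, 0), 1.5)
  dplyr::mutate(variants,
                m = as.integer(m),
                ccf = clip(v$vaf * scale),
                ccf_low = clip(ci$lower * scale),
                ccf_high = clip(ci$upper * scale),
                ccf_gt1 = .data$ccf > 1)
}

# Wilson score interval for x successes in n trials
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' Classify copy-number segments as clonal, subclonal, rescued or absent
#'
#' A segment is a *loss* when its total copy number falls below the
#' rounded sample ploidy or it shows loss of heterozygosity
#' (`minor_cn == 0`). Classes by copy-number fraction: `clonal` at
#' `>= 0.9`, `subclonal` strictly between 0.1 and 0.9, and `absent` at
#' `<= 0.1` — except that a loss at `<= 0.1` is *rescued-subclonal* when
#' the same loss (an overlapping loss segment at fraction `> 0.1`) is
#' present in at least one other sample of the same patient. Samples whose
#' purity/ploidy solution is unclear (`purity_clear == FALSE`) are
#' `excluded` outright. Segments with total copy number above 4 are
#' flagged (`high_amp`) so downstream driver analyses can ignore
#' amplifications.
#'
#' @param segments Segment tibble (see [read_segments()]).
#' @param samples Sample sheet with `sample`, `patient`, `ploidy`,
#'   `purity_clear`.
#' @return `segments` with `is_loss`, `high_amp` and `class` appended
#'   (`class` in `clonal, subclonal, absent, rescued-subclonal, excluded`).
#' @export
classify_segments <- function(segments, samples) {
  validate_segments(segments)
  seg <- dplyr::left_join(
    segments,
    dplyr::distinct(samples[, c("sample", "patient", "ploidy", "purity_clear")]),
    by = "sample")
  seg <- dplyr::mutate(seg,
    total_cn = .data$major_cn + .data$minor_cn,
    loh = .data$minor_cn == 0,
    is_loss = .data$total_cn < round(.data$ploidy) | .data$loh,
    high_amp = .data$total_cn > 4)

  base_class <- dplyr::case_when(
    !seg$purity_clear ~ "excluded",
    seg$cn_fraction >= 0.9 ~ "clonal",
    seg$cn_fraction > 0.1 ~ "subclonal",
    TRUE ~ "absent")

  # rescue: low-fraction loss present at > 0.1 in another sample of the patient
  rescue <- rep(FALSE, nrow(seg))
  low_loss <- which(base_class == "absent" & seg$is_loss)
  if (length(low_loss)) {
    support <- which(seg$is_loss & seg$cn_fraction > 0.1 & seg$purity_clear)
    if (length(support)) {
      lg <- GenomicRanges::GRanges(
        paste(seg$patient[low_loss], seg$chrom[low_loss], sep = "!"),
        IRanges::IRanges(seg$start[low_loss] + 1, seg$end[low_loss]))
      sgr <- GenomicRanges::GRanges(
        paste(seg$patient[support], seg$chrom[support], sep = "!"),
        IRanges::IRanges(seg$start[support] + 1, seg$end[support]))
      hits <- GenomicRanges::findOverlaps(lg, sgr)
      other <- seg$sample[low_loss][S4Vectors::queryHits(hits)] !=
        seg$sample[support][S4Vectors::subjectHits(hits)]
      rescue[low_loss[unique(S4Vectors::queryHits(hits)[other])]] <- TRUE
    }
  }
  seg$class <- ifelse(rescue, "rescued-subclonal", base_class)
  dplyr::select(seg, -"patient", -"ploidy", -"purity_clear")
}

#' Paired test for FFPE deamination artifacts by VAF bin
#'
#' Formalin fixation deaminates cytosine, inflating low-VAF C>T (and
#' reverse-strand G>A) calls. For each patient with a matched fresh-frozen
#' (FF) and FFPE aliquot, the fraction of SNVs that are C>T or G>A is
#' computed per VAF bin, and a one-sided paired t-test of FFPE > FF is run
#' per bin. Pairs with no SNVs in a bin are dropped from that bin with a
#' warning; if all paired differences are zero, `p = 1` by convention.
#'
#' @param variants Variant tibble with `sample`, `ref`, `alt` and `vaf`.
#' @param samples Sample sheet with `sample`, `patient`, `preservation`
#'   (`FF`/`FFPE`) and `timepoint`; FF/FFPE aliquots of the same patient
#'   and timepoint are paired.
#' @param vaf_bins Numeric vector of closed-left, open-right bin edges.
#' @return A tibble, one row per bin: `bin`, `n_pairs`, `mean_diff`
#'   (mean FFPE minus FF fraction) and `p`.
#' @export
ffpe_transition_test <- function(variants, samples,
                                 vaf_bins = c(0.01, 0.10, 0.25)) {
  meta <- samples[, c("sample", "patient", "preservation", "timepoint")]
  # only patient/timepoint groups with both an FF and an FFPE aliquot pair up
  paired <- meta |>
    dplyr::group_by(.data$patient, .data$timepoint) |>
    dplyr::filter(all(c("FF", "FFPE") %in% .data$preservation)) |>
    dplyr::ungroup()
  v <- dplyr::inner_join(variants, paired, by = "sample")
  v <- dplyr::filter(v, !is.na(.data$vaf))
  v <- dplyr::mutate(v, transition = (.data$ref == "C" & .data$alt == "T") |
                       (.data$ref == "G" & .data$alt == "A"))
  bins <- tibble::tibble(lo = vaf_bins[-length(vaf_bins)],
                         hi = vaf_bins[-1])
  all_pairs <- dplyr::distinct(paired[, c("patient", "timepoint")])
  out <- purrr::pmap_dfr(bins, function(lo, hi) {
    vb <- dplyr::filter(v, .data$vaf >= lo, .data$vaf < hi)
    frac <- vb |>
      dplyr::group_by(.data$patient, .data$timepoint, .data$preservation) |>
      dplyr::summarise(frac = mean(.data$transition), n = dplyr::n(),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "preservation",
                         values_from = c("frac", "n"))
    frac <- dplyr::left_join(all_pairs, frac,
                             by = c("patient", "timepoint"))
    if (!all(c("frac_FF", "frac_FFPE") %in% names(frac))) {
      frac$frac_FF <- frac$frac_FF %||% NA_real_
      frac$frac_FFPE <- frac$frac_FFPE %||% NA_real_
    }
    complete <- !is.na(frac$frac_FF) & !is.na(frac$frac_FFPE)
    if (any(!complete)) {
      warning(sum(!complete), " pair(s) without SNVs in bin [", lo, ", ", hi,
              ") dropped", call. = FALSE)
    }
    frac <- frac[complete, ]
    if (nrow(frac) < 2) {
      stop("need >= 2 matched FF/FFPE pairs with SNVs in bin [", lo, ", ", hi,
           ")", call. = FALSE)
    }
    d <- frac$frac_FFPE - frac$frac_FF
    stderr <- stats::sd(d) / sqrt(length(d))
    p <- if (all(d == 0)) {
      1
    } else if (stderr < 10 * .Machine$double.eps * abs(mean(d))) {
      # constant nonzero shift: degenerate t, direction decides
      if (mean(d) > 0) 0 else 1
    } else {
      stats::t.test(d, alternative = "greater")$p.value
    }
    tibble::tibble(bin = sprintf("[%g,%g)", lo, hi),
                   n_pairs = nrow(frac), mean_diff = mean(d), p = p)
  })
  out
}
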