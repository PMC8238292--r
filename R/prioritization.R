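#' Genes under subclonal loss before treatment but not after
#'
#' For each patient with classified segments at both timepoints, a gene
#' qualifies when at least one pre-treatment loss segment of class
#' `subclonal` or `rescued-subclonal` overlaps it (any overlap of at
#' least 1 bp) and no post-treatment loss segment at copy-number fraction
#' above 0.1 overlaps it. Patients with excluded samples (unclear
#' purity/ploidy) at either timepoint are skipped with a warning.
#'
#' @param classified_segments Output of [classify_segments()] for all
#'   samples of the cohort.
#' @param samples Sample sheet tibble (`sample`, `patient`, `timepoint`,
#'   `preservation`, `purity_clear`).
#' @param gene_model Tibble of gene intervals (`gene`, `chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param post_detect_fraction Copy-number fraction above which a
#'   post-treatment loss counts as detectable.
#' @return Tibble with `patient` and `gene`, one row per qualifying gene.
#' @export
lost_genes_per_patient <- function(classified_segments, samples, gene_model,
                                   post_detect_fraction = 0.1) {
  seg <- dplyr::left_join(
    classified_segments,
    dplyr::distinct(samples[, c("sample", "patient", "timepoint")]),
    by = "sample")
  gg <- GenomicRanges::GRanges(gene_model$chrom,
                               IRanges::IRanges(gene_model$start + 1,
                                                gene_model$end))
  genes_hit <- function(s) {
    if (nrow(s) == 0) return(character(0))
    sg <- GenomicRanges::GRanges(s$chrom,
                                 IRanges::IRanges(s$start + 1, s$end))
    hits <- GenomicRanges::findOverlaps(gg, sg)
    unique(gene_model$gene[S4Vectors::queryHits(hits)])
  }
  excluded_pts <- unique(samples$patient[!samples$purity_clear])
  out <- list()
  for (pt in unique(seg$patient)) {
    ps <- seg[seg$patient == pt, ]
    if (pt %in% excluded_pts || any(ps$class == "excluded")) {
      warning("patient ", pt, " skipped: sample(s) with unclear purity/ploidy",
              call. = FALSE)
      next
    }
    if (!all(c("BX", "TX") %in% ps$timepoint)) next
    pre_loss <- ps[ps$timepoint == "BX" & ps$is_loss &
                     ps$class %in% c("subclonal", "rescued-subclonal"), ]
    post_loss <- ps[ps$timepoint == "TX" & ps$is_loss &
                      ps$cn_fraction > post_detect_fraction, ]
    genes <- setdiff(genes_hit(pre_loss), genes_hit(post_loss))
    if (length(genes)) {
      out[[pt]] <- tibble::tibble(patient = pt, gene = sort(genes))
    }
  }
  if (!length(out)) return(tibble::tibble(patient = character(),
                                          gene = character()))
  dplyr::bind_rows(out)
}

#' Intersect per-patient lost-gene sets across selected responders
#'
#' @param lost Tibble from [lost_genes_per_patient()].
#' @param patients Character vector of selected patient ids (typically the
#'   best responders with paired data).
#' @return Character vector of genes lost subclonally before treatment in
#'   every selected patient and detectable in none afterwards.
#' @export
overlap_candidates <- function(lost, patients) {
  if (!length(patients)) stop("empty patient selection", call. = FALSE)
  sets <- lapply(patients, function(pt) lost$gene[lost$patient == pt])
  sort(Reduce(intersect, sets))
}

#' Rank candidate genes by post-treatment overexpression
#'
#' Applies the expression prioritization thresholds of
#' [filter_candidates()] to the candidate set and ranks survivors by
#' descending log fold change, ties by ascending FDR. Candidates absent
#' from the tested expression universe are retained with missing DE
#' values, ranked last, with a warning.
#'
#' @param candidates Character vector of candidate genes (from
#'   [overlap_candidates()]).
#' @param de DE results tibble from [de_test()].
#' @param lfc_min,fdr_max,lcpm_min Expression thresholds.
#' @return Tibble of surviving candidates with DE columns and `rank`.
#' @export
rank_candidates <- function(candidates, de, lfc_min = 1, fdr_max = 0.05,
                            lcpm_min = 3) {
  cand <- tibble::tibble(gene = candidates)
  merged <- dplyr::left_join(cand, de, by = "gene")
  untested <- is.na(merged$p)
  if (any(untested)) {
    warning(sum(untested), " candidate(s) absent from the DE universe",
            call. = FALSE)
  }
  pass <- dplyr::filter(merged, !is.na(.data$p), .data$logFC > lfc_min,
                        .data$fdr < fdr_max, .data$logCPM > lcpm_min)
  pass <- dplyr::arrange(pass, dplyr::desc(.data$logFC), .data$fdr)
  missing <- merged[untested, ]
  out <- dplyr::bind_rows(pass, missing)
  dplyr::mutate(out, rank = dplyr::row_number())
}
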