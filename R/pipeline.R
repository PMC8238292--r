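#' Default analysis thresholds
#'
#' Every numeric threshold used by the pipeline, with the defaults the
#' analysis is defined by: subclonality bounds (0.1/0.9 copy-number
#' fraction), post-treatment detectability floor (0.1), stable-clone CCF
#' delta (0.1), segment-shift delta (0.25), reciprocal segment overlap
#' (0.5), expression prioritization cutoffs (logFC > 1, FDR < 0.05,
#' logCPM > 3), FFPE VAF bins, and the FISH minimum cell count (50).
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(subclonal_min = 0.1, subclonal_max = 0.9,
       post_detect_fraction = 0.1,
       stable_delta = 0.1, shift_delta = 0.25,
       min_reciprocal_overlap = 0.5,
       lfc_min = 1, fdr_max = 0.05, lcpm_min = 3,
       vaf_bins = c(0.01, 0.10, 0.25),
       fish_min_cells = 50,
       k_max = 6)
}

#' Run the full analysis chain on an in-memory cohort
#'
#' Sequences the analysis stages: CCF estimation and per-sample clonal
#' clustering with longitudinal matching; segment subclonality
#' classification and pre/post segment-pair comparison; the FFPE
#' transition test; differential expression (post- vs pre-treatment
#' fresh-frozen samples); overlap-plus-expression candidate-gene
#' prioritization across the selected responders; FISH prevalence and the
#' prevalence-volume correlation; and the splice-junction variant ratio.
#'
#' @param cohort A `sim_cohort` (or an equivalently shaped list read from
#'   disk by [read_cohort()]).
#' @param responders Patient ids whose lost-gene sets are intersected;
#'   default is the `n_best_responders` patients with the smallest
#'   residual volume.
#' @param thresholds Named list as [default_thresholds()]; partial
#'   overrides are merged onto the defaults.
#' @param seed Seed for the deterministic clustering initialization.
#' @param cluster_clones Set `FALSE` to skip per-sample CCF clustering.
#' @return A list of class `neoclone_report` with one element per stage
#'   plus the thresholds and seed used.
#' @export
analyze_cohort <- function(cohort, responders = NULL, thresholds = list(),
                           seed = 1L, cluster_clones = TRUE) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  samples <- cohort$samples
  if (is.null(responders)) {
    vols <- dplyr::distinct(samples[, c("patient", "residual_volume_cc")])
    vols <- vols[order(vols$residual_volume_cc), ]
    responders <- utils::head(vols$patient, 3)
  }

  variants <- annotate_variants(cohort$variants, cohort$segments)
  ccfs <- estimate_ccfs(variants, samples)
  classified <- classify_segments(cohort$segments, samples)

  ffpe <- tryCatch(
    ffpe_transition_test(cohort$variants, samples, vaf_bins = th$vaf_bins),
    error = function(e) NULL)

  clones <- NULL
  changes <- NULL
  segment_shift <- NULL
  if (cluster_clones) {
    clones <- list(); changes <- list(); segment_shift <- list()
    for (pt in unique(samples$patient)) {
      ff <- samples[samples$patient == pt & samples$preservation == "FF", ]
      s_pre <- ff$sample[ff$timepoint == "BX"]
      s_post <- ff$sample[ff$timepoint == "TX"]
      if (length(s_pre) != 1 || length(s_post) != 1) next
      fit_one <- function(s) {
        cc <- ccfs[ccfs$sample == s & ccfs$in_segment, ]
        if (nrow(cc) < 5) return(NULL)
        cluster_ccfs(cc, purity = ff$purity[ff$sample == s],
                     k_max = th$k_max, seed = seed)
      }
      pre_fit <- fit_one(s_pre)
      post_fit <- fit_one(s_post)
      if (!is.null(pre_fit) && !is.null(post_fit)) {
        clones[[pt]] <- list(pre = pre_fit, post = post_fit)
        changes[[pt]] <- match_longitudinal(pre_fit, post_fit,
                                            delta = th$stable_delta)
      }
      cmp <- tryCatch(compare_segment_pairs(
        cohort$segments[cohort$segments$sample == s_pre, ],
        cohort$segments[cohort$segments$sample == s_post, ],
        min_reciprocal_overlap = th$min_reciprocal_overlap,
        shift_delta = th$shift_delta), error = function(e) NULL)
      if (!is.null(cmp)) segment_shift[[pt]] <- cmp$shift_stat
    }
  }

  # DE: post-treatment vs pre-treatment fresh-frozen samples
  ff <- samples[samples$preservation == "FF", ]
  groups <- factor(ifelse(ff$timepoint == "TX", "post", "pre"),
                   levels = c("pre", "post"))
  de <- de_test(cohort$counts[, ff$sample, drop = FALSE], groups)

  lost <- lost_genes_per_patient(classified, samples, cohort$gene_model,
                                 post_detect_fraction = th$post_detect_fraction)
  candidates <- overlap_candidates(lost, responders)
  ranked <- rank_candidates(candidates, de, lfc_min = th$lfc_min,
                            fdr_max = th$fdr_max, lcpm_min = th$lcpm_min)

  prevalence <- fish_prevalence(cohort$fish, min_cells = th$fish_min_cells)
  pre_prev <- prevalence[prevalence$sample %in%
                           samples$sample[samples$timepoint == "BX"], ]
  correlation <- tryCatch(response_correlation(pre_prev, samples),
                          error = function(e) NULL)

  jr <- cohort$junctions |>
    tidyr::pivot_wider(names_from = "junction_id", values_from = "reads")
  junction <- if (ncol(jr) >= 3) {
    dplyr::bind_cols(jr["sample"],
                     junction_ratio(jr[[3]], jr[[2]]))
  } else NULL

  report <- list(
    thresholds = th, seed = seed, responders = responders,
    n_variants = nrow(cohort$variants),
    ccfs = ccfs, classified_segments = classified,
    ffpe = ffpe, clones = clones, clonal_changes = changes,
    segment_shift = segment_shift,
    de = de, lost_genes = lost, candidates = candidates,
    ranked_candidates = ranked,
    fish_prevalence = prevalence, response_correlation = correlation,
    junction_ratio = junction)
  class(report) <- "neoclone_report"
  report
}

#' Read a cohort written by [write_cohort()] back from disk
#'
#' @param dir Directory holding the cohort files.
#' @return A list shaped like a `sim_cohort` (without ground truth).
#' @export
read_cohort <- function(dir) {
  sheet_path <- file.path(dir, "samples.csv")
  samples <- read_sample_sheet(sheet_path)
  vcfs <- stats::setNames(file.path(dir, paste0(samples$sample, ".vcf")),
                          samples$sample)
  missing <- vcfs[!file.exists(vcfs)]
  if (length(missing)) stop("missing VCF(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  inputs <- read_somatic_inputs(vcfs, file.path(dir, "segments.tsv"),
                                sheet_path)
  counts_path <- file.path(dir, "counts.tsv")
  if (!file.exists(counts_path)) stop("missing counts file: ", counts_path,
                                      call. = FALSE)
  counts <- as_count_matrix(readr::read_tsv(counts_path,
                                            show_col_types = FALSE))
  # BED column order: chrom, start, end, name
  gene_model <- readr::read_tsv(file.path(dir, "genes.bed"),
                                col_names = c("chrom", "start", "end", "gene"),
                                show_col_types = FALSE)
  structure(list(
    variants = inputs$variants, segments = inputs$segments,
    samples = inputs$samples, counts = counts,
    gene_model = gene_model[, c("gene", "chrom", "start", "end")],
    junctions = readr::read_tsv(file.path(dir, "junctions.tsv"),
                                show_col_types = FALSE),
    fish = readr::read_tsv(file.path(dir, "fish.tsv"),
                           show_col_types = FALSE)),
    class = "sim_cohort")
}

#' Run the pipeline from files on disk and write a JSON report
#'
#' @param config Either a path to a JSON run configuration or a list with
#'   at least `input_dir`; optional `output_dir`, `responders`,
#'   `thresholds` (partial overrides), `seed`.
#' @return The report (invisibly the JSON path is attached as
#'   `attr(, "path")` when written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$input_dir)) stop("config needs input_dir", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cohort <- stage("read_inputs", read_cohort(config$input_dir))
  report <- stage("analysis", analyze_cohort(
    cohort,
    responders = config$responders,
    thresholds = config$thresholds %||% list(),
    seed = config$seed %||% 1L))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$output_dir, "report.json")
    jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    attr(report, "path") <- path
  }
  invisible(report)
}

# machine-readable, timestamp-free payload (deterministic for fixed input)
report_payload <- function(report) {
  list(
    package_version = as.character(utils::packageVersion("neoclone")),
    seed = report$seed,
    thresholds = report$thresholds,
    responders = report$responders,
    n_variants = report$n_variants,
    ffpe = report$ffpe,
    segment_shift = report$segment_shift,
    clonal_changes = lapply(report$clonal_changes, as.data.frame),
    candidates = report$candidates,
    ranked_candidates = as.data.frame(report$ranked_candidates),
    de_top = as.data.frame(utils::head(report$de, 20)),
    fish_prevalence = as.data.frame(report$fish_prevalence),
    response_correlation = if (is.null(report$response_correlation)) NULL
      else as.data.frame(report$response_correlation),
    junction_ratio = if (is.null(report$junction_ratio)) NULL
      else as.data.frame(report$junction_ratio))
}

#' @export
print.neoclone_report <- function(x, ...) {
  cat("neoclone pipeline report\n")
  cat("  candidates after overlap:", length(x$candidates), "\n")
  if (nrow(x$ranked_candidates)) {
    cat("  top-ranked candidate:", x$ranked_candidates$gene[1], "\n")
  }
  if (!is.null(x$response_correlation)) {
    rc <- x$response_correlation
    dd <- rc[rc$state == "frac_deep_deletion", ]
    if (nrow(dd) && isTRUE(dd$defined)) {
      cat(sprintf("  deep-deletion prevalence vs volume: rho = %.3f (p = %.3g)\n",
                  dd$rho, dd$p))
    }
  }
  invisible(x)
}
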