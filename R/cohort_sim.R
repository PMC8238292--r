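#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the statistical structure of a simulated neoadjuvant cohort:
#' each patient contributes a pre-treatment biopsy (BX, with one
#' fresh-frozen and one FFPE aliquot) and a post-treatment sample (TX).
#' A "sensitivity gene" is planted as a subclonal copy-number loss in the
#' best responders' pre-treatment samples and is absent post-treatment;
#' the same gene is overexpressed after treatment in the count matrix.
#' Residual tumor volume decreases monotonically with the pre-treatment
#' deep-deletion prevalence (`volume = v_max * (1 - prevalence)^volume_k *
#' lognormal noise`), which also drives the simulated FISH cell
#' populations.
#'
#' @param n_patients Number of patients.
#' @param clones_per_tumor Integer range `c(min, max)` of clones per tumor
#'   (one is always clonal at CCF 1).
#' @param purity_range Tumor purity range, fractions in (0, 1].
#' @param mean_depth Mean sequencing depth (Poisson) per variant.
#' @param n_snvs_per_patient True somatic SNVs per patient.
#' @param n_genes Genes in the simulated gene model and count matrix.
#' @param planted_gene_id Identifier of the planted sensitivity gene; must
#'   index a simulated gene (ids are `G0001 ... G<n_genes>`).
#' @param deep_del_prevalence_range Range of pre-treatment deep-deletion
#'   prevalence across patients.
#' @param ffpe_artifact_rate Expected FFPE deamination artifacts per true
#'   SNV (injected as new low-VAF C>T/G>A calls).
#' @param de_logfc Planted log2 fold change of the sensitivity gene,
#'   post- vs pre-treatment.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_best_responders Patients (lowest residual volume) that carry
#'   the planted subclonal loss pre-treatment.
#' @param noise_loss_rate Expected number of random subclonal losses per
#'   sample (background candidate noise).
#' @param v_max,volume_k,volume_sdlog Residual-volume model: maximum
#'   volume (cc), prevalence exponent, and lognormal noise sd.
#' @param n_fish_cells Cells scored per FISH sample.
#' @param single_loss_frac Fraction of non-deleted cells carrying a single
#'   copy of the target in FISH simulations.
#' @param fish_qc_fail_rate Fraction of cells without a centromere signal.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 12,
                       clones_per_tumor = c(2, 3),
                       purity_range = c(0.3, 0.9),
                       mean_depth = 80,
                       n_snvs_per_patient = 100,
                       n_genes = 2000,
                       planted_gene_id = "G0042",
                       deep_del_prevalence_range = c(0.02, 0.30),
                       ffpe_artifact_rate = 0.2,
                       de_logfc = 2,
                       dispersion = 0.1,
                       seed = 1L,
                       n_best_responders = 3,
                       noise_loss_rate = 3,
                       v_max = 10,
                       volume_k = 6,
                       volume_sdlog = 0.4,
                       n_fish_cells = 500,
                       single_loss_frac = 0.2,
                       fish_qc_fail_rate = 0.02) {
  cfg <- as.list(environment())
  check_range <- function(x, name) {
    if (length(x) != 2 || x[1] > x[2]) {
      stop("degenerate range for ", name, " (need min <= max)", call. = FALSE)
    }
  }
  check_range(clones_per_tumor, "clones_per_tumor")
  check_range(purity_range, "purity_range")
  check_range(deep_del_prevalence_range, "deep_del_prevalence_range")
  stopifnot(n_patients >= 0, mean_depth > 0,
            purity_range[1] > 0, purity_range[2] <= 1,
            all(deep_del_prevalence_range >= 0),
            all(deep_del_prevalence_range <= 1),
            ffpe_artifact_rate >= 0, dispersion > 0, n_genes >= 1)
  if (n_patients > 0 &&
      !planted_gene_id %in% sprintf("G%04d", seq_len(n_genes))) {
    stop("planted_gene_id must index a simulated gene (G0001..G",
         sprintf("%04d", n_genes), ")", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

GENE_WIDTH <- 1e4
GENE_GAP <- 9e4
GENES_PER_CHROM <- 250

sim_gene_model <- function(n_genes) {
  i <- seq_len(n_genes) - 1
  chrom_idx <- i %/% GENES_PER_CHROM + 1
  slot <- i %% GENES_PER_CHROM
  tibble::tibble(
    gene = sprintf("G%04d", i + 1),
    chrom = paste0("chr", chrom_idx),
    start = slot * (GENE_WIDTH + GENE_GAP),
    end = slot * (GENE_WIDTH + GENE_GAP) + GENE_WIDTH)
}

chrom_lengths <- function(gene_model) {
  dplyr::summarise(dplyr::group_by(gene_model, .data$chrom),
                   len = max(.data$end) + GENE_GAP, .groups = "drop")
}

#' Simulate a synthetic longitudinal neoadjuvant cohort
#'
#' Generates, per patient, a pre-treatment biopsy (fresh-frozen and FFPE
#' aliquots) and a post-treatment sample with: clonal/subclonal SNVs whose
#' VAFs follow the purity/copy-number/CCF forward model; allele-specific
#' copy-number segments including planted and background subclonal losses;
#' FFPE-only low-VAF C>T/G>A artifacts; negative-binomial expression
#' counts with the planted gene overexpressed post-treatment;
#' splice-junction read counts in the sub-percent variant regime; per-cell
#' FISH signal counts whose deep-deletion prevalence drives residual tumor
#' volume; and a clinical sample sheet.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all tables are written
#'   to disk (VCF per sample, `segments.tsv`, `counts.tsv`,
#'   `junctions.tsv`, `fish.tsv`, `samples.csv`, `genes.bed`,
#'   `ground_truth.json`).
#' @return A list of class `sim_cohort` with tibbles `variants`,
#'   `segments`, `samples`, `gene_model`, `junctions`, `fish`, a counts
#'   matrix `counts`, and `truth` (clone CCFs pre/post, planted-loss
#'   status, DE status, deep-deletion prevalences, residual volumes).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- withr::with_seed(config$seed, simulate_cohort_impl(config))
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

simulate_cohort_impl <- function(cfg) {
  gene_model <- sim_gene_model(cfg$n_genes)
  empty <- list(
    variants = tibble::tibble(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              ref_count = integer(), alt_count = integer(),
                              sample = character(), depth = integer(),
                              vaf = double(), artifact = logical()),
    segments = tibble::tibble(sample = character(), chrom = character(),
                              start = double(), end = double(),
                              major_cn = integer(), minor_cn = integer(),
                              cn_fraction = double()),
    samples = tibble::tibble(patient = character(), sample = character(),
                             timepoint = character(),
                             preservation = character(), purity = double(),
                             ploidy = double(), purity_clear = logical(),
                             residual_volume_cc = double(),
                             response = character()),
    counts = matrix(0, 0, 0), gene_model = gene_model,
    junctions = tibble::tibble(junction_id = character(),
                               sample = character(), reads = integer()),
    fish = tibble::tibble(sample = character(), cell_id = character(),
                          target_signals = integer(),
                          centromere_signals = integer()),
    truth = list(clone_ccfs = tibble::tibble(), planted_loss = tibble::tibble(),
                 de_status = tibble::tibble(), prevalence = tibble::tibble(),
                 volumes = tibble::tibble(), planted_gene = cfg$planted_gene_id),
    config = cfg)
  class(empty) <- "sim_cohort"
  if (cfg$n_patients == 0) return(empty)

  pts <- sprintf("P%02d", seq_len(cfg$n_patients))

  # patient-level truth: prevalence -> volume (monotone decreasing + noise)
  prev <- stats::runif(cfg$n_patients, cfg$deep_del_prevalence_range[1],
                       cfg$deep_del_prevalence_range[2])
  volume <- cfg$v_max * (1 - prev)^cfg$volume_k *
    exp(stats::rnorm(cfg$n_patients, 0, cfg$volume_sdlog))
  best <- order(volume)[seq_len(min(cfg$n_best_responders, cfg$n_patients))]
  planted <- seq_len(cfg$n_patients) %in% best

  any_tumor <- volume > 0.01
  volume[!any_tumor] <- 0
  max_gleason <- ifelse(volume <= 0.2, 6L,
                        6L + stats::rbinom(cfg$n_patients, 3, 0.5))
  involution <- volume < stats::median(volume) | planted
  response <- classify_response(volume, max_gleason, any_tumor, involution)

  purity_bx <- stats::runif(cfg$n_patients, cfg$purity_range[1],
                            cfg$purity_range[2])
  purity_tx <- stats::runif(cfg$n_patients, cfg$purity_range[1],
                            cfg$purity_range[2])

  chroms <- chrom_lengths(gene_model)
  planted_iv <- gene_model[gene_model$gene == cfg$planted_gene_id, ]

  variants <- list(); segments <- list(); samples <- list()
  clone_truth <- list(); fish <- list(); snv_clones <- list()
  for (p in seq_len(cfg$n_patients)) {
    pt <- pts[p]
    s_bx <- paste0(pt, "_BX_FF")
    s_ffpe <- paste0(pt, "_BX_FFPE")
    s_tx <- paste0(pt, "_TX_FF")

    clone_choices <- seq(cfg$clones_per_tumor[1], cfg$clones_per_tumor[2])
    n_clones <- clone_choices[sample.int(length(clone_choices), 1)]
    ccf_pre <- c(1, sort(stats::runif(n_clones - 1, 0.15, 0.7),
                         decreasing = TRUE))
    ccf_post <- pmin(pmax(ccf_pre + stats::rnorm(n_clones, 0, 0.02), 0), 1)
    ccf_post[1] <- 1
    sensitive_clone <- if (planted[p] && n_clones >= 2) n_clones else NA
    if (!is.na(sensitive_clone)) ccf_post[sensitive_clone] <- 0
    clone_truth[[p]] <- tibble::tibble(patient = pt,
                                       clone = seq_len(n_clones),
                                       ccf_pre = ccf_pre, ccf_post = ccf_post)

    # SNVs: uniform positions away from the planted locus, CNt = 2, m = 1
    n_snv <- cfg$n_snvs_per_patient
    ci <- sample.int(nrow(chroms), n_snv, replace = TRUE)
    pos <- floor(stats::runif(n_snv, 1, chroms$len[ci])) + 1L
    on_planted <- chroms$chrom[ci] == planted_iv$chrom &
      pos > planted_iv$start & pos <= planted_iv$end
    pos[on_planted] <- pos[on_planted] + GENE_WIDTH + 1L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    clone_of <- sample.int(n_clones, n_snv, replace = TRUE,
                           prob = c(2, rep(1, n_clones - 1)))
    snv_clones[[p]] <- tibble::tibble(patient = pt, chrom = chroms$chrom[ci],
                                      pos = pos, clone = clone_of)

    draw_sample <- function(sample_id, purity, ccfs) {
      vaf <- purity * 1 * ccfs[clone_of] / (purity * 2 + 2 * (1 - purity))
      depth <- stats::rpois(n_snv, cfg$mean_depth)
      altc <- stats::rbinom(n_snv, depth, vaf)
      keep <- altc > 0
      tibble::tibble(chrom = chroms$chrom[ci], pos = pos, ref = ref,
                     alt = alt, ref_count = depth - altc, alt_count = altc,
                     sample = sample_id, artifact = FALSE)[keep, ]
    }
    v_bx <- draw_sample(s_bx, purity_bx[p], ccf_pre)
    v_ffpe <- draw_sample(s_ffpe, purity_bx[p], ccf_pre)
    v_tx <- draw_sample(s_tx, purity_tx[p], ccf_post)

    # FFPE deamination artifacts: new low-VAF C>T / G>A calls
    n_art <- stats::rpois(1, cfg$ffpe_artifact_rate * n_snv)
    if (n_art > 0) {
      aci <- sample.int(nrow(chroms), n_art, replace = TRUE)
      is_ct <- stats::runif(n_art) < 0.5
      avaf <- stats::runif(n_art, 0.01, 0.10)
      adepth <- stats::rpois(n_art, cfg$mean_depth)
      aalt <- stats::rbinom(n_art, adepth, avaf)
      art <- tibble::tibble(
        chrom = chroms$chrom[aci],
        pos = floor(stats::runif(n_art, 1, chroms$len[aci])) + 1L,
        ref = ifelse(is_ct, "C", "G"), alt = ifelse(is_ct, "T", "A"),
        ref_count = adepth - aalt, alt_count = aalt, sample = s_ffpe,
        artifact = TRUE)[aalt > 0, ]
      v_ffpe <- dplyr::bind_rows(v_ffpe, art)
    }
    variants[[p]] <- dplyr::bind_rows(v_bx, v_ffpe, v_tx)

    # segments: neutral background broken by subclonal losses
    losses_bx <- sim_noise_losses(cfg, gene_model)
    if (planted[p]) {
      losses_bx <- dplyr::bind_rows(
        losses_bx,
        tibble::tibble(chrom = planted_iv$chrom, start = planted_iv$start,
                       end = planted_iv$end,
                       cn_fraction = stats::runif(1, 0.3, 0.6)))
    }
    losses_tx <- sim_noise_losses(cfg, gene_model)
    segments[[p]] <- dplyr::bind_rows(
      build_segments(s_bx, chroms, losses_bx),
      build_segments(s_ffpe, chroms, losses_bx),
      build_segments(s_tx, chroms, losses_tx))

    # FISH: deep-deletion prevalence pre; depleted post in responders
    prev_post <- prev[p] * pmin(volume[p] / cfg$v_max, 1)
    fish[[p]] <- dplyr::bind_rows(
      sim_fish_sample(s_bx, prev[p], cfg),
      sim_fish_sample(s_tx, prev_post, cfg))

    samples[[p]] <- tibble::tibble(
      patient = pt,
      sample = c(s_bx, s_ffpe, s_tx),
      timepoint = c("BX", "BX", "TX"),
      preservation = c("FF", "FFPE", "FF"),
      purity = c(purity_bx[p], purity_bx[p], purity_tx[p]),
      ploidy = 2,
      purity_clear = TRUE,
      residual_volume_cc = volume[p],
      response = response[p])
  }

  samples <- dplyr::bind_rows(samples)
  ff_samples <- samples$sample[samples$preservation == "FF"]
  expr <- sim_expression_matrix(cfg, ff_samples,
                                grepl("_TX_", ff_samples))
  junctions <- sim_junctions(ff_samples)

  out <- list(
    variants = add_vaf(dplyr::bind_rows(variants)),
    segments = dplyr::bind_rows(segments),
    samples = samples,
    counts = expr$counts,
    gene_model = gene_model,
    junctions = junctions,
    fish = dplyr::bind_rows(fish),
    truth = list(
      clone_ccfs = dplyr::bind_rows(clone_truth),
      snv_clones = dplyr::bind_rows(snv_clones),
      planted_loss = tibble::tibble(patient = pts, planted = planted),
      de_status = expr$de_status,
      prevalence = tibble::tibble(patient = pts, prevalence_pre = prev),
      volumes = tibble::tibble(patient = pts, residual_volume_cc = volume,
                               response = response),
      planted_gene = cfg$planted_gene_id),
    config = cfg)
  class(out) <- "sim_cohort"
  out
}

# random subclonal single-copy losses over random genes; the planted locus
# is reserved so background noise cannot contradict the declared ground truth
sim_noise_losses <- function(cfg, gene_model) {
  gene_model <- gene_model[gene_model$gene != cfg$planted_gene_id, ]
  n <- stats::rpois(1, cfg$noise_loss_rate)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), cn_fraction = double()))
  }
  g <- gene_model[sample.int(nrow(gene_model), min(n, nrow(gene_model))), ]
  tibble::tibble(chrom = g$chrom, start = g$start, end = g$end,
                 cn_fraction = stats::runif(nrow(g), 0.15, 0.85))
}

# split each chromosome's neutral 1+1 background around loss intervals
build_segments <- function(sample_id, chroms, losses) {
  purrr::pmap_dfr(chroms, function(chrom, len) {
    l <- losses[losses$chrom == chrom, ]
    l <- l[order(l$start), ]
    l <- l[!duplicated(l$start), ]
    bounds <- c(0, rbind(l$start, l$end), len)
    segs <- tibble::tibble(start = bounds[-length(bounds)],
                           end = bounds[-1])
    segs <- segs[segs$start < segs$end, ]
    is_loss <- segs$start %in% l$start & segs$end %in% l$end
    tibble::tibble(sample = sample_id, chrom = chrom,
                   start = segs$start, end = segs$end,
                   major_cn = 1L, minor_cn = ifelse(is_loss, 0L, 1L),
                   cn_fraction = ifelse(is_loss,
                                        l$cn_fraction[match(segs$start,
                                                            l$start)], 1))
  })
}

sim_fish_sample <- function(sample_id, prev_deep, cfg) {
  n <- cfg$n_fish_cells
  u <- stats::runif(n)
  state <- ifelse(u < prev_deep, "deep",
                  ifelse(u < prev_deep + cfg$single_loss_frac *
                           (1 - prev_deep), "single", "two_plus"))
  target <- ifelse(state == "deep", 0L,
                   ifelse(state == "single", 1L,
                          2L + stats::rbinom(n, 1, 0.1)))
  centromere <- 1L + stats::rbinom(n, 2, 0.5)
  qc_fail <- stats::runif(n) < cfg$fish_qc_fail_rate
  centromere[qc_fail] <- 0L
  tibble::tibble(sample = sample_id,
                 cell_id = sprintf("%s_c%04d", sample_id, seq_len(n)),
                 target_signals = target,
                 centromere_signals = centromere)
}

sim_expression_matrix <- function(cfg, sample_ids, is_post) {
  base_mu <- stats::rlnorm(cfg$n_genes, log(100), 1)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  lib <- stats::runif(length(sample_ids), 0.8, 1.2)
  planted_idx <- match(cfg$planted_gene_id, genes)
  fc <- rep(1, cfg$n_genes)
  mu <- outer(base_mu, lib)
  mu[planted_idx, is_post] <- mu[planted_idx, is_post] * 2^cfg$de_logfc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, sample_ids))
  de_status <- tibble::tibble(gene = genes,
                              is_de = seq_len(cfg$n_genes) == planted_idx,
                              true_logfc = ifelse(
                                seq_len(cfg$n_genes) == planted_idx,
                                cfg$de_logfc, 0))
  list(counts = counts, de_status = de_status)
}

sim_junctions <- function(sample_ids) {
  purrr::map_dfr(sample_ids, function(s) {
    canonical <- stats::rpois(1, 200)
    variant <- stats::rpois(1, canonical * stats::runif(1, 0.001, 0.008))
    tibble::tibble(junction_id = c("AR_FL_e3e4", "AR_V7_e3ce3"),
                   sample = s,
                   reads = as.integer(c(canonical, variant)))
  })
}

#' Negative-binomial two-group expression simulator
#'
#' Small stand-alone generator for differential-expression calibration
#' studies: `n_de` genes get a planted log2 fold change in group 2, the
#' rest are null; gene-wise baseline means are log-normal.
#'
#' @param n_genes Number of genes.
#' @param n1,n2 Samples per group.
#' @param n_de Number of differentially expressed genes.
#' @param logfc Planted log2 fold change.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @return List with `counts` (genes x samples), `groups` (factor,
#'   levels `g1`, `g2`), `is_de` (logical per gene).
#' @export
simulate_expression <- function(n_genes = 1000, n1 = 6, n2 = 7, n_de = 50,
                                logfc = 2, dispersion = 0.1) {
  base_mu <- stats::rlnorm(n_genes, log(100), 1)
  is_de <- seq_len(n_genes) <= n_de
  lib <- stats::runif(n1 + n2, 0.8, 1.2)
  mu <- outer(base_mu, lib)
  mu[is_de, seq(n1 + 1, n1 + n2)] <- mu[is_de, seq(n1 + 1, n1 + n2)] * 2^logfc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                   sprintf("S%02d", seq_len(n1 + n2))))
  list(counts = counts,
       groups = factor(rep(c("g1", "g2"), c(n1, n2))),
       is_de = is_de)
}

#' Classify pathologic response from residual tumor burden
#'
#' Complete response (CR) means no identifiable residual tumor (ypT0).
#' Minimal residual disease (MRD) requires residual tumor volume of at
#' most 0.2 cc with no high-grade elements (Gleason score at most 3+3,
#' i.e. 6). Larger residual tumors are partial response (PR) when there
#' is histologic evidence of tumor involution and no response (NR)
#' otherwise.
#'
#' @param residual_volume_cc Residual tumor volume in cc (non-negative).
#' @param max_gleason Highest Gleason score present (sum; 6 = 3+3).
#' @param any_tumor Logical, identifiable residual tumor present.
#' @param involution Logical, histologic evidence of tumor involution.
#' @return Character vector in `c("CR", "MRD", "PR", "NR")`.
#' @export
#' @examples
#' classify_response(0, NA, any_tumor = FALSE, involution = FALSE)
#' classify_response(0.15, 6, any_tumor = TRUE, involution = TRUE)
classify_response <- function(residual_volume_cc, max_gleason, any_tumor,
                              involution) {
  if (any(residual_volume_cc < 0, na.rm = TRUE)) {
    stop("residual volume must be >= 0", call. = FALSE)
  }
  dplyr::case_when(
    !any_tumor ~ "CR",
    residual_volume_cc <= 0.2 & max_gleason <= 6 ~ "MRD",
    involution ~ "PR",
    TRUE ~ "NR")
}

#' Write a simulated cohort to disk
#'
#' Writes one VCF v4.2 per sample (FORMAT fields `AD` and `DP`) plus
#' `segments.tsv`, `counts.tsv`, `junctions.tsv`, `fish.tsv`,
#' `samples.csv`, `genes.bed` and `ground_truth.json`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("output directory not writable: ", dir, call. = FALSE)
  }
  for (s in unique(cohort$samples$sample)) {
    write_vcf(cohort$variants[cohort$variants$sample == s, ], s,
              file.path(dir, paste0(s, ".vcf")))
  }
  readr::write_tsv(cohort$segments[, c("sample", "chrom", "start", "end",
                                       "major_cn", "minor_cn",
                                       "cn_fraction")],
                   file.path(dir, "segments.tsv"))
  counts_df <- tibble::as_tibble(cohort$counts, rownames = "gene")
  readr::write_tsv(counts_df, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(cohort$fish, file.path(dir, "fish.tsv"))
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"))
  readr::write_tsv(cohort$gene_model[, c("chrom", "start", "end", "gene")],
                   file.path(dir, "genes.bed"), col_names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_vcf <- function(variants, sample_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neoclone-simulator",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  v <- variants[order(variants$chrom, variants$pos), ]
  body <- if (nrow(v) == 0) character(0) else {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d",
            v$chrom, v$pos, v$ref, v$alt, v$ref_count, v$alt_count,
            v$ref_count + v$alt_count)
  }
  writeLines(c(header, body), path)
}
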