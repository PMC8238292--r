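#' Classify per-cell FISH copy states
#'
#' Cells without a centromere (control-probe) signal fail hybridization
#' QC. Among passing cells, zero target signals is a deep deletion, one is
#' a single-copy loss, and two or more is the retained (`two_plus`) state.
#'
#' @param cells Tibble with `sample`, `cell_id`, `target_signals`,
#'   `centromere_signals`.
#' @return `cells` with a `state` column in
#'   `c("deep_deletion", "single_loss", "two_plus", "qc_fail")`.
#' @export
classify_cells <- function(cells) {
  stopifnot(all(cells$target_signals >= 0),
            all(cells$centromere_signals >= 0))
  dplyr::mutate(cells, state = dplyr::case_when(
    .data$centromere_signals == 0 ~ "qc_fail",
    .data$target_signals == 0 ~ "deep_deletion",
    .data$target_signals == 1 ~ "single_loss",
    TRUE ~ "two_plus"))
}

#' Per-sample prevalence of FISH copy states
#'
#' Fractions of QC-passing cells in each copy state with Wilson binomial
#' confidence intervals. Samples with fewer passing cells than
#' `min_cells` are flagged low-confidence rather than dropped.
#'
#' @param cells Tibble of scored cells (see [classify_cells()]).
#' @param min_cells Minimum passing cells for a confident estimate.
#' @param conf_level Confidence level of the Wilson intervals.
#' @return Tibble, one row per sample: `n_cells_pass`,
#'   `frac_deep_deletion`, `frac_single_loss`, `frac_two_plus`, the
#'   corresponding `*_low`/`*_high` interval bounds, and `low_confidence`.
#' @export
fish_prevalence <- function(cells, min_cells = 50, conf_level = 0.95) {
  cl <- classify_cells(cells)
  pass <- dplyr::filter(cl, .data$state != "qc_fail")
  out <- pass |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_cells_pass = dplyr::n(),
      n_deep = sum(.data$state == "deep_deletion"),
      n_single = sum(.data$state == "single_loss"),
      n_two = sum(.data$state == "two_plus"),
      .groups = "drop")
  add_state <- function(df, n_col, prefix) {
    ci <- wilson_ci(df[[n_col]], df$n_cells_pass, conf_level)
    df[[paste0("frac_", prefix)]] <- df[[n_col]] / df$n_cells_pass
    df[[paste0("frac_", prefix, "_low")]] <- ci$lower
    df[[paste0("frac_", prefix, "_high")]] <- ci$upper
    df
  }
  out <- add_state(out, "n_deep", "deep_deletion")
  out <- add_state(out, "n_single", "single_loss")
  out <- add_state(out, "n_two", "two_plus")
  out$low_confidence <- out$n_cells_pass < min_cells
  dplyr::select(out, -"n_deep", -"n_single", -"n_two")
}

#' Spearman correlation of pre-treatment prevalence with residual volume
#'
#' Rank correlation of each copy-state prevalence in pre-treatment
#' samples against the patient's residual tumor volume. With the planted
#' biology (deep-deletion-rich tumors respond), deep-deletion prevalence
#' correlates negatively with volume. The p-value is an exact permutation
#' p for small n (full enumeration for n <= 8; the exact null
#' distribution from [stats::cor.test()] for n <= 10 without ties) and
#' asymptotic otherwise. A constant prevalence vector gives an undefined
#' correlation, flagged via `defined = FALSE`.
#'
#' @param prevalence Tibble from [fish_prevalence()] restricted to
#'   pre-treatment samples.
#' @param samples Sample sheet with `sample`, `patient`,
#'   `residual_volume_cc`.
#' @param states Prevalence columns to correlate.
#' @return Tibble with `state`, `n`, `rho`, `p`, `defined`.
#' @export
response_correlation <- function(prevalence, samples,
                                 states = c("frac_deep_deletion",
                                            "frac_two_plus")) {
  merged <- dplyr::inner_join(
    prevalence,
    dplyr::distinct(samples[, c("sample", "patient", "residual_volume_cc")]),
    by = "sample")
  if (nrow(merged) < 4) {
    stop("need >= 4 patients with prevalence and volume", call. = FALSE)
  }
  purrr::map_dfr(states, function(st) {
    x <- merged[[st]]
    y <- merged$residual_volume_cc
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(state = st, n = length(x), rho = NA_real_,
                            p = NA_real_, defined = FALSE))
    }
    res <- spearman_test(x, y)
    tibble::tibble(state = st, n = length(x), rho = res$rho, p = res$p,
                   defined = TRUE)
  })
}

# two-sided Spearman test; exact permutation p at small n
spearman_test <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    perms <- permutations_of(n)
    rx <- rank(x)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    p <- stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  }
  list(rho = rho, p = p)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Pre- vs post-treatment change in FISH copy-state prevalence
#'
#' Per-state prevalence difference (post minus pre) with a Wald
#' two-proportion confidence interval.
#'
#' @param pre,post Single rows of [fish_prevalence()] output for the same
#'   patient's pre- and post-treatment samples.
#' @param conf_level Confidence level.
#' @return Tibble with `state`, `pre`, `post`, `delta`, `delta_low`,
#'   `delta_high`.
#' @export
pre_post_change <- function(pre, post, conf_level = 0.95) {
  if (is.null(pre) || is.null(post) || nrow(pre) != 1 || nrow(post) != 1) {
    stop("need exactly one pre and one post prevalence summary",
         call. = FALSE)
  }
  if (isTRUE(pre$low_confidence) || isTRUE(post$low_confidence)) {
    stop("prevalence summary failed the minimum-cell QC", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  states <- c("deep_deletion", "single_loss", "two_plus")
  purrr::map_dfr(states, function(st) {
    p1 <- pre[[paste0("frac_", st)]]
    p2 <- post[[paste0("frac_", st)]]
    se <- sqrt(p1 * (1 - p1) / pre$n_cells_pass +
                 p2 * (1 - p2) / post$n_cells_pass)
    tibble::tibble(state = st, pre = p1, post = p2, delta = p2 - p1,
                   delta_low = p2 - p1 - z * se,
                   delta_high = p2 - p1 + z * se)
  })
}

#' Scatter of deep-deletion prevalence against residual tumor volume
#'
#' @param prevalence Pre-treatment prevalence tibble.
#' @param samples Sample sheet with `sample` and `residual_volume_cc`.
#' @param state Prevalence column to plot.
#' @return A ggplot.
#' @export
plot_response_correlation <- function(prevalence, samples,
                                      state = "frac_deep_deletion") {
  merged <- dplyr::inner_join(
    prevalence,
    dplyr::distinct(samples[, c("sample", "residual_volume_cc")]),
    by = "sample")
  ggplot2::ggplot(merged,
                  ggplot2::aes(.data[[state]],
                               .data$residual_volume_cc)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey50", linetype = 2) +
    ggplot2::labs(x = "Pre-treatment prevalence",
                  y = "Residual tumor volume (cc)") +
    ggplot2::theme_bw()
}
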