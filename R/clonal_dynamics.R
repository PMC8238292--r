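#' Cluster variant CCFs into clonal populations
#'
#' Fits finite binomial mixtures to alt-read counts, with each component's
#' success probability tied to a cluster cancer-cell fraction through the
#' forward map used by [estimate_ccfs()]:
#' \eqn{p_{ik} = \phi_k \rho m_i / (\rho C_{t,i} + 2(1-\rho))}. The number
#' of components is selected by BIC over `1..k_max`. Initialization is a
#' deterministic k-means++-style seeding on the per-variant CCF point
#' estimates under the given seed, so results are reproducible.
#'
#' @param ccf_tbl Tibble from [estimate_ccfs()] for a single sample:
#'   needs `alt_count`, `depth`, `m`, `total_cn`, `ccf`.
#' @param purity Tumor purity of the sample, in (0, 1].
#' @param k_max Largest number of clusters tried (capped at the number of
#'   usable variants).
#' @param seed Integer seed controlling initialization.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `ccf_clusters`: list with `clusters` (tibble
#'   of `cluster`, `mean_ccf`, `weight`, `n_variants`), `assignments`
#'   (hard assignment per variant), `k`, `loglik` (final), `loglik_trace`,
#'   and `bic` (tibble over candidate K).
#' @export
cluster_ccfs <- function(ccf_tbl, purity, k_max = 6, seed = 1L,
                         max_iter = 200, tol = 1e-8) {
  use <- !is.na(ccf_tbl$ccf) & ccf_tbl$depth > 0
  d <- ccf_tbl[use, ]
  n <- nrow(d)
  if (n < 5) stop("need >= 5 CCF estimates to cluster (got ", n, ")",
                  call. = FALSE)
  stopifnot(purity > 0, purity <= 1)
  a <- purity * d$m / (purity * d$total_cn + 2 * (1 - purity))
  k_max <- min(k_max, n)

  fits <- withr::with_seed(seed, {
    lapply(seq_len(k_max), function(k) {
      fit_binom_mixture(d$alt_count, d$depth, a, d$ccf, k, max_iter, tol)
    })
  })
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  best <- which.min(bic)
  fit <- fits[[best]]

  ord <- order(-fit$phi)
  relabel <- match(seq_along(ord), ord)
  assignments <- rep(NA_integer_, nrow(ccf_tbl))
  assignments[use] <- relabel[fit$assign]
  clusters <- tibble::tibble(
    cluster = seq_along(ord),
    mean_ccf = fit$phi[ord],
    weight = fit$w[ord],
    n_variants = as.integer(tabulate(relabel[fit$assign], length(ord))))
  out <- list(clusters = clusters, assignments = assignments,
              k = best, loglik = fit$loglik,
              loglik_trace = fit$trace,
              bic = tibble::tibble(k = seq_len(k_max), bic = bic))
  class(out) <- "ccf_clusters"
  out
}

# EM for a K-component binomial mixture with p_i = a_i * phi_k.
# The log-likelihood is checked to be non-decreasing each iteration.
fit_binom_mixture <- function(alt, depth, a, ccf_point, k,
                              max_iter = 200, tol = 1e-8) {
  n <- length(alt)
  phi <- kmeanspp_centers(ccf_point, k)
  w <- rep(1 / k, k)
  clamp_p <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  lc <- lchoose(depth, alt) # constant part of the binomial log-density
  binom_ll <- function(p) lc + alt * log(p) + (depth - alt) * log1p(-p)
  comp_loglik <- function(phi) {
    # n x k matrix of log w_k + log Binom(alt | depth, a * phi_k)
    vapply(seq_len(k), function(j) {
      binom_ll(clamp_p(a * phi[j])) + log(w[j])
    }, numeric(n))
  }
  phi_max <- min(1.5, 0.999 / max(a))
  # weighted binomial log-likelihood in phi (concave); Newton with an
  # optimize() fallback keeps the M-step an exact maximization
  wll <- function(r, ph) sum(r * binom_ll(clamp_p(a * ph)))
  mstep_phi <- function(r, ph) {
    ph <- min(max(ph, 1e-6), phi_max)
    for (step in 1:50) {
      ap <- pmin(a * ph, 1 - 1e-12)
      g <- sum(r * (alt / ph - (depth - alt) * a / (1 - ap)))
      h <- -sum(r * (alt / ph^2 + (depth - alt) * a^2 / (1 - ap)^2))
      if (!is.finite(g) || !is.finite(h) || h >= 0) break
      ph_new <- min(max(ph - g / h, 1e-6), phi_max)
      if (abs(ph_new - ph) < 1e-9) {
        ph <- ph_new
        break
      }
      ph <- ph_new
    }
    ph
  }
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lm <- matrix(comp_loglik(phi), nrow = n)
    mx <- do.call(pmax, as.data.frame(lm))
    lse <- mx + log(rowSums(exp(lm - mx)))
    ll <- sum(lse)
    if (ll < ll_old - 1e-6) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    trace <- c(trace, ll)
    resp <- exp(lm - lse)
    w <- colMeans(resp)
    phi <- vapply(seq_len(k), function(j) {
      r <- resp[, j]
      if (sum(r) < 1e-12) return(phi[j])
      cand <- mstep_phi(r, phi[j])
      if (wll(r, cand) + 1e-9 < wll(r, phi[j])) {
        cand <- stats::optimize(function(ph) wll(r, ph),
                                interval = c(0, phi_max), maximum = TRUE,
                                tol = 1e-7)$maximum
      }
      cand
    }, numeric(1))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  lm <- matrix(comp_loglik(phi), nrow = n)
  assign <- max.col(lm, ties.method = "first")
  n_par <- 2 * k - 1 # k CCFs + k-1 free weights
  list(phi = phi, w = w, assign = assign, loglik = trace[length(trace)],
       trace = trace, bic = -2 * trace[length(trace)] + n_par * log(n))
}

# deterministic-given-RNG-state k-means++ seeding on 1-D points
kmeanspp_centers <- function(x, k) {
  centers <- x[sample.int(length(x), 1)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(xi) min((xi - centers)^2), numeric(1))
    if (all(d2 == 0)) {
      centers <- c(centers, rep(centers[1], k - length(centers)))
      break
    }
    centers <- c(centers, x[sample.int(length(x), 1, prob = d2)])
  }
  centers
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat(sprintf("CCF clustering: K = %d (BIC-selected), loglik = %.2f\n",
              x$k, x$loglik))
  print(x$clusters)
  invisible(x)
}

#' Match clonal clusters across timepoints and call direction of change
#'
#' Greedy nearest-CCF one-to-one matching between pre- and post-treatment
#' clusters (ties broken in favor of larger clusters). Matched pairs with
#' `|delta_ccf| <= delta` are `stable`, otherwise `growing`/`shrinking` by
#' sign of the post-minus-pre difference; unmatched pre-treatment clusters
#' are `extinct`, unmatched post-treatment clusters `emerging`.
#'
#' @param pre,post `ccf_clusters` objects or tibbles with `cluster`,
#'   `mean_ccf`, `n_variants`.
#' @param delta Absolute CCF change below which a matched clone is stable.
#' @return Tibble of clonal changes: `pre_cluster`, `post_cluster`,
#'   `pre_ccf`, `post_ccf`, `delta_ccf`, `direction`.
#' @export
match_longitudinal <- function(pre, post, delta = 0.1) {
  as_tbl <- function(x) if (inherits(x, "ccf_clusters")) x$clusters else x
  pre <- as_tbl(pre); post <- as_tbl(post)
  np <- nrow(pre); nq <- nrow(post)
  links <- tibble::tibble(pre_cluster = integer(), post_cluster = integer())
  if (np > 0 && nq > 0) {
    cand <- tidyr::expand_grid(i = seq_len(np), j = seq_len(nq))
    cand$dist <- abs(pre$mean_ccf[cand$i] - post$mean_ccf[cand$j])
    cand$size <- pre$n_variants[cand$i] + post$n_variants[cand$j]
    cand <- cand[order(cand$dist, -cand$size), ]
    used_i <- logical(np); used_j <- logical(nq)
    for (row in seq_len(nrow(cand))) {
      i <- cand$i[row]; j <- cand$j[row]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      links <- dplyr::bind_rows(links,
                                tibble::tibble(pre_cluster = i,
                                               post_cluster = j))
    }
  }
  matched <- dplyr::mutate(links,
    pre_ccf = pre$mean_ccf[.data$pre_cluster],
    post_ccf = post$mean_ccf[.data$post_cluster],
    delta_ccf = .data$post_ccf - .data$pre_ccf,
    direction = dplyr::case_when(
      abs(.data$delta_ccf) <= delta ~ "stable",
      .data$delta_ccf > 0 ~ "growing",
      TRUE ~ "shrinking"))
  extinct <- setdiff(seq_len(np), matched$pre_cluster)
  emerging <- setdiff(seq_len(nq), matched$post_cluster)
  dplyr::bind_rows(
    matched,
    tibble::tibble(pre_cluster = extinct, post_cluster = NA_integer_,
                   pre_ccf = pre$mean_ccf[extinct], post_ccf = NA_real_,
                   delta_ccf = -pre$mean_ccf[extinct], direction = "extinct"),
    tibble::tibble(pre_cluster = NA_integer_, post_cluster = emerging,
                   pre_ccf = NA_real_, post_ccf = post$mean_ccf[emerging],
                   delta_ccf = post$mean_ccf[emerging], direction = "emerging"))
}

#' Compare copy-number fractions of matched segments across timepoints
#'
#' Orthogonal (SNV-free) view of clonal change: segments from a
#' pre-treatment and a post-treatment sample are matched by reciprocal
#' genomic overlap and their copy-number fractions paired. The shift
#' statistic is the fraction of matched pre-treatment *loss* segments
#' whose copy-number fraction moved by more than `shift_delta`.
#'
#' @param pre_segments,post_segments Segment tibbles for one sample each.
#' @param min_reciprocal_overlap Minimum overlap fraction required of both
#'   segments.
#' @param shift_delta Absolute copy-number-fraction change defining a
#'   shifted segment.
#' @param ploidy Sample ploidy used in the loss definition for
#'   pre-treatment segments.
#' @return Object of class `segment_comparison`: list with `pairs`
#'   (tibble: coordinates, `cn_fraction_pre`, `cn_fraction_post`,
#'   `is_loss_pre`), `shift_stat` (`NA` when no loss segments match) and
#'   `n_pairs`.
#' @export
compare_segment_pairs <- function(pre_segments, post_segments,
                                  min_reciprocal_overlap = 0.5,
                                  shift_delta = 0.25, ploidy = 2) {
  if (nrow(pre_segments) == 0 || nrow(post_segments) == 0) {
    stop("both samples must have segments", call. = FALSE)
  }
  gr <- function(s) GenomicRanges::GRanges(
    s$chrom, IRanges::IRanges(s$start + 1, s$end))
  g1 <- gr(pre_segments); g2 <- gr(post_segments)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  empty <- function() {
    out <- list(pairs = tibble::tibble(chrom = character(),
                                       cn_fraction_pre = double(),
                                       cn_fraction_post = double(),
                                       is_loss_pre = logical()),
                shift_stat = NA_real_, n_pairs = 0L)
    class(out) <- "segment_comparison"
    out
  }
  if (length(hits) == 0) return(empty())
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(g1)[qh],
                                           IRanges::ranges(g2)[sh]))
  rec <- pmin(ov / IRanges::width(g1)[qh], ov / IRanges::width(g2)[sh])
  keep <- rec >= min_reciprocal_overlap
  if (!any(keep)) return(empty())
  qh <- qh[keep]; sh <- sh[keep]; rec <- rec[keep]
  # best match per pre segment, one-to-one
  ord <- order(-rec)
  seen_q <- logical(nrow(pre_segments)); seen_s <- logical(nrow(post_segments))
  sel <- ord[vapply(ord, function(i) {
    if (seen_q[qh[i]] || seen_s[sh[i]]) return(FALSE)
    seen_q[qh[i]] <<- TRUE; seen_s[sh[i]] <<- TRUE
    TRUE
  }, logical(1))]
  p1 <- pre_segments[qh[sel], ]; p2 <- post_segments[sh[sel], ]
  pairs <- tibble::tibble(
    chrom = p1$chrom, start = p1$start, end = p1$end,
    cn_fraction_pre = p1$cn_fraction,
    cn_fraction_post = p2$cn_fraction,
    is_loss_pre = (p1$major_cn + p1$minor_cn) < round(ploidy) |
      p1$minor_cn == 0)
  loss <- pairs[pairs$is_loss_pre, ]
  shift <- if (nrow(loss) == 0) NA_real_ else
    mean(abs(loss$cn_fraction_post - loss$cn_fraction_pre) > shift_delta)
  out <- list(pairs = pairs, shift_stat = shift, n_pairs = nrow(pairs))
  class(out) <- "segment_comparison"
  out
}

#' @export
print.segment_comparison <- function(x, ...) {
  cat(sprintf("Segment-pair comparison: %d matched pairs, shift statistic %s\n",
              x$n_pairs,
              ifelse(is.na(x$shift_stat), "undefined",
                     sprintf("%.3f", x$shift_stat))))
  invisible(x)
}

#' Scatter of matched segment copy-number fractions with density contours
#'
#' Reproduces the pre- vs post-treatment copy-number-fraction scatter with
#' a 2D kernel-density overlay; points on the diagonal indicate unchanged
#' clonal composition.
#'
#' @param object A `segment_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot segment_comparison
#' @export
autoplot.segment_comparison <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(.data$cn_fraction_pre,
                                    .data$cn_fraction_post)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Copy-number fraction (pre-treatment)",
                  y = "Copy-number fraction (post-treatment)") +
    ggplot2::theme_bw()
  if (nrow(object$pairs) >= 10 &&
      stats::sd(object$pairs$cn_fraction_pre) > 0 &&
      stats::sd(object$pairs$cn_fraction_post) > 0) {
    p <- p + ggplot2::geom_density_2d(color = "cyan3")
  }
  p
}
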