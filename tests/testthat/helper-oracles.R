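# Independent oracles used across tests. These deliberately use naive
# enumeration / textbook formulas, not the package's code paths.

# rejection probability by enumerating every (stage-1, stage-2) outcome pair
oracle_reject <- function(r1, n1, r, n, p) {
  x1 <- 0:n1
  x2 <- 0:(n - n1)
  pr <- outer(dbinom(x1, n1, p), dbinom(x2, n - n1, p))
  rej <- outer(x1, x2, function(a, b) a > r1 & a + b > r)
  sum(pr[rej])
}

# naive exhaustive design search built on oracle_reject
oracle_search <- function(p0, p1, alpha, beta, n_max) {
  adm <- list()
  for (n in 2:n_max) for (n1 in 1:(n - 1)) for (r1 in 0:(n1 - 1)) {
    for (r in r1:(n - 1)) {
      a <- oracle_reject(r1, n1, r, n, p0)
      if (a > alpha) next
      b <- oracle_reject(r1, n1, r, n, p1)
      if (b < 1 - beta) break # power decreases in r
      en <- n1 + (1 - pbinom(r1, n1, p0)) * (n - n1)
      adm[[length(adm) + 1]] <- c(r1, n1, r, n, en)
    }
  }
  tab <- do.call(rbind, adm)
  colnames(tab) <- c("r1", "n1", "r", "n", "en")
  list(optimal = tab[order(tab[, "en"], tab[, "n"])[1], ],
       minimax = tab[order(tab[, "n"], tab[, "en"])[1], ])
}

# textbook Benjamini-Hochberg: sort, n*p/rank, cumulative min from the top
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(n * p[o] / seq_len(n))))
  pmin(adj, 1)[order(o)]
}

# CCF transform written out directly from its definition
oracle_ccf <- function(vaf, purity, cnt, m) {
  vaf * (purity * cnt + 2 * (1 - purity)) / (purity * m)
}

# binomial-read draws for planted clones, shaped like estimate_ccfs() output
make_ccf_tbl <- function(ccfs_by_variant, depth_mean, purity, cnt = 2, m = 1) {
  n <- length(ccfs_by_variant)
  depth <- rpois(n, depth_mean)
  vaf <- purity * m * ccfs_by_variant / (purity * cnt + 2 * (1 - purity))
  alt <- rbinom(n, depth, vaf)
  tibble::tibble(alt_count = alt, depth = depth, m = as.integer(m),
                 total_cn = as.integer(cnt),
                 ccf = ifelse(depth > 0,
                              oracle_ccf(alt / depth, purity, cnt, m), NA))
}

# small cohort configuration for fast simulator-driven tests
small_config <- function(seed, ...) {
  sim_config(n_patients = 8, n_snvs_per_patient = 60, n_genes = 50,
             planted_gene_id = "G0005", n_fish_cells = 80,
             n_best_responders = 2, seed = seed, ...)
}
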