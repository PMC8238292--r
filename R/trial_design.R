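#' Construct a Simon two-stage design with exact operating characteristics
#'
#' A Simon two-stage phase II design enrolls `n1` patients in stage 1 and
#' stops for futility if at most `r1` responses are seen; otherwise accrual
#' continues to `n` patients in total and the null response rate is rejected
#' when the total number of responses exceeds `r`.
#'
#' @param r1 Maximum stage-1 responses that trigger a futility stop.
#' @param n1 Stage-1 sample size.
#' @param r Maximum total responses that fail to reject the null.
#' @param n Maximum sample size.
#' @param p0 Null (uninteresting) response probability.
#' @param p1 Alternative response probability the trial should detect.
#'
#' @return An object of class `simon_design`: a list with the design
#'   parameters and exact operating characteristics `alpha_actual`
#'   (type I error at `p0`), `power_actual` (rejection probability at `p1`),
#'   `pet0` (probability of early termination under `p0`) and `en0`
#'   (expected sample size under `p0`).
#' @export
#' @examples
#' d <- simon_design(0, 9, 2, 17, p0 = 0.05, p1 = 0.25)
#' d$alpha_actual
simon_design <- function(r1, n1, r, n, p0, p1) {
  validate_design_fields(r1, n1, r, n)
  stopifnot(p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1)
  d <- list(r1 = r1, n1 = n1, r = r, n = n, p0 = p0, p1 = p1)
  class(d) <- "simon_design"
  et <- early_termination(d, p0)
  d$alpha_actual <- reject_probability(d, p0)
  d$power_actual <- reject_probability(d, p1)
  d$pet0 <- et$pet
  d$en0 <- et$en
  d
}

validate_design_fields <- function(r1, n1, r, n) {
  ok <- length(r1) == 1 && length(n1) == 1 && length(r) == 1 && length(n) == 1 &&
    !anyNA(c(r1, n1, r, n)) &&
    r1 >= 0 && r1 <= n1 && n1 < n && r1 <= r && r <= n
  if (!ok) {
    stop("invalid design fields: need 0 <= r1 <= n1 < n and r1 <= r <= n",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact rejection probability of a Simon two-stage design
#'
#' Probability that the trial continues past stage 1 and observes strictly
#' more than `r` total responses, i.e.
#' \deqn{\sum_{x = r_1 + 1}^{n_1} \mathrm{Bin}(x; n_1, p)\,
#'       P(Y > r - x),\quad Y \sim \mathrm{Bin}(n - n_1, p).}
#'
#' @param design A `simon_design`.
#' @param p Response probability, in \[0, 1\] (vectorized).
#' @return Rejection probability (same length as `p`).
#' @export
reject_probability <- function(design, p) {
  validate_design_fields(design$r1, design$n1, design$r, design$n)
  stopifnot(all(p >= 0), all(p <= 1))
  n2 <- design$n - design$n1
  vapply(p, function(pp) {
    x <- seq(design$r1 + 1, design$n1)
    sum(stats::dbinom(x, design$n1, pp) *
          stats::pbinom(design$r - x, n2, pp, lower.tail = FALSE))
  }, numeric(1))
}

#' Early-termination probability and expected sample size
#'
#' @param design A `simon_design`.
#' @param p Response probability.
#' @return A list with `pet`, the probability of stopping after stage 1
#'   (binomial CDF at `r1`), and `en`, the expected sample size
#'   `n1 + (1 - pet) * (n - n1)`.
#' @export
early_termination <- function(design, p) {
  validate_design_fields(design$r1, design$n1, design$r, design$n)
  stopifnot(p >= 0, p <= 1)
  pet <- stats::pbinom(design$r1, design$n1, p)
  list(pet = pet, en = design$n1 + (1 - pet) * (design$n - design$n1))
}

#' Exhaustive search for optimal and minimax Simon two-stage designs
#'
#' Enumerates every design `(r1, n1, r, n)` with `n <= n_max`, keeps those
#' with exact type I error at most `alpha` and exact power at least
#' `1 - beta`, and returns two admissible designs: the *optimal* design
#' minimizing the expected sample size under `p0` (ties broken by smaller
#' `n`) and the *minimax* design minimizing `n` (ties broken by smaller
#' expected sample size under `p0`).
#'
#' @param p0 Null response probability (historical/uninteresting rate).
#' @param p1 Alternative response probability worth detecting; must exceed `p0`.
#' @param alpha One-sided type I error bound.
#' @param beta Type II error bound (power bound is `1 - beta`).
#' @param n_max Largest total sample size searched.
#' @return An object of class `simon_search`: list with elements `optimal`
#'   and `minimax`, each a [simon_design()].
#' @export
#' @examples
#' s <- simon_search(0.05, 0.25, alpha = 0.05, beta = 0.20)
#' s$optimal$n
simon_search <- function(p0, p1, alpha, beta, n_max = 60) {
  if (!(p0 > 0 && p1 < 1 && p1 > p0)) {
    stop("invalid hypothesis pair: need 0 < p0 < p1 < 1", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, n_max >= 2)
  power_min <- 1 - beta

  best <- list() # rows: r1, n1, r, n, alpha, power, en0
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1)) {
      n2 <- n - n1
      x <- 0:n1
      b0 <- stats::dbinom(x, n1, p0)
      b1 <- stats::dbinom(x, n1, p1)
      r_vals <- 0:(n - 1)
      # tail0[i, j] = P(Bin(n2, p0) > r_j - x_i); rejection needs total > r
      tail0 <- outer(x, r_vals, function(xi, rj) {
        stats::pbinom(rj - xi, n2, p0, lower.tail = FALSE)
      })
      tail1 <- outer(x, r_vals, function(xi, rj) {
        stats::pbinom(rj - xi, n2, p1, lower.tail = FALSE)
      })
      # cumulating contributions of x = r1+1 .. n1 from the bottom row up:
      # rej[i, j] = sum over x >= i of b[x] * tail[x, j]  (i indexes r1 = i - 1)
      rev_cumsum <- function(m) apply(m, 2, function(col) rev(cumsum(rev(col))))
      rej0 <- rev_cumsum(b0 * tail0)
      rej1 <- rev_cumsum(b1 * tail1)
      for (r1 in 0:(n1 - 1)) {
        i <- r1 + 2 # contributions start at x = r1 + 1
        if (i > n1 + 1) next
        ok <- which(rej0[i, ] <= alpha & rej1[i, ] >= power_min &
                      r_vals >= r1)
        if (!length(ok)) next
        pet0 <- stats::pbinom(r1, n1, p0)
        en0 <- n1 + (1 - pet0) * n2
        for (j in ok) {
          best[[length(best) + 1L]] <- c(r1, n1, r_vals[j], n,
                                         rej0[i, j], rej1[i, j], en0)
        }
      }
    }
  }
  if (!length(best)) {
    stop("no admissible design with n <= ", n_max, "; increase n_max",
         call. = FALSE)
  }
  tab <- do.call(rbind, best)
  colnames(tab) <- c("r1", "n1", "r", "n", "alpha", "power", "en0")
  ord_opt <- order(tab[, "en0"], tab[, "n"])
  ord_mm <- order(tab[, "n"], tab[, "en0"])
  mk <- function(row) simon_design(unname(row["r1"]), unname(row["n1"]),
                                   unname(row["r"]), unname(row["n"]),
                                   p0 = p0, p1 = p1)
  out <- list(optimal = mk(tab[ord_opt[1], ]),
              minimax = mk(tab[ord_mm[1], ]),
              p0 = p0, p1 = p1, alpha = alpha, beta = beta, n_max = n_max)
  class(out) <- "simon_search"
  out
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("Simon two-stage design: r1/n1 = %d/%d, r/n = %d/%d\n",
              x$r1, x$n1, x$r, x$n))
  cat(sprintf("  p0 = %.3f, p1 = %.3f\n", x$p0, x$p1))
  cat(sprintf("  alpha = %.4f, power = %.4f, PET(p0) = %.4f, EN(p0) = %.2f\n",
              x$alpha_actual, x$power_actual, x$pet0, x$en0))
  invisible(x)
}

#' @export
print.simon_search <- function(x, ...) {
  cat(sprintf("Simon two-stage search: p0 = %.3f, p1 = %.3f, alpha = %.3f, power = %.3f\n",
              x$p0, x$p1, x$alpha, 1 - x$beta))
  cat("Optimal (min EN under p0):\n")
  print(x$optimal)
  cat("Minimax (min n):\n")
  print(x$minimax)
  invisible(x)
}

#' Tidy a Simon design or design search into a tibble
#'
#' @param x A `simon_design` or `simon_search` object.
#' @param ... Unused.
#' @return One row per design with parameters and operating characteristics.
#' @method tidy simon_design
#' @export
tidy.simon_design <- function(x, ...) {
  tibble::tibble(r1 = x$r1, n1 = x$n1, r = x$r, n = x$n,
                 p0 = x$p0, p1 = x$p1,
                 alpha_actual = x$alpha_actual, power_actual = x$power_actual,
                 pet0 = x$pet0, en0 = x$en0)
}

#' @rdname tidy.simon_design
#' @method tidy simon_search
#' @export
tidy.simon_search <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.simon_design(x$optimal), criterion = "optimal",
                  .before = 1),
    dplyr::mutate(tidy.simon_design(x$minimax), criterion = "minimax",
                  .before = 1)
  )
}

#' One-row summary of a Simon design search
#'
#' @param x A `simon_search` object.
#' @param ... Unused.
#' @method glance simon_search
#' @export
glance.simon_search <- function(x, ...) {
  tibble::tibble(p0 = x$p0, p1 = x$p1, alpha = x$alpha, beta = x$beta,
                 n_max = x$n_max,
                 optimal_n = x$optimal$n, optimal_en0 = x$optimal$en0,
                 minimax_n = x$minimax$n, minimax_en0 = x$minimax$en0)
}
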