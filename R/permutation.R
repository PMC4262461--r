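period_index <- function(gbi) as.integer(factor(gbi$period))

# Observed SD / CV / mean of the off-diagonal HWIs of a GBI.
observed_hwi_stats <- function(gbi) {
  v <- offdiag_values(hwi_matrix(gbi)$hwi)
  v <- v[!is.na(v)]
  m <- mean(v)
  s <- sd(v)
  c(sd = s, cv = if (m > 0) s / m else NA_real_, mean = m)
}

#' One marginal-preserving checkerboard flip
#'
#' Performs a single random flip: a sampling period with at least two
#' groups is drawn, then two groups and two individuals showing the
#' checkerboard pattern (one in the first group only, the other in the
#' second only), and the two are swapped. Group sizes and every
#' individual's within-period group count are unchanged. Infeasible draws
#' are rejected and redrawn.
#'
#' @param gbi a `gbi` object.
#' @param n_flips number of successful flips to perform; default 1.
#' @param retry_cap maximum consecutive infeasible draws before declaring
#'   the data unswappable.
#' @return The flipped `gbi` with attribute `attempts` (number of draws
#'   used, counting rejections).
#' @export
checkerboard_flip <- function(gbi, n_flips = 1, retry_cap = 10000) {
  stopifnot(inherits(gbi, "gbi"))
  m <- gbi$matrix + 0L       # force a copy; cpp_flips works in place
  attempts <- cpp_flips(m, period_index(gbi), as.integer(n_flips),
                        as.integer(retry_cap))
  out <- gbi
  out$matrix <- m
  attr(out, "attempts") <- attempts
  out
}

#' Group-permutation test for non-random association
#'
#' Tests the null hypothesis of no preferred or avoided companions, given
#' each individual's daily availability and the observed group sizes, by
#' permuting group memberships within daily sampling periods (the
#' checkerboard-flip null of Bejder et al., in the sequential-chain
#' variant: one long flip chain started from the observed matrix, sampled
#' every `flips_per_permutation` successful flips after a burn-in). On
#' every sampled matrix the half-weight indices are recomputed and their
#' standard deviation, coefficient of variation and mean recorded.
#'
#' A higher SD in the real data than in the permuted data indicates
#' preferred/avoided companions; the CV is the sharper statistic for
#' long-term preferences because short-term association lowers the mean
#' and can mask structure in the SD. p-values use the `(r + 1)/(n + 1)`
#' convention; both tails are reported since publications differ in which
#' direction they print.
#'
#' @param gbi a (filtered) `gbi` object.
#' @param n_permutations number of sampled permuted matrices (>= 100).
#' @param flips_per_permutation successful flips between samples.
#' @param seed optional integer seed for reproducibility.
#' @param burn_in successful flips discarded before the first sample.
#' @param alpha two-sided significance level used for the long-term
#'   preference flag (conventionally 0.05; some studies use 0.03).
#' @param retry_cap see [checkerboard_flip()].
#' @return Object of class `assoc_permtest`: per-statistic results
#'   (`observed`, `null_values`, `p_greater`, `p_less`), flip diagnostics,
#'   and `long_term_preferred` (`TRUE` when the observed CV exceeds the
#'   null at level `alpha`, i.e. `p_greater <= alpha / 2`).
#' @export
permutation_test <- function(gbi, n_permutations = 1000,
                             flips_per_permutation = 1000, seed = NULL,
                             burn_in = 10000, alpha = 0.05,
                             retry_cap = 10000) {
  stopifnot(inherits(gbi, "gbi"))
  if (n_permutations < 100) stop("use at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  obs <- observed_hwi_stats(gbi)
  chain <- cpp_chain_stats(gbi$matrix, period_index(gbi),
                           as.integer(n_permutations),
                           as.integer(flips_per_permutation),
                           as.integer(burn_in), as.integer(retry_cap))
  null <- chain$stats
  res <- lapply(c(sd = "sd", cv = "cv", mean = "mean"), function(stat) {
    nv <- null[, stat]
    list(statistic = stat, observed = unname(obs[stat]), null_values = nv,
         null_mean = mean(nv),
         p_greater = (sum(nv >= obs[stat]) + 1) / (n_permutations + 1),
         p_less = (sum(nv <= obs[stat]) + 1) / (n_permutations + 1),
         n_permutations = n_permutations,
         flips_per_permutation = flips_per_permutation)
  })
  structure(list(statistics = res, seed = seed, alpha = alpha,
                 burn_in = burn_in, attempts = chain$attempts,
                 n_permutations = n_permutations,
                 flips_per_permutation = flips_per_permutation,
                 long_term_preferred =
                   isTRUE(res$cv$p_greater <= alpha / 2)),
            class = "assoc_permtest")
}

#' @export
print.assoc_permtest <- function(x, ...) {
  cat(sprintf("group permutation test: %d permutations x %d flips (burn-in %d)\n",
              x$n_permutations, x$flips_per_permutation, x$burn_in))
  for (s in x$statistics) {
    cat(sprintf("  %-4s observed %.5f  null mean %.5f  p(null >= obs) %.4f  p(null <= obs) %.4f\n",
                toupper(s$statistic), s$observed, s$null_mean,
                s$p_greater, s$p_less))
  }
  cat(sprintf("  long-term preferred companions (CV, level %.2f): %s\n",
              x$alpha, if (x$long_term_preferred) "yes" else "no"))
  invisible(x)
}

#' Permutation p-value with stabilisation
#'
#' Doubles the number of permutations, starting from `start_n`, until two
#' successive estimates of `p_greater` differ by less than `tolerance`
#' (the usual practice of increasing permutations until the p value
#' stabilises). Deterministic for a fixed seed.
#'
#' @param gbi a `gbi` object.
#' @param statistic one of `"sd"`, `"cv"`, `"mean"`.
#' @param seed optional seed.
#' @param start_n initial permutation count (>= 100).
#' @param tolerance stabilisation tolerance on p; default 0.001.
#' @param cap maximum permutation count; if reached, the last estimate is
#'   returned with `stabilized = FALSE` and a warning.
#' @param flips_per_permutation,burn_in as in [permutation_test()].
#' @return List with `p`, `n_used`, `trace` (p at each doubling) and
#'   `stabilized`.
#' @export
stabilized_pvalue <- function(gbi, statistic = "cv", seed = NULL,
                              start_n = 100, tolerance = 0.001, cap = 1e6,
                              flips_per_permutation = 100, burn_in = 1000) {
  stopifnot(statistic %in% c("sd", "cv", "mean"))
  if (start_n < 100) stop("start_n must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- start_n
  trace <- numeric(0)
  p_prev <- NA_real_
  repeat {
    pt <- permutation_test(gbi, n_permutations = n,
                           flips_per_permutation = flips_per_permutation,
                           burn_in = burn_in)
    p <- pt$statistics[[statistic]]$p_greater
    trace <- c(trace, p)
    if (!is.na(p_prev) && abs(p - p_prev) < tolerance) {
      return(list(p = p, n_used = n, trace = trace, stabilized = TRUE))
    }
    p_prev <- p
    if (2 * n > cap) {
      warning("permutation cap reached before the p value stabilized")
      return(list(p = p, n_used = n, trace = trace, stabilized = FALSE))
    }
    n <- 2L * n
  }
}

#' Mantel test between two square matrices
#'
#' Pearson correlation of the off-diagonal elements, with a null built by
#' jointly permuting the rows and columns of the second matrix; used e.g.
#' to ask whether association strength depends on a dyadic covariate such
#' as same-sex membership. Two-sided p by the `(r + 1)/(n + 1)` rule on
#' `|r|`.
#'
#' @param m1,m2 symmetric matrices with identical dimensions (and labels,
#'   when present); diagonals are ignored.
#' @param n_permutations number of label permutations; default 1000.
#' @param seed optional seed.
#' @return List with `r`, `p` (two-sided), `p_greater` (one-sided),
#'   `n_permutations`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 1000, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have identical dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must carry identical labels")
  }
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v2 <- m2[ut]
  ok <- !is.na(v1) & !is.na(v2)
  if (sd(v1[ok]) == 0 || sd(v2[ok]) == 0) {
    stop("constant matrix: Mantel correlation undefined")
  }
  r_obs <- cor(v1[ok], v2[ok])
  n <- nrow(m1)
  r_null <- vapply(seq_len(n_permutations), function(k) {
    p <- sample.int(n)
    vp <- m2[p, p][ut]
    cor(v1[ok], vp[ok])
  }, numeric(1))
  list(r = r_obs,
       p = (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_permutations + 1),
       p_greater = (sum(r_null >= r_obs) + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Chi-square test on a dyad class contingency table
#'
#' Pearson chi-square on a table of dyad counts, e.g. HWI class bins by
#' sex pairing, asking whether the distribution over association classes
#' differs between pairings.
#'
#' @param counts matrix or table of non-negative integer counts.
#' @return List with `chi2`, `df`, `p` and the expected counts.
#' @export
dyad_class_chisquare <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("some expected cell counts are zero; merge sparse classes first")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}
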