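assoc_weights <- function(am) {
  stopifnot(inherits(am, "assoc_matrix"))
  w <- am$hwi
  w[is.na(w)] <- 0
  diag(w) <- 0
  w
}

#' Node strength (weighted degree)
#'
#' Sum of an individual's association indices over all other individuals —
#' a measure of gregariousness.
#'
#' @param am an `assoc_matrix`.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(am) {
  rowSums(assoc_weights(am))
}

#' Weighted clustering coefficient
#'
#' Proportion of an individual's neighbours that are themselves
#' neighbours, generalised to weighted graphs (Holme et al. convention):
#' \deqn{C_i = \frac{\sum_{j,k} w_{ij} w_{jk} w_{ki}}
#'                  {w_{\max} \sum_{j \ne k} w_{ij} w_{ik}},}
#' normalised by the largest weight in the matrix so that a binary
#' triangle scores 1. Undefined (NA) for individuals with fewer than two
#' weighted neighbours.
#'
#' @param am an `assoc_matrix`.
#' @return Named numeric vector in `[0, 1]` (NA where undefined).
#' @export
clustering_coefficient <- function(am) {
  w <- assoc_weights(am)
  wmax <- max(w)
  if (wmax == 0) return(setNames(rep(NA_real_, ncol(w)), colnames(w)))
  num <- diag(w %*% w %*% w)
  s <- rowSums(w)
  den <- wmax * (s^2 - rowSums(w^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  setNames(out, colnames(w))
}

#' Affinity (weighted mean strength of neighbours)
#'
#' \deqn{a_i = \sum_j w_{ij} s_j / s_i,} the association-weighted mean
#' strength of an individual's neighbours; high affinity among
#' high-strength individuals indicates that well-connected animals
#' preferentially associate with each other. Undefined (NA) for
#' zero-strength individuals.
#'
#' @param am an `assoc_matrix`.
#' @return Named numeric vector of affinities.
#' @export
affinity <- function(am) {
  w <- assoc_weights(am)
  s <- rowSums(w)
  out <- ifelse(s > 0, as.numeric(w %*% s) / s, NA_real_)
  setNames(out, colnames(w))
}

network_metric <- function(am, metric) {
  switch(metric,
         strength = node_strength(am),
         clustering = clustering_coefficient(am),
         affinity = affinity(am),
         stop("unknown metric: ", metric))
}

#' Permutation significance of a population-mean network metric
#'
#' Compares the observed population mean of a network metric with its
#' distribution over the within-period group-permutation null (same chain
#' as [permutation_test()]).
#'
#' @param gbi a `gbi` object.
#' @param metric `"strength"`, `"clustering"` or `"affinity"`.
#' @param n_permutations,flips_per_permutation,burn_in,seed,retry_cap as
#'   in [permutation_test()].
#' @return List with `observed`, `null_values`, `p_greater`, `p_less`,
#'   `p_two_sided`.
#' @export
metric_significance <- function(gbi, metric = "strength",
                                n_permutations = 1000,
                                flips_per_permutation = 100, seed = NULL,
                                burn_in = 1000, retry_cap = 10000) {
  stopifnot(inherits(gbi, "gbi"))
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(network_metric(hwi_matrix(gbi), metric), na.rm = TRUE)
  chain <- cpp_chain_gbis(gbi$matrix, period_index(gbi),
                          as.integer(n_permutations),
                          as.integer(flips_per_permutation),
                          as.integer(burn_in), as.integer(retry_cap))
  null <- vapply(chain$samples, function(m) {
    mean(network_metric(hwi_matrix(m), metric), na.rm = TRUE)
  }, numeric(1))
  pg <- (sum(null >= obs) + 1) / (n_permutations + 1)
  pl <- (sum(null <= obs) + 1) / (n_permutations + 1)
  list(metric = metric, observed = obs, null_values = null,
       null_mean = mean(null), p_greater = pg, p_less = pl,
       p_two_sided = min(1, 2 * min(pg, pl)),
       n_permutations = n_permutations)
}

#' Bootstrap standard errors for network metrics
#'
#' Resamples group sightings (GBI rows) with replacement, recomputes the
#' metric, and reports the standard deviation over replicates as the
#' per-individual standard error. Groups are the sampling unit for
#' association data, so they are the resampling unit.
#'
#' @param gbi a `gbi` object with at least 2 groups.
#' @param metric `"strength"`, `"clustering"` or `"affinity"`.
#' @param n_boot number of bootstrap replicates; default 1000.
#' @param seed optional seed.
#' @return Named numeric vector of standard errors (NA-aware: replicates
#'   in which a metric is undefined for an individual are dropped for that
#'   individual).
#' @export
bootstrap_se <- function(gbi, metric = "strength", n_boot = 1000,
                         seed = NULL) {
  stopifnot(inherits(gbi, "gbi"))
  G <- nrow(gbi$matrix)
  if (G < 2) {
    warning("fewer than 2 groups: bootstrap SE is degenerate (0)")
    return(setNames(rep(0, ncol(gbi$matrix)), colnames(gbi$matrix)))
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = ncol(gbi$matrix),
                 dimnames = list(NULL, colnames(gbi$matrix)))
  for (b in seq_len(n_boot)) {
    rows <- sample.int(G, G, replace = TRUE)
    m <- gbi$matrix[rows, , drop = FALSE]
    reps[b, ] <- network_metric(hwi_matrix(m), metric)
  }
  apply(reps, 2, sd, na.rm = TRUE)
}

# Beta-binomial log-likelihood of dyadic joint-sighting counts x out of n,
# parameterised by log(a), log(b) of the beta of true association indices.
betabin_negll <- function(theta, x, n) {
  a <- exp(theta[1]); b <- exp(theta[2])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
  -sum(lchoose(n, x) + lbeta(a + x, b + n - x) - lbeta(a, b))
}

beta_cv <- function(a, b) sqrt(b / (a * (a + b + 1)))

fit_betabin_cv <- function(x, n, reltol = 1e-8) {
  # method-of-moments start and fallback
  p_hat <- sum(x) / sum(n)
  var_obs <- var(x / n)
  samp_var <- mean(p_hat * (1 - p_hat) / n)
  var_true <- max(var_obs - samp_var, 0)
  S_mom <- if (p_hat > 0) sqrt(var_true) / p_hat else 0
  if (var_true <= 0 || p_hat <= 0 || p_hat >= 1) {
    return(list(S = S_mom, S_mom = S_mom, converged = FALSE,
                a = NA_real_, b = NA_real_))
  }
  # beta with mean p_hat, variance var_true
  nu0 <- max(p_hat * (1 - p_hat) / var_true - 1, 0.01)
  start <- log(c(p_hat * nu0, (1 - p_hat) * nu0))
  fit <- tryCatch(
    optim(start, betabin_negll, x = x, n = n, method = "Nelder-Mead",
          control = list(reltol = reltol, maxit = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    warning("beta-binomial likelihood fit failed; reporting the ",
            "method-of-moments estimate")
    return(list(S = S_mom, S_mom = S_mom, converged = FALSE,
                a = NA_real_, b = NA_real_))
  }
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  list(S = beta_cv(a, b), S_mom = S_mom, converged = TRUE, a = a, b = b)
}

#' Social differentiation
#'
#' Estimates the coefficient of variation S of the *true* association
#' indices — a measure of how far the society departs from homogeneous
#' association (S near 0: uniform society; S above about 0.5: well
#' differentiated; above 2: extremely so). Each dyad's joint-sighting
#' count is modelled as binomial given its true index, with true indices
#' following a beta distribution fitted by maximum likelihood; S is the
#' CV of the fitted beta. A method-of-moments estimate (observed variance
#' minus mean binomial sampling variance) is reported alongside, and a
#' jackknife over individuals supplies the standard error.
#'
#' @param am an `assoc_matrix`; alternatively supply `x` and `n` directly
#'   as vectors of per-dyad joint counts and sample sizes.
#' @param x,n optional per-dyad joint-sighting counts and dyad sample
#'   sizes, overriding `am`. For an association matrix, `n` is taken as
#'   `d_i + d_j - x_ij` (the simple-ratio denominator).
#' @param jackknife compute a delete-one-individual jackknife SE (only
#'   when `am` is supplied); default `TRUE`.
#' @return List with `S` (maximum-likelihood CV), `S_mom`
#'   (method-of-moments), `se` (jackknife SE or NA), `well_differentiated`
#'   (`S > 0.5`), and the fitted beta parameters.
#' @export
social_differentiation <- function(am = NULL, x = NULL, n = NULL,
                                   jackknife = TRUE) {
  if (is.null(x) || is.null(n)) {
    stopifnot(inherits(am, "assoc_matrix"))
    ut <- upper.tri(am$x)
    x <- am$x[ut]
    dsum <- outer(am$d, am$d, "+")[ut]
    n <- dsum - x
    keep <- n > 0
    x <- x[keep]; n <- n[keep]
  }
  if (length(unique(x / n)) == 1) {
    return(list(S = 0, S_mom = 0, se = 0, well_differentiated = FALSE,
                a = NA_real_, b = NA_real_, converged = TRUE))
  }
  fit <- fit_betabin_cv(x, n)
  se <- NA_real_
  if (jackknife && !is.null(am)) {
    ids <- colnames(am$hwi)
    thetas <- vapply(seq_along(ids), function(i) {
      ut <- upper.tri(am$x)
      drop <- outer(seq_along(ids) == i, seq_along(ids) == i, "|")
      keep <- ut & !drop
      xi <- am$x[keep]
      ni <- (outer(am$d, am$d, "+") - am$x)[keep]
      ok <- ni > 0
      fit_betabin_cv(xi[ok], ni[ok])$S
    }, numeric(1))
    B <- length(thetas)
    se <- sqrt((B - 1) / B * sum((thetas - mean(thetas))^2))
  }
  list(S = fit$S, S_mom = fit$S_mom, se = se,
       well_differentiated = fit$S > 0.5, a = fit$a, b = fit$b,
       converged = fit$converged)
}
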