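# --- pairwise period-to-period association counts ------------------------

# Per-period association structures for LAR estimation. Periods are
# calendar days; after daily de-duplication an individual belongs to at
# most one group per day, so the day-level association matrix is well
# defined. Returns, for every ordered period pair (t, t'), the number of
# (ordered) associated pairs at t that are still associated at t'
# (numerator) and the number whose first member was identified at t'
# (denominator).
lar_paircounts <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  dates <- sort(unique(gbi$period))
  n <- ncol(gbi$matrix)
  Tn <- length(dates)
  if (Tn < 2) stop("need at least 2 sampling periods for a lagged rate")
  M <- matrix(0, nrow = Tn, ncol = n * n)     # vectorised A_t (assoc at t)
  P <- matrix(0, nrow = Tn, ncol = n)         # presence (identified) at t
  RS <- matrix(0, nrow = Tn, ncol = n)        # number of associates at t
  for (t in seq_len(Tn)) {
    rows <- which(gbi$period == dates[t])
    A <- matrix(0, n, n)
    for (g in rows) {
      mem <- which(gbi$matrix[g, ] == 1)
      if (length(mem) > 1) A[mem, mem] <- 1
      P[t, mem] <- 1
    }
    diag(A) <- 0
    M[t, ] <- as.numeric(A)
    RS[t, ] <- rowSums(A)
  }
  N <- M %*% t(M)        # ordered associated-pair carryover counts
  D <- RS %*% t(P)       # ordered pairs at t with first member seen at t'
  list(N = N, D = D, dates = dates)
}

# Aggregate period-pair counts into lag bins. `exclude` is an optional
# logical vector over periods (TRUE = leave out, for jackknifing).
bin_lar <- function(pc, breaks, exclude = NULL) {
  Tn <- length(pc$dates)
  lag <- outer(pc$dates, pc$dates, function(a, b) as.numeric(b - a))
  keep <- lag > 0
  if (!is.null(exclude)) {
    keep <- keep & !outer(exclude, exclude, "|")
  }
  idx <- which(keep)
  lg <- lag[idx]
  bin <- findInterval(lg, breaks, left.open = TRUE) + 1L
  num <- as.numeric(rowsum(pc$N[idx], bin))
  den <- as.numeric(rowsum(pc$D[idx], bin))
  wlag <- as.numeric(rowsum(lg * pc$D[idx], bin))
  present <- sort(unique(bin))
  data.frame(bin = present, lag = ifelse(den > 0, wlag / den, NA),
             num = num, den = den, g = ifelse(den > 0, num / den, NA))
}

# Log-spaced candidate break points covering lags 1..max_lag, then bins
# with a denominator below `min_den` merged upward into their neighbour.
auto_breaks <- function(pc, n_bins = 12, min_den = 20) {
  lag <- outer(pc$dates, pc$dates, function(a, b) as.numeric(b - a))
  pos <- lag > 0
  max_lag <- max(lag[pos])
  breaks <- unique(round(exp(seq(log(1), log(max_lag),
                                 length.out = n_bins))))
  breaks <- sort(unique(c(0, breaks)))
  b <- bin_lar(pc, breaks)
  # merge sparse bins upward (into the next-larger lag bin)
  while (any(b$den < min_den) && length(breaks) > 2) {
    worst <- which(b$den < min_den)[1]
    drop_edge <- min(worst + 1, length(breaks))
    breaks <- breaks[-drop_edge]
    b <- bin_lar(pc, breaks)
  }
  breaks
}

date_blocks <- function(dates, block_days) {
  as.integer(floor(as.numeric(dates - min(dates)) / block_days))
}

#' Lagged association rate
#'
#' Estimates g(tau), the probability that two individuals associated at
#' some day are still associated tau days later, by the ratio-of-sums
#' estimator: over all ordered day pairs whose separation falls in a lag
#' bin, the number of associated pairs seen together again divided by the
#' number of associated pairs whose first member was identified at the
#' later day. Standard errors come from a delete-one-block jackknife over
#' contiguous date blocks.
#'
#' @param gbi a `gbi` object with dated sampling periods.
#' @param lag_bins optional numeric vector of bin break points (days,
#'   left-open); when `NULL`, log-spaced bins are built and bins with a
#'   denominator below `min_den` are merged upward.
#' @param min_den minimum denominator count per bin for automatic binning.
#' @param block_days jackknife block length in days; default 30.
#' @return Object of class `lar_curve`: data frame columns `lag`
#'   (denominator-weighted mean lag), `g`, `se`, `num`, `den`, plus
#'   attributes `null_rate` and `breaks`. Bins with zero denominator are
#'   dropped.
#' @export
lagged_association_rate <- function(gbi, lag_bins = NULL, min_den = 20,
                                    block_days = 30) {
  pc <- lar_paircounts(gbi)
  breaks <- if (is.null(lag_bins)) auto_breaks(pc, min_den = min_den)
            else sort(unique(c(0, lag_bins)))
  full <- bin_lar(pc, breaks)
  full <- full[full$den > 0, , drop = FALSE]
  blocks <- date_blocks(pc$dates, block_days)
  se <- rep(NA_real_, nrow(full))
  if (length(unique(blocks)) >= 3) {
    gj <- sapply(sort(unique(blocks)), function(b) {
      bj <- bin_lar(pc, breaks, exclude = blocks == b)
      bj$g[match(full$bin, bj$bin)]
    })
    B <- ncol(gj)
    se <- apply(gj, 1, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2) return(NA_real_)
      sqrt((length(z) - 1) / length(z) * sum((z - mean(z))^2))
    })
  }
  out <- cbind(full[, c("lag", "g")], se = se, full[, c("num", "den")])
  rownames(out) <- NULL
  structure(out, class = c("lar_curve", "data.frame"),
            null_rate = null_association_rate(gbi), breaks = breaks,
            block_days = block_days)
}

#' Null association rate
#'
#' The expected lagged association rate if individuals mixed at random:
#' the probability that a given prior associate is among the (on average)
#' `k - 1` companions an individual is seen with, out of the `N - 1`
#' other identified individuals, where `k - 1` is the mean number of
#' identified associates per individual sighting. Equals `(k - 1)/(N - 1)`
#' in a population of N individuals always seen in groups of k.
#'
#' @param gbi a `gbi` object.
#' @return Scalar null rate.
#' @export
null_association_rate <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  n <- ncol(gbi$matrix)
  if (n < 2) return(NA_real_)
  sizes <- rowSums(gbi$matrix)
  total_members <- sum(sizes)
  mean_associates <- sum(sizes * (sizes - 1)) / total_members
  mean_associates / (n - 1)
}

# --- the eight-model exponential family ----------------------------------

# Each model maps an unconstrained parameter vector to g(tau) in [0,1].
# Models without rapid disassociation (RD) are constrained to g(0) = 1;
# RD models leave the component proportions free (their shortfall from 1
# is the rapidly-disassociating fraction). Proportions use logistic
# transforms, decays log transforms; two-component models split a total
# persistent mass u into a constant and a decaying part to keep
# a2 + a3 <= 1 without penalties.
lar_model_defs <- function() {
  lg <- function(x) 1 / (1 + exp(-x))
  list(
    list(name = "CC", components = c("CC"), K = 0,
         g = function(p, tau) rep(1, length(tau)),
         natural = function(p) c(a2 = 1)),
    list(name = "CA", components = c("CA"), K = 1,
         g = function(p, tau) exp(-exp(p[1]) * tau),
         natural = function(p) c(a1 = exp(p[1]))),
    list(name = "CC+CA", components = c("CC", "CA"), K = 2,
         g = function(p, tau) lg(p[1]) + (1 - lg(p[1])) * exp(-exp(p[2]) * tau),
         natural = function(p) c(a2 = lg(p[1]), a3 = 1 - lg(p[1]),
                                 a1 = exp(p[2]))),
    list(name = "RD+CC", components = c("RD", "CC"), K = 1,
         g = function(p, tau) rep(lg(p[1]), length(tau)),
         natural = function(p) c(a2 = lg(p[1]))),
    list(name = "RD+CA", components = c("RD", "CA"), K = 2,
         g = function(p, tau) lg(p[1]) * exp(-exp(p[2]) * tau),
         natural = function(p) c(a3 = lg(p[1]), a1 = exp(p[2]))),
    list(name = "RD+CC+CA", components = c("RD", "CC", "CA"), K = 3,
         g = function(p, tau) {
           u <- lg(p[1]); v <- lg(p[2])
           u * v + u * (1 - v) * exp(-exp(p[3]) * tau)
         },
         natural = function(p) {
           u <- lg(p[1]); v <- lg(p[2])
           c(a2 = u * v, a3 = u * (1 - v), a1 = exp(p[3]))
         }),
    list(name = "2CA", components = c("CA", "CA2"), K = 3,
         g = function(p, tau) {
           v <- lg(p[1])
           v * exp(-exp(p[2]) * tau) + (1 - v) * exp(-exp(p[3]) * tau)
         },
         natural = function(p) c(a3 = lg(p[1]), a4 = 1 - lg(p[1]),
                                 a1 = exp(p[2]), a2 = exp(p[3]))),
    list(name = "RD+2CA", components = c("RD", "CA", "CA2"), K = 4,
         g = function(p, tau) {
           u <- lg(p[1]); v <- lg(p[2])
           u * v * exp(-exp(p[3]) * tau) +
             u * (1 - v) * exp(-exp(p[4]) * tau)
         },
         natural = function(p) {
           u <- lg(p[1]); v <- lg(p[2])
           c(a3 = u * v, a4 = u * (1 - v), a1 = exp(p[3]), a2 = exp(p[4]))
         })
  )
}

binom_loglik <- function(g, num, den) {
  g <- pmin(pmax(g, 1e-10), 1 - 1e-10)
  sum(num * log(g) + (den - num) * log(1 - g))
}

binom_deviance <- function(g, num, den) {
  g <- pmin(pmax(g, 1e-10), 1 - 1e-10)
  p_sat <- num / den
  term1 <- ifelse(num > 0, num * log(p_sat / g), 0)
  term2 <- ifelse(den - num > 0, (den - num) * log((1 - p_sat) / (1 - g)), 0)
  2 * sum(term1 + term2)
}

fit_one_model <- function(def, binned, n_starts = 5, reltol = 1e-8,
                          start_at = NULL) {
  tau <- binned$lag; num <- binned$num; den <- binned$den
  if (def$K == 0) {
    ll <- binom_loglik(def$g(NULL, tau), num, den)
    return(list(par = numeric(0), logQL = ll,
                deviance = binom_deviance(def$g(NULL, tau), num, den),
                converged = TRUE))
  }
  negll <- function(p) -binom_loglik(def$g(p, tau), num, den)
  g_obs <- num / den
  g_inf <- mean(g_obs[tau >= quantile(tau, 0.7)])
  base <- switch(def$name,
    "CA" = c(log(0.3)),
    "CC+CA" = c(stats::qlogis(min(max(g_inf, 0.05), 0.95)), log(0.3)),
    "RD+CC" = c(stats::qlogis(min(max(mean(g_obs), 0.05), 0.95))),
    "RD+CA" = c(stats::qlogis(min(max(g_obs[1], 0.05), 0.95)), log(0.3)),
    "RD+CC+CA" = c(stats::qlogis(min(max(g_obs[1], 0.05), 0.95)),
                   stats::qlogis(min(max(g_inf / max(g_obs[1], 0.05), 0.05),
                                     0.95)), log(0.3)),
    "2CA" = c(0, log(0.5), log(0.02)),
    "RD+2CA" = c(stats::qlogis(min(max(g_obs[1], 0.05), 0.95)), 0,
                 log(0.5), log(0.02)))
  starts <- list(base)
  if (!is.null(start_at)) starts <- c(list(start_at), starts)
  for (s in seq_len(max(0, n_starts - length(starts)))) {
    starts[[length(starts) + 1]] <- base + stats::rnorm(def$K, sd = 1)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      if (def$K == 1) {
        optim(st, negll, method = "BFGS",
              control = list(reltol = reltol, maxit = 5000))
      } else {
        optim(st, negll, method = "Nelder-Mead",
              control = list(reltol = reltol, maxit = 5000))
      },
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(list(par = rep(NA_real_, def$K), logQL = NA_real_,
                deviance = NA_real_, converged = FALSE))
  }
  list(par = best$par, logQL = -best$value,
       deviance = binom_deviance(def$g(best$par, tau), num, den),
       converged = best$convergence == 0)
}

#' Fit the eight-model exponential family to a lagged association rate
#'
#' Models the lagged association rate as combinations of constant
#' companions (CC: permanent associates, a constant level), casual
#' acquaintances (CA: associations decaying exponentially over a
#' characteristic time of `1/a1` days) and rapid disassociation (RD:
#' associates lost immediately, expressed as the component proportions
#' summing to less than one). The eight forms are: `{CC}`, `{CA}`,
#' `{CC+CA}`, `{RD+CC}`, `{RD+CA}`, `{RD+CC+CA}` (i.e.
#' `g = a2 + a3 exp(-a1 tau)`), `{2CA}` (two decay time scales) and
#' `{RD+2CA}`. Parameters are fitted by maximising the binomial
#' quasi-likelihood of the per-bin numerator/denominator counts
#' (multi-start Nelder-Mead); overdispersion `c_hat` is estimated from
#' the most general model's deviance over its residual degrees of
#' freedom, and models are ranked by
#' `QAIC = deviance / c_hat + 2 (K + 1)` (the +1 counts `c_hat`).
#' Differences above 2 QAIC units are conventionally read as no support
#' for the weaker model.
#'
#' @param gbi a `gbi` object, or a precomputed `lar_curve`.
#' @param lag_bins,min_den,block_days as in [lagged_association_rate()]
#'   (ignored when a `lar_curve` is supplied).
#' @param seed optional seed for the multi-start optimiser.
#' @param n_starts random restarts per model; default 5.
#' @param jackknife `"best"` (default) computes delete-one-block jackknife
#'   SEs for the top-ranked model's parameters, `"none"` skips them,
#'   `"all"` computes them for every model.
#' @return Object of class `lar_fit`: list with `models` (ranked data
#'   frame: name, K, logQL, deviance, QAIC, dQAIC), `fits` (per-model
#'   natural parameters and jackknife SEs where computed), `c_hat`,
#'   `curve` (the `lar_curve` used), `best` (name of the lowest-QAIC
#'   model) and `ca_duration_days` (reciprocal of the best model's decay
#'   exponent, the conventional casual-acquaintance duration, when the
#'   model has one).
#' @export
fit_lar_models <- function(gbi, lag_bins = NULL, min_den = 20,
                           block_days = 30, seed = NULL, n_starts = 5,
                           jackknife = c("best", "none", "all")) {
  jackknife <- match.arg(jackknife)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(gbi, "lar_curve")) {
    curve <- gbi
    pc <- NULL
    if (jackknife != "none") {
      jackknife <- "none"
    }
  } else {
    pc <- lar_paircounts(gbi)
    curve <- lagged_association_rate(gbi, lag_bins = lag_bins,
                                     min_den = min_den,
                                     block_days = block_days)
  }
  binned <- data.frame(lag = curve$lag, num = curve$num, den = curve$den)
  defs <- lar_model_defs()
  fits <- lapply(defs, fit_one_model, binned = binned, n_starts = n_starts)
  names(fits) <- vapply(defs, `[[`, "", "name")

  general <- fits[["RD+2CA"]]
  df_gen <- nrow(binned) - defs[[8]]$K
  c_hat <- if (df_gen > 0 && is.finite(general$deviance)) {
    max(general$deviance / df_gen, 1)
  } else 1

  tab <- data.frame(
    model = names(fits),
    K = vapply(defs, `[[`, 0, "K"),
    logQL = vapply(fits, `[[`, 0, "logQL") / c_hat,
    deviance = vapply(fits, `[[`, 0, "deviance"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  tab$QAIC <- tab$deviance / c_hat + 2 * (tab$K + 1)
  tab$QAIC[!tab$converged] <- NA
  tab <- tab[order(tab$QAIC), , drop = FALSE]
  tab$dQAIC <- tab$QAIC - min(tab$QAIC, na.rm = TRUE)
  rownames(tab) <- NULL
  best_name <- tab$model[1]

  params <- lapply(seq_along(defs), function(i) {
    if (any(is.na(fits[[i]]$par)) && defs[[i]]$K > 0) return(NULL)
    p <- defs[[i]]$natural(fits[[i]]$par)
    # report faster decay first for two-timescale models
    if (all(c("a1", "a2") %in% names(p)) &&
        defs[[i]]$name %in% c("2CA", "RD+2CA") && p["a1"] < p["a2"]) {
      p[c("a1", "a2")] <- p[c("a2", "a1")]
      if (all(c("a3", "a4") %in% names(p))) {
        p[c("a3", "a4")] <- p[c("a4", "a3")]
      }
    }
    p
  })
  names(params) <- names(fits)

  jack <- list()
  if (jackknife != "none" && !is.null(pc)) {
    blocks <- date_blocks(pc$dates, block_days)
    ub <- sort(unique(blocks))
    which_models <- if (jackknife == "best") best_name else names(fits)
    if (length(ub) >= 3) {
      for (mn in which_models) {
        i <- match(mn, names(fits))
        if (defs[[i]]$K == 0) next
        reps <- sapply(ub, function(b) {
          bj <- bin_lar(pc, attr(curve, "breaks"), exclude = blocks == b)
          bj <- bj[bj$den > 0, , drop = FALSE]
          f <- fit_one_model(defs[[i]],
                             data.frame(lag = bj$lag, num = bj$num,
                                        den = bj$den),
                             n_starts = 1, start_at = fits[[i]]$par)
          defs[[i]]$natural(f$par)
        })
        if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
        B <- ncol(reps)
        jack[[mn]] <- apply(reps, 1, function(z)
          sqrt((B - 1) / B * sum((z - mean(z))^2)))
        names(jack[[mn]]) <- names(params[[mn]])
      }
    } else {
      warning("fewer than 3 jackknife blocks; parameter SEs not computed")
    }
  }

  bp <- params[[best_name]]
  ca_dur <- if (!is.null(bp) && "a1" %in% names(bp)) 1 / bp[["a1"]] else NA_real_
  structure(list(models = tab, params = params, jackknife_se = jack,
                 c_hat = c_hat, curve = curve, best = best_name,
                 ca_duration_days = ca_dur),
            class = "lar_fit")
}

#' @export
print.lar_fit <- function(x, ...) {
  cat(sprintf("lagged association rate model selection (c_hat = %.3f)\n",
              x$c_hat))
  print(x$models[, c("model", "K", "deviance", "QAIC", "dQAIC")],
        digits = 6)
  bp <- x$params[[x$best]]
  cat(sprintf("best model: %s (%s)\n", x$best,
              paste(sprintf("%s = %.3f", names(bp), bp), collapse = ", ")))
  if (is.finite(x$ca_duration_days)) {
    cat(sprintf("approximate casual-acquaintance duration: %.1f days\n",
                x$ca_duration_days))
  }
  invisible(x)
}

#' Delete-one-block jackknife standard errors
#'
#' Splits the sampling periods into contiguous date blocks, re-evaluates
#' an estimator with each block left out, and returns
#' `sqrt((B - 1)/B * sum((theta_b - mean)^2))` per component.
#'
#' @param gbi a `gbi` object.
#' @param estimator function taking a `gbi` and returning a numeric
#'   vector (constant length across blocks).
#' @param block_days block length in days; default 30. At least 3 blocks
#'   are required.
#' @return Numeric vector of standard errors (named when the estimator
#'   returns named values).
#' @export
jackknife_errors <- function(gbi, estimator, block_days = 30) {
  stopifnot(inherits(gbi, "gbi"))
  blocks <- date_blocks(gbi$period, block_days)
  ub <- sort(unique(blocks))
  if (length(ub) < 3) {
    stop("need at least 3 jackknife blocks; shorten block_days or extend the data")
  }
  reps <- sapply(ub, function(b) {
    keep <- blocks != b
    sub <- gbi
    sub$matrix <- gbi$matrix[keep, , drop = FALSE]
    sub$period <- gbi$period[keep]
    sub$covariates <- gbi$covariates[keep, , drop = FALSE]
    estimator(sub)
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  B <- ncol(reps)
  out <- apply(reps, 1, function(z)
    sqrt((B - 1) / B * sum((z - mean(z))^2)))
  if (!is.null(rownames(reps))) names(out) <- rownames(reps)
  out
}
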