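# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity with naive loops so the package implementations
# are checked against a second, independent route.

# random binary group-by-individual matrix (as a bare matrix)
random_gbi_matrix <- function(n_groups, n_ind, p = 0.35) {
  m <- matrix(as.integer(runif(n_groups * n_ind) < p), n_groups, n_ind)
  colnames(m) <- sprintf("I%02d", seq_len(n_ind))
  rownames(m) <- sprintf("g%02d", seq_len(n_groups))
  m
}

# construct a gbi object directly from a list of days, each day a list of
# character vectors (groups of individual ids)
gbi_from_days <- function(days, individuals = NULL,
                          start = as.Date("2010-01-01"),
                          dates = NULL) {
  if (is.null(individuals)) {
    individuals <- sort(unique(unlist(days)))
  }
  if (is.null(dates)) dates <- start + seq_along(days) - 1
  rows <- list()
  for (d in seq_along(days)) {
    for (g in seq_along(days[[d]])) {
      rows[[length(rows) + 1]] <- list(date = dates[d],
                                       gid = sprintf("g%02d", g),
                                       members = days[[d]][[g]])
    }
  }
  m <- matrix(0L, nrow = length(rows), ncol = length(individuals),
              dimnames = list(
                vapply(rows, function(r) paste(r$date, r$gid, sep = "/"), ""),
                individuals))
  period <- as.Date(vapply(rows, function(r) as.character(r$date), ""))
  for (i in seq_along(rows)) m[i, rows[[i]]$members] <- 1L
  structure(list(
    matrix = m, period = period,
    covariates = data.frame(trammel_net = FALSE,
                            group_size_observed = rowSums(m),
                            n_identified = rowSums(m),
                            row.names = rownames(m)),
    individuals = data.frame(individual_id = individuals, sex = "UN",
                             age_class = "A", stringsAsFactors = FALSE)),
    class = "gbi")
}

# assoc_matrix from a plain symmetric weight matrix (counts synthesised)
assoc_from_weights <- function(w, d = NULL) {
  diag(w) <- NA
  if (is.null(colnames(w))) {
    colnames(w) <- rownames(w) <- sprintf("I%02d", seq_len(ncol(w)))
  }
  if (is.null(d)) d <- rep(10, ncol(w))
  names(d) <- colnames(w)
  x <- w
  x[is.na(x)] <- 0
  structure(list(hwi = w, x = x, d = d, individuals = NULL),
            class = "assoc_matrix")
}

# --- oracles -------------------------------------------------------------

brute_hwi <- function(m) {
  n <- ncol(m)
  h <- matrix(NA_real_, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      x <- 0
      for (g in seq_len(nrow(m))) if (m[g, i] == 1 && m[g, j] == 1) x <- x + 1
      di <- sum(m[, i]); dj <- sum(m[, j])
      if (di + dj > 0) h[i, j] <- 2 * x / (di + dj)
    }
  }
  h
}

brute_strength <- function(w) {
  w[is.na(w)] <- 0; diag(w) <- 0
  out <- numeric(ncol(w))
  for (i in seq_len(ncol(w))) for (j in seq_len(ncol(w)))
    if (j != i) out[i] <- out[i] + w[i, j]
  setNames(out, colnames(w))
}

brute_clustering <- function(w) {
  w[is.na(w)] <- 0; diag(w) <- 0
  n <- ncol(w); wmax <- max(w)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      num <- num + w[i, j] * w[j, k] * w[k, i]
      den <- den + w[i, j] * w[i, k]
    }
    if (den > 0 && wmax > 0) out[i] <- num / (wmax * den)
  }
  setNames(out, colnames(w))
}

brute_affinity <- function(w) {
  w[is.na(w)] <- 0; diag(w) <- 0
  s <- brute_strength(w)
  out <- rep(NA_real_, ncol(w))
  for (i in seq_len(ncol(w))) {
    if (s[i] > 0) out[i] <- sum(w[i, ] * s) / s[i]
  }
  setNames(out, colnames(w))
}

# edge-sum form of weighted Newman modularity (independent of the
# package's community-sum form)
brute_modularity <- function(w, partition) {
  w[is.na(w)] <- 0; diag(w) <- 0
  W2 <- sum(w)                      # 2W
  if (W2 == 0) return(0)
  s <- unname(rowSums(w))
  q <- 0
  for (i in seq_len(ncol(w))) for (j in seq_len(ncol(w))) {
    if (i == j) next
    if (partition[i] == partition[j]) {
      q <- q + (w[i, j] - s[i] * s[j] / W2) / W2
    }
  }
  # the community-sum form includes the diagonal of the null term
  q - sum((s / W2)^2)
}

# all set partitions of 1..n as lists of integer label vectors
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1)) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c)
  }
  out
}

rand_index <- function(p1, p2) {
  n <- length(p1)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same1 <- p1[i] == p1[j]; same2 <- p2[i] == p2[j]
    if (same1 == same2) agree <- agree + 1
  }
  agree / total
}

# naive average-linkage agglomeration on a similarity matrix; returns the
# cophenetic similarity matrix (merge heights), which identifies the tree
brute_average_linkage <- function(sim) {
  n <- ncol(sim)
  diag(sim) <- NA
  clusters <- as.list(seq_len(n))
  coph <- matrix(NA_real_, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_val <- -Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      val <- mean(sim[clusters[[a]], clusters[[b]]])
      if (val > best_val + 1e-12) { best_val <- val; best <- c(a, b) }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]]) {
      coph[i, j] <- coph[j, i] <- best_val
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(sim)
  coph
}

# exhaustive lagged-association-rate numerator/denominator per exact lag
brute_lar <- function(gbi) {
  dates <- sort(unique(gbi$period))
  n <- ncol(gbi$matrix)
  assoc <- function(t) {
    A <- matrix(FALSE, n, n)
    for (g in which(gbi$period == dates[t])) {
      mem <- which(gbi$matrix[g, ] == 1)
      if (length(mem) > 1) A[mem, mem] <- TRUE
    }
    diag(A) <- FALSE
    A
  }
  present <- function(t) {
    out <- rep(FALSE, n)
    for (g in which(gbi$period == dates[t]))
      out[gbi$matrix[g, ] == 1] <- TRUE
    out
  }
  res <- list()
  for (t1 in seq_along(dates)) {
    A1 <- assoc(t1)
    for (t2 in seq_along(dates)) {
      lag <- as.numeric(dates[t2] - dates[t1])
      if (lag <= 0) next
      A2 <- assoc(t2); P2 <- present(t2)
      num <- 0; den <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        if (A1[i, j] && P2[i]) {
          den <- den + 1
          if (A2[i, j]) num <- num + 1
        }
      }
      key <- as.character(lag)
      if (is.null(res[[key]])) res[[key]] <- c(num = 0, den = 0)
      res[[key]] <- res[[key]] + c(num = num, den = den)
    }
  }
  lags <- sort(as.numeric(names(res)))
  data.frame(lag = lags,
             num = vapply(as.character(lags), function(k) res[[k]]["num"], 0),
             den = vapply(as.character(lags), function(k) res[[k]]["den"], 0),
             row.names = NULL)
}

# small ready-made sighting data frame: one group of two on one day plus
# padding fields
tiny_sightings <- function() {
  data.frame(
    date = as.Date(c("2010-06-01", "2010-06-01", "2010-06-02")),
    group_id = c("g1", "g1", "g1"),
    individual_id = c("PHD1", "PHD2", "PHD1"),
    sex = c("F", "M", "F"),
    age_class = c("A", "A", "A"),
    group_size_observed = c(2L, 2L, 1L),
    n_identified = c(2L, 2L, 1L),
    trammel_net = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}
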