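#' Half-weight association index matrix
#'
#' Computes the half-weight index for every dyad,
#' \deqn{HWI_{AB} = \frac{2N_{AB}}{N_A + N_B},}
#' where \eqn{N_{AB}} is the number of groups in which A and B were seen
#' together and \eqn{N_A}, \eqn{N_B} are each individual's total sighting
#' counts. A value of 0 means the pair was never seen in the same group; 1
#' means the two were always together. The half-weight form corrects for
#' pairs being more readily scored apart than together.
#'
#' Dyads whose combined sighting count is zero are undefined and returned
#' as `NA`.
#'
#' @param gbi a `gbi` object from [build_gbi()] (or a plain binary matrix
#'   with individuals in columns).
#' @return An object of class `assoc_matrix`: list with `hwi` (symmetric,
#'   diagonal `NA`), `x` (joint-sighting counts), `d` (per-individual
#'   sighting totals), `individuals` (attribute data frame, when known).
#' @export
hwi_matrix <- function(gbi) {
  m <- if (inherits(gbi, "gbi")) gbi$matrix else as.matrix(gbi)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty group-by-individual matrix")
  storage.mode(m) <- "double"
  x <- crossprod(m)            # joint sighting counts, diagonal = d
  d <- diag(x)
  denom <- outer(d, d, "+")
  hwi <- ifelse(denom > 0, 2 * x / denom, NA_real_)
  diag(hwi) <- NA_real_
  diag(x) <- 0
  structure(list(hwi = hwi, x = x, d = d,
                 individuals = if (inherits(gbi, "gbi")) gbi$individuals
                               else NULL),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  v <- offdiag_values(x$hwi)
  cat(sprintf("half-weight association matrix: %d individuals, %d dyads\n",
              length(x$d), length(v)))
  cat(sprintf("  mean HWI %.3f, SD %.3f, range %.2f-%.2f\n",
              mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

# Unordered off-diagonal values of a symmetric matrix (upper triangle).
offdiag_values <- function(m) m[upper.tri(m)]

#' Per-individual association summaries
#'
#' Mean, maximum and minimum HWI for each individual (over defined,
#' off-diagonal dyads), together with a summary of dyads by sex pairing
#' (female-female, male-male, female-male, and pairings involving
#' unknown-sex individuals).
#'
#' @param am an `assoc_matrix` with individual attributes.
#' @return List with `individuals` (per-individual data frame) and
#'   `sex_pairings` (per-pairing dyad counts and HWI summaries).
#' @export
individual_summary <- function(am) {
  stopifnot(inherits(am, "assoc_matrix"))
  h <- am$hwi
  per_ind <- data.frame(
    individual_id = colnames(h),
    n_sightings = as.numeric(am$d),
    mean_hwi = apply(h, 1, mean, na.rm = TRUE),
    max_hwi = apply(h, 1, max, na.rm = TRUE),
    min_hwi = apply(h, 1, min, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(per_ind) <- NULL

  pairings <- NULL
  if (!is.null(am$individuals)) {
    sex <- am$individuals$sex[match(colnames(h), am$individuals$individual_id)]
    iu <- which(upper.tri(h), arr.ind = TRUE)
    s1 <- pmin(sex[iu[, 1]], sex[iu[, 2]])
    s2 <- pmax(sex[iu[, 1]], sex[iu[, 2]])
    pairing <- paste(s1, s2, sep = "-")
    v <- h[iu]
    keep <- !is.na(v)
    pairings <- do.call(rbind, lapply(split(v[keep], pairing[keep]), function(z)
      data.frame(n = length(z), mean = mean(z), sd = sd(z),
                 min = min(z), max = max(z))))
    pairings <- cbind(pairing = rownames(pairings), pairings)
    rownames(pairings) <- NULL
  }
  list(individuals = per_ind, sex_pairings = pairings)
}

#' Classify dyads as preferred, avoided or neutral
#'
#' A dyad is a preferred association when its HWI is at least twice the
#' mean index (computed over all unordered off-diagonal dyads, zeros
#' included — approximately twice the expected value under fully random
#' association), and an avoided association when its HWI is exactly zero.
#' Dyads are additionally binned as low (<0.3), moderate (0.3-0.5,
#' boundaries included) or high (>0.5).
#'
#' Because dyad-total conventions differ between reports (unordered pairs,
#' ordered non-self pairs, or all ordered pairs including self), the
#' returned object records all three counts.
#'
#' @param am an `assoc_matrix`.
#' @return List of class `dyad_classification` with `dyads` (one row per
#'   unordered dyad: ids, hwi, label, bin), `threshold`, `mean_hwi`,
#'   `per_individual` (counts of preferred and avoided partners) and
#'   `dyad_counts` (the three counting conventions).
#' @export
classify_dyads <- function(am) {
  stopifnot(inherits(am, "assoc_matrix"))
  h <- am$hwi
  n <- ncol(h)
  iu <- which(upper.tri(h), arr.ind = TRUE)
  v <- h[iu]
  ok <- !is.na(v)
  mean_hwi <- mean(v[ok])
  threshold <- 2 * mean_hwi
  label <- rep(NA_character_, length(v))
  label[ok] <- "neutral"
  label[ok & v >= threshold] <- "preferred"
  label[ok & v == 0] <- "avoided"
  bin <- rep(NA_character_, length(v))
  bin[ok & v < 0.3] <- "low"
  bin[ok & v >= 0.3 & v <= 0.5] <- "moderate"
  bin[ok & v > 0.5] <- "high"
  ids <- colnames(h)
  dyads <- data.frame(
    id1 = ids[iu[, 1]], id2 = ids[iu[, 2]], hwi = v,
    label = factor(label, levels = c("preferred", "avoided", "neutral")),
    bin = factor(bin, levels = c("low", "moderate", "high")),
    stringsAsFactors = FALSE)
  count_for <- function(lab) {
    idx <- which(dyads$label == lab)
    tab <- table(factor(c(dyads$id1[idx], dyads$id2[idx]), levels = ids))
    as.integer(tab)
  }
  per_individual <- data.frame(
    individual_id = ids,
    n_preferred = count_for("preferred"),
    n_avoided = count_for("avoided"),
    stringsAsFactors = FALSE)
  structure(list(
    dyads = dyads, threshold = threshold, mean_hwi = mean_hwi,
    per_individual = per_individual,
    dyad_counts = c(unordered = n * (n - 1) / 2,
                    ordered = n * (n - 1),
                    ordered_with_self = n * n)),
    class = "dyad_classification")
}

#' @export
print.dyad_classification <- function(x, ...) {
  tab <- table(x$dyads$label)
  cat(sprintf("dyad classification: threshold %.4f (2 x mean %.4f)\n",
              x$threshold, x$mean_hwi))
  cat(sprintf("  preferred %d, avoided %d, neutral %d of %d unordered dyads\n",
              tab[["preferred"]], tab[["avoided"]], tab[["neutral"]],
              x$dyad_counts[["unordered"]]))
  invisible(x)
}

#' Write an association matrix as labelled delimited text
#'
#' @param am an `assoc_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_assoc_matrix <- function(am, path, sep = ",") {
  stopifnot(inherits(am, "assoc_matrix"))
  write.table(data.frame(individual_id = colnames(am$hwi), am$hwi,
                         check.names = FALSE),
              path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Edge list of an association matrix
#'
#' One row per unordered dyad with its HWI and joint-sighting count;
#' suitable for sociogram drawing or import into network tools. An
#' optional minimum HWI keeps only the stronger edges (sociograms
#' conventionally show associations at or above some cut-off such as
#' 0.30).
#'
#' @param am an `assoc_matrix`.
#' @param min_hwi keep dyads with `hwi >= min_hwi`; default 0 drops only
#'   zero-weight and undefined dyads.
#' @return Data frame with columns `id1`, `id2`, `hwi`, `x`.
#' @export
assoc_edgelist <- function(am, min_hwi = 0) {
  stopifnot(inherits(am, "assoc_matrix"))
  iu <- which(upper.tri(am$hwi), arr.ind = TRUE)
  v <- am$hwi[iu]
  keep <- !is.na(v) & v > 0 & v >= min_hwi
  ids <- colnames(am$hwi)
  out <- data.frame(id1 = ids[iu[keep, 1]], id2 = ids[iu[keep, 2]],
                    hwi = v[keep], x = am$x[iu[keep, , drop = FALSE]],
                    stringsAsFactors = FALSE)
  out[order(-out$hwi), , drop = FALSE]
}
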