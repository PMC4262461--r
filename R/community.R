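#' Average-linkage dendrogram of an association matrix
#'
#' Agglomerative hierarchical clustering of the individuals with average
#' linkage, operating on similarity = HWI (internally converted to the
#' distance `1 - HWI`; all reported heights are re-expressed in similarity
#' units, so a merge at height 0.6 means the merged clusters share a mean
#' association of 0.6). Undefined dyads are treated as zero association.
#' Ties are resolved deterministically by label order.
#'
#' @param am an `assoc_matrix` with at least 2 individuals.
#' @return Object of class `assoc_dendrogram`: list with `hclust` (the
#'   underlying tree, heights in distance units) and `merge_similarity`
#'   (heights in HWI units, non-increasing along the merge sequence).
#' @export
average_linkage <- function(am) {
  stopifnot(inherits(am, "assoc_matrix"))
  w <- assoc_weights(am)
  if (ncol(w) < 2) stop("need at least 2 individuals to cluster")
  hc <- hclust(as.dist(1 - w), method = "average")
  structure(list(hclust = hc, merge_similarity = 1 - hc$height,
                 labels = colnames(w)),
            class = "assoc_dendrogram")
}

#' @export
print.assoc_dendrogram <- function(x, ...) {
  cat(sprintf("average-linkage dendrogram of %d individuals; merges at similarity %.3f-%.3f\n",
              length(x$labels), max(x$merge_similarity),
              min(x$merge_similarity)))
  invisible(x)
}

#' Cophenetic correlation of a dendrogram with its association matrix
#'
#' Pearson correlation between the off-diagonal association indices and
#' the similarity at which each pair joins the dendrogram. Values of at
#' least 0.80 are conventionally read as the dendrogram being a good
#' representation of the association structure.
#'
#' @param dend an `assoc_dendrogram` built from `am`.
#' @param am the `assoc_matrix` the dendrogram was built from.
#' @return List with `correlation` and `good_match` (`correlation >= 0.8`).
#' @export
cophenetic_correlation <- function(dend, am) {
  stopifnot(inherits(dend, "assoc_dendrogram"), inherits(am, "assoc_matrix"))
  w <- assoc_weights(am)
  coph_sim <- 1 - as.matrix(cophenetic(dend$hclust))
  coph_sim <- coph_sim[colnames(w), colnames(w)]
  v1 <- offdiag_values(w)
  v2 <- offdiag_values(coph_sim)
  if (sd(v1) == 0) stop("constant association matrix: correlation undefined")
  r <- cor(v1, v2)
  list(correlation = r, good_match = r >= 0.8)
}

#' Newman modularity of a community partition
#'
#' Weighted modularity
#' \deqn{Q = \sum_c \left[\frac{W_c}{W} -
#'       \left(\frac{G_c}{\sum_i g_i}\right)^2\right],}
#' where \eqn{W} is the total edge weight, \eqn{W_c} the weight inside
#' community \eqn{c}, and \eqn{g_i} a per-individual gregariousness whose
#' community sums \eqn{G_c} define the null expectation. With the default
#' `type = "standard"`, \eqn{g_i} is the strength (sum of association
#' indices), which gives the usual weighted Newman Q. With
#' `type = "gregariousness"` the null is controlled for how much each
#' individual associates in the *sampling* sense: \eqn{g_i} is its total
#' co-occurrence count (supply `greg` to use another measure). A single
#' community scores exactly 0 under both types.
#'
#' @param am an `assoc_matrix`.
#' @param partition community labels, one per individual (any type
#'   coercible to factor), in matrix column order or named by individual.
#' @param type `"standard"` or `"gregariousness"`.
#' @param greg optional per-individual gregariousness vector overriding
#'   the `type` default.
#' @return The modularity Q (numeric scalar).
#' @export
modularity_q <- function(am, partition, type = c("standard",
                                                 "gregariousness"),
                         greg = NULL) {
  type <- match.arg(type)
  w <- assoc_weights(am)
  n <- ncol(w)
  partition <- align_partition(partition, colnames(w))
  if (is.null(greg)) {
    greg <- if (type == "standard") rowSums(w) else rowSums(am$x)
  }
  W <- sum(w) / 2
  if (W == 0 || sum(greg) == 0) return(0)
  comms <- split(seq_len(n), partition)
  sum(vapply(comms, function(idx) {
    Wc <- sum(w[idx, idx, drop = FALSE]) / 2
    Gc <- sum(greg[idx])
    Wc / W - (Gc / sum(greg))^2
  }, numeric(1)))
}

align_partition <- function(partition, labels) {
  if (!is.null(names(partition))) {
    if (!all(labels %in% names(partition))) {
      stop("partition does not cover all individuals")
    }
    partition <- partition[labels]
  } else if (length(partition) != length(labels)) {
    stop("partition must assign a community to every individual")
  }
  factor(partition)
}

#' Modularity-maximising dendrogram cut
#'
#' Evaluates the modularity of the partition induced at every merge
#' height of the dendrogram and returns the cut that maximises Q
#' (candidate partitions are restricted to dendrogram cuts). Ties are
#' broken toward fewer communities. A Q of at least 0.3 is conventionally
#' required for a division to be considered useful; lower maxima are
#' still returned, flagged as such.
#'
#' @param dend an `assoc_dendrogram`.
#' @param am the `assoc_matrix` it was built from.
#' @param type,greg passed to [modularity_q()].
#' @return Object of class `community_partition`: list with `communities`
#'   (named vector of unit labels), `q` (the maximised modularity),
#'   `cut_similarity` (the association index at which the division
#'   occurs), `n_communities`, `modularity_by_k` (Q for every candidate
#'   cut), `useful` (`q >= 0.3`) and `modularity_type`.
#' @export
best_cut <- function(dend, am, type = c("standard", "gregariousness"),
                     greg = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(dend, "assoc_dendrogram"))
  hc <- dend$hclust
  n <- length(dend$labels)
  ks <- seq_len(n)
  qs <- vapply(ks, function(k) {
    modularity_q(am, cutree(hc, k = k), type = type, greg = greg)
  }, numeric(1))
  best_k <- ks[which.max(qs)]          # which.max takes the first (fewest
  q <- qs[best_k]                      # communities) among exact ties
  communities <- cutree(hc, k = best_k)
  cut_sim <- if (best_k == 1) min(dend$merge_similarity) else
    dend$merge_similarity[n - best_k + 1]
  structure(list(communities = communities, q = q,
                 cut_similarity = cut_sim, n_communities = best_k,
                 modularity_by_k = setNames(qs, ks), useful = q >= 0.3,
                 modularity_type = type),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community division: %d unit(s), modularity Q = %.3f (%s)\n",
              x$n_communities, x$q,
              if (x$useful) "useful division, Q >= 0.3"
              else "not high enough to represent useful community divisions"))
  sizes <- table(x$communities)
  cat("  unit sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Within- and between-unit association summary
#'
#' Mean HWI within each social unit and between each pair of units, the
#' usual contrast when comparing cohesion of the recovered communities.
#'
#' @param am an `assoc_matrix`.
#' @param partition community labels (as in [modularity_q()]).
#' @return Data frame with columns `unit1`, `unit2`, `n_dyads`,
#'   `mean_hwi`, `max_hwi`.
#' @export
unit_contrasts <- function(am, partition) {
  w <- am$hwi
  partition <- align_partition(partition, colnames(w))
  iu <- which(upper.tri(w), arr.ind = TRUE)
  u1 <- as.character(partition[iu[, 1]])
  u2 <- as.character(partition[iu[, 2]])
  key <- paste(pmin(u1, u2), pmax(u1, u2), sep = "|")
  v <- w[iu]
  out <- do.call(rbind, lapply(split(v, key), function(z)
    data.frame(n_dyads = length(z), mean_hwi = mean(z, na.rm = TRUE),
               max_hwi = max(z, na.rm = TRUE))))
  parts <- strsplit(rownames(out), "|", fixed = TRUE)
  out <- cbind(unit1 = vapply(parts, `[`, "", 1),
               unit2 = vapply(parts, `[`, "", 2), out)
  rownames(out) <- NULL
  out
}

#' Export a dendrogram as newick text
#'
#' Writes the average-linkage tree in newick format. Branch lengths are in
#' the dendrogram's native distance units (`1 - HWI`), so tip-to-ancestor
#' depth corresponds to dissimilarity; the merge similarities themselves
#' are available as `dend$merge_similarity`.
#'
#' @param dend an `assoc_dendrogram`.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "assoc_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
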