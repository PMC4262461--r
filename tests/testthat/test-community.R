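test_that("average linkage merges by mean similarity with hand-checked heights", {
  # AB = 0.8, AC = BC = 0.2: AB merge first, C joins at (0.2 + 0.2)/2
  w <- matrix(c(NA, 0.8, 0.2,
                0.8, NA, 0.2,
                0.2, 0.2, NA), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- average_linkage(assoc_from_weights(w))
  expect_equal(dend$merge_similarity, c(0.8, 0.2))

  # two 2-cliques with zero between-association: final merge at 0
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 0.9
  w2[3, 4] <- w2[4, 3] <- 0.7
  diag(w2) <- NA
  dimnames(w2) <- list(letters[1:4], letters[1:4])
  d2 <- average_linkage(assoc_from_weights(w2))
  expect_equal(sort(d2$merge_similarity), c(0, 0.7, 0.9))
  expect_equal(min(d2$merge_similarity), 0)

  # random matrices: same tree as a naive agglomerative oracle
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    wr <- matrix(runif(n * n), n, n); wr <- (wr + t(wr)) / 2; diag(wr) <- NA
    dimnames(wr) <- list(sprintf("I%d", 1:n), sprintf("I%d", 1:n))
    am <- assoc_from_weights(wr)
    dr <- average_linkage(am)
    coph_pkg <- 1 - as.matrix(cophenetic(dr$hclust))
    coph_pkg <- coph_pkg[colnames(wr), colnames(wr)]
    coph_oracle <- brute_average_linkage(wr)
    diag(coph_pkg) <- NA
    expect_equal(coph_pkg, coph_oracle, tolerance = 1e-9)
    # heights are monotone non-increasing in similarity
    expect_true(all(diff(dr$merge_similarity) <= 1e-12))
  }
})

test_that("cophenetic correlation is exact for ultrametric matrices and matches its oracle", {
  # build an ultrametric similarity matrix from a known tree
  w <- matrix(0.1, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[3, 4] <- w[4, 3] <- 0.6
  diag(w) <- NA
  dimnames(w) <- list(letters[1:4], letters[1:4])
  am <- assoc_from_weights(w)
  dend <- average_linkage(am)
  res <- cophenetic_correlation(dend, am)
  expect_equal(res$correlation, 1)
  expect_true(res$good_match)

  set.seed(31)
  n <- 7
  wr <- matrix(runif(n * n), n, n); wr <- (wr + t(wr)) / 2; diag(wr) <- NA
  dimnames(wr) <- list(sprintf("I%d", 1:n), sprintf("I%d", 1:n))
  am2 <- assoc_from_weights(wr)
  d2 <- average_linkage(am2)
  r2 <- cophenetic_correlation(d2, am2)
  coph <- brute_average_linkage(wr)
  expect_equal(r2$correlation,
               cor(wr[upper.tri(wr)], coph[upper.tri(coph)]))

  wc <- matrix(0.5, 3, 3); diag(wc) <- NA
  dimnames(wc) <- list(letters[1:3], letters[1:3])
  amc <- assoc_from_weights(wc)
  expect_error(cophenetic_correlation(average_linkage(amc), amc),
               "constant")
})

test_that("modularity matches closed forms and the brute-force evaluator", {
  # one community: exactly zero, both types
  set.seed(41)
  n <- 6
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- NA
  dimnames(w) <- list(sprintf("I%d", 1:n), sprintf("I%d", 1:n))
  am <- assoc_from_weights(w)
  one <- rep(1, n)
  expect_equal(modularity_q(am, one), 0)
  expect_equal(modularity_q(am, one, type = "gregariousness"), 0)

  # two equal disconnected components split correctly: Q = 1/2
  wd <- matrix(0, 6, 6)
  wd[1:3, 1:3] <- 0.4; wd[4:6, 4:6] <- 0.4; diag(wd) <- NA
  dimnames(wd) <- list(sprintf("I%d", 1:6), sprintf("I%d", 1:6))
  amd <- assoc_from_weights(wd)
  expect_equal(modularity_q(amd, c(1, 1, 1, 2, 2, 2)), 0.5)

  # random (matrix, partition) pairs agree with the edge-sum oracle
  for (rep in 1:50) {
    nn <- sample(4:9, 1)
    wr <- matrix(runif(nn * nn), nn, nn); wr <- (wr + t(wr)) / 2
    diag(wr) <- NA
    dimnames(wr) <- list(sprintf("I%d", 1:nn), sprintf("I%d", 1:nn))
    part <- sample(1:3, nn, replace = TRUE)
    expect_equal(modularity_q(assoc_from_weights(wr), part),
                 brute_modularity(wr, part), tolerance = 1e-12)
  }

  # named partitions are aligned by label
  p <- setNames(c(1, 1, 1, 2, 2, 2), sprintf("I%d", 1:6))
  expect_equal(modularity_q(amd, p[sample(6)]), 0.5)
  expect_error(modularity_q(amd, p[1:5]), "cover")
})

test_that("the modularity-maximising cut recovers planted units and degenerates sanely", {
  # planted two-block matrix: the cut recovers the blocks
  set.seed(51)
  w <- matrix(runif(64, 0, 0.05), 8, 8)
  w[1:4, 1:4] <- w[1:4, 1:4] + 0.6
  w[5:8, 5:8] <- w[5:8, 5:8] + 0.6
  w <- (w + t(w)) / 2; diag(w) <- NA
  dimnames(w) <- list(sprintf("I%d", 1:8), sprintf("I%d", 1:8))
  am <- assoc_from_weights(w)
  dend <- average_linkage(am)
  cut <- best_cut(dend, am)
  expect_equal(cut$n_communities, 2)
  expect_equal(rand_index(cut$communities, rep(1:2, each = 4)), 1)
  expect_gt(cut$q, 0.3)
  expect_true(cut$useful)
  # the cut similarity is the level at which the two units would join
  expect_equal(cut$cut_similarity, min(dend$merge_similarity))

  # uniform matrix: no structure, single community, Q about zero
  wu <- matrix(0.4, 6, 6); diag(wu) <- NA
  dimnames(wu) <- list(sprintf("I%d", 1:6), sprintf("I%d", 1:6))
  amu <- assoc_from_weights(wu)
  cutu <- best_cut(average_linkage(amu), amu)
  expect_equal(cutu$n_communities, 1)
  expect_equal(cutu$q, 0)
  expect_false(cutu$useful)

  # boundary cuts: k = n gives singletons, k = 1 one community
  expect_equal(length(unique(cutree(dend$hclust, k = 8))), 8)
  expect_equal(length(unique(cutree(dend$hclust, k = 1))), 1)
  expect_equal(length(cut$modularity_by_k), 8)

  # a low-Q division is still reported, flagged as not useful
  set.seed(52)
  wl <- matrix(runif(49, 0.3, 0.5), 7, 7); wl <- (wl + t(wl)) / 2
  diag(wl) <- NA
  dimnames(wl) <- list(sprintf("I%d", 1:7), sprintf("I%d", 1:7))
  aml <- assoc_from_weights(wl)
  cutl <- best_cut(average_linkage(aml), aml)
  expect_lt(cutl$q, 0.3)
  expect_false(cutl$useful)
})

test_that("unit contrasts and newick export describe the division", {
  w <- matrix(0.1, 6, 6)
  w[1:3, 1:3] <- 0.7; w[4:6, 4:6] <- 0.5; diag(w) <- NA
  dimnames(w) <- list(sprintf("I%d", 1:6), sprintf("I%d", 1:6))
  am <- assoc_from_weights(w)
  ct <- unit_contrasts(am, c(1, 1, 1, 2, 2, 2))
  within1 <- ct[ct$unit1 == "1" & ct$unit2 == "1", ]
  between <- ct[ct$unit1 == "1" & ct$unit2 == "2", ]
  expect_equal(within1$mean_hwi, 0.7)
  expect_equal(between$mean_hwi, 0.1)
  expect_equal(within1$n_dyads, 3)
  expect_equal(between$n_dyads, 9)

  dend <- average_linkage(am)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(w))
})
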