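test_that("strength, clustering and affinity match hand and brute-force values", {
  # 3-clique with all HWIs 0.5: strength 1, clustering 1 scaled by wmax
  w <- matrix(0.5, 3, 3); diag(w) <- NA
  dimnames(w) <- list(c("A", "B", "C"), c("A", "B", "C"))
  am <- assoc_from_weights(w)
  expect_equal(unname(node_strength(am)), rep(1, 3))
  # binary triangle: clustering 1 everywhere
  wb <- matrix(1, 3, 3); diag(wb) <- NA
  expect_equal(unname(clustering_coefficient(assoc_from_weights(wb))),
               rep(1, 3))
  # path A-B-C: the middle vertex closes no triangle
  wp <- matrix(0, 3, 3); wp[1, 2] <- wp[2, 1] <- 1; wp[2, 3] <- wp[3, 2] <- 1
  diag(wp) <- NA
  cc <- clustering_coefficient(assoc_from_weights(wp))
  expect_equal(unname(cc[2]), 0)
  # isolated individual: zero strength, masked affinity
  wi <- matrix(0, 3, 3); wi[1, 2] <- wi[2, 1] <- 0.4; diag(wi) <- NA
  am_i <- assoc_from_weights(wi)
  expect_equal(unname(node_strength(am_i))[3], 0)
  expect_true(is.na(affinity(am_i)[3]))

  # regular graph: affinity equals the common strength
  wr <- matrix(0.2, 5, 5); diag(wr) <- NA
  ar <- assoc_from_weights(wr)
  expect_equal(unname(affinity(ar)), rep(0.8, 5))

  # 4-node star, hand computed: centre strength 3w, leaves w;
  # centre affinity = leaf strength = w; leaf affinity = centre strength
  ws <- matrix(0, 4, 4); ws[1, 2:4] <- 0.3; ws[2:4, 1] <- 0.3; diag(ws) <- NA
  as_ <- assoc_from_weights(ws)
  expect_equal(unname(node_strength(as_)), c(0.9, 0.3, 0.3, 0.3))
  expect_equal(unname(affinity(as_)), c(0.3, 0.9, 0.9, 0.9))

  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    wrnd <- matrix(runif(n * n), n, n); wrnd <- (wrnd + t(wrnd)) / 2
    diag(wrnd) <- NA
    arnd <- assoc_from_weights(wrnd)
    expect_equal(unname(node_strength(arnd)), unname(brute_strength(wrnd)))
    expect_equal(unname(clustering_coefficient(arnd)),
                 unname(brute_clustering(wrnd)))
    expect_equal(unname(affinity(arnd)), unname(brute_affinity(wrnd)))
    # relabelling invariance
    p <- sample(n)
    wp2 <- wrnd[p, p]
    expect_equal(unname(node_strength(assoc_from_weights(wp2))),
                 unname(node_strength(arnd))[p])
  }
})

test_that("high-strength individuals connect to high-strength partners in assortative networks", {
  soc <- generate_society(society_config(seed = 8, n_seasons = 1,
                                         days_per_season = 80,
                                         detection_prob = 0.6))
  gbi <- build_gbi(apply_inclusion_filters(
    daily_dedup(simulate_sightings(soc)))$table)
  am <- hwi_matrix(gbi)
  s <- node_strength(am)
  a <- affinity(am)
  ok <- !is.na(a)
  expect_gt(cor(s[ok], a[ok]), 0)
})

test_that("metric significance is seeded and flags planted modular structure", {
  # two fully separated constant companionships: the starkest modular
  # structure the permutation null can be confronted with
  soc <- generate_society(society_config(seed = 13, n_individuals = 18,
                                         clique_size = 9,
                                         n_communities = 2,
                                         cc_fraction = 1, ca_fraction = 0,
                                         n_seasons = 1,
                                         days_per_season = 100,
                                         between_unit_mixing = 0,
                                         residency_probs = c(r = 0.7),
                                         n_calves = 0, id_prob = 1,
                                         strangers_rate = 0,
                                         detection_prob = 0.9))
  gbi <- build_gbi(apply_inclusion_filters(
    daily_dedup(simulate_sightings(soc)))$table)
  r1 <- metric_significance(gbi, "clustering", n_permutations = 300,
                            flips_per_permutation = 50, burn_in = 500,
                            seed = 4)
  r2 <- metric_significance(gbi, "clustering", n_permutations = 300,
                            flips_per_permutation = 50, burn_in = 500,
                            seed = 4)
  expect_identical(r1$p_two_sided, r2$p_two_sided)
  # within fully closed companionships every associate pair is mutual, so
  # the observed clustering (1) exceeds anything the permutation null,
  # which mixes the two units, can produce
  expect_equal(r1$observed, 1)
  expect_gt(r1$observed, r1$null_mean)
  expect_lt(r1$p_two_sided, 0.05)
})

test_that("bootstrap SEs behave like sampling errors", {
  g <- gbi_from_days(list(list(c("A", "B", "C"))))
  expect_warning(se0 <- bootstrap_se(g, "strength", n_boot = 20),
                 "degenerate")
  expect_equal(unname(se0), c(0, 0, 0))

  set.seed(3)
  m <- random_gbi_matrix(20, 8)
  g1 <- gbi_from_days(list(list("A")))   # scaffold, replaced below
  g1$matrix <- m
  g1$period <- as.Date("2010-01-01") + seq_len(nrow(m))
  se1 <- bootstrap_se(g1, "strength", n_boot = 400, seed = 10)
  expect_identical(se1, bootstrap_se(g1, "strength", n_boot = 400, seed = 10))

  # doubling every group shrinks the SE by about 1/sqrt(2)
  g2 <- g1
  g2$matrix <- rbind(m, m)
  g2$period <- c(g1$period, g1$period)
  se2 <- bootstrap_se(g2, "strength", n_boot = 400, seed = 11)
  ratio <- mean(se2 / se1, na.rm = TRUE)
  expect_gt(ratio, 1 / sqrt(2) - 0.15)
  expect_lt(ratio, 1 / sqrt(2) + 0.15)
})

test_that("social differentiation recovers homogeneous and structured regimes", {
  # identical dyads: exactly zero
  n_dyads <- 40
  res0 <- social_differentiation(x = rep(3, n_dyads), n = rep(30, n_dyads))
  expect_equal(res0$S, 0)
  expect_false(res0$well_differentiated)

  # near-homogeneous simulated dyads: estimate shrinks toward zero
  set.seed(5)
  x_h <- rbinom(200, 50, 0.3)
  res_h <- social_differentiation(x = x_h, n = rep(50, 200))
  expect_lt(res_h$S, 0.2)

  # beta-distributed truth: estimate near the closed-form CV, flag set
  a <- 2; b <- 5
  true_cv <- sqrt(b / (a * (a + b + 1)))
  set.seed(6)
  p <- rbeta(300, a, b)
  x_b <- rbinom(300, 30, p)
  res_b <- social_differentiation(x = x_b, n = rep(30, 300))
  expect_equal(res_b$S, true_cv, tolerance = 0.12)
  expect_true(res_b$well_differentiated)
  expect_gt(res_b$S_mom, 0.3)

  # matrix route with jackknife SE
  set.seed(12)
  gm <- build_gbi(apply_inclusion_filters(daily_dedup(
    simulate_sightings(generate_society(society_config(
      seed = 12, n_seasons = 1, days_per_season = 60,
      detection_prob = 0.6)))))$table)
  am <- hwi_matrix(gm)
  res_m <- social_differentiation(am)
  expect_gt(res_m$S, 0)
  expect_true(is.finite(res_m$se))
  expect_gt(res_m$se, 0)
})
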