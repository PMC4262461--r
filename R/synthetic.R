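# Fission-fusion society simulator with planted ground truth.
#
# The generative model mirrors how small coastal dolphin societies are
# described: permanent cliques ("constant companions") that surface and
# travel together; pairs of cliques that fuse into a larger group for a
# bout whose duration decays exponentially ("casual acquaintances"); and
# occasional one-day aggregations of otherwise unrelated groups ("rapid
# disassociation"). Cliques belong to social communities, and bout
# partners are drawn preferentially within the community, which plants a
# two-block association structure on top of the clique structure.

#' Configure a synthetic fission-fusion society
#'
#' Defaults emulate a small, seasonally surveyed photo-identification
#' study: 33 marked individuals in 11 cliques of 3, two social communities,
#' eight 14-day summer survey seasons a year apart, residency classes from
#' occasional to very frequent, roughly 100 recorded group sightings,
#' mean observed group size near 5, and association dynamics mixing
#' constant companions with casual acquaintances lasting a few days.
#'
#' `cc_fraction`, `ca_fraction` and `ca_decay_per_day` set the *realized*
#' lagged association rate of the society: g(tau) ~= cc + ca *
#' exp(-decay * tau), the remaining share dissolving within a day. The
#' generator internally corrects bout formation rates for the probability
#' that two cliques re-fuse by chance, so the planted curve is what the
#' estimator should recover.
#'
#' @param n_individuals number of marked individuals (calves extra).
#' @param clique_size individuals per permanent clique (must divide
#'   `n_individuals`).
#' @param n_communities number of planted social units.
#' @param between_unit_mixing relative weight of a cross-community bout
#'   partner (0 = fully separated units).
#' @param cc_fraction,ca_fraction,ca_decay_per_day planted lagged
#'   association rate components (fractions sum to at most 1; the rest is
#'   rapid disassociation). Decay is per day.
#' @param n_seasons,days_per_season,season_spacing_days survey calendar;
#'   one season of `n` days with spacing 0 gives `n` consecutive days.
#' @param residency_probs named per-class daily surfacing probabilities
#'   of a clique; classes are assigned to cliques cyclically.
#' @param detection_prob probability that a surfaced group is recorded on
#'   a survey day.
#' @param id_prob per-member photo-identification probability within a
#'   recorded group.
#' @param strangers_rate Poisson mean of unidentifiable extra animals per
#'   group (inflates observed group size only).
#' @param n_calves number of dependent calves, each attached to a random
#'   female and emitted with age class `C`.
#' @param calf_presence probability a calf accompanies its mother's group.
#' @param trammel_prob per-community probability that a recorded group
#'   has a trammel net within 100 m (recycled over communities).
#' @param preference_free if `TRUE`, ignore all social structure: each
#'   individual surfaces independently and groups are a random partition
#'   of the day's individuals (the null model for calibration studies).
#' @param mean_group_size target group size for the preference-free
#'   partition.
#' @param seed default seed used by [simulate_sightings()].
#' @return List of class `society_config`.
#' @export
society_config <- function(n_individuals = 33, clique_size = 3,
                           n_communities = 2, between_unit_mixing = 0.05,
                           cc_fraction = 0.4, ca_fraction = 0.3,
                           ca_decay_per_day = 0.3,
                           n_seasons = 8, days_per_season = 14,
                           season_spacing_days = 365,
                           residency_probs = c(very_frequent = 0.9,
                                               frequent = 0.65,
                                               low_frequent = 0.45,
                                               rare = 0.25,
                                               occasional = 0.05),
                           detection_prob = 0.25, id_prob = 0.95,
                           strangers_rate = 0.3, n_calves = 2,
                           calf_presence = 0.9,
                           trammel_prob = c(0.30, 0.45),
                           preference_free = FALSE, mean_group_size = 5,
                           seed = 1L) {
  stopifnot(n_individuals >= 2, clique_size >= 1,
            n_individuals %% clique_size == 0,
            cc_fraction >= 0, ca_fraction >= 0,
            cc_fraction + ca_fraction <= 1,
            ca_decay_per_day > 0, n_seasons >= 1, days_per_season >= 1,
            all(residency_probs >= 0 & residency_probs <= 1),
            detection_prob > 0, detection_prob <= 1)
  structure(as.list(environment()), class = "society_config")
}

survey_dates <- function(config) {
  starts <- as.Date("2005-06-15") +
    (seq_len(config$n_seasons) - 1) * config$season_spacing_days
  as.Date(unlist(lapply(starts, function(s)
    seq(s, by = 1, length.out = config$days_per_season))),
    origin = "1970-01-01")
}

# Daily clique-level fission-fusion dynamics: bouts (fused clique pairs
# with exponential lifetime), surfacing, and one-day contacts between
# surfaced solo cliques. Returns one record per day: the surfaced groups
# (vectors of clique ids), their types ("solo"/"bout"/"contact"), and the
# surfaced-clique indicator. Shared by the sighting simulator and by the
# rate calibration pilot.
sim_clique_days <- function(n_days, U, clique_presence, clique_comm,
                            rho, lambda, delta, mixing) {
  partner <- rep(NA_integer_, U)
  target_pairs <- rho * U / 2
  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    paired <- which(!is.na(partner) & seq_len(U) < partner)
    for (k in paired) {
      if (runif(1) < delta) {
        partner[partner[k]] <- NA_integer_
        partner[k] <- NA_integer_
      }
    }
    n_pairs <- sum(!is.na(partner)) / 2
    want <- floor(target_pairs + runif(1))
    free <- which(is.na(partner))
    while (n_pairs < want && length(free) >= 2) {
      a <- free[sample.int(length(free), 1)]
      others <- setdiff(free, a)
      w <- ifelse(clique_comm[others] == clique_comm[a], 1, mixing)
      if (sum(w) == 0) break
      b <- others[sample.int(length(others), 1, prob = w)]
      partner[a] <- b; partner[b] <- a
      free <- setdiff(free, c(a, b))
      n_pairs <- n_pairs + 1
    }
    # surfacing: solo cliques independently, fused pairs jointly at the
    # rarer member's rate
    groups <- list(); types <- character(0)
    for (k in seq_len(U)) {
      if (!is.na(partner[k])) {
        if (k < partner[k] &&
            runif(1) < min(clique_presence[k],
                           clique_presence[partner[k]])) {
          groups[[length(groups) + 1]] <- c(k, partner[k])
          types <- c(types, "bout")
        }
      } else if (runif(1) < clique_presence[k]) {
        groups[[length(groups) + 1]] <- k
        types <- c(types, "solo")
      }
    }
    # one-day contacts between surfaced solo cliques (at most one per
    # clique per day, community-weighted like bout formation)
    solo_idx <- which(types == "solo")
    n_events <- min(rpois(1, lambda), floor(length(solo_idx) / 2))
    for (e in seq_len(n_events)) {
      if (length(solo_idx) < 2) break
      a <- solo_idx[sample.int(length(solo_idx), 1)]
      others <- setdiff(solo_idx, a)
      comm_a <- clique_comm[groups[[a]][1]]
      w <- ifelse(clique_comm[vapply(groups[others], `[`, 0L, 1)] == comm_a,
                  1, mixing)
      if (sum(w) == 0) break
      b <- others[sample.int(length(others), 1, prob = w)]
      groups[[a]] <- c(groups[[a]], groups[[b]])
      types[a] <- "contact"
      groups[[b]] <- integer(0)
      solo_idx <- setdiff(solo_idx, c(a, b))
    }
    keep <- vapply(groups, length, 0L) > 0
    present <- rep(FALSE, U)
    present[unlist(groups)] <- TRUE
    out[[d]] <- list(groups = groups[keep], types = types[keep],
                     present = present)
  }
  out
}

# Measure, from a pilot run of the clique dynamics, the realized dyad-day
# composition (constant companions / bout / contact) and the chance-
# re-fusion floor q: the probability that a specific cross-clique pair is
# together on a day, given that the first clique surfaced (the stationary
# long-lag association rate of cross dyads).
pilot_composition <- function(days, u, U) {
  wcc <- choose(u, 2)
  cc <- ca <- rd <- 0
  together <- matrix(0, U, U)
  present_days <- rep(0, U)
  for (day in days) {
    present_days <- present_days + day$present
    cc <- cc + sum(day$present) * wcc
    for (g in seq_along(day$groups)) {
      grp <- day$groups[[g]]
      if (length(grp) < 2) next
      if (day$types[g] == "bout") ca <- ca + u^2 else rd <- rd + u^2
      for (a in grp) for (b in grp) if (a != b) {
        together[a, b] <- together[a, b] + 1
      }
    }
  }
  num <- 0; den <- 0
  for (i in seq_len(U)) {
    for (j in seq_len(U)) {
      if (i == j || together[i, j] == 0 || present_days[i] == 0) next
      num <- num + together[i, j] * (together[i, j] / present_days[i])
      den <- den + together[i, j]
    }
  }
  list(cc = cc, ca = ca, rd = rd, q = if (den > 0) num / den else 0)
}

# Solve bout-formation rates so the realized LAR matches the configured
# components, with a first-order correction for chance re-fusion of two
# cliques (which adds a constant floor to cross-clique association).
solve_bout_rates <- function(config, p_bar) {
  u <- config$clique_size
  U <- config$n_individuals / u
  cc <- config$cc_fraction; ca <- config$ca_fraction
  rd <- 1 - cc - ca
  if (u < 2) {                     # no within-clique dyads: all mass is CA/RD
    cc <- 0
  }
  if (U < 2 || (ca == 0 && rd == 0)) {
    return(list(rho = 0, rd_rate = 0, q = 0))
  }
  wcc <- choose(u, 2)
  q <- 0
  rho <- 0; lambda <- 0
  for (it in 1:25) {
    cc_adj <- max((cc - q) / (1 - q), 0.01)
    ca_adj <- ca / (1 - q)
    rd_adj <- max(1 - cc_adj - ca_adj, 0)
    if (wcc > 0) {
      rho <- min((ca_adj / cc_adj) * (2 * wcc / u^2), 0.9)
      lambda <- (rd_adj / cc_adj) * (p_bar * U * wcc) / u^2
    } else {
      # clique size 1: scale against a nominal per-capita rate
      rho <- min(ca_adj, 0.9)
      lambda <- rd_adj * p_bar * U / 2
    }
    # chance that a specific clique pair is together anyway: via an
    # ongoing bout, or via a one-day contact among free surfaced cliques
    m_free <- max(p_bar * U * (1 - rho), 2)
    q_new <- rho / (U - 1) + 2 * lambda / (m_free * (m_free - 1))
    if (abs(q_new - q) < 1e-10) break
    q <- q_new
  }
  list(rho = rho, rd_rate = lambda, q = q)
}

#' Generate a society with planted ground truth
#'
#' Assigns individuals to permanent cliques, cliques to communities and
#' residency classes, draws sex and age attributes, and precomputes the
#' bout-formation rates that realise the configured association dynamics.
#'
#' @param config a `society_config`.
#' @return Object of class `society`: list with `individuals` (id,
#'   clique, community, sex, age_class, residency_class, presence_prob),
#'   `calves` (id, mother), `expected_propensity` (matrix of daily
#'   association probabilities given co-presence), `lar_truth`
#'   (`a2`, `a3`, `a1` of the planted lagged association rate),
#'   `bout` (internal rates) and `config`. Deterministic given
#'   `config$seed`.
#' @export
generate_society <- function(config) {
  stopifnot(inherits(config, "society_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  u <- config$clique_size
  U <- n / u
  ids <- sprintf("IND%02d", seq_len(n))
  clique <- rep(seq_len(U), each = u)
  community <- ((clique - 1) %% config$n_communities) + 1
  res_levels <- names(config$residency_probs)
  res_class <- res_levels[((seq_len(U) - 1) %% length(res_levels)) + 1]
  presence <- unname(config$residency_probs[res_class])

  # sex skewed by community: one female-biased unit, the rest male-biased
  sex <- character(n)
  for (i in seq_len(n)) {
    pr <- if (community[i] == 1) c(F = 0.55, M = 0.20, UN = 0.25)
          else c(F = 0.15, M = 0.60, UN = 0.25)
    sex[i] <- sample(names(pr), 1, prob = pr)
  }
  age <- sample(c("A", "J"), n, replace = TRUE, prob = c(0.7, 0.3))

  individuals <- data.frame(
    individual_id = ids, clique = clique, community = community,
    sex = sex, age_class = age, residency_class = res_class[clique],
    presence_prob = presence[clique], stringsAsFactors = FALSE)

  calves <- NULL
  if (config$n_calves > 0 && !config$preference_free) {
    mothers <- ids[sex == "F"]
    if (length(mothers) > 0) {
      calves <- data.frame(
        individual_id = sprintf("CALF%02d", seq_len(config$n_calves)),
        mother = sample(mothers, config$n_calves,
                        replace = config$n_calves > length(mothers)),
        stringsAsFactors = FALSE)
    }
  }

  p_bar <- mean(individuals$presence_prob[!duplicated(clique)])
  bout <- solve_bout_rates(config, p_bar)

  # Calibrate the analytic rates against a pilot run of the clique
  # dynamics: the approximations above ignore day-to-day fluctuation in
  # the surfaced pool and the exact conditioning of the lagged rate, so
  # the realized composition and re-fusion floor are measured and the
  # rates adjusted until the planted curve holds by construction.
  cc <- config$cc_fraction; ca <- config$ca_fraction
  delta <- 1 - exp(-config$ca_decay_per_day)
  if (!config$preference_free && U >= 2 && (bout$rho > 0 ||
                                            bout$rd_rate > 0)) {
    clique_presence <- individuals$presence_prob[!duplicated(clique)]
    clique_comm <- community[!duplicated(clique)]
    for (iter in 1:3) {
      pilot <- sim_clique_days(800, U, clique_presence, clique_comm,
                               bout$rho, bout$rd_rate, delta,
                               config$between_unit_mixing)
      st <- pilot_composition(pilot, u, U)
      q <- min(st$q, 0.9 * max(cc, 0.05))
      if (u >= 2 && st$cc > 0) {
        cc_adj <- max((cc - q) / (1 - q), 0.02)
        ca_adj <- ca / (1 - q)
        rd_adj <- max(1 - cc_adj - ca_adj, 0)
        if (st$ca > 0) {
          bout$rho <- min(bout$rho * (ca_adj / cc_adj) / (st$ca / st$cc),
                          0.9)
        }
        if (st$rd > 0) {
          bout$rd_rate <- bout$rd_rate *
            (rd_adj / cc_adj) / (st$rd / st$cc)
        }
      } else if (u == 1 && st$ca > 0 && st$rd > 0) {
        # no within-clique anchor: only the bout/contact ratio matters
        rd_target <- max(1 - cc - ca, 0)
        if (rd_target > 0 && ca > 0) {
          bout$rd_rate <- bout$rd_rate *
            (rd_target / ca) / (st$rd / st$ca)
        }
      }
      bout$q <- st$q
    }
  }

  # expected P(associated | both surfaced), the planted propensity matrix
  prop <- matrix(0, n, n, dimnames = list(ids, ids))
  same_clique <- outer(clique, clique, "==")
  same_comm <- outer(community, community, "==")
  cross <- bout$q
  prop[same_comm & !same_clique] <- cross
  prop[!same_comm] <- cross * config$between_unit_mixing
  prop[same_clique] <- 1
  diag(prop) <- NA
  if (config$preference_free) {
    prop[] <- NA
  }

  structure(list(individuals = individuals, calves = calves,
                 expected_propensity = prop,
                 lar_truth = c(a2 = config$cc_fraction,
                               a3 = config$ca_fraction,
                               a1 = config$ca_decay_per_day),
                 bout = bout, config = config),
            class = "society")
}

#' @export
print.society <- function(x, ...) {
  cat(sprintf("synthetic society: %d individuals, %d cliques, %d communities%s\n",
              nrow(x$individuals), length(unique(x$individuals$clique)),
              length(unique(x$individuals$community)),
              if (x$config$preference_free) " (preference-free)" else ""))
  invisible(x)
}

#' Planted community partition of a society
#' @param society a `society`.
#' @return Named integer vector: community per individual.
#' @export
true_partition <- function(society) {
  setNames(society$individuals$community, society$individuals$individual_id)
}

#' Planted clique (constant-companion) membership
#' @param society a `society`.
#' @return Named integer vector: clique per individual.
#' @export
true_cliques <- function(society) {
  setNames(society$individuals$clique, society$individuals$individual_id)
}

#' Simulate a sighting table from a society
#'
#' Runs the daily fission-fusion process over the survey calendar: cliques
#' surface according to their residency class; fused clique pairs (bouts)
#' surface and are recorded as one group; bouts dissolve each day with
#' probability `1 - exp(-ca_decay_per_day)` and new ones form,
#' preferentially within communities, to keep the planted association
#' composition; occasional one-day aggregations provide rapid
#' disassociation. Recorded groups get partial photo-identification,
#' unidentified extras, calves accompanying their mothers, and a
#' community-dependent trammel-net flag.
#'
#' In a `preference_free` society individuals surface independently and
#' each day's individuals are partitioned into groups at random, so no
#' dyad is preferred or avoided given daily availability.
#'
#' @param society a `society` from [generate_society()].
#' @param seed optional seed (defaults to `config$seed + 1` so a config
#'   fully determines both society and sightings).
#' @return A `sighting_table` (not yet de-duplicated or filtered; by
#'   construction each individual appears at most once per day).
#' @export
simulate_sightings <- function(society, seed = NULL) {
  stopifnot(inherits(society, "society"))
  config <- society$config
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  dates <- survey_dates(config)
  if (config$preference_free) {
    return(simulate_random_sightings(society, dates))
  }
  ind <- society$individuals
  u <- config$clique_size
  U <- nrow(ind) / u
  clique_members <- split(ind$individual_id, ind$clique)
  clique_comm <- ind$community[!duplicated(ind$clique)]
  clique_presence <- ind$presence_prob[!duplicated(ind$clique)]
  delta <- 1 - exp(-config$ca_decay_per_day)
  dyn <- sim_clique_days(length(dates), U, clique_presence, clique_comm,
                         society$bout$rho, society$bout$rd_rate, delta,
                         config$between_unit_mixing)

  rows <- list()
  for (d in seq_along(dates)) {
    # detection and recording
    gnum <- 0
    for (grp in dyn[[d]]$groups) {
      if (runif(1) > config$detection_prob) next
      gnum <- gnum + 1
      members <- unlist(clique_members[grp], use.names = FALSE)
      idd <- members[runif(length(members)) < config$id_prob]
      if (length(idd) == 0) idd <- members[sample.int(length(members), 1)]
      calf_rows <- character(0)
      if (!is.null(society$calves)) {
        with_mother <- society$calves$mother %in% idd &
          runif(nrow(society$calves)) < config$calf_presence
        calf_rows <- society$calves$individual_id[with_mother]
      }
      size <- length(members) + length(calf_rows) + rpois(1, config$strangers_rate)
      comm <- clique_comm[grp[1]]
      tp <- config$trammel_prob[((comm - 1) %% length(config$trammel_prob)) + 1]
      all_ids <- c(idd, calf_rows)
      idx <- match(all_ids, ind$individual_id)
      rows[[length(rows) + 1]] <- data.frame(
        date = dates[d], group_id = sprintf("G%02d", gnum),
        individual_id = all_ids,
        sex = ifelse(is.na(idx), "UN", ind$sex[idx]),
        age_class = ifelse(is.na(idx), "C", ind$age_class[idx]),
        group_size_observed = size,
        n_identified = length(all_ids),
        trammel_net = runif(1) < tp, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("simulation produced no sightings; raise detection_prob or presence")
  as_sighting_table(do.call(rbind, rows))
}

# Preference-free observation model: independent daily presence, random
# partition into groups of roughly the configured mean size.
simulate_random_sightings <- function(society, dates) {
  config <- society$config
  ind <- society$individuals
  rows <- list()
  for (d in seq_along(dates)) {
    here <- ind$individual_id[runif(nrow(ind)) < ind$presence_prob]
    if (length(here) < 1) next
    here <- sample(here)
    gnum <- 0
    while (length(here) > 0) {
      size <- min(1 + rpois(1, config$mean_group_size - 1), length(here))
      members <- here[seq_len(size)]
      here <- here[-seq_len(size)]
      if (runif(1) > config$detection_prob) next
      gnum <- gnum + 1
      idx <- match(members, ind$individual_id)
      rows[[length(rows) + 1]] <- data.frame(
        date = dates[d], group_id = sprintf("G%02d", gnum),
        individual_id = members, sex = ind$sex[idx],
        age_class = ind$age_class[idx],
        group_size_observed = length(members) +
          rpois(1, config$strangers_rate),
        n_identified = length(members),
        trammel_net = runif(1) < 0.35, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("simulation produced no sightings; raise detection_prob or presence")
  as_sighting_table(do.call(rbind, rows))
}
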