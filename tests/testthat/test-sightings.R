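test_that("delimited input parses, maps dialects, and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tiny_sightings()
  names(df) <- c("Date", "Grp", "ID", "Sex", "Age", "Size", "NID", "Net")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  tab <- read_sightings(path, dialect = list(
    date = "Date", group_id = "Grp", individual_id = "ID", sex = "Sex",
    age_class = "Age", group_size_observed = "Size", n_identified = "NID",
    trammel_net = "Net"))
  expect_s3_class(tab, "sighting_table")
  expect_equal(nrow(tab), 3)
  expect_equal(length(unique(paste(tab$date, tab$group_id))), 2)
  expect_setequal(unique(tab$individual_id), c("PHD1", "PHD2"))

  # write-then-read identity on a simulated table
  soc <- generate_society(society_config(seed = 42))
  sim <- simulate_sightings(soc)
  out <- withr::local_tempfile(fileext = ".csv")
  write_sightings(sim, out)
  back <- read_sightings(out)
  expect_equal(as.data.frame(back), as.data.frame(sim))
})

test_that("validation rejects malformed and contradictory records", {
  df <- tiny_sightings()
  df$sex[3] <- "M"                      # PHD1 is F on rows 1, M on row 3
  expect_error(as_sighting_table(df), "PHD1")
  df <- tiny_sightings()
  df$n_identified[1] <- 5L              # more identified than present
  expect_error(as_sighting_table(df), "n_identified")
  df <- tiny_sightings()
  df$individual_id[2] <- "PHD1"         # repeated within a group
  expect_error(as_sighting_table(df), "repeated")
  expect_error(read_sightings(withr::local_tempfile(fileext = ".csv")),
               "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_sightings(path), "missing required column")
})

test_that("daily de-duplication keeps the first group of the day and is idempotent", {
  df <- data.frame(
    date = as.Date("2010-06-01"),
    group_id = c("g1", "g1", "g2", "g2"),
    individual_id = c("A", "B", "A", "C"),   # A seen twice on the day
    sex = "UN", age_class = "A",
    group_size_observed = 2L, n_identified = 2L, trammel_net = FALSE,
    stringsAsFactors = FALSE)
  dd <- daily_dedup(as_sighting_table(df))
  expect_equal(sort(dd$group_id[dd$individual_id == "A"]), "g1")
  expect_equal(nrow(dd), 3)                 # C's membership in g2 untouched
  expect_true("C" %in% dd$individual_id[dd$group_id == "g2"])
  expect_equal(as.data.frame(daily_dedup(dd)), as.data.frame(dd))

  # an explicit time column overrides lexicographic group order
  df$time <- c("09:00", "09:00", "07:30", "07:30")
  dd2 <- daily_dedup(as_sighting_table(df))
  expect_equal(dd2$group_id[dd2$individual_id == "A"], "g2")

  # one sighting per day across days: a no-op
  soc <- generate_society(society_config(seed = 3))
  sim <- simulate_sightings(soc)
  expect_equal(nrow(daily_dedup(sim)), nrow(sim))

  # randomized overlapping groups: at most one occurrence per day each
  set.seed(11)
  rows <- do.call(rbind, lapply(1:3, function(g) data.frame(
    date = as.Date("2010-06-01"), group_id = paste0("g", g),
    individual_id = sample(LETTERS[1:8], 5),
    sex = "UN", age_class = "A", group_size_observed = 5L,
    n_identified = 5L, trammel_net = FALSE, stringsAsFactors = FALSE)))
  dd3 <- daily_dedup(as_sighting_table(rows))
  counts <- table(dd3$date, dd3$individual_id)
  expect_true(all(counts <= 1))
})

test_that("inclusion filters apply the coverage, calf and count rules in order", {
  mk_group <- function(date, gid, ids, size, nid, age = "A") data.frame(
    date = as.Date(date), group_id = gid, individual_id = ids,
    sex = "UN", age_class = age, group_size_observed = as.integer(size),
    n_identified = as.integer(nid), trammel_net = FALSE,
    stringsAsFactors = FALSE)
  # groups of 10 with 7 identified (0.7 < 0.8) are dropped; 8 with 4 kept
  base <- do.call(rbind, lapply(1:6, function(d)
    mk_group(as.Date("2010-06-01") + d, "g1", c("A", "B"), 2, 2)))
  big_bad <- mk_group("2010-06-20", "g9", LETTERS[1:7], 10, 7)
  big_ok <- mk_group("2010-06-21", "g9", LETTERS[1:4], 8, 4)
  tab <- daily_dedup(as_sighting_table(rbind(base, big_bad, big_ok)))
  res <- apply_inclusion_filters(tab, min_sightings = 1)
  expect_false(any(grepl("2010-06-20", paste(res$table$date))))
  expect_true(any(res$table$date == as.Date("2010-06-21")))
  expect_true(any(grepl("identified fraction", res$exclusions$reason)))

  # calves go, and the minimum sighting count is applied afterwards
  calf <- do.call(rbind, lapply(1:7, function(d)
    mk_group(as.Date("2010-07-01") + d, "g2", "CALF1", 1, 1, age = "C")))
  tab2 <- daily_dedup(as_sighting_table(rbind(base, calf)))
  res2 <- apply_inclusion_filters(tab2, min_sightings = 6)
  expect_false("CALF1" %in% res2$table$individual_id)
  expect_setequal(unique(res2$table$individual_id), c("A", "B"))

  # precondition: filters refuse tables not yet de-duplicated
  expect_error(apply_inclusion_filters(as_sighting_table(base)),
               "daily_dedup")
  # empty outcome is an explicit error
  expect_error(
    apply_inclusion_filters(daily_dedup(as_sighting_table(base)),
                            min_sightings = 100),
    "no analysable individuals")

  # a table built to leave exactly 23 qualifying individuals
  keep <- sprintf("K%02d", 1:23)
  drop <- sprintf("D%02d", 1:7)
  rows <- rbind(
    do.call(rbind, lapply(1:6, function(d)
      mk_group(as.Date("2011-06-01") + d, "g1", keep, 23, 23))),
    do.call(rbind, lapply(1:3, function(d)
      mk_group(as.Date("2011-07-01") + d, "g1", drop, 7, 7))))
  res3 <- apply_inclusion_filters(daily_dedup(as_sighting_table(rows)),
                                  large_group_size = 30)
  expect_equal(ncol(build_gbi(res3$table)$matrix), 23)
  # filtering never increases a sighting count
  before <- table(rows$individual_id)
  after <- table(res3$table$individual_id)
  expect_true(all(after[names(after)] <= before[names(after)]))
})

test_that("group-by-individual matrix has the right marginals and is deterministic", {
  df <- data.frame(
    date = as.Date("2010-06-01") + c(0, 0, 1, 1),
    group_id = "g1",
    individual_id = c("A", "B", "B", "C"),
    sex = "UN", age_class = "A", group_size_observed = 2L,
    n_identified = 2L, trammel_net = FALSE, stringsAsFactors = FALSE)
  g <- build_gbi(as_sighting_table(df))
  expect_equal(dim(g$matrix), c(2, 3))
  expect_equal(unname(colSums(g$matrix)), c(1, 2, 1))
  expect_equal(sum(g$matrix), nrow(df))

  soc <- generate_society(society_config(seed = 5))
  sim <- daily_dedup(simulate_sightings(soc))
  g2 <- build_gbi(sim)
  expect_equal(colSums(g2$matrix),
               c(table(sim$individual_id))[colnames(g2$matrix)])
  expect_equal(unname(rowSums(g2$matrix)),
               unname(g2$covariates$n_identified))
  expect_identical(g2$matrix, build_gbi(sim)$matrix)
})

test_that("residence profiles bin counts and compute annual fractions", {
  mk <- function(id, dates) data.frame(
    date = as.Date(dates), group_id = "g1", individual_id = id,
    sex = "UN", age_class = "A", group_size_observed = 3L,
    n_identified = 3L, trammel_net = FALSE, stringsAsFactors = FALSE)
  d1 <- as.Date("2005-06-01") + 0:36      # 37 sightings
  d2 <- as.Date("2005-06-01") + 0:2       # 3 sightings
  tab <- as_sighting_table(rbind(mk("VF", d1), mk("OC", d2)))
  prof <- residence_profiles(tab)
  expect_equal(as.character(prof$residence_class[prof$individual_id == "VF"]),
               "very_frequent")
  expect_equal(as.character(prof$residence_class[prof$individual_id == "OC"]),
               "occasional")
  # the printed bins leave a count of exactly 21 unclassified
  expect_true(is.na(residence_class(21)))
  expect_equal(as.character(residence_class(c(22, 20, 13, 9, 1))),
               c("very_frequent", "frequent", "low_frequent", "rare",
                 "occasional"))

  # annual residence: sightings of the individual / group sightings that year
  mk2 <- function(id, dates, gid) data.frame(
    date = as.Date(dates), group_id = gid, individual_id = id,
    sex = "UN", age_class = "A", group_size_observed = 2L,
    n_identified = 2L, trammel_net = FALSE, stringsAsFactors = FALSE)
  tab2 <- as_sighting_table(rbind(
    mk2("A", c("2005-06-01", "2005-06-02", "2006-06-01"), "g1"),
    mk2("B", c("2005-06-01", "2006-06-01", "2006-06-02"), "g1"),
    mk2("B", "2005-06-03", "g2")))
  # 2005 has 3 distinct group sightings, 2006 has 2
  prof2 <- residence_profiles(tab2)
  expect_equal(prof2$res_2005[prof2$individual_id == "A"], 2 / 3)
  expect_equal(prof2$res_2006[prof2$individual_id == "A"], 1 / 2)
  expect_equal(prof2$res_2005[prof2$individual_id == "B"], 2 / 3)
  expect_equal(prof2$res_2006[prof2$individual_id == "B"], 1)
})

test_that("attribute overrides reclassify individuals without touching the file", {
  tab <- as_sighting_table(tiny_sightings())
  tab2 <- override_attributes(tab, list(PHD2 = c(sex = "UN")))
  expect_true(all(tab2$sex[tab2$individual_id == "PHD2"] == "UN"))
  expect_warning(override_attributes(tab, list(NOPE = c(sex = "F"))),
                 "unknown individual")
})
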