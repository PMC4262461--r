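#' @useDynLib finsoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd cor var optim quantile cutree as.dist cophenetic
#'   hclust chisq.test rbinom rpois runif setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

SEX_LEVELS <- c("F", "M", "UN", "EM")
AGE_LEVELS <- c("A", "J", "C")

REQUIRED_COLUMNS <- c(
  "date", "group_id", "individual_id", "sex", "age_class",
  "group_size_observed", "n_identified", "trammel_net"
)

#' Construct a validated sighting table
#'
#' A sighting table is the long-format record all other stages consume: one
#' row per individual per group sighting, with the calendar date, a group
#' identifier unique within its date, the individual identifier, its sex
#' (`F`, `M`, `UN` for unknown, or `EM` for "estimated male"), age class
#' (`A` adult, `J` juvenile, `C` calf), the observed group size, the number
#' of group members that were photo-identified, and whether a trammel net
#' lay within 100 m of the group. An optional `time` column records
#' within-day observation order and is used to resolve "first sighting of
#' the day"; without it, groups are ordered lexicographically by
#' `group_id`.
#'
#' @param df data frame with at least the columns `date`, `group_id`,
#'   `individual_id`, `sex`, `age_class`, `group_size_observed`,
#'   `n_identified`, `trammel_net` (and optionally `time`).
#' @param deduped logical; marks the table as already passed through
#'   [daily_dedup()]. Used to enforce filter preconditions.
#' @return A `data.frame` of class `sighting_table`.
#' @seealso [read_sightings()], [daily_dedup()], [apply_inclusion_filters()]
#' @export
as_sighting_table <- function(df, deduped = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("sighting table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$date <- as.Date(df$date)
  for (col in c("group_id", "individual_id", "sex", "age_class")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$group_size_observed <- as.integer(df$group_size_observed)
  df$n_identified <- as.integer(df$n_identified)
  df$trammel_net <- as.logical(df$trammel_net)
  problems <- validate_sightings(df)
  if (length(problems) > 0) {
    stop("invalid sighting table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(df, class = c("sighting_table", "data.frame"), deduped = deduped)
}

# Returns a character vector of validation problems (empty when valid).
# Row numbers refer to rows of `df` (header excluded).
validate_sightings <- function(df) {
  problems <- character(0)
  bad_date <- which(is.na(df$date))
  if (length(bad_date) > 0) {
    problems <- c(problems, paste0("unparseable date on row(s) ",
                                   paste(head(bad_date, 5), collapse = ", ")))
  }
  bad_sex <- which(!df$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0) {
    problems <- c(problems, paste0(
      "sex must be one of ", paste(SEX_LEVELS, collapse = "/"),
      " on row(s) ", paste(head(bad_sex, 5), collapse = ", ")))
  }
  bad_age <- which(!df$age_class %in% AGE_LEVELS)
  if (length(bad_age) > 0) {
    problems <- c(problems, paste0(
      "age_class must be one of ", paste(AGE_LEVELS, collapse = "/"),
      " on row(s) ", paste(head(bad_age, 5), collapse = ", ")))
  }
  bad_size <- which(is.na(df$group_size_observed) | df$group_size_observed < 1L)
  if (length(bad_size) > 0) {
    problems <- c(problems, paste0("group_size_observed must be >= 1 on row(s) ",
                                   paste(head(bad_size, 5), collapse = ", ")))
  }
  bad_id_count <- which(!is.na(df$n_identified) & !is.na(df$group_size_observed) &
                          (df$n_identified < 0L |
                             df$n_identified > df$group_size_observed))
  if (length(bad_id_count) > 0) {
    problems <- c(problems, paste0(
      "n_identified must lie in [0, group_size_observed] on row(s) ",
      paste(head(bad_id_count, 5), collapse = ", ")))
  }
  # each individual at most once per group
  key <- paste(df$date, df$group_id, df$individual_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    problems <- c(problems, paste0(
      "individual repeated within a group on row(s) ",
      paste(head(dup, 5), collapse = ", ")))
  }
  # per-individual attributes constant across the table
  for (col in c("sex", "age_class")) {
    n_vals <- tapply(df[[col]], df$individual_id,
                     function(x) length(unique(x)))
    bad <- names(n_vals)[n_vals > 1]
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "contradictory ", col, " for individual(s): ",
        paste(bad, collapse = ", ")))
    }
  }
  # group covariates constant within a group
  gkey <- paste(df$date, df$group_id, sep = "\r")
  for (col in c("group_size_observed", "n_identified", "trammel_net")) {
    n_vals <- tapply(df[[col]], gkey, function(x) length(unique(x)))
    bad <- names(n_vals)[n_vals > 1]
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "covariate ", col, " varies within group(s): ",
        paste(gsub("\r", "/", head(bad, 5)), collapse = ", ")))
    }
  }
  problems
}

#' Read a sighting table from delimited text
#'
#' @param path path to a delimited text file with a header row; dates must
#'   be ISO-8601 (`YYYY-MM-DD`).
#' @param dialect optional named list/vector mapping canonical column names
#'   (see [as_sighting_table()]) to the column names used in the file,
#'   e.g. `list(individual_id = "ID", date = "Date")`.
#' @param sep field separator, comma by default.
#' @return A `sighting_table`.
#' @export
read_sightings <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src) > 0) {
      stop("dialect refers to column(s) absent from the file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(dialect)) {
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "),
         "; use `dialect` to map your column names", call. = FALSE)
  }
  as_sighting_table(raw)
}

#' Write a sighting table as delimited text
#'
#' @param table a `sighting_table`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_sightings <- function(table, path, sep = ",") {
  df <- as.data.frame(table)
  df$date <- format(df$date, "%Y-%m-%d")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only each individual's first sighting of the day
#'
#' Repeated sightings of the same individual within a day are serially
#' autocorrelated; only the first group of the day is retained for each
#' individual. "First" is resolved by the `time` column when present,
#' otherwise by lexicographic `group_id`. Memberships of other individuals
#' in later groups are unaffected, so group sizes in retained rows still
#' reflect the original field observation.
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @param table a `sighting_table`.
#' @return A `sighting_table` in which every individual occurs in at most
#'   one group per date, flagged as de-duplicated.
#' @export
daily_dedup <- function(table) {
  stopifnot(inherits(table, "sighting_table"))
  df <- as.data.frame(table)
  ord_key <- if ("time" %in% names(df)) as.character(df$time) else df$group_id
  ord <- order(df$date, ord_key, df$group_id, df$individual_id)
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(paste(df$date, df$individual_id, sep = "\r"))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_sighting_table(out, deduped = TRUE)
}

#' Apply the standard inclusion filters
#'
#' Applies, in a fixed order and in a single pass: (1) group-quality — for
#' groups larger than `large_group_size` individuals, only observations in
#' which at least `min_identified_frac` of members were photo-identified
#' are retained; (2) calf exclusion — calves associate with their mothers
#' rather than by choice; (3) minimum sighting count — individuals seen
#' fewer than `min_sightings` times after the previous steps are dropped.
#' Counts are not re-filtered after the final step, so per-individual
#' totals reported downstream are stable.
#'
#' @param table a de-duplicated `sighting_table` (see [daily_dedup()]).
#' @param min_sightings minimum number of (daily) sightings for an
#'   individual to enter association analyses; default 6.
#' @param exclude_calves drop rows of age class `C`; default `TRUE`.
#' @param large_group_size groups strictly larger than this are subject to
#'   the identification-coverage rule; default 8.
#' @param min_identified_frac minimum identified fraction for large groups;
#'   default 0.8.
#' @return A list with elements `table` (the filtered `sighting_table`) and
#'   `exclusions` (a data frame listing every excluded group or individual
#'   with its reason).
#' @export
apply_inclusion_filters <- function(table, min_sightings = 6,
                                    exclude_calves = TRUE,
                                    large_group_size = 8,
                                    min_identified_frac = 0.8) {
  stopifnot(inherits(table, "sighting_table"))
  if (!isTRUE(attr(table, "deduped"))) {
    stop("apply daily_dedup() before the inclusion filters", call. = FALSE)
  }
  df <- as.data.frame(table)
  exclusions <- data.frame(level = character(0), id = character(0),
                           reason = character(0), stringsAsFactors = FALSE)

  # 1. group quality: large groups with insufficient identification coverage
  gkey <- paste(df$date, df$group_id, sep = "/")
  ginfo <- df[!duplicated(gkey), c("date", "group_id", "group_size_observed",
                                   "n_identified")]
  gfrac <- ginfo$n_identified / ginfo$group_size_observed
  bad_groups <- ginfo[ginfo$group_size_observed > large_group_size &
                        gfrac < min_identified_frac, , drop = FALSE]
  if (nrow(bad_groups) > 0) {
    bad_keys <- paste(bad_groups$date, bad_groups$group_id, sep = "/")
    exclusions <- rbind(exclusions, data.frame(
      level = "group", id = bad_keys,
      reason = sprintf("identified fraction %.2f < %.2f in group of %d",
                       (bad_groups$n_identified /
                          bad_groups$group_size_observed),
                       min_identified_frac, bad_groups$group_size_observed),
      stringsAsFactors = FALSE))
    df <- df[!gkey %in% bad_keys, , drop = FALSE]
  }

  # 2. calves
  if (exclude_calves) {
    calves <- unique(df$individual_id[df$age_class == "C"])
    if (length(calves) > 0) {
      exclusions <- rbind(exclusions, data.frame(
        level = "individual", id = calves, reason = "calf",
        stringsAsFactors = FALSE))
      df <- df[!df$individual_id %in% calves, , drop = FALSE]
    }
  }

  # 3. minimum sighting count (single pass; not iterated to a fixed point)
  counts <- table(df$individual_id)
  rare <- names(counts)[counts < min_sightings]
  if (length(rare) > 0) {
    exclusions <- rbind(exclusions, data.frame(
      level = "individual", id = rare,
      reason = sprintf("only %d sighting(s) < %d",
                       as.integer(counts[rare]), min_sightings),
      stringsAsFactors = FALSE))
    df <- df[!df$individual_id %in% rare, , drop = FALSE]
  }

  if (nrow(df) == 0 || length(unique(df$individual_id)) == 0) {
    stop("no analysable individuals remain after filtering", call. = FALSE)
  }
  rownames(df) <- NULL
  list(table = as_sighting_table(df, deduped = TRUE), exclusions = exclusions)
}

#' Build the group-by-individual occurrence matrix
#'
#' Converts a (filtered) sighting table into the binary group-by-individual
#' (GBI) matrix on which association indices and the permutation null
#' operate: one row per group sighting, one column per individual, entry 1
#' when the individual was identified in the group. The daily sampling
#' period, group covariates and individual attributes are carried along.
#'
#' @param table a `sighting_table`.
#' @return An object of class `gbi`: a list with `matrix` (integer 0/1,
#'   rows labelled `date/group_id`, columns by individual), `period` (the
#'   `Date` of each row), `covariates` (per-row `trammel_net`,
#'   `group_size_observed`, `n_identified`), and `individuals` (per-column
#'   `individual_id`, `sex`, `age_class`).
#' @export
build_gbi <- function(table) {
  stopifnot(inherits(table, "sighting_table"))
  df <- as.data.frame(table)
  gkey <- paste(df$date, df$group_id, sep = "/")
  groups <- unique(gkey)
  inds <- sort(unique(df$individual_id))
  m <- matrix(0L, nrow = length(groups), ncol = length(inds),
              dimnames = list(groups, inds))
  m[cbind(match(gkey, groups), match(df$individual_id, inds))] <- 1L
  first <- !duplicated(gkey)
  covariates <- data.frame(
    trammel_net = df$trammel_net[first],
    group_size_observed = df$group_size_observed[first],
    n_identified = df$n_identified[first],
    row.names = groups, stringsAsFactors = FALSE)
  ind_first <- !duplicated(df$individual_id)
  ind_df <- df[ind_first, c("individual_id", "sex", "age_class")]
  ind_df <- ind_df[match(inds, ind_df$individual_id), , drop = FALSE]
  rownames(ind_df) <- NULL
  structure(list(matrix = m, period = df$date[first],
                 covariates = covariates, individuals = ind_df),
            class = "gbi")
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("group-by-individual matrix: %d groups x %d individuals, %d sampling days\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$period))))
  invisible(x)
}

RESIDENCE_LEVELS <- c("very_frequent", "frequent", "low_frequent",
                      "rare", "occasional")

# Sighting-count bins as conventionally printed: >21 / 14-20 / 10-13 / 4-9 /
# 1-3. A count of exactly 21 falls in none of the printed bins and is
# returned as NA rather than silently reassigned.
residence_class <- function(n) {
  cls <- rep(NA_character_, length(n))
  cls[n >= 1 & n <= 3] <- "occasional"
  cls[n >= 4 & n <= 9] <- "rare"
  cls[n >= 10 & n <= 13] <- "low_frequent"
  cls[n >= 14 & n <= 20] <- "frequent"
  cls[n > 21] <- "very_frequent"
  factor(cls, levels = RESIDENCE_LEVELS)
}

#' Per-individual residence profiles
#'
#' Summarises site fidelity and sighting context per individual: total
#' sighting count, residence class (`very_frequent` >21, `frequent` 14-20,
#' `low_frequent` 10-13, `rare` 4-9, `occasional` 1-3 sightings), annual
#' residence (the individual's sightings each year divided by the total
#' number of group sightings that year), the fraction of its sightings with
#' a trammel net within 100 m, and the fraction of its sightings in groups
#' larger than the pooled mean group size.
#'
#' @param table a `sighting_table` (filtered or not; the caller's choice).
#' @param pooled_mean_group_size cut-off between small and large groups;
#'   when `NULL` (default) it is computed as the mean observed size over
#'   the distinct groups in `table`.
#' @return A data frame with one row per individual; annual residence
#'   fractions appear as columns named `res_<year>`.
#' @export
residence_profiles <- function(table, pooled_mean_group_size = NULL) {
  stopifnot(inherits(table, "sighting_table"))
  df <- as.data.frame(table)
  gkey <- paste(df$date, df$group_id, sep = "/")
  first <- !duplicated(gkey)
  if (is.null(pooled_mean_group_size)) {
    pooled_mean_group_size <- mean(df$group_size_observed[first])
  }
  year <- format(df$date, "%Y")
  groups_per_year <- tapply(gkey[first], year[first],
                            function(x) length(unique(x)))
  inds <- sort(unique(df$individual_id))
  years <- sort(names(groups_per_year))
  res <- matrix(0, nrow = length(inds), ncol = length(years),
                dimnames = list(inds, years))
  cnt <- table(df$individual_id, year)
  res[rownames(cnt), colnames(cnt)] <- cnt
  res <- sweep(res, 2, as.numeric(groups_per_year[years]), "/")
  n_sightings <- as.integer(table(df$individual_id)[inds])
  big <- df$group_size_observed > pooled_mean_group_size
  out <- data.frame(
    individual_id = inds,
    n_sightings = n_sightings,
    residence_class = residence_class(n_sightings),
    pct_with_trammel = as.numeric(
      tapply(df$trammel_net, df$individual_id, mean)[inds]),
    pct_large_groups = as.numeric(tapply(big, df$individual_id, mean)[inds]),
    stringsAsFactors = FALSE)
  res_df <- as.data.frame(res)
  names(res_df) <- paste0("res_", years)
  out <- cbind(out, res_df)
  rownames(out) <- NULL
  attr(out, "pooled_mean_group_size") <- pooled_mean_group_size
  out
}

#' Override recorded individual attributes
#'
#' Supports caller-side data edits such as reclassifying "estimated male"
#' individuals as unknown sex before association analysis, without touching
#' the raw input.
#'
#' @param table a `sighting_table`.
#' @param overrides named list: `overrides[[individual_id]]` is a named
#'   character vector with entries among `sex` and `age_class`, e.g.
#'   `list(PHD2 = c(sex = "UN"))`.
#' @return The edited `sighting_table` (de-duplication flag preserved).
#' @export
override_attributes <- function(table, overrides) {
  stopifnot(inherits(table, "sighting_table"))
  df <- as.data.frame(table)
  for (id in names(overrides)) {
    rows <- df$individual_id == id
    if (!any(rows)) {
      warning("override for unknown individual: ", id)
      next
    }
    ov <- overrides[[id]]
    for (field in names(ov)) {
      stopifnot(field %in% c("sex", "age_class"))
      df[rows, field] <- ov[[field]]
    }
  }
  as_sighting_table(df, deduped = isTRUE(attr(table, "deduped")))
}
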