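IND_REQUIRED <- c("id", "species", "year", "plot", "subplot", "climate",
                  "management", "size_t0", "survived", "size_t1",
                  "reproductive", "seed_heads")
SUB_REQUIRED <- c("species", "year", "plot", "subplot", "climate",
                  "management", "seeds", "fall_seedlings", "spring_seedlings",
                  "total_seedlings", "new_plants")
HEAD_REQUIRED <- c("species", "plot", "seeds")

add_log_sizes <- function(ind) {
  ind$z <- log(ind$size_t0)
  ind$z1 <- ifelse(!is.na(ind$size_t1), log(ind$size_t1), NA_real_)
  ind
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s table: missing column(s) %s", what,
          paste(missing, collapse = ", "))
  }
}

#' Assemble and validate a census object
#'
#' Checks the schema and row-level invariants of the three census tables:
#' positive sizes (log size is taken on ingest), sizes present exactly for
#' survivors, zero seed heads on non-flowering plants, nonnegative counts,
#' fall + spring seedlings summing to the recorded total, and factor levels
#' drawn from the climate/management enumerations. Violations are reported
#' with their row numbers.
#'
#' @param individuals,subplots,seed_heads The three tables (data frames).
#' @return A validated object of class `census`, with log sizes `z`, `z1`
#'   added to the individual table.
#' @export
as_census <- function(individuals, subplots, seed_heads) {
  check_columns(individuals, IND_REQUIRED, "individual")
  check_columns(subplots, SUB_REQUIRED, "subplot")
  check_columns(seed_heads, HEAD_REQUIRED, "seed-head")
  individuals$survived <- as.logical(individuals$survived)
  individuals$reproductive <- as.logical(individuals$reproductive)
  if (!"is_new" %in% names(individuals)) individuals$is_new <- FALSE
  individuals$is_new <- as.logical(individuals$is_new)

  problems <- character()
  bad <- function(rows, msg) {
    if (length(rows)) {
      sprintf("%s (rows %s)", msg,
              paste(utils::head(rows, 10), collapse = ", "))
    } else character()
  }
  problems <- c(
    problems,
    bad(which(!is.finite(individuals$size_t0) | individuals$size_t0 <= 0),
        "size_t0 must be > 0"),
    bad(which(individuals$survived &
              (is.na(individuals$size_t1) | individuals$size_t1 <= 0)),
        "survivors need size_t1 > 0"),
    bad(which(!individuals$reproductive & individuals$seed_heads > 0),
        "seed_heads must be 0 for non-reproductive plants"),
    bad(which(individuals$seed_heads < 0), "seed_heads must be >= 0"),
    bad(which(!individuals$climate %in% CLIMATE_LEVELS),
        sprintf("climate must be one of %s",
                paste(CLIMATE_LEVELS, collapse = "/"))),
    bad(which(!individuals$management %in% MANAGEMENT_LEVELS),
        sprintf("management must be one of %s",
                paste(MANAGEMENT_LEVELS, collapse = "/")))
  )
  cnt_cols <- c("seeds", "fall_seedlings", "spring_seedlings",
                "total_seedlings", "new_plants")
  for (cc in cnt_cols) {
    problems <- c(problems,
                  if (length(w <- which(subplots[[cc]] < 0)))
                    sprintf("subplot table: %s must be >= 0 (rows %s)", cc,
                            paste(utils::head(w, 10), collapse = ", ")))
  }
  w <- which(subplots$total_seedlings !=
             subplots$fall_seedlings + subplots$spring_seedlings)
  if (length(w)) {
    problems <- c(problems,
                  sprintf("subplot table: total_seedlings != fall + spring (rows %s)",
                          paste(utils::head(w, 10), collapse = ", ")))
  }
  if (length(w <- which(seed_heads$seeds < 0))) {
    problems <- c(problems,
                  sprintf("seed-head table: seeds must be >= 0 (rows %s)",
                          paste(utils::head(w, 10), collapse = ", ")))
  }
  if (length(problems)) {
    stopf("census validation failed:\n  - %s",
          paste(problems, collapse = "\n  - "))
  }
  individuals <- add_log_sizes(individuals)
  structure(list(individuals = individuals, subplots = subplots,
                 seed_heads = seed_heads),
            class = "census")
}

#' Read / write a census as three CSV files
#'
#' Files are UTF-8 CSV with '.' decimal separator: `individuals.csv`,
#' `subplots.csv`, `seed_heads.csv` in `dir`. Reading validates all row
#' invariants via [as_census()]; writing drops the derived log-size columns
#' so that read-then-write is the identity on the stored fields.
#'
#' @param dir Directory containing (or to receive) the three files.
#' @param census A `census` object.
#' @return `read_census()` returns a validated `census`;
#'   `write_census()` returns `dir` invisibly.
#' @export
read_census <- function(dir) {
  paths <- file.path(dir, c("individuals.csv", "subplots.csv",
                            "seed_heads.csv"))
  for (p in paths) if (!file.exists(p)) stopf("file not found: %s", p)
  ind <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  sub <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  heads <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  as_census(ind, sub, heads)
}

#' @rdname read_census
#' @export
write_census <- function(census, dir) {
  stopifnot(inherits(census, "census"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ind <- census$individuals
  ind$z <- NULL
  ind$z1 <- NULL
  utils::write.csv(ind, file.path(dir, "individuals.csv"), row.names = FALSE)
  utils::write.csv(census$subplots, file.path(dir, "subplots.csv"),
                   row.names = FALSE)
  utils::write.csv(census$seed_heads, file.path(dir, "seed_heads.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Per-combination sample sizes
#'
#' @param census A `census` object.
#' @return A data frame of record counts per species x year x treatment
#'   combination.
#' @export
census_counts <- function(census) {
  ind <- census$individuals
  agg <- stats::aggregate(
    list(n = ind$id),
    by = list(species = ind$species, year = ind$year,
              climate = ind$climate, management = ind$management),
    FUN = length)
  agg[order(agg$species, agg$year, agg$climate, agg$management), ]
}

#' Quasi-extinction status of each species x treatment combination
#'
#' A stratum is flagged quasi-extinct in a census year when it holds fewer
#' than 25 individuals in total AND fewer than 10 flowering individuals
#' (both conditions strict, so exactly 25 or exactly 10 does not trigger
#' the flag). Quasi-extinct strata are skipped by downstream fitting.
#'
#' @param census A `census` object (or its individual table).
#' @param year Census year to evaluate; default the latest year present.
#' @return A data frame with one row per species x combination: `n_total`,
#'   `n_flowering`, `extinct`.
#' @export
quasi_extinct <- function(census, year = NULL) {
  ind <- if (inherits(census, "census")) census$individuals else census
  year <- year %||% max(ind$year)
  ind <- ind[ind$year == year, , drop = FALSE]
  combos <- treatment_combinations()
  species <- unique(ind$species)
  if (length(species) == 0L) species <- NA_character_
  grid <- merge(data.frame(species = species, stringsAsFactors = FALSE),
                combos)
  grid$n_total <- NA_integer_
  grid$n_flowering <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    sel <- ind$species == grid$species[i] &
      ind$climate == grid$climate[i] & ind$management == grid$management[i]
    grid$n_total[i] <- sum(sel)
    grid$n_flowering[i] <- sum(sel & ind$reproductive)
  }
  grid$year <- year
  grid$extinct <- grid$n_total < 25 & grid$n_flowering < 10
  grid[order(grid$species, grid$climate, grid$management), ]
}
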