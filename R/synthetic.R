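#' Design of a synthetic factorial census
#'
#' Describes the sampling design the generator emulates: a 2x2 factorial of
#' climate (ambient/future) by management (grazing/mowing), with replicate
#' plots (subunits) per combination, subplots nested in plots, a fixed number
#' of annual April-to-April transitions, an initial log-size distribution and
#' a seeds-per-head sampling scheme.
#'
#' Defaults mirror the field design the package targets: five plots per
#' combination, eight 50 x 50 cm subplots per plot, four annual transitions
#' starting in 2018, and per-combination cohort sizes of 1141, 1079, 1075 and
#' 1353 individuals (ambient-grazing, ambient-mowing, future-grazing,
#' future-mowing) matching the pooled census of a common perennial grass.
#'
#' @param n_individuals Named (or length-4 unnamed, canonical combination
#'   order) integer vector: first-year individuals per treatment combination.
#' @param n_plots Replicate plots per treatment combination.
#' @param n_subplots Subplots per plot.
#' @param n_years Number of annual transitions to simulate.
#' @param first_year Calendar year of the first census (t0 of transition 1).
#' @param init_mean,init_sd Mean and SD of the initial log-size distribution.
#' @param head_mean,head_dispersion Mean and negative-binomial dispersion
#'   (`size` parameter) of seeds per seed head. The seeds-per-head
#'   distribution is a modelling convenience of the generator, not a field
#'   estimate.
#' @param heads_sampled Seed heads sampled per plot for the lab seed counts
#'   (two or more).
#' @param species Species code written into every table.
#' @return A list of class `census_design`.
#' @export
census_design <- function(n_individuals = c(ambient.grazing = 1141,
                                            ambient.mowing = 1079,
                                            future.grazing = 1075,
                                            future.mowing = 1353),
                          n_plots = 5L, n_subplots = 8L, n_years = 4L,
                          first_year = 2018L,
                          init_mean = 1.0, init_sd = 0.8,
                          head_mean = 20, head_dispersion = 50,
                          heads_sampled = 10L, species = "SYN") {
  combos <- treatment_combinations()
  labs <- combo_label(combos$climate, combos$management)
  if (is.null(names(n_individuals))) {
    if (length(n_individuals) == 1L) {
      n_individuals <- rep(n_individuals, 4L)
    }
    names(n_individuals) <- labs
  }
  if (!all(labs %in% names(n_individuals))) {
    stopf("n_individuals must cover every treatment combination (%s)",
          paste(labs, collapse = ", "))
  }
  n_individuals <- n_individuals[labs]
  if (any(n_individuals < 1)) stopf("need >= 1 individual per combination")
  if (n_plots < 1 || n_subplots < 1) stopf("need >= 1 plot and subplot")
  if (n_years < 1) stopf("need >= 1 transition year")
  if (heads_sampled < 2) stopf("at least two seed heads are sampled per plot")
  if (init_sd <= 0) stopf("init_sd must be > 0")
  structure(list(
    n_individuals = n_individuals, n_plots = as.integer(n_plots),
    n_subplots = as.integer(n_subplots), n_years = as.integer(n_years),
    first_year = as.integer(first_year),
    init_mean = init_mean, init_sd = init_sd,
    head_mean = head_mean, head_dispersion = head_dispersion,
    heads_sampled = as.integer(heads_sampled), species = species
  ), class = "census_design")
}

#' Ground truth for the synthetic census generator
#'
#' Pairs a sampling design with one `vital_rate_params` set per treatment
#' combination (the generative model) and a random seed. All downstream
#' stages can then be tested against known truth.
#'
#' @param params A single [vital_rate_params()] object (recycled to all four
#'   combinations) or a named list with one set per combination label
#'   (`"ambient.grazing"`, ...).
#' @param design A [census_design()].
#' @param seed Integer seed driving the hierarchical random streams.
#' @return A list of class `census_truth` with elements `params` (named list
#'   of 4), `design` and `seed`.
#' @seealso [default_truth()], [simulate_census()]
#' @export
census_truth <- function(params, design = census_design(), seed = 1L) {
  combos <- treatment_combinations()
  labs <- combo_label(combos$climate, combos$management)
  if (inherits(params, "vital_rate_params") ||
      (is.numeric(params) && !is.null(names(params)))) {
    params <- stats::setNames(
      lapply(labs, function(l) as_vital_rate_params(params, label = l)), labs)
  } else {
    if (!all(labs %in% names(params))) {
      stopf("params must name every combination (%s)",
            paste(labs, collapse = ", "))
    }
    params <- stats::setNames(
      lapply(labs, function(l) as_vital_rate_params(params[[l]], label = l)),
      labs)
  }
  structure(list(params = params, design = design, seed = as.integer(seed)),
            class = "census_truth")
}

#' Default ground truth patterned on a persistent perennial grass
#'
#' A field-realistic parameterisation: size-dependent survival and flowering,
#' near-unit growth autoregression, seed output of order tens per flowering
#' plant, recruitment of a few percent per seed, and modest treatment
#' contrasts (future climate depresses survival; mowing raises seed output),
#' so treatment comparisons and LTRE decompositions are non-degenerate.
#'
#' @inheritParams census_truth
#' @param design A [census_design()].
#' @return A `census_truth`.
#' @export
default_truth <- function(design = census_design(), seed = 1L) {
  base <- c(
    surv_int = 0.5, surv_slope = 0.8,
    grow_int = 0.3, grow_slope = 0.9, grow_sd = 0.4,
    flow_int = -1.0, flow_slope = 1.2,
    seed_int = 2.0, seed_slope = 0.5,
    theta_f = 0.05, theta_s = 0.02, estab = 0.3,
    recruit_mean = -0.5, recruit_sd = 0.5
  )
  combos <- treatment_combinations()
  params <- lapply(seq_len(nrow(combos)), function(i) {
    p <- base
    if (combos$climate[i] == "future") p["surv_int"] <- p["surv_int"] - 0.15
    if (combos$management[i] == "mowing") {
      p["seed_int"] <- p["seed_int"] + 0.2
      p["flow_int"] <- p["flow_int"] + 0.1
    }
    p
  })
  names(params) <- combo_label(combos$climate, combos$management)
  census_truth(params, design = design, seed = seed)
}

draw_counts <- function(n, trials, rate) {
  ## Binomial thinning when the per-seed rate is a probability; Poisson when
  ## field ratios exceed 1 (seed input underestimated).
  if (rate <= 1) stats::rbinom(n, size = round(trials), prob = rate)
  else stats::rpois(n, lambda = rate * trials)
}

#' Simulate a factorial census with known ground truth
#'
#' Generates the three census tables (individual transitions, subplot seed
#' and seedling counts, per-plot seeds-per-head samples) under the
#' size-structured generative model: Bernoulli survival and flowering with
#' logit-linear size dependence, Gaussian growth on log size, seed heads with
#' Poisson counts scaled so a flowering plant's expected seed output is
#' `exp(seed_int + seed_slope * z)`, negative-binomial seeds per head,
#' binomial (or Poisson, for rates above 1) fall and spring recruitment from
#' subplot seed totals, binomial establishment of counted seedlings, and
#' Gaussian recruit log sizes. Recruits enter the individual table the
#' following April; survivors carry their size forward. Individuals keep
#' their plot and subplot, respecting the nested design.
#'
#' One integer seed drives a hierarchy of per-table, per-combination,
#' per-year streams, so regeneration is bit-identical given the seed.
#'
#' @param truth A [census_truth()].
#' @param seed Optional override of `truth$seed`.
#' @return An object of class `census`: a list with data frames
#'   `individuals`, `subplots` and `seed_heads`, carrying the truth as an
#'   attribute.
#' @examples
#' cen <- simulate_census(default_truth(census_design(
#'   n_individuals = 200, n_years = 1)))
#' head(cen$individuals)
#' @export
simulate_census <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "census_truth"))
  seed <- as.integer(seed %||% truth$seed)
  d <- truth$design
  combos <- treatment_combinations()
  years <- seq(d$first_year, length.out = d$n_years)

  ind_rows <- list()
  sub_rows <- list()
  id_counter <- 0L

  for (k in seq_len(nrow(combos))) {
    clim <- combos$climate[k]
    mgmt <- combos$management[k]
    lab <- combo_label(clim, mgmt)
    p <- truth$params[[lab]]
    plots <- sprintf("%s%s_%d", substr(clim, 1, 1), substr(mgmt, 1, 1),
                     seq_len(d$n_plots))
    subplots <- as.vector(t(outer(plots, seq_len(d$n_subplots),
                                  function(pl, s) sprintf("%s_s%d", pl, s))))
    plot_of <- rep(plots, each = d$n_subplots)

    ## initial cohort, spread round-robin over subplots
    set.seed(sub_seed(seed, lab, "init"))
    n0 <- d$n_individuals[[lab]]
    sp_idx <- rep_len(seq_along(subplots), n0)
    cohort <- data.frame(
      id = sprintf("%s_i%d", lab, id_counter + seq_len(n0)),
      plot = plot_of[sp_idx], subplot = subplots[sp_idx],
      z = stats::rnorm(n0, d$init_mean, d$init_sd),
      is_new = FALSE, stringsAsFactors = FALSE
    )
    id_counter <- id_counter + n0

    for (yr in years) {
      set.seed(sub_seed(seed, lab, yr, "transitions"))
      n <- nrow(cohort)
      z <- cohort$z
      survived <- stats::rbinom(n, 1, inv_logit(p[["surv_int"]] +
                                                p[["surv_slope"]] * z)) == 1
      z1 <- ifelse(survived,
                   stats::rnorm(n, p[["grow_int"]] + p[["grow_slope"]] * z,
                                p[["grow_sd"]]),
                   NA_real_)
      flowering <- stats::rbinom(n, 1, inv_logit(p[["flow_int"]] +
                                                 p[["flow_slope"]] * z)) == 1
      ## heads scaled so E[seeds | flowering] = exp(seed_int + seed_slope z)
      mu_seeds <- exp(p[["seed_int"]] + p[["seed_slope"]] * z)
      heads <- integer(n)
      heads[flowering] <- stats::rpois(sum(flowering),
                                       mu_seeds[flowering] / d$head_mean)
      seeds_total <- numeric(n)
      has_heads <- which(heads > 0)
      if (length(has_heads)) {
        per_head <- stats::rnbinom(sum(heads[has_heads]),
                                   size = d$head_dispersion,
                                   mu = d$head_mean)
        seeds_total[has_heads] <-
          vapply(split(per_head, rep(seq_along(has_heads), heads[has_heads])),
                 sum, numeric(1))
      }

      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        id = cohort$id, species = d$species, year = yr,
        plot = cohort$plot, subplot = cohort$subplot,
        climate = clim, management = mgmt,
        size_t0 = exp(z), survived = survived,
        size_t1 = ifelse(survived, exp(z1), NA_real_),
        reproductive = flowering, seed_heads = heads,
        seeds_total = seeds_total, is_new = cohort$is_new,
        stringsAsFactors = FALSE
      )

      ## subplot-level seed totals and seedling counts
      set.seed(sub_seed(seed, lab, yr, "recruitment"))
      seed_sum <- vapply(subplots, function(s) {
        sum(seeds_total[cohort$subplot == s])
      }, numeric(1), USE.NAMES = FALSE)
      rf <- mapply(function(s) draw_counts(1, s, p[["theta_f"]]), seed_sum)
      rs <- mapply(function(s) draw_counts(1, s, p[["theta_s"]]), seed_sum)
      rsum <- rf + rs
      ni <- stats::rbinom(length(rsum), rsum, min(p[["estab"]], 1))
      sub_rows[[length(sub_rows) + 1L]] <- data.frame(
        species = d$species, year = yr, plot = plot_of, subplot = subplots,
        climate = clim, management = mgmt,
        seeds = seed_sum, fall_seedlings = rf, spring_seedlings = rs,
        total_seedlings = rsum, new_plants = ni, stringsAsFactors = FALSE
      )

      ## next April's cohort: survivors plus established recruits
      if (yr < max(years)) {
        set.seed(sub_seed(seed, lab, yr, "recruit_sizes"))
        surv_cohort <- data.frame(
          id = cohort$id[survived], plot = cohort$plot[survived],
          subplot = cohort$subplot[survived], z = z1[survived],
          is_new = rep(FALSE, sum(survived)), stringsAsFactors = FALSE
        )
        n_new <- sum(ni)
        if (n_new > 0) {
          new_cohort <- data.frame(
            id = sprintf("%s_i%d", lab, id_counter + seq_len(n_new)),
            plot = rep(plot_of, ni), subplot = rep(subplots, ni),
            z = stats::rnorm(n_new, p[["recruit_mean"]], p[["recruit_sd"]]),
            is_new = TRUE, stringsAsFactors = FALSE
          )
          id_counter <- id_counter + n_new
          cohort <- rbind(surv_cohort, new_cohort)
        } else {
          cohort <- surv_cohort
        }
        if (nrow(cohort) == 0L) break
      }
    }
  }

  ## lab seed-head samples, per plot
  set.seed(sub_seed(seed, "seed_heads"))
  all_plots <- unlist(lapply(seq_len(nrow(combos)), function(k) {
    sprintf("%s%s_%d", substr(combos$climate[k], 1, 1),
            substr(combos$management[k], 1, 1), seq_len(d$n_plots))
  }))
  heads_tab <- data.frame(
    species = d$species,
    plot = rep(all_plots, each = d$heads_sampled),
    head_id = rep(seq_len(d$heads_sampled), length(all_plots)),
    seeds = stats::rnbinom(length(all_plots) * d$heads_sampled,
                           size = d$head_dispersion, mu = d$head_mean),
    stringsAsFactors = FALSE
  )

  individuals <- do.call(rbind, ind_rows)
  individuals <- add_log_sizes(individuals)
  subplots <- do.call(rbind, sub_rows)
  rownames(individuals) <- rownames(subplots) <- rownames(heads_tab) <- NULL
  structure(list(individuals = individuals, subplots = subplots,
                 seed_heads = heads_tab),
            class = "census", truth = truth)
}

#' @export
print.census <- function(x, ...) {
  cat("Census:", nrow(x$individuals), "individual-year records,",
      nrow(x$subplots), "subplot-year records,",
      nrow(x$seed_heads), "sampled seed heads\n")
  cat("  species:", paste(unique(x$individuals$species), collapse = ", "),
      "| years:", paste(sort(unique(x$individuals$year)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a ground-truth specification as YAML
#'
#' The file round-trips losslessly: design, per-combination parameters and
#' seed.
#'
#' @param truth A [census_truth()].
#' @param path File path.
#' @return `read_truth()` returns a `census_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "census_truth"))
  d <- truth$design
  obj <- list(
    seed = truth$seed,
    design = list(
      n_individuals = as.list(d$n_individuals),
      n_plots = d$n_plots, n_subplots = d$n_subplots,
      n_years = d$n_years, first_year = d$first_year,
      init_mean = d$init_mean, init_sd = d$init_sd,
      head_mean = d$head_mean, head_dispersion = d$head_dispersion,
      heads_sampled = d$heads_sampled, species = d$species
    ),
    params = lapply(truth$params, function(p) as.list(unclass(p)))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  d <- obj$design
  design <- census_design(
    n_individuals = unlist(d$n_individuals),
    n_plots = d$n_plots, n_subplots = d$n_subplots, n_years = d$n_years,
    first_year = d$first_year, init_mean = d$init_mean, init_sd = d$init_sd,
    head_mean = d$head_mean, head_dispersion = d$head_dispersion,
    heads_sampled = d$heads_sampled, species = d$species
  )
  census_truth(lapply(obj$params, unlist), design = design, seed = obj$seed)
}
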