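subset_census <- function(census, species = NULL, years = NULL) {
  ind <- census$individuals
  sub <- census$subplots
  heads <- census$seed_heads
  if (!is.null(species)) {
    ind <- ind[ind$species %in% species, , drop = FALSE]
    sub <- sub[sub$species %in% species, , drop = FALSE]
    heads <- heads[heads$species %in% species, , drop = FALSE]
  }
  if (!is.null(years)) {
    ind <- ind[ind$year %in% years, , drop = FALSE]
    sub <- sub[sub$year %in% years, , drop = FALSE]
  }
  structure(list(individuals = ind, subplots = sub, seed_heads = heads),
            class = "census")
}

STRATA_ALL <- c("ambient.grazing", "ambient.mowing", "future.grazing",
                "future.mowing", "ambient", "future", "grazing", "mowing")

#' Fit the full size-structured demographic model
#'
#' The one-call fit: estimates all seven vital-rate components from a
#' census (pooling transitions across years unless `years` restricts them),
#' assembles the 14-parameter set for each treatment combination and each
#' main effect, builds the two-stage IPM kernel for every stratum on a
#' common size domain, and computes the asymptotic growth rate lambda.
#'
#' Regression components are fitted jointly with full size x climate x
#' management interactions; main-effect parameter sets are parameter-wise
#' means of the two combinations sharing the level. Strata that are
#' quasi-extinct in the latest census year (fewer than 25 individuals and
#' fewer than 10 flowering) are reported and excluded from the lambda
#' table.
#'
#' @param census A `census` object (see [read_census()],
#'   [simulate_census()]).
#' @param species,years Optional subsetting before fitting; per-year fits
#'   reproduce yearly-transition models.
#' @param random_effects Include a `(1 | plot)` grouping term in the
#'   regression components (lme4); only population-level coefficients feed
#'   the kernel.
#' @param n_bins,eviction Kernel discretization, see [ipm_kernel()].
#' @param limits Optional `c(L, U)` log-size integration limits; default
#'   the observed range padded by half a growth SD ([size_limits()]).
#' @param theta_method Aggregation of the discrete rates, see
#'   [estimate_discrete_rates()].
#' @param drop_extinct Exclude quasi-extinct strata from kernels and the
#'   lambda table (default TRUE).
#' @return An object of class `ipm_fit` with components `params` (named
#'   list of 8 [vital_rate_params()]), `kernels`, `lambda` (data frame of
#'   lambda and log lambda per stratum), `limits`, `extinct`, and the call
#'   settings. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `simulate`, `residuals`.
#' @examples
#' cen <- simulate_census(default_truth(census_design(
#'   n_individuals = 400, n_years = 2)))
#' fit <- ipm_fit(cen, random_effects = FALSE)
#' fit
#' coef(fit, "ambient.grazing")
#' @export
ipm_fit <- function(census, species = NULL, years = NULL,
                    random_effects = TRUE, n_bins = 200L,
                    eviction = c("renorm", "none"), limits = NULL,
                    theta_method = c("subplot_mean", "pooled"),
                    drop_extinct = TRUE) {
  eviction <- match.arg(eviction)
  theta_method <- match.arg(theta_method)
  census <- subset_census(census, species, years)
  if (nrow(census$individuals) == 0L) stopf("no census records to fit")

  ext <- quasi_extinct(census)
  extinct_combos <- combo_label(ext$climate, ext$management)[ext$extinct]
  if (drop_extinct && length(extinct_combos)) {
    message("quasi-extinct strata excluded from lambda: ",
            paste(extinct_combos, collapse = ", "))
  }
  skip <- if (drop_extinct) extinct_combos else character()

  surv <- fit_survival(census, "factorial", random_effects)
  grow <- fit_growth(census, "factorial", random_effects)
  repr <- fit_reproduction(census, "factorial", random_effects)
  seeds <- fit_seeds(census, "factorial", random_effects)
  discrete <- estimate_discrete_rates(census, "factorial", theta_method)
  params <- extract_treatment_params(surv, grow, repr, seeds, discrete,
                                     skip = skip)
  if (!length(params)) stopf("no fittable strata remain")

  grow_sd <- mean(vapply(params[intersect(names(params), STRATA_ALL[1:4])],
                         function(p) p[["grow_sd"]], 0))
  limits <- limits %||% size_limits(census, grow_sd)

  kernels <- list()
  for (s in names(params)) {
    kernels[[s]] <- ipm_kernel(params[[s]], limits[1], limits[2],
                               n_bins = n_bins, eviction = eviction)
  }
  lam <- vapply(kernels, lambda, 0)
  lam_tab <- data.frame(stratum = names(kernels), lambda = unname(lam),
                        log_lambda = log(unname(lam)),
                        stringsAsFactors = FALSE)

  structure(list(params = params, kernels = kernels, lambda = lam_tab,
                 limits = limits, extinct = ext, census = census,
                 settings = list(n_bins = as.integer(n_bins),
                                 eviction = eviction,
                                 random_effects = random_effects,
                                 theta_method = theta_method,
                                 years = years, species = species)),
            class = "ipm_fit")
}

#' @export
print.ipm_fit <- function(x, digits = 4, ...) {
  cat("Two-stage IPM fit (", x$settings$n_bins, " bins on [",
      sprintf("%.3f", x$limits[1]), ", ", sprintf("%.3f", x$limits[2]),
      "])\n", sep = "")
  tab <- x$lambda
  tab$lambda <- round(tab$lambda, digits)
  tab$log_lambda <- round(tab$log_lambda, digits)
  print(tab, row.names = FALSE)
  if (any(x$extinct$extinct)) {
    cat("quasi-extinct strata:",
        paste(combo_label(x$extinct$climate, x$extinct$management)[
          x$extinct$extinct], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ipm_fit <- function(object, ...) {
  structure(list(fit = object,
                 params = do.call(rbind,
                                  lapply(object$params, as.data.frame))),
            class = "summary.ipm_fit")
}

#' @export
print.summary.ipm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nFitted parameters:\n")
  tab <- x$params
  tab$value <- round(tab$value, digits)
  if (!is.null(tab$se)) tab$se <- round(tab$se, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ipm_fit <- function(object, stratum = NULL, ...) {
  if (!is.null(stratum)) return(object$params[[stratum]])
  m <- vapply(object$params, as.numeric, numeric(length(PARAM_NAMES)))
  rownames(m) <- PARAM_NAMES
  m
}

#' Predicted vital rates at given sizes
#'
#' @param object An `ipm_fit`.
#' @param newdata Data frame with a `z` (log size) or `size_t0` column;
#'   default the fitted mesh.
#' @param type Which vital-rate curve to evaluate.
#' @param stratum Stratum label (default `"ambient.grazing"`).
#' @param ... Unused.
#' @return Numeric vector of predictions: survival or flowering probability,
#'   expected log size at t1, or expected seed count.
#' @export
predict.ipm_fit <- function(object, newdata = NULL,
                            type = c("survival", "growth", "reproduction",
                                     "seeds"),
                            stratum = "ambient.grazing", ...) {
  type <- match.arg(type)
  p <- object$params[[stratum]]
  if (is.null(p)) stopf("unknown stratum '%s'", stratum)
  z <- if (is.null(newdata)) object$kernels[[1]]$mesh
  else if (!is.null(newdata$z)) newdata$z
  else log(newdata$size_t0)
  switch(type,
         survival = inv_logit(p[["surv_int"]] + p[["surv_slope"]] * z),
         growth = p[["grow_int"]] + p[["grow_slope"]] * z,
         reproduction = inv_logit(p[["flow_int"]] + p[["flow_slope"]] * z),
         seeds = exp(p[["seed_int"]] + p[["seed_slope"]] * z))
}

#' @export
residuals.ipm_fit <- function(object, stratum = NULL, ...) {
  ind <- object$census$individuals
  ok <- ind$survived & !is.na(ind$z1)
  ind <- ind[ok, , drop = FALSE]
  lab <- combo_label(ind$climate, ind$management)
  if (!is.null(stratum)) {
    ind <- ind[lab == stratum, , drop = FALSE]
    lab <- lab[lab == stratum]
  }
  pred <- numeric(nrow(ind))
  for (s in unique(lab)) {
    p <- object$params[[s]]
    sel <- lab == s
    pred[sel] <- p[["grow_int"]] + p[["grow_slope"]] * ind$z[sel]
  }
  stats::setNames(ind$z1 - pred, ind$id)
}

#' @export
plot.ipm_fit <- function(x, stratum = "ambient.grazing", ...) {
  k <- x$kernels[[stratum]]
  if (is.null(k)) stopf("no kernel for stratum '%s'", stratum)
  B <- k$A[-1, -1]
  graphics::image(k$mesh, k$mesh, t(B),
                  xlab = "log size at t0", ylab = "log size at t1",
                  main = sprintf("%s kernel (lambda = %.3f)", stratum,
                                 lambda(k)), ...)
  invisible(x)
}

#' Simulate a census from the fitted parameters
#'
#' Uses the fitted per-combination parameter sets as ground truth for the
#' synthetic generator, yielding parametric-bootstrap-style replicate
#' censuses.
#'
#' @param object An `ipm_fit`.
#' @param nsim Number of censuses.
#' @param seed Base seed.
#' @param design A [census_design()]; default mirrors the fitted census's
#'   first-year per-combination sample sizes.
#' @param ... Unused.
#' @return A `census` (or a list of them when `nsim > 1`).
#' @export
simulate.ipm_fit <- function(object, nsim = 1, seed = 1L, design = NULL,
                             ...) {
  if (is.null(design)) {
    ind <- object$census$individuals
    y0 <- min(ind$year)
    first <- ind[ind$year == y0, , drop = FALSE]
    n0 <- table(factor(combo_label(first$climate, first$management),
                       levels = STRATA_ALL[1:4]))
    n0 <- pmax(as.integer(n0), 1L)
    names(n0) <- STRATA_ALL[1:4]
    design <- census_design(n_individuals = n0,
                            n_years = length(unique(ind$year)))
  }
  sims <- lapply(seq_len(nsim), function(i) {
    simulate_census(census_truth(object$params[1:4], design = design,
                                 seed = sub_seed(seed, "sim", i)))
  })
  if (nsim == 1) sims[[1]] else sims
}
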