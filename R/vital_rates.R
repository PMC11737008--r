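## ---- low-level fitters -----------------------------------------------------

## Logistic fit with a weakly ridge-penalized fallback for complete
## separation (all-0 or all-1 outcomes are common in small post-drought
## strata). X is a dense model matrix.
fit_logistic <- function(X, y, penalty = 1e-3) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  co <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(co)) || any(abs(co) > 12)
  if (!separated) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V)) separated <- TRUE
    else return(list(coef = co, vcov = V, separated = FALSE))
  }
  ## ridge-penalized maximum likelihood
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * penalty * sum(b^2)
  }
  gr <- function(b) {
    p <- inv_logit(drop(X %*% b))
    -drop(crossprod(X, y - p)) + penalty * b
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  co <- stats::setNames(opt$par, colnames(X))
  p <- inv_logit(drop(X %*% co))
  H <- crossprod(X * sqrt(p * (1 - p))) + diag(penalty, ncol(X))
  V <- solve(H)
  warnf("complete separation in a Bernoulli fit; ridge-penalized estimates returned")
  list(coef = co, vcov = V, separated = TRUE)
}

fit_poisson <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  fit$coefficients[is.na(fit$coefficients)] <- 0  # aliased columns
  w <- fit$weights
  V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = fit$coefficients, vcov = V, separated = FALSE)
}

fit_gaussian <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  fit$coefficients[is.na(fit$coefficients)] <- 0  # aliased columns
  rdf <- length(y) - fit$rank
  sigma <- if (rdf > 0) sqrt(sum(fit$residuals^2) / rdf) else 0
  if (rdf == 0) warnf("saturated growth fit: residual SD is 0")
  XtXi <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = fit$coefficients, vcov = sigma^2 * XtXi, sigma = sigma)
}

## ---- factorial model machinery --------------------------------------------

## Treatment-contrast coefficient names produced by ~ z * climate * management
FACT_TERMS <- c("(Intercept)", "z", "climatefuture", "managementmowing",
                "z:climatefuture", "z:managementmowing",
                "climatefuture:managementmowing",
                "z:climatefuture:managementmowing")

factorial_matrix <- function(data) {
  data$climate <- factor(data$climate, levels = CLIMATE_LEVELS)
  data$management <- factor(data$management, levels = MANAGEMENT_LEVELS)
  stats::model.matrix(~ z * climate * management, data = data)
}

## Contrast vectors assembling per-combination intercept and slope from the
## factorial coefficients (sums of main effects and interactions).
combo_contrast <- function(climate, management, which, terms) {
  f <- climate == "future"
  m <- management == "mowing"
  v <- stats::setNames(numeric(length(terms)), terms)
  if (which == "int") {
    v["(Intercept)"] <- 1
    if (f) v["climatefuture"] <- 1
    if (m) v["managementmowing"] <- 1
    if (f && m) v["climatefuture:managementmowing"] <- 1
  } else {
    v["z"] <- 1
    if (f) v["z:climatefuture"] <- 1
    if (m) v["z:managementmowing"] <- 1
    if (f && m) v["z:climatefuture:managementmowing"] <- 1
  }
  v
}

## Mixed-model fit with a plot grouping term (plots are nested in climate by
## construction: plot labels are unique). Falls back to the fixed-effects fit
## when the variance component is degenerate or the fit fails.
fit_factorial_mixed <- function(data, family) {
  data$climate <- factor(data$climate, levels = CLIMATE_LEVELS)
  data$management <- factor(data$management, levels = MANAGEMENT_LEVELS)
  res <- tryCatch({
    if (identical(family, "gaussian")) {
      fm <- suppressWarnings(suppressMessages(
        lme4::lmer(y ~ z * climate * management + (1 | plot), data = data,
                   REML = FALSE)))
    } else {
      fm <- suppressWarnings(suppressMessages(
        lme4::glmer(y ~ z * climate * management + (1 | plot), data = data,
                    family = family)))
    }
    if (lme4::isSingular(fm, tol = 1e-5)) {
      warnf("plot variance component is degenerate; refitting without it")
      NULL
    } else {
      co <- lme4::fixef(fm)
      V <- as.matrix(stats::vcov(fm))
      sigma <- if (identical(family, "gaussian")) stats::sigma(fm) else NULL
      list(coef = co, vcov = V, sigma = sigma, separated = FALSE)
    }
  }, error = function(e) {
    warnf("mixed-model fit failed (%s); using fixed-effects fit",
          conditionMessage(e))
    NULL
  })
  res
}

## One joint factorial fit of `y ~ z * climate * management`, returning
## per-combination (intercept, slope) with standard errors.
fit_factorial <- function(data, family = c("binomial", "poisson", "gaussian"),
                          random_effects = FALSE) {
  family <- match.arg(family)
  strata <- unique(data[, c("climate", "management")])
  single <- nrow(strata) == 1L
  fit <- if (random_effects && !single) fit_factorial_mixed(data, family)
  else NULL
  if (is.null(fit)) {
    X <- if (single) cbind("(Intercept)" = 1, z = data$z)
    else factorial_matrix(data)
    fit <- switch(family,
                  binomial = fit_logistic(X, data$y),
                  poisson = fit_poisson(X, data$y),
                  gaussian = fit_gaussian(X, data$y))
  }
  terms <- names(fit$coef)
  combos <- if (single) strata else treatment_combinations()
  out <- data.frame(climate = combos$climate, management = combos$management,
                    int = NA_real_, slope = NA_real_,
                    se_int = NA_real_, se_slope = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    if (single) {
      ci <- stats::setNames(c(1, 0), terms)
      cs <- stats::setNames(c(0, 1), terms)
    } else {
      ci <- combo_contrast(combos$climate[i], combos$management[i], "int",
                           terms)
      cs <- combo_contrast(combos$climate[i], combos$management[i], "slope",
                           terms)
    }
    out$int[i] <- sum(ci * fit$coef)
    out$slope[i] <- sum(cs * fit$coef)
    out$se_int[i] <- sqrt(drop(ci %*% fit$vcov %*% ci))
    out$se_slope[i] <- sqrt(drop(cs %*% fit$vcov %*% cs))
  }
  ## per-combination sample size
  out$n <- as.integer(table(factor(
    combo_label(data$climate, data$management),
    levels = combo_label(out$climate, out$management))))
  attr(out, "sigma") <- fit$sigma
  attr(out, "separated") <- isTRUE(fit$separated)
  out
}

## ---- the seven vital-rate components ---------------------------------------

vr_data <- function(census, rows, response) {
  ind <- census$individuals[rows, , drop = FALSE]
  data.frame(y = response, z = ind$z, climate = ind$climate,
             management = ind$management, plot = ind$plot,
             stringsAsFactors = FALSE)
}

#' Fit the size-dependent survival regression
#'
#' Logistic (Bernoulli, logit link) regression of survival to t1 on log size
#' at t0. Under `stratification = "factorial"` a single joint fit with full
#' size x climate x management interactions is used and per-combination
#' intercept/slope pairs are assembled from coefficient sums; `"none"` fits
#' one stratum ignoring treatments. With `random_effects = TRUE` a plot
#' grouping term (plots nested in climate) is included and only the
#' population-level coefficients are extracted. Complete separation triggers
#' a ridge-penalized fallback with a warning.
#'
#' @param census A `census` object.
#' @param stratification `"factorial"` or `"none"`.
#' @param random_effects Include a `(1 | plot)` term via lme4.
#' @return A data frame with one row per stratum: `int`, `slope`, standard
#'   errors and `n`.
#' @export
fit_survival <- function(census, stratification = c("factorial", "none"),
                         random_effects = FALSE) {
  stratification <- match.arg(stratification)
  ind <- census$individuals
  if (nrow(ind) < 2L) stopf("need at least 2 records to fit survival")
  d <- vr_data(census, seq_len(nrow(ind)), as.numeric(ind$survived))
  if (stratification == "none") d$climate <- d$management <- "pooled"
  fit_factorial(d, "binomial", random_effects)
}

#' Fit the growth regression
#'
#' Least-squares regression of log size at t1 on log size at t0, survivors
#' only; the residual SD is the growth SD of the kernel.
#'
#' @inheritParams fit_survival
#' @return A data frame per stratum with `int`, `slope`, `sd`, SEs and `n`.
#' @export
fit_growth <- function(census, stratification = c("factorial", "none"),
                       random_effects = FALSE) {
  stratification <- match.arg(stratification)
  rows <- which(census$individuals$survived &
                !is.na(census$individuals$z1))
  if (length(rows) < 3L) stopf("need at least 3 survivors to fit growth")
  d <- vr_data(census, rows, census$individuals$z1[rows])
  if (stratification == "none") d$climate <- d$management <- "pooled"
  out <- fit_factorial(d, "gaussian", random_effects)
  out$sd <- attr(out, "sigma")
  out
}

#' Fit the flowering-probability regression
#'
#' Logistic regression of reproductive status at t0 on log size; otherwise
#' identical in structure to [fit_survival()].
#'
#' @inheritParams fit_survival
#' @export
fit_reproduction <- function(census, stratification = c("factorial", "none"),
                             random_effects = FALSE) {
  stratification <- match.arg(stratification)
  ind <- census$individuals
  if (nrow(ind) < 2L) stopf("need at least 2 records to fit reproduction")
  d <- vr_data(census, seq_len(nrow(ind)), as.numeric(ind$reproductive))
  if (stratification == "none") d$climate <- d$management <- "pooled"
  fit_factorial(d, "binomial", random_effects)
}

## Per-individual seed counts: heads x mean seeds-per-head in the plot,
## falling back to the species-wide mean where a plot has no lab sample.
seed_estimates <- function(census) {
  ind <- census$individuals
  heads <- census$seed_heads
  plot_mean <- tapply(heads$seeds, heads$plot, mean)
  species_mean <- mean(heads$seeds)
  if (!length(heads$seeds) || !is.finite(species_mean)) {
    stopf("seed-head table is empty; cannot estimate seeds per head")
  }
  per_head <- as.numeric(plot_mean[ind$plot])
  missing <- is.na(per_head)
  if (any(missing)) {
    message(sum(missing), " record(s) in plots without seed-head samples; ",
            "species-wide mean seeds-per-head used")
    per_head[missing] <- species_mean
  }
  ind$seed_heads * per_head
}

#' Fit the seed-production regression
#'
#' Poisson regression (natural-log link) of per-individual seed count on log
#' size, flowering individuals only. Seed counts are estimated as seed heads
#' times the mean seeds-per-head measured in the same plot (species-wide
#' mean where a plot lacks lab samples), so they need not be integers; the
#' fit maximises the Poisson likelihood of these estimated counts.
#'
#' @inheritParams fit_survival
#' @export
fit_seeds <- function(census, stratification = c("factorial", "none"),
                      random_effects = FALSE) {
  stratification <- match.arg(stratification)
  counts <- seed_estimates(census)
  rows <- which(census$individuals$reproductive)
  if (!length(rows)) stopf("no reproductive individuals; cannot fit seeds")
  d <- vr_data(census, rows, counts[rows])
  if (stratification == "none") d$climate <- d$management <- "pooled"
  fit_factorial(d, "poisson", random_effects)
}

#' Estimate the discrete vital rates
#'
#' Fall recruitment `theta_f` and spring recruitment `theta_s` are means of
#' per-subplot seedlings-per-seed ratios over subplot-years with nonzero
#' seed totals; establishment `B` is the mean of per-subplot new-plants per
#' counted seedling over subplot-years with seedlings, clipped to 1 with a
#' warning if it exceeds 1. The recruit log-size distribution
#' (`recruit_mean`, `recruit_sd`) comes from individuals first recorded in
#' the stratum (`is_new`). `theta_method = "pooled"` instead uses the
#' ratio-of-totals estimator.
#'
#' @inheritParams fit_survival
#' @param theta_method `"subplot_mean"` (default) or `"pooled"`.
#' @return A data frame per stratum with `theta_f`, `theta_s`, `estab`,
#'   `recruit_mean`, `recruit_sd` and the subplot/recruit counts used.
#' @export
estimate_discrete_rates <- function(census,
                                    stratification = c("factorial", "none"),
                                    theta_method = c("subplot_mean",
                                                     "pooled")) {
  stratification <- match.arg(stratification)
  theta_method <- match.arg(theta_method)
  sub <- census$subplots
  ind <- census$individuals
  if (stratification == "none") {
    sub$climate <- sub$management <- "pooled"
    ind$climate <- ind$management <- "pooled"
    combos <- data.frame(climate = "pooled", management = "pooled",
                         stringsAsFactors = FALSE)
  } else {
    combos <- treatment_combinations()
  }
  out <- combos
  out$theta_f <- out$theta_s <- out$estab <- NA_real_
  out$recruit_mean <- out$recruit_sd <- NA_real_
  out$n_subplots <- out$n_recruits <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    s <- sub[sub$climate == combos$climate[i] &
             sub$management == combos$management[i], , drop = FALSE]
    with_seeds <- s$seeds > 0
    if (any(with_seeds)) {
      if (theta_method == "subplot_mean") {
        out$theta_f[i] <- mean(s$fall_seedlings[with_seeds] /
                               s$seeds[with_seeds])
        out$theta_s[i] <- mean(s$spring_seedlings[with_seeds] /
                               s$seeds[with_seeds])
      } else {
        out$theta_f[i] <- sum(s$fall_seedlings[with_seeds]) /
          sum(s$seeds[with_seeds])
        out$theta_s[i] <- sum(s$spring_seedlings[with_seeds]) /
          sum(s$seeds[with_seeds])
      }
    }
    with_sdl <- s$total_seedlings > 0
    if (any(with_sdl)) {
      b <- if (theta_method == "subplot_mean") {
        mean(s$new_plants[with_sdl] / s$total_seedlings[with_sdl])
      } else {
        sum(s$new_plants[with_sdl]) / sum(s$total_seedlings[with_sdl])
      }
      if (b > 1) {
        warnf("establishment estimate %.3g > 1; clipped to 1", b)
        b <- 1
      }
      out$estab[i] <- b
    }
    out$n_subplots[i] <- sum(with_seeds)
    zr <- ind$z[ind$is_new & ind$climate == combos$climate[i] &
                ind$management == combos$management[i]]
    out$n_recruits[i] <- length(zr)
    if (length(zr) >= 2L) {
      out$recruit_mean[i] <- mean(zr)
      out$recruit_sd[i] <- stats::sd(zr)
    }
  }
  out
}

## ---- parameter extraction ---------------------------------------------------

#' Assemble per-stratum parameter sets and main effects
#'
#' Collects the factorial fits of all seven vital-rate components into one
#' [vital_rate_params()] set per treatment combination, then builds the four
#' main-effect sets (ambient, future, grazing, mowing) by parameter-wise
#' averaging of the two combinations sharing the level — the averaging rule
#' operates on parameters, never on lambda.
#'
#' @param surv,grow,repr,seeds Outputs of the four regression fitters
#'   (factorial stratification).
#' @param discrete Output of [estimate_discrete_rates()].
#' @param skip Combination labels to leave out (e.g. quasi-extinct strata);
#'   a main effect whose member combination is skipped is omitted rather
#'   than an error.
#' @return A named list of up to 8 `vital_rate_params`: the four
#'   combinations (`"ambient.grazing"`, ...) and the four main effects
#'   (`"ambient"`, `"future"`, `"grazing"`, `"mowing"`). A missing
#'   combination not listed in `skip` is an error.
#' @export
extract_treatment_params <- function(surv, grow, repr, seeds, discrete,
                                     skip = character()) {
  combos <- treatment_combinations()
  labs <- combo_label(combos$climate, combos$management)
  pick <- function(df, i) {
    j <- which(df$climate == combos$climate[i] &
               df$management == combos$management[i])
    if (length(j) != 1L) {
      stopf("combination %s missing from a fitted component; main effects unavailable",
            labs[i])
    }
    df[j, , drop = FALSE]
  }
  out <- vector("list", 8L)
  names(out) <- c(labs, "ambient", "future", "grazing", "mowing")
  for (i in seq_len(nrow(combos))) {
    if (labs[i] %in% skip) next
    s <- pick(surv, i); g <- pick(grow, i); r <- pick(repr, i)
    f <- pick(seeds, i); dr <- pick(discrete, i)
    if (anyNA(c(dr$theta_f, dr$theta_s, dr$estab, dr$recruit_mean,
                dr$recruit_sd))) {
      stopf("combination %s: discrete rates unavailable (no admissible subplots or recruits)",
            labs[i])
    }
    se <- c(surv_int = s$se_int, surv_slope = s$se_slope,
            grow_int = g$se_int, grow_slope = g$se_slope, grow_sd = NA,
            flow_int = r$se_int, flow_slope = r$se_slope,
            seed_int = f$se_int, seed_slope = f$se_slope,
            theta_f = NA, theta_s = NA, estab = NA,
            recruit_mean = NA, recruit_sd = NA)
    n <- c(regression = s$n, subplots = dr$n_subplots,
           recruits = dr$n_recruits)
    out[[labs[i]]] <- vital_rate_params(
      surv_int = s$int, surv_slope = s$slope,
      grow_int = g$int, grow_slope = g$slope, grow_sd = g$sd,
      flow_int = r$int, flow_slope = r$slope,
      seed_int = f$int, seed_slope = f$slope,
      theta_f = dr$theta_f, theta_s = dr$theta_s, estab = dr$estab,
      recruit_mean = dr$recruit_mean, recruit_sd = dr$recruit_sd,
      label = labs[i], se = se, n = n)
  }
  main <- function(l1, l2, lab) {
    if (is.null(out[[l1]]) || is.null(out[[l2]])) return(NULL)
    average_params(out[[l1]], out[[l2]], label = lab)
  }
  out[["ambient"]] <- main("ambient.grazing", "ambient.mowing", "ambient")
  out[["future"]] <- main("future.grazing", "future.mowing", "future")
  out[["grazing"]] <- main("ambient.grazing", "future.grazing", "grazing")
  out[["mowing"]] <- main("ambient.mowing", "future.mowing", "mowing")
  out[!vapply(out, is.null, TRUE)]
}

## ---- fast single-stratum refit (resampling inner loop) ----------------------

## Pooled (no treatment terms, no random effects) 14-parameter fit of one
## stratum, used by bootstrap and permutation refits where speed matters.
## `seed_counts` are precomputed per-individual seed estimates.
fit_stratum_fast <- function(ind, sub, seed_counts) {
  X <- cbind(1, ind$z)
  sv <- fit_logistic(X, as.numeric(ind$survived))
  grows <- ind$survived & !is.na(ind$z1)
  if (sum(grows) < 3L) return(NULL)
  g <- fit_gaussian(X[grows, , drop = FALSE], ind$z1[grows])
  rp <- fit_logistic(X, as.numeric(ind$reproductive))
  fl <- which(ind$reproductive)
  if (!length(fl)) return(NULL)
  fs <- fit_poisson(X[fl, , drop = FALSE], seed_counts[fl])
  ws <- sub$seeds > 0
  if (!any(ws)) return(NULL)
  theta_f <- mean(sub$fall_seedlings[ws] / sub$seeds[ws])
  theta_s <- mean(sub$spring_seedlings[ws] / sub$seeds[ws])
  wr <- sub$total_seedlings > 0
  if (!any(wr)) return(NULL)
  b <- min(mean(sub$new_plants[wr] / sub$total_seedlings[wr]), 1)
  zr <- ind$z[ind$is_new]
  if (length(zr) < 2L) return(NULL)
  tryCatch(vital_rate_params(
    surv_int = sv$coef[1], surv_slope = sv$coef[2],
    grow_int = g$coef[1], grow_slope = g$coef[2],
    grow_sd = max(g$sigma, 1e-8),
    flow_int = rp$coef[1], flow_slope = rp$coef[2],
    seed_int = fs$coef[1], seed_slope = fs$coef[2],
    theta_f = theta_f, theta_s = theta_s, estab = b,
    recruit_mean = mean(zr), recruit_sd = max(stats::sd(zr), 1e-8)),
    error = function(e) NULL)
}
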