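## Rows of the individual/subplot tables belonging to a stratum label:
## either a treatment combination ("ambient.grazing") or a main-effect
## level ("ambient", "grazing", ...).
stratum_filter <- function(df, stratum) {
  if (stratum %in% CLIMATE_LEVELS) return(df$climate == stratum)
  if (stratum %in% MANAGEMENT_LEVELS) return(df$management == stratum)
  parts <- strsplit(stratum, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[1] %in% CLIMATE_LEVELS &&
      parts[2] %in% MANAGEMENT_LEVELS) {
    return(df$climate == parts[1] & df$management == parts[2])
  }
  stopf("unknown stratum '%s'", stratum)
}

## Pooled 14-parameter fit of a record subset -> lambda (fast path used by
## resampling loops; power-iteration eigenvalue).
lambda_of_subset <- function(ind, sub, seed_counts, L, U, n_bins) {
  p <- suppressWarnings(fit_stratum_fast(ind, sub, seed_counts))
  if (is.null(p)) return(NA_real_)
  k <- tryCatch(ipm_kernel(p, L, U, n_bins = n_bins),
                error = function(e) NULL)
  if (is.null(k)) return(NA_real_)
  lambda(k, method = "power")
}

#' Bootstrap distribution of lambda for one stratum
#'
#' Two-level nonparametric bootstrap honouring both sampling designs:
#' individual transition records are resampled with replacement (feeding the
#' four size regressions and the recruit-size distribution), and
#' subplot-year records are resampled with replacement (feeding the
#' recruitment and establishment ratios). Each replicate refits all vital
#' rates as a pooled (treatment-free, fixed-effects) fit of the stratum's
#' data, rebuilds the kernel on the stratum's fixed size domain, and records
#' lambda.
#'
#' @param census A `census` object.
#' @param stratum Combination label (`"ambient.grazing"`, ...) or
#'   main-effect level (`"ambient"`, `"grazing"`, ...), whose records are
#'   pooled.
#' @param n_boot Number of replicates (default 1000, the standard setting).
#' @param seed Integer seed; the distribution is reproducible given it.
#' @param n_bins,limits Kernel discretization and log-size limits; limits
#'   default to the stratum's observed range via [size_limits()].
#' @return An object of class `lambda_distribution`: the vector of
#'   bootstrap lambdas plus mean and SD of log lambda. Replicates whose
#'   refit fails are dropped (an error if more than 10%).
#' @export
bootstrap_lambda <- function(census, stratum, n_boot = 1000L, seed = 1L,
                             n_bins = 200L, limits = NULL) {
  ind <- census$individuals[stratum_filter(census$individuals, stratum), ,
                            drop = FALSE]
  sub <- census$subplots[stratum_filter(census$subplots, stratum), ,
                         drop = FALSE]
  if (nrow(ind) == 0L) stopf("no records in stratum '%s'", stratum)
  counts <- seed_estimates(
    structure(list(individuals = ind, subplots = sub,
                   seed_heads = census$seed_heads), class = "census"))
  if (is.null(limits)) {
    g <- suppressWarnings(fit_stratum_fast(ind, sub, counts))
    if (is.null(g)) stopf("stratum '%s' is not fittable", stratum)
    limits <- size_limits(structure(list(individuals = ind),
                                    class = "census"), g[["grow_sd"]])
  }
  lam <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(sub_seed(seed, "boot", b))
    ri <- sample.int(nrow(ind), replace = TRUE)
    rs <- sample.int(nrow(sub), replace = TRUE)
    lam[b] <- lambda_of_subset(ind[ri, , drop = FALSE],
                               sub[rs, , drop = FALSE], counts[ri],
                               limits[1], limits[2], n_bins)
  }
  dropped <- sum(is.na(lam))
  if (dropped > 0.1 * n_boot) {
    stopf("%d of %d bootstrap replicates failed to fit", dropped, n_boot)
  }
  lam <- lam[!is.na(lam)]
  structure(list(stratum = stratum, lambda = lam,
                 mean_log_lambda = mean(log(lam)),
                 sd_log_lambda = stats::sd(log(lam)),
                 n_boot = n_boot, dropped = dropped, seed = seed),
            class = "lambda_distribution")
}

#' @export
print.lambda_distribution <- function(x, ...) {
  cat(sprintf(
    "Bootstrap lambda [%s]: %d replicates (%d dropped)\n  mean log lambda = %.4f, sd = %.4f\n",
    x$stratum, length(x$lambda), x$dropped, x$mean_log_lambda,
    ifelse(is.na(x$sd_log_lambda), 0, x$sd_log_lambda)))
  invisible(x)
}

#' Plot-level permutation test for a treatment contrast
#'
#' Treatments are applied at the plot (subunit) scale, so plots are the
#' exchangeable units. The observed statistic is `T = lambda(A) -
#' lambda(B)`, each lambda from a pooled fit of the stratum's records on a
#' common size domain. The null is built by reassigning the group label
#' across the plots of both strata (keeping each plot's records intact),
#' refitting everything and recomputing `T`. When the assignment space is
#' small enough it is enumerated exhaustively; otherwise `n_perm` random
#' reassignments are drawn and the add-one estimator
#' `p = (1 + #{|T*| >= |T|}) / (1 + n_perm)` avoids p = 0.
#'
#' @param census A `census` object.
#' @param stratum_a,stratum_b The two strata to compare (combination labels
#'   or main-effect levels, e.g. `"ambient.grazing"` vs `"ambient.mowing"`,
#'   or `"grazing"` vs `"mowing"`).
#' @param n_perm Number of permutations (default 1000, the standard
#'   setting).
#' @param seed Integer seed.
#' @param n_bins Kernel bins for the refits.
#' @return An object of class `permutation_test`: observed statistic,
#'   two-sided p-value, null distribution, and whether enumeration was
#'   exhaustive.
#' @export
permutation_test <- function(census, stratum_a, stratum_b, n_perm = 1000L,
                             seed = 1L, n_bins = 200L) {
  ind <- census$individuals
  sub <- census$subplots
  selA <- stratum_filter(ind, stratum_a)
  selB <- stratum_filter(ind, stratum_b)
  if (any(selA & selB)) stopf("strata overlap; labels are not exchangeable")
  counts <- seed_estimates(census)

  plotsA <- unique(ind$plot[selA])
  plotsB <- unique(ind$plot[selB])
  if (length(plotsA) < 2L || length(plotsB) < 2L) {
    stopf("need at least 2 plots per group for a permutation test")
  }
  pool <- c(plotsA, plotsB)
  nA <- length(plotsA)

  keep <- selA | selB
  ind <- ind[keep, , drop = FALSE]
  counts <- counts[keep]
  sub <- sub[stratum_filter(sub, stratum_a) |
             stratum_filter(sub, stratum_b), , drop = FALSE]

  ## common size domain across both groups
  gsd <- suppressWarnings(fit_stratum_fast(ind, sub, counts))
  if (is.null(gsd)) stopf("combined strata are not fittable")
  limits <- size_limits(structure(list(individuals = ind),
                                  class = "census"), gsd[["grow_sd"]])

  stat_for <- function(a_plots) {
    inA <- ind$plot %in% a_plots
    sA <- sub$plot %in% a_plots
    lA <- lambda_of_subset(ind[inA, , drop = FALSE],
                           sub[sA, , drop = FALSE], counts[inA],
                           limits[1], limits[2], n_bins)
    lB <- lambda_of_subset(ind[!inA, , drop = FALSE],
                           sub[!sA, , drop = FALSE], counts[!inA],
                           limits[1], limits[2], n_bins)
    lA - lB
  }
  t_obs <- stat_for(plotsA)
  if (is.na(t_obs)) stopf("observed strata are not fittable")

  n_space <- choose(length(pool), nA)
  exhaustive <- n_space <= n_perm
  if (exhaustive) {
    assignments <- utils::combn(pool, nA, simplify = FALSE)
    t_null <- vapply(assignments, stat_for, 0)
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12, na.rm = TRUE)
    n_used <- length(t_null)
  } else {
    t_null <- rep(NA_real_, n_perm)
    for (i in seq_len(n_perm)) {
      set.seed(sub_seed(seed, "perm", i))
      t_null[i] <- stat_for(sample(pool, nA))
    }
    n_used <- sum(!is.na(t_null))
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12, na.rm = TRUE)) /
      (1 + n_used)
  }
  structure(list(stratum_a = stratum_a, stratum_b = stratum_b,
                 statistic = t_obs, p_value = p, null = t_null,
                 n_perm = n_used, exhaustive = exhaustive, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test %s vs %s: T = %.4f, p = %.4g (%s, %d permutations)\n",
    x$stratum_a, x$stratum_b, x$statistic, x$p_value,
    if (x$exhaustive) "exhaustive" else "random", x$n_perm))
  invisible(x)
}
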