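#' Treatment effect sizes on lambda
#'
#' The management effect is `lambda(grazing) - lambda(mowing)` and the
#' climate effect is `lambda(ambient) - lambda(future)`, both from the
#' main-effect strata, so positive values indicate a preference for the
#' grazing or ambient treatment and negative values for mowing or future.
#'
#' @param fit An `ipm_fit`, or a named numeric vector of lambdas containing
#'   the main-effect strata (`grazing`, `mowing`, `ambient`, `future`).
#' @param species Optional species label carried into the result.
#' @param scale `"lambda"` (default) or `"log"` to difference log lambdas.
#' @return A data frame with one row per axis: `axis`, `value`,
#'   `preference`. A missing level drops that axis with a message.
#' @export
effect_size <- function(fit, species = NA_character_,
                        scale = c("lambda", "log")) {
  scale <- match.arg(scale)
  lam <- if (inherits(fit, "ipm_fit")) {
    stats::setNames(fit$lambda$lambda, fit$lambda$stratum)
  } else fit
  if (scale == "log") lam <- log(lam)
  rows <- list()
  if (all(c("grazing", "mowing") %in% names(lam))) {
    v <- unname(lam["grazing"] - lam["mowing"])
    rows$management <- data.frame(
      species = species, axis = "management", value = v,
      preference = if (v > 0) "grazing" else if (v < 0) "mowing" else "none",
      stringsAsFactors = FALSE)
  } else message("management effect skipped: a main-effect level is missing")
  if (all(c("ambient", "future") %in% names(lam))) {
    v <- unname(lam["ambient"] - lam["future"])
    rows$climate <- data.frame(
      species = species, axis = "climate", value = v,
      preference = if (v > 0) "ambient" else if (v < 0) "future" else "none",
      stringsAsFactors = FALSE)
  } else message("climate effect skipped: a main-effect level is missing")
  do.call(rbind, unname(rows))
}

#' Flowering duration from start and end months
#'
#' Duration is counted inclusively in months: flowering from May (5) to
#' June (6) lasts 2 months.
#'
#' @param start_month,end_month Numeric months (1-12), e.g. means across
#'   treatments.
#' @return Numeric duration in months.
#' @export
flowering_duration <- function(start_month, end_month) {
  end_month - start_month + 1
}

#' Regress treatment effect sizes on flowering phenology
#'
#' Simple per-predictor ordinary least-squares fits of the species effect
#' sizes on mean flowering start month and on flowering duration (computed
#' inclusively from mean start and end months via [flowering_duration()]).
#'
#' @param effects Data frame as returned by [effect_size()] (rows for
#'   several species), with columns `species`, `axis`, `value`.
#' @param phenology Data frame with columns `species`, `start_month`,
#'   `end_month` (one row per species; if several, e.g. per treatment,
#'   months are averaged within species first).
#' @return A data frame with one row per axis x predictor: slope,
#'   intercept, `r_squared`, `p_value`, `n`. Fewer than 3 species with both
#'   values is an error.
#' @export
phenology_regression <- function(effects, phenology) {
  ph <- stats::aggregate(phenology[, c("start_month", "end_month")],
                         by = list(species = phenology$species),
                         FUN = mean)
  ph$duration <- flowering_duration(ph$start_month, ph$end_month)
  out <- list()
  for (ax in unique(effects$axis)) {
    e <- effects[effects$axis == ax, , drop = FALSE]
    m <- merge(e, ph, by = "species")
    m <- m[stats::complete.cases(m[, c("value", "start_month",
                                       "duration")]), , drop = FALSE]
    if (nrow(m) < 3L) {
      stopf("axis '%s': need >= 3 species with effect size and phenology (got %d)",
            ax, nrow(m))
    }
    for (pred in c("start_month", "duration")) {
      fm <- stats::lm(m$value ~ m[[pred]])
      sm <- suppressWarnings(summary(fm))
      out[[paste(ax, pred)]] <- data.frame(
        axis = ax, predictor = pred,
        intercept = unname(stats::coef(fm)[1]),
        slope = unname(stats::coef(fm)[2]),  # NA when the predictor is constant
        r_squared = sm$r.squared,
        p_value = tryCatch(sm$coefficients[2, 4],
                           error = function(e) NA_real_),
        n = nrow(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
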