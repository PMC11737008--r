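## The 14 parameters of the two-stage IPM, in fixed order. Names follow the
## field's usual shorthand: surv/grow/flow/seed regressions on log size z,
## plus the discrete recruitment and establishment rates and the recruit
## log-size distribution.
PARAM_NAMES <- c(
  "surv_int", "surv_slope",
  "grow_int", "grow_slope", "grow_sd",
  "flow_int", "flow_slope",
  "seed_int", "seed_slope",
  "theta_f", "theta_s",
  "estab",
  "recruit_mean", "recruit_sd"
)

## Grouping of the 14 parameters into the five demographic processes used to
## summarise LTRE decompositions.
PARAM_STAGE <- c(
  surv_int = "survival", surv_slope = "survival",
  grow_int = "growth", grow_slope = "growth", grow_sd = "growth",
  flow_int = "reproduction", flow_slope = "reproduction",
  seed_int = "reproduction", seed_slope = "reproduction",
  theta_f = "recruitment", theta_s = "recruitment",
  estab = "establishment",
  recruit_mean = "establishment", recruit_sd = "establishment"
)

LTRE_STAGES <- c("survival", "growth", "reproduction", "recruitment",
                 "establishment")

#' Names and process grouping of the 14 IPM parameters
#'
#' @return `param_names()` returns the character vector of the 14 parameter
#'   names in canonical order; `param_stages()` returns the named character
#'   vector mapping each parameter to its demographic process (survival,
#'   growth, reproduction, recruitment, establishment).
#' @export
param_names <- function() PARAM_NAMES

#' @rdname param_names
#' @export
param_stages <- function() PARAM_STAGE

#' Construct a vital-rate parameter set
#'
#' Bundles the 14 parameters that fully determine one stratum's integral
#' projection model: logistic survival and flowering-probability regressions
#' on log size (intercept/slope, logit scale), the Gaussian growth regression
#' (intercept/slope/residual SD on the log-size scale), the log-link seed
#' count regression, mean fall and spring per-seed recruitment rates, the
#' seedling establishment probability, and the recruit log-size distribution
#' (mean, SD).
#'
#' @param surv_int,surv_slope Survival logistic regression, logit scale.
#' @param grow_int,grow_slope,grow_sd Growth regression of log size at t1 on
#'   log size at t0; `grow_sd` is the residual SD and must be positive.
#' @param flow_int,flow_slope Flowering (reproduction) probability logistic
#'   regression, logit scale.
#' @param seed_int,seed_slope Seed count regression, natural-log link.
#' @param theta_f,theta_s Mean fall / spring seedlings per seed (nonnegative;
#'   may exceed 1 when seed input is underestimated in the field).
#' @param estab Seedling establishment probability in `[0, 1]`.
#' @param recruit_mean,recruit_sd Mean and SD of recruit log size;
#'   `recruit_sd` must be positive.
#' @param label Optional stratum label (e.g. `"ambient.grazing"`).
#' @param se Optional named numeric vector of standard errors.
#' @param n Optional named vector of sample sizes used per component.
#'
#' @return An object of class `vital_rate_params`: a named numeric vector of
#'   length 14 with attributes `label`, `se` and `n`.
#' @examples
#' p <- vital_rate_params(surv_int = 0.5, surv_slope = 0.8,
#'   grow_int = 0.3, grow_slope = 0.9, grow_sd = 0.4,
#'   flow_int = -1, flow_slope = 1.2, seed_int = 2, seed_slope = 0.5,
#'   theta_f = 0.05, theta_s = 0.02, estab = 0.3,
#'   recruit_mean = 0.1, recruit_sd = 0.5)
#' p
#' @export
vital_rate_params <- function(surv_int, surv_slope,
                              grow_int, grow_slope, grow_sd,
                              flow_int, flow_slope,
                              seed_int, seed_slope,
                              theta_f, theta_s, estab,
                              recruit_mean, recruit_sd,
                              label = NULL, se = NULL, n = NULL) {
  vals <- vapply(list(surv_int, surv_slope, grow_int, grow_slope, grow_sd,
                      flow_int, flow_slope, seed_int, seed_slope,
                      theta_f, theta_s, estab, recruit_mean, recruit_sd),
                 function(v) as.numeric(v)[1], 0)
  x <- stats::setNames(vals, PARAM_NAMES)
  as_vital_rate_params(x, label = label, se = se, n = n)
}

#' Coerce a named numeric vector to a `vital_rate_params` object
#'
#' @param x Named numeric vector containing all 14 parameters (extra names
#'   are an error; order is normalised).
#' @inheritParams vital_rate_params
#' @return A `vital_rate_params` object.
#' @export
as_vital_rate_params <- function(x, label = NULL, se = NULL, n = NULL) {
  if (inherits(x, "vital_rate_params")) {
    if (!is.null(label)) attr(x, "label") <- label
    return(x)
  }
  x <- unlist(x)
  if (!all(PARAM_NAMES %in% names(x))) {
    stopf("missing parameters: %s",
          paste(setdiff(PARAM_NAMES, names(x)), collapse = ", "))
  }
  if (!all(names(x) %in% PARAM_NAMES)) {
    stopf("unknown parameters: %s",
          paste(setdiff(names(x), PARAM_NAMES), collapse = ", "))
  }
  x <- x[PARAM_NAMES]
  validate_params(x)
  structure(x, class = "vital_rate_params",
            label = label, se = se, n = n)
}

validate_params <- function(x) {
  if (any(!is.finite(x))) {
    stopf("nonfinite parameter(s): %s",
          paste(names(x)[!is.finite(x)], collapse = ", "))
  }
  if (x[["grow_sd"]] <= 0) stopf("grow_sd must be > 0 (got %g)", x[["grow_sd"]])
  if (x[["recruit_sd"]] <= 0) {
    stopf("recruit_sd must be > 0 (got %g)", x[["recruit_sd"]])
  }
  for (p in c("theta_f", "theta_s", "estab")) {
    if (x[[p]] < 0) stopf("%s must be >= 0 (got %g)", p, x[[p]])
  }
  invisible(x)
}

#' @export
print.vital_rate_params <- function(x, digits = 4, ...) {
  lab <- attr(x, "label")
  cat("Vital-rate parameter set",
      if (!is.null(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  m <- matrix(unclass(x), nrow = 1,
              dimnames = list("", names(x)))
  print(round(m, digits))
  invisible(x)
}

#' @export
as.data.frame.vital_rate_params <- function(x, ...) {
  out <- data.frame(parameter = names(x), value = as.numeric(x),
                    stage = unname(PARAM_STAGE[names(x)]),
                    stringsAsFactors = FALSE)
  se <- attr(x, "se")
  out$se <- if (!is.null(se)) as.numeric(se[out$parameter]) else NA_real_
  lab <- attr(x, "label")
  if (!is.null(lab)) out <- cbind(stratum = lab, out)
  out
}

#' Average parameter sets (main-effect construction)
#'
#' The parameter set for one factor level is the arithmetic mean, parameter
#' by parameter, of the two treatment-combination sets sharing that level
#' (e.g. ambient = mean of ambient-grazing and ambient-mowing). The rule
#' operates on parameters, never on derived quantities such as lambda.
#'
#' @param ... Two or more `vital_rate_params` objects.
#' @param label Label for the averaged set.
#' @return A `vital_rate_params` object.
#' @export
average_params <- function(..., label = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "vital_rate_params")) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2L) stopf("need at least two parameter sets to average")
  m <- vapply(sets, function(p) as.numeric(as_vital_rate_params(p)),
              numeric(length(PARAM_NAMES)))
  as_vital_rate_params(stats::setNames(rowMeans(m), PARAM_NAMES),
                       label = label)
}
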