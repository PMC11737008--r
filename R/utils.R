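#' @keywords internal
"_PACKAGE"

## Levels of the two experimental factors. Plots (subunits) are nested in
## climate; each plot carries exactly one management type.
CLIMATE_LEVELS <- c("ambient", "future")
MANAGEMENT_LEVELS <- c("grazing", "mowing")

#' Treatment combinations of the factorial design
#'
#' @return A data frame with columns `climate` and `management`, one row per
#'   combination, in the canonical order ambient-grazing, ambient-mowing,
#'   future-grazing, future-mowing.
#' @export
treatment_combinations <- function() {
  data.frame(
    climate = rep(CLIMATE_LEVELS, each = 2L),
    management = rep(MANAGEMENT_LEVELS, 2L),
    stringsAsFactors = FALSE
  )
}

combo_label <- function(climate, management) paste(climate, management, sep = ".")

inv_logit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

## Derive a 31-bit sub-seed from a base seed and a stream label, so each
## table/year/replicate gets its own reproducible stream.
sub_seed <- function(seed, ...) {
  key <- paste(seed, ..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
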