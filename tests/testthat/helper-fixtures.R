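## Shared fixtures, built in code. The small census is cached per test run.
.fixtures <- new.env(parent = emptyenv())

small_census <- function() {
  if (is.null(.fixtures$census)) {
    .fixtures$truth <- default_truth(
      census_design(n_individuals = 400, n_years = 2), seed = 7)
    .fixtures$census <- simulate_census(.fixtures$truth)
  }
  .fixtures$census
}

small_truth <- function() {
  small_census()
  .fixtures$truth
}

## Hand-specified parameter set used by kernel/sensitivity/LTRE tests.
hand_params <- function(...) {
  base <- list(surv_int = 0.5, surv_slope = 0.8,
               grow_int = 0.3, grow_slope = 0.9, grow_sd = 0.4,
               flow_int = -1.0, flow_slope = 1.2,
               seed_int = 2.0, seed_slope = 0.5,
               theta_f = 0.05, theta_s = 0.02, estab = 0.3,
               recruit_mean = -0.5, recruit_sd = 0.5)
  mods <- list(...)
  base[names(mods)] <- mods
  do.call(vital_rate_params, base)
}

## Minimal hand-built census from an individual table; subplot and seed-head
## tables are valid fillers unless supplied.
make_census <- function(ind, sub = NULL, heads = NULL) {
  ind$id <- ind$id %||% sprintf("i%d", seq_len(nrow(ind)))
  ind$species <- ind$species %||% "SYN"
  ind$year <- ind$year %||% 2018L
  ind$plot <- ind$plot %||% "ag_1"
  ind$subplot <- ind$subplot %||% "ag_1_s1"
  ind$climate <- ind$climate %||% "ambient"
  ind$management <- ind$management %||% "grazing"
  ind$seed_heads <- ind$seed_heads %||% 0L
  ind$reproductive <- ind$reproductive %||% FALSE
  ind$is_new <- ind$is_new %||% FALSE
  if (is.null(sub)) {
    sub <- data.frame(species = "SYN", year = 2018L, plot = "ag_1",
                      subplot = "ag_1_s1", climate = "ambient",
                      management = "grazing", seeds = 100,
                      fall_seedlings = 5L, spring_seedlings = 2L,
                      total_seedlings = 7L, new_plants = 2L,
                      stringsAsFactors = FALSE)
  }
  if (is.null(heads)) {
    heads <- data.frame(species = "SYN", plot = "ag_1", head_id = 1:2,
                        seeds = c(10, 10), stringsAsFactors = FALSE)
  }
  as_census(ind, sub, heads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent by-hand midpoint construction of the 4x4 iteration matrix
## (3 size bins + seedling class), written with explicit loops.
hand_kernel_3bin <- function(p, L, U) {
  h <- (U - L) / 3
  mesh <- c(L + h / 2, L + 3 * h / 2, L + 5 * h / 2)
  s <- function(z) 1 / (1 + exp(-(p[["surv_int"]] + p[["surv_slope"]] * z)))
  g <- function(z1, z) dnorm(z1, p[["grow_int"]] + p[["grow_slope"]] * z,
                             p[["grow_sd"]])
  pf <- function(z) 1 / (1 + exp(-(p[["flow_int"]] + p[["flow_slope"]] * z)))
  f <- function(z) exp(p[["seed_int"]] + p[["seed_slope"]] * z)
  eta <- function(z1) dnorm(z1, p[["recruit_mean"]], p[["recruit_sd"]])
  A <- matrix(0, 4, 4)
  for (i in 1:3) {
    for (j in 1:3) {
      A[i + 1, j + 1] <- h * (s(mesh[j]) * g(mesh[i], mesh[j]) +
                                pf(mesh[j]) * f(mesh[j]) * p[["theta_f"]] *
                                  p[["estab"]] * eta(mesh[i]))
    }
    A[i + 1, 1] <- h * p[["estab"]] * eta(mesh[i])
    A[1, i + 1] <- pf(mesh[i]) * f(mesh[i]) * p[["theta_s"]]
  }
  A[1, 1] <- 0
  A
}

## A fully degenerate census: every individual row identical, every subplot
## row identical. Resampling it can never change any estimate.
degenerate_census <- function(n = 40) {
  ind <- data.frame(
    id = sprintf("i%d", seq_len(n)), species = "SYN", year = 2018L,
    plot = rep(c("ag_1", "ag_2"), length.out = n),
    subplot = "s1", climate = "ambient", management = "grazing",
    size_t0 = 3, survived = TRUE, size_t1 = 3, reproductive = TRUE,
    seed_heads = 2L, is_new = TRUE, stringsAsFactors = FALSE)
  sub <- data.frame(species = "SYN", year = 2018L,
                    plot = rep(c("ag_1", "ag_2"), each = 3),
                    subplot = paste0("s", 1:6), climate = "ambient",
                    management = "grazing", seeds = 100,
                    fall_seedlings = 5L, spring_seedlings = 5L,
                    total_seedlings = 10L, new_plants = 2L,
                    stringsAsFactors = FALSE)
  heads <- data.frame(species = "SYN", plot = rep(c("ag_1", "ag_2"), 2),
                      head_id = c(1, 1, 2, 2), seeds = 10,
                      stringsAsFactors = FALSE)
  as_census(ind, sub, heads)
}
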