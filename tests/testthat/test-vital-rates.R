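test_that("an even split of fates at every size gives a flat logistic at 0", {
  z <- rep(seq(-1, 2, length.out = 30), each = 2)
  ind <- data.frame(size_t0 = exp(z),
                    survived = rep(c(TRUE, FALSE), 30),
                    size_t1 = ifelse(rep(c(TRUE, FALSE), 30), exp(z), NA),
                    reproductive = FALSE, seed_heads = 0L)
  sv <- fit_survival(make_census(ind), "none")
  expect_lt(abs(sv$int), 1e-6)
  expect_lt(abs(sv$slope), 1e-6)
})

test_that("identity growth is interpolated exactly with zero residual SD", {
  z <- seq(-1, 2, length.out = 20)
  ind <- data.frame(size_t0 = exp(z), survived = TRUE, size_t1 = exp(z),
                    reproductive = FALSE, seed_heads = 0L)
  gr <- fit_growth(make_census(ind), "none")
  expect_equal(gr$int, 0, tolerance = 1e-10)
  expect_equal(gr$slope, 1, tolerance = 1e-10)
  expect_equal(gr$sd, 0, tolerance = 1e-10)
})

test_that("complete separation falls back to a penalized fit", {
  z <- seq(-1, 2, length.out = 40)
  ind <- data.frame(size_t0 = exp(z), survived = TRUE, size_t1 = exp(z),
                    reproductive = FALSE, seed_heads = 0L)
  expect_warning(sv <- fit_survival(make_census(ind), "none"),
                 "separation")
  p_hat <- 1 / (1 + exp(-(sv$int + sv$slope * z)))
  expect_true(all(p_hat >= 0.99))
  ## mirrored: nothing flowers
  expect_warning(rp <- fit_reproduction(make_census(ind), "none"),
                 "separation")
  q_hat <- 1 / (1 + exp(-(rp$int + rp$slope * z)))
  expect_true(all(q_hat <= 0.01))
})

test_that("constant seed output yields a log-scale intercept and no slope", {
  z <- seq(0, 2, length.out = 50)
  ## one head each, lab mean 10 seeds/head -> every count is exactly 10
  ind <- data.frame(size_t0 = exp(z), survived = TRUE, size_t1 = exp(z),
                    reproductive = TRUE, seed_heads = 1L)
  heads <- data.frame(species = "SYN", plot = "ag_1", head_id = 1:2,
                      seeds = c(10, 10))
  fs <- fit_seeds(make_census(ind, heads = heads), "none")
  expect_equal(fs$int, log(10), tolerance = 1e-6)
  expect_equal(fs$slope, 0, tolerance = 1e-6)
})

test_that("missing plot-level head samples fall back to the species mean", {
  z <- seq(0, 2, length.out = 20)
  ind <- data.frame(size_t0 = exp(z), survived = TRUE, size_t1 = exp(z),
                    reproductive = TRUE, seed_heads = 1L,
                    plot = rep(c("ag_1", "ag_2"), 10))
  heads <- data.frame(species = "SYN", plot = "ag_1", head_id = 1:2,
                      seeds = c(8, 12))
  expect_message(fs <- fit_seeds(make_census(ind, heads = heads), "none"),
                 "species-wide")
  expect_equal(fs$int, log(10), tolerance = 1e-6)
})

test_that("discrete rates are means of admissible per-subplot ratios", {
  sub <- data.frame(
    species = "SYN", year = 2018L, plot = "ag_1",
    subplot = paste0("s", 1:3), climate = "ambient",
    management = "grazing",
    seeds = c(100, 10, 0), fall_seedlings = c(5L, 3L, 2L),
    spring_seedlings = c(0L, 0L, 0L), total_seedlings = c(5L, 3L, 2L),
    new_plants = c(1L, 0L, 1L), stringsAsFactors = FALSE)
  ind <- data.frame(size_t0 = exp(c(0.1, 0.4, -0.2)), survived = FALSE,
                    size_t1 = NA_real_, reproductive = FALSE,
                    seed_heads = 0L, is_new = TRUE)
  dr <- estimate_discrete_rates(make_census(ind, sub = sub), "none")
  ## theta_f = mean(5/100, 3/10); the zero-seed subplot is excluded
  expect_equal(dr$theta_f, mean(c(0.05, 0.3)))
  expect_equal(dr$theta_s, 0)
  ## B = mean(1/5, 0/3, 1/2)
  expect_equal(dr$estab, mean(c(0.2, 0, 0.5)))
  expect_equal(dr$recruit_mean, mean(c(0.1, 0.4, -0.2)))
  expect_equal(dr$recruit_sd, sd(c(0.1, 0.4, -0.2)))
  expect_equal(dr$n_subplots, 2L)
  ## pooled alternative: ratio of totals
  drp <- estimate_discrete_rates(make_census(ind, sub = sub), "none",
                                 theta_method = "pooled")
  expect_equal(drp$theta_f, 8 / 110)
})

test_that("single-ratio subplots reproduce the ratio exactly", {
  sub <- data.frame(species = "SYN", year = 2018L, plot = "ag_1",
                    subplot = "s1", climate = "ambient",
                    management = "grazing", seeds = 100,
                    fall_seedlings = 5L, spring_seedlings = 0L,
                    total_seedlings = 5L, new_plants = 1L,
                    stringsAsFactors = FALSE)
  ind <- data.frame(size_t0 = exp(c(0, 1)), survived = FALSE,
                    size_t1 = NA_real_, reproductive = FALSE,
                    seed_heads = 0L, is_new = TRUE)
  dr <- estimate_discrete_rates(make_census(ind, sub = sub), "none")
  expect_equal(dr$theta_f, 0.05)
  expect_equal(dr$estab, 0.2)
})

test_that("main effects are parameter-wise means of the combinations", {
  combos <- treatment_combinations()
  reg <- function(ints, slopes, sds = NULL) {
    out <- data.frame(climate = combos$climate,
                      management = combos$management,
                      int = ints, slope = slopes,
                      se_int = 0.01, se_slope = 0.01, n = 100L,
                      stringsAsFactors = FALSE)
    if (!is.null(sds)) out$sd <- sds
    out
  }
  surv <- reg(c(0.2, 0.4, 0.1, 0.3), rep(0.8, 4))
  grow <- reg(rep(0.3, 4), rep(0.9, 4), sds = rep(0.4, 4))
  repr <- reg(rep(-1, 4), rep(1.2, 4))
  seeds <- reg(rep(2, 4), rep(0.5, 4))
  discrete <- data.frame(climate = combos$climate,
                         management = combos$management,
                         theta_f = c(0.1, 0.2, 0.3, 0.4), theta_s = 0.02,
                         estab = 0.3, recruit_mean = -0.5,
                         recruit_sd = 0.5, n_subplots = 10L,
                         n_recruits = 20L, stringsAsFactors = FALSE)
  ps <- extract_treatment_params(surv, grow, repr, seeds, discrete)
  expect_equal(ps$ambient[["surv_int"]], mean(c(0.2, 0.4)))
  expect_equal(ps$future[["surv_int"]], mean(c(0.1, 0.3)))
  expect_equal(ps$grazing[["theta_f"]], 0.2)
  expect_equal(ps$mowing[["theta_f"]], 0.3)
  ## identical combinations collapse to identical main effects
  surv2 <- reg(rep(0.2, 4), rep(0.8, 4))
  ps2 <- extract_treatment_params(surv2, grow, repr, seeds,
                                  transform(discrete, theta_f = 0.1))
  expect_equal(as.numeric(ps2$ambient), as.numeric(ps2$ambient.grazing))
  ## averaging parameter sets directly agrees
  expect_equal(as.numeric(average_params(ps$ambient.grazing,
                                         ps$ambient.mowing)),
               as.numeric(ps$ambient))
})

test_that("factorial joint fit recovers per-combination truth", {
  cen <- small_census()
  tr <- small_truth()
  sv <- fit_survival(cen, "factorial")
  for (i in seq_len(nrow(sv))) {
    lab <- paste(sv$climate[i], sv$management[i], sep = ".")
    expect_lt(abs(sv$int[i] - tr$params[[lab]][["surv_int"]]),
              max(0.3, 3 * sv$se_int[i]))
  }
  ## future climate depresses the survival intercept in truth; check the
  ## fitted contrast points the same way on average
  d_truth <- 0.15
  d_fit <- mean(sv$int[sv$climate == "ambient"]) -
    mean(sv$int[sv$climate == "future"])
  expect_lt(abs(d_fit - d_truth), 0.4)
})
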