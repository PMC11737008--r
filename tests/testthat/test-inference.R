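## Identical records in every plot: two grazing and two mowing plots whose
## data cannot differ under any relabeling.
constant_contrast_census <- function(n_graz = 2, n_mow = 2) {
  mk_plot <- function(plot, mgmt) {
    data.frame(
      id = paste0(plot, "_i", 1:10), species = "SYN", year = 2018L,
      plot = plot, subplot = paste0(plot, "_s1"), climate = "ambient",
      management = mgmt, size_t0 = 3, survived = TRUE, size_t1 = 3,
      reproductive = TRUE, seed_heads = 2L, is_new = TRUE,
      stringsAsFactors = FALSE)
  }
  mk_sub <- function(plot, mgmt) {
    data.frame(species = "SYN", year = 2018L, plot = plot,
               subplot = paste0(plot, "_s1"), climate = "ambient",
               management = mgmt, seeds = 100, fall_seedlings = 5L,
               spring_seedlings = 5L, total_seedlings = 10L,
               new_plants = 2L, stringsAsFactors = FALSE)
  }
  plots <- c(paste0("g", seq_len(n_graz)), paste0("m", seq_len(n_mow)))
  mgmts <- rep(c("grazing", "mowing"), c(n_graz, n_mow))
  ind <- do.call(rbind, Map(mk_plot, plots, mgmts))
  sub <- do.call(rbind, Map(mk_sub, plots, mgmts))
  heads <- data.frame(species = "SYN", plot = plots, head_id = 1,
                      seeds = 10, stringsAsFactors = FALSE)
  as_census(ind, sub, heads)
}

test_that("resampling fully degenerate data has zero bootstrap variance", {
  cen <- degenerate_census()
  bs <- bootstrap_lambda(cen, "ambient.grazing", n_boot = 60, seed = 1)
  expect_equal(bs$dropped, 0)
  expect_equal(sd(bs$lambda), 0)
  expect_true(all(bs$lambda == bs$lambda[1]))
})

test_that("bootstrap is reproducible and stable across seeds", {
  cen <- small_census()
  b1 <- bootstrap_lambda(cen, "ambient.grazing", n_boot = 200, seed = 5,
                         n_bins = 100)
  b2 <- bootstrap_lambda(cen, "ambient.grazing", n_boot = 200, seed = 5,
                         n_bins = 100)
  expect_identical(b1$lambda, b2$lambda)
  b3 <- bootstrap_lambda(cen, "ambient.grazing", n_boot = 200, seed = 6,
                         n_bins = 100)
  expect_false(identical(b1$lambda, b3$lambda))
  ## Monte-Carlo stability of the spread estimate across seeds
  expect_lt(abs(b1$sd_log_lambda - b3$sd_log_lambda) / b1$sd_log_lambda,
            0.35)
})

test_that("bootstrap mean tracks the point estimate", {
  cen <- small_census()
  fit <- ipm_fit(cen, random_effects = FALSE, n_bins = 100)
  point <- fit$lambda$log_lambda[fit$lambda$stratum == "ambient.grazing"]
  bs <- bootstrap_lambda(cen, "ambient.grazing", n_boot = 200, seed = 2,
                         n_bins = 100, limits = fit$limits)
  expect_lt(abs(bs$mean_log_lambda - point), 0.02)
})

test_that("permutation p-value is 1 when the statistic cannot vary", {
  cen <- constant_contrast_census()
  pt <- permutation_test(cen, "grazing", "mowing", n_perm = 10, seed = 1,
                         n_bins = 40)
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
  expect_true(pt$exhaustive)  # C(4, 2) = 6 <= 10
})

test_that("permutation p-values are valid probabilities", {
  cen <- small_census()
  pt <- permutation_test(cen, "ambient.grazing", "ambient.mowing",
                         n_perm = 30, seed = 3, n_bins = 80)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_false(pt$exhaustive)  # C(10, 5) = 252 > 30
  pt2 <- permutation_test(cen, "ambient.grazing", "ambient.mowing",
                          n_perm = 300, seed = 3, n_bins = 80)
  expect_true(pt2$exhaustive)
  expect_equal(pt2$n_perm, choose(10, 5))
})

test_that("groups with fewer than two plots are refused", {
  cen <- constant_contrast_census(n_graz = 1, n_mow = 2)
  expect_error(permutation_test(cen, "grazing", "mowing", n_perm = 10),
               "2 plots")
})
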