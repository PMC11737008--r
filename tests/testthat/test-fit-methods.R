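test_that("the fitted model object carries all strata and methods work", {
  fit <- ipm_fit(small_census(), random_effects = FALSE, n_bins = 80)
  expect_s3_class(fit, "ipm_fit")
  expect_setequal(fit$lambda$stratum,
                  c("ambient.grazing", "ambient.mowing", "future.grazing",
                    "future.mowing", "ambient", "future", "grazing",
                    "mowing"))
  expect_true(all(fit$lambda$lambda > 0))
  expect_equal(fit$lambda$log_lambda, log(fit$lambda$lambda))

  cm <- coef(fit)
  expect_equal(dim(cm), c(14L, 8L))
  expect_equal(rownames(cm), param_names())
  p <- coef(fit, "ambient.grazing")
  expect_s3_class(p, "vital_rate_params")

  ## main-effect parameters are means of their member combinations
  expect_equal(as.numeric(coef(fit, "ambient")),
               (as.numeric(coef(fit, "ambient.grazing")) +
                  as.numeric(coef(fit, "ambient.mowing"))) / 2)

  pr <- predict(fit, data.frame(z = c(0, 1)), type = "survival")
  expect_true(all(pr > 0 & pr < 1))
  expect_gt(pr[2], pr[1])  # survival increases with size in this fit
  gr <- predict(fit, data.frame(z = 1), type = "growth")
  expect_equal(gr, coef(fit, "ambient.grazing")[["grow_int"]] +
                 coef(fit, "ambient.grazing")[["grow_slope"]])

  res <- residuals(fit, stratum = "ambient.grazing")
  expect_lt(abs(mean(res)), 0.05)
  expect_output(print(fit), "log_lambda")
  expect_output(print(summary(fit)), "Fitted parameters")
})

test_that("simulate() round-trips through the generator", {
  fit <- ipm_fit(small_census(), random_effects = FALSE, n_bins = 80)
  sim <- simulate(fit, seed = 9)
  expect_s3_class(sim, "census")
  expect_setequal(unique(combo_labels <- paste(sim$individuals$climate,
                                               sim$individuals$management,
                                               sep = ".")),
                  c("ambient.grazing", "ambient.mowing", "future.grazing",
                    "future.mowing"))
  ## same first-year cohort sizes as the fitted census
  y0 <- min(sim$individuals$year)
  first <- sim$individuals[sim$individuals$year == y0, ]
  orig <- small_census()$individuals
  orig_first <- orig[orig$year == min(orig$year), ]
  expect_equal(nrow(first), nrow(orig_first))
})

test_that("quasi-extinct strata are excluded from the lambda table", {
  cen <- small_census()
  ind <- cen$individuals
  ## collapse future.mowing to a remnant population in the last year
  last <- max(ind$year)
  fm <- ind$climate == "future" & ind$management == "mowing" &
    ind$year == last
  drop <- which(fm)
  keep_few <- drop[seq_len(min(20, length(drop)))]
  ind2 <- ind[-setdiff(drop, keep_few), ]
  ind2$reproductive[ind2$climate == "future" &
                      ind2$management == "mowing" &
                      ind2$year == last] <- FALSE
  ind2$seed_heads[ind2$climate == "future" & ind2$management == "mowing" &
                    ind2$year == last] <- 0L
  ind2$z <- ind2$z1 <- NULL
  cen2 <- as_census(ind2, cen$subplots, cen$seed_heads)
  expect_message(fit <- ipm_fit(cen2, random_effects = FALSE, n_bins = 60),
                 "quasi-extinct")
  expect_false("future.mowing" %in% fit$lambda$stratum)
  expect_false("future" %in% fit$lambda$stratum)
  expect_false("mowing" %in% fit$lambda$stratum)
  expect_true("ambient.grazing" %in% fit$lambda$stratum)
})
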