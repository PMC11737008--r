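test_that("regeneration with one seed is identical and seeds differ", {
  d <- census_design(n_individuals = 120, n_years = 2)
  a <- simulate_census(census_truth(hand_params(), d, seed = 42))
  b <- simulate_census(census_truth(hand_params(), d, seed = 42))
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$subplots, b$subplots)
  expect_identical(a$seed_heads, b$seed_heads)
  c3 <- simulate_census(census_truth(hand_params(), d, seed = 43))
  expect_false(identical(a$individuals, c3$individuals))
})

test_that("first-year cohorts match the design's per-combination sizes", {
  cen <- simulate_census(default_truth(census_design(n_years = 1), seed = 3))
  counts <- census_counts(cen)
  got <- setNames(counts$n, paste(counts$climate, counts$management,
                                  sep = "."))
  expect_equal(got[["ambient.grazing"]], 1141)
  expect_equal(got[["ambient.mowing"]], 1079)
  expect_equal(got[["future.grazing"]], 1075)
  expect_equal(got[["future.mowing"]], 1353)
})

test_that("an overwhelming survival intercept keeps every individual alive", {
  tr <- census_truth(hand_params(surv_int = 10, surv_slope = 0),
                     census_design(n_individuals = 150, n_years = 2),
                     seed = 5)
  cen <- simulate_census(tr)
  expect_true(all(cen$individuals$survived))
})

test_that("generated data converge to the generating vital rates", {
  cen <- simulate_census(census_truth(
    hand_params(), census_design(n_individuals = 2000, n_years = 2),
    seed = 11))
  sv <- fit_survival(cen, "none")
  expect_lt(abs(sv$int - 0.5), 0.15)
  expect_lt(abs(sv$slope - 0.8), 0.15)
  gr <- fit_growth(cen, "none")
  expect_lt(abs(gr$int - 0.3), 0.1)
  expect_lt(abs(gr$slope - 0.9), 0.1)
  expect_lt(abs(gr$sd - 0.4), 0.05)
  rp <- fit_reproduction(cen, "none")
  expect_lt(abs(rp$int - (-1.0)), 0.15)
  expect_lt(abs(rp$slope - 1.2), 0.15)
  ## growth residuals are centred with the generating SD
  res <- cen$individuals$z1 - (0.3 + 0.9 * cen$individuals$z)
  res <- res[!is.na(res)]
  expect_lt(abs(mean(res)), 0.02)
  expect_lt(abs(sd(res) - 0.4), 0.02)
})

test_that("seedling counts track the recruitment rate times seed totals", {
  cen <- simulate_census(census_truth(
    hand_params(), census_design(n_individuals = 2000, n_years = 2),
    seed = 13))
  sub <- cen$subplots
  expect_lt(abs(sum(sub$fall_seedlings) / sum(sub$seeds) - 0.05), 0.01)
  expect_lt(abs(sum(sub$spring_seedlings) / sum(sub$seeds) - 0.02), 0.01)
})

test_that("ground-truth YAML specification round-trips losslessly", {
  tr <- default_truth(census_design(n_individuals = 50, n_years = 2),
                      seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(tr, path)
  tr2 <- read_truth(path)
  expect_equal(tr2$seed, tr$seed)
  expect_equal(tr2$design[names(tr$design)], tr$design[names(tr$design)])
  for (s in names(tr$params)) {
    expect_equal(as.numeric(tr2$params[[s]]), as.numeric(tr$params[[s]]),
                 tolerance = 1e-12)
  }
  ## identical simulations from the round-tripped truth
  expect_identical(simulate_census(tr)$individuals,
                   simulate_census(tr2)$individuals)
})

test_that("an invalid design is refused", {
  expect_error(census_design(n_individuals = 0), "individual")
  expect_error(census_design(n_plots = 0), "plot")
  expect_error(
    census_truth(list(ambient.grazing = hand_params()), census_design()),
    "combination")
})
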