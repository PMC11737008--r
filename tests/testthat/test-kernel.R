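test_that("3-bin kernel entries match an explicit midpoint computation", {
  p <- hand_params()
  k <- ipm_kernel(p, L = -1, U = 3.5, n_bins = 3, eviction = "none")
  expect_equal(k$A, hand_kernel_3bin(p, -1, 3.5), tolerance = 1e-12)
  expect_equal(k$mesh, c(-0.25, 1.25, 2.75))
})

test_that("eviction renormalization makes growth columns sum to survival", {
  p <- hand_params()
  k <- ipm_kernel(p, L = -2, U = 4, n_bins = 120, eviction = "renorm")
  ## strip the recruitment pathways: the remaining column sums are s(z_j)
  fert <- (1 / (1 + exp(-(p[["flow_int"]] + p[["flow_slope"]] * k$mesh)))) *
    exp(p[["seed_int"]] + p[["seed_slope"]] * k$mesh)
  eta <- k$A[-1, 1] / k$h / p[["estab"]]
  SG <- k$A[-1, -1] - k$h * p[["theta_f"]] * p[["estab"]] *
    outer(eta, fert)
  s_expected <- 1 / (1 + exp(-(p[["surv_int"]] + p[["surv_slope"]] *
                                 k$mesh)))
  expect_equal(colSums(SG), s_expected, tolerance = 1e-12)
  ## and the recruit-size vector integrates to one
  expect_equal(k$h * sum(eta), 1, tolerance = 1e-12)
})

test_that("lambda of a diagonal matrix is its diagonal value", {
  A <- diag(0.5, 10)
  expect_equal(lambda(A, method = "eigen"), 0.5)
  expect_equal(lambda(A, method = "power"), 0.5, tolerance = 1e-8)
})

test_that("power iteration and eigendecomposition agree on random matrices", {
  set.seed(42)
  for (i in 1:3) {
    A <- matrix(runif(201 * 201), 201, 201)
    le <- lambda(A, method = "eigen")
    lp <- lambda(A, method = "power")
    expect_lt(abs(le - lp) / le, 1e-8)
  }
})

test_that("halving the bin width changes lambda by less than 1%", {
  p <- hand_params()
  l200 <- lambda(ipm_kernel(p, -2, 4, n_bins = 200))
  l400 <- lambda(ipm_kernel(p, -2, 4, n_bins = 400))
  expect_lt(abs(l200 - l400) / l200, 1e-2)
})

test_that("without reproduction the population declines", {
  p <- hand_params(flow_int = -50)
  k <- ipm_kernel(p, -2, 4, n_bins = 100)
  ## seedling production row vanishes
  expect_true(all(k$A[1, ] < 1e-12))
  lam <- lambda(k)
  s_max <- max(1 / (1 + exp(-(p[["surv_int"]] + p[["surv_slope"]] *
                                k$mesh))))
  expect_lt(lam, s_max)
  expect_lt(lam, 1)
})

test_that("zero recruitment rates sever both seedling pathways", {
  p <- hand_params(theta_f = 0, theta_s = 0)
  k <- ipm_kernel(p, -2, 4, n_bins = 50)
  expect_true(all(k$A[1, ] == 0))
  ## continuous block reduces to pure survival-growth
  ps <- hand_params(theta_f = 0, theta_s = 0, estab = 0)
  ks <- ipm_kernel(ps, -2, 4, n_bins = 50)
  expect_equal(k$A[-1, -1], ks$A[-1, -1])
})

test_that("lambda is invariant to relabeling the mesh", {
  p <- hand_params()
  A <- ipm_kernel(p, -2, 4, n_bins = 60)$A
  set.seed(1)
  perm <- sample(nrow(A))
  expect_equal(lambda(A[perm, perm]), lambda(A), tolerance = 1e-10)
})

test_that("lambda is monotone in recruitment and intercept parameters", {
  base <- hand_params()
  l0 <- lambda(ipm_kernel(base, -2, 4, n_bins = 80))
  for (nm in c("theta_f", "theta_s", "estab", "surv_int", "flow_int",
               "seed_int")) {
    up <- unclass(base)
    up[nm] <- up[nm] + 0.05
    l1 <- lambda(ipm_kernel(as_vital_rate_params(up), -2, 4, n_bins = 80))
    expect_gte(l1, l0)
  }
})

test_that("degenerate kernel inputs are refused with clear errors", {
  expect_error(ipm_kernel(hand_params(), 2, -2), "L < U")
  expect_error(ipm_kernel(hand_params(), -2, 4, n_bins = 2), "n_bins")
  bad <- unclass(hand_params())
  bad["grow_sd"] <- -1
  expect_error(as_vital_rate_params(bad), "grow_sd")
})
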