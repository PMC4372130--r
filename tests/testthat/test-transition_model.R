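test_that("kappa is the linear predictor over stack layers", {
  stack <- manual_stack(list(contagion_defor = matrix(c(0, 0.5, 1, 0.25), 2)))
  spec0 <- predictor_spec("FtoD")
  expect_equal(kappa(spec0, 0, stack, 1:4), rep(0, 4))
  expect_equal(kappa(spec0, -2, stack, 1:4), rep(-2, 4))
  spec1 <- predictor_spec("FtoD", "contagion_defor")
  # intercept -2.00 with contagion coefficient 4.00 cancels at contagion 0.5
  expect_equal(kappa(spec1, c(-2, 4), stack, 2), 0)
  expect_equal(kappa(spec1, c(-2, 4), stack, 1:4), c(-2, 0, 2, -1))
  expect_error(kappa(spec1, c(-2), stack, 1), "coefficients")
  expect_error(kappa(predictor_spec("FtoD", "palu"), c(0, 1), stack, 1),
               "RtoD")
})

test_that("transition probability is logistic with the right landmarks", {
  expect_equal(transition_probability(0), 0.5)
  expect_equal(transition_probability(log(3)), 0.75)
  expect_equal(transition_probability(-50), 0, tolerance = 1e-12)
  expect_equal(transition_probability(50), 1, tolerance = 1e-12)
  k <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(transition_probability(k)) > 0))
})

test_that("log-likelihood matches a brute-force per-cell loop", {
  expect_equal(log_likelihood(1, 0.5), log(0.5))
  expect_equal(log_likelihood(c(1, 0), c(1 - 1e-15, 1e-15)), 0,
               tolerance = 1e-9)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      z <- rbinom(20, 1, 0.4)
      p <- runif(20, 0.01, 0.99)
    })
    brute <- 0
    for (i in 1:20)
      brute <- brute + if (z[i] == 1) log(p[i]) else log(1 - p[i])
    expect_equal(log_likelihood(z, p), brute, tolerance = 1e-10)
  }
  expect_error(log_likelihood(c(1, 0), 0.5), "length")
})

test_that("the saturated prediction maximises the log-likelihood", {
  withr::with_seed(42, {
    z <- rbinom(30, 1, 0.5)
    saturated <- log_likelihood(z, z)
    for (i in 1:20)
      expect_true(saturated >= log_likelihood(z, runif(30)))
  })
})

test_that("transition outcomes pick source cells and exclude third-class moves", {
  initial <- tg(matrix(c(ST_F, ST_F, ST_F, ST_R, ST_D, NA), 2, 3), 2000)
  final <- tg(matrix(c(ST_D, ST_F, ST_R, ST_D, ST_R, NA), 2, 3), 2004)
  ftd <- transition_outcomes(initial, final, "FtoD")
  expect_equal(ftd$cells, c(1L, 2L))  # F->R cell 3 excluded
  expect_equal(ftd$z, c(1L, 0L))
  rtd <- transition_outcomes(initial, final, "RtoD")
  expect_equal(rtd$cells, 4L)
  expect_equal(rtd$z, 1L)
  dtr <- transition_outcomes(initial, final, "DtoR")
  expect_equal(dtr$cells, 5L)
  expect_equal(dtr$z, 1L)
})

test_that("intercept-only posterior matches the closed-form MLE", {
  # 30% positives: posterior mean of logistic(intercept) must sit near 0.3,
  # i.e. intercept near logit(0.3) = -0.847
  n <- 4000
  stack <- manual_stack(list())
  z <- withr::with_seed(11, as.integer(runif(n) < 0.3))
  post <- fit_mcmc(predictor_spec("FtoD"), z, stack, seq_len(n),
                   quick_chain(seed = 2))
  p_hat <- unname(transition_probability(post$mean[1]))
  expect_equal(p_hat, mean(z), tolerance = 0.03)
  expect_equal(post$mean[[1]], log(0.3 / 0.7), tolerance = 0.15)
  expect_true(post$ci95[1, 1] <= post$mean[1] &&
                post$mean[1] <= post$ci95[2, 1])
})

test_that("MCMC recovers coefficients of a simulated logistic truth", {
  truth <- c("(Intercept)" = -1, contagion_defor = 3)
  pair <- make_truth_pair("FtoD", truth, shape = c(71, 71), seed = 4)
  post <- fit_mcmc(pair$spec, pair$z, pair$stack, pair$cells,
                   quick_chain(seed = 8, n_iter = 6000))
  for (j in 1:2)
    expect_true(post$ci95[1, j] <= truth[j] && truth[j] <= post$ci95[2, j],
                label = names(truth)[j])
})

test_that("chains are deterministic given the seed", {
  pair <- make_truth_pair("FtoD", c("(Intercept)" = -1.5, protected = -1),
                          shape = c(60, 60), seed = 6)
  a <- fit_mcmc(pair$spec, pair$z, pair$stack, pair$cells, quick_chain(3))
  b <- fit_mcmc(pair$spec, pair$z, pair$stack, pair$cells, quick_chain(3))
  expect_identical(a$samples, b$samples)
  d <- fit_mcmc(pair$spec, pair$z, pair$stack, pair$cells, quick_chain(4))
  expect_false(identical(a$samples, d$samples))
})

test_that("fits refuse underdetermined problems", {
  stack <- manual_stack(list(contagion_defor = matrix(runif(9), 3)))
  expect_error(fit_mcmc(predictor_spec("FtoD", "contagion_defor"),
                        rep(1L, 9), stack, 1:9, quick_chain()),
               "at least")
})

test_that("stepwise selection finds the single active driver", {
  truth <- c("(Intercept)" = -1.5, dist_roads = -2e-3)
  pair <- make_truth_pair("FtoD", truth, shape = c(71, 71), seed = 9)
  fit <- forward_stepwise(
    "FtoD", c("contagion_defor", "dist_rivers", "dist_roads",
              "dist_settlements", "protected"),
    pair$initial, pair$final, pair$stack,
    chain = quick_chain(seed = 21, n_iter = 2000), split_seed = 31)
  expect_true("dist_roads" %in% fit$spec$covariates)
  expect_true(fit$train_ll <= 0 && fit$test_ll <= 0)
})

test_that("stepwise stays near intercept-only when all candidates are inert", {
  truth <- c("(Intercept)" = -1.2)
  pair <- make_truth_pair("FtoD", truth, shape = c(100, 100), seed = 13)
  fit <- forward_stepwise(
    "FtoD", c("dist_rivers", "dist_settlements", "protected"),
    pair$initial, pair$final, pair$stack,
    chain = quick_chain(seed = 22, n_iter = 2000), split_seed = 32)
  expect_lte(length(fit$spec$covariates), 1)
})

test_that("stepwise is reproducible from its seeds", {
  pair <- make_truth_pair("FtoD", c("(Intercept)" = -1.5, protected = -1.2),
                          shape = c(60, 60), seed = 14)
  run <- function() forward_stepwise(
    "FtoD", c("protected", "dist_rivers"), pair$initial, pair$final,
    pair$stack, chain = quick_chain(seed = 5, n_iter = 1500),
    split_seed = 7)
  a <- run()
  b <- run()
  expect_identical(a$spec$covariates, b$spec$covariates)
  expect_identical(a$posterior$samples, b$posterior$samples)
  expect_identical(a$test_ll, b$test_ll)
})

test_that("degenerate splits are reported with the transition name", {
  # a pair with exactly one transition event: one half must be all-zero
  initial <- tg(matrix(ST_F, 10, 10), 2000)
  final_cells <- initial$cells
  final_cells[1] <- ST_D
  final <- tg(matrix(final_cells, 10, 10), 2001)
  stack <- manual_stack(list(protected = matrix(runif(100), 10)))
  expect_error(forward_stepwise("FtoD", "protected", initial, final, stack,
                                chain = quick_chain(), split_seed = 1),
               "FtoD")
})

test_that("fitted coefficients reproduce the expected driver signs", {
  # deforestation near roads and outside protection; regeneration far from
  # roads: the qualitative structure the three transitions show in practice
  ftd_truth <- c("(Intercept)" = -1.5, dist_roads = -1.5e-3,
                 protected = -1.5)
  pair <- make_truth_pair("FtoD", ftd_truth, shape = c(71, 71), seed = 17)
  post <- fit_mcmc(pair$spec, pair$z, pair$stack, pair$cells,
                   quick_chain(seed = 41, n_iter = 4000))
  expect_lt(post$mean[["dist_roads"]], 0)
  expect_lt(post$mean[["protected"]], 0)
  dtr_truth <- c("(Intercept)" = -2, dist_roads = 1.5e-3)
  pair2 <- make_truth_pair("DtoR", dtr_truth, shape = c(71, 71), seed = 18)
  post2 <- fit_mcmc(pair2$spec, pair2$z, pair2$stack, pair2$cells,
                    quick_chain(seed = 42, n_iter = 4000))
  expect_gt(post2$mean[["dist_roads"]], 0)
})

test_that("fit results serialise to JSON and back", {
  pair <- make_truth_pair("FtoD", c("(Intercept)" = -1.5, protected = -1),
                          shape = c(60, 60), seed = 19)
  fit <- forward_stepwise("FtoD", "protected", pair$initial, pair$final,
                          pair$stack, chain = quick_chain(6, 1500),
                          split_seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  csv <- sub("\\.json$", "_samples.csv", f)
  write_fit(fit, f, samples_csv = csv)
  fit2 <- read_fit(f)
  expect_identical(fit2$spec$covariates, fit$spec$covariates)
  expect_equal(unname(fit2$posterior$mean), unname(fit$posterior$mean),
               tolerance = 1e-12)
  expect_equal(fit2$test_ll, fit$test_ll)
})
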