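test_that("design enumeration reproduces the worked examples", {
  d <- enumerate_designs(c(1991, 1995), 2011)
  expect_equal(nrow(d), 1)
  expect_equal(d$transition_length, 4)
  expect_equal(d$time_step, 5)
  # a six-year transition from 1991 never lands on 2011
  expect_equal(nrow(enumerate_designs(c(1991, 1997), 2011)), 0)
  # the calibration end must precede the target
  expect_equal(nrow(enumerate_designs(c(2010, 2011), 2011)), 0)
  # three 1991 starts reach 2011 at steps 5, 4 and 2
  d91 <- enumerate_designs(c(1991, 1995, 1996, 2001), 2011)
  expect_equal(d91$time_step[d91$end_year == 1995], 5)
  expect_equal(d91$time_step[d91$start_year == 1991 & d91$end_year == 1996],
               4)
  expect_equal(d91$time_step[d91$start_year == 1991 & d91$end_year == 2001],
               2)
})

test_that("enumeration equals brute-force forward rolling", {
  brute <- function(years, target) {
    years <- sort(unique(years))
    out <- list()
    for (s in years) for (e in years[years > s]) {
      if (e >= target) next
      y <- e
      repeat {
        y <- y + (e - s)
        if (y >= target) break
      }
      if (y == target)
        out[[length(out) + 1]] <- c(s, e)
    }
    out
  }
  for (seed in 1:5) {
    years <- withr::with_seed(seed, sort(sample(1986:2010, 12)))
    d <- enumerate_designs(years, 2011)
    b <- brute(years, 2011)
    expect_equal(nrow(d), length(b))
    if (nrow(d))
      expect_identical(Map(c, d$start_year, d$end_year), b)
  }
})

test_that("time steps count from the calibration start year", {
  expect_equal(time_step_of(model_design(1991, 1995), 2011), 5)
  expect_equal(time_step_of(model_design(1991, 1996), 2011), 4)
  expect_equal(time_step_of(model_design(1991, 2001), 2011), 2)
  expect_error(time_step_of(model_design(1991, 1997), 2011), "never")
  # identity: start + step * length lands exactly on the target
  for (seed in 1:3) {
    years <- withr::with_seed(seed, sort(sample(1986:2010, 10)))
    d <- enumerate_designs(years, 2011)
    if (nrow(d))
      expect_true(all(d$start_year + d$time_step * d$transition_length ==
                        2011))
  }
})

test_that("validation years intersect predictions with available maps", {
  des <- model_design(2005, 2006)
  expect_equal(validation_years(des, 2006:2011, 2011),
               c(2007, 2008, 2009, 2010, 2011))
  des10 <- model_design(1991, 2001)
  expect_equal(validation_years(des10, c(1991, 2001, 2011), 2011), 2011)
  expect_equal(time_step_of(des10, 2011), 2)
  # a design whose prediction years miss every available map
  expect_length(validation_years(model_design(2000, 2003),
                                 c(2004, 2005, 2007), 2011), 0)
})

test_that("trend test matches the closed-form OLS solution", {
  x <- 1:10
  withr::with_seed(3, y <- 2.5 - 0.3 * x + rnorm(10, 0, 0.4))
  tr <- trend_test(y, x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / 8
  t_stat <- slope / sqrt(s2 / sxx)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(tr$slope, slope, tolerance = 1e-10)
  expect_equal(tr$t_statistic, t_stat, tolerance = 1e-10)
  expect_equal(tr$r_squared, r2, tolerance = 1e-10)
  expect_equal(tr$degrees_freedom, 8)
  expect_equal(tr$p_value, 2 * pt(-abs(t_stat), 8), tolerance = 1e-10)
})

test_that("trend test handles exact and degenerate inputs", {
  tr <- trend_test(2 * (1:5) + 1, 1:5)
  expect_equal(tr$r_squared, 1)
  expect_lt(tr$p_value, 1e-6)
  trc <- trend_test(rep(3, 5), 1:5)
  expect_equal(trc$slope, 0)
  expect_equal(trc$r_squared, 0)
  expect_error(trend_test(1:5, rep(2, 5)), "zero variance")
  expect_error(trend_test(1:2, 1:2), "at least 3")
})

test_that("landscape composition and rates follow their definitions", {
  all_f <- tg(matrix(ST_F, 4, 4), 2000)
  later <- tg(matrix(ST_F, 4, 4), 2002)
  comp <- landscape_composition(build_series(list(all_f, later)))
  expect_equal(comp$proportions$forest, c(1, 1))
  expect_equal(comp$proportions$regen, c(0, 0))
  # 4-cell toy: one of four forest cells cleared over 2 years
  a <- tg(matrix(c(ST_F, ST_F, ST_F, ST_F), 2, 2), 2000)
  b <- tg(matrix(c(ST_F, ST_D, ST_F, ST_F), 2, 2), 2002)
  comp2 <- landscape_composition(build_series(list(a, b)))
  ftd <- subset(comp2$rates, transition == "FtoD")
  expect_equal(ftd$rate, 0.25 / 2)
  # proportions always sum to one over valid cells
  scn <- synthetic_scenario(shape = c(50, 50), seed = 20,
                            years = c(2000, 2003, 2006))
  comp3 <- landscape_composition(generate_truth_series(scn))
  expect_equal(comp3$proportions$forest + comp3$proportions$regen +
                 comp3$proportions$deforested, rep(1, 3))
})

test_that("sequential ANOVA decomposes the variance exactly", {
  make_results <- function(seed, effect = 0) {
    avail <- 1991:2011
    designs <- enumerate_designs(avail, 2011)
    rows <- do.call(rbind, lapply(seq_len(nrow(designs)), function(i) {
      des <- model_design(designs$start_year[i], designs$end_year[i])
      vy <- validation_years(des, avail, 2011)
      if (!length(vy)) return(NULL)
      data.frame(start_year = des$start_year, end_year = des$end_year,
                 transition_length = des$transition_length,
                 validation_year = vy,
                 time_step = vapply(vy, function(y) time_step_of(des, y),
                                    integer(1)))
    }))
    withr::with_seed(seed, {
      rows$perfect_match <- 50 + effect * (rows$start_year - 1991) +
        rnorm(nrow(rows), 0, 3)
    })
    rows
  }
  res <- make_results(1, effect = 2)
  tab <- anova_decomposition(res)
  ss <- tab$`Sum Sq`
  total <- sum((res$perfect_match - mean(res$perfect_match))^2)
  expect_equal(sum(ss), total, tolerance = 1e-8)
  expect_equal(nrow(tab), 15)  # 14 terms + residuals
  # a response linear in initial year loads (almost) all model SS on it
  model_ss <- sum(ss[-length(ss)])
  expect_gt(ss[1] / model_ss, 0.95)
  # row order does not matter
  res_perm <- res[withr::with_seed(2, sample(nrow(res))), ]
  expect_equal(anova_decomposition(res_perm)$`Sum Sq`, ss)
})

test_that("ANOVA reports collinear terms and degenerate factors", {
  res <- data.frame(start_year = rep(c(1991, 1995), each = 4),
                    transition_length = rep(c(2, 4), 4),
                    time_step = rep(c(1, 2), 4),
                    validation_year = rep(c(1991, 1995), each = 4) + 1,
                    perfect_match = rnorm(8))
  # validation year = start + 1 is collinear with start year
  expect_error(anova_decomposition(res), "collinear")
  res2 <- data.frame(start_year = 1991, transition_length = c(2, 4),
                     time_step = c(1, 2), validation_year = c(1995, 1999),
                     perfect_match = rnorm(2))
  expect_error(anova_decomposition(res2), "distinct")
})

test_that("univariate series fit per interval and need three intervals", {
  scn <- synthetic_scenario(shape = c(60, 60), seed = 25,
                            years = c(2000, 2001, 2002, 2003, 2004))
  s <- generate_truth_series(scn)
  ser <- univariate_parameter_series(s, scn$features, "contagion_defor",
                                     "FtoD", chain = quick_chain(2, 2000))
  expect_equal(nrow(ser), 4)
  expect_true(all(ser$lower <= ser$mean & ser$mean <= ser$upper))
  # constant truth: the fitted series shows no significant trend
  tr <- trend_test(ser$mean, ser$end_year)
  expect_gt(tr$p_value, 0.05)
  short <- build_series(list(s$grids[[1]], s$grids[[2]]))
  expect_error(univariate_parameter_series(short, scn$features,
                                           "contagion_defor", "FtoD"),
               "at least 3")
})

test_that("a design grid runs end to end and tabulates matches", {
  scn <- synthetic_scenario(shape = c(60, 60), seed = 26,
                            years = 2000:2004,
                            initial_props = c(forest = 0.6,
                                              deforested = 0.25,
                                              regen = 0.15))
  s <- generate_truth_series(scn)
  designs <- data.frame(start_year = 2000, end_year = 2001)
  res <- run_design_grid(
    s, scn$features, designs,
    candidates = list(FtoD = c("contagion_defor", "protected"),
                      RtoD = "contagion_defor",
                      DtoR = "contagion_regen"),
    chain = quick_chain(3, 1500), n_iterations = 3, last_year = 2003)
  expect_equal(nrow(res), 2)  # validation at 2002 and 2003
  expect_equal(res$validation_year, c(2002, 2003))
  expect_equal(res$time_step, c(2, 3))
  expect_true(all(res$perfect_match >= 0 & res$perfect_match <= 100))
})
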