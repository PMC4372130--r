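# shared fixture builders for the lccsim test suite

# grid from a plain matrix of state codes
tg <- function(m, year = 2000, cell_size = 30) {
  lc_grid(matrix(as.integer(m), nrow = nrow(m)), year = year,
          cell_size = cell_size)
}

# short state-code aliases (avoid masking base::F)
ST_F <- lccsim::LC_FOREST
ST_D <- lccsim::LC_DEFORESTED
ST_R <- lccsim::LC_REGEN

# short chain for unit tests (acceptance tests choose their own)
quick_chain <- function(seed = 1, n_iter = 3000) {
  chain_config(n_iter = n_iter, n_keep = 500, seed = seed)
}

# a covariate stack built directly from named layers (no landscape needed)
manual_stack <- function(layers, year = 2000) {
  structure(list(year = as.integer(year), layers = layers, static = NULL),
            class = "covariate_stack")
}

# a fit_result with a degenerate posterior pinned at `beta` (for driving the
# simulator with known coefficients)
pinned_fit <- function(transition, covariates, beta) {
  spec <- predictor_spec(transition, covariates)
  samples <- matrix(rep(beta, each = 100), nrow = 100)
  colnames(samples) <- c("(Intercept)", covariates)
  post <- structure(list(samples = samples, mean = colMeans(samples),
                         ci95 = apply(samples, 2, quantile,
                                      probs = c(0.025, 0.975)),
                         acceptance = 0.4),
                    class = "coef_posterior")
  structure(list(spec = spec, posterior = post, train_ll = NA_real_,
                 test_ll = NA_real_, split_seed = NA_integer_),
            class = "fit_result")
}

# single-interval calibration pair drawn from a known logistic truth over an
# all-source-class landscape (plus optional sprinkled other-class cells so
# contagion varies); returns everything a fit needs
make_truth_pair <- function(transition, beta, shape = c(70, 70), seed = 1,
                            mix = 0.1) {
  feats <- make_features(shape, seed)
  src <- lccsim:::transition_source(transition)
  tgt <- lccsim:::transition_target(transition)
  others <- setdiff(c(ST_F, ST_D, ST_R), src)
  cells_m <- withr::with_seed(seed + 500L, {
    m <- matrix(src, shape[1], shape[2])
    if (mix > 0) {
      n_mix <- round(mix * length(m))
      idx <- sample.int(length(m), n_mix)
      m[idx] <- sample(others, n_mix, replace = TRUE)
    }
    m
  })
  initial <- lc_grid(cells_m, year = 2000)
  pre <- initial
  pre$year <- 1999L
  hist <- build_series(list(pre, initial))
  stack <- assemble_stack(initial, hist, feats, 2000)
  spec <- predictor_spec(transition, names(beta)[-1])
  out <- transition_outcomes(initial, initial, transition)  # all z = 0 yet
  cells <- out$cells
  p <- transition_probability(kappa(spec, unname(beta), stack, cells))
  z <- withr::with_seed(seed + 900L, as.integer(runif(length(cells)) < p))
  final_cells <- initial$cells
  final_cells[cells[z == 1]] <- tgt
  final <- lc_grid(final_cells, year = 2001)
  list(initial = initial, final = final, stack = stack, spec = spec,
       cells = cells, z = z, features = feats, history = hist)
}
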