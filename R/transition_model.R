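#' Predictor specification for one transition model
#'
#' Defines which covariates enter the linear predictor of a transition's
#' logistic model. The intercept is always included. The land-use history
#' metrics (`palu`, `arf`, `fc`) are valid only for the
#' regeneration-to-deforested transition, where clearance history carries
#' information; the other transitions draw on the remaining six layers.
#'
#' @param transition one of `"FtoD"`, `"RtoD"`, `"DtoR"`.
#' @param covariates character vector of covariate layer names (may be
#'   empty for an intercept-only model).
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(transition, covariates = character(0)) {
  transition <- match.arg(transition, LC_TRANSITIONS)
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates)) stop("duplicate covariate names")
  bad <- setdiff(covariates, covariate_names())
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  hist_only <- intersect(covariates, c("palu", "arf", "fc"))
  if (length(hist_only) && transition != "RtoD")
    stop("history metrics (", paste(hist_only, collapse = ", "),
         ") are only available for the RtoD transition")
  structure(list(transition = transition, covariates = covariates),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("<predictor_spec %s> kappa ~ 1%s\n", x$transition,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else ""))
  invisible(x)
}

#' MCMC chain configuration
#'
#' @param n_iter total Metropolis-Hastings iterations (default 20000).
#' @param burn_frac fraction of iterations discarded as burn-in, during
#'   which proposal scales adapt (default 0.5).
#' @param n_keep retained posterior draws after thinning (default 1000).
#' @param seed RNG seed making the chain reproducible.
#' @param prior_halfwidth half-width of the flat box prior on standardised
#'   coefficients (default 50; effectively uninformative).
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 20000, burn_frac = 0.5, n_keep = 1000,
                         seed = 1, prior_halfwidth = 50) {
  stopifnot(n_iter > 10, burn_frac > 0, burn_frac < 1, n_keep >= 100)
  structure(list(n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 n_keep = as.integer(n_keep), seed = as.integer(seed),
                 prior_halfwidth = prior_halfwidth),
            class = "chain_config")
}

#' Linear predictor of the transition probability
#'
#' Evaluates `kappa = b0 + sum_j b_j * layer_j[x]` at the requested cells,
#' with covariate layers taken from the stack in their natural units
#' (metres for distances, proportions for contagion, years/counts for the
#' history metrics).
#'
#' @param spec a [predictor_spec()].
#' @param coefficients numeric vector: intercept followed by one coefficient
#'   per covariate in `spec` order.
#' @param stack a `covariate_stack` from [assemble_stack()].
#' @param cells integer vector of cell indices (matrix linear indices).
#' @return Numeric vector of linear predictor values at `cells`.
#' @export
kappa <- function(spec, coefficients, stack, cells) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (length(coefficients) != 1 + length(spec$covariates))
    stop("expected ", 1 + length(spec$covariates), " coefficients, got ",
         length(coefficients))
  k <- rep(coefficients[1], length(cells))
  for (i in seq_along(spec$covariates)) {
    nm <- spec$covariates[i]
    layer <- stack$layers[[nm]]
    if (is.null(layer)) stop("stack is missing layer '", nm, "'")
    k <- k + coefficients[i + 1] * layer[cells]
  }
  k
}

#' Logistic transition probability
#'
#' Maps the linear predictor onto a probability via the logistic function
#' `P = 1 / (1 + exp(-kappa))`: strictly increasing, 0.5 at `kappa = 0`,
#' approaching 0 and 1 in the tails.
#'
#' @param kappa_values numeric vector of linear predictor values.
#' @return Probabilities in \[0, 1\].
#' @export
transition_probability <- function(kappa_values) {
  stats::plogis(kappa_values)
}

PROB_EPS <- 1e-12

#' Bernoulli log-likelihood of observed transitions
#'
#' `sum log(P)` over cells that changed (`z = 1`) plus `sum log(1 - P)` over
#' cells that did not (`z = 0`), in nats. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` so the sum is finite for saturated predictions.
#'
#' @param z integer vector of observed outcomes in \{0, 1\}.
#' @param p numeric vector of predicted transition probabilities.
#' @return The log-likelihood (a nonpositive number up to clamping).
#' @export
log_likelihood <- function(z, p) {
  if (length(z) != length(p)) stop("z and p must have the same length")
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  sum(z * log(p) + (1 - z) * log(1 - p))
}

#' Observed transition outcomes for a calibration pair
#'
#' For a calibration interval defined by two maps: the cells in the
#' transition's source class at the initial date, each labelled `z = 1` if
#' it is in the target class at the final date and `z = 0` if it stayed in
#' the source class. Cells that moved to the third class are excluded from
#' that transition's likelihood, as are nodata cells.
#'
#' @param initial,final [lc_grid()] maps of the calibration pair.
#' @param transition one of `"FtoD"`, `"RtoD"`, `"DtoR"`.
#' @return List with `cells` (linear indices) and `z` (0/1 integer vector).
#' @export
transition_outcomes <- function(initial, final, transition) {
  transition <- match.arg(transition, LC_TRANSITIONS)
  if (!identical(dim(initial$cells), dim(final$cells)))
    stop("initial and final maps have different shapes")
  src <- transition_source(transition)
  tgt <- transition_target(transition)
  ok <- !is.na(initial$cells) & !is.na(final$cells)
  in_src <- ok & initial$cells == src
  stayed <- in_src & final$cells == src
  moved <- in_src & final$cells == tgt
  cells <- which(stayed | moved)
  list(cells = cells, z = as.integer(moved[cells]))
}

# design matrix (with intercept) for a spec at given cells
design_matrix <- function(spec, stack, cells) {
  X <- matrix(1, length(cells), 1 + length(spec$covariates))
  for (i in seq_along(spec$covariates)) {
    layer <- stack$layers[[spec$covariates[i]]]
    if (is.null(layer)) stop("stack is missing layer '", spec$covariates[i], "'")
    X[, i + 1] <- layer[cells]
  }
  if (anyNA(X)) stop("covariates contain NA at requested cells")
  colnames(X) <- c("(Intercept)", spec$covariates)
  X
}

#' Fit a transition model by Metropolis-Hastings sampling
#'
#' Samples the posterior of the logistic transition model's coefficients
#' under the Bernoulli likelihood and independent flat box priors, using a
#' component-wise Gaussian random-walk sampler with step-size adaptation
#' during burn-in. Covariates are standardised internally for sampler
#' conditioning and the retained draws are back-transformed, so reported
#' coefficients are on the natural covariate scale (e.g. per metre for
#' distances).
#'
#' @param spec a [predictor_spec()].
#' @param z observed 0/1 outcomes at `cells`.
#' @param stack covariate stack of the calibration start date.
#' @param cells cell indices entering the likelihood.
#' @param chain a [chain_config()].
#' @return An object of class `coef_posterior`: `samples` (draws x
#'   coefficients matrix), `mean`, `ci95` (2.5/97.5 percentile bounds),
#'   `acceptance`.
#' @export
fit_mcmc <- function(spec, z, stack, cells, chain = chain_config()) {
  stopifnot(inherits(chain, "chain_config"))
  X <- design_matrix(spec, stack, cells)
  p <- ncol(X)
  if (length(cells) < 10 * p)
    stop("need at least ", 10 * p, " cells to fit ", p, " coefficients")
  mu <- c(0, if (p > 1) colMeans(X[, -1, drop = FALSE]) else NULL)
  sg <- c(1, if (p > 1) apply(X[, -1, drop = FALSE], 2, sd) else NULL)
  sg[sg < 1e-12] <- 1  # constant layers: leave unscaled (unidentifiable)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  Xs[, 1] <- 1
  # collapse identical covariate rows into weighted binomial groups;
  # the likelihood is unchanged and the sampler cost drops with the
  # number of distinct rows (large when covariates are discrete)
  key <- do.call(paste, c(as.data.frame(Xs), sep = "\r"))
  grp <- match(key, unique(key))
  w <- as.numeric(tabulate(grp))
  y <- as.numeric(rowsum(as.numeric(z), grp)[, 1])
  Xg <- Xs[match(seq_along(w), grp), , drop = FALSE]
  n_burn <- as.integer(chain$n_iter * chain$burn_frac)
  res <- withr::with_seed(chain$seed,
    mh_logistic(Xg, y, w, chain$n_iter, n_burn, chain$n_keep,
                -chain$prior_halfwidth, chain$prior_halfwidth))
  if (res$acceptance < 0.01 || res$acceptance > 0.9)
    warning(sprintf("MH acceptance rate %.3f outside (0.01, 0.9) for %s",
                    res$acceptance, spec$transition))
  a <- res$samples
  # back-transform standardised draws to natural covariate scale
  samples <- a
  if (p > 1) {
    samples[, -1] <- sweep(a[, -1, drop = FALSE], 2, sg[-1], "/")
    samples[, 1] <- a[, 1] -
      as.vector(a[, -1, drop = FALSE] %*% (mu[-1] / sg[-1]))
  }
  colnames(samples) <- colnames(X)
  structure(list(samples = samples,
                 mean = colMeans(samples),
                 ci95 = apply(samples, 2, quantile, probs = c(0.025, 0.975)),
                 acceptance = res$acceptance),
            class = "coef_posterior")
}

#' @export
print.coef_posterior <- function(x, ...) {
  cat(sprintf("<coef_posterior> %d draws, acceptance %.2f\n",
              nrow(x$samples), x$acceptance))
  print(signif(rbind(mean = x$mean, x$ci95), 4))
  invisible(x)
}

# seeded 50/50 split of cell positions into train/test halves
split_half <- function(n, seed) {
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(n / 2)
  list(train = sort(idx[seq_len(n_train)]), test = sort(idx[-seq_len(n_train)]))
}

#' Forward stepwise covariate selection by held-out likelihood
#'
#' Starting from the intercept-only model, each step tentatively adds every
#' remaining candidate covariate, fits the augmented model on a randomly
#' selected half of the source-class cells, and scores it by the
#' log-likelihood of the held-out half evaluated at the posterior mean
#' coefficients. The addition with the highest test likelihood is kept; the
#' search stops when no addition improves it. One 50/50 split is drawn per
#' run (from `split_seed`) and reused across steps so test likelihoods are
#' comparable; ties are broken toward fewer covariates, then candidate
#' order.
#'
#' @param transition one of `"FtoD"`, `"RtoD"`, `"DtoR"`.
#' @param candidates character vector of candidate covariate names.
#' @param initial,final the calibration pair of maps.
#' @param stack covariate stack at the initial date.
#' @param chain a [chain_config()]; each candidate fit uses a seed derived
#'   deterministically from `chain$seed`.
#' @param split_seed seed of the 50/50 train/test split.
#' @return An object of class `fit_result`: `spec`, `posterior` (the
#'   selected model refitted on the training half), `train_ll`, `test_ll`,
#'   `split_seed`.
#' @export
forward_stepwise <- function(transition, candidates, initial, final, stack,
                             chain = chain_config(), split_seed = 1) {
  transition <- match.arg(transition, LC_TRANSITIONS)
  if (!length(candidates)) stop("need at least one candidate covariate")
  out <- transition_outcomes(initial, final, transition)
  if (length(out$cells) < 20)
    stop("too few ", transition, " source cells for a split fit")
  halves <- split_half(length(out$cells), split_seed)
  tr_cells <- out$cells[halves$train]
  tr_z <- out$z[halves$train]
  te_cells <- out$cells[halves$test]
  te_z <- out$z[halves$test]
  if (!any(tr_z == 1) || !any(te_z == 1))
    stop("degenerate 50/50 split for ", transition,
         ": a half contains no observed transitions")

  score <- function(spec, fit_seed) {
    cfg <- chain
    cfg$seed <- fit_seed
    post <- fit_mcmc(spec, tr_z, stack, tr_cells, cfg)
    b <- post$mean
    list(post = post,
         train_ll = log_likelihood(
           tr_z, transition_probability(kappa(spec, b, stack, tr_cells))),
         test_ll = log_likelihood(
           te_z, transition_probability(kappa(spec, b, stack, te_cells))))
  }

  derive_seed <- function(step, cand) {
    as.integer((chain$seed + 10007L * step + 101L * cand) %% 2147483647L)
  }

  current <- predictor_spec(transition)
  best <- score(current, derive_seed(0L, 0L))
  remaining <- candidates
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    improved <- FALSE
    step_best <- NULL
    step_spec <- NULL
    step_drop <- NA_integer_
    for (ci in seq_along(remaining)) {
      cand_spec <- predictor_spec(transition, c(current$covariates,
                                                remaining[ci]))
      cand <- score(cand_spec, derive_seed(step_i, ci))
      # strict improvement required: ties favour the smaller model,
      # and among additions the earlier candidate
      beats <- cand$test_ll > best$test_ll &&
        (is.null(step_best) || cand$test_ll > step_best$test_ll)
      if (beats) {
        step_best <- cand
        step_spec <- cand_spec
        step_drop <- ci
        improved <- TRUE
      }
    }
    if (!improved) break
    current <- step_spec
    best <- step_best
    remaining <- remaining[-step_drop]
    if (!length(remaining)) break
  }
  structure(list(spec = current, posterior = best$post,
                 train_ll = best$train_ll, test_ll = best$test_ll,
                 split_seed = split_seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  train ll %.2f, test ll %.2f (split seed %d)\n",
              x$train_ll, x$test_ll, x$split_seed))
  print(x$posterior)
  invisible(x)
}

#' Fit one fixed transition model on a calibration pair
#'
#' Convenience wrapper: builds the outcomes for the transition in `spec`
#' from the calibration pair and fits the posterior on all source cells
#' (no train/test split). Used for univariate parameter series and for
#' fitting a known model structure.
#'
#' @inheritParams forward_stepwise
#' @param spec a [predictor_spec()].
#' @return A `fit_result` whose `train_ll` is the full-data likelihood at
#'   the posterior mean and whose `test_ll` is `NA`.
#' @export
fit_transition <- function(spec, initial, final, stack,
                           chain = chain_config()) {
  out <- transition_outcomes(initial, final, spec$transition)
  post <- fit_mcmc(spec, out$z, stack, out$cells, chain)
  ll <- log_likelihood(
    out$z, transition_probability(kappa(spec, post$mean, stack, out$cells)))
  structure(list(spec = spec, posterior = post, train_ll = ll,
                 test_ll = NA_real_, split_seed = NA_integer_),
            class = "fit_result")
}

#' Serialise a fit result to JSON
#'
#' Writes the selected covariates, posterior means, 95% credible bounds,
#' likelihoods and seeds as JSON, and (optionally) the retained posterior
#' draws as CSV.
#'
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @param samples_csv optional path for a CSV of posterior draws.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, samples_csv = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(transition = fit$spec$transition,
              covariates = fit$spec$covariates,
              mean = as.list(fit$posterior$mean),
              ci95 = list(lower = as.list(fit$posterior$ci95[1, ]),
                          upper = as.list(fit$posterior$ci95[2, ])),
              train_ll = fit$train_ll, test_ll = fit$test_ll,
              split_seed = fit$split_seed,
              acceptance = fit$posterior$acceptance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(samples_csv))
    write.csv(as.data.frame(fit$posterior$samples), samples_csv,
              row.names = FALSE)
  invisible(path)
}
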