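#' MCMC configuration
#'
#' Desk-scale defaults (4,000 iterations, 1,000 burn-in, thin 2, 3 chains)
#' keep a full community fit in the tens of seconds while passing the
#' oracle-equivalence and parameter-recovery checks; [mcmc_config_paper()]
#' returns the long production settings (3 chains of 250,000 iterations,
#' 20,000 burn-in, thin 20).
#'
#' @param chains Number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; every chain derives its own stream from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 3, iterations = 4000, burn_in = 1000,
                        thin = 2, seed = 1) {
  stopifnot(chains >= 1, burn_in < iterations, thin >= 1)
  structure(list(chains = chains, iterations = iterations,
                 burn_in = burn_in, thin = thin, seed = seed),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_paper <- function(seed = 1) {
  mcmc_config(chains = 3, iterations = 250000, burn_in = 20000, thin = 20,
              seed = seed)
}

#' Prior settings for the community occupancy model
#'
#' Weakly informative defaults standard for BUGS-style community occupancy
#' models: community means are Normal(0, sd 2.25) on the logit scale (nearly
#' flat on the probability scale), community standard deviations are
#' Uniform(0, 5).
#'
#' @param mu_sd Prior sd of every community mean (logit scale).
#' @param sd_upper Upper bound of the uniform prior on community sds.
#' @return An `occu_priors` list.
#' @export
occu_priors <- function(mu_sd = 2.25, sd_upper = 5) {
  stopifnot(mu_sd > 0, sd_upper > 0)
  structure(list(mu_sd = mu_sd, sd_upper = sd_upper), class = "occu_priors")
}

#' Fit the hierarchical community occupancy model
#'
#' Fits, to one landscape, the community occupancy model
#' \deqn{z_{ij} \sim Bern(\psi_{ij}),\quad
#'       logit(\psi_{ij}) = \alpha_{i,site[j]} + \beta1_i x_{canopy,j} +
#'       \beta2_i x_{village,j}}
#' \deqn{y_{ijk} \sim Bern(z_{ij} \, p_{ijk}),\quad
#'       logit(p_{ijk}) = \alpha.p_i + \beta.e_i \, Effort_{jk}}
#' with all species-level parameters drawn from community-level normal
#' distributions. Detection is conditioned on the latent state (`z * p`), as
#' the Royle-Dorazio framework requires. Effort (active camera-days per
#' occasion) is z-scored over active cells before entering the detection
#' predictor; cells with zero effort contribute nothing to the likelihood.
#' Units with zero detections are excluded from fitting (with a message), as
#' only recorded species carry information under this observation model.
#'
#' Sampling is by a built-in Metropolis-within-Gibbs algorithm: `z` from its
#' exact full conditional, species-level scalars by adaptive random-walk
#' proposals tuned during burn-in, community means by conjugate normal draws,
#' community sds by random-walk Metropolis.
#'
#' @param history A `detection_history` for the landscape's stations.
#' @param covariates Station table carrying `station_id`, `site_id` and the
#'   normalized covariate columns (`canopy_z`, `village_density_z` by
#'   default; see [normalize_covariates()]).
#' @param mcmc An [mcmc_config()].
#' @param priors An [occu_priors()].
#' @param covariate_cols Length-2 character vector naming the occupancy
#'   covariate columns in `covariates`.
#' @return An `occu_fit` object: list with `draws` (list of per-chain
#'   matrices, one named column per parameter), `units`, `sites`,
#'   `covariates`, `mcmc`, `priors`, `rhat` (tibble), `converged` (all
#'   parameters' R-hat < 1.1) and `dropped_units`.
#' @export
fit_community_occupancy <- function(history, covariates,
                                    mcmc = mcmc_config(),
                                    priors = occu_priors(),
                                    covariate_cols = c("canopy_z",
                                                       "village_density_z")) {
  stopifnot(inherits(history, "detection_history"))
  check_columns(covariates, c("station_id", "site_id", covariate_cols),
                "covariates")
  cov <- covariates[match(history$station_ids, covariates$station_id), ]
  if (anyNA(cov$station_id)) {
    stop_defaunate("covariates missing for some stations in the history",
                   "defaunate_config_error")
  }
  x1 <- cov[[covariate_cols[1]]]
  x2 <- cov[[covariate_cols[2]]]
  for (x in list(x1, x2)) {
    if (sd(x) == 0) {
      stop_defaunate("constant covariate column; normalize upstream",
                     "defaunate_constant_error")
    }
  }
  sites <- sort(unique(cov$site_id))
  site_idx <- match(cov$site_id, sites)

  # drop never-detected units
  n_det <- apply(history$y, 1, sum)
  keep <- n_det > 0
  dropped <- history$units[!keep]
  if (length(dropped) > 0) {
    message(sprintf("excluding %d unit(s) with zero detections: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  y <- history$y[keep, , , drop = FALSE]
  units <- history$units[keep]
  I <- length(units); J <- length(history$station_ids); K <- dim(y)[3]
  if (I == 0) {
    stop_defaunate("no units with detections; nothing to fit",
                   "defaunate_config_error")
  }

  effort <- history$effort
  active <- effort > 0
  effort_z <- zscore_effort(effort, active)

  # y must be 0 wherever effort is 0 (structural zeros)
  for (k in seq_len(K)) {
    yk <- matrix(y[, , k], nrow = I)
    if (any(yk[, !active[, k], drop = FALSE] > 0)) {
      stop_defaunate("detections found in zero-effort cells",
                     "defaunate_config_error")
    }
  }

  S <- length(sites)
  par_names <- c(
    as.vector(outer(seq_len(I), seq_len(S),
                    function(i, s) sprintf("alpha[%d,%d]", i, s))),
    sprintf("b1[%d]", seq_len(I)), sprintf("b2[%d]", seq_len(I)),
    sprintf("a.p[%d]", seq_len(I)), sprintf("b.e[%d]", seq_len(I)),
    sprintf("mu.alpha[%d]", seq_len(S)), sprintf("sd.alpha[%d]", seq_len(S)),
    "mu.b1", "sd.b1", "mu.b2", "sd.b2", "mu.p", "sd.p", "mu.e", "sd.e"
  )

  draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(substream_seed(mcmc$seed, paste0("chain", ch)))
    inits <- list(
      alpha = matrix(rnorm(I * S, 0, 1), I, S),
      b1 = rnorm(I, 0, 0.5), b2 = rnorm(I, 0, 0.5),
      ap = rnorm(I, 0, 0.5), be = rnorm(I, 0, 0.5),
      mu_alpha = rnorm(S, 0, 0.5), sd_alpha = runif(S, 0.5, 1.5),
      mu_b1 = rnorm(1, 0, 0.5), sd_b1 = runif(1, 0.5, 1.5),
      mu_b2 = rnorm(1, 0, 0.5), sd_b2 = runif(1, 0.5, 1.5),
      mu_p = rnorm(1, 0, 0.5), sd_p = runif(1, 0.5, 1.5),
      mu_e = rnorm(1, 0, 0.5), sd_e = runif(1, 0.5, 1.5)
    )
    mat <- community_occu_mcmc(
      as.integer(y), dim(y), effort_z, as.integer(site_idx),
      as.numeric(x1), as.numeric(x2), S,
      mcmc$iterations, mcmc$burn_in, mcmc$thin,
      priors$mu_sd, priors$sd_upper, inits)
    colnames(mat) <- par_names
    draws[[ch]] <- mat
  }

  fit <- structure(
    list(draws = draws, units = units, sites = sites,
         covariates = cov, covariate_cols = covariate_cols,
         mcmc = mcmc, priors = priors, dropped_units = dropped),
    class = "occu_fit")
  fit$rhat <- gelman_rubin(fit)
  fit$converged <- all(fit$rhat$rhat < 1.1, na.rm = TRUE)
  if (!fit$converged) {
    warn(sprintf(
      "MCMC not converged: max R-hat %.3f (threshold 1.1); %s",
      max(fit$rhat$rhat, na.rm = TRUE),
      "inspect gelman_rubin(fit) and consider longer chains"))
  }
  fit
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf(
    "<occu_fit> %d units, %d stations, %d sites; %d chains x %d retained draws\n",
    length(x$units), nrow(x$covariates), length(x$sites),
    length(x$draws), nrow(x$draws[[1]])))
  cat(sprintf("  converged (all R-hat < 1.1): %s\n", x$converged))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from between- and within-chain variances:
#' with `m` chains of `n` draws, \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n)/W}}.
#' Parameters whose total variance is zero (e.g. chains stuck at an identical
#' constant) are defined to have R-hat 1. Values below 1.1 are taken as
#' converged.
#'
#' @param x An `occu_fit`, or a list of per-chain draw matrices with matching
#'   named columns.
#' @return Tibble with columns `parameter`, `rhat`.
#' @export
gelman_rubin <- function(x) {
  draws <- if (inherits(x, "occu_fit")) x$draws else x
  if (!is.list(draws) || length(draws) < 2) {
    stop_defaunate("gelman_rubin needs >= 2 chains", "defaunate_config_error")
  }
  n <- nrow(draws[[1]])
  if (n < 10) {
    stop_defaunate("gelman_rubin needs >= 10 retained draws per chain",
                   "defaunate_config_error")
  }
  params <- colnames(draws[[1]])
  rhat <- vapply(params, function(p) {
    ch <- vapply(draws, function(d) d[, p], numeric(n))  # n x m
    W <- mean(apply(ch, 2, stats::var))
    B_n <- stats::var(colMeans(ch))  # = B/n
    if (B_n == 0) return(1)  # no between-chain variance (incl. all-constant)
    if (W == 0) return(Inf)
    sqrt(((n - 1) / n * W + B_n) / W)
  }, numeric(1))
  tibble::tibble(parameter = params, rhat = unname(rhat))
}

#' Posterior summaries (mean, sd, 75% and 95% BCIs)
#'
#' Pools draws across chains and reports, per parameter, the posterior mean,
#' standard deviation, and the 75% and 95% Bayesian credible intervals — the
#' (12.5, 87.5) and (2.5, 97.5) percentiles of the pooled draws
#' (linear-interpolation quantiles, R type 7).
#'
#' @param x An `occu_fit` or a list of per-chain draw matrices.
#' @param params Optional character vector restricting to some parameters.
#' @return Tibble with columns `parameter`, `mean`, `sd`, `lower75`,
#'   `upper75`, `lower95`, `upper95`.
#' @export
summarize_posterior <- function(x, params = NULL) {
  draws <- if (inherits(x, "occu_fit")) x$draws else x
  pooled <- do.call(rbind, draws)
  if (!is.null(params)) pooled <- pooled[, params, drop = FALSE]
  qs <- t(apply(pooled, 2, quantile, probs = c(0.125, 0.875, 0.025, 0.975),
                names = FALSE))
  tibble::tibble(
    parameter = colnames(pooled),
    mean = unname(colMeans(pooled)),
    sd = unname(apply(pooled, 2, sd)),
    lower75 = unname(qs[, 1]), upper75 = unname(qs[, 2]),
    lower95 = unname(qs[, 3]), upper95 = unname(qs[, 4])
  )
}

#' @rdname summarize_posterior
#' @param ... Unused.
#' @export
tidy.occu_fit <- function(x, ...) summarize_posterior(x)

#' One-row model overview
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return Tibble with unit/station/site counts, draw counts, max R-hat and
#'   the convergence flag.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    n_units = length(x$units),
    n_stations = nrow(x$covariates),
    n_sites = length(x$sites),
    chains = length(x$draws),
    draws_per_chain = nrow(x$draws[[1]]),
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Detection-layer log-likelihood given the latent states
#'
#' Sum over cells with nonzero effort of the Bernoulli log-mass of `y` given
#' `z * p`, with `logit p = a.p + b.e * effort`. A detection where `z = 0`
#' is impossible and yields `-Inf`. Exposed mainly as the explicit likelihood
#' contract of the model (tests check the sampler against it).
#'
#' @param z Binary unit x station matrix of latent states.
#' @param params List with numeric vectors `a_p`, `b_e` (one per unit).
#' @param history A `detection_history`; effort is z-scored over active cells
#'   exactly as in [fit_community_occupancy()].
#' @return Scalar log-likelihood.
#' @export
occupancy_log_likelihood <- function(z, params, history) {
  y <- history$y
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  stopifnot(all(dim(z) == c(I, J)),
            length(params$a_p) == I, length(params$b_e) == I)
  effort <- history$effort
  active <- effort > 0
  ez <- zscore_effort(effort, active)
  ll <- 0
  for (i in seq_len(I)) {
    p <- plogis(params$a_p[i] + params$b_e[i] * ez)  # J x K
    mu <- sweep(p, 1, z[i, ], "*")
    yi <- matrix(y[i, , ], J, K)
    cell <- ifelse(yi == 1, log(mu), log1p(-mu))
    cell[!active] <- 0
    ll <- ll + sum(cell)
  }
  ll
}
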