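#' Posterior draws of species-by-site occupancy
#'
#' For every retained draw, computes station-level occupancy
#' \eqn{\psi_{ij} = logistic(\alpha_{i,site[j]} + \beta1_i x_{1j} +
#' \beta2_i x_{2j})} and averages over the stations of each site, giving the
#' site-level occupancy of each unit at each draw. Station-averaged
#' \eqn{\psi} (rather than \eqn{\psi} at mean covariates) is used, so a
#' site's value reflects its realized covariate distribution.
#'
#' @param fit An `occu_fit`.
#' @return A `psi_draws` object: numeric array draw x unit x site with
#'   dimnames, carrying the fit's unit and site labels.
#' @export
species_site_occupancy <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  cov <- fit$covariates
  sites <- fit$sites
  x1 <- cov[[fit$covariate_cols[1]]]
  x2 <- cov[[fit$covariate_cols[2]]]
  site_idx <- match(cov$site_id, sites)
  if (any(table(factor(site_idx, levels = seq_along(sites))) == 0)) {
    stop_defaunate("a site has zero stations", "defaunate_config_error")
  }
  pooled <- do.call(rbind, fit$draws)
  n_draw <- nrow(pooled)
  I <- length(fit$units); S <- length(sites)
  psi <- array(NA_real_, dim = c(n_draw, I, S),
               dimnames = list(NULL, fit$units, sites))
  for (i in seq_len(I)) {
    a_cols <- sprintf("alpha[%d,%d]", i, seq_len(S))
    alpha_d <- pooled[, a_cols, drop = FALSE]       # n_draw x S
    b1_d <- pooled[, sprintf("b1[%d]", i)]
    b2_d <- pooled[, sprintf("b2[%d]", i)]
    # linear predictor: n_draw x J
    lin <- alpha_d[, site_idx, drop = FALSE] +
      outer(b1_d, x1) + outer(b2_d, x2)
    p <- plogis(lin)
    for (s in seq_len(S)) {
      psi[, i, s] <- rowMeans(p[, site_idx == s, drop = FALSE])
    }
  }
  structure(psi, class = "psi_draws")
}

#' @export
print.psi_draws <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<psi_draws> %d draws x %d units x %d sites\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Tidy species-by-site occupancy summaries
#'
#' @param x A `psi_draws` array from [species_site_occupancy()].
#' @param ... Unused.
#' @return Tibble with `unit_id`, `site_id`, posterior `mean`, `sd` and 75%
#'   and 95% BCI bounds.
#' @export
tidy.psi_draws <- function(x, ...) {
  units <- dimnames(x)[[2]]
  sites <- dimnames(x)[[3]]
  purrr::map_dfr(seq_along(units), function(i) {
    purrr::map_dfr(seq_along(sites), function(s) {
      v <- x[, i, s]
      q <- quantile(v, c(0.125, 0.875, 0.025, 0.975), names = FALSE)
      tibble::tibble(unit_id = units[i], site_id = sites[s],
                     mean = mean(v), sd = sd(v),
                     lower75 = q[1], upper75 = q[2],
                     lower95 = q[3], upper95 = q[4])
    })
  })
}

#' Covariate effect sizes per unit and community averages
#'
#' Posterior summaries of the two occupancy coefficients for every unit and
#' of the community means, with flags for whether the 75% and 95% BCIs
#' exclude zero (the usual reading of "a clear covariate effect" at each
#' credibility level).
#'
#' @param fit An `occu_fit`.
#' @return Tibble with `unit_id` (`"(community)"` for the community means),
#'   `covariate` (the fitted covariate column names), posterior `mean`, `sd`,
#'   BCI bounds, and logicals `excludes_zero_75`, `excludes_zero_95`.
#' @export
effect_sizes <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  I <- length(fit$units)
  pars <- c(sprintf("b1[%d]", seq_len(I)), sprintf("b2[%d]", seq_len(I)),
            "mu.b1", "mu.b2")
  s <- summarize_posterior(fit, pars)
  s$unit_id <- c(fit$units, fit$units, "(community)", "(community)")
  s$covariate <- c(rep(fit$covariate_cols, each = I), fit$covariate_cols)
  s$excludes_zero_75 <- s$lower75 > 0 | s$upper75 < 0
  s$excludes_zero_95 <- s$lower95 > 0 | s$upper95 < 0
  dplyr::select(s, "unit_id", "covariate", "mean", "sd",
                "lower75", "upper75", "lower95", "upper95",
                "excludes_zero_75", "excludes_zero_95")
}

#' Interval plot of covariate effect sizes
#'
#' Thick bars are 75% BCIs, thin bars 95% BCIs, points posterior means;
#' faceted by covariate.
#'
#' @param effects Tibble from [effect_sizes()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(y = .data$unit_id, x = .data$mean)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower95, xmax = .data$upper95),
      height = 0, linewidth = 0.3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower75, xmax = .data$upper75),
      height = 0, linewidth = 1) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "Effect size (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Caterpillar plot of species-by-site occupancy estimates
#'
#' @param object A `psi_draws` array.
#' @param ... Unused.
#' @return A ggplot object (mean and 95% BCI per unit and site).
#' @export
autoplot.psi_draws <- function(object, ...) {
  d <- tidy.psi_draws(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$unit_id,
                                  color = .data$site_id)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower95, xmax = .data$upper95),
      height = 0, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Occupancy probability", y = NULL, color = "Site") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Fit a single-species occupancy model with known detection probability
#'
#' A deliberately small model used to validate the MCMC machinery against
#' dense-grid numerical integration: one species, a fixed per-occasion
#' detection probability `p`, and logit-linear occupancy
#' \eqn{logit(\psi_j) = \alpha + \beta x_j} with independent Normal(0,
#' `prior_sd`) priors on \eqn{\alpha, \beta}. The latent states are
#' marginalized analytically (each station's likelihood is
#' \eqn{\psi_j \prod_k p^{y_{jk}} (1-p)^{1-y_{jk}} + (1-\psi_j) [y_{j\cdot}=0]}),
#' so the sampler is a plain random-walk Metropolis on \eqn{(\alpha, \beta)}.
#'
#' @param y Binary station x occasion detection matrix.
#' @param x Station covariate vector.
#' @param p Known per-occasion detection probability in (0, 1).
#' @param prior_sd Prior sd of both coefficients (default 2.25).
#' @param iterations,burn_in,thin,chains MCMC settings.
#' @param seed Integer seed.
#' @return List with `draws` (list of per-chain matrices with columns
#'   `alpha`, `beta`) and `psi_mean` (posterior mean of the station-averaged
#'   occupancy).
#' @export
fit_single_species <- function(y, x, p, prior_sd = 2.25, iterations = 20000,
                               burn_in = 2000, thin = 2, chains = 2,
                               seed = 1) {
  stopifnot(is.matrix(y), length(x) == nrow(y), p > 0, p < 1)
  J <- nrow(y); K <- ncol(y)
  ydet <- rowSums(y)
  det_ll <- ydet * log(p) + (K - ydet) * log1p(-p)  # given z = 1
  none <- ydet == 0
  loglik <- function(a, b) {
    lin <- a + b * x
    psi <- plogis(lin)
    sum(log(psi * exp(det_ll) + (1 - psi) * none))
  }
  logpost <- function(a, b) {
    loglik(a, b) + stats::dnorm(a, 0, prior_sd, log = TRUE) +
      stats::dnorm(b, 0, prior_sd, log = TRUE)
  }
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("ss-chain", ch)))
    a <- rnorm(1); b <- rnorm(1)
    lp <- logpost(a, b)
    keep <- matrix(NA_real_, (iterations - burn_in) %/% thin, 2,
                   dimnames = list(NULL, c("alpha", "beta")))
    row <- 0
    step <- c(0.4, 0.4)
    acc <- c(0L, 0L); tries <- c(0L, 0L)
    for (it in seq_len(iterations)) {
      for (w in 1:2) {
        prop_a <- a + (w == 1) * rnorm(1, 0, step[1])
        prop_b <- b + (w == 2) * rnorm(1, 0, step[2])
        lp_new <- logpost(prop_a, prop_b)
        tries[w] <- tries[w] + 1L
        if (log(runif(1)) < lp_new - lp) {
          a <- prop_a; b <- prop_b; lp <- lp_new; acc[w] <- acc[w] + 1L
        }
      }
      if (it <= burn_in && it %% 100 == 0) {
        rate <- acc / pmax(tries, 1)
        step <- step * ifelse(rate < 0.25, 0.8, ifelse(rate > 0.45, 1.25, 1))
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        row <- row + 1
        keep[row, ] <- c(a, b)
      }
    }
    draws[[ch]] <- keep
  }
  pooled <- do.call(rbind, draws)
  psi_mean <- mean(vapply(seq_len(nrow(pooled)), function(r) {
    mean(plogis(pooled[r, 1] + pooled[r, 2] * x))
  }, numeric(1)))
  list(draws = draws, psi_mean = psi_mean)
}
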