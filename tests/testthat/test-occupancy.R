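test_that("Gelman-Rubin statistic behaves at its analytic anchors", {
  n <- 1000
  set.seed(5)
  ch <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "p"))
  # exact copies: between-chain variance 0 -> R-hat exactly 1
  expect_equal(gelman_rubin(list(ch, ch))$rhat, 1)

  # separated chains: direct formula evaluation as the oracle
  a <- matrix(rnorm(n, 0, 1), ncol = 1, dimnames = list(NULL, "p"))
  b <- matrix(rnorm(n, 5, 1), ncol = 1, dimnames = list(NULL, "p"))
  r <- gelman_rubin(list(a, b))$rhat
  W <- mean(c(var(a[, 1]), var(b[, 1])))
  B_n <- var(c(mean(a[, 1]), mean(b[, 1])))
  expect_equal(r, sqrt(((n - 1) / n * W + B_n) / W))
  expect_gt(r, 1.5)

  # same distribution, large n: near 1
  set.seed(6)
  c1 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "p"))
  c2 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "p"))
  expect_lt(gelman_rubin(list(c1, c2))$rhat, 1.05)

  # constant everywhere: total variance 0 -> defined as 1
  k <- matrix(rep(2, 100), ncol = 1, dimnames = list(NULL, "p"))
  expect_equal(gelman_rubin(list(k, k))$rhat, 1)

  expect_error(gelman_rubin(list(ch)), class = "defaunate_config_error")
})

test_that("Gelman-Rubin agrees with coda's point estimate", {
  set.seed(8)
  draws <- lapply(1:3, function(i) {
    matrix(rnorm(2000, i * 0.05), ncol = 1, dimnames = list(NULL, "theta"))
  })
  mine <- gelman_rubin(draws)$rhat
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(draws, coda::mcmc)),
                          autoburnin = FALSE)$psrf[1, 1]
  # coda applies a d.f. correction absent from the classic formula
  expect_equal(mine, cd, tolerance = 0.02)
})

test_that("posterior summaries use linear-interpolation percentiles", {
  const <- matrix(rep(3.2, 50), ncol = 1, dimnames = list(NULL, "a"))
  s <- summarize_posterior(list(const, const))
  expect_equal(s$mean, 3.2)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower75, s$upper75, s$lower95, s$upper95), rep(3.2, 4))

  d <- matrix(as.numeric(1:100), ncol = 1, dimnames = list(NULL, "a"))
  s2 <- summarize_posterior(list(d))
  expect_equal(s2$lower95, 3.475)
  expect_equal(s2$upper95, 97.525)

  set.seed(2)
  r <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "a"))
  s3 <- summarize_posterior(list(r))
  expect_gte(s3$lower75, s3$lower95)
  expect_lte(s3$upper75, s3$upper95)
})

test_that("detection log-likelihood matches brute-force summation", {
  st <- fixture_stations(n = 1, deploy_days = 10)
  rec <- tibble::tibble(station_id = "S1", unit_id = "u1",
                        date = st$deploy_start)
  h <- build_detection_history(rec, st)
  # one station, one occasion, effort covariate degenerates to 0:
  # p = plogis(a_p); choose a_p = 0 -> p = 0.5, y = 1, z = 1 -> log 0.5
  expect_message(
    ll <- occupancy_log_likelihood(matrix(1, 1, 1),
                                   list(a_p = 0, b_e = 0.7), h),
    "constant")
  expect_equal(ll, log(0.5))

  # z = 0 with all-zero detections contributes exactly 0
  h0 <- build_detection_history(rec[0, ], st, units = "u1")
  expect_message(
    ll0 <- occupancy_log_likelihood(matrix(0, 1, 1),
                                    list(a_p = 0.3, b_e = 0.1), h0))
  expect_equal(ll0, 0)

  # impossible state: detection where z = 0
  expect_message(
    llimp <- occupancy_log_likelihood(matrix(0, 1, 1),
                                      list(a_p = 0, b_e = 0), h))
  expect_equal(llimp, -Inf)

  # random fixture vs explicit triple loop
  st2 <- fixture_stations(n = 4, deploy_days = 63)
  set.seed(21)
  rec2 <- tibble::tibble(
    station_id = sample(st2$station_id, 30, replace = TRUE),
    unit_id = sample(c("u1", "u2"), 30, replace = TRUE),
    date = st2$deploy_start[1] + sample(0:62, 30, replace = TRUE)
  )
  h2 <- build_detection_history(rec2, st2, units = c("u1", "u2"))
  z <- matrix(1L, 2, 4)
  z[2, 3] <- 0L
  if (any(h2$y[2, 3, ] == 1)) z[2, 3] <- 1L
  params <- list(a_p = c(-0.5, 0.2), b_e = c(0.3, -0.1))
  ll2 <- occupancy_log_likelihood(z, params, h2)

  active <- h2$effort > 0
  ez <- matrix(NA_real_, 4, 7)
  ez[active] <- (h2$effort[active] - mean(h2$effort[active])) /
    sd(h2$effort[active])
  brute <- 0
  for (i in 1:2) {
    for (j in 1:4) {
      for (k in 1:7) {
        if (!active[j, k]) next
        p <- plogis(params$a_p[i] + params$b_e[i] * ez[j, k]) * z[i, j]
        brute <- brute + dbinom(h2$y[i, j, k], 1, p, log = TRUE)
      }
    }
  }
  expect_equal(ll2, brute)
})

test_that("single-species sampler is reproducible and well-behaved", {
  set.seed(31)
  y <- matrix(rbinom(12, 1, 0.4), 3, 4)
  y[2, ] <- 0
  x <- c(-1, 0, 1)
  f1 <- fit_single_species(y, x, p = 0.5, iterations = 4000, burn_in = 500,
                           seed = 4)
  f2 <- fit_single_species(y, x, p = 0.5, iterations = 4000, burn_in = 500,
                           seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_gt(f1$psi_mean, 0)
  expect_lt(f1$psi_mean, 1)
  expect_error(fit_single_species(y, x, p = 1.2))
})

test_that("community fit recovers parameters and flags convergence on a small landscape", {
  sl <- small_landscape(seed = 2, n_units = 10, stations_per_site = 15)
  fit <- suppressWarnings(suppressMessages(
    fit_community_occupancy(sl$history, sl$stations,
                            mcmc = mcmc_config(iterations = 3000,
                                               burn_in = 800, seed = 5))))
  expect_s3_class(fit, "occu_fit")
  g <- glance(fit)
  expect_equal(g$chains, 3)
  expect_equal(g$draws_per_chain, 1100)
  expect_true(all(tidy(fit)$sd >= 0))
  # hyper-sds must remain positive in every draw
  for (ch in fit$draws) {
    expect_true(all(ch[, grepl("^sd\\.", colnames(ch))] > 0))
  }
  # zero-detection units are excluded
  expect_true(all(apply(sl$history$y[fit$units, , ], 1, sum) > 0))
})

test_that("community sampler agrees with an independent JAGS fit", {
  sl <- small_landscape(seed = 12, n_units = 8, stations_per_site = 12)
  fit <- suppressMessages(
    fit_community_occupancy(sl$history, sl$stations,
                            mcmc = mcmc_config(iterations = 8000,
                                               burn_in = 2000, seed = 3)))
  mine <- summarize_posterior(fit, c("mu.b1", "mu.b2", "mu.p", "mu.e"))

  model_str <- "
  model {
    for (i in 1:I) {
      for (s in 1:S) { alpha[i,s] ~ dnorm(mu.alpha[s], tau.alpha[s]) }
      b1[i] ~ dnorm(mu.b1, tau.b1); b2[i] ~ dnorm(mu.b2, tau.b2)
      a.p[i] ~ dnorm(mu.p, tau.p); b.e[i] ~ dnorm(mu.e, tau.e)
      for (j in 1:J) {
        logit(psi[i,j]) <- alpha[i,site[j]] + b1[i]*x1[j] + b2[i]*x2[j]
        z[i,j] ~ dbern(psi[i,j])
        for (k in 1:K) {
          logit(p[i,j,k]) <- a.p[i] + b.e[i]*ez[j,k]
          y[i,j,k] ~ dbern(z[i,j]*p[i,j,k])
        }
      }
    }
    for (s in 1:S) {
      mu.alpha[s] ~ dnorm(0, 0.1975)
      tau.alpha[s] <- pow(sd.alpha[s], -2); sd.alpha[s] ~ dunif(0, 5)
    }
    mu.b1 ~ dnorm(0, 0.1975); tau.b1 <- pow(sd.b1, -2); sd.b1 ~ dunif(0, 5)
    mu.b2 ~ dnorm(0, 0.1975); tau.b2 <- pow(sd.b2, -2); sd.b2 ~ dunif(0, 5)
    mu.p ~ dnorm(0, 0.1975); tau.p <- pow(sd.p, -2); sd.p ~ dunif(0, 5)
    mu.e ~ dnorm(0, 0.1975); tau.e <- pow(sd.e, -2); sd.e ~ dunif(0, 5)
  }"
  h <- sl$history
  keep <- apply(h$y, 1, sum) > 0
  y <- h$y[keep, , , drop = FALSE]
  active <- h$effort > 0
  ez <- h$effort
  ez[active] <- (ez[active] - mean(ez[active])) / sd(ez[active])
  ez[!active] <- 0
  ymiss <- y
  for (k in seq_len(dim(y)[3])) ymiss[, !active[, k], k] <- NA
  sites <- sort(unique(sl$stations$site_id))
  data <- list(
    y = ymiss, I = dim(y)[1], J = dim(y)[2], K = dim(y)[3],
    S = length(sites), site = match(sl$stations$site_id, sites),
    x1 = sl$stations$canopy_z, x2 = sl$stations$village_density_z, ez = ez
  )
  set.seed(99)
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = list(z = apply(y, c(1, 2), max)),
                          n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 1500)
  js <- rjags::coda.samples(jm, c("mu.b1", "mu.b2", "mu.p", "mu.e"), 6000)
  jsum <- summary(js)$statistics

  for (p in c("mu.b1", "mu.b2", "mu.p", "mu.e")) {
    m <- mine$mean[mine$parameter == p]
    jm_mean <- jsum[p, "Mean"]
    jm_sd <- jsum[p, "SD"]
    expect_lt(abs(m - jm_mean), max(0.4 * jm_sd, 0.1),
              label = sprintf("|%s: %0.3f - %0.3f|", p, m, jm_mean))
  }
})

test_that("species-site occupancy matches closed forms and brute-force averaging", {
  # hand-built fit: 1 unit, 2 sites (2 + 1 stations), point-mass draws
  units <- "u1"
  cov <- tibble::tibble(
    station_id = c("A1", "A2", "B1"),
    site_id = c("sA", "sA", "sB"),
    c1 = c(0, 0, 0), c2 = c(0, 0, 0)
  )
  a <- 0.7
  dm <- matrix(rep(c(a, a, 0, 0), each = 20), nrow = 20,
               dimnames = list(NULL, c("alpha[1,1]", "alpha[1,2]",
                                       "b1[1]", "b2[1]")))
  fit <- structure(list(draws = list(dm), units = units,
                        sites = c("sA", "sB"), covariates = cov,
                        covariate_cols = c("c1", "c2")),
                   class = "occu_fit")
  psi <- species_site_occupancy(fit)
  expect_equal(dim(unclass(psi)), c(20, 1, 2))
  expect_equal(unique(as.vector(psi[, "u1", "sA"])), plogis(a))
  expect_equal(unique(as.vector(psi[, "u1", "sB"])), plogis(a))

  # random draws, nonzero covariates: brute-force per-draw averaging oracle
  set.seed(14)
  cov$c1 <- c(-0.5, 1.2, 0.3); cov$c2 <- c(0.1, -1, 0.7)
  dm2 <- cbind(`alpha[1,1]` = rnorm(20), `alpha[1,2]` = rnorm(20),
               `b1[1]` = rnorm(20), `b2[1]` = rnorm(20))
  fit$draws <- list(dm2)
  fit$covariates <- cov
  psi2 <- species_site_occupancy(fit)
  for (r in c(1, 7, 20)) {
    stn_psi <- unname(plogis(dm2[r, paste0("alpha[1,", c(1, 1, 2), "]")] +
                               dm2[r, "b1[1]"] * cov$c1 +
                               dm2[r, "b2[1]"] * cov$c2))
    expect_equal(psi2[r, 1, "sA"], mean(stn_psi[1:2]))
    expect_equal(psi2[r, 1, "sB"], stn_psi[3]) # single-station site
  }
  td <- tidy(psi2)
  expect_equal(nrow(td), 2)
  expect_true(all(td$lower95 <= td$lower75 & td$upper75 <= td$upper95))
})

test_that("effect-size zero-exclusion flags equal brute-force percentile checks", {
  set.seed(17)
  I <- 3
  draws <- cbind(
    matrix(rnorm(600 * I, mean = rep(c(2, 0, -0.1), each = 600), sd = 1),
           600, I, dimnames = list(NULL, sprintf("b1[%d]", 1:I))),
    matrix(abs(rnorm(600 * I)) + 0.01, 600, I,
           dimnames = list(NULL, sprintf("b2[%d]", 1:I))),
    `mu.b1` = rnorm(600, 0, 0.05), `mu.b2` = rnorm(600, 3, 0.2)
  )
  fit <- fake_fit(list(draws), units = c("ua", "ub", "uc"))
  es <- effect_sizes(fit)
  expect_equal(nrow(es), 2 * I + 2)
  # all-positive draws exclude zero everywhere
  expect_true(all(es$excludes_zero_95[es$covariate == "c2" &
                                        es$unit_id != "(community)"]))
  # flags equal direct percentile checks on the pooled draws
  for (r in seq_len(nrow(es))) {
    par <- if (es$unit_id[r] == "(community)") {
      paste0("mu.", sub("c", "b", es$covariate[r]))
    } else {
      sprintf("%s[%d]", sub("c", "b", es$covariate[r]),
              match(es$unit_id[r], fit$units))
    }
    q95 <- quantile(draws[, par], c(0.025, 0.975), names = FALSE)
    expect_equal(es$excludes_zero_95[r], q95[1] > 0 | q95[2] < 0)
    q75 <- quantile(draws[, par], c(0.125, 0.875), names = FALSE)
    expect_equal(es$excludes_zero_75[r], q75[1] > 0 | q75[2] < 0)
  }
})

test_that("station order does not affect the fitted posterior", {
  sl <- small_landscape(seed = 23, n_units = 10, stations_per_site = 20)
  mc <- mcmc_config(iterations = 10000, burn_in = 2500, seed = 9)
  fit1 <- suppressWarnings(suppressMessages(
    fit_community_occupancy(sl$history, sl$stations, mcmc = mc)))
  set.seed(77)
  perm <- sample(nrow(sl$stations))
  st_p <- sl$stations[perm, ]
  h_p <- build_detection_history(sl$bundle$records, st_p,
                                 units = sl$bundle$traits$unit_id)
  fit2 <- suppressWarnings(suppressMessages(
    fit_community_occupancy(h_p, st_p, mcmc = mc)))
  s1 <- summarize_posterior(fit1, c("mu.b1", "mu.b2", "mu.p"))
  s2 <- summarize_posterior(fit2, c("mu.b1", "mu.b2", "mu.p"))
  # identical posteriors up to Monte-Carlo error: compare on the sd scale
  expect_true(all(abs(s1$mean - s2$mean) < 0.4 * pmax(s1$sd, s2$sd)))
  expect_true(all(abs(s1$sd - s2$sd) < 0.4 * pmax(s1$sd, s2$sd)))
})

test_that("logistic and logit round-trip through the psi scale", {
  x <- c(-30, -3, 0, 0.5, 10)
  expect_equal(qlogis(plogis(x)), x, tolerance = 1e-12)
  sl <- small_landscape(seed = 3, n_units = 5, stations_per_site = 8)
  fit <- suppressWarnings(suppressMessages(
    fit_community_occupancy(sl$history, sl$stations,
                            mcmc = mcmc_config(iterations = 2000,
                                               burn_in = 500, seed = 2))))
  psi <- species_site_occupancy(fit)
  expect_true(all(psi > 0 & psi < 1))
})
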