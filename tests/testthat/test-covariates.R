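test_that("canopy fraction counts vegetation pixels", {
  expect_equal(canopy_fraction(matrix(0, 5, 5)), 1.0)

  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  expect_equal(canopy_fraction(checker), 0.5)

  set.seed(3)
  m <- matrix(0, 10, 10)
  m[sample(100, 100 - 37)] <- 1 # 37 vegetation (0) pixels
  expect_equal(canopy_fraction(m), 0.37)

  expect_error(canopy_fraction(matrix(c(0, 0.4, 1, 1), 2)),
               "binarize", class = "defaunate_format_error")

  # pixel replication (doubling resolution) leaves the fraction unchanged
  up <- m[rep(1:10, each = 2), rep(1:10, each = 2)]
  expect_equal(canopy_fraction(up), canopy_fraction(m))

  # polarity flag flips which class is vegetation
  expect_equal(canopy_fraction(m, vegetation = "light"), 0.63)
})

test_that("station canopy averages the photo fractions", {
  five <- replicate(5, matrix(c(0, 1), 2, 2), simplify = FALSE)
  f <- canopy_fraction(five[[1]])
  expect_equal(station_canopy(five), f)

  mats <- list(matrix(0, 2, 2),                 # 1.0
               matrix(c(0, 1, 0, 1), 2),        # 0.5
               matrix(c(0, 1, 1, 0), 2),        # 0.5
               matrix(c(1, 0, 0, 1), 2),        # 0.5
               matrix(1, 2, 2))                 # 0.0
  expect_equal(station_canopy(mats), 0.5)

  expect_warning(out <- station_canopy(mats[1:3]), "5 canopy photos")
  expect_equal(out, mean(c(1, 0.5, 0.5)))
  expect_error(station_canopy(list()), class = "defaunate_format_error")

  # oracle: independent mean of per-photo fractions on random rasters
  set.seed(11)
  rnd <- replicate(5, matrix(rbinom(64, 1, 0.4), 8, 8), simplify = FALSE)
  expect_equal(station_canopy(rnd),
               mean(vapply(rnd, function(r) mean(r == 0), numeric(1))))
})

test_that("village density follows the quartic kernel", {
  st <- tibble::tibble(station_id = "S1", x = 0, y = 0)

  expect_equal(village_density(st, tibble::tibble(x = 16000, y = 0))$village_density, 0)
  expect_equal(village_density(st, tibble::tibble(x = 0, y = 0))$village_density, 1)
  expect_equal(village_density(st, tibble::tibble(x = 7500, y = 0))$village_density,
               (1 - 0.25)^2)
  expect_error(village_density(st, tibble::tibble(x = 0, y = 0), radius = -1),
               class = "defaunate_config_error")

  # monotone in distance of a single village; additive over villages
  ds <- seq(0, 14999, length.out = 50)
  vals <- vapply(ds, function(d) {
    village_density(st, tibble::tibble(x = d, y = 0))$village_density
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))

  vs <- tibble::tibble(x = c(1000, 9000, 20000), y = c(0, -3000, 5))
  total <- village_density(st, vs)$village_density
  parts <- vapply(seq_len(nrow(vs)), function(i) {
    village_density(st, vs[i, ])$village_density
  }, numeric(1))
  expect_equal(total, sum(parts))
})

test_that("covariate normalization is per-group, exact and idempotent", {
  st <- tibble::tibble(
    station_id = sprintf("S%d", 1:6),
    landscape_id = rep(c("L1", "L2"), each = 3),
    canopy = c(1, 2, 3, 10, 20, 60),
    village_density = c(0.3, 0.1, 0.9, 4, 5, 9)
  )
  out <- normalize_covariates(st)
  expect_equal(out$canopy_z[1:3], c(-1, 0, 1))
  for (l in c("L1", "L2")) {
    g <- out[out$landscape_id == l, ]
    expect_equal(mean(g$canopy_z), 0, tolerance = 1e-9)
    expect_equal(sd(g$canopy_z), 1, tolerance = 1e-9)
    expect_equal(mean(g$village_density_z), 0, tolerance = 1e-9)
  }

  # idempotent: normalizing an already-normalized column is the identity
  st2 <- dplyr::mutate(out, canopy = .data$canopy_z)
  out2 <- normalize_covariates(st2, cols = "canopy")
  expect_equal(out2$canopy_z, out$canopy_z, tolerance = 1e-12)

  st$canopy[1:3] <- 5
  expect_error(normalize_covariates(st),
               class = "defaunate_constant_error")
})

test_that("moment-matching subsetter finds near-optimal subsets", {
  vals <- seq(0.1, 1.0, by = 0.1)

  # trivial cases
  full <- subset_match(vals, mean(vals), sd(vals), 10, seed = 1)
  expect_equal(sort(as.integer(full)), 1:10)
  expect_equal(attr(full, "loss"), 0)
  one <- subset_match(vals, 0.72, 0.1, 1, seed = 1)
  expect_equal(vals[as.integer(one)], 0.7)
  expect_error(subset_match(vals, 0.5, 0.1, 11),
               class = "defaunate_config_error")

  # Monte-Carlo oracle: the greedy subset beats almost all random subsets
  sel <- subset_match(vals, target_mean = 0.83, target_sd = 0.05, n_out = 4,
                      seed = 7)
  loss <- function(idx) {
    abs(mean(vals[idx]) - 0.83) / 0.05 + abs(sd(vals[idx]) - 0.05) / 0.05
  }
  set.seed(99)
  rand_losses <- replicate(10000, loss(sample(10, 4)))
  expect_gte(mean(attr(sel, "loss") <= rand_losses), 0.99)
})
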