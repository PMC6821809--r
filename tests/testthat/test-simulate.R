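test_that("generated stations respect the spacing target and are reproducible", {
  cfg <- scenario_config(n_landscapes = 1, sites_per_landscape = 1,
                         stations_per_site = 80)
  st <- generate_stations(cfg, seed = 2)
  nn <- vapply(seq_len(nrow(st)), function(i) {
    d <- sqrt((st$x - st$x[i])^2 + (st$y - st$y[i])^2)
    min(d[-i])
  }, numeric(1))
  expect_lt(abs(mean(nn) - 2500) / 2500, 0.1)

  expect_identical(generate_stations(cfg, seed = 2), st)
  expect_false(identical(generate_stations(cfg, seed = 3), st))

  one <- scenario_config(n_landscapes = 1, sites_per_landscape = 1,
                         stations_per_site = 1)
  expect_equal(nrow(generate_stations(one, seed = 1)), 1)

  # four stations at 2.5 km target: mean NN distance in [2.25, 2.75] km
  four <- scenario_config(n_landscapes = 1, sites_per_landscape = 1,
                          stations_per_site = 4)
  st4 <- generate_stations(four, seed = 5)
  nn4 <- vapply(1:4, function(i) {
    d <- sqrt((st4$x - st4$x[i])^2 + (st4$y - st4$y[i])^2)
    min(d[-i])
  }, numeric(1))
  expect_gte(mean(nn4), 2250)
  expect_lte(mean(nn4), 2750)
})

test_that("generated covariates hit their target moments and bounds", {
  cfg <- scenario_config(n_landscapes = 1, sites_per_landscape = 3,
                         stations_per_site = 80, canopy_mean = 0.8,
                         canopy_sd = 0.05)
  st <- generate_stations(cfg, seed = 4)
  vi <- generate_villages(st, cfg, seed = 4)
  out <- generate_covariates(st, vi, cfg, seed = 4)
  expect_true(all(out$canopy >= 0 & out$canopy <= 1))
  expect_lt(abs(mean(out$canopy) - 0.8), 0.03)
  expect_true(all(out$village_density >= 0))

  novil <- generate_covariates(st, vi[0, ], cfg, seed = 4)
  expect_true(all(novil$village_density == 0))
})

test_that("community draws follow their hyperparameters", {
  cfg0 <- scenario_config(n_landscapes = 1, n_units = 40,
                          hyper = list(list(sd_alpha = 0, sd_b1 = 0,
                                            sd_b2 = 0, sd_p = 0, sd_e = 0)))
  comm0 <- generate_community(cfg0, seed = 3)
  expect_true(all(comm0$b1 == comm0$hyper$mu_b1))
  expect_true(all(comm0$alpha == comm0$hyper$mu_alpha))

  cfg <- scenario_config(n_landscapes = 1, n_units = 400)
  comm <- generate_community(cfg, seed = 8)
  h <- comm$hyper
  expect_lt(abs(mean(comm$b1) - h$mu_b1), 3 * h$sd_b1 / sqrt(400))
  expect_identical(generate_community(cfg, seed = 8)$b1, comm$b1)
})

test_that("detection simulation honours its degenerate limits", {
  cfg <- scenario_config(n_landscapes = 1, sites_per_landscape = 1,
                         stations_per_site = 10, n_units = 3)
  st <- generate_stations(cfg, seed = 1)
  vi <- generate_villages(st, cfg, seed = 1)
  st <- generate_covariates(st, vi, cfg, seed = 1)
  comm <- generate_community(cfg, seed = 1)

  # psi ~ 0: no occupancy, no records
  never <- comm
  never$alpha[] <- -50; never$b1[] <- 0; never$b2[] <- 0
  sim0 <- simulate_detections(never, st, cfg, seed = 2)
  expect_equal(nrow(sim0$records), 0)
  expect_true(all(sim0$truth$z == 0))

  # psi ~ 1 and p ~ 1: a record for every unit, station and occasion
  always <- comm
  always$alpha[] <- 50; always$b1[] <- 0; always$b2[] <- 0
  always$a_p[] <- 50; always$b_e[] <- 0
  sim1 <- simulate_detections(always, st, cfg, seed = 2)
  n_cells <- sum(sim1$truth$effort > 0) * cfg$n_units
  expect_equal(sum(sim1$truth$y), n_cells)
  expect_equal(nrow(sim1$records), n_cells)
})

test_that("realized presence frequencies match the closed-form detection probability", {
  # one unit, many stations, constant psi and p, constant K
  cfg <- scenario_config(n_landscapes = 1, sites_per_landscape = 1,
                         stations_per_site = 500, n_units = 1,
                         deploy_days = 70,
                         hyper = list(list(mu_alpha = 0.4, sd_alpha = 0,
                                           sd_b1 = 0, mu_b1 = 0,
                                           sd_b2 = 0, mu_b2 = 0,
                                           mu_p = -0.6, sd_p = 0,
                                           mu_e = 0, sd_e = 0)))
  st <- generate_stations(cfg, seed = 6)
  vi <- generate_villages(st, cfg, seed = 6)
  st <- generate_covariates(st, vi, cfg, seed = 6)
  comm <- generate_community(cfg, seed = 6)
  sim <- suppressMessages(simulate_detections(comm, st, cfg, seed = 7))
  K <- 7
  psi <- plogis(0.4); p <- plogis(-0.6)
  expected <- psi * (1 - (1 - p)^K)
  naive <- mean(apply(sim$truth$y[1, , ], 1, max))
  expect_lt(abs(naive - expected), 3 * sqrt(expected * (1 - expected) / 500))
})

test_that("simulated records round-trip exactly into the generating tensor", {
  set.seed(100)
  for (rep in 1:10) {
    cfg <- scenario_config(
      n_landscapes = 1,
      sites_per_landscape = sample(1:3, 1),
      stations_per_site = sample(5:20, 1),
      n_units = sample(2:10, 1)
    )
    seed <- sample.int(10000, 1)
    b <- simulate_study(cfg, seed = seed)
    st <- b$stations
    h <- build_detection_history(b$records, st, units = b$traits$unit_id)
    expect_identical(h$y, b$truth$L1$y, )
    expect_equal(h$effort, b$truth$L1$effort)
    # every record inside its deployment window
    j <- match(b$records$station_id, st$station_id)
    expect_true(all(b$records$date >= st$deploy_start[j] &
                      b$records$date <= st$deploy_end[j]))
  }
})

test_that("the paper-scale fixture loads through the I/O layer and keeps its contrast", {
  dir <- tempfile("fixture")
  b <- paper_scale_fixture(seed = 1, dir = dir)
  expect_setequal(list.files(dir),
                  c("records.csv", "stations.csv", "traits.csv",
                    "villages.csv"))
  st <- read_stations(file.path(dir, "stations.csv"))
  tr <- read_species_traits(file.path(dir, "traits.csv"))
  rec <- read_detection_records(file.path(dir, "records.csv"), st)
  vi <- read_villages(file.path(dir, "villages.csv"))
  expect_equal(nrow(st), 480)   # 2 landscapes x 3 sites x 80 stations
  expect_equal(nrow(tr), 30)
  expect_gt(nrow(rec), 0)
  merged <- merge_to_analysis_units(rec, tr)
  expect_setequal(unique(merged$unit_id), unique(b$records$unit_id))
  # the generating contrast: L1 canopy-driven, L2 village-driven
  expect_equal(b$truth$L1$params$hyper$mu_b1, 1)
  expect_equal(b$truth$L1$params$hyper$mu_b2, 0)
  expect_equal(b$truth$L2$params$hyper$mu_b1, 0)
  expect_equal(b$truth$L2$params$hyper$mu_b2, -1)
})
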