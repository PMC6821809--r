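# Small in-code fixtures shared across test files.

fixture_stations <- function(n = 3, deploy_days = 60,
                             start = as.Date("2015-01-01")) {
  tibble::tibble(
    station_id = sprintf("S%d", seq_len(n)),
    site_id = "siteA",
    landscape_id = "L1",
    x = 1e6 + seq_len(n) * 2500,
    y = 1e6,
    deploy_start = start,
    deploy_end = start + deploy_days - 1L
  )
}

fixture_traits <- function() {
  tibble::tibble(
    unit_id = c("Manis spp.", "civet", "muntjac"),
    member_species = list(c("Manis pentadactyla", "Manis javanica"),
                          "Paradoxurus hermaphroditus",
                          "Muntiacus muntjak"),
    iucn = c("CR", "LC", "DD"),
    body_mass_g = c(5000, 3200, 14000),
    pair_id = c("p1", "p2", "p3")
  )
}

write_fixture_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# A deliberately small simulated landscape for fast model tests.
small_landscape <- function(seed = 1, n_units = 8, stations_per_site = 12,
                            sites = 2, hyper = list()) {
  cfg <- scenario_config(
    n_landscapes = 1, sites_per_landscape = sites,
    stations_per_site = stations_per_site, n_units = n_units,
    hyper = list(hyper)
  )
  b <- simulate_study(cfg, seed = seed)
  st <- normalize_covariates(b$stations, group = NULL)
  h <- build_detection_history(b$records, st, units = b$traits$unit_id)
  list(bundle = b, stations = st, history = h, config = cfg)
}

# Minimal hand-built occu_fit-shaped object for summary-level functions.
fake_fit <- function(draw_list, units, covariate_cols = c("c1", "c2")) {
  structure(list(draws = draw_list, units = units,
                 covariate_cols = covariate_cols),
            class = "occu_fit")
}
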