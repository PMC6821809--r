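#' Scenario configuration for the synthetic study generator
#'
#' Defaults emulate the source study design: two landscapes (one "hunted",
#' one "degraded") of three sites each, 80 stations per site spaced ~2.5 km
#' on a jittered grid, 70-day deployments pooled into 10-day occasions (7
#' occasions), and a 30-unit community whose logit-scale occupancy and
#' detection parameters are drawn from community-level normal distributions
#' with canopy and village-density effects.
#'
#' `hyper` holds one list of community hyperparameters per landscape, each
#' with elements `mu_alpha`, `sd_alpha` (site intercepts), `mu_b1`, `sd_b1`
#' (canopy effect), `mu_b2`, `sd_b2` (village-density effect), `mu_p`, `sd_p`
#' (detection intercept) and `mu_e`, `sd_e` (effort slope; effort enters the
#' detection predictor z-scored).
#'
#' `canopy_mean`/`canopy_sd` are the target canopy-closure moments per
#' landscape (defaults 0.77/0.20 and 0.83/0.05, the degraded vs hunted
#' contrast of the emulated design); `n_villages` gives village counts per
#' landscape.
#'
#' @param n_landscapes,sites_per_landscape,stations_per_site,n_units Design
#'   counts.
#' @param spacing Target station spacing in meters (default 2500).
#' @param deploy_days Deployment length in days: either a single value or a
#'   `c(min, max)` range sampled uniformly per station. The default
#'   `c(61, 70)` gives every station exactly 7 ten-day occasions (six full
#'   plus a trailing partial), a ~65-day mean deployment, and varying
#'   trailing effort, as real staggered deployments do.
#' @param occasion_length Occasion length in days (default 10).
#' @param canopy_mean,canopy_sd Canopy moments, recycled across landscapes.
#' @param n_villages Villages per landscape, recycled.
#' @param hyper List of per-landscape hyperparameter lists (recycled if one).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_landscapes = 2, sites_per_landscape = 3,
                            stations_per_site = 80, spacing = 2500,
                            n_units = 30, deploy_days = c(61, 70),
                            occasion_length = 10,
                            canopy_mean = c(0.77, 0.83),
                            canopy_sd = c(0.20, 0.05),
                            n_villages = c(8, 25),
                            hyper = NULL) {
  stopifnot(n_landscapes >= 1, sites_per_landscape >= 1,
            stations_per_site >= 1, n_units >= 1, spacing > 0,
            all(deploy_days >= 1), length(deploy_days) %in% 1:2,
            occasion_length >= 1)
  default_hyper <- list(
    mu_alpha = 0, sd_alpha = 1,
    mu_b1 = 1, sd_b1 = 0.5,
    mu_b2 = -0.5, sd_b2 = 0.5,
    mu_p = -1, sd_p = 0.5,
    mu_e = 0.3, sd_e = 0.2
  )
  if (is.null(hyper)) hyper <- list(default_hyper)
  if (!is.null(names(hyper)) && "mu_b1" %in% names(hyper)) hyper <- list(hyper)
  hyper <- rep_len(hyper, n_landscapes)
  hyper <- lapply(hyper, function(h) utils::modifyList(default_hyper, h))
  for (h in hyper) {
    if (any(unlist(h[grepl("^sd_", names(h))]) < 0)) {
      stop_defaunate("hyperparameter sds must be >= 0",
                     "defaunate_config_error")
    }
  }
  structure(list(
    n_landscapes = n_landscapes,
    sites_per_landscape = sites_per_landscape,
    stations_per_site = stations_per_site,
    spacing = spacing, n_units = n_units,
    deploy_days = deploy_days, occasion_length = occasion_length,
    canopy_mean = rep_len(canopy_mean, n_landscapes),
    canopy_sd = rep_len(canopy_sd, n_landscapes),
    n_villages = rep_len(n_villages, n_landscapes),
    hyper = hyper
  ), class = "scenario_config")
}

#' Generate camera-trap stations on a jittered grid
#'
#' Lays each site out as a near-square grid at the target spacing with
#' uniform positional jitter of ±8% of the spacing, so the mean
#' nearest-neighbor distance stays within 10% of the target. Sites within a
#' landscape are placed side by side with a one-spacing gap; landscapes are
#' far apart. Deployment windows all last `deploy_days`, with start dates
#' staggered over 60 days within each site.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return Station tibble (as from [read_stations()]).
#' @export
generate_stations <- function(config, seed = 1) {
  set.seed(substream_seed(seed, "stations"))
  n <- config$stations_per_site
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  sp <- config$spacing
  out <- purrr::map_dfr(seq_len(config$n_landscapes), function(l) {
    purrr::map_dfr(seq_len(config$sites_per_landscape), function(s) {
      gx <- ((seq_len(n) - 1) %% ncol_grid)
      gy <- ((seq_len(n) - 1) %/% ncol_grid)
      jit <- if (n > 1) 0.08 * sp else 0
      x0 <- 1e6 * l + (s - 1) * (ncol_grid + 1) * sp
      tibble::tibble(
        station_id = sprintf("L%d-S%d-%03d", l, s, seq_len(n)),
        site_id = sprintf("L%d-S%d", l, s),
        landscape_id = sprintf("L%d", l),
        x = x0 + gx * sp + runif(n, -jit, jit),
        y = 1e6 + gy * sp + runif(n, -jit, jit),
        deploy_start = as.Date("2015-01-01") +
          sample.int(60, n, replace = TRUE) - 1L,
        deploy_end = NA
      )
    })
  })
  dd <- config$deploy_days
  len <- if (length(dd) == 2) {
    sample(seq(dd[1], dd[2]), nrow(out), replace = TRUE)
  } else {
    rep(dd, nrow(out))
  }
  out$deploy_end <- out$deploy_start + len - 1L
  out
}

#' Generate village points around each landscape's stations
#'
#' Villages are placed uniformly in the bounding box of the landscape's
#' stations expanded by 10 km on every side, mimicking settlements around
#' the survey-area periphery.
#'
#' @param stations Station tibble.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return Village tibble with `x`, `y`, `landscape_id`.
#' @export
generate_villages <- function(stations, config, seed = 1) {
  set.seed(substream_seed(seed, "villages"))
  buffer <- 10000
  purrr::map_dfr(seq_len(config$n_landscapes), function(l) {
    land <- sprintf("L%d", l)
    st <- stations[stations$landscape_id == land, ]
    nv <- config$n_villages[l]
    tibble::tibble(
      x = runif(nv, min(st$x) - buffer, max(st$x) + buffer),
      y = runif(nv, min(st$y) - buffer, max(st$y) + buffer),
      landscape_id = land
    )
  })
}

#' Generate station covariates (canopy closure, village density)
#'
#' Canopy closure is a smooth spatial field: Gaussian-kernel-smoothed white
#' noise over the stations (kernel range twice the station spacing), rescaled
#' to the landscape's target mean/sd and clamped to `[0, 1]`. Village density
#' is computed from the generated village points with [village_density()].
#'
#' @param stations Station tibble.
#' @param villages Village tibble.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return `stations` with `canopy` and `village_density` columns appended.
#' @export
generate_covariates <- function(stations, villages, config, seed = 1) {
  set.seed(substream_seed(seed, "covariates"))
  canopy <- rep(NA_real_, nrow(stations))
  range2 <- (2 * config$spacing)^2
  for (l in seq_len(config$n_landscapes)) {
    land <- sprintf("L%d", l)
    idx <- which(stations$landscape_id == land)
    st <- stations[idx, ]
    noise <- rnorm(length(idx))
    d2 <- outer(st$x, st$x, "-")^2 + outer(st$y, st$y, "-")^2
    w <- exp(-d2 / (2 * range2))
    field <- as.vector(w %*% noise) / rowSums(w)
    field <- (field - mean(field)) / sd(field)
    canopy[idx] <- pmin(1, pmax(0, config$canopy_mean[l] +
                                  config$canopy_sd[l] * field))
  }
  stations$canopy <- canopy
  village_density(stations, villages)
}

#' Draw a synthetic community from its hyperparameters
#'
#' Per-unit occupancy intercepts (one per site), covariate coefficients and
#' detection parameters are drawn from the landscape's community normal
#' distributions.
#'
#' @param config A [scenario_config()].
#' @param landscape Landscape index (selects the hyperparameter set).
#' @param seed Integer seed.
#' @return List with `units` (character), matrix `alpha` (unit x site) and
#'   vectors `b1`, `b2`, `a_p`, `b_e`; the generating hyperparameters are
#'   attached as `hyper`.
#' @export
generate_community <- function(config, landscape = 1, seed = 1) {
  set.seed(substream_seed(seed, paste0("community", landscape)))
  h <- config$hyper[[landscape]]
  I <- config$n_units
  S <- config$sites_per_landscape
  list(
    units = sprintf("unit%02d", seq_len(I)),
    alpha = matrix(rnorm(I * S, h$mu_alpha, h$sd_alpha), I, S),
    b1 = rnorm(I, h$mu_b1, h$sd_b1),
    b2 = rnorm(I, h$mu_b2, h$sd_b2),
    a_p = rnorm(I, h$mu_p, h$sd_p),
    b_e = rnorm(I, h$mu_e, h$sd_e),
    hyper = h
  )
}

#' Simulate detection records for one landscape
#'
#' Normalizes the covariates within the landscape exactly as the fitting
#' routine will, draws the latent occupancy states `z ~ Bern(psi)`, then
#' occasion-level detections `y ~ Bern(z * p)` with effort (z-scored active
#' days) on the detection predictor, and converts detections into dated
#' records (one record per detected unit-station-occasion, dated to the
#' occasion's first day — the pipeline only uses occasion-level presence).
#'
#' @param community Output of [generate_community()].
#' @param stations Station tibble for one landscape, with `canopy` and
#'   `village_density` columns.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `records` (tibble `station_id`, `unit_id`, `date`) and
#'   `truth` (list: `psi`, `z`, `y`, `effort`, `effort_z`, `params`,
#'   `covariates`).
#' @export
simulate_detections <- function(community, stations, config, seed = 1) {
  set.seed(substream_seed(seed, "detections"))
  st <- normalize_covariates(stations, group = NULL)
  sites <- sort(unique(st$site_id))
  site_idx <- match(st$site_id, sites)
  I <- length(community$units); J <- nrow(st)

  # effort exactly as build_detection_history() will compute it
  empty <- tibble::tibble(station_id = character(), unit_id = character(),
                          date = as.Date(character()))
  h0 <- build_detection_history(empty, st,
                                occasion_length = config$occasion_length,
                                units = community$units)
  effort <- h0$effort
  K <- ncol(effort)
  active <- effort > 0
  effort_z <- zscore_effort(effort, active)

  lin <- community$alpha[, site_idx, drop = FALSE] +
    outer(community$b1, st$canopy_z) +
    outer(community$b2, st$village_density_z)
  psi <- plogis(lin)
  z <- matrix(rbinom(I * J, 1, psi), I, J)

  y <- array(0L, dim = c(I, J, K),
             dimnames = list(community$units, st$station_id, NULL))
  for (k in seq_len(K)) {
    act <- which(active[, k])
    if (length(act) == 0) next
    p <- plogis(outer(community$a_p, rep(1, length(act))) +
                  outer(community$b_e, effort_z[act, k]))
    y[, act, k] <- rbinom(I * length(act), 1, z[, act, drop = FALSE] * p)
  }

  hits <- which(y == 1L, arr.ind = TRUE)
  records <- tibble::tibble(
    station_id = st$station_id[hits[, 2]],
    unit_id = community$units[hits[, 1]],
    date = st$deploy_start[hits[, 2]] +
      (hits[, 3] - 1L) * config$occasion_length
  )
  records <- dplyr::arrange(records, .data$unit_id, .data$station_id,
                            .data$date)
  list(
    records = records,
    truth = list(psi = psi, z = z, y = y, effort = effort,
                 effort_z = effort_z, params = community,
                 covariates = st)
  )
}

#' Generate a complete synthetic study
#'
#' Chains the generators into a full input bundle: stations, villages,
#' covariates, one community per landscape (the same unit labels across
#' landscapes, mirroring cross-landscape analysis units), detection records,
#' and a trait table with IUCN categories and body masses. The ground truth
#' of every landscape is kept for recovery testing.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed driving every stage through named sub-streams.
#' @param dir Optional directory; when given, the bundle is also written as
#'   `records.csv`, `stations.csv`, `traits.csv`, `villages.csv`.
#' @return List with `records`, `stations` (covariates included), `villages`,
#'   `traits`, `truth` (per-landscape list), `config`, `seed`.
#' @export
simulate_study <- function(config = scenario_config(), seed = 1, dir = NULL) {
  stations <- generate_stations(config, seed)
  villages <- generate_villages(stations, config, seed)
  stations <- generate_covariates(stations, villages, config, seed)

  set.seed(substream_seed(seed, "traits"))
  units <- sprintf("unit%02d", seq_len(config$n_units))
  traits <- tibble::tibble(
    unit_id = units,
    member_species = as.list(units),
    iucn = sample(c("LC", "NT", "VU", "EN", "CR", "DD"), config$n_units,
                  replace = TRUE, prob = c(0.35, 0.2, 0.2, 0.1, 0.05, 0.1)),
    body_mass_g = round(exp(runif(config$n_units, log(500), log(150000)))),
    pair_id = units
  )

  records <- list(); truth <- list()
  for (l in seq_len(config$n_landscapes)) {
    land <- sprintf("L%d", l)
    st_l <- stations[stations$landscape_id == land, ]
    comm <- generate_community(config, l, seed)
    sim <- simulate_detections(comm, st_l, config,
                               substream_seed(seed, paste0("landscape", l)))
    records[[l]] <- sim$records
    truth[[land]] <- sim$truth
  }
  records <- dplyr::bind_rows(records)

  bundle <- list(records = records, stations = stations,
                 villages = villages[, c("x", "y")], traits = traits,
                 truth = truth, config = config, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    raw <- dplyr::rename(records, species = "unit_id")
    write_detection_records(raw[, c("station_id", "species", "date")],
                            file.path(dir, "records.csv"))
    write_stations(stations[, c("station_id", "site_id", "landscape_id",
                                "x", "y", "deploy_start", "deploy_end")],
                   file.path(dir, "stations.csv"))
    write_species_traits(traits, file.path(dir, "traits.csv"))
    write_villages(bundle$villages, file.path(dir, "villages.csv"))
  }
  bundle
}

#' Paper-scale synthetic fixture with a covariate-driver contrast
#'
#' The standard two-landscape bundle in which landscape `L1` ("degraded")
#' has occupancy driven by canopy closure only (community-mean canopy effect
#' 1) and landscape `L2` ("hunted") by village density only (community-mean
#' village effect -1) — the qualitative contrast the analysis is designed to
#' detect. In each landscape the non-driving covariate is strictly null: its
#' community mean and spread are both 0, so no species responds to it at
#' all.
#'
#' @param seed Integer seed.
#' @param dir Optional output directory (see [simulate_study()]).
#' @return As [simulate_study()].
#' @export
paper_scale_fixture <- function(seed = 1, dir = NULL) {
  config <- scenario_config(
    hyper = list(
      list(mu_b1 = 1, sd_b1 = 0.5, mu_b2 = 0, sd_b2 = 0),
      list(mu_b1 = 0, sd_b1 = 0, mu_b2 = -1, sd_b2 = 0.5)
    )
  )
  simulate_study(config, seed = seed, dir = dir)
}
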