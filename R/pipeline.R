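#' Pipeline configuration
#'
#' Assembles (or reads from a YAML file) the configuration driving
#' [run_pipeline()]. Analysis defaults equal the emulated design's stated
#' values: 10-day occasions, 2.5% functional-extinction threshold, 15 km
#' kernel radius, 30,000 Monte-Carlo draws; MCMC defaults are the desk-scale
#' [mcmc_config()] (use `mcmc = mcmc_config_paper()` for production-scale
#' chains).
#'
#' @param input Either `"simulate"` (generate a synthetic bundle) or a named
#'   list of paths `records`, `stations`, `traits`, `villages`.
#' @param output_dir Directory for stage outputs and the run manifest.
#' @param occasion_length,extinction_threshold,kernel_radius,n_draws
#'   Analysis parameters.
#' @param schemes Weight schemes for the historical index.
#' @param reference_site Reference for the occupancy-based index; `NULL`
#'   picks the first site of the first landscape (by sorted label).
#' @param mcmc An [mcmc_config()].
#' @param scenario A [scenario_config()] (used when `input = "simulate"`).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "simulate", output_dir = tempfile("run"),
                            occasion_length = 10,
                            extinction_threshold = 0.025,
                            kernel_radius = 15000,
                            schemes = c("equal", "conservation", "size"),
                            reference_site = NULL,
                            n_draws = 30000,
                            mcmc = mcmc_config(),
                            scenario = scenario_config(),
                            seed = 1) {
  if (is.list(input)) {
    missing_files <- unlist(input)[!file.exists(unlist(input))]
    if (length(missing_files) > 0) {
      stop_defaunate(sprintf("input file(s) not found: %s",
                             paste(missing_files, collapse = ", ")),
                     "defaunate_io_error")
    }
  }
  structure(list(
    input = input, output_dir = output_dir,
    occasion_length = occasion_length,
    extinction_threshold = extinction_threshold,
    kernel_radius = kernel_radius, schemes = schemes,
    reference_site = reference_site, n_draws = n_draws,
    mcmc = mcmc, scenario = scenario, seed = seed
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose top-level keys match the
#'   `pipeline_config()` arguments (`mcmc` and `scenario` as nested maps).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_defaunate(sprintf("config file not found: %s", path),
                   "defaunate_io_error")
  }
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$mcmc)) args$mcmc <- do.call(mcmc_config, raw$mcmc)
  if (!is.null(raw$scenario)) {
    args$scenario <- do.call(scenario_config, raw$scenario)
  }
  do.call(pipeline_config, args)
}

#' Run the full defaunation pipeline
#'
#' Executes, with stage-boundary logging: input loading or simulation;
#' detection-history construction; covariate computation and normalization;
#' the historical defaunation index per site and landscape; one community
#' occupancy fit per landscape; and the Monte-Carlo occupancy-based
#' defaunation index. Each stage's table is written to `output_dir` as CSV,
#' plus a JSON run manifest recording seed, configuration and counts.
#' Failures propagate with the stage name in the error message.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's outputs (`bundle`,
#'   `histories`, `stations`, `historical_d`, `fits`, `psi`, `occupancy_d`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"),
                    ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_defaunate(sprintf("pipeline stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "defaunate_pipeline_error")
    })
  }

  # -- input --
  bundle <- stage("input", {
    if (identical(config$input, "simulate")) {
      log_stage("simulating synthetic study (seed %d)", config$seed)
      simulate_study(config$scenario, seed = config$seed)
    } else {
      log_stage("reading input tables")
      stations <- read_stations(config$input$stations)
      records <- read_detection_records(config$input$records, stations)
      traits <- read_species_traits(config$input$traits)
      villages <- read_villages(config$input$villages)
      list(records = merge_to_analysis_units(records, traits),
           stations = stations, traits = traits, villages = villages)
    }
  })
  log_stage("input: %d records, %d stations, %d units, %d villages",
            nrow(bundle$records), nrow(bundle$stations),
            nrow(bundle$traits), nrow(bundle$villages))

  # -- covariates --
  stations <- stage("covariates", {
    st <- bundle$stations
    if (!"village_density" %in% names(st)) {
      st <- village_density(st, bundle$villages,
                            radius = config$kernel_radius)
    }
    if (!"canopy" %in% names(st)) {
      stop_defaunate(
        "station table lacks 'canopy'; compute it with station_canopy()",
        "defaunate_config_error")
    }
    normalize_covariates(st)
  })
  readr::write_csv(stations, file.path(config$output_dir, "covariates.csv"))

  landscapes <- sort(unique(stations$landscape_id))

  # -- detection histories (one per landscape) --
  histories <- stage("histories", {
    setNames(lapply(landscapes, function(l) {
      st <- stations[stations$landscape_id == l, ]
      rec <- bundle$records[bundle$records$station_id %in% st$station_id, ]
      build_detection_history(rec, st,
                              occasion_length = config$occasion_length,
                              units = bundle$traits$unit_id)
    }), landscapes)
  })
  for (l in landscapes) {
    log_stage("landscape %s: %d occasions, %d detection cells", l,
              dim(histories[[l]]$y)[3], sum(histories[[l]]$y))
  }

  # -- historical defaunation --
  historical_d <- stage("historical_defaunation", {
    reference <- tibble::tibble(unit_id = bundle$traits$unit_id)
    dplyr::bind_rows(lapply(landscapes, function(l) {
      st <- stations[stations$landscape_id == l, ]
      per_site <- historical_defaunation(
        histories[[l]], st, bundle$traits, reference,
        schemes = config$schemes,
        threshold = config$extinction_threshold, by = "site_id")
      per_land <- historical_defaunation(
        histories[[l]], st, bundle$traits, reference,
        schemes = config$schemes,
        threshold = config$extinction_threshold, by = "landscape_id")
      dplyr::bind_rows(
        dplyr::rename(per_site, group = "site_id"),
        dplyr::rename(per_land, group = "landscape_id"))
    }))
  })
  readr::write_csv(historical_d,
                   file.path(config$output_dir, "historical_defaunation.csv"))
  log_stage("historical defaunation: %d group x scheme values",
            nrow(historical_d))

  # -- occupancy fits, one per landscape --
  fits <- stage("occupancy_fit", {
    setNames(lapply(landscapes, function(l) {
      log_stage("fitting community occupancy model for landscape %s", l)
      st <- stations[stations$landscape_id == l, ]
      mc <- config$mcmc
      mc$seed <- substream_seed(config$seed, paste0("fit-", l))
      fit_community_occupancy(histories[[l]], st, mcmc = mc)
    }), landscapes)
  })
  summaries <- dplyr::bind_rows(lapply(landscapes, function(l) {
    dplyr::mutate(tidy(fits[[l]]), landscape_id = l, .before = 1)
  }))
  readr::write_csv(summaries,
                   file.path(config$output_dir, "posterior_summaries.csv"))
  rhats <- dplyr::bind_rows(lapply(landscapes, function(l) {
    dplyr::mutate(fits[[l]]$rhat, landscape_id = l, .before = 1)
  }))
  readr::write_csv(rhats, file.path(config$output_dir, "rhat.csv"))

  # -- occupancy-based defaunation --
  psi <- stage("species_site_occupancy", {
    lapply(fits, species_site_occupancy)
  })
  occupancy_d <- stage("occupancy_defaunation", {
    # pool sites of all landscapes that share the fitted unit set
    shared <- Reduce(intersect, lapply(fits, function(f) f$units))
    if (length(shared) == 0) {
      stop_defaunate("no unit occurs in every landscape",
                     "defaunate_config_error")
    }
    n_min <- min(vapply(psi, nrow, 1L))
    psi_all <- NULL
    for (l in landscapes) {
      x <- unclass(psi[[l]])[seq_len(n_min), shared, , drop = FALSE]
      psi_all <- if (is.null(psi_all)) x else
        abind_3(psi_all, x)
    }
    ref <- config$reference_site %||% dimnames(psi_all)[[3]][1]
    occupancy_defaunation(psi_all, ref, n_draws = config$n_draws,
                          seed = substream_seed(config$seed, "occud"))
  })
  readr::write_csv(tibble::as_tibble(occupancy_d),
                   file.path(config$output_dir, "occupancy_defaunation.csv"))
  log_stage("occupancy defaunation: reference %s, %d sites",
            attr(occupancy_d, "reference_site"), nrow(occupancy_d))

  manifest <- list(
    package_version = as.character(utils::packageVersion("defaunate")),
    seed = config$seed,
    occasion_length = config$occasion_length,
    extinction_threshold = config$extinction_threshold,
    kernel_radius = config$kernel_radius,
    n_draws = config$n_draws,
    mcmc = unclass(config$mcmc),
    counts = list(
      records = nrow(bundle$records), stations = nrow(stations),
      units = nrow(bundle$traits), landscapes = length(landscapes)
    ),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(bundle = bundle, stations = stations,
                 histories = histories, historical_d = historical_d,
                 fits = fits, psi = psi, occupancy_d = occupancy_d,
                 manifest = manifest))
}

# bind two draw x unit x site arrays along the site dimension
abind_3 <- function(a, b) {
  stopifnot(dim(a)[1] == dim(b)[1], dim(a)[2] == dim(b)[2])
  out <- array(NA_real_, dim = c(dim(a)[1], dim(a)[2],
                                 dim(a)[3] + dim(b)[3]),
               dimnames = list(NULL, dimnames(a)[[2]],
                               c(dimnames(a)[[3]], dimnames(b)[[3]])))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}
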