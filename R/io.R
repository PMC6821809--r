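#' Read camera-trap detection records
#'
#' Reads a comma-delimited file of raw detection records, one row per
#' station/species/date. Dates must be ISO-8601 (`YYYY-MM-DD`); two cameras at
#' a station are assumed to have been collapsed upstream, so a row means "this
#' species was photographed at this station on this date by at least one
#' camera".
#'
#' @param path Path to a CSV file with header columns `station_id`, `species`,
#'   `date`.
#' @param stations Optional station table (see [read_stations()]). When given,
#'   records at stations absent from the table trigger a warning naming them.
#' @return A tibble with columns `station_id` (character), `species`
#'   (character) and `date` (`Date`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("station_id,species,date", "S1,Manis javanica,2015-03-02"), f)
#' read_detection_records(f)
#' @export
read_detection_records <- function(path, stations = NULL) {
  df <- read_csv_checked(path, c("station_id", "species", "date"),
                         "detection record file")
  df$date <- parse_iso_dates(as.character(df$date), "detection record file")
  df <- tibble::tibble(
    station_id = as.character(df$station_id),
    species    = as.character(df$species),
    date       = df$date
  )
  if (!is.null(stations)) {
    unknown <- setdiff(df$station_id, stations$station_id)
    if (length(unknown) > 0) {
      warn(sprintf(
        "detection records reference unknown station(s): %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  df
}

#' Read the camera-trap station table
#'
#' Station coordinates must be planar (projected, in meters): the kernel radii
#' and spacing used downstream are metric, so coordinate pairs that look like
#' longitude/latitude are rejected rather than silently treated as meters.
#' Deployments shorter than 60 days raise a warning (the survey design assumes
#' a 60-day minimum) but are kept.
#'
#' @param path CSV with header columns `station_id`, `site_id`,
#'   `landscape_id`, `x`, `y`, `deploy_start`, `deploy_end`.
#' @return A tibble with typed columns (`x`, `y` numeric; deployment dates as
#'   `Date`).
#' @export
read_stations <- function(path) {
  cols <- c("station_id", "site_id", "landscape_id", "x", "y",
            "deploy_start", "deploy_end")
  df <- read_csv_checked(path, cols, "station file")
  out <- tibble::tibble(
    station_id   = as.character(df$station_id),
    site_id      = as.character(df$site_id),
    landscape_id = as.character(df$landscape_id),
    x            = as.numeric(df$x),
    y            = as.numeric(df$y),
    deploy_start = parse_iso_dates(as.character(df$deploy_start), "station file"),
    deploy_end   = parse_iso_dates(as.character(df$deploy_end), "station file")
  )
  validate_stations(out)
}

validate_stations <- function(out) {
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    bad <- which(!is.finite(out$x) | !is.finite(out$y))
    stop_defaunate(
      sprintf("station file: non-finite coordinates at row(s) %s",
              paste(bad, collapse = ", ")),
      "defaunate_row_error"
    )
  }
  if (nrow(out) > 0 &&
      all(abs(out$x) <= 180) && all(abs(out$y) <= 90)) {
    stop_defaunate(
      paste(
        "station coordinates look like longitude/latitude degrees;",
        "planar coordinates in meters are required (project them upstream)"
      ),
      "defaunate_crs_error"
    )
  }
  if (anyDuplicated(out$station_id)) {
    stop_defaunate("station file: duplicated station_id values",
                   "defaunate_format_error")
  }
  days <- as.integer(out$deploy_end - out$deploy_start) + 1L
  if (any(days < 1L)) {
    stop_defaunate("station file: deploy_end precedes deploy_start",
                   "defaunate_format_error")
  }
  if (any(days < 60L)) {
    warn(sprintf(
      "%d station(s) deployed < 60 days (design minimum): %s",
      sum(days < 60L),
      paste(utils::head(out$station_id[days < 60L], 5), collapse = ", ")
    ))
  }
  out
}

#' Read the species trait table
#'
#' One row per analysis unit (a species, or a cross-landscape species pair /
#' genus-level group). `member_species` lists the raw species names merged
#' into the unit, separated by semicolons; `iucn` must be one of `LC`, `NT`,
#' `VU`, `EN`, `CR`, `DD`; `body_mass_g` is the average adult body mass in
#' grams.
#'
#' @param path CSV with header columns `unit_id`, `member_species`, `iucn`,
#'   `body_mass_g`, `pair_id`.
#' @return A tibble; `member_species` is a list-column of character vectors.
#' @export
read_species_traits <- function(path) {
  cols <- c("unit_id", "member_species", "iucn", "body_mass_g", "pair_id")
  df <- read_csv_checked(path, cols, "trait file")
  out <- tibble::tibble(
    unit_id        = as.character(df$unit_id),
    member_species = strsplit(as.character(df$member_species), ";", fixed = TRUE),
    iucn           = as.character(df$iucn),
    body_mass_g    = as.numeric(df$body_mass_g),
    pair_id        = as.character(df$pair_id)
  )
  out$member_species <- lapply(out$member_species, trimws)
  validate_traits(out)
}

iucn_levels <- c("LC", "NT", "VU", "EN", "CR", "DD")

validate_traits <- function(out) {
  bad <- !out$iucn %in% iucn_levels
  if (any(bad)) {
    stop_defaunate(
      sprintf("trait file: invalid IUCN categories %s (allowed: %s)",
              paste(unique(out$iucn[bad]), collapse = ", "),
              paste(iucn_levels, collapse = ", ")),
      "defaunate_format_error"
    )
  }
  if (any(!is.finite(out$body_mass_g) | out$body_mass_g <= 0)) {
    stop_defaunate("trait file: body_mass_g must be > 0 for every unit",
                   "defaunate_format_error")
  }
  if (anyDuplicated(out$unit_id)) {
    stop_defaunate("trait file: duplicated unit_id values",
                   "defaunate_format_error")
  }
  out
}

#' Read village point locations
#'
#' @param path CSV with header columns `x`, `y`, planar coordinates in meters.
#' @return A tibble with numeric `x`, `y`.
#' @export
read_villages <- function(path) {
  df <- read_csv_checked(path, c("x", "y"), "village file")
  out <- tibble::tibble(x = as.numeric(df$x), y = as.numeric(df$y))
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    bad <- which(!is.finite(out$x) | !is.finite(out$y))
    stop_defaunate(
      sprintf("village file: blank or non-finite coordinate at row(s) %s",
              paste(bad, collapse = ", ")),
      "defaunate_row_error"
    )
  }
  out
}

#' Write the tabular inputs back to CSV
#'
#' Inverse of the corresponding readers; `write_*(read_*(f))` round-trips
#' field-identically.
#'
#' @param x Tibble as returned by the matching reader.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write-tables
NULL

#' @rdname write-tables
#' @export
write_detection_records <- function(x, path) {
  x$date <- format(x$date, "%Y-%m-%d")
  readr::write_csv(x[, c("station_id", "species", "date")], path)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_stations <- function(x, path) {
  x$deploy_start <- format(x$deploy_start, "%Y-%m-%d")
  x$deploy_end <- format(x$deploy_end, "%Y-%m-%d")
  readr::write_csv(
    x[, c("station_id", "site_id", "landscape_id", "x", "y",
          "deploy_start", "deploy_end")], path)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_species_traits <- function(x, path) {
  x$member_species <- vapply(x$member_species, paste, "", collapse = ";")
  readr::write_csv(
    x[, c("unit_id", "member_species", "iucn", "body_mass_g", "pair_id")],
    path)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_villages <- function(x, path) {
  readr::write_csv(x[, c("x", "y")], path)
  invisible(path)
}

#' Relabel raw species records by analysis unit
#'
#' Maps every raw species name onto its analysis unit via the trait table's
#' `member_species` lists (e.g. the two pangolins *Manis pentadactyla* and
#' *M. javanica* both map to the unit "Manis spp."). Records of two merged
#' species at the same station on the same date collapse to a single
#' unit-level record.
#'
#' @param records Tibble from [read_detection_records()].
#' @param traits Tibble from [read_species_traits()].
#' @return A tibble with columns `station_id`, `unit_id`, `date`; at most one
#'   row per (unit, station, date).
#' @export
merge_to_analysis_units <- function(records, traits) {
  check_columns(records, c("station_id", "species", "date"), "records")
  map <- tibble::tibble(
    species = unlist(traits$member_species),
    unit_id = rep(traits$unit_id, lengths(traits$member_species))
  )
  if (anyDuplicated(map$species)) {
    dup <- unique(map$species[duplicated(map$species)])
    stop_defaunate(
      sprintf("species mapped to more than one analysis unit: %s",
              paste(dup, collapse = ", ")),
      "defaunate_config_error"
    )
  }
  unmapped <- setdiff(unique(records$species), map$species)
  if (length(unmapped) > 0) {
    stop_defaunate(
      sprintf("species not present in any unit's member_species: %s",
              paste(unmapped, collapse = ", ")),
      "defaunate_config_error"
    )
  }
  records %>%
    dplyr::left_join(map, by = "species") %>%
    dplyr::distinct(.data$station_id, .data$unit_id, .data$date) %>%
    dplyr::arrange(.data$unit_id, .data$station_id, .data$date)
}

read_csv_checked <- function(path, cols, what) {
  if (!file.exists(path)) {
    stop_defaunate(sprintf("%s not found: %s", what, path),
                   "defaunate_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, cols, what)
  df
}
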