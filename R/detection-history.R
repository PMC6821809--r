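#' Pool detection records into an occasion-structured detection history
#'
#' Divides each station's deployment into consecutive occasions of
#' `occasion_length` days, anchored at that station's own `deploy_start`. A
#' trailing partial occasion is retained with its remaining active days as
#' effort (the occupancy model carries effort as a detection covariate, so no
#' data need be discarded). `y[i, j, k] = 1` iff unit `i` was recorded at
#' station `j` at least once during occasion `k`.
#'
#' @param records Unit-level records (columns `station_id`, `unit_id`,
#'   `date`), e.g. from [merge_to_analysis_units()] or [simulate_study()].
#' @param stations Station table (see [read_stations()]).
#' @param occasion_length Occasion length in days (default 10).
#' @param units Optional character vector fixing the unit index (so units with
#'   zero records appear as all-zero rows); defaults to the units present in
#'   `records`.
#' @return A `detection_history`: list with binary array `y`
#'   (unit x station x occasion), matrix `effort` (station x occasion, active
#'   camera-days, 0 beyond a station's deployment), `occasion_length`, and the
#'   `units` / `station_ids` index maps.
#' @examples
#' st <- tibble::tibble(
#'   station_id = "S1", site_id = "A", landscape_id = "L", x = 0, y = 0,
#'   deploy_start = as.Date("2015-01-01"), deploy_end = as.Date("2015-03-01")
#' )
#' rec <- tibble::tibble(station_id = "S1", unit_id = "u1",
#'                       date = as.Date("2015-01-11"))
#' h <- build_detection_history(rec, st)
#' h$y[1, 1, ]
#' @export
build_detection_history <- function(records, stations, occasion_length = 10,
                                    units = NULL) {
  stopifnot(occasion_length >= 1)
  check_columns(records, c("station_id", "unit_id", "date"), "records")
  check_columns(stations, c("station_id", "deploy_start", "deploy_end"),
                "stations")

  units <- units %||% sort(unique(records$unit_id))
  station_ids <- stations$station_id
  n_days <- as.integer(stations$deploy_end - stations$deploy_start) + 1L
  n_occ <- ceiling(n_days / occasion_length)
  K <- max(n_occ)

  effort <- matrix(0, nrow = length(station_ids), ncol = K,
                   dimnames = list(station_ids, NULL))
  for (j in seq_along(station_ids)) {
    full <- n_days[j] %/% occasion_length
    effort[j, seq_len(full)] <- occasion_length
    if (n_occ[j] > full) effort[j, n_occ[j]] <- n_days[j] %% occasion_length
  }

  y <- array(0L, dim = c(length(units), length(station_ids), K),
             dimnames = list(units, station_ids, NULL))
  if (nrow(records) > 0) {
    ui <- match(records$unit_id, units)
    ji <- match(records$station_id, station_ids)
    if (anyNA(ui)) {
      stop_defaunate(
        sprintf("records contain unit(s) outside the unit index: %s",
                paste(unique(records$unit_id[is.na(ui)]), collapse = ", ")),
        "defaunate_config_error")
    }
    if (anyNA(ji)) {
      stop_defaunate(
        sprintf("records at station(s) missing from the station table: %s",
                paste(unique(records$station_id[is.na(ji)]), collapse = ", ")),
        "defaunate_config_error")
    }
    day <- as.integer(records$date - stations$deploy_start[ji]) + 1L
    bad <- day < 1L | day > n_days[ji]
    if (any(bad)) {
      b <- which(bad)[1]
      stop_defaunate(
        sprintf(
          "record outside deployment window: unit %s at station %s on %s",
          records$unit_id[b], records$station_id[b],
          format(records$date[b])),
        "defaunate_window_error")
    }
    ki <- ceiling(day / occasion_length)
    y[cbind(ui, ji, ki)] <- 1L
  }

  structure(
    list(y = y, effort = effort, occasion_length = occasion_length,
         units = units, station_ids = station_ids),
    class = "detection_history"
  )
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf(
    "<detection_history> %d units x %d stations x %d occasions (%d-day)\n",
    length(x$units), length(x$station_ids), dim(x$y)[3], x$occasion_length))
  cat(sprintf("  detections: %d cells; effort: %.0f camera-days\n",
              sum(x$y), sum(x$effort)))
  invisible(x)
}

#' Station-level presence matrix
#'
#' Logical OR of the detection history over occasions: 1 if the unit was
#' recorded at least once at the station. This is the input to the
#' functional-extinction rule and is by construction independent of the
#' occasion length used for pooling.
#'
#' @param history A `detection_history`.
#' @return Integer matrix (unit x station) of 0/1, with dimnames.
#' @export
station_presence <- function(history) {
  stopifnot(inherits(history, "detection_history"))
  pres <- apply(history$y, c(1, 2), max)
  storage.mode(pres) <- "integer"
  pres
}

#' Detection history as a long tibble
#'
#' @param x A `detection_history`.
#' @param ... Unused.
#' @return Tibble with columns `unit_id`, `station_id`, `occasion`, `y`,
#'   `effort`; only occasions with nonzero effort are included.
#' @export
tidy.detection_history <- function(x, ...) {
  K <- dim(x$y)[3]
  out <- tidyr::expand_grid(
    unit_id = x$units, station_id = x$station_ids, occasion = seq_len(K)
  )
  out$y <- as.vector(x$y[cbind(
    match(out$unit_id, x$units), match(out$station_id, x$station_ids),
    out$occasion)])
  out$effort <- x$effort[cbind(match(out$station_id, x$station_ids),
                               out$occasion)]
  out[out$effort > 0, ]
}

#' Export detection and effort tensors as wide CSV
#'
#' One row per unit x station with one column per occasion, plus a matching
#' effort table (row per station).
#'
#' @param history A `detection_history`.
#' @param y_path,effort_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_detection_history <- function(history, y_path, effort_path) {
  K <- dim(history$y)[3]
  occ_cols <- paste0("occ", seq_len(K))
  yw <- tidyr::expand_grid(unit_id = history$units,
                           station_id = history$station_ids)
  ym <- matrix(aperm(history$y, c(2, 1, 3)), ncol = K)
  colnames(ym) <- occ_cols
  readr::write_csv(dplyr::bind_cols(yw, tibble::as_tibble(ym)), y_path)
  ew <- tibble::tibble(station_id = history$station_ids)
  em <- history$effort
  colnames(em) <- occ_cols
  readr::write_csv(dplyr::bind_cols(ew, tibble::as_tibble(em)), effort_path)
  invisible(c(y_path, effort_path))
}
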