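#' Species importance weights for the defaunation index
#'
#' Four weighting schemes are supported:
#' \describe{
#'   \item{equal}{every unit weighs 1.}
#'   \item{conservation}{IUCN Red List category: LC = 1, NT = 2, VU = 3,
#'     EN = 4, CR = 5; Data Deficient units take the midpoint 2.5.}
#'   \item{size}{average body mass (g) raised to the 3/4 power, the classic
#'     metabolic scaling of ecological function with body size.}
#'   \item{rank}{ascending body-mass rank (1 = lightest, ties averaged); a
#'     robustness variant that caps the leverage of the very largest species.}
#' }
#'
#' @param traits Trait table (see [read_species_traits()]).
#' @param scheme One of `"equal"`, `"conservation"`, `"size"`, `"rank"`.
#' @return Named numeric vector of weights, one per `unit_id`.
#' @examples
#' tr <- tibble::tibble(unit_id = c("a", "b"), iucn = c("CR", "DD"),
#'                      body_mass_g = c(10000, 800))
#' species_weights(tr, "conservation") # 5, 2.5
#' species_weights(tr, "size")[["a"]]  # 10000^0.75 = 1000
#' @export
species_weights <- function(traits,
                            scheme = c("equal", "conservation", "size",
                                       "rank")) {
  scheme <- match.arg(scheme)
  check_columns(traits, "unit_id", "traits")
  w <- switch(
    scheme,
    equal = rep(1, nrow(traits)),
    conservation = {
      check_scheme_trait(traits, "iucn", scheme)
      unname(c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5, DD = 2.5)[traits$iucn])
    },
    size = {
      check_scheme_trait(traits, "body_mass_g", scheme)
      traits$body_mass_g^0.75
    },
    rank = {
      check_scheme_trait(traits, "body_mass_g", scheme)
      rank(traits$body_mass_g, ties.method = "average")
    }
  )
  setNames(as.numeric(w), traits$unit_id)
}

check_scheme_trait <- function(traits, col, scheme) {
  check_columns(traits, col, "traits")
  bad <- is.na(traits[[col]])
  if (any(bad)) {
    stop_defaunate(
      sprintf("scheme '%s' needs '%s' for unit(s): %s", scheme, col,
              paste(traits$unit_id[bad], collapse = ", ")),
      "defaunate_config_error")
  }
}

#' Functional-extinction classification from station presence
#'
#' A unit is considered functionally extinct at a site if it was recorded at
#' strictly fewer than `threshold` (default 2.5%) of the site's camera-trap
#' stations — too few records to constitute an ecologically functional
#' population. The comparison is on the station *fraction* and is strict: a
#' unit at exactly the threshold fraction survives. Units never recorded are
#' functionally extinct.
#'
#' @param presence Binary unit x station matrix for one site (see
#'   [station_presence()]).
#' @param threshold Station fraction in (0, 1); default 0.025.
#' @return Tibble with `unit_id`, `n_stations_present`, `frac_stations`,
#'   `functionally_extinct` (logical) and `present` (0/1, the focal
#'   assemblage entry).
#' @export
functional_extinction <- function(presence, threshold = 0.025) {
  if (threshold <= 0 || threshold >= 1) {
    stop_defaunate("threshold must lie strictly between 0 and 1",
                   "defaunate_config_error")
  }
  n_st <- ncol(presence)
  if (is.null(n_st) || n_st == 0) {
    stop_defaunate("presence matrix has no stations",
                   "defaunate_config_error")
  }
  n_pres <- unname(rowSums(presence > 0))
  frac <- n_pres / n_st
  tibble::tibble(
    unit_id = rownames(presence) %||% as.character(seq_len(nrow(presence))),
    n_stations_present = as.integer(n_pres),
    frac_stations = frac,
    functionally_extinct = frac < threshold,
    present = as.integer(frac >= threshold)
  )
}

#' Weighted defaunation index D(r, f)
#'
#' The signed, weighted dissimilarity between a focal assemblage `f` and a
#' reference assemblage `r`:
#' \deqn{D(r,f) = \frac{\sum_k \omega_k (N_{k,r} - N_{k,f})}
#'                     {\sum_k \omega_k (N_{k,r} + N_{k,f})}}
#' where \eqn{N_{k,r}}, \eqn{N_{k,f}} are presence/absence (or, for the
#' occupancy-based variant, occupancy probabilities) of unit `k` and
#' \eqn{\omega_k \ge 0} its importance weight. `D` lies in `[-1, 1]`;
#' positive values mean the focal assemblage is more defaunated than the
#' reference, negative values less.
#'
#' @param reference,focal Numeric vectors over the same aligned units
#'   (binary, or in `[0, 1]` for occupancy-based use).
#' @param weights Nonnegative weights, same length (default equal).
#' @return Scalar `D`.
#' @examples
#' defaunation_index(rep(1, 45), rep(c(1, 0), c(20, 25))) # 25/65 = 0.385
#' @export
defaunation_index <- function(reference, focal,
                              weights = rep(1, length(reference))) {
  if (length(focal) != length(reference) ||
      length(weights) != length(reference)) {
    stop_defaunate(
      "reference, focal and weights must align over the same units",
      "defaunate_config_error")
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop_defaunate("weights must be nonnegative and not all zero",
                   "defaunate_config_error")
  }
  denom <- sum(weights * (reference + focal))
  if (denom <= 0) {
    stop_defaunate(
      "defaunation index undefined: both assemblages empty (denominator 0)",
      "defaunate_config_error")
  }
  sum(weights * (reference - focal)) / denom
}

#' Historical defaunation per site and weighting scheme
#'
#' Convenience wrapper chaining [station_presence()],
#' [functional_extinction()] and [defaunation_index()] across the sites of a
#' survey: the focal assemblage at each site is the set of reference units
#' surviving the functional-extinction rule; the reference assemblage is all
#' units on the site's historical list.
#'
#' @param history A `detection_history` covering all stations.
#' @param stations Station table (`station_id`, `site_id`, `landscape_id`).
#' @param traits Trait table for the reference units.
#' @param reference Tibble naming the historical reference list: column
#'   `unit_id`, optional `landscape_id` restricting a unit to one landscape
#'   (absent/NA = applies everywhere).
#' @param schemes Weight schemes to evaluate (see [species_weights()]).
#' @param threshold Functional-extinction threshold (see
#'   [functional_extinction()]).
#' @param by Either `"site_id"` (default) or `"landscape_id"`: the grouping
#'   at which assemblages are formed and the station fraction computed.
#' @return Tibble with `site_id` (or `landscape_id`), `scheme`, `D`,
#'   `n_reference`, `n_extinct`.
#' @export
historical_defaunation <- function(history, stations, traits, reference,
                                   schemes = c("equal", "conservation",
                                               "size"),
                                   threshold = 0.025, by = "site_id") {
  stopifnot(by %in% c("site_id", "landscape_id"))
  check_columns(reference, "unit_id", "reference")
  pres_all <- station_presence(history)
  groups <- unique(stations[[by]])
  out <- purrr::map_dfr(groups, function(g) {
    st <- stations$station_id[stations[[by]] == g]
    land <- unique(stations$landscape_id[stations[[by]] == g])
    ref_units <- reference
    if ("landscape_id" %in% names(reference)) {
      ref_units <- reference[is.na(reference$landscape_id) |
                               reference$landscape_id %in% land, ]
    }
    units <- ref_units$unit_id
    missing_tr <- setdiff(units, traits$unit_id)
    if (length(missing_tr) > 0) {
      stop_defaunate(
        sprintf("reference unit(s) missing from traits: %s",
                paste(missing_tr, collapse = ", ")),
        "defaunate_config_error")
    }
    pres <- matrix(0L, nrow = length(units), ncol = length(st),
                   dimnames = list(units, st))
    have <- intersect(units, rownames(pres_all))
    pres[have, ] <- pres_all[have, st, drop = FALSE]
    fe <- functional_extinction(pres, threshold)
    tr <- traits[match(units, traits$unit_id), ]
    purrr::map_dfr(schemes, function(sch) {
      w <- species_weights(tr, sch)
      tibble::tibble(
        !!by := g,
        scheme = sch,
        D = defaunation_index(rep(1, length(units)), fe$present, w),
        n_reference = length(units),
        n_extinct = sum(fe$functionally_extinct)
      )
    })
  })
  out
}

#' Bar chart of defaunation values by site and weighting scheme
#'
#' @param d Tibble from [historical_defaunation()].
#' @return A ggplot object.
#' @export
plot_defaunation <- function(d) {
  grp <- names(d)[1]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[grp]], y = .data$D,
                                  fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Defaunation index D",
                  fill = "Weighting") +
    ggplot2::theme_minimal()
}
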