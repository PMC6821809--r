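#' Canopy closure fraction from a binarized canopy photograph
#'
#' Upward canopy photographs are binarized upstream into vegetation vs open
#' sky; this returns the vegetation fraction of pixels. Inputs with more than
#' two distinct pixel values are rejected so that thresholding decisions stay
#' explicit and upstream.
#'
#' @param raster Numeric/integer/logical matrix, or path to a single-channel
#'   PNG. Exactly two pixel classes allowed (one is fine, e.g. all
#'   vegetation).
#' @param vegetation Which class codes vegetation: `"dark"` (default; the
#'   lower pixel value, e.g. black = 0) or `"light"`.
#' @return Vegetation fraction in `[0, 1]`.
#' @examples
#' canopy_fraction(matrix(c(0, 0, 1, 0), 2)) # 0.75
#' @export
canopy_fraction <- function(raster, vegetation = c("dark", "light")) {
  vegetation <- match.arg(vegetation)
  if (is.character(raster) && length(raster) == 1) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop_defaunate("reading PNG canopy photos requires the 'png' package",
                     "defaunate_io_error")
    }
    raster <- png::readPNG(raster)
    if (length(dim(raster)) == 3) raster <- raster[, , 1]
  }
  vals <- sort(unique(as.vector(raster)))
  if (length(vals) > 2) {
    stop_defaunate(
      sprintf(
        "canopy raster has %d distinct pixel values; binarize it first",
        length(vals)),
      "defaunate_format_error")
  }
  if (length(vals) == 1) {
    # Single-class image: relative polarity is uninformative, so class 0
    # (black) is vegetation and anything else sky, whatever `vegetation` is.
    return(if (vals == 0) 1 else 0)
  }
  veg_val <- if (vegetation == "dark") vals[1] else vals[2]
  mean(as.vector(raster) == veg_val)
}

#' Mean canopy closure for a station
#'
#' Averages the vegetation fraction over the station's canopy photographs.
#' The field protocol takes five (grid center + four corners); fewer are
#' accepted with a warning and the mean is over those present.
#'
#' @param rasters List of matrices or PNG paths (see [canopy_fraction()]).
#' @param vegetation Passed to [canopy_fraction()].
#' @return Mean canopy closure in `[0, 1]`.
#' @export
station_canopy <- function(rasters, vegetation = "dark") {
  if (length(rasters) == 0) {
    stop_defaunate("no canopy rasters supplied for station",
                   "defaunate_format_error")
  }
  if (length(rasters) != 5) {
    warn(sprintf("expected 5 canopy photos per station, got %d; %s",
                 length(rasters), "averaging over those present"))
  }
  mean(vapply(rasters, canopy_fraction, numeric(1), vegetation = vegetation))
}

#' Village density at camera-trap stations
#'
#' Kernel density of village points evaluated at each station, using the
#' unnormalized quartic (biweight) kernel
#' \eqn{K(d) = (1 - (d/r)^2)^2} for \eqn{d < r} and 0 beyond; contributions
#' are summed over villages. The value is unitless and serves as a proxy for
#' hunting accessibility; any constant normalization a GIS package would
#' apply is irrelevant because covariates are z-scored before modeling.
#'
#' @param stations Station table with planar `x`, `y` in meters.
#' @param villages Village table with planar `x`, `y` in meters.
#' @param radius Kernel radius in meters (default 15 km, chosen so every
#'   station falls inside the hunting halo of some village in the source
#'   design).
#' @return `stations` with a `village_density` column appended.
#' @examples
#' st <- tibble::tibble(station_id = "S1", x = 0, y = 0)
#' vi <- tibble::tibble(x = 7500, y = 0)
#' village_density(st, vi)$village_density # (1 - 0.25)^2 = 0.5625
#' @export
village_density <- function(stations, villages, radius = 15000) {
  if (!is.numeric(radius) || radius <= 0) {
    stop_defaunate("kernel radius must be positive", "defaunate_config_error")
  }
  check_columns(stations, c("x", "y"), "stations")
  dens <- rep(0, nrow(stations))
  if (nrow(villages) > 0) {
    d2 <- outer(stations$x, villages$x, "-")^2 +
      outer(stations$y, villages$y, "-")^2
    u <- d2 / radius^2
    k <- (1 - u)^2
    k[u >= 1] <- 0
    dens <- rowSums(k)
  }
  dplyr::mutate(stations, village_density = dens)
}

#' Normalize station covariates within landscapes
#'
#' z-scores the given covariate columns independently within each group
#' (covariates are scaled independently between the hunted and the degraded
#' landscape, so effect sizes are comparable within, not across, landscapes).
#' Appends `<col>_z` columns.
#'
#' @param stations Station table containing the covariate columns.
#' @param cols Character vector of covariate column names (default canopy and
#'   village density).
#' @param group Grouping column name (default `"landscape_id"`); `NULL`
#'   normalizes over all rows.
#' @return `stations` with `<col>_z` columns appended; each has mean 0 and
#'   sample sd 1 within every group.
#' @export
normalize_covariates <- function(stations,
                                 cols = c("canopy", "village_density"),
                                 group = "landscape_id") {
  check_columns(stations, c(cols, group), "stations")
  g <- if (is.null(group)) rep(1L, nrow(stations)) else stations[[group]]
  for (col in cols) {
    z <- rep(NA_real_, nrow(stations))
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) < 2) {
        stop_defaunate(
          sprintf("group '%s' has < 2 stations; cannot normalize", lev),
          "defaunate_constant_error")
      }
      z[idx] <- zscore(stations[[col]][idx],
                       sprintf("'%s' values in group '%s'", col, lev))
    }
    stations[[paste0(col, "_z")]] <- z
  }
  stations
}

#' Select a station subset matching target covariate moments
#'
#' Greedy swap search for a subset of `n_out` values whose mean and sd are
#' closest to targets; used to subset the degraded landscape's canopy-closure
#' distribution to the hunted landscape's mean and spread as a robustness
#' device. Starting from a random subset, single in/out swaps are accepted
#' while they reduce the loss `|mean - target_mean|/target_sd +
#' |sd - target_sd|/target_sd`; several random restarts keep the search out
#' of poor local optima.
#'
#' @param values Numeric vector of source covariate values (one per station).
#' @param target_mean,target_sd Moments to match (`target_sd > 0`).
#' @param n_out Subset size, `1 <= n_out <= length(values)`.
#' @param n_restarts Random restarts (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of selected indices, with attributes
#'   `achieved_mean`, `achieved_sd` and `loss`.
#' @export
subset_match <- function(values, target_mean, target_sd, n_out,
                         n_restarts = 10, seed = NULL) {
  n <- length(values)
  if (n_out < 1 || n_out > n) {
    stop_defaunate(sprintf("n_out = %d infeasible for %d values", n_out, n),
                   "defaunate_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (target_sd <= 0) {
    stop_defaunate("target_sd must be > 0", "defaunate_config_error")
  }
  loss_fn <- function(idx) {
    m <- mean(values[idx])
    s <- if (length(idx) > 1) sd(values[idx]) else 0
    abs(m - target_mean) / target_sd + abs(s - target_sd) / target_sd
  }
  if (n_out == 1) {
    best <- which.min(abs(values - target_mean))
    sel <- best
  } else if (n_out == n) {
    sel <- seq_len(n)
  } else {
    best_loss <- Inf
    sel <- NULL
    for (r in seq_len(n_restarts)) {
      idx <- sort(sample.int(n, n_out))
      cur <- loss_fn(idx)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        outside <- setdiff(seq_len(n), idx)
        for (i in idx) {
          cand_loss <- vapply(outside, function(o) {
            loss_fn(c(setdiff(idx, i), o))
          }, numeric(1))
          b <- which.min(cand_loss)
          if (cand_loss[b] < cur - 1e-12) {
            idx <- sort(c(setdiff(idx, i), outside[b]))
            cur <- cand_loss[b]
            outside <- setdiff(seq_len(n), idx)
            improved <- TRUE
          }
        }
      }
      if (cur < best_loss) {
        best_loss <- cur
        sel <- idx
      }
    }
  }
  structure(sel,
            achieved_mean = mean(values[sel]),
            achieved_sd = if (length(sel) > 1) sd(values[sel]) else 0,
            loss = loss_fn(sel))
}
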