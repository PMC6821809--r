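# Internal helpers shared across modules.

logit <- function(p) qlogis(p)
logistic <- function(x) plogis(x)

# Stop with a classed condition so callers/tests can match on error class.
stop_defaunate <- function(message, class) {
  abort(message, class = c(class, "defaunate_error"))
}

# Validate that a data frame has the given columns, else a format error.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_defaunate(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      "defaunate_format_error"
    )
  }
  invisible(df)
}

# Parse ISO-8601 dates; report offending rows (1-based data rows) by line
# number in the file (header is line 1).
parse_iso_dates <- function(x, what) {
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  suppressWarnings(out[ok] <- as.Date(x[ok], format = "%Y-%m-%d"))
  # as.Date() silently rolls over some impossible dates on some platforms;
  # round-trip to be strict about e.g. "2014-13-40".
  ok[ok] <- !is.na(out[ok]) & format(out[ok], "%Y-%m-%d") == x[ok]
  if (!all(ok)) {
    bad <- which(!ok)
    stop_defaunate(
      sprintf(
        "%s: unparsable date(s) %s at file line(s) %s",
        what,
        paste(unique(x[bad]), collapse = ", "),
        paste(bad + 1L, collapse = ", ")
      ),
      "defaunate_row_error"
    )
  }
  as.Date(x, format = "%Y-%m-%d")
}

# z-score with the sample standard deviation; errors on constant input.
zscore <- function(x, what = "values") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_defaunate(
      sprintf("%s are constant; z-scores are undefined", what),
      "defaunate_constant_error"
    )
  }
  (x - mean(x)) / s
}

# Draw a reproducible stream seed for a named sub-stage from a master seed,
# keeping results independent across stages and below .Machine$integer.max.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score effort over active cells; if effort is constant the slope is
# unidentifiable (confounded with the detection intercept), so the covariate
# degenerates to 0 everywhere with a message.
zscore_effort <- function(effort, active) {
  out <- matrix(NA_real_, nrow(effort), ncol(effort))
  vals <- effort[active]
  if (length(vals) < 2 || sd(vals) == 0) {
    message("effort is constant across active cells; effort covariate set to 0")
    out[active] <- 0
  } else {
    out[active] <- (vals - mean(vals)) / sd(vals)
  }
  out
}
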