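# Cultivation time-series analysis: specific growth rates from log-linear
# fits, depletion times by threshold-crossing interpolation, interval
# specific rates with log-mean biomass weighting, and biomass-normalized
# cross-strain production comparisons aligned by time since depletion.

#' Cultivation time series container
#'
#' @param data tibble with columns `strain`, `replicate`, `time_h`, `cdw`
#'   (g/L), `co2` (volume-corrected respiration) and one column per tracked
#'   compound concentration (mmol/L, or mg/L for pigments and germicidins).
#'   Times must be strictly increasing; cdw positive.
#' @return a `cultivation_ts` tibble.
#' @export
cultivation_ts <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("strain", "time_h", "cdw") %in% names(data)))
  if (is.unsorted(data$time_h, strictly = TRUE)) {
    abort("times must be strictly increasing", class = "switchflux_usage_error")
  }
  if (any(data$cdw <= 0)) {
    abort("cdw must be positive", class = "switchflux_usage_error")
  }
  structure(data, class = c("cultivation_ts", class(data)))
}

ts_compounds <- function(ts) {
  setdiff(names(ts), c("strain", "replicate", "time_h", "cdw", "co2"))
}

#' Estimate the specific growth rate
#'
#' Least-squares slope of `ln(cdw)` against time over a window. With
#' `window = "auto"` the window is chosen among the prefixes (of at least
#' `min_points` points) ending at or before the earliest depletion event,
#' maximizing the fit R-squared; ties go to the longest prefix.
#'
#' @param ts a [cultivation_ts()].
#' @param window numeric `(t_start, t_end)` in hours, or `"auto"`.
#' @param min_points minimum points in an auto window.
#' @param depletion_threshold concentration threshold defining depletion for
#'   the auto window.
#' @return a `growth_fit` with [tidy()] and [glance()] methods; `glance()`
#'   reports `mu` (1/h), the window, `r_squared` and `n`.
#' @export
estimate_growth_rate <- function(ts, window = "auto", min_points = 4L,
                                 depletion_threshold = 0) {
  stopifnot(inherits(ts, "cultivation_ts"))
  if (identical(window, "auto")) {
    deps <- vapply(ts_compounds(ts), function(cmp) {
      detect_depletion(ts, cmp, depletion_threshold)
    }, numeric(1))
    t_cut <- if (all(is.na(deps))) max(ts$time_h) else min(deps, na.rm = TRUE)
    idx_max <- max(which(ts$time_h <= t_cut))
    if (idx_max < min_points) {
      abort("fewer than 'min_points' samples before the depletion event",
            class = "switchflux_usage_error")
    }
    cand <- min_points:idx_max
    fits <- lapply(cand, function(k) growth_fit(ts[seq_len(k), ]))
    r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
    best <- max(which(r2 >= max(r2) - 1e-12))   # ties -> longest prefix
    fit <- fits[[best]]
  } else {
    sub <- ts[ts$time_h >= window[1] & ts$time_h <= window[2], ]
    if (nrow(sub) < 3) {
      abort("growth window must contain at least 3 points",
            class = "switchflux_usage_error")
    }
    fit <- growth_fit(sub)
  }
  fit
}

growth_fit <- function(sub) {
  if (any(sub$cdw <= 0)) {
    abort("non-positive cdw in growth window", class = "switchflux_usage_error")
  }
  y <- log(sub$cdw)
  x <- sub$time_h
  if (isTRUE(all.equal(var(y), 0))) {
    fit <- list(mu = 0, intercept = y[1], r_squared = 1)
  } else {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    ss_res <- sum((y - intercept - slope * x)^2)
    fit <- list(mu = slope, intercept = intercept,
                r_squared = 1 - ss_res / sum((y - mean(y))^2))
  }
  structure(c(fit, list(window = range(sub$time_h), n = nrow(sub),
                        strain = sub$strain[1])),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> mu = ", format(x$mu), " 1/h over [",
      x$window[1], ", ", x$window[2], "] h (R2 = ",
      format(x$r_squared, digits = 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(strain = x$strain, mu = x$mu, t_start = x$window[1],
         t_end = x$window[2], r_squared = x$r_squared, n = x$n)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("mu", "log_cdw0"), estimate = c(x$mu, x$intercept))
}

#' Detect a depletion time by threshold crossing
#'
#' Linear interpolation of the first downward crossing of `threshold`.
#' Returns `NA` when the compound never crosses. Non-monotone chatter
#' around the threshold (a later upward re-crossing) takes the first
#' crossing and emits a warning.
#'
#' @param ts a [cultivation_ts()].
#' @param compound column name of the tracked compound.
#' @param threshold concentration threshold (same unit as the column).
#' @return depletion time in hours, or `NA_real_` for "never depleted".
#' @export
detect_depletion <- function(ts, compound, threshold = 0) {
  if (!compound %in% names(ts)) {
    abort(paste0("compound '", compound, "' not tracked"),
          class = "switchflux_usage_error")
  }
  v <- ts[[compound]]
  t <- ts$time_h
  n <- length(v)
  cross <- which(v[-n] > threshold & v[-1] <= threshold)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  if (any(v[seq_len(n) > i + 1] > threshold)) {
    warn(paste0("'", compound, "' re-crosses the threshold after depletion; ",
                "using the first crossing"))
  }
  t[i] + (v[i] - threshold) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
}

#' Interval-wise specific uptake/secretion rates
#'
#' For each sampling interval, `q = dC / (dt * X_bar)` with `X_bar` the
#' logarithmic mean biomass over the interval (exact for exponential
#' growth). Negative rates denote consumption. The interval growth rate
#' `mu = ln(X2/X1)/dt` is included as compound `"biomass"`.
#'
#' @param ts a [cultivation_ts()].
#' @param compounds compound columns to process; default all tracked.
#' @return tibble `strain`, `t_start`, `t_end`, `t_mid`, `compound`, `q`
#'   (mmol/gDW/h; `"biomass"` rows are 1/h).
#' @export
specific_rates <- function(ts, compounds = ts_compounds(ts)) {
  stopifnot(inherits(ts, "cultivation_ts"))
  n <- nrow(ts)
  if (n < 2) abort("need at least 2 time points", class = "switchflux_usage_error")
  dt <- diff(ts$time_h)
  if (any(dt == 0)) abort("zero-length interval", class = "switchflux_usage_error")
  x1 <- ts$cdw[-n]
  x2 <- ts$cdw[-1]
  xbar <- ifelse(abs(x2 - x1) < 1e-12 * pmax(x1, x2),
                 x1, (x2 - x1) / log(x2 / x1))
  base <- tibble(strain = ts$strain[-n], t_start = ts$time_h[-n],
                 t_end = ts$time_h[-1],
                 t_mid = (ts$time_h[-n] + ts$time_h[-1]) / 2)
  rows <- lapply(compounds, function(cmp) {
    dc <- diff(ts[[cmp]])
    mutate(base, compound = cmp, q = dc / (dt * xbar))
  })
  mu_rows <- mutate(base, compound = "biomass", q = log(x2 / x1) / dt)
  bind_rows(c(rows, list(mu_rows)))
}

#' Glucose-to-glutamate uptake ratio per interval
#'
#' @param rates output of [specific_rates()].
#' @param glucose,glutamate compound names.
#' @return tibble `strain`, `t_mid`, `ratio` (of uptake magnitudes; `NA`
#'   where the glutamate rate is not an uptake).
#' @export
uptake_ratio <- function(rates, glucose = "glucose", glutamate = "glutamate") {
  wide <- tidyr::pivot_wider(
    filter(rates, .data$compound %in% c(glucose, glutamate)),
    names_from = "compound", values_from = "q")
  mutate(wide,
         ratio = if_else(.data[[glutamate]] < 0,
                         .data[[glucose]] / .data[[glutamate]], NA_real_),
         .keep = "unused")[, c("strain", "t_mid", "ratio")]
}

interp_at <- function(t, v, t0) stats::approx(t, v, xout = t0, rule = 2)$y

#' Cross-strain production comparison at depletion-aligned time
#'
#' Biomass-normalized titer (concentration / cdw) of a compound evaluated
#' at equal time after the depletion event in a reference and an alternative
#' strain's series. By default both are evaluated at the largest
#' time-after-depletion covered by both runs (end-of-run alignment); a
#' rate-based variant compares post-depletion titer slopes instead.
#'
#' @param ts_ref,ts_alt [cultivation_ts()] of the reference and alternative
#'   strains.
#' @param compound compound column present in both.
#' @param align_by only `"depletion"` is supported.
#' @param depletion_compound compound defining the alignment event.
#' @param at time after depletion (h) at which to evaluate; default
#'   end-of-run.
#' @param method `"titer"` (default) or `"rate"` (least-squares slope of the
#'   normalized titer over the post-depletion window).
#' @param threshold depletion threshold.
#' @return percent reduction `100 * (1 - alt / ref)` with attributes
#'   `ref_value`, `alt_value`, `aligned_time_after_depletion`.
#' @export
production_comparison <- function(ts_ref, ts_alt, compound,
                                  align_by = "depletion",
                                  depletion_compound = "phosphate",
                                  at = NULL, method = c("titer", "rate"),
                                  threshold = 0) {
  method <- match.arg(method)
  stopifnot(align_by == "depletion")
  for (ts in list(ts_ref, ts_alt)) {
    if (!compound %in% names(ts)) {
      abort(paste0("compound '", compound, "' not tracked in both series"),
            class = "switchflux_usage_error")
    }
  }
  d_ref <- detect_depletion(ts_ref, depletion_compound, threshold)
  d_alt <- detect_depletion(ts_alt, depletion_compound, threshold)
  if (is.na(d_ref) || is.na(d_alt)) {
    abort("depletion alignment impossible: no depletion event detected",
          class = "switchflux_usage_error")
  }
  if (method == "titer") {
    if (is.null(at)) {
      at <- min(max(ts_ref$time_h) - d_ref, max(ts_alt$time_h) - d_alt)
    }
    val <- function(ts, d) {
      interp_at(ts$time_h, ts[[compound]], d + at) /
        interp_at(ts$time_h, ts$cdw, d + at)
    }
    ref <- val(ts_ref, d_ref)
    alt <- val(ts_alt, d_alt)
  } else {
    slope <- function(ts, d) {
      sub <- ts[ts$time_h >= d, ]
      y <- sub[[compound]] / sub$cdw
      unname(coef(lm(y ~ sub$time_h))[2])
    }
    ref <- slope(ts_ref, d_ref)
    alt <- slope(ts_alt, d_alt)
    at <- NA_real_
  }
  structure(100 * (1 - alt / ref),
            ref_value = ref, alt_value = alt,
            aligned_time_after_depletion = at)
}

ts_units <- function(compound) {
  dplyr::case_when(compound == "cdw" ~ "g/L",
                   compound == "co2" ~ "mmol/L/h",
                   compound %in% c("germA", "germB", "act", "red",
                                   "cda", "cpk") ~ "mg/L",
                   TRUE ~ "mmol/L")
}

#' Write / read a cultivation time series as long-format TSV
#'
#' Interchange format: one row per (time, variable) with columns `strain`,
#' `replicate`, `time_h`, `variable`, `value`, `unit`.
#'
#' @param ts a [cultivation_ts()].
#' @param path TSV file path.
#' @return `write_cultivation_tsv()` returns `path` invisibly;
#'   `read_cultivation_tsv()` returns a [cultivation_ts()].
#' @export
write_cultivation_tsv <- function(ts, path) {
  long <- tidyr::pivot_longer(as_tibble(ts),
                              c("cdw", "co2", all_of(ts_compounds(ts))),
                              names_to = "variable", values_to = "value")
  long$unit <- ts_units(long$variable)
  readr::write_tsv(long[, c("strain", "replicate", "time_h", "variable",
                            "value", "unit")], path)
  invisible(path)
}

#' @rdname write_cultivation_tsv
#' @export
read_cultivation_tsv <- function(path) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    strain = "c", replicate = "i", time_h = "d", variable = "c",
    value = "d", unit = "c"), progress = FALSE)
  wide <- tidyr::pivot_wider(long[, c("strain", "replicate", "time_h",
                                      "variable", "value")],
                             names_from = "variable", values_from = "value")
  cultivation_ts(wide)
}
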