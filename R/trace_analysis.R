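#' Construct a fluorescence trace
#'
#' A timestamped single-channel fluorescence recording with per-cell
#' calibration anchors (Fmin, Fmax) and optional labeled application
#' windows (e.g. a caffeine pulse).
#'
#' @param time Time in seconds, strictly increasing.
#' @param F Raw fluorescence, arbitrary units.
#' @param channel `"cyto"` (cytoplasmic indicator, e.g. G-GECO1.1) or
#'   `"er"` (ER-luminal, e.g. R-CEPIA1er).
#' @param Fmin,Fmax Calibration floor/ceiling; `Fmin` may be `NULL`
#'   when the channel default applies (see [normalize_trace()]).
#' @param events Named list of `c(start, end)` windows in seconds.
#' @return A `ca_trace` data frame.
#' @export
ca_trace <- function(time, F, channel = c("cyto", "er"),
                     Fmin = NULL, Fmax = NULL, events = list()) {
  channel <- match.arg(channel)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (length(time) != length(F)) stop("time and F must match", call. = FALSE)
  if (!is.null(Fmin) && !is.null(Fmax) && Fmax <= Fmin) {
    stop("calibration error: Fmax must exceed Fmin", call. = FALSE)
  }
  structure(data.frame(time = time, F = F),
            class = c("ca_trace", "data.frame"),
            channel = channel, Fmin = Fmin, Fmax = Fmax, events = events)
}

#' Min-max normalize a fluorescence trace
#'
#' Returns \eqn{(F - F_{min})/(F_{max} - F_{min})}. When a per-cell
#' `Fmin` was not recorded, channel-specific population defaults are
#' used: the ER-luminal indicator floor averages 7.655% of Fmax, the
#' cytoplasmic indicator floor is 0.
#'
#' @param trace A [ca_trace()] with at least `Fmax` set.
#' @param er_floor_frac Default ER floor as a fraction of Fmax.
#' @return A normalized `ca_trace` (anchors become 0 and 1).
#' @export
normalize_trace <- function(trace, er_floor_frac = 0.07655) {
  stopifnot(inherits(trace, "ca_trace"))
  Fmax <- attr(trace, "Fmax")
  if (is.null(Fmax)) stop("calibration error: Fmax is required", call. = FALSE)
  Fmin <- attr(trace, "Fmin")
  if (is.null(Fmin)) {
    Fmin <- if (attr(trace, "channel") == "er") er_floor_frac * Fmax else 0
  }
  if (Fmax <= Fmin) stop("calibration error: Fmax must exceed Fmin", call. = FALSE)
  ca_trace((as.data.frame(trace))$time, (trace$F - Fmin) / (Fmax - Fmin),
           channel = attr(trace, "channel"), Fmin = 0, Fmax = 1,
           events = attr(trace, "events"))
}

#' Detect Ca2+ oscillation events in a normalized trace
#'
#' Events are excursions above a rolling-median baseline plus
#' `k` robust noise units (MAD of the baseline-subtracted signal), with
#' hysteresis: an event starts when the signal crosses the high
#' threshold and cannot restart until it has fallen below the low
#' threshold (a fraction `hysteresis` of the high one) and a refractory
#' interval has elapsed. Deterministic given the configuration.
#'
#' @param trace A normalized [ca_trace()].
#' @param baseline_window_s Rolling-median window, seconds (default 15).
#' @param k Threshold in MAD units above baseline (default 5).
#' @param hysteresis Low threshold as a fraction of the high (default 0.5).
#' @param refractory_s Minimum inter-event interval, seconds (default 2).
#' @param window Optional `c(start, end)` seconds restricting the
#'   analysis. By default, if the trace carries a labeled
#'   `"calibration"` event window, everything from its start onward is
#'   excluded so calibration segments never count as events.
#' @return List of class `oscillation_report`: `event_count`,
#'   `frequency_per_min`, `mean_amplitude`, `baseline`, `event_times`.
#' @export
detect_oscillations <- function(trace, baseline_window_s = 15, k = 5,
                                hysteresis = 0.5, refractory_s = 2,
                                window = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  t <- trace$time; x <- trace$F
  if (is.null(window)) {
    cal <- attr(trace, "events")[["calibration"]]
    if (!is.null(cal)) window <- c(t[1], cal[1] - 1e-9)
  }
  if (!is.null(window)) {
    keep <- t >= window[1] & t < window[2]
    t <- t[keep]; x <- x[keep]
  }
  dur <- t[length(t)] - t[1]
  dt <- stats::median(diff(t))
  if (dur < 30 || dt > 1) {
    stop("insufficient data: need >= 30 s sampled at >= 1 Hz", call. = FALSE)
  }
  w <- round(baseline_window_s / dt)
  if (w %% 2 == 0) w <- w + 1
  w <- max(3, min(w, length(x) - (1 - length(x) %% 2)))
  base <- stats::runmed(x, w, endrule = "median")
  sigma <- stats::mad(x - base)
  hi <- base + k * sigma
  lo <- base + hysteresis * k * sigma
  events <- numeric(0); amps <- numeric(0)
  armed <- TRUE; last_event <- -Inf
  i <- 1
  while (i <= length(x)) {
    if (armed && x[i] > hi[i] && (t[i] - last_event) >= refractory_s) {
      # ride the excursion to its peak, then disarm until it falls below lo
      j <- i
      while (j < length(x) && x[j + 1] >= lo[j + 1]) j <- j + 1
      peak <- which.max(x[i:j]) + i - 1
      events <- c(events, t[peak])
      amps <- c(amps, x[peak] - base[peak])
      last_event <- t[peak]
      armed <- FALSE
      i <- j + 1
      next
    }
    if (!armed && x[i] < lo[i]) armed <- TRUE
    i <- i + 1
  }
  structure(list(event_count = length(events),
                 frequency_per_min = length(events) / (dur / 60),
                 mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
                 baseline = stats::median(base),
                 event_times = events),
            class = "oscillation_report")
}

#' Upper envelope of the ER Ca2+ level
#'
#' The "upper level" of a sawtooth ER-luminal trace is estimated as the
#' 95th percentile of the normalized signal within a window — close to
#' the peak of each refill cycle but robust to noise (a design choice:
#' the quantile, not the max).
#'
#' @param trace A normalized ER [ca_trace()].
#' @param window Optional `c(start, end)` seconds; default whole trace.
#' @param probs Quantile used for the envelope (default 0.95).
#' @return Level in normalized units.
#' @export
upper_er_level <- function(trace, window = NULL, probs = 0.95) {
  stopifnot(inherits(trace, "ca_trace"))
  x <- trace$F; t <- trace$time
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    if (!any(keep)) stop("empty window", call. = FALSE)
    x <- x[keep]
  }
  unname(stats::quantile(x, probs, type = 7))
}

#' Fit a Hill dose-response curve to caffeine peak responses
#'
#' Monotone four-parameter Hill fit
#' \eqn{y = floor + (ceiling - floor) \, d^{h} / (d^{h} + EC_{50}^{h})}
#' by nonlinear least squares, used for the caffeine dose dependence of
#' Ca2+ transients (doses in mM).
#'
#' @param dose Doses in mM (>= 4 distinct values spanning >= 1.5 log
#'   units).
#' @param response Peak normalized responses, same length.
#' @return List of class `dose_response_fit`: `EC50` (mM), `hill`,
#'   `floor`, `ceiling`, `r_squared`, `converged`,
#'   `ec50_in_range` (whether the EC50 lies inside the tested doses).
#' @export
caffeine_dose_response <- function(dose, response) {
  if (length(dose) != length(response)) stop("dose and response must match", call. = FALSE)
  ud <- sort(unique(dose))
  if (length(ud) < 4 || log10(max(ud) / min(ud)) < 1.5) {
    stop("need >= 4 doses spanning >= 1.5 log units", call. = FALSE)
  }
  dat <- data.frame(ld = log10(dose), y = response)
  starts <- lapply(ud, function(e) list(floor = min(response),
                                        ceiling = max(response),
                                        lec50 = log10(e), hill = 1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ floor + (ceiling - floor) * stats::plogis(hill * log(10) * (ld - lec50)),
        data = dat, start = s,
        lower = c(floor = -1, ceiling = 0, lec50 = log10(min(ud)) - 3, hill = 0.1),
        upper = c(floor = 1, ceiling = 10, lec50 = log10(max(ud)) + 3, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(EC50 = NA_real_, hill = NA_real_, floor = NA_real_,
                          ceiling = NA_real_, r_squared = NA_real_,
                          converged = FALSE, ec50_in_range = NA),
                     class = "dose_response_fit"))
  }
  co <- stats::coef(best$fit)
  ec50 <- 10^co[["lec50"]]
  sst <- sum((dat$y - mean(dat$y))^2)
  structure(list(EC50 = ec50, hill = co[["hill"]], floor = co[["floor"]],
                 ceiling = co[["ceiling"]],
                 r_squared = 1 - best$sse / sst, converged = TRUE,
                 ec50_in_range = ec50 >= min(ud) && ec50 <= max(ud)),
            class = "dose_response_fit")
}

#' Five-number summary with mean and SEM for per-cell scalars
#'
#' Quartiles use linear interpolation (`quantile` type 7), matching the
#' box-and-whisker convention of minimum, Q1, median, Q3, maximum.
#' SEM is the sample SD over sqrt(n); it is `NA` for a single value.
#'
#' @param values Per-cell scalar measurements (n >= 1).
#' @return Named list: min, q1, median, q3, max, mean, sd, sem, n.
#' @export
summarize_cells <- function(values) {
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}
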