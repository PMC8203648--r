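# Stimulation paradigms and HRF-convolved design matrices.

#' Construct a stimulation paradigm
#'
#' A paradigm is an ordered table of stimulation events together with the
#' acquisition timing (repetition time and number of volumes). Events are
#' trapezoidal blocks: a linear ramp of `ramp` seconds up to the plateau,
#' `plateau` seconds at full intensity, then off.
#'
#' @param events data frame with columns `kind` (one of `"heat"`, `"laser"`,
#'   `"costim"`), `onset` (s from scan start), `ramp` (s), `plateau` (s) and
#'   `magnitude` (unitless label, e.g. a temperature).
#' @param tr repetition time in seconds.
#' @param n_volumes number of acquired volumes.
#' @return An object of class `paradigm`: list with `events`, `tr`,
#'   `n_volumes` and `duration = tr * n_volumes`.
#' @examples
#' p <- paradigm(data.frame(kind = "heat", onset = 100, ramp = 5,
#'                          plateau = 15, magnitude = 50),
#'               tr = 4, n_volumes = 975)
#' p$duration
#' @export
paradigm <- function(events, tr, n_volumes) {
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0,
            is.numeric(n_volumes), length(n_volumes) == 1L, n_volumes >= 1)
  cols <- c("kind", "onset", "ramp", "plateau", "magnitude")
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(kind = character(), onset = numeric(),
                         ramp = numeric(), plateau = numeric(),
                         magnitude = numeric())
  }
  events <- as.data.frame(events)[, cols]
  if (nrow(events)) {
    if (!all(events$kind %in% c("heat", "laser", "costim")))
      stop("unknown event kind(s): ",
           paste(setdiff(events$kind, c("heat", "laser", "costim")), collapse = ", "))
    if (any(events$onset < 0)) stop("event onsets must be >= 0")
    if (any(events$ramp < 0)) stop("event ramps must be >= 0")
    if (any(events$plateau <= 0)) stop("event plateaus must be > 0")
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    ends <- events$onset + events$ramp + events$plateau
    duration <- tr * n_volumes
    if (nrow(events) > 1L && any(ends[-nrow(events)] > events$onset[-1L] + 1e-9)) {
      i <- which(ends[-nrow(events)] > events$onset[-1L] + 1e-9)[1L]
      stop(sprintf("events overlap: %s at %gs runs into %s at %gs",
                   events$kind[i], events$onset[i],
                   events$kind[i + 1L], events$onset[i + 1L]))
    }
    if (ends[nrow(events)] > duration + 1e-9) {
      i <- nrow(events)
      stop(sprintf(
        "paradigm exceeds scan duration: %s event at %gs ends at %gs but the scan lasts %gs",
        events$kind[i], events$onset[i], ends[i], duration))
    }
  }
  structure(list(events = events, tr = tr, n_volumes = as.integer(n_volumes),
                 duration = tr * n_volumes),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("<paradigm> %d events, TR %gs, %d volumes (%.1f min)\n",
              nrow(x$events), x$tr, x$n_volumes, x$duration / 60))
  if (nrow(x$events))
    print(table(factor(x$events$kind, levels = c("heat", "laser", "costim"))))
  invisible(x)
}

#' Heat / laser co-stimulation paradigm
#'
#' Builds the default co-stimulation protocol: `n_heat` heat-class stimuli,
#' every second of which is combined with simultaneous laser application
#' ("costim"), and one laser-only stimulus interspersed after each heat-class
#' stimulus. Consecutive stimuli of any kind are separated by `interval`
#' seconds, so heat-class events recur every `2 * interval` seconds. The
#' first stimulus starts after an initial rest of `initial_rest` seconds.
#'
#' Defaults reproduce a 65-min run: 16 heat-class stimuli of 50 degC, 20 s
#' each (5 s ramp, 15 s plateau), 100 s stimulus interval, sampled at an
#' effective TR of 4 s over 975 volumes.
#'
#' @param n_heat number of heat-class (heat-only plus costim) stimuli.
#' @param interval seconds between consecutive stimuli of any kind.
#' @param stim_duration total stimulus duration (ramp + plateau) in seconds.
#' @param ramp linear-ramp duration in seconds.
#' @param tr repetition time (s) of the series the paradigm is sampled at.
#' @param n_volumes number of volumes.
#' @param heat_magnitude temperature label for heat-class events (degC).
#' @param initial_rest seconds before the first stimulus onset.
#' @return A [paradigm()].
#' @examples
#' p <- build_costim_paradigm()
#' table(p$events$kind)
#' @export
build_costim_paradigm <- function(n_heat = 16, interval = 100,
                                  stim_duration = 20, ramp = 5,
                                  tr = 4, n_volumes = 975,
                                  heat_magnitude = 50,
                                  initial_rest = interval) {
  stopifnot(n_heat >= 0, interval >= stim_duration, ramp >= 0,
            stim_duration > ramp)
  plateau <- stim_duration - ramp
  ev <- NULL
  if (n_heat >= 1) {
    i <- seq_len(n_heat)
    heat_onsets <- initial_rest + (i - 1) * 2 * interval
    heat_kind <- ifelse(i %% 2 == 0, "costim", "heat")
    laser_onsets <- heat_onsets + interval
    ev <- rbind(
      data.frame(kind = heat_kind, onset = heat_onsets, ramp = ramp,
                 plateau = plateau, magnitude = heat_magnitude),
      data.frame(kind = "laser", onset = laser_onsets, ramp = ramp,
                 plateau = plateau, magnitude = NA_real_))
  }
  paradigm(ev, tr = tr, n_volumes = n_volumes)
}

#' Wild-type ascending-heat paradigm
#'
#' `n_sets` repetitions of an ascending temperature list (innocuous to
#' noxious), applied after an initial rest. Defaults reproduce a 50-min
#' session: three sets of 40/45/50/55 degC, 20 s stimuli (5 s ramp),
#' 2 min initial rest and a stimulus interval of 3 min 40 s.
#'
#' @param temperatures ascending temperatures (degC), one event per entry
#'   and set.
#' @param n_sets number of ascending sets.
#' @param initial_rest seconds of rest before the first onset.
#' @param stim_duration stimulus duration (ramp + plateau) in seconds.
#' @param interval inter-onset interval in seconds.
#' @param ramp ramp duration in seconds.
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @return A [paradigm()] whose events are all heat-class with `magnitude`
#'   set to the temperature.
#' @examples
#' p <- build_wt_heat_paradigm()
#' nrow(p$events)
#' @export
build_wt_heat_paradigm <- function(temperatures = c(40, 45, 50, 55),
                                   n_sets = 3, initial_rest = 120,
                                   stim_duration = 20, interval = 220,
                                   ramp = 5, tr = 4, n_volumes = 750) {
  stopifnot(length(temperatures) >= 1, n_sets >= 1, stim_duration > ramp)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly ascending")
  temps <- rep(temperatures, times = n_sets)
  onsets <- initial_rest + (seq_along(temps) - 1) * interval
  ev <- data.frame(kind = "heat", onset = onsets, ramp = ramp,
                   plateau = stim_duration - ramp, magnitude = temps)
  paradigm(ev, tr = tr, n_volumes = n_volumes)
}

#' Two-gamma HRF parameters
#'
#' Parameters of the canonical two-gamma haemodynamic response function:
#' a positive response lobe peaking at `time_to_peak` seconds followed by an
#' undershoot peaking at `undershoot_peak` seconds, scaled down by
#' `response_undershoot_ratio`. `dispersion` / `u_dispersion` control the
#' width of the two lobes.
#'
#' @param time_to_peak response peak latency (s).
#' @param undershoot_peak undershoot peak latency (s); must exceed
#'   `time_to_peak`.
#' @param response_undershoot_ratio ratio of response to undershoot
#'   amplitude (> 0).
#' @param dispersion,u_dispersion dispersion (s) of the response and
#'   undershoot lobes.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(time_to_peak = 5, undershoot_peak = 15,
                       response_undershoot_ratio = 6,
                       dispersion = 1, u_dispersion = 1) {
  stopifnot(time_to_peak > 0, undershoot_peak > 0,
            response_undershoot_ratio > 0, dispersion > 0, u_dispersion > 0)
  if (time_to_peak >= undershoot_peak)
    stop("time_to_peak must be smaller than undershoot_peak")
  structure(list(time_to_peak = time_to_peak,
                 undershoot_peak = undershoot_peak,
                 response_undershoot_ratio = response_undershoot_ratio,
                 dispersion = dispersion, u_dispersion = u_dispersion),
            class = "hrf_params")
}

# Unnormalized two-gamma impulse response. Each lobe is written so its mode
# falls exactly at the stated peak latency.
.two_gamma_raw <- function(t, p) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  a1 <- p$time_to_peak / p$dispersion
  a2 <- p$undershoot_peak / p$u_dispersion
  lobe1 <- (tp / p$time_to_peak)^a1 * exp(-(tp - p$time_to_peak) / p$dispersion)
  lobe2 <- (tp / p$undershoot_peak)^a2 * exp(-(tp - p$undershoot_peak) / p$u_dispersion)
  out[pos] <- lobe1 - lobe2 / p$response_undershoot_ratio
  out
}

#' Two-gamma haemodynamic response function
#'
#' Difference of two gamma-density-shaped lobes, zero for `t <= 0` and
#' normalized to unit peak. The response lobe peaks at
#' `params$time_to_peak`; the undershoot lobe, scaled by
#' `1 / response_undershoot_ratio`, peaks at `params$undershoot_peak`.
#'
#' @param t time in seconds (vectorized; any real values).
#' @param params an [hrf_params()] object.
#' @return Numeric vector of unitless response values with peak 1.
#' @examples
#' two_gamma_hrf(0:10, hrf_params())
#' @export
two_gamma_hrf <- function(t, params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  # peak of the difference sits within a dispersion of the response peak
  grid <- seq(max(0, params$time_to_peak - 2 * params$dispersion),
              params$time_to_peak + 2 * params$dispersion, by = 1e-3)
  peak <- max(.two_gamma_raw(grid, params))
  .two_gamma_raw(t, params) / peak
}

# Trapezoidal stimulus waveform on a time grid: linear ramp to 1 over
# `ramp` seconds, plateau, then off.
.trapezoid <- function(t, onset, ramp, plateau) {
  s <- numeric(length(t))
  rel <- t - onset
  on <- rel >= 0 & rel < ramp + plateau
  if (ramp > 0) {
    s[on] <- pmin(rel[on] / ramp, 1)
  } else {
    s[on] <- 1
  }
  s
}

# Fixed predictor ordering used throughout the package.
.kind_levels <- c("heat", "laser", "costim")

#' HRF-convolved design matrix
#'
#' One predictor per stimulus kind present in the paradigm (fixed order
#' heat, laser, costim), each the trapezoidal stimulus waveform convolved
#' with the two-gamma HRF, sampled at the volume acquisition times
#' `0, tr, 2 tr, ...`, and normalized to unit peak. Optional nuisance
#' columns (constant and linear drift) are appended.
#'
#' @param paradigm a [paradigm()].
#' @param params an [hrf_params()].
#' @param dt convolution grid resolution in seconds.
#' @param drift if `TRUE`, append `constant` and `drift` columns.
#' @return Numeric matrix with `n_volumes` rows; attribute
#'   `stimulus_columns` names the stimulus predictors.
#' @examples
#' X <- design_matrix(build_costim_paradigm())
#' colnames(X)
#' @export
design_matrix <- function(paradigm, params = hrf_params(), dt = 0.1,
                          drift = TRUE) {
  stopifnot(inherits(paradigm, "paradigm"), dt > 0)
  nv <- paradigm$n_volumes
  kinds <- .kind_levels[.kind_levels %in% paradigm$events$kind]
  t_fine <- seq(0, paradigm$duration, by = dt)
  hrf_support <- params$undershoot_peak + 12 * params$u_dispersion
  h <- two_gamma_hrf(seq(0, hrf_support, by = dt), params)
  vol_idx <- round((seq_len(nv) - 1) * paradigm$tr / dt) + 1L
  cols <- lapply(kinds, function(k) {
    ev <- paradigm$events[paradigm$events$kind == k, , drop = FALSE]
    s <- numeric(length(t_fine))
    for (i in seq_len(nrow(ev)))
      s <- s + .trapezoid(t_fine, ev$onset[i], ev$ramp[i], ev$plateau[i])
    x <- stats::convolve(s, rev(h), type = "open")[seq_along(t_fine)] * dt
    x <- x[vol_idx]
    # causality: the response is identically zero before the first onset
    # (clears FFT round-off from the circular convolution)
    x[(vol_idx - 1) * dt < min(ev$onset)] <- 0
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk
    x
  })
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, nv, 0)
  colnames(X) <- kinds
  if (drift) {
    tt <- seq_len(nv) - (nv + 1) / 2
    X <- cbind(X, constant = 1, drift = tt / max(abs(tt)))
  }
  attr(X, "stimulus_columns") <- kinds
  attr(X, "tr") <- paradigm$tr
  X
}

#' Write / read a paradigm event table as TSV
#'
#' Columns: `kind`, `onset_s`, `ramp_s`, `plateau_s`, `magnitude`.
#'
#' @param paradigm a [paradigm()].
#' @param path file path.
#' @rdname paradigm_tsv
#' @export
write_paradigm_tsv <- function(paradigm, path) {
  ev <- paradigm$events
  out <- data.frame(kind = ev$kind, onset_s = ev$onset, ramp_s = ev$ramp,
                    plateau_s = ev$plateau, magnitude = ev$magnitude)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param tr,n_volumes acquisition timing for the reconstructed paradigm.
#' @rdname paradigm_tsv
#' @export
read_paradigm_tsv <- function(path, tr, n_volumes) {
  d <- utils::read.delim(path)
  paradigm(data.frame(kind = d$kind, onset = d$onset_s, ramp = d$ramp_s,
                      plateau = d$plateau_s, magnitude = d$magnitude),
           tr = tr, n_volumes = n_volumes)
}
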