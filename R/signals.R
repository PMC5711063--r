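#' Sinusoidal couch-motion trace
#'
#' Generates the sinusoidal displacement signal used to drive the motion
#' stage: amplitude 5/10/15 mm (peak-to-peak couch displacement 10/20/30 mm)
#' at a 4 s breathing period in the reference protocol.
#'
#' @param amplitude half peak-to-peak amplitude in mm, >= 0.
#' @param period breathing period in seconds, > 0.
#' @param duration trace duration in seconds, >= `dt`.
#' @param dt sampling interval in seconds (default 0.01 s, fine enough to
#'   resolve the 47 ms control latency as a fractional-sample shift).
#' @param phase phase offset in radians.
#' @return A displacement [resp_trace] with
#'   `values[i] = amplitude * sin(2*pi*t_i/period + phase)`.
#' @examples
#' tr <- gen_sine(amplitude = 5, period = 4, duration = 60)
#' diff(range(tr$values))  # peak-to-peak 10 mm
#' @export
gen_sine <- function(amplitude, period, duration, dt = 0.01, phase = 0) {
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("`amplitude` must be >= 0", call. = FALSE)
  }
  if (!is.finite(period) || period <= 0) {
    stop("`period` must be > 0", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) {
    stop("`dt` must be > 0", call. = FALSE)
  }
  if (!is.finite(duration) || duration < dt) {
    stop("`duration` must be >= `dt`", call. = FALSE)
  }
  t <- seq(0, duration, by = dt)
  resp_trace(amplitude * sin(2 * pi * t / period + phase), dt = dt,
             kind = "displacement")
}

#' Parameters of the irregular breathing generator
#'
#' @param displacement_pp target peak-to-peak displacement in mm
#'   (10/20/30 mm in the reference protocol).
#' @param period_mean mean breathing period in seconds (default 4 s).  A
#'   warning is emitted outside the physiological 2.9--5.6 s range.
#' @param period_sd per-cycle period jitter sd in seconds.
#' @param amplitude_cv per-cycle amplitude coefficient of variation.
#' @param drift_sd baseline random-walk step sd in mm per cycle.
#' @param duration trace duration in seconds (default 60 s).
#' @param dt sampling interval in seconds.
#' @param seed integer RNG seed; the generator is fully reproducible per seed.
#' @return A `breathing_params` list, validated.
#' @export
breathing_params <- function(displacement_pp, period_mean = 4,
                             period_sd = 0.3, amplitude_cv = 0.15,
                             drift_sd = 0.5, duration = 60, dt = 0.01,
                             seed = 1L) {
  if (!is.finite(displacement_pp) || displacement_pp <= 0) {
    stop("`displacement_pp` must be > 0", call. = FALSE)
  }
  if (!is.finite(period_mean) || period_mean <= 0) {
    stop("`period_mean` must be > 0", call. = FALSE)
  }
  if (period_mean < 2.9 || period_mean > 5.6) {
    warning("`period_mean` outside the physiological 2.9-5.6 s range",
            call. = FALSE)
  }
  if (period_sd < 0 || amplitude_cv < 0 || drift_sd < 0) {
    stop("jitter parameters must be >= 0", call. = FALSE)
  }
  if (duration < period_mean) {
    stop("`duration` must cover at least one mean period", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  structure(list(displacement_pp = displacement_pp,
                 period_mean = period_mean, period_sd = period_sd,
                 amplitude_cv = amplitude_cv, drift_sd = drift_sd,
                 duration = duration, dt = dt, seed = as.integer(seed)),
            class = "breathing_params")
}

#' Irregular ("human") breathing displacement trace
#'
#' Concatenates breathing cycles with per-cycle period jitter
#' (Normal(period_mean, period_sd)) and amplitude jitter
#' (Normal(1, amplitude_cv) times displacement_pp / 2), each cycle a
#' raised-cosine inhale/exhale shape starting and ending at end-exhale, plus
#' a random-walk baseline drift (one step per cycle, linearly interpolated
#' within a cycle).  The finished trace is rescaled so its global
#' peak-to-peak displacement equals `displacement_pp` exactly, with the
#' minimum (deepest end-exhale) at 0 mm.
#'
#' @param params a [breathing_params] object.
#' @return A displacement [resp_trace].  The attribute `"cycle_bounds"`
#'   carries the sample indices of the generated cycle boundaries
#'   (end-exhale instants), useful as a segmentation ground truth.
#' @export
gen_breathing <- function(params) {
  if (!inherits(params, "breathing_params")) {
    stop("`params` must be a breathing_params object", call. = FALSE)
  }
  p <- params
  withr::with_seed(p$seed, {
    # draw cycles until the duration is covered
    n_guess <- ceiling(p$duration / max(p$period_mean - 4 * p$period_sd, 0.5)) + 2L
    periods <- stats::rnorm(n_guess, p$period_mean, p$period_sd)
    periods <- pmax(periods, 0.25 * p$period_mean)  # guard absurd draws
    while (sum(periods) < p$duration) {
      extra <- max(stats::rnorm(1, p$period_mean, p$period_sd),
                   0.25 * p$period_mean)
      periods <- c(periods, extra)
    }
    ncyc <- which(cumsum(periods) >= p$duration)[1]
    periods <- periods[seq_len(ncyc)]
    amps <- pmax(stats::rnorm(ncyc, 1, p$amplitude_cv), 0.1) *
      p$displacement_pp / 2
    base <- cumsum(c(0, stats::rnorm(ncyc, 0, p$drift_sd)))
  })

  starts <- c(0, cumsum(periods))
  t <- seq(0, p$duration, by = p$dt)
  cyc <- findInterval(t, starts, rightmost.closed = FALSE)
  cyc <- pmin(pmax(cyc, 1L), length(periods))
  tau <- (t - starts[cyc]) / periods[cyc]          # cycle phase in [0, 1)
  baseline <- base[cyc] + tau * (base[cyc + 1L] - base[cyc])
  x <- baseline + amps[cyc] * (1 - cos(2 * pi * tau)) / 2

  rng <- range(x)
  if (diff(rng) <= 0) stop("degenerate breathing trace", call. = FALSE)
  x <- (x - rng[1]) * p$displacement_pp / diff(rng)

  tr <- resp_trace(x, dt = p$dt, kind = "displacement")
  bounds <- round(starts[starts <= p$duration + 1e-9] / p$dt) + 1L
  attr(tr, "cycle_bounds") <- bounds[bounds <= length(x)]
  tr
}

#' Strain-gauge transducer model
#'
#' Linear transduction of abdominal displacement into a bridge voltage:
#' `v = volts_per_mm * x + offset_v + noise`.
#'
#' @param volts_per_mm sensitivity in V/mm, nonzero.
#' @param offset_v bridge offset voltage in V.
#' @param noise_sd additive Gaussian noise sd in V, >= 0.
#' @param seed integer RNG seed for the noise.
#' @return A `gauge_model` list.
#' @export
gauge_model <- function(volts_per_mm, offset_v = 0, noise_sd = 0, seed = 1L) {
  if (!is.finite(volts_per_mm) || volts_per_mm == 0) {
    stop("`volts_per_mm` must be nonzero", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(volts_per_mm = volts_per_mm, offset_v = offset_v,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gauge_model")
}

#' Transduce a displacement trace into a surrogate voltage trace
#'
#' @param disp a displacement [resp_trace].
#' @param gm a [gauge_model].
#' @return A voltage [resp_trace] with the same sampling.
#' @export
transduce <- function(disp, gm) {
  stopifnot_trace(disp, kind = "displacement")
  if (!inherits(gm, "gauge_model")) {
    stop("`gm` must be a gauge_model", call. = FALSE)
  }
  v <- gm$volts_per_mm * disp$values + gm$offset_v
  if (gm$noise_sd > 0) {
    v <- v + withr::with_seed(gm$seed,
                              stats::rnorm(length(v), 0, gm$noise_sd))
  }
  resp_trace(v, dt = disp$dt, t0 = disp$t0, kind = "voltage")
}
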