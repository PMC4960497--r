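# Seeded simulator of TSST-structured physiological sessions. Stress phases
# elevate mean heart rate and skin conductance relative to a 5-min seated
# baseline, with between-subject variability in both baseline level and
# reactivity; ground-truth beat times are returned so the beat detector can
# be scored against the generator.

PPG_ANALYSIS_HZ <- 64
EDA_ANALYSIS_HZ <- 4
PULSE_RISE_S <- 0.12     # raised-cosine upstroke duration
PULSE_DECAY_S <- 0.25    # exponential diastolic decay constant
SCR_TAU_RISE_S <- 0.75
SCR_TAU_DECAY_S <- 4

#' Reactivity configuration for the session simulator
#'
#' Parameterizes the qualitative stress pattern: stress phases raise heart
#' rate and skin conductance above the seated baseline, with between-subject
#' spread in baseline level and in the size of the stress response. The
#' anticipation phase receives `anticipation_fraction` of the full stress
#' delta, producing intermediate, deliberately unlabeled blocks.
#'
#' @param baseline_hr_mean,baseline_hr_sd_between population baseline heart
#'   rate, bpm (default 70 +/- 8 between subjects).
#' @param hr_delta_stress_mean,hr_delta_stress_sd stress-induced heart-rate
#'   rise, bpm (default 15 +/- 5).
#' @param ibi_jitter_cv coefficient of variation of beat-to-beat interval
#'   jitter (default 0.04).
#' @param baseline_eda_mean,baseline_eda_sd_between tonic skin conductance,
#'   microsiemens (default 4.0 +/- 1.5).
#' @param eda_delta_stress_mean,eda_delta_stress_sd stress-induced tonic
#'   rise, microsiemens (default 2.0 +/- 0.7).
#' @param scr_rate_baseline,scr_rate_stress phasic skin-conductance-response
#'   rate, events/min (default 2 at rest, 6 under stress).
#' @param scr_amp_mean mean SCR peak amplitude, microsiemens (default 0.3).
#' @param measurement_noise_sd Gaussian EDA sensor noise, microsiemens
#'   (default 0.02).
#' @param anticipation_fraction fraction of the stress delta applied during
#'   TSST-P (default 0.5).
#' @return a `reactivity_config` list.
#' @export
reactivity_config <- function(baseline_hr_mean = 70,
                              baseline_hr_sd_between = 8,
                              hr_delta_stress_mean = 15,
                              hr_delta_stress_sd = 5,
                              ibi_jitter_cv = 0.04,
                              baseline_eda_mean = 4.0,
                              baseline_eda_sd_between = 1.5,
                              eda_delta_stress_mean = 2.0,
                              eda_delta_stress_sd = 0.7,
                              scr_rate_baseline = 2,
                              scr_rate_stress = 6,
                              scr_amp_mean = 0.3,
                              measurement_noise_sd = 0.02,
                              anticipation_fraction = 0.5) {
  cfg <- list(baseline_hr_mean = baseline_hr_mean,
              baseline_hr_sd_between = baseline_hr_sd_between,
              hr_delta_stress_mean = hr_delta_stress_mean,
              hr_delta_stress_sd = hr_delta_stress_sd,
              ibi_jitter_cv = ibi_jitter_cv,
              baseline_eda_mean = baseline_eda_mean,
              baseline_eda_sd_between = baseline_eda_sd_between,
              eda_delta_stress_mean = eda_delta_stress_mean,
              eda_delta_stress_sd = eda_delta_stress_sd,
              scr_rate_baseline = scr_rate_baseline,
              scr_rate_stress = scr_rate_stress,
              scr_amp_mean = scr_amp_mean,
              measurement_noise_sd = measurement_noise_sd,
              anticipation_fraction = anticipation_fraction)
  sds <- c("baseline_hr_sd_between", "hr_delta_stress_sd", "ibi_jitter_cv",
           "baseline_eda_sd_between", "eda_delta_stress_sd",
           "measurement_noise_sd")
  rates <- c("scr_rate_baseline", "scr_rate_stress", "scr_amp_mean")
  for (f in names(cfg)) {
    if (!is.finite(cfg[[f]])) stop(sprintf("reactivity_config: %s must be finite", f))
  }
  if (any(unlist(cfg[sds]) < 0)) {
    stop("reactivity_config: standard deviations must be >= 0", call. = FALSE)
  }
  if (any(unlist(cfg[rates]) < 0)) {
    stop("reactivity_config: rates and amplitudes must be >= 0", call. = FALSE)
  }
  if (cfg$baseline_hr_mean <= 40 || cfg$baseline_hr_mean >= 180) {
    stop("reactivity_config: baseline_hr_mean must be physiologic (40-180 bpm)",
         call. = FALSE)
  }
  if (cfg$anticipation_fraction < 0 || cfg$anticipation_fraction > 1) {
    stop("reactivity_config: anticipation_fraction must be in [0, 1]",
         call. = FALSE)
  }
  structure(cfg, class = "reactivity_config")
}

# Stereotyped pulse waveform: raised-cosine upstroke over PULSE_RISE_S then
# exponential decay; evaluated at times since beat onset, 0 outside support.
.pulse_shape <- function(t_rel) {
  v <- numeric(length(t_rel))
  rise <- t_rel >= 0 & t_rel < PULSE_RISE_S
  v[rise] <- 0.5 * (1 - cos(pi * t_rel[rise] / PULSE_RISE_S))
  fall <- t_rel >= PULSE_RISE_S
  v[fall] <- exp(-(t_rel[fall] - PULSE_RISE_S) / PULSE_DECAY_S)
  v
}

#' Simulate a PPG trace with known beat times
#'
#' Beat onsets are laid down sequentially: each inter-beat interval is
#' `60 / HR(minute)` perturbed by multiplicative Gaussian jitter with the
#' given coefficient of variation, truncated so the implied instantaneous
#' rate stays in the physiologic 40-180 bpm range. Each beat is rendered as
#' a stereotyped pulse (fast raised-cosine upstroke, slower exponential
#' decay) summed onto the trace. The returned ground-truth beat times mark
#' the upstroke midpoint — the point the derivative-based detector locates.
#'
#' @param hr_trajectory per-minute mean heart rate, bpm, each in (40, 180).
#' @param jitter_cv IBI jitter coefficient of variation (>= 0).
#' @param rate output sampling rate, Hz (>= 32; default 64).
#' @param seed integer RNG seed.
#' @return list with `trace` (PPG [signal_trace()]) and `beat_times`
#'   (ground-truth upstroke times, seconds).
#' @export
simulate_ppg <- function(hr_trajectory, jitter_cv = 0.04,
                         rate = PPG_ANALYSIS_HZ, seed = 1L) {
  if (any(hr_trajectory <= 40 | hr_trajectory >= 180)) {
    stop("simulate_ppg: hr_trajectory must lie strictly inside (40, 180) bpm",
         call. = FALSE)
  }
  if (rate < 32) stop("simulate_ppg: rate must be >= 32 Hz", call. = FALSE)
  n_min <- length(hr_trajectory)
  duration <- n_min * 60
  onsets <- with_seed(seed, {
    t <- 0.5
    out <- numeric(0)
    while (t < duration) {
      out <- c(out, t)
      minute <- min(floor(t / 60), n_min - 1)
      ibi <- (60 / hr_trajectory[minute + 1]) *
        (1 + stats::rnorm(1, 0, jitter_cv))
      ibi <- min(max(ibi, 60 / IBI_BPM_MAX), 60 / IBI_BPM_MIN)
      t <- t + ibi
    }
    out
  })
  n <- as.integer(round(duration * rate))
  x <- numeric(n)
  support <- PULSE_RISE_S + 5 * PULSE_DECAY_S
  n_sup <- as.integer(ceiling(support * rate))
  for (o in onsets) {
    i0 <- as.integer(ceiling(o * rate))           # first sample at/after onset
    if (i0 > n - 1L) next
    idx <- max(i0, 0L):min(i0 + n_sup, n - 1L)
    x[idx + 1L] <- x[idx + 1L] + .pulse_shape(idx / rate - o)
  }
  list(trace = signal_trace(x, rate, "PPG"),
       beat_times = onsets + PULSE_RISE_S / 2)
}

# SCR kernel normalized to unit peak amplitude.
.scr_shape <- function(t_rel) {
  v <- numeric(length(t_rel))
  pos <- t_rel >= 0
  raw <- exp(-t_rel[pos] / SCR_TAU_DECAY_S) - exp(-t_rel[pos] / SCR_TAU_RISE_S)
  tpk <- log(SCR_TAU_DECAY_S / SCR_TAU_RISE_S) /
    (1 / SCR_TAU_RISE_S - 1 / SCR_TAU_DECAY_S)
  peak <- exp(-tpk / SCR_TAU_DECAY_S) - exp(-tpk / SCR_TAU_RISE_S)
  v[pos] <- raw / peak
  v
}

#' Simulate an EDA trace
#'
#' Tonic level is interpolated piecewise-linearly through the per-minute
#' trajectory (anchored at minute midpoints). Phasic skin conductance
#' responses occur at Poisson event times with the per-minute rate; each has
#' an exponentially distributed peak amplitude (mean `scr_amp_mean`) and the
#' biexponential shape `exp(-t/4) - exp(-t/0.75)` (seconds), unit-peak
#' normalized. Gaussian measurement noise is added and the trace clipped at
#' 0 microsiemens.
#'
#' @param tonic_trajectory per-minute tonic level, microsiemens (>= 0).
#' @param scr_rate per-minute SCR rate, events/min (recycled to the
#'   trajectory length).
#' @param config a [reactivity_config()] (supplies `scr_amp_mean` and
#'   `measurement_noise_sd`).
#' @param rate output sampling rate, Hz (default 4).
#' @param seed integer RNG seed.
#' @return an EDA [signal_trace()].
#' @export
simulate_eda <- function(tonic_trajectory, scr_rate,
                         config = reactivity_config(),
                         rate = EDA_ANALYSIS_HZ, seed = 1L) {
  if (any(tonic_trajectory < 0)) {
    stop("simulate_eda: tonic trajectory must be non-negative", call. = FALSE)
  }
  n_min <- length(tonic_trajectory)
  scr_rate <- rep_len(scr_rate, n_min)
  duration <- n_min * 60
  n <- as.integer(round(duration * rate))
  tt <- (0:(n - 1L)) / rate
  tonic <- if (n_min == 1L) rep(tonic_trajectory, n) else
    stats::approx(x = 60 * (seq_len(n_min) - 0.5), y = tonic_trajectory,
                  xout = tt, rule = 2)$y
  x <- with_seed(seed, {
    out <- tonic
    for (k in seq_len(n_min)) {
      n_ev <- stats::rpois(1, scr_rate[k])
      if (n_ev == 0L) next
      ev_t <- 60 * (k - 1) + stats::runif(n_ev, 0, 60)
      amps <- stats::rexp(n_ev, rate = 1 / config$scr_amp_mean)
      for (j in seq_len(n_ev)) {
        i0 <- as.integer(ceiling(ev_t[j] * rate))
        if (i0 > n - 1L) next
        idx <- max(i0, 0L):min(i0 + as.integer(30 * rate), n - 1L)
        out[idx + 1L] <- out[idx + 1L] +
          amps[j] * .scr_shape(idx / rate - ev_t[j])
      }
    }
    if (config$measurement_noise_sd > 0) {
      out <- out + stats::rnorm(n, 0, config$measurement_noise_sd)
    }
    pmax(out, 0)
  })
  signal_trace(x, rate, "EDA")
}

#' Simulate one TSST session with ground truth
#'
#' The session follows the standard protocol — baseline `[0, 300)`, TSST-P
#' `[300, 600)`, TSST-S `[600, 900)`, TSST-A `[900, 1200)` seconds. The
#' participant's baseline heart rate, baseline skin conductance, and stress
#' deltas are drawn from the between-subject distributions of `config`;
#' both stress phases receive the full delta (and the stress SCR rate),
#' the anticipation phase `anticipation_fraction` of each.
#'
#' @param participant_id character scalar.
#' @param config a [reactivity_config()].
#' @param seed integer RNG seed.
#' @return list with `session` (a [tsst_session()]; PPG 64 Hz, EDA 4 Hz)
#'   and `truth` (a `ground_truth` list: drawn parameters, per-minute
#'   programmed HR, and ground-truth beat times).
#' @export
simulate_session <- function(participant_id, config = reactivity_config(),
                             seed = 1L) {
  stopifnot(inherits(config, "reactivity_config"))
  draws <- with_seed(seed, list(
    baseline_hr = stats::rnorm(1, config$baseline_hr_mean,
                               config$baseline_hr_sd_between),
    hr_delta = stats::rnorm(1, config$hr_delta_stress_mean,
                            config$hr_delta_stress_sd),
    baseline_eda = max(0.5, stats::rnorm(1, config$baseline_eda_mean,
                                         config$baseline_eda_sd_between)),
    eda_delta = max(0, stats::rnorm(1, config$eda_delta_stress_mean,
                                    config$eda_delta_stress_sd)),
    ppg_seed = sample.int(.Machine$integer.max - 1L, 1L),
    eda_seed = sample.int(.Machine$integer.max - 1L, 1L)
  ))
  frac <- c(BASELINE = 0, TSST_P = config$anticipation_fraction,
            TSST_S = 1, TSST_A = 1)
  phase_per_min <- rep(names(frac), each = 5L)
  hr_per_min <- draws$baseline_hr + frac[phase_per_min] * draws$hr_delta
  hr_per_min <- pmin(pmax(hr_per_min, 42), 178)
  eda_per_min <- pmax(0, draws$baseline_eda +
                        frac[phase_per_min] * draws$eda_delta)
  scr_per_min <- config$scr_rate_baseline + frac[phase_per_min] *
    (config$scr_rate_stress - config$scr_rate_baseline)

  ppg <- simulate_ppg(hr_per_min, config$ibi_jitter_cv,
                      rate = PPG_ANALYSIS_HZ, seed = draws$ppg_seed)
  eda <- simulate_eda(eda_per_min, scr_per_min, config,
                      rate = EDA_ANALYSIS_HZ, seed = draws$eda_seed)
  session <- tsst_session(participant_id, ppg$trace, eda,
                          standard_tsst_schedule())
  truth <- structure(list(
    participant_id = participant_id,
    beat_times = ppg$beat_times,
    hr_per_minute = unname(hr_per_min),
    phase_per_minute = unname(phase_per_min),
    baseline_hr = draws$baseline_hr,
    hr_delta = draws$hr_delta,
    baseline_eda = draws$baseline_eda,
    eda_delta = draws$eda_delta
  ), class = "ground_truth")
  list(session = session, truth = truth)
}

#' Simulate a cohort of TSST sessions
#'
#' Per-participant seeds are drawn deterministically from `master_seed`, so
#' the whole cohort is reproducible from one integer.
#'
#' @param n number of participants (>= 1; the default working cohort is 20).
#' @param config a [reactivity_config()].
#' @param master_seed integer RNG seed.
#' @return list of `n` elements, each a `list(session, truth)` as returned
#'   by [simulate_session()].
#' @export
simulate_cohort <- function(n = 20L, config = reactivity_config(),
                            master_seed = 1L) {
  if (!is.finite(n) || n < 1) {
    stop("simulate_cohort: n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    simulate_session(sprintf("P%02d", i), config, seed = seeds[i])
  })
}

#' Inject transient motion artifacts into a trace
#'
#' Optional confound generator (off by default in all simulations): adds
#' short half-sine transients at Poisson times, emulating motion-induced
#' excursions.
#'
#' @param trace a [signal_trace()].
#' @param rate_per_min artifact rate, events/min.
#' @param amplitude peak artifact amplitude (signal units).
#' @param duration_s artifact duration, seconds (default 0.5).
#' @param seed integer RNG seed.
#' @return the corrupted [signal_trace()].
#' @export
add_motion_artifacts <- function(trace, rate_per_min = 1, amplitude = 2,
                                 duration_s = 0.5, seed = 1L) {
  stopifnot(inherits(trace, "signal_trace"))
  dur <- trace_duration(trace)
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  x <- trace$samples
  x <- with_seed(seed, {
    n_ev <- stats::rpois(1, rate_per_min * dur / 60)
    if (n_ev > 0L) {
      ev_t <- stats::runif(n_ev, 0, dur)
      for (tev in ev_t) {
        i0 <- as.integer(floor(tev * fs))
        if (i0 > n - 1L) next
        idx <- max(i0, 0L):min(i0 + as.integer(duration_s * fs), n - 1L)
        rel <- (idx / fs - tev) / duration_s
        x[idx + 1L] <- x[idx + 1L] + amplitude * sin(pi * pmax(0, pmin(1, rel)))
      }
    }
    x
  })
  signal_trace(x, fs, trace$channel, trace$start_offset)
}
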