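#' Facial-contraction protocol timeline
#'
#' Generates the event timeline of the facial-contraction protocol: five
#' facial muscles (Frontalis, Masseter, Orbicularis Oculi, Orbicularis Oris,
#' Zygomatic), each contracted 15 times per eye condition — five long (3 s),
#' five medium (1 s) and five short (0.5 s) contractions in seeded random
#' order — with a 2 s neutral period after every contraction. The protocol is
#' executed once with eyes open and once with eyes closed (two contiguous
#' halves of the record), giving 150 contractions per participant and 225 s
#' of EMG-contaminated signal per participant.
#'
#' @param n_participants Number of participants (>= 1); participants are
#'   concatenated in time.
#' @param seed Integer seed controlling the duration-class permutation within
#'   each muscle block; `NULL` uses the ambient RNG state.
#' @return An object of class `protocol_timeline`: list with `events` (data
#'   frame: `participant`, `eye_condition`, `muscle`, `duration_class`,
#'   `duration_s`, `onset_s`), `n_participants`, `total_duration_s`, and
#'   `condition_bounds` (start/end seconds of each eye-condition block).
#' @examples
#' tl <- generate_protocol(1, seed = 1)
#' nrow(tl$events)        # 150
#' sum(tl$events$duration_s)  # 225 s contaminated
#' @export
generate_protocol <- function(n_participants, seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 1 || n_participants != round(n_participants))
    stop("'n_participants' must be a positive integer", call. = FALSE)

  muscles <- c("Frontalis", "Masseter", "OrbicularisOculi",
               "OrbicularisOris", "Zygomatic")
  dur_by_class <- c(long = 3, medium = 1, short = 0.5)
  gap_s <- 2
  lead_in_s <- 2   # neutral pre-roll before each muscle block

  with_seed(seed, {
    rows <- vector("list", 0L)
    bounds <- vector("list", 0L)
    t0 <- 0
    for (p in seq_len(n_participants)) {
      for (cond in c("open", "closed")) {
        block_start <- t0
        for (m in muscles) {
          t0 <- t0 + lead_in_s
          classes <- sample(rep(names(dur_by_class), each = 5L))
          for (cl in classes) {
            d <- dur_by_class[[cl]]
            rows[[length(rows) + 1L]] <- data.frame(
              participant = p, eye_condition = cond, muscle = m,
              duration_class = cl, duration_s = d, onset_s = t0)
            t0 <- t0 + d + gap_s
          }
        }
        bounds[[length(bounds) + 1L]] <- data.frame(
          participant = p, eye_condition = cond,
          start_s = block_start, end_s = t0)
      }
    }
    ev <- do.call(rbind, rows)
    structure(list(events = ev,
                   n_participants = as.integer(n_participants),
                   total_duration_s = t0,
                   condition_bounds = do.call(rbind, bounds)),
              class = "protocol_timeline")
  })
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat(sprintf("<protocol_timeline> %d participants, %d events, %.1f s total (%.1f s contracted)\n",
              x$n_participants, nrow(x$events), x$total_duration_s,
              sum(x$events$duration_s)))
  invisible(x)
}

#' Parameters for the synthetic EEG/EMG generator
#'
#' @param fs Sampling rate in Hz (default 5000, the acquisition rate of the
#'   emulated protocol).
#' @param eeg_band_powers Named numeric vector of per-band variances in
#'   microvolts squared for Delta/Theta/Alpha/Beta/Gamma during open eyes.
#' @param alpha_closed_gain Multiplicative factor (>= 1) applied to the
#'   alpha-band variance during closed-eyes blocks (default 4: pronounced
#'   posterior alpha enhancement on eye closure).
#' @param emg_band Two-element numeric: surface-EMG band in Hz
#'   (default c(20, 450)).
#' @param snr_db Target in-burst SNR of the contaminated mixture in dB
#'   (default -10, heavy contamination).
#' @param envelope_rise_ms Trapezoidal burst-envelope rise/fall time in ms
#'   (default 50).
#' @param baseline_db Baseline (non-burst) EMG-channel noise level in dB
#'   relative to the unit burst level (default -40).
#' @param seed Integer root seed for all random draws, or `NULL`.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(fs = 5000,
                         eeg_band_powers = c(Delta = 40, Theta = 15,
                                             Alpha = 20, Beta = 10,
                                             Gamma = 2),
                         alpha_closed_gain = 4,
                         emg_band = c(20, 450),
                         snr_db = -10,
                         envelope_rise_ms = 50,
                         baseline_db = -40,
                         seed = NULL) {
  stopifnot(fs > 0, length(emg_band) == 2L)
  if (!(emg_band[1] > 0 && emg_band[1] < emg_band[2] && emg_band[2] < fs / 2))
    stop("need 0 < emg_band[1] < emg_band[2] < fs/2", call. = FALSE)
  if (alpha_closed_gain < 1)
    stop("'alpha_closed_gain' must be >= 1", call. = FALSE)
  need <- c("Delta", "Theta", "Alpha", "Beta", "Gamma")
  if (!all(need %in% names(eeg_band_powers)))
    stop("'eeg_band_powers' must name all of ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(fs = fs, eeg_band_powers = eeg_band_powers,
                 alpha_closed_gain = alpha_closed_gain, emg_band = emg_band,
                 snr_db = snr_db, envelope_rise_ms = envelope_rise_ms,
                 baseline_db = baseline_db, seed = seed),
            class = "synth_params")
}

# canonical EEG rhythm band edges in Hz (left-closed, right-open)
eeg_bands <- function() {
  list(Delta = c(0.5, 4), Theta = c(4, 7), Alpha = c(7, 13),
       Beta = c(13, 30), Gamma = c(30, 70))
}

# brick-wall zero-phase band-pass via FFT bin masking; keeps |f| in [low, high]
fft_bandpass <- function(x, fs, low, high) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)             # two-sided frequency of each bin
  X <- stats::fft(x)
  X[f < low | f > high] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# white noise shaped to [low, high] Hz, rescaled to unit variance
band_noise <- function(n, fs, low, high) {
  y <- fft_bandpass(stats::rnorm(n), fs, low, high)
  y / stats::sd(y)
}

#' Synthesize background EEG for a protocol timeline
#'
#' Colored-noise EEG built as a superposition of band-limited Gaussian
#' oscillations in the five canonical rhythm bands, with the alpha-band
#' variance multiplied by `alpha_closed_gain` during closed-eyes blocks.
#'
#' @param timeline A `protocol_timeline`.
#' @param params A `synth_params`.
#' @return A [time_series()] of length `timeline$total_duration_s * fs`.
#' @export
synthesize_eeg <- function(timeline, params) {
  stopifnot(inherits(timeline, "protocol_timeline"),
            inherits(params, "synth_params"))
  fs <- params$fs
  n <- round(timeline$total_duration_s * fs)
  bands <- eeg_bands()
  closed <- closed_flags(timeline, n, fs)

  seed <- if (is.null(params$seed)) NULL else
    substream_seed(params$seed, "eeg")
  with_seed(seed, {
    x <- numeric(n)
    for (b in names(bands)) {
      comp <- band_noise(n, fs, bands[[b]][1], bands[[b]][2]) *
        sqrt(params$eeg_band_powers[[b]])
      if (b == "Alpha" && params$alpha_closed_gain != 1)
        comp[closed] <- comp[closed] * sqrt(params$alpha_closed_gain)
      x <- x + comp
    }
    time_series(x, fs)
  })
}

# logical vector flagging samples inside closed-eyes blocks
closed_flags <- function(timeline, n, fs) {
  closed <- logical(n)
  cb <- timeline$condition_bounds
  cb <- cb[cb$eye_condition == "closed", , drop = FALSE]
  for (i in seq_len(nrow(cb))) {
    a <- floor(cb$start_s[i] * fs) + 1L
    b <- min(n, ceiling(cb$end_s[i] * fs))
    if (b >= a) closed[a:b] <- TRUE
  }
  closed
}

#' Synthesize the facial-EMG channel and its ground-truth mask
#'
#' Band-limited Gaussian noise amplitude-modulated by a trapezoidal envelope
#' that is nonzero exactly during protocol contractions (unit plateau level),
#' plus a low baseline noise floor. The returned mask marks the
#' envelope-nonzero samples.
#'
#' @inheritParams synthesize_eeg
#' @return List with `emg` (a [time_series()]) and `mask` (an
#'   [contamination_mask()]).
#' @export
synthesize_emg <- function(timeline, params) {
  stopifnot(inherits(timeline, "protocol_timeline"),
            inherits(params, "synth_params"))
  fs <- params$fs
  n <- round(timeline$total_duration_s * fs)
  env <- burst_envelope(timeline, n, fs, params$envelope_rise_ms)

  seed <- if (is.null(params$seed)) NULL else
    substream_seed(params$seed, "emg")
  with_seed(seed, {
    carrier <- band_noise(n, fs, params$emg_band[1], params$emg_band[2])
    baseline <- band_noise(n, fs, params$emg_band[1], params$emg_band[2]) *
      10^(params$baseline_db / 20)
    list(emg = time_series(env * carrier + baseline, fs),
         mask = contamination_mask(env > 0, fs))
  })
}

# trapezoidal gate: ramps lie inside the event so support == event support
burst_envelope <- function(timeline, n, fs, rise_ms) {
  env <- numeric(n)
  nr <- max(1L, round(rise_ms / 1000 * fs))
  for (i in seq_len(nrow(timeline$events))) {
    a <- floor(timeline$events$onset_s[i] * fs) + 1L
    b <- min(n, a + round(timeline$events$duration_s[i] * fs) - 1L)
    len <- b - a + 1L
    if (len <= 0L) next
    r <- min(nr, floor(len / 2))
    e <- rep(1, len)
    if (r > 0L) {
      ramp <- seq_len(r) / (r + 1)
      e[seq_len(r)] <- ramp
      e[len - r + seq_len(r)] <- rev(ramp)
    }
    env[a:b] <- e
  }
  env
}

#' Mix EEG with scaled EMG at a target in-burst SNR
#'
#' Scales the EMG channel by the gain `g` that makes the ratio of EEG to
#' scaled-EMG power over mask-high samples equal the requested SNR, then adds
#' it to the EEG: `out = eeg + g * emg` with
#' `10*log10(P_eeg / P_gemg) = snr_db` over in-burst samples.
#'
#' @param eeg,emg [time_series()] objects of equal length and rate.
#' @param mask An [contamination_mask()] flagging the in-burst samples.
#' @param snr_db Target in-burst SNR in dB (e.g. -10: EMG power 10x EEG).
#' @return A [time_series()] with attributes `emg_gain` (the applied gain)
#'   and `snr_db`.
#' @export
mix <- function(eeg, emg, mask, snr_db) {
  stopifnot(inherits(eeg, "ts_uv"), inherits(emg, "ts_uv"),
            inherits(mask, "emg_mask"))
  if (length(eeg) != length(emg) || length(eeg) != length(mask))
    stop("'eeg', 'emg' and 'mask' must have equal lengths", call. = FALSE)
  if (eeg$fs != emg$fs)
    stop("sampling rates differ", call. = FALSE)
  hi <- mask$flags
  if (!any(hi))
    stop("mask has no high samples: mixing gain undefined", call. = FALSE)
  p_eeg <- mean(eeg$samples[hi]^2)
  p_emg <- mean(emg$samples[hi]^2)
  if (p_emg <= 0)
    stop("EMG power over mask-high samples is zero: gain undefined",
         call. = FALSE)
  g <- sqrt(p_eeg / (p_emg * 10^(snr_db / 10)))
  out <- time_series(eeg$samples + g * emg$samples, eeg$fs)
  attr(out, "emg_gain") <- g
  attr(out, "snr_db") <- snr_db
  out
}

#' One-call synthetic recording
#'
#' Convenience wrapper: protocol, EEG, EMG, mask and contaminated mixture in
#' one seeded object.
#'
#' @param n_participants Number of participants.
#' @param params A [synth_params()]; its `seed` drives all randomness.
#' @param duration_s Optional crop: keep only the first `duration_s` seconds.
#' @return List with `timeline`, `eeg`, `emg`, `mask`, `mixed`, `emg_gain`.
#' @export
synthesize_recording <- function(n_participants = 1, params = synth_params(),
                                 duration_s = NULL) {
  tl <- generate_protocol(n_participants,
                          seed = if (is.null(params$seed)) NULL else
                            substream_seed(params$seed, "protocol"))
  eeg <- synthesize_eeg(tl, params)
  em <- synthesize_emg(tl, params)
  mx <- mix(eeg, em$emg, em$mask, params$snr_db)
  out <- list(timeline = tl, eeg = eeg, emg = em$emg, mask = em$mask,
              mixed = mx, emg_gain = attr(mx, "emg_gain"))
  if (!is.null(duration_s)) {
    keep <- seq_len(min(length(eeg), round(duration_s * params$fs)))
    out$eeg <- time_series(eeg$samples[keep], params$fs)
    out$emg <- time_series(em$emg$samples[keep], params$fs)
    out$mask <- contamination_mask(em$mask$flags[keep], params$fs)
    out$mixed <- time_series(mx$samples[keep], params$fs)
  }
  out
}
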