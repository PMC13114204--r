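# Synthetic multichannel EEG with exact ground-truth seizure annotations.
#
# Background activity is spectrally shaped Gaussian noise (amplitude profile
# 1/f^(beta/2), i.e. power 1/f^beta) plus optional sinusoidal rhythms, drawn
# independently per channel from a counter-based per-channel substream of
# one global seed (so adding channels never reshuffles existing ones).
# Seizure episodes add a shared morphological template, scaled by the event
# gain (relative to the background standard deviation) and a per-channel
# random gain in [0.5, 1.5] that mimics the inter-channel coherence of
# ictal activity. The generator makes no claim of physiological realism.

# run expr with a local RNG state, restoring the caller's stream
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

channelSeed <- function(seed, ch) {
  as.integer((as.numeric(seed) * 1009 + ch * 99991) %% 2147483647)
}

#' Configuration for the synthetic EEG generator
#'
#' @param durationS total recording duration, seconds.
#' @param nChannels number of channels (default 18, the common clinical
#'   montage size).
#' @param fs sampling rate in Hz (default 256).
#' @param beta background spectral exponent: power proportional to
#'   `1/f^beta` (default 1, pink-like scalp background).
#' @param rhythms `data.frame` with columns `freq_hz`, `amplitude`
#'   (amplitude relative to `noiseSd`); default a modest 10 Hz
#'   alpha-like component.
#' @param events `data.frame` with columns `onset_s`, `duration_s`, `type`
#'   (one of `"spike_wave"`, `"rhythmic_burst"`, `"sharp_wave"`) and `gain`
#'   (amplitude of the injected template relative to the background
#'   standard deviation; `>= 0`, 0 injects nothing but keeps the
#'   annotation).
#' @param noiseSd background standard deviation in microvolts (default 20,
#'   a typical awake scalp EEG amplitude scale).
#' @param seed integer seed driving all randomness.
#' @return a validated `synthConfig` list.
#' @export
synthConfig <- function(durationS, nChannels = 18L, fs = 256,
                        beta = 1.0,
                        rhythms = data.frame(freq_hz = 10, amplitude = 0.3),
                        events = NULL, noiseSd = 20, seed = 1L) {
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         type = character(0), gain = numeric(0))
  stopifnot(durationS > 0, nChannels >= 1, fs > 0, noiseSd > 0)
  if (nrow(events) > 0L) {
    if (!all(c("onset_s", "duration_s", "type", "gain") %in% names(events)))
      stop("events need columns onset_s, duration_s, type, gain")
    if (any(events$gain < 0)) stop("event gain must be >= 0")
    if (any(events$onset_s < 0) ||
        any(events$onset_s + events$duration_s > durationS + 1e-9))
      stop("events must lie within [0, durationS]")
    o <- order(events$onset_s)
    events <- events[o, , drop = FALSE]
    ends <- events$onset_s + events$duration_s
    if (nrow(events) > 1L && any(events$onset_s[-1] < ends[-nrow(events)])) {
      bad <- which(events$onset_s[-1] < ends[-nrow(events)])[1]
      stop(sprintf("overlapping events: event at %gs overlaps event at %gs",
                   events$onset_s[bad + 1], events$onset_s[bad]))
    }
  }
  structure(list(durationS = durationS, nChannels = as.integer(nChannels),
                 fs = fs, beta = beta, rhythms = rhythms, events = events,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "synthConfig")
}

#' Load a generator configuration from YAML or JSON
#'
#' The file may contain any of the [synthConfig()] fields; `events` and
#' `rhythms` are given as lists of records (or data frames in JSON).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a validated [synthConfig()].
#' @export
synthConfigFromFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  for (fld in c("events", "rhythms"))
    if (!is.null(raw[[fld]]) && !is.data.frame(raw[[fld]])) {
      x <- raw[[fld]]
      raw[[fld]] <- if (!is.null(names(x)))
        as.data.frame(x)                     # named list of columns (YAML)
      else do.call(rbind, lapply(x, as.data.frame))  # list of records
    }
  do.call(synthConfig, raw)
}

#' Seizure waveform templates
#'
#' Returns a zero-mean waveform with maximum absolute amplitude 1 of length
#' `round(duration_s * fs)`. Types: `"spike_wave"` is a repeating ~3 Hz
#' sharp transient followed by a slower rounded half-wave (spike-and-slow-wave
#' composite); `"rhythmic_burst"` is an amplitude-ramped ~6 Hz sinusoid;
#' `"sharp_wave"` is a train of isolated asymmetric transients.
#'
#' @param type template type.
#' @param duration_s template duration, seconds.
#' @param fs sampling rate, Hz.
#' @return numeric vector of length `round(duration_s * fs)`.
#' @export
makeTemplate <- function(type, duration_s, fs) {
  stopifnot(duration_s > 0, fs > 0)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  w <- switch(type,
    spike_wave = {
      phase <- (t * 3) %% 1                    # 3 Hz spike-and-wave cycles
      spike <- exp(-((phase - 0.10) / 0.035)^2)
      slow <- -0.65 * sin(pi * pmax(0, pmin(1, (phase - 0.25) / 0.7)))
      spike + slow
    },
    rhythmic_burst = {
      ramp <- pmin(1, t / max(t[2], 0.25 * duration_s))  # amplitude ramp-in
      ramp * sin(2 * pi * 6 * t)
    },
    sharp_wave = {
      phase <- t %% 1                          # one transient per second
      rise <- exp(-((phase - 0.30) / 0.020)^2)
      fall <- exp(-((phase - 0.36) / 0.055)^2)
      rise - 0.7 * fall
    },
    stop("unknown template type: ", type))
  w <- w - mean(w)
  w / max(abs(w))
}

# one channel of 1/f^(beta/2)-shaped unit-variance noise plus rhythms
shapedBackground <- function(n, fs, beta, rhythms, seed) {
  withLocalSeed(seed, {
    z <- stats::rnorm(n)
    Z <- stats::fft(z)
    f <- c(0, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f)                       # two-sided frequency axis
    amp <- ifelse(f > 0, 1 / pmax(f, fs / n)^(beta / 2), 0)
    x <- Re(stats::fft(Z * amp, inverse = TRUE)) / n
    x <- x / stats::sd(x)
    if (nrow(rhythms) > 0L) {
      t <- (seq_len(n) - 1) / fs
      for (r in seq_len(nrow(rhythms)))
        x <- x + rhythms$amplitude[r] *
          sin(2 * pi * rhythms$freq_hz[r] * t + stats::runif(1, 0, 2 * pi))
    }
    x
  })
}

#' Generate a synthetic EEG recording
#'
#' @param cfg a [synthConfig()].
#' @return an [EEGRecording-class] whose annotations are exactly the
#'   configured events. The same configuration and seed give bit-identical
#'   output.
#' @examples
#' cfg <- synthConfig(durationS = 20, nChannels = 2, seed = 7,
#'   events = data.frame(onset_s = 5, duration_s = 5,
#'                       type = "spike_wave", gain = 5))
#' rec <- generateRecording(cfg)
#' annotations(rec)
#' @export
generateRecording <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  n <- round(cfg$durationS * cfg$fs)
  data <- matrix(0, cfg$nChannels, n)
  ev <- cfg$events
  templates <- lapply(seq_len(nrow(ev)), function(i)
    makeTemplate(ev$type[i], ev$duration_s[i], cfg$fs))
  for (ch in seq_len(cfg$nChannels)) {
    sd_ch <- channelSeed(cfg$seed, ch)
    x <- cfg$noiseSd * shapedBackground(n, cfg$fs, cfg$beta, cfg$rhythms, sd_ch)
    if (nrow(ev) > 0L) {
      chGains <- withLocalSeed(channelSeed(cfg$seed + 1L, ch),
                               stats::runif(nrow(ev), 0.5, 1.5))
      for (i in seq_len(nrow(ev))) {
        i0 <- floor(ev$onset_s[i] * cfg$fs) + 1L
        idx <- i0:min(n, i0 + length(templates[[i]]) - 1L)
        x[idx] <- x[idx] + cfg$noiseSd * ev$gain[i] * chGains[i] *
          templates[[i]][seq_along(idx)]
      }
    }
    data[ch, ] <- x
  }
  ann <- if (nrow(ev) > 0L)
    data.frame(onset_s = ev$onset_s, offset_s = ev$onset_s + ev$duration_s)
  else NULL
  EEGRecording(data, fs = cfg$fs, annotations = ann)
}

#' Write a recording as an EDF + annotation CSV fixture pair
#'
#' @param rec an [EEGRecording-class].
#' @param basePath path without extension; writes `<basePath>.edf` and
#'   `<basePath>.csv`.
#' @return named character vector of the two paths, invisibly.
#' @export
writeRecordingFixture <- function(rec, basePath) {
  edf <- paste0(basePath, ".edf")
  csv <- paste0(basePath, ".csv")
  writeEDF(rec, edf)
  writeAnnotations(annotations(rec), csv)
  invisible(c(edf = edf, annotations = csv))
}
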