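#' Synthesize a click-train audio proxy with controllable beat uncertainty
#'
#' Generates a mono click train at a nominal tempo. Gaussian timing jitter
#' on each beat and Poisson distractor onsets degrade the regularity of
#' the pulse, which raises the pulse entropy computed by [pulse_entropy()];
#' jitter 0 and distractor rate 0 give a perfectly isochronous train whose
#' inter-onset intervals equal the beat period exactly (in samples).
#'
#' @param tempo_bpm nominal tempo, 40-240 beats per minute.
#' @param timing_jitter_sd standard deviation of the Gaussian timing
#'   perturbation of each beat, in seconds.
#' @param noise_onset_rate rate of Poisson distractor clicks, events/second.
#' @param duration clip length in seconds (>= 5).
#' @param sample_rate sampling rate in Hz (default 22050, adequate for
#'   onset analysis at half the usual compute).
#' @param seed integer seed; same seed, identical waveform.
#' @return An object of class `groove_audio`: list with `samples`
#'   (numeric in `[-1, 1]`), `sample_rate`, and `onsets_s` (the true onset
#'   times, kept for testing).
#' @export
simulate_click_audio <- function(tempo_bpm = 120, timing_jitter_sd = 0,
                                 noise_onset_rate = 0, duration = 6,
                                 sample_rate = 22050L, seed = 1L) {
  if (tempo_bpm < 40 || tempo_bpm > 240) {
    abort("`tempo_bpm` must lie in [40, 240].")
  }
  if (duration < 5) abort("`duration` must be at least 5 seconds.")
  period <- 60 / tempo_bpm
  if (timing_jitter_sd >= period / 2) {
    warn("timing jitter sd is at least half the beat period; beat identity is lost.")
  }
  with_seed(seed, {
    # beats live on an exact sample grid so a jitter-free train has
    # perfectly constant inter-onset intervals (in samples)
    period_samp <- round(period * sample_rate)
    start_samp <- round(0.05 * sample_rate)
    n_beats <- floor(((duration - 0.1) * sample_rate - start_samp) /
                       period_samp) + 1L
    beats <- (start_samp + (seq_len(n_beats) - 1L) * period_samp) /
      sample_rate
    if (timing_jitter_sd > 0) {
      beats <- beats + rnorm(length(beats), 0, timing_jitter_sd)
    }
    distract <- numeric(0)
    if (noise_onset_rate > 0) {
      n_d <- rpois(1, noise_onset_rate * duration)
      distract <- runif(n_d, 0, duration - 0.05)
    }
    n <- round(duration * sample_rate)
    x <- numeric(n)
    click <- click_shape(sample_rate)
    place <- function(times, amp) {
      for (tt in times) {
        i0 <- round(tt * sample_rate) + 1L
        if (i0 < 1L || i0 > n) next
        i1 <- min(n, i0 + length(click) - 1L)
        x[i0:i1] <<- x[i0:i1] + amp * click[seq_len(i1 - i0 + 1L)]
      }
    }
    place(beats, 1)
    place(distract, 0.8)
    peak <- max(abs(x))
    if (peak > 0) x <- 0.9 * x / peak
    structure(
      list(samples = x, sample_rate = sample_rate,
           onsets_s = sort(c(beats, distract))),
      class = "groove_audio"
    )
  })
}

# 4 ms decaying 3 kHz burst
click_shape <- function(sample_rate) {
  t <- seq(0, 0.004, by = 1 / sample_rate)
  sin(2 * pi * 3000 * t) * exp(-t / 0.0012)
}

#' @export
print.groove_audio <- function(x, ...) {
  cat("<groove_audio> ", length(x$samples) / x$sample_rate, " s at ",
      x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Minimal mono 16-bit PCM WAV writer / reader
#'
#' Writes a waveform in `[-1, 1]` as a canonical 44-byte-header RIFF/WAVE
#' file with one 16-bit PCM channel, and reads such files back.
#'
#' @param audio a `groove_audio` or a numeric vector in `[-1, 1]`.
#' @param path file path.
#' @param sample_rate sampling rate, required when `audio` is a bare vector.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   `groove_audio`.
#' @export
write_wav <- function(audio, path, sample_rate = NULL) {
  if (inherits(audio, "groove_audio")) {
    samples <- audio$samples
    sample_rate <- audio$sample_rate
  } else {
    samples <- audio
    if (is.null(sample_rate)) abort("`sample_rate` required for a bare vector.")
  }
  pcm <- as.integer(round(clamp(samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") abort("not a RIFF/WAVE file.")
  sample_rate <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found.")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      if (is.null(bits) || bits != 16L || channels != 1L) {
        abort("only mono 16-bit PCM WAV is supported.")
      }
      pcm <- readBin(con, "integer", sz %/% 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(structure(
        list(samples = pcm / 32767, sample_rate = sample_rate,
             onsets_s = NULL),
        class = "groove_audio"
      ))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
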