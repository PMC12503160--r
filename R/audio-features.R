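#' Onset-strength envelope (half-wave-rectified spectral flux)
#'
#' Short-time Fourier magnitude spectra are computed with a Hann window,
#' and the onset strength at each frame is the sum over frequency of the
#' positive part of the magnitude increase since the previous frame. The
#' result is a non-negative novelty curve whose peaks mark note onsets.
#'
#' @param audio a `groove_audio` (see [simulate_click_audio()] /
#'   [read_wav()]).
#' @param frame_length STFT window length in samples (default 1024).
#' @param hop hop size in samples (default 256; the envelope frame rate is
#'   `sample_rate / hop`).
#' @return An object of class `groove_envelope`: list with `values`
#'   (non-negative numeric), `frame_rate`, `source_sample_rate`, `params`.
#' @export
onset_envelope <- function(audio, frame_length = 1024L, hop = 256L) {
  stopifnot(inherits(audio, "groove_audio"))
  x <- audio$samples
  sr <- audio$sample_rate
  if (length(x) / sr < 5) abort("audio must be at least 5 seconds long.")
  if (hop >= frame_length) abort("frame length must exceed the hop.")
  if (all(x == 0)) warn("silent audio; onset envelope is all zero.")
  n_frames <- max(1L, floor((length(x) - frame_length) / hop) + 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(frame_length) / (frame_length + 1))
  nb <- frame_length %/% 2L + 1L
  mag <- matrix(0, nb, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + frame_length)] * win
    mag[, f] <- Mod(fft(seg)[seq_len(nb)])
  }
  flux <- c(0, colSums(pmax(mag[, -1L, drop = FALSE] -
                              mag[, -n_frames, drop = FALSE], 0)))
  structure(
    list(
      values = flux, frame_rate = sr / hop, source_sample_rate = sr,
      params = list(frame_length = frame_length, hop = hop)
    ),
    class = "groove_envelope"
  )
}

#' Beat-lag autocorrelation of an onset envelope
#'
#' Autocorrelation of the mean-centred envelope, normalized so that lag 0
#' equals 1, restricted to a beat-plausible lag window (default 0.25-2 s,
#' i.e. 30-240 bpm; lag 0 itself is excluded). Negative correlations are
#' floored at 0 so the curve can serve as the non-negative
#' pseudo-distribution that [entropy_of_acf()] expects. A constant
#' envelope has no periodicity evidence and yields an all-zero curve.
#'
#' @param env a `groove_envelope`.
#' @param lag_min,lag_max lag window in seconds.
#' @return A tibble with columns `lag_s` and `acf` plus attributes
#'   `lag_window` and `frame_rate`.
#' @export
beat_autocorrelation <- function(env, lag_min = 0.25, lag_max = 2) {
  stopifnot(inherits(env, "groove_envelope"))
  n <- length(env$values)
  dur <- n / env$frame_rate
  if (lag_min <= 0 || lag_max <= lag_min) {
    abort("need 0 < lag_min < lag_max.")
  }
  if (lag_max > dur / 2) {
    abort("lag window exceeds half the envelope duration.")
  }
  lmin <- max(1L, round(lag_min * env$frame_rate))
  lmax <- round(lag_max * env$frame_rate)
  v <- env$values - mean(env$values)
  if (all(v == 0)) {
    r <- rep(0, lmax - lmin + 1L)
  } else {
    r <- as.numeric(acf(v, lag.max = lmax, plot = FALSE,
                        demean = FALSE)$acf)[(lmin + 1L):(lmax + 1L)]
    r <- pmax(r, 0)
  }
  out <- tibble(lag_s = (lmin:lmax) / env$frame_rate, acf = r)
  attr(out, "lag_window") <- c(lag_min, lag_max)
  attr(out, "frame_rate") <- env$frame_rate
  out
}

#' Normalized Shannon entropy of an autocorrelation curve
#'
#' Treats the non-negative autocorrelation values over the lag window as a
#' pseudo-distribution (normalized to sum 1 over the N lags) and returns
#' its Shannon entropy divided by log N, so the result lies in `[0, 1]`:
#' 0 for a single sharp periodicity (one-hot curve), 1 for a flat curve
#' with no beat evidence. An all-zero curve is defined as entropy 1 with a
#' flag (no periodicity evidence at all). This is the inverse-pulse-clarity
#' index: low values mean a clear, certain beat.
#'
#' @param acf_values numeric vector of non-negative autocorrelation values
#'   (flooring negatives is the caller's job; see
#'   [beat_autocorrelation()]), or the tibble that function returns.
#' @param lag_window optional `c(min, max)` seconds, recorded on the result.
#' @param params optional list of upstream parameters, recorded verbatim.
#' @return An object of class `groove_pulse_entropy`: list with `entropy`
#'   in `[0, 1]`, `acf`, `lag_window`, `no_evidence` flag, `params`.
#' @examples
#' entropy_of_acf(c(0, 1, 0, 0))$entropy            # 0
#' entropy_of_acf(rep(0.2, 5))$entropy              # 1
#' entropy_of_acf(c(0.5, 0.25, 0.25))$entropy       # ~0.9464
#' @export
entropy_of_acf <- function(acf_values, lag_window = NULL, params = list()) {
  if (is.data.frame(acf_values)) {
    lag_window <- lag_window %||% attr(acf_values, "lag_window")
    acf_values <- acf_values$acf
  }
  if (length(acf_values) < 2) abort("need at least 2 lags.")
  if (any(!is.finite(acf_values)) || any(acf_values < 0)) {
    abort("autocorrelation values must be finite and non-negative.")
  }
  no_evidence <- all(acf_values == 0)
  if (no_evidence) {
    h <- 1
  } else {
    p <- acf_values / sum(acf_values)
    p <- p[p > 0]
    h <- -sum(p * log(p)) / log(length(acf_values))
  }
  structure(
    list(entropy = h, acf = acf_values, lag_window = lag_window,
         no_evidence = no_evidence, params = params),
    class = "groove_pulse_entropy"
  )
}

#' @export
print.groove_pulse_entropy <- function(x, ...) {
  cat("<groove_pulse_entropy> ", format(x$entropy, digits = 4),
      if (x$no_evidence) " (no periodicity evidence)", "\n", sep = "")
  invisible(x)
}

#' Pulse entropy of an audio excerpt
#'
#' Chains [onset_envelope()], [beat_autocorrelation()] and
#' [entropy_of_acf()] under a single parameter record: an entropy-based
#' inverse index of pulse clarity. Music with a clear, certain beat has
#' low pulse entropy; an unclear or uncertain beat raises it.
#'
#' @inheritParams onset_envelope
#' @inheritParams beat_autocorrelation
#' @return A `groove_pulse_entropy`.
#' @export
pulse_entropy <- function(audio, frame_length = 1024L, hop = 256L,
                          lag_min = 0.25, lag_max = 2) {
  env <- onset_envelope(audio, frame_length = frame_length, hop = hop)
  ac <- beat_autocorrelation(env, lag_min = lag_min, lag_max = lag_max)
  entropy_of_acf(
    ac,
    params = list(
      frame_length = frame_length, hop = hop,
      lag_min = lag_min, lag_max = lag_max,
      frame_rate = env$frame_rate,
      sample_rate = audio$sample_rate
    )
  )
}
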