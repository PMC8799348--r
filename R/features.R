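#' Spectral configuration for frequency-domain features
#'
#' @param fs Sampling rate in Hz.
#' @param zc_threshold Amplitude threshold (epsilon) for the zero-crossing
#'   count; band-pass filtered sEMG has negligible DC offset so the default
#'   is 0.
#' @param fr_low_band Low frequency band `[LLC, ULC]` in Hz for the frequency
#'   ratio; default `c(20, 250)` (lower half of the 20-500 Hz sEMG
#'   pass-band).
#' @param fr_high_band High frequency band `[LHC, UHC]` in Hz; default
#'   `c(250, 500)`.
#' @return A list of class `"spectral_config"`.
#' @export
spectral_config <- function(fs = 1000, zc_threshold = 0,
                            fr_low_band = c(20, 250),
                            fr_high_band = c(250, 500)) {
  stopifnot(fs > 0, zc_threshold >= 0,
            length(fr_low_band) == 2L, length(fr_high_band) == 2L,
            fr_low_band[1] >= 0, fr_low_band[1] < fr_low_band[2],
            fr_high_band[1] < fr_high_band[2], fr_high_band[2] <= fs / 2)
  structure(list(fs = fs, zc_threshold = zc_threshold,
                 fr_low_band = fr_low_band, fr_high_band = fr_high_band),
            class = "spectral_config")
}

#' One-sided power spectrum of a window channel
#'
#' Power is the squared magnitude of the discrete Fourier transform over the
#' one-sided frequency grid `[0, fs/2]`.  The two-sided power summed and
#' divided by the window length equals the signal energy (Parseval).
#'
#' @param channel_signal Numeric vector (length >= 2).
#' @param config A [spectral_config()].
#' @return A list with `freqs` (Hz) and `power` (squared DFT magnitude).
#' @export
power_spectrum <- function(channel_signal, config = spectral_config()) {
  w <- length(channel_signal)
  if (w < 2L) stop("signal must have at least 2 samples")
  sp <- stats::fft(channel_signal)
  half <- floor(w / 2)
  idx <- seq_len(half + 1L)
  list(freqs = (idx - 1L) * config$fs / w,
       power = Mod(sp[idx])^2)
}

.feature_names <- c("RMS", "MAV", "WL", "ZC", "DASDV", "LOG", "SSI",
                    "TM3", "TM4", "TM5", "FR", "IEMG", "MFMN", "MFMD")

#' Names of the fourteen window features, in canonical order
#'
#' @return Character vector of length 14.
#' @export
feature_names <- function() .feature_names

#' Evaluate one time- or frequency-domain sEMG feature
#'
#' Implements the fourteen classical features used by the classifier: root
#' mean square (RMS), mean absolute value (MAV), waveform length (WL),
#' zero crossings (ZC), difference absolute standard deviation (DASDV),
#' LOG detector, simple square integral (SSI), absolute third to fifth
#' temporal moments (TM3, TM4, TM5), frequency ratio (FR), integrated EMG
#' (IEMG), mean frequency (MFMN) and median frequency (MFMD).
#'
#' ZC counts indices where consecutive samples have strictly opposite sign
#' and the step exceeds the threshold epsilon.  LOG is evaluated as
#' `exp(mean(S))`; set `log_conventional = TRUE` for the textbook
#' `exp(mean(log(|S|)))` variant.  Band and moment integrals are discrete
#' sums over the one-sided power spectrum; FR uses bins whose centre lies in
#' `[low, high)`.  A spectrum with zero total power defines MFMN = MFMD = 0,
#' and FR with zero high-band power returns `NaN` with a warning.
#'
#' @param name One of `feature_names()`.
#' @param channel_signal Numeric vector of window samples (length >= 2).
#' @param config A [spectral_config()].
#' @param log_conventional Use the conventional LOG detector variant.
#' @return A single numeric value.
#' @export
evaluate_feature <- function(name, channel_signal,
                             config = spectral_config(),
                             log_conventional = FALSE) {
  s <- as.numeric(channel_signal)
  w <- length(s)
  if (w < 2L) stop("signal must have at least 2 samples")
  name <- match.arg(name, .feature_names)
  switch(name,
    RMS = sqrt(mean(s^2)),
    MAV = mean(abs(s)),
    WL = sum(abs(diff(s))),
    ZC = {
      prod_neg <- s[-w] * s[-1L] < 0
      big_step <- abs(s[-w] - s[-1L]) >= config$zc_threshold
      sum(prod_neg & big_step)
    },
    DASDV = sqrt(sum(diff(s)^2) / (w - 1L)),
    LOG = if (log_conventional) exp(mean(log(abs(s)))) else exp(mean(s)),
    SSI = sum(s^2),
    TM3 = abs(mean(s^3)),
    TM4 = abs(mean(s^4)),
    TM5 = abs(mean(s^5)),
    FR = {
      ps <- power_spectrum(s, config)
      lo <- .band_power(ps, config$fr_low_band)
      hi <- .band_power(ps, config$fr_high_band)
      if (hi == 0) {
        warning("zero high-band power: frequency ratio undefined")
        NaN
      } else lo / hi
    },
    IEMG = sum(abs(s)),
    MFMN = {
      ps <- power_spectrum(s, config)
      tot <- sum(ps$power)
      if (tot == 0) 0 else sum(ps$freqs * ps$power) / tot
    },
    MFMD = {
      ps <- power_spectrum(s, config)
      tot <- sum(ps$power)
      if (tot == 0) 0
      else ps$freqs[which(cumsum(ps$power) >= tot / 2)[1L]]
    }
  )
}

.band_power <- function(ps, band) {
  sum(ps$power[ps$freqs >= band[1] & ps$freqs < band[2]])
}

#' Build the per-channel feature vector
#'
#' Returns `c(1, x1, ..., x14)` — a fixed leading 1 (so the outer-product
#' feature map retains the original features in its first row and column)
#' followed by the fourteen features of [evaluate_feature()] in canonical
#' order.
#'
#' @inheritParams evaluate_feature
#' @return Numeric vector of length 15 named `c("one", feature_names())`.
#' @export
build_feature_vector <- function(channel_signal, config = spectral_config(),
                                 log_conventional = FALSE) {
  vals <- vapply(.feature_names, evaluate_feature,
                 numeric(1L), channel_signal = channel_signal,
                 config = config, log_conventional = log_conventional)
  c(one = 1, vals)
}

#' Export a per-channel feature table as delimited text
#'
#' One row per (window, channel), columns `window`, `channel`, `label` and
#' the fourteen features.
#'
#' @param windows A list of windows as produced by [slide_windows()] or the
#'   synthetic generator.
#' @param path Output path; when `NULL` the data frame is returned invisibly
#'   without writing.
#' @param config A [spectral_config()].
#' @param sep Field separator.
#' @return The feature data frame, invisibly.
#' @export
export_feature_table <- function(windows, path = NULL,
                                 config = spectral_config(), sep = "\t") {
  rows <- lapply(seq_along(windows), function(k) {
    win <- windows[[k]]
    t(vapply(seq_len(nrow(win$data)), function(ch) {
      build_feature_vector(win$data[ch, ], config)[-1L]
    }, numeric(length(.feature_names))))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- .feature_names
  meta <- data.frame(
    window = rep(seq_along(windows), each = nrow(windows[[1L]]$data)),
    channel = rep(seq_len(nrow(windows[[1L]]$data)), length(windows)),
    label = rep(vapply(windows, function(w)
      if (is.null(w$label)) NA_character_ else as.character(w$label),
      character(1L)), each = nrow(windows[[1L]]$data)))
  out <- cbind(meta, as.data.frame(tab))
  if (!is.null(path))
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  invisible(out)
}
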