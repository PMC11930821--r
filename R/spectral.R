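#' Welch power spectral density estimate
#'
#' Hann-windowed, linearly detrended, 50%-overlapping segment-averaged
#' periodogram (one-sided). This is the conventional robust estimator used
#' here in place of any particular toolbox implementation.
#'
#' @param x Numeric vector sampled at `fs` Hz.
#' @param fs Sampling rate, Hz (default 1).
#' @param seg_len Segment length in samples (default 500, resolving 0.002 Hz
#'   at 1 Hz sampling).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 1, seg_len = 500, overlap = 0.5) {
  n <- length(x)
  if (n < seg_len) {
    stop("trace too short: need at least ", seg_len, " samples (",
         seg_len / fs, " s at ", fs, " Hz)", call. = FALSE)
  }
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  k <- seq_len(seg_len) - 1L
  win <- 0.5 * (1 - cos(2 * pi * k / (seg_len - 1)))  # Hann
  u <- sum(win^2)
  tt <- seq_len(seg_len)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- stats::residuals(stats::lm.fit(cbind(1, tt), seg))  # linear detrend
    X <- stats::fft(seg * win)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when seg_len even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (seg_len %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Normalized low-frequency spectrum of a CBFi trace
#'
#' Welch periodogram of the (raw, unsmoothed) flow-index series, restricted
#' to the analysis band and normalized to unit total in-band power.
#'
#' @param trace A `cbfi_trace` sampled at 1 Hz.
#' @param band Frequency band, Hz (default `c(0.002, 0.4)`).
#' @param seg_s Welch segment length, s (default 500).
#' @param use_smooth Use the smoothed series instead of the raw one
#'   (default `FALSE`; the 8-s mean attenuates the upper band).
#' @param subject_id Label stored on the result.
#' @return Data frame of class `dcs_spectrum` with columns `freq`,
#'   `power_norm`; attributes `subject_id` and `power_total` (raw in-band
#'   power before normalization).
#' @export
cbfi_spectrum <- function(trace, band = c(0.002, 0.4), seg_s = 500,
                          use_smooth = FALSE, subject_id = "subject") {
  stopifnot(inherits(trace, "cbfi_trace"), length(band) == 2, band[1] < band[2])
  x <- if (use_smooth) trace$cbfi_smooth else trace$cbfi
  x <- x[is.finite(x)]
  min_s <- max(seg_s, ceiling(1 / band[1]))
  if (length(x) < min_s) {
    stop("trace too short for the requested band: need at least ", min_s,
         " s at 1 Hz to resolve ", band[1], " Hz", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate input: constant trace has no spectral content", call. = FALSE)
  }
  w <- welch_psd(x, fs = 1, seg_len = seg_s)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  total <- sum(w$psd[sel])
  if (total <= 0) stop("degenerate input: zero in-band power", call. = FALSE)
  out <- data.frame(freq = w$freq[sel], power_norm = w$psd[sel] / total)
  attr(out, "subject_id") <- subject_id
  attr(out, "power_total") <- total
  attr(out, "df_hz") <- 1 / seg_s
  class(out) <- c("dcs_spectrum", "data.frame")
  out
}

#' Average spectra across subjects
#'
#' Pointwise mean of normalized spectra on an identical frequency grid,
#' renormalized to unit sum.
#'
#' @param spectra Non-empty list of `dcs_spectrum` on the same grid.
#' @return A `dcs_spectrum` with `subject_id = "average"`.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) == 0) stop("empty spectrum list", call. = FALSE)
  lapply(spectra, function(s) stopifnot(inherits(s, "dcs_spectrum")))
  f0 <- spectra[[1]]$freq
  for (s in spectra[-1]) {
    if (length(s$freq) != length(f0) || any(s$freq != f0)) {
      stop("spectra are not on the same frequency grid", call. = FALSE)
    }
  }
  p <- rowMeans(vapply(spectra, `[[`, numeric(length(f0)), "power_norm"))
  out <- data.frame(freq = f0, power_norm = p / sum(p))
  attr(out, "subject_id") <- "average"
  class(out) <- c("dcs_spectrum", "data.frame")
  out
}

#' Write spectra as delimited text
#'
#' @param spectra A `dcs_spectrum` or list of them.
#' @param path Output CSV path (columns `freq_hz`, `power_norm`, `subject_id`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "dcs_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(freq_hz = s$freq, power_norm = s$power_norm,
               subject_id = attr(s, "subject_id"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
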