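#' Band-pass filter specification for the period-3 component
#'
#' Coding DNA shows excess spectral power at the codon frequency 2*pi/3
#' radians/sample (period 3 nt); a narrow band-pass centred there suppresses
#' the flat and low-frequency background before the wavelet stage. The
#' default is an order-4 Butterworth band-pass of bandwidth 0.04*pi, applied
#' forward-backward (zero phase) so called peaks are not displaced.
#'
#' @param center_frequency Centre, radians/sample, in (0, pi).
#' @param bandwidth Full passband width, radians/sample.
#' @param order Filter order (even for the IIR design; 2 cascaded biquads by
#'   default). For `design = "fir_window"` this is the FIR tap count minus 1
#'   and should be large (hundreds) for a narrow band.
#' @param design `"resonator_iir"` (Butterworth, default) or `"fir_window"`
#'   (Hamming-window FIR).
#' @return A `bandpass_spec` list.
#' @export
bandpass_spec <- function(center_frequency = 2 * pi / 3,
                          bandwidth = 0.04 * pi,
                          order = 4L,
                          design = c("resonator_iir", "fir_window")) {
  design <- match.arg(design)
  if (!(center_frequency > 0 && center_frequency < pi)) {
    wx_abort("center_frequency must lie in (0, pi)", "wx_config_error")
  }
  if (bandwidth <= 0) wx_abort("bandwidth must be > 0", "wx_config_error")
  order <- as.integer(order)
  if (order < 2L) wx_abort("order must be >= 2", "wx_config_error")
  if (design == "resonator_iir" && order %% 2L != 0L) {
    wx_abort("IIR band-pass order must be even", "wx_config_error")
  }
  structure(list(center_frequency = center_frequency, bandwidth = bandwidth,
                 order = order, design = design),
            class = "bandpass_spec")
}

bandpass_edges <- function(spec) {
  lo <- (spec$center_frequency - spec$bandwidth / 2) / pi
  hi <- (spec$center_frequency + spec$bandwidth / 2) / pi
  if (lo <= 0 || hi >= 1) {
    wx_abort("band edges fall outside (0, pi)", "wx_config_error")
  }
  c(lo, hi)
}

#' Enhance the period-3 component of an EIIP signal
#'
#' Zero-phase (forward-backward) band-pass filtering around 2*pi/3. Output
#' length equals input length and peak positions are preserved.
#'
#' @param signal A `wx_signal` tibble at stage `"eiip"`.
#' @param spec A [bandpass_spec()].
#' @return A `wx_signal` tibble at stage `"bandpassed"`.
#' @export
bandpass_period3 <- function(signal, spec = bandpass_spec()) {
  assert_stage(signal, "eiip", "bandpass_period3")
  edges <- bandpass_edges(spec)
  if (spec$design == "resonator_iir") {
    min_len <- 10L * spec$order
    bf <- signal::butter(spec$order %/% 2L, edges, type = "pass")
    apply_one <- function(v) signal::filtfilt(bf, v - mean(v))
  } else {
    # Linear-phase FIR applied centred (sides = 2) is already zero phase.
    # Window smearing of a narrow passband depresses the centre gain at
    # moderate orders, so renormalize to unit gain at the centre frequency.
    taps <- signal::fir1(spec$order, edges, type = "pass")
    gain <- Mod(sum(taps * exp(-1i * spec$center_frequency *
                                 seq_along(taps))))
    if (gain < 1e-6) {
      wx_abort("FIR order too low for the requested bandwidth",
               "wx_config_error")
    }
    taps <- taps / gain
    half <- spec$order %/% 2L
    min_len <- half + 1L
    apply_one <- function(v) {
      v0 <- v - mean(v)
      n <- length(v0)
      # reflect-pad so the centred convolution is defined at the edges
      ext <- c(rev(v0[seq_len(half)]), v0, rev(v0[seq(n - half + 1L, n)]))
      y <- stats::filter(ext, taps, sides = 2)
      as.numeric(y[seq(half + 1L, length.out = n)])
    }
  }
  bad <- signal |>
    dplyr::count(.data$sequence_id) |>
    dplyr::filter(.data$n < min_len)
  if (nrow(bad)) {
    wx_abort(sprintf(
      "sequence '%s' too short for band-pass filtering (%d < %d nt)",
      bad$sequence_id[1], bad$n[1], min_len))
  }
  signal_map(signal, apply_one, "bandpassed")
}
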