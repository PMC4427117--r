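#' Per-position wavelet energy profile
#'
#' Squares the coefficients of the selected sub-bands and maps each
#' coefficient's energy back onto the sequence: a level-`l` coefficient
#' covers `2^l` positions, over which its squared magnitude is spread
#' uniformly. Selected bands are summed and optionally smoothed with a
#' centred moving average. After band-passing at 2*pi/3 the period-3
#' component lives in the level-1 detail band (frequencies above pi/2), so
#' the default source is the detail levels.
#'
#' @param decomp A `wavelet_decomposition` from [dwt_decompose()].
#' @param source Which bands contribute: `"detail_levels"`, `"approx"` or
#'   `"all"`.
#' @param smooth_window Centred moving-average width (odd positive integer;
#'   1 = no smoothing).
#' @return A `wx_signal` tibble at stage `"energy"`, length equal to the
#'   original sequence, all values >= 0.
#' @export
energy_profile <- function(decomp,
                           source = c("detail_levels", "approx", "all"),
                           smooth_window = 1L) {
  source <- match.arg(source)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    wx_abort("smooth_window must be a positive odd integer", "wx_config_error")
  }
  n <- decomp$original_length
  bands <- list()
  if (source %in% c("detail_levels", "all")) {
    for (l in seq_len(decomp$levels)) {
      bands[[length(bands) + 1L]] <- list(coef = decomp$details[[l]], level = l)
    }
  }
  if (source %in% c("approx", "all")) {
    bands[[length(bands) + 1L]] <- list(coef = decomp$approx,
                                        level = decomp$levels)
  }
  if (!length(bands)) wx_abort("empty band selection", "wx_config_error")
  prof <- numeric(n)
  for (b in bands) {
    stride <- 2L^b$level
    core_len <- ceiling(n / stride)
    extra <- length(b$coef) - core_len
    left <- max(0L, extra %/% 2L)
    core <- b$coef[seq(left + 1L, length.out = core_len)]
    prof <- prof + rep(core^2 / stride, each = stride)[seq_len(n)]
  }
  prof <- roll_mean_partial(prof, smooth_window)
  id <- if (is.na(decomp$sequence_id)) "seq1" else decomp$sequence_id
  numeric_signal(id, prof, "energy")
}

# Centred moving average with shrinking windows at the edges (keeps length
# and non-negativity).
roll_mean_partial <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Denoising specification for the energy profile
#'
#' Three pluggable smoothers for the raw energy profile: a centred moving
#' average (default, window 51 nt — below the shortest exon the caller is
#' asked to keep, wide enough to kill the within-codon energy ripple), a
#' normalized-LMS adaptive line enhancer (predicts the correlated, slowly
#' varying component of the profile from its own recent past and returns the
#' prediction), and wavelet shrinkage (universal soft threshold on the detail
#' coefficients of the profile itself).
#'
#' @param method `"moving_average"`, `"lms_canceller"` or `"wavelet_shrink"`.
#' @param window Moving-average width, odd positive integer.
#' @param mu LMS adaptation step, in (0, 1).
#' @param filter_order LMS predictor length (taps).
#' @param threshold_rule Shrinkage rule; `"universal"` =
#'   `sigma * sqrt(2 log n)` with `sigma` estimated from the finest detail
#'   band by the median absolute deviation.
#' @return A `denoise_spec` list.
#' @export
denoise_spec <- function(method = c("moving_average", "lms_canceller",
                                    "wavelet_shrink"),
                         window = 51L, mu = 0.05, filter_order = 16L,
                         threshold_rule = "universal") {
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    wx_abort("window must be a positive odd integer", "wx_config_error")
  }
  if (!(mu > 0 && mu < 1)) wx_abort("mu must be in (0, 1)", "wx_config_error")
  filter_order <- as.integer(filter_order)
  if (filter_order < 1L) wx_abort("filter_order must be >= 1", "wx_config_error")
  threshold_rule <- match.arg(threshold_rule, "universal")
  structure(list(method = method, window = window, mu = mu,
                 filter_order = filter_order,
                 threshold_rule = threshold_rule),
            class = "denoise_spec")
}

#' Denoise an energy profile
#'
#' @param profile A `wx_signal` tibble at stage `"energy"`.
#' @param spec A [denoise_spec()].
#' @return A `wx_signal` tibble at stage `"denoised"`, same length,
#'   non-negative.
#' @export
adaptive_denoise <- function(profile, spec = denoise_spec()) {
  assert_stage(profile, "energy", "adaptive_denoise")
  f <- switch(spec$method,
    moving_average = function(v) roll_mean_partial(v, spec$window),
    lms_canceller = function(v) lms_enhance(v, spec$mu, spec$filter_order),
    wavelet_shrink = function(v) wavelet_shrink(v)
  )
  signal_map(profile, function(v) pmax(f(v), 0), "denoised")
}

# Normalized-LMS adaptive line enhancer: predict x[i] from the p previous
# samples; the prediction tracks the correlated (smooth) component.
lms_enhance <- function(x, mu, p) {
  n <- length(x)
  if (n <= p + 1L) return(x)
  w <- numeric(p)
  y <- x
  for (i in seq(p + 1L, n)) {
    u <- x[(i - 1L):(i - p)]
    yh <- sum(w * u)
    e <- x[i] - yh
    w <- w + mu * e * u / (sum(u * u) + 1e-12)
    y[i] <- yh
  }
  y
}

# Universal-threshold soft shrinkage using the package's own DWT.
wavelet_shrink <- function(x, wavelet = "coif5", levels = 2L) {
  fb <- wavelet_filters(wavelet)
  if (length(x) < fb$length * 2L^levels) return(x)
  d <- dwt_decompose(x, wavelet, levels, boundary = "symmetric")
  sigma <- stats::mad(d$details[[1]])
  thr <- sigma * sqrt(2 * log(length(x)))
  d$details <- purrr::map(d$details, function(cd) {
    sign(cd) * pmax(abs(cd) - thr, 0)
  })
  dwt_reconstruct(d)
}

#' Normalize a profile to [0, 1] by its maximum
#'
#' Per-sequence scaling so that call thresholds are comparable across genes.
#'
#' @param profile A `wx_signal` tibble at stage `"energy"` or `"denoised"`.
#' @return A `wx_signal` tibble at stage `"normalized"`, values in [0, 1].
#' @export
normalize_profile <- function(profile) {
  assert_stage(profile, c("energy", "denoised"), "normalize_profile")
  signal_map(profile, function(v) {
    m <- max(v)
    if (!(m > 0)) wx_abort("degenerate profile: maximum is not > 0")
    v / m
  }, "normalized")
}
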