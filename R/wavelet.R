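# Orthogonal wavelet filter banks. Scaling (low-pass analysis) taps are the
# published constants for each family; the remaining three filters follow
# from the quadrature-mirror relations
#   rec_lo = reverse(dec_lo),  dec_hi[k] = (-1)^(k+1) dec_lo[L-1-k] (0-based),
#   rec_hi = reverse(dec_hi).
wx_dec_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(
    -1.05974017850690317016e-02, 3.28830116668851965556e-02,
    3.08413818355607639854e-02, -1.87034811719093085891e-01,
    -2.79837694168598542788e-02, 6.30880767929858921050e-01,
    7.14846570552915672181e-01, 2.30377813308896506328e-01
  ),
  coif5 = c(
    -9.60401011276789414862e-08, -1.62379951720483375900e-07,
    2.06122039857887834848e-06, 3.70072771133947961531e-06,
    -2.12702216725156142865e-05, -4.12198619242655009951e-05,
    1.40356328123732431454e-04, 3.01857941668244784440e-04,
    -6.37558926125881154229e-04, -1.66162730392987881625e-03,
    2.43157544253828862210e-03, 6.76152022062041693079e-03,
    -9.15950733867616252726e-03, -1.97583916009654650403e-02,
    3.26747994670573554954e-02, 4.12875304721178337797e-02,
    -1.05563151307337232954e-01, -6.20377515749819599677e-02,
    4.37982306659163378448e-01, 7.74293622860327435120e-01,
    4.21571266730754345975e-01, -5.20466702535547637298e-02,
    -9.19215880600860874017e-02, 2.81697442705323534973e-02,
    2.34083221189277830565e-02, -1.01315848469002763726e-02,
    -4.15931262757864017576e-03, 2.17829437784569472647e-03,
    3.58577741161757678184e-04, -2.12081862067494000086e-04
  )
)

#' Filter bank of an orthogonal wavelet
#'
#' @param name `"coif5"` (default pipeline wavelet), `"db4"` or `"haar"`.
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` (numeric taps)
#'   and `length` (support width).
#' @export
wavelet_filters <- function(name = "coif5") {
  dec_lo <- wx_dec_lo[[name]]
  if (is.null(dec_lo)) {
    wx_abort(sprintf("unknown wavelet '%s' (available: %s)", name,
                     paste(names(wx_dec_lo), collapse = ", ")),
             "wx_config_error")
  }
  L <- length(dec_lo)
  dec_hi <- (-1)^seq_len(L) * dec_lo[L:1]
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = L)
}

# Full (polynomial) convolution.
conv_full <- function(x, y) stats::convolve(x, rev(y), type = "open")

extend_signal <- function(x, pad, mode) {
  n <- length(x)
  switch(mode,
    symmetric = c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1L, n)])),
    zero = c(numeric(pad), x, numeric(pad)),
    periodic = c(x[seq(n - pad + 1L, n)], x, x[seq_len(pad)])
  )
}

# One analysis step, extension modes: extend by L-1, convolve, downsample.
dwt_step_ext <- function(x, filt, L, mode) {
  n <- length(x)
  full <- conv_full(extend_signal(x, L - 1L, mode), filt)
  m <- (n + L - 1L) %/% 2L
  full[seq(L + 1L, by = 2L, length.out = m)]
}

# One synthesis step (extension modes): upsample, convolve with synthesis
# filters, trim the L-2 transient each side, keep the first n samples.
idwt_step_ext <- function(ca, cd, fb, n) {
  L <- fb$length
  up <- function(cc) {
    u <- numeric(2L * length(cc) - 1L)
    u[seq(1L, by = 2L, length.out = length(cc))] <- cc
    u
  }
  y <- conv_full(up(ca), fb$rec_lo) + conv_full(up(cd), fb$rec_hi)
  y <- y[seq(L - 1L, length(y) - (L - 2L))]
  y[seq_len(n)]
}

# Periodized (circular) analysis: exactly orthogonal, n must be even,
# coefficient count n/2 per band. c[k] = sum_j f[j] x[(2k + L/2 - j) mod n].
dwt_step_per <- function(x, filt, L) {
  n <- length(x)
  m <- n %/% 2L
  pos <- 2L * seq_len(m) - 2L + L %/% 2L
  out <- numeric(m)
  for (j in seq_len(L)) {
    out <- out + filt[j] * x[(pos - (j - 1L)) %% n + 1L]
  }
  out
}

# Periodized synthesis = transpose of the (orthonormal) analysis operator.
idwt_step_per <- function(ca, cd, fb, n) {
  L <- fb$length
  pos <- 2L * seq_len(length(ca)) - 2L + L %/% 2L
  y <- numeric(n)
  for (j in seq_len(L)) {
    idx <- (pos - (j - 1L)) %% n + 1L
    y[idx] <- y[idx] + fb$dec_lo[j] * ca + fb$dec_hi[j] * cd
  }
  y
}

#' Multilevel discrete wavelet transform
#'
#' Mallat pyramid: at each level the running approximation is split by the
#' analysis filter pair into a coarser approximation and a detail band.
#' Boundary handling is either redundant extension (`"symmetric"`, the
#' pipeline default, plus `"zero"` and `"periodic"`) with per-band length
#' `floor((n + L - 1)/2)`, or `"periodization"` (circular, exactly
#' orthogonal, per-band length `n/2`, requires the length divisible by
#' `2^levels`). All modes reconstruct the input exactly (to floating-point
#' round-off); only periodization also conserves energy exactly.
#'
#' @param x A single-sequence `wx_signal` tibble or a numeric vector.
#' @param wavelet Wavelet name, see [wavelet_filters()].
#' @param levels Number of decomposition levels (>= 1).
#' @param boundary Boundary mode, see Details.
#' @return A `wavelet_decomposition` object: approximation coefficients of
#'   the coarsest level, detail coefficients per level, and the bookkeeping
#'   needed for exact reconstruction. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
#' @examples
#' d <- dwt_decompose(sin(2 * pi * (0:255) / 3), "coif5", levels = 2)
#' max(abs(dwt_reconstruct(d) - sin(2 * pi * (0:255) / 3)))
dwt_decompose <- function(x, wavelet = "coif5", levels = 2L,
                          boundary = c("symmetric", "periodization",
                                       "zero", "periodic")) {
  boundary <- match.arg(boundary)
  sequence_id <- NA_character_
  if (is.data.frame(x)) {
    sequence_id <- unique(x$sequence_id)
    x <- signal_values(x)
  }
  x <- as.numeric(x)
  levels <- as.integer(levels)
  if (levels < 1L) wx_abort("levels must be >= 1", "wx_config_error")
  fb <- wavelet_filters(wavelet)
  L <- fb$length
  n <- length(x)
  if (boundary == "periodization" && n %% 2L^levels != 0L) {
    wx_abort(sprintf(
      "periodization needs a length divisible by 2^levels (got %d)", n))
  }
  approx <- x
  details <- vector("list", levels)
  input_lengths <- integer(levels)
  for (lev in seq_len(levels)) {
    if (length(approx) < L) {
      wx_abort(sprintf(
        "decomposition level %d too deep: %d samples < support %d",
        lev, length(approx), L))
    }
    input_lengths[lev] <- length(approx)
    if (boundary == "periodization") {
      details[[lev]] <- dwt_step_per(approx, fb$dec_hi, L)
      approx <- dwt_step_per(approx, fb$dec_lo, L)
    } else {
      details[[lev]] <- dwt_step_ext(approx, fb$dec_hi, L, boundary)
      approx <- dwt_step_ext(approx, fb$dec_lo, L, boundary)
    }
  }
  structure(
    list(wavelet = wavelet, levels = levels, boundary = boundary,
         approx = approx, details = details,
         input_lengths = input_lengths, original_length = n,
         sequence_id = sequence_id),
    class = "wavelet_decomposition"
  )
}

#' Invert a multilevel discrete wavelet transform
#'
#' @param decomp A `wavelet_decomposition` from [dwt_decompose()].
#' @return Numeric vector of length `decomp$original_length`.
#' @export
dwt_reconstruct <- function(decomp) {
  fb <- wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (lev in rev(seq_len(decomp$levels))) {
    n <- decomp$input_lengths[lev]
    a <- if (decomp$boundary == "periodization") {
      idwt_step_per(a, decomp$details[[lev]], fb, n)
    } else {
      idwt_step_ext(a, decomp$details[[lev]], fb, n)
    }
  }
  a
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %s, %d level(s), %s boundary, n = %d\n",
    x$wavelet, x$levels, x$boundary, x$original_length))
  cat(sprintf("  approx: %d coefficients; details: %s\n",
              length(x$approx),
              paste(vapply(x$details, length, 1L), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wavelet_decomposition <- function(x, ...) {
  bands <- c(
    purrr::map(seq_len(x$levels), function(l) {
      tibble(band = "detail", level = l, index = seq_along(x$details[[l]]),
             coefficient = x$details[[l]])
    }),
    list(tibble(band = "approx", level = x$levels,
                index = seq_along(x$approx), coefficient = x$approx))
  )
  dplyr::bind_rows(bands)
}

#' @exportS3Method generics::glance
glance.wavelet_decomposition <- function(x, ...) {
  tibble(
    wavelet = x$wavelet, levels = x$levels, boundary = x$boundary,
    original_length = x$original_length,
    n_coefficients = length(x$approx) + sum(vapply(x$details, length, 1L)),
    coefficient_energy = sum(x$approx^2) +
      sum(vapply(x$details, function(d) sum(d^2), 1.0))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.wavelet_decomposition <- function(object, ...) {
  td <- tidy(object)
  td$panel <- ifelse(td$band == "approx", "approx",
                     paste0("detail L", td$level))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$index, y = .data$coefficient)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free", ncol = 1) +
    ggplot2::labs(x = "coefficient index", y = "coefficient")
}
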