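# Fixed biased codon-position composition (rows = codon position, columns =
# A, C, G, T). Any triple of distinct position distributions produces a
# period-3 component; this one is G-rich at position 1, A-rich at position 2
# and pyrimidine-rich at position 3, echoing the classic coding-strand
# skews.
wx_codon_profile <- matrix(
  c(0.10, 0.10, 0.70, 0.10,
    0.60, 0.10, 0.10, 0.20,
    0.10, 0.50, 0.10, 0.30),
  nrow = 3, byrow = TRUE,
  dimnames = list(NULL, c("A", "C", "G", "T"))
)

#' Generate a synthetic eukaryotic gene with planted exons
#'
#' Emulates the alternating exon/intron architecture of a eukaryotic gene:
#' introns (including a leading and a trailing one, so `n_exons + 1` noncoding
#' units) are drawn i.i.d. from a background composition set by
#' `background_gc`; exon positions are drawn from three codon-position
#' specific distributions obtained by mixing the background with a fixed
#' biased profile, `P_k = (1 - codon_bias) * background + codon_bias * B_k`.
#' `codon_bias = 0` gives exons indistinguishable from background;
#' `codon_bias = 1` gives the fully biased composition and a strong period-3
#' signature. The same seed always reproduces the same gene.
#'
#' @param n_exons Number of exons.
#' @param exon_length_range,intron_length_range Integer `(min, max)` segment
#'   lengths in nt, sampled uniformly.
#' @param codon_bias Strength of the codon-position bias, in [0, 1].
#' @param background_gc Background G+C fraction, in (0, 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `wx_gene` list: `$sequences` (tibble `id`, `seq`), `$exons`
#'   (`wx_intervals`, label `"exon"`), `$params`.
#' @export
#' @examples
#' g <- generate_gene(n_exons = 2, seed = 7)
#' g$exons
generate_gene <- function(n_exons = 5L,
                          exon_length_range = c(150L, 300L),
                          intron_length_range = c(200L, 400L),
                          codon_bias = 0.8,
                          background_gc = 0.5,
                          seed = 1L) {
  n_exons <- as.integer(n_exons)
  if (n_exons < 1L) wx_abort("n_exons must be >= 1", "wx_config_error")
  chk_range <- function(r, what) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      wx_abort(paste0(what, " must be an increasing positive (min, max) pair"),
               "wx_config_error")
    }
    r
  }
  exon_length_range <- chk_range(exon_length_range, "exon_length_range")
  intron_length_range <- chk_range(intron_length_range, "intron_length_range")
  if (codon_bias < 0 || codon_bias > 1) {
    wx_abort("codon_bias must be in [0, 1]", "wx_config_error")
  }
  if (background_gc <= 0 || background_gc >= 1) {
    wx_abort("background_gc must be in (0, 1)", "wx_config_error")
  }
  bases <- c("A", "C", "G", "T")
  bg <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
          G = background_gc / 2, T = (1 - background_gc) / 2)
  pos_probs <- lapply(1:3, function(k) {
    (1 - codon_bias) * bg + codon_bias * wx_codon_profile[k, ]
  })
  withr::with_seed(as.integer(seed), {
    draw_len <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
    pieces <- character(0)
    starts <- integer(0); ends <- integer(0)
    cursor <- 0L
    for (i in seq_len(n_exons)) {
      li <- draw_len(intron_length_range)
      pieces <- c(pieces, paste(
        sample(bases, li, replace = TRUE, prob = bg), collapse = ""))
      cursor <- cursor + li
      le <- draw_len(exon_length_range)
      codon_pos <- rep_len(1:3, le)
      exon_chars <- vapply(codon_pos, function(k) {
        sample(bases, 1L, prob = pos_probs[[k]])
      }, character(1))
      pieces <- c(pieces, paste(exon_chars, collapse = ""))
      starts <- c(starts, cursor)
      cursor <- cursor + le
      ends <- c(ends, cursor)
    }
    lt <- draw_len(intron_length_range)
    pieces <- c(pieces, paste(
      sample(bases, lt, replace = TRUE, prob = bg), collapse = ""))
  })
  id <- sprintf("synth_seed%d", as.integer(seed))
  structure(list(
    sequences = tibble(id = id, seq = paste(pieces, collapse = "")),
    exons = genomic_intervals(rep(id, n_exons), starts, ends, label = "exon"),
    params = list(n_exons = n_exons, exon_length_range = exon_length_range,
                  intron_length_range = intron_length_range,
                  codon_bias = codon_bias, background_gc = background_gc,
                  seed = as.integer(seed))
  ), class = "wx_gene")
}

#' @export
print.wx_gene <- function(x, ...) {
  cat(sprintf("<wx_gene> %s: %d nt, %d exon(s), codon_bias %.2f, seed %d\n",
              x$sequences$id[1], nchar(x$sequences$seq[1]),
              nrow(x$exons), x$params$codon_bias, x$params$seed))
  invisible(x)
}

#' Sliding-window Fourier period-3 strength (independent oracle)
#'
#' For each of the four binary base-indicator tracks, the squared magnitude
#' of the window's discrete Fourier component at 2*pi/3 is computed and the
#' four are summed and divided by the window length. This classic spectral
#' period-3 score is independent of the wavelet pipeline and serves as its
#' verification oracle: for an exact period-3 sequence the interior value
#' approaches `window / 3`; a constant (homopolymer) sequence scores 0 when
#' the window is a multiple of 3.
#'
#' @param seqs A tibble with columns `id` and `seq`, or a single string.
#' @param window Window length, a positive multiple of 3, at most the
#'   sequence length.
#' @return A `wx_signal` tibble at stage `"energy"`: the centred window score
#'   at each position (edges take the nearest full-window value).
#' @export
period3_strength <- function(seqs, window = 99L) {
  window <- as.integer(window)
  if (window < 3L || window %% 3L != 0L) {
    wx_abort("window must be a positive multiple of 3", "wx_config_error")
  }
  if (is.character(seqs)) seqs <- tibble(id = "seq1", seq = toupper(seqs))
  rows <- purrr::map(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    n <- nchar(s)
    if (window > n) {
      wx_abort(sprintf("window %d exceeds sequence length %d", window, n))
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    tw <- exp(-1i * 2 * pi / 3 * (seq_len(n) - 1L))
    score <- numeric(n - window + 1L)
    for (b in c("A", "C", "G", "T")) {
      v <- as.numeric(chars == b) * tw
      cs <- c(0 + 0i, cumsum(v))
      wsum <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
      score <- score + Mod(wsum)^2
    }
    score <- score / window
    centers <- seq_len(n - window + 1L) + (window - 1L) %/% 2L
    full <- numeric(n)
    full[centers] <- score
    full[seq_len(centers[1] - 1L)] <- score[1]
    if (centers[length(centers)] < n) {
      full[(centers[length(centers)] + 1L):n] <- score[length(score)]
    }
    numeric_signal(seqs$id[i], full, "energy")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wx_signal", class(tibble()))
  out
}
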