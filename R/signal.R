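#' Construct a per-position numeric signal
#'
#' Signals are the common currency of the pipeline: one real value per
#' nucleotide position, tagged with the sequence it came from and the
#' processing stage that produced it (`"eiip"`, `"bandpassed"`, `"energy"`,
#' `"denoised"`, `"normalized"`). A signal tibble may hold several sequences
#' stacked long-form; all pipeline verbs operate per `sequence_id`.
#'
#' @param sequence_id Character scalar, identifier of the source sequence.
#' @param values Numeric vector, one value per position (finite).
#' @param stage Processing stage label.
#' @return A tibble with columns `sequence_id`, `pos` (1-based position),
#'   `value` and `stage`, of class `wx_signal`.
#' @export
#' @examples
#' numeric_signal("x", c(0.1, 0.4, 0.2), "energy")
numeric_signal <- function(sequence_id, values,
                           stage = c("eiip", "bandpassed", "energy",
                                     "denoised", "normalized")) {
  stage <- match.arg(stage)
  values <- as.numeric(values)
  if (length(values) && !all(is.finite(values))) {
    wx_abort("signal values must be finite")
  }
  out <- tibble(
    sequence_id = as.character(sequence_id),
    pos = seq_along(values),
    value = values,
    stage = stage
  )
  class(out) <- c("wx_signal", class(out))
  out
}

# Stage guard used by every pipeline verb.
assert_stage <- function(x, allowed, what) {
  if (!is.data.frame(x) || !all(c("sequence_id", "pos", "value") %in% names(x))) {
    wx_abort(sprintf("%s expects a signal tibble (sequence_id, pos, value)", what))
  }
  st <- unique(x$stage %||% NA_character_)
  if (!all(st %in% allowed)) {
    wx_abort(sprintf(
      "%s expects a signal at stage %s, got %s",
      what, paste(allowed, collapse = "/"), paste(st, collapse = ",")
    ), class = "wx_data_error")
  }
  invisible(x)
}

# Apply f (numeric vector -> numeric vector of equal length) per sequence,
# relabelling the stage. Keeps the long tibble layout.
signal_map <- function(x, f, stage) {
  parts <- split(x, x$sequence_id)
  out <- purrr::map(parts, function(p) {
    p <- p[order(p$pos), ]
    numeric_signal(p$sequence_id[1], f(p$value), stage)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("wx_signal", class(tibble()))
  res
}

# Values of a single-sequence signal, ordered by position.
signal_values <- function(x) {
  if (length(unique(x$sequence_id)) != 1L) {
    wx_abort("expected a signal for a single sequence")
  }
  x$value[order(x$pos)]
}

#' @exportS3Method ggplot2::autoplot
autoplot.wx_signal <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~sequence_id, scales = "free", ncol = 1) +
    ggplot2::labs(x = "position (nt)", y = "value")
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start + 1, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick"
    )
  }
  p
}
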