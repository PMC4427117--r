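#' Region-calling specification
#'
#' Candidate exons are maximal runs of profile positions at or above the
#' threshold; nearby runs are merged and short remnants dropped. The default
#' threshold 0.35 is the lowest level at which the worked benchmark gene is
#' called perfectly; minimum length 50 nt and merge gap 20 nt reflect that
#' real exons are rarely shorter than ~50 nt while narrow dips inside one
#' exon's energy plateau are artefacts.
#'
#' @param threshold Call threshold on the normalized profile, in (0, 1).
#' @param min_region_length Minimum called-region length (nt) kept after
#'   merging.
#' @param merge_gap Runs separated by at most this many positions are merged.
#' @return A `caller_spec` list.
#' @export
caller_spec <- function(threshold = 0.35, min_region_length = 50L,
                        merge_gap = 20L) {
  if (!(threshold > 0 && threshold < 1)) {
    wx_abort("threshold must lie strictly in (0, 1)", "wx_config_error")
  }
  min_region_length <- as.integer(min_region_length)
  merge_gap <- as.integer(merge_gap)
  if (min_region_length < 1L) {
    wx_abort("min_region_length must be >= 1", "wx_config_error")
  }
  if (merge_gap < 0L) wx_abort("merge_gap must be >= 0", "wx_config_error")
  structure(list(threshold = threshold,
                 min_region_length = min_region_length,
                 merge_gap = merge_gap),
            class = "caller_spec")
}

#' Call candidate exons from a normalized energy profile
#'
#' Positions with `value >= threshold` (inclusive, so ties are deterministic)
#' form runs; runs separated by `<= merge_gap` positions are merged; merged
#' runs shorter than `min_region_length` are dropped.
#'
#' @param profile A `wx_signal` tibble at stage `"normalized"`.
#' @param spec A [caller_spec()].
#' @return A `wx_intervals` tibble (0-based half-open), label `"predicted"`.
#' @export
#' @examples
#' p <- numeric_signal("x", c(.1, .1, .9, .8, .2), "normalized")
#' call_regions(p, caller_spec(0.5, min_region_length = 1, merge_gap = 0))
call_regions <- function(profile, spec = caller_spec()) {
  assert_stage(profile, "normalized", "call_regions")
  parts <- split(profile, profile$sequence_id)
  rows <- purrr::map(parts, function(p) {
    p <- p[order(p$pos), ]
    hit <- p$pos[p$value >= spec$threshold]
    if (!length(hit)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(start = hit, width = 1L),
                          min.gapwidth = spec$merge_gap + 1L)
    ir <- ir[IRanges::width(ir) >= spec$min_region_length]
    if (!length(ir)) return(NULL)
    tibble(sequence_id = p$sequence_id[1],
           start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir))
  })
  rows <- dplyr::bind_rows(rows)
  if (!nrow(rows)) return(genomic_intervals(label = "predicted"))
  genomic_intervals(rows$sequence_id, rows$start, rows$end,
                    label = "predicted")
}

#' Call regions over a grid of thresholds
#'
#' One call set per threshold with identical merge/min-length settings;
#' useful for sensitivity/specificity trade-off tables and ROC curves.
#'
#' @param profile A `wx_signal` tibble at stage `"normalized"`.
#' @param thresholds Numeric vector of thresholds in (0, 1); must be
#'   non-empty.
#' @param spec A [caller_spec()] supplying merge/min-length settings (its
#'   own threshold is ignored).
#' @return A tibble of intervals with an extra leading `threshold` column.
#' @export
threshold_sweep <- function(profile, thresholds, spec = caller_spec()) {
  if (!length(thresholds)) wx_abort("empty threshold list", "wx_config_error")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    wx_abort("thresholds must lie strictly in (0, 1)", "wx_config_error")
  }
  purrr::map(thresholds, function(t) {
    s <- spec
    s$threshold <- t
    calls <- call_regions(profile, s)
    if (nrow(calls) == 0L) {
      tibble(threshold = t, sequence_id = character(),
             start = integer(), end = integer(), label = character())
    } else {
      dplyr::bind_cols(tibble(threshold = rep(t, nrow(calls))),
                       as_tibble(calls))
    }
  }) |>
    dplyr::bind_rows()
}
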