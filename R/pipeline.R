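#' Default pipeline configuration
#'
#' One nested list holding every tunable of the detection chain; the CLI
#' reads the same structure from YAML ([load_config()]) and every run writes
#' the fully resolved configuration next to its outputs.
#'
#' @return A named nested list (sections `mapping`, `bandpass`, `wavelet`,
#'   `energy`, `denoise`, `caller`, `evaluation`).
#' @export
default_config <- function() {
  list(
    mapping = list(
      eiip = list(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335),
      n_policy = "mean"
    ),
    bandpass = list(
      center_frequency = 2 * pi / 3,
      bandwidth = 0.04 * pi,
      order = 4L,
      design = "resonator_iir"
    ),
    wavelet = list(name = "coif5", levels = 2L, boundary = "symmetric"),
    energy = list(source = "detail_levels", smooth_window = 101L),
    denoise = list(method = "moving_average", window = 51L, mu = 0.05,
                   filter_order = 16L, threshold_rule = "universal"),
    caller = list(threshold = 0.35, min_region_length = 50L, merge_gap = 20L),
    evaluation = list(level = "segment", overlap_rule = 0.5)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      wx_abort(paste0("unknown configuration key: ", here), "wx_config_error")
    }
    if (is.list(base[[nm]])) {
      if (!is.list(user[[nm]])) {
        wx_abort(paste0("configuration section expected at: ", here),
                 "wx_config_error")
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      wx_abort(paste0("config file not found: ", path), "wx_config_error")
    }
    user <- tryCatch(yaml::read_yaml(path), error = function(e) {
      wx_abort(paste0("cannot parse config: ", conditionMessage(e)),
               "wx_config_error")
    })
    cfg <- merge_config(cfg, user %||% list())
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  config_specs(cfg)   # constructors validate their own fields
  invisible(cfg)
}

config_specs <- function(cfg) {
  list(
    eiip = do.call(eiip_table, cfg$mapping$eiip),
    n_policy = match.arg(cfg$mapping$n_policy, c("mean", "error")),
    bandpass = bandpass_spec(cfg$bandpass$center_frequency,
                             cfg$bandpass$bandwidth, cfg$bandpass$order,
                             cfg$bandpass$design),
    wavelet = cfg$wavelet$name,
    levels = as.integer(cfg$wavelet$levels),
    boundary = match.arg(cfg$wavelet$boundary,
                         c("symmetric", "periodization", "zero", "periodic")),
    source = match.arg(cfg$energy$source,
                       c("detail_levels", "approx", "all")),
    smooth_window = as.integer(cfg$energy$smooth_window),
    denoise = denoise_spec(cfg$denoise$method, cfg$denoise$window,
                           cfg$denoise$mu, cfg$denoise$filter_order,
                           cfg$denoise$threshold_rule),
    caller = caller_spec(cfg$caller$threshold, cfg$caller$min_region_length,
                         cfg$caller$merge_gap)
  )
}

#' Run the full exon-detection pipeline
#'
#' For each record: EIIP mapping, zero-phase band-pass at 2*pi/3, multilevel
#' DWT, per-position energy, denoising, per-record normalization, threshold
#' calling. Records shorter than `support * 2^levels` nt are skipped with a
#' warning (too short for a stable decomposition); the remaining records are
#' processed.
#'
#' @param seqs A tibble with columns `id` and `seq` (e.g. from [read_fasta()]
#'   or [generate_gene()]`$sequences`).
#' @param config Pipeline configuration, see [default_config()].
#' @return An `exon_scan` object: `$regions` (`wx_intervals`, label
#'   `"predicted"`), `$profiles` (`wx_signal`, stage `"normalized"`),
#'   `$skipped` (ids), `$config`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
#' @examples
#' g <- generate_gene(n_exons = 1, codon_bias = 1, seed = 3)
#' scan <- detect_exons(g$sequences)
#' tidy(scan)
detect_exons <- function(seqs, config = default_config()) {
  validate_config(config)
  sp <- config_specs(config)
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    wx_abort("detect_exons expects a tibble with columns id and seq")
  }
  if (nrow(seqs) == 0L) wx_abort("no records")
  min_len <- wavelet_filters(sp$wavelet)$length * 2L^sp$levels
  profiles <- list()
  regions <- list()
  skipped <- character()
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$id[i]
    if (nchar(seqs$seq[i]) < min_len) {
      rlang::warn(sprintf(
        "skipping record '%s': %d nt < required %d", id,
        nchar(seqs$seq[i]), min_len))
      skipped <- c(skipped, id)
      next
    }
    prof <- map_eiip(seqs[i, , drop = FALSE], sp$eiip, sp$n_policy) |>
      bandpass_period3(sp$bandpass) |>
      dwt_decompose(sp$wavelet, sp$levels, sp$boundary) |>
      energy_profile(sp$source, sp$smooth_window) |>
      adaptive_denoise(sp$denoise) |>
      normalize_profile()
    profiles[[id]] <- prof
    regions[[id]] <- call_regions(prof, sp$caller)
  }
  if (!length(profiles) && length(skipped) == nrow(seqs)) {
    wx_abort("no records long enough to process")
  }
  prof_tbl <- dplyr::bind_rows(profiles)
  class(prof_tbl) <- c("wx_signal", class(tibble()))
  reg_tbl <- dplyr::bind_rows(regions)
  if (!nrow(reg_tbl)) {
    reg_tbl <- genomic_intervals(label = "predicted")
  } else {
    reg_tbl <- genomic_intervals(reg_tbl$sequence_id, reg_tbl$start,
                                 reg_tbl$end, label = "predicted")
  }
  structure(list(regions = reg_tbl, profiles = prof_tbl, skipped = skipped,
                 config = config),
            class = "exon_scan")
}

#' @export
print.exon_scan <- function(x, ...) {
  cat(sprintf("<exon_scan> %d sequence(s), %d region(s) called%s\n",
              length(unique(x$profiles$sequence_id)), nrow(x$regions),
              if (length(x$skipped)) {
                paste0(", skipped: ", paste(x$skipped, collapse = ", "))
              } else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exon_scan <- function(x, ...) as_tibble(x$regions)

#' @exportS3Method generics::glance
glance.exon_scan <- function(x, ...) {
  x$profiles |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(length = dplyr::n(),
                     mean_energy = mean(.data$value),
                     .groups = "drop") |>
    dplyr::left_join(
      as_tibble(x$regions) |>
        dplyr::group_by(.data$sequence_id) |>
        dplyr::summarise(n_regions = dplyr::n(),
                         called_nt = sum(.data$end - .data$start),
                         .groups = "drop"),
      by = "sequence_id") |>
    dplyr::mutate(n_regions = dplyr::coalesce(.data$n_regions, 0L),
                  called_nt = dplyr::coalesce(.data$called_nt, 0L))
}

#' @exportS3Method ggplot2::autoplot
autoplot.exon_scan <- function(object, truth = NULL, ...) {
  p <- autoplot(object$profiles, regions = object$regions) +
    ggplot2::geom_hline(yintercept = object$config$caller$threshold,
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(y = "normalized period-3 energy")
  if (!is.null(truth) && nrow(truth)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(truth),
      ggplot2::aes(xmin = .data$start + 1, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.12, fill = "seagreen")
  }
  p
}
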