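#' EIIP lookup table
#'
#' The electron-ion interaction potential (EIIP) of a nucleotide is the
#' average energy of its delocalized electrons; it maps each base to a single
#' real number, so one numeric sequence carries the whole record (against
#' four binary indicator tracks). Defaults are the standard values
#' A = 0.1260, G = 0.0806, T = 0.1335, C = 0.1340.
#'
#' @param A,C,G,T Per-base potentials (dimensionless, Rydberg scale).
#' @return A named numeric vector over `A`, `C`, `G`, `T`.
#' @export
eiip_table <- function(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335) {
  v <- c(A = A, C = C, G = G, T = T)
  if (!all(is.finite(v))) wx_abort("EIIP values must be finite", "wx_config_error")
  v
}

#' Map DNA sequences to EIIP numeric signals
#'
#' Position-wise, stateless lookup: position `i` of the output equals the
#' table entry for the base at position `i`. `N` bases either abort
#' (`n_policy = "error"`) or map to the mean of the four table values with a
#' warning (`"mean"`, the default, so occasional ambiguous calls in real
#' records do not kill a run).
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]),
#'   or a single character string.
#' @param table EIIP table from [eiip_table()].
#' @param n_policy How to treat `N`: `"mean"` or `"error"`.
#' @return A `wx_signal` tibble at stage `"eiip"`.
#' @export
#' @examples
#' map_eiip("TTCACTAGCA")
map_eiip <- function(seqs, table = eiip_table(),
                     n_policy = c("mean", "error")) {
  n_policy <- match.arg(n_policy)
  if (is.character(seqs)) seqs <- tibble(id = "seq1", seq = toupper(seqs))
  if (!all(c("id", "seq") %in% names(seqs))) {
    wx_abort("map_eiip expects columns id and seq")
  }
  n_value <- mean(table)
  rows <- purrr::map(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    chars <- strsplit(seqs$seq[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c(names(table), "N"))
    if (length(bad)) {
      wx_abort(sprintf("record '%s': invalid character '%s' at position %d",
                       id, chars[bad[1]], bad[1]))
    }
    ns <- which(chars == "N")
    if (length(ns)) {
      if (n_policy == "error") {
        wx_abort(sprintf("record '%s': ambiguous base N at position %d",
                         id, ns[1]))
      }
      rlang::warn(sprintf(
        "record '%s': %d N base(s) mapped to table mean %.6f",
        id, length(ns), n_value
      ))
    }
    vals <- unname(table[chars])
    vals[is.na(vals)] <- n_value
    numeric_signal(id, vals, "eiip")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wx_signal", class(tibble()))
  out
}
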