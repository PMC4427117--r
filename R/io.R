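#' Read DNA sequences from a FASTA file
#'
#' Records are uppercased on ingest and validated to the alphabet
#' `{A,C,G,T,N}`. RNA (`U`) and IUPAC ambiguity codes other than `N` are
#' rejected with the offending record and position named.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) wx_abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) wx_abort(paste0("malformed FASTA: ", conditionMessage(e)))
  )
  if (length(set) == 0L) wx_abort("empty FASTA file: no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) validate_dna(seqs[[i]], ids[[i]])
  tibble(id = unname(ids), seq = unname(seqs))
}

validate_dna <- function(seq, id) {
  if (!nzchar(seq)) {
    wx_abort(sprintf("empty record '%s'", id))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    wx_abort(sprintf(
      "record '%s': invalid character '%s' at position %d (alphabet is A,C,G,T,N)",
      id, chars[bad[1]], bad[1]
    ))
  }
  invisible(seq)
}

#' Construct a set of genomic intervals
#'
#' Intervals are kept 0-based, half-open internally; conversion to and from
#' 1-based closed conventions happens only at format boundaries
#' ([read_annotation()], [write_regions()]). Overlapping or book-ended input
#' intervals are merged and the result is sorted by `sequence_id` and `start`.
#'
#' @param sequence_id Character vector of sequence identifiers.
#' @param start,end Integer vectors, 0-based half-open coordinates
#'   (`start < end`).
#' @param label `"exon"` (annotation) or `"predicted"` (pipeline output).
#' @return A tibble with columns `sequence_id`, `start`, `end`, `label`,
#'   classed `wx_intervals`.
#' @export
genomic_intervals <- function(sequence_id = character(), start = integer(),
                              end = integer(), label = "predicted") {
  label <- match.arg(label, c("predicted", "exon"))
  if (length(start) != length(end) || length(start) != length(sequence_id)) {
    wx_abort("sequence_id, start and end must have equal length")
  }
  start <- as.integer(start); end <- as.integer(end)
  if (length(start)) {
    if (any(start < 0)) wx_abort("interval start must be >= 0")
    if (any(start >= end)) {
      i <- which(start >= end)[1]
      wx_abort(sprintf("invalid interval [%d, %d): start must be < end",
                       start[i], end[i]))
    }
  }
  out <- tibble(sequence_id = as.character(sequence_id),
                start = start, end = end)
  if (nrow(out)) {
    gr <- GenomicRanges::reduce(intervals_to_granges(out))
    out <- granges_to_intervals(gr)
  }
  out$label <- rep(label, nrow(out))
  class(out) <- c("wx_intervals", class(tibble()))
  out
}

# 0-based half-open tibble <-> 1-based closed GRanges
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$sequence_id,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_intervals <- function(gr) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  tibble(
    sequence_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read exon annotations from BED or GFF3
#'
#' BED coordinates are used as-is (already 0-based half-open); GFF3 features
#' (1-based closed `[s, e]`) become `[s-1, e)`. Only `exon` features are kept
#' from GFF3. Overlapping intervals are merged. Minus-strand features are
#' rejected: the detector is single-strand.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; `"auto"` guesses from the extension.
#' @param label Label to attach, `"exon"` by default.
#' @return A `wx_intervals` tibble (see [genomic_intervals()]).
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            label = "exon") {
  format <- match.arg(format)
  if (!file.exists(path)) wx_abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) wx_abort(sprintf("cannot parse %s as %s: %s",
                                         path, format, conditionMessage(e)))
  )
  if (format == "gff3") {
    type <- as.character(gr$type %||% character())
    if (any(type == "exon")) gr <- gr[type == "exon"]
  }
  if (any(as.character(GenomicRanges::strand(gr)) == "-")) {
    wx_abort("minus-strand annotations are not supported (single-strand analysis)")
  }
  if (length(gr) == 0L) wx_abort(paste0("no intervals found in ", path))
  x <- granges_to_intervals(GenomicRanges::reduce(gr, ignore.strand = TRUE))
  genomic_intervals(x$sequence_id, x$start, x$end, label = label)
}

#' Write predicted or annotated regions to BED or GFF3
#'
#' BED output is minimal 3-column (`seqid start end`, 0-based half-open);
#' GFF3 output carries `exon` features in 1-based closed coordinates.
#' `read_annotation(write_regions(x))` round-trips the coordinates exactly.
#'
#' @param regions A `wx_intervals` tibble.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  regions <- regions[order(regions$sequence_id, regions$start), ]
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d", regions$sequence_id, regions$start,
                     regions$end)
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) wx_abort(paste0("cannot write ", path))
  } else {
    if (nrow(regions) == 0L) {
      writeLines("##gff-version 3", path)
    } else {
      gr <- intervals_to_granges(regions)
      gr$source <- "wavexon"
      gr$type <- "exon"
      rtracklayer::export(gr, path, format = "gff3")
    }
  }
  invisible(path)
}
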