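# Shared fixture builders; everything is generated in code at test time.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_bed <- function(df) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(sprintf("%s\t%d\t%d", df$sequence_id, df$start, df$end), path)
  path
}

# A normalized profile straight from values in [0, 1].
norm_profile <- function(values, id = "x") {
  numeric_signal(id, values, "normalized")
}

# Brute-force Mann-Whitney AUC: fraction of (positive, negative) pairs where
# the positive scores higher (ties count 1/2).
mw_auc <- function(values, positive) {
  pos <- values[positive]
  neg <- values[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
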