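# Internal helpers shared across modules.

# DNA is the internal alphabet everywhere; U -> T happens here, at the
# boundary, and nowhere else.
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  x
}

revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

dna_to_rna <- function(x) chartr("T", "U", x)

# One seed in, per-stage streams out: stage k uses (seed + k * 1000003)
# mod (2^31 - 1) so stages are reproducible in isolation.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 1000003) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Comma-join a list column for TSV export.
join_col <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))

split_col <- function(x) {
  out <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
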