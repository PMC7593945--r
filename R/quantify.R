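#' Construct an in-memory read set
#'
#' A read set is the unit the counting engines consume: one sample's reads,
#' normalized to uppercase DNA.
#'
#' @param sequences Character vector of read sequences.
#' @param sample_id Sample identifier.
#' @return An object of class `read_set`.
#' @export
read_set <- function(sequences, sample_id) {
  structure(list(sample_id = sample_id,
                 sequences = normalize_dna(sequences, "read")),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> sample '%s': %d reads\n",
              x$sample_id, length(x$sequences)))
  invisible(x)
}

#' Read a FASTQ file into a read set
#'
#' Reads are assumed already adapter-trimmed; only sequence content is kept.
#' Gzipped files are handled transparently.
#'
#' @param path FASTQ / FASTQ.gz path.
#' @param sample_id Sample id; defaults to the file name without extensions.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  read_set(as.character(seqs), sample_id)
}

as_read_sets <- function(reads) {
  if (inherits(reads, "read_set")) reads <- list(reads)
  stopifnot(all(vapply(reads, inherits, logical(1), "read_set")))
  ids <- vapply(reads, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in read sets", call. = FALSE)
  names(reads) <- ids
  reads
}

new_count_matrix <- function(counts, feature_class, ledger) {
  structure(list(counts = counts, feature_class = feature_class,
                 ledger = ledger),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> class %s: %d features x %d samples\n",
              x$feature_class, nrow(x$counts), ncol(x$counts)))
  print(x$ledger, row.names = FALSE)
  invisible(x)
}

make_ledger <- function(sample_id, total, assigned, ambiguous = 0L, filtered = 0L) {
  data.frame(sample_id = sample_id, total = total, assigned = assigned,
             ambiguous = ambiguous, filtered = filtered,
             unmatched = total - assigned - ambiguous - filtered,
             stringsAsFactors = FALSE)
}

# Exact-match engine shared by tRF and miRNA counting. A read is assigned to
# a feature iff, after stripping up to `trim_trailing_a` 3' A's (fewest
# stripped wins), it equals the feature sequence. Feature sequences must be
# pairwise distinct, so each read maps to at most one feature.
count_exact <- function(reads, feat_ids, feat_seqs, feature_class,
                        trim_trailing_a = 0L) {
  if (anyDuplicated(feat_seqs))
    stop("duplicate ", feature_class, " sequences in annotation", call. = FALSE)
  reads <- as_read_sets(reads)
  counts <- matrix(0L, nrow = length(feat_ids), ncol = length(reads),
                   dimnames = list(feat_ids, names(reads)))
  ledger <- NULL
  for (s in names(reads)) {
    seqs <- reads[[s]]$sequences
    tab <- table(seqs)
    u <- names(tab); n <- as.integer(tab)
    hit <- rep(NA_integer_, length(u))
    cand <- u
    for (j in 0:trim_trailing_a) {
      todo <- which(is.na(hit) & nchar(cand) >= 1L)
      if (length(todo) == 0L) break
      m <- match(cand[todo], feat_seqs)
      hit[todo[!is.na(m)]] <- m[!is.na(m)]
      # strip one more trailing A where possible
      is_a <- endsWith(cand, "A")
      cand[is_a] <- substr(cand[is_a], 1L, nchar(cand[is_a]) - 1L)
      cand[!is_a] <- ""   # cannot strip further: stop considering
    }
    ok <- !is.na(hit)
    counts[, s] <- as.integer(tapply(n[ok], factor(hit[ok], levels = seq_along(feat_ids)),
                                     sum, default = 0L))
    ledger <- rbind(ledger, make_ledger(s, length(seqs), sum(n[ok])))
  }
  new_count_matrix(counts, feature_class, ledger)
}

#' Count annotated tRFs directly in reads
#'
#' Direct sequence counting of an annotated fragment catalogue in raw reads,
#' with no alignment step. In `exact` mode a read is assigned to a tRF iff,
#' after stripping up to `trim_trailing_a` 3' A's (the library prep
#' polyadenylates small RNAs, so templated fragments can carry short 3'
#' A-tails), the read equals the tRF sequence. In `contained` mode the tRF
#' sequence must occur as a substring of the read; a read containing several
#' tRFs is assigned to the longest one (ties broken by lexicographically
#' smallest `trf_id`). Every read contributes at most one count.
#'
#' @param reads A [read_set()] or list of them (one per sample).
#' @param trfs data.frame from [load_trf_table()]; sequences must be
#'   pairwise distinct.
#' @param mode `"exact"` (default) or `"contained"`.
#' @param trim_trailing_a Maximum number of 3' A's stripped before exact
#'   comparison (default 0; ignored in contained mode, where trailing bases
#'   do not prevent a substring hit).
#' @return A `count_matrix` (features x samples, plus a per-sample ledger of
#'   assigned / ambiguous / filtered / unmatched reads).
#' @export
count_trfs <- function(reads, trfs, mode = c("exact", "contained"),
                       trim_trailing_a = 0L) {
  mode <- match.arg(mode)
  if (anyDuplicated(trfs$sequence))
    stop("duplicate tRF sequences in annotation", call. = FALSE)
  if (mode == "exact")
    return(count_exact(reads, trfs$trf_id, trfs$sequence, "tRF",
                       trim_trailing_a))

  reads <- as_read_sets(reads)
  ord <- order(-nchar(trfs$sequence), trfs$trf_id)  # longest match, then smallest id
  counts <- matrix(0L, nrow = nrow(trfs), ncol = length(reads),
                   dimnames = list(trfs$trf_id, names(reads)))
  ledger <- NULL
  for (s in names(reads)) {
    seqs <- reads[[s]]$sequences
    tab <- table(seqs)
    u <- names(tab); n <- as.integer(tab)
    hit <- rep(NA_integer_, length(u))
    for (k in ord) {
      todo <- is.na(hit)
      if (!any(todo)) break
      m <- grepl(trfs$sequence[k], u[todo], fixed = TRUE)
      hit[which(todo)[m]] <- k
    }
    ok <- !is.na(hit)
    counts[, s] <- as.integer(tapply(n[ok], factor(hit[ok], levels = seq_len(nrow(trfs))),
                                     sum, default = 0L))
    ledger <- rbind(ledger, make_ledger(s, length(seqs), sum(n[ok])))
  }
  new_count_matrix(counts, "tRF", ledger)
}

#' Count intact tRNAs with a minimum read-length filter
#'
#' Reads shorter than `min_read_len` nt are discarded (tallied as filtered):
#' only long reads are accepted as evidence of intact tRNA rather than
#' fragments. A surviving read matches a reference entry iff it occurs as a
#' substring of the entry's mature sequence with at most `max_mismatches`
#' Hamming mismatches at some offset (no indels). Reads matching exactly one
#' entry are counted; reads matching two or more entries are tallied as
#' ambiguous and not counted.
#'
#' @param reads A [read_set()] or list of them.
#' @param ref Collapsed unique-sequence reference from [collapse_unique()].
#' @param min_read_len Minimum read length in nt (default 40).
#' @param max_mismatches Maximum Hamming mismatches per match (default 0).
#' @return A `count_matrix` with feature class `"tRNA"`.
#' @export
count_trnas <- function(reads, ref, min_read_len = 40L, max_mismatches = 0L) {
  stopifnot(min_read_len >= 1L, max_mismatches >= 0L)
  if (nrow(ref) == 0L) stop("empty tRNA reference", call. = FALSE)
  reads <- as_read_sets(reads)
  subject <- Biostrings::DNAStringSet(ref$sequence)
  counts <- matrix(0L, nrow = nrow(ref), ncol = length(reads),
                   dimnames = list(ref$ref_id, names(reads)))
  ledger <- NULL
  for (s in names(reads)) {
    seqs <- reads[[s]]$sequences
    keep <- nchar(seqs) >= min_read_len
    n_filtered <- sum(!keep)
    tab <- table(seqs[keep])
    u <- names(tab); n <- as.integer(tab)
    assigned <- 0L; ambiguous <- 0L
    for (i in seq_along(u)) {
      hits <- which(Biostrings::vcountPattern(
        u[i], subject, max.mismatch = max_mismatches,
        with.indels = FALSE, fixed = TRUE) > 0L)
      if (length(hits) == 1L) {
        counts[hits, s] <- counts[hits, s] + n[i]
        assigned <- assigned + n[i]
      } else if (length(hits) >= 2L) {
        ambiguous <- ambiguous + n[i]
      }
    }
    ledger <- rbind(ledger, make_ledger(s, length(seqs), assigned,
                                        ambiguous, n_filtered))
  }
  new_count_matrix(counts, "tRNA", ledger)
}

#' Count mature miRNAs by exact sequence match
#'
#' Identical contract to [count_trfs()] exact mode, keyed by mature miRNA
#' sequence.
#'
#' @inheritParams count_trfs
#' @param mirnas data.frame from [load_mirna_fasta()].
#' @return A `count_matrix` with feature class `"miRNA"`.
#' @export
count_mirnas <- function(reads, mirnas, trim_trailing_a = 0L) {
  count_exact(reads, mirnas$mirna_id, mirnas$sequence, "miRNA",
              trim_trailing_a)
}

#' Normalize counts to reads per million
#'
#' RPM is computed within a feature class: the default denominator for each
#' sample is that sample's total of assigned reads of the class (the three
#' small-RNA classes come from separately prepared libraries, so they are
#' normalized separately). The whole-library total (including ambiguous,
#' filtered and unmatched reads) is available via
#' `denominator = "library"`.
#'
#' @param cm A `count_matrix`.
#' @param denominator `"class"` (default) or `"library"`.
#' @return An `rpm_matrix`: list with `values` (features x samples),
#'   `feature_class`, `denominator` and the per-sample totals used.
#' @export
rpm <- function(cm, denominator = c("class", "library")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$counts < 0L)) stop("negative counts", call. = FALSE)
  totals <- if (denominator == "class") colSums(cm$counts)
            else cm$ledger$total[match(colnames(cm$counts), cm$ledger$sample_id)]
  zero <- totals == 0
  if (any(zero))
    warning("sample(s) with zero denominator yield all-zero RPM: ",
            paste(colnames(cm$counts)[zero], collapse = ", "), call. = FALSE)
  denom <- ifelse(zero, 1, totals)
  vals <- sweep(cm$counts, 2L, denom, "/") * 1e6
  vals[, zero] <- 0
  structure(list(values = vals, feature_class = cm$feature_class,
                 denominator = denominator, totals = totals),
            class = "rpm_matrix")
}

#' @export
print.rpm_matrix <- function(x, ...) {
  cat(sprintf("<rpm_matrix> class %s: %d features x %d samples (denominator: %s)\n",
              x$feature_class, nrow(x$values), ncol(x$values), x$denominator))
  invisible(x)
}

rpm_values <- function(x) {
  if (inherits(x, "rpm_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected an rpm_matrix or a numeric matrix", call. = FALSE)
}
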