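#' Load tRNA gene sequences from a FASTA file
#'
#' Parses a FASTA file of tRNA gene bodies with GtRNAdb-style headers
#' (`tRNA-<AminoAcid>-<Anticodon>-<locus>`). Gene bodies are taken as
#' intronless; `U` is converted to `T` and case is normalized. Headers from
#' which no amino acid / anticodon token can be parsed are routed to a
#' rejects table rather than silently dropped.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A list with components `genes` (data.frame with columns
#'   `gene_id`, `amino_acid`, `anticodon`, `sequence`, `is_mito`) and
#'   `rejects` (data.frame with columns `header`, `reason`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tRNA-Gly-GCC-2-1", "GCATTGGTGGTTCAGTGGTAGAATTCTCGC"), fa)
#' load_trna_fasta(fa)$genes
#' @export
load_trna_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(seqs)
  bodies <- normalize_dna(as.character(seqs), "tRNA gene body")

  pat <- "tRNA-([A-Za-z]{3,4})-([ACGTUacgtu]{3})"
  m <- regmatches(headers, regexec(pat, headers))
  ok <- lengths(m) == 3L & nchar(bodies) > 0L

  genes <- data.frame(
    gene_id    = vapply(strsplit(headers[ok], "[ \t]"), `[`, character(1), 1L),
    amino_acid = vapply(m[ok], `[`, character(1), 2L),
    anticodon  = normalize_dna(vapply(m[ok], `[`, character(1), 3L), "anticodon"),
    sequence   = bodies[ok],
    is_mito    = grepl("MT-|mito|^mt", headers[ok], ignore.case = TRUE),
    stringsAsFactors = FALSE
  )
  rejects <- data.frame(
    header = headers[!ok],
    reason = ifelse(nchar(bodies[!ok]) == 0L, "empty sequence",
                    "no parseable tRNA-<AA>-<anticodon> token"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in FASTA: ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  list(genes = genes, rejects = rejects)
}

#' Construct mature tRNA sequences
#'
#' Appends the post-transcriptional 3' `CCA` to every gene body, nuclear and
#' mitochondrial alike; genomically encoded CCA is not detected, so a body
#' already ending in CCA yields a mature ending `CCACCA`. Matures shorter
#' than `min_len` are flagged unusable: they can never satisfy the
#' intact-tRNA read-length filter downstream.
#'
#' @param genes data.frame as returned in `load_trna_fasta()$genes`.
#' @param min_len Minimum usable mature length in nt (default 40).
#' @return data.frame with columns `gene_id`, `amino_acid`, `anticodon`,
#'   `sequence` (mature, ends `CCA`), `length`, `usable`, `family`
#'   (isoacceptor family, `<AminoAcid>-<Anticodon>`).
#' @export
build_mature <- function(genes, min_len = 40L) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0L)
  seq <- paste0(genes$sequence, "CCA")
  data.frame(
    gene_id    = genes$gene_id,
    amino_acid = genes$amino_acid,
    anticodon  = genes$anticodon,
    sequence   = seq,
    length     = nchar(seq),
    usable     = nchar(seq) >= min_len,
    family     = paste0(genes$amino_acid, "-", genes$anticodon),
    stringsAsFactors = FALSE
  )
}

#' Collapse mature tRNAs to a unique-sequence reference
#'
#' Merges identical mature sequences into single reference entries (the
#' "artificial genome" counted against downstream). The entry id is the
#' lexicographically first member gene id; member ids are kept sorted.
#' Identical sequences from different isoacceptor families are merged with
#' the full family set recorded and a warning.
#'
#' @param matures data.frame from [build_mature()].
#' @return data.frame with columns `ref_id`, `sequence`, `members` (list
#'   column of gene ids), `families` (list column of isoacceptor families).
#' @export
collapse_unique <- function(matures) {
  stopifnot(is.data.frame(matures), nrow(matures) > 0L)
  if (anyDuplicated(matures$gene_id))
    stop("duplicate gene_id among matures: ambiguous identity", call. = FALSE)
  idx <- split(seq_len(nrow(matures)), matures$sequence)
  entries <- lapply(idx, function(i) {
    members <- sort(matures$gene_id[i])
    fams <- sort(unique(matures$family[i]))
    list(ref_id = members[1], sequence = matures$sequence[i][1],
         members = members, families = fams)
  })
  multi_fam <- vapply(entries, function(e) length(e$families) > 1L, logical(1))
  if (any(multi_fam))
    warning("identical mature sequence shared across isoacceptor families: ",
            paste(vapply(entries[multi_fam], `[[`, character(1), "ref_id"),
                  collapse = ", "), call. = FALSE)
  out <- data.frame(
    ref_id   = vapply(entries, `[[`, character(1), "ref_id"),
    sequence = vapply(entries, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE
  )
  out$members <- unname(lapply(entries, `[[`, "members"))
  out$families <- unname(lapply(entries, `[[`, "families"))
  out <- out[order(out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load an annotated tRF table
#'
#' Reads a tRFdb-style tab-separated table with columns
#' `trf_id type sequence parents` (parents comma-separated
#' `AminoAcid-Anticodon` families; may be empty). Fragment type must be one
#' of `tRF-1`, `tRF-3`, `tRF-5`, and when the id embeds a type numeral
#' (e.g. `tRF-5003b`) it must agree with the declared type.
#'
#' @param path Path to the TSV, or a data.frame with the same columns.
#' @return data.frame with columns `trf_id`, `type`, `sequence`, `length`,
#'   `parents` (list column).
#' @export
load_trf_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("trf_id", "type", "sequence")
  if (!all(need %in% names(tab)))
    stop("tRF table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  tab$sequence <- normalize_dna(tab$sequence, "tRF sequence")
  bad_type <- !tab$type %in% c("tRF-1", "tRF-3", "tRF-5")
  if (any(bad_type))
    stop("unknown tRF type token: ", tab$type[bad_type][1], call. = FALSE)

  dup <- duplicated(tab$sequence) | duplicated(tab$sequence, fromLast = TRUE)
  if (any(dup)) {
    conf <- tapply(tab$trf_id, tab$sequence, function(v) length(unique(v)) > 1L)
    if (any(conf))
      stop("duplicate tRF sequence with conflicting ids", call. = FALSE)
  }
  # id numeral, when present, must match the declared type
  num <- sub("^tRF-([135]).*$", "\\1", tab$trf_id)
  has_num <- grepl("^tRF-[135]", tab$trf_id)
  mism <- has_num & paste0("tRF-", num) != tab$type
  if (any(mism))
    stop("trf_id/type mismatch for ", tab$trf_id[mism][1], call. = FALSE)

  len <- nchar(tab$sequence)
  if (any(len < 14L | len > 40L))
    warning("tRF sequence length outside 14-40 nt for: ",
            paste(tab$trf_id[len < 14L | len > 40L], collapse = ", "),
            call. = FALSE)
  parents <- if (!"parents" %in% names(tab)) rep(list(character(0)), nrow(tab))
             else if (is.list(tab$parents)) lapply(tab$parents, as.character)
             else split_col(tab$parents)
  out <- data.frame(trf_id = tab$trf_id, type = tab$type,
                    sequence = tab$sequence, length = len,
                    stringsAsFactors = FALSE)
  out$parents <- parents
  out
}

#' Validate tRFs against a collapsed tRNA reference
#'
#' Marks each tRF-5 whose sequence is a prefix of at least one parent-family
#' mature sequence as `CONSISTENT`, and each tRF-3 that is a suffix of at
#' least one as `CONSISTENT`; failures are `INCONSISTENT`. tRF-1 fragments
#' derive from the pre-tRNA 3' trailer, which the mature reference does not
#' contain, so they are `UNCHECKED`. When a tRF declares no parent family
#' the whole reference is searched.
#'
#' @param trfs data.frame from [load_trf_table()].
#' @param ref data.frame from [collapse_unique()].
#' @return data.frame with columns `trf_id`, `type`, `status`.
#' @export
validate_trfs <- function(trfs, ref) {
  stopifnot(nrow(ref) > 0L)
  ref_fams <- ref$families
  status <- character(nrow(trfs))
  for (i in seq_len(nrow(trfs))) {
    type <- trfs$type[i]
    if (type == "tRF-1") { status[i] <- "UNCHECKED"; next }
    par <- trfs$parents[[i]]
    cand <- if (length(par) == 0L) seq_len(nrow(ref)) else
      which(vapply(ref_fams, function(f) any(f %in% par), logical(1)))
    s <- trfs$sequence[i]
    hit <- if (type == "tRF-5")
      any(startsWith(ref$sequence[cand], s))
    else
      any(endsWith(ref$sequence[cand], s))
    status[i] <- if (hit) "CONSISTENT" else "INCONSISTENT"
  }
  data.frame(trf_id = trfs$trf_id, type = trfs$type, status = status,
             stringsAsFactors = FALSE)
}

#' Load mature miRNA sequences from FASTA
#'
#' Reads a miRBase-style mature miRNA FASTA; RNA alphabet is converted to
#' DNA internally. Duplicate sequences are an error because exact-match
#' counting requires an unambiguous feature per read.
#'
#' @param path FASTA path.
#' @return data.frame with columns `mirna_id`, `sequence`, `length`.
#' @export
load_mirna_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- data.frame(
    mirna_id = vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L),
    sequence = normalize_dna(as.character(seqs), "miRNA sequence"),
    stringsAsFactors = FALSE
  )
  out$length <- nchar(out$sequence)
  if (any(out$length < 16L | out$length > 28L))
    warning("miRNA length outside 16-28 nt for: ",
            paste(out$mirna_id[out$length < 16L | out$length > 28L],
                  collapse = ", "), call. = FALSE)
  if (anyDuplicated(out$sequence))
    stop("duplicate mature miRNA sequence in input", call. = FALSE)
  out
}
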