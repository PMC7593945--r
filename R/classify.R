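#' Assign a tRF subtype from its major type and length
#'
#' Length-based subtype scheme: tRF-5 fragments of 14-16, 22-24 and 28-30 nt
#' are subtypes 5a, 5b and 5c (D-loop vs D-stem cleavage products); tRF-3
#' fragments around 18 and 22 nt are 3a and 3b (windows of +/- 1 nt around
#' those point lengths so real annotations do not fall through; see
#' `trf3a_window` / `trf3b_window`). Fragments longer than `half_threshold`
#' nt are putative tRNA halves, the products of anticodon-loop cleavage.
#' tRF-1 fragments (pre-tRNA 3' trailers) keep subtype `"1"` at any length
#' up to 40 nt. Lengths falling in none of the windows return
#' `"unclassified"`, never the nearest bin.
#'
#' @param major_type Character vector over `{"tRF-1","tRF-3","tRF-5"}`.
#' @param length Integer vector of fragment lengths (nt), recycled against
#'   `major_type`.
#' @param half_threshold Lengths strictly greater than this are halves
#'   (default 30).
#' @param trf3a_window,trf3b_window Integer ranges for the tRF-3 subtypes
#'   (defaults 17-19 and 21-23).
#' @return Character vector over
#'   `{"5a","5b","5c","3a","3b","1","half","unclassified"}`.
#' @export
subtype_from_length <- function(major_type, length, half_threshold = 30L,
                                trf3a_window = 17:19, trf3b_window = 21:23) {
  stopifnot(all(length >= 1L))
  n <- max(base::length(major_type), base::length(length))
  major_type <- rep_len(major_type, n)
  length <- rep_len(length, n)
  bad <- !major_type %in% c("tRF-1", "tRF-3", "tRF-5")
  if (any(bad)) stop("unknown major_type: ", major_type[bad][1], call. = FALSE)

  out <- rep("unclassified", n)
  is5 <- major_type == "tRF-5"
  is3 <- major_type == "tRF-3"
  is1 <- major_type == "tRF-1"
  out[is5 & length >= 14L & length <= 16L] <- "5a"
  out[is5 & length >= 22L & length <= 24L] <- "5b"
  out[is5 & length >= 28L & length <= 30L] <- "5c"
  out[is3 & length %in% trf3a_window] <- "3a"
  out[is3 & length %in% trf3b_window] <- "3b"
  out[(is5 | is3) & length > half_threshold] <- "half"
  out[is1 & length <= 40L] <- "1"
  out
}

#' Detect a 5' oligo-G motif
#'
#' TRUE iff the first `min_run` characters of the sequence are all G. A 5'
#' run of guanosines marks putative translation-initiation-inhibiting
#' fragments.
#'
#' @param sequence Character vector of sequences.
#' @param min_run Minimum run length (default 4).
#' @return Logical vector.
#' @export
detect_oligoG <- function(sequence, min_run = 4L) {
  if (min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  stopifnot(all(nchar(sequence) > 0L))
  nchar(sequence) >= min_run &
    substr(sequence, 1L, min_run) == strrep("G", min_run)
}

#' Map a tRF to its parent isoacceptor families
#'
#' For tRF-5 returns the families whose mature sequence has the fragment as
#' a prefix; for tRF-3, as a suffix; tRF-1 fragments return their declared
#' parent families unchanged (the mature reference does not contain the
#' pre-tRNA trailer). The result is united with any families declared in the
#' annotation; an empty result is allowed and flagged by the caller.
#'
#' @param trf One-row data.frame (or list) with `type`, `sequence`,
#'   `parents`.
#' @param ref Collapsed reference from [collapse_unique()].
#' @return Character vector of isoacceptor families (`Aa-Anticodon`).
#' @export
parent_isoacceptors <- function(trf, ref) {
  if (nrow(ref) == 0L) stop("empty reference", call. = FALSE)
  type <- trf$type[[1]]
  s <- trf$sequence[[1]]
  declared <- unlist(trf$parents, use.names = FALSE)
  if (type == "tRF-1") return(sort(unique(declared)))
  hit <- if (type == "tRF-5") startsWith(ref$sequence, s)
         else endsWith(ref$sequence, s)
  fams <- unlist(ref$families[hit], use.names = FALSE)
  sort(unique(c(fams, declared)))
}

#' Convert an anticodon to the codon it decodes
#'
#' The codon is the reverse complement of the anticodon, reported in the RNA
#' alphabet together with the amino acid of the standard genetic code.
#'
#' @param anticodon Character vector of 3-mers over `{A,C,G,T}` (U accepted).
#' @return data.frame with columns `anticodon`, `codon` (RNA alphabet),
#'   `amino_acid` (one-letter code, `*` for stop).
#' @export
anticodon_to_codon <- function(anticodon) {
  anticodon <- normalize_dna(anticodon, "anticodon")
  if (any(nchar(anticodon) != 3L))
    stop("anticodon must be a 3-mer", call. = FALSE)
  codon_dna <- revcomp(anticodon)
  aa <- unname(Biostrings::GENETIC_CODE[codon_dna])
  data.frame(anticodon = anticodon, codon = dna_to_rna(codon_dna),
             amino_acid = aa, stringsAsFactors = FALSE)
}

#' Classify a tRF catalogue
#'
#' Builds the full classification table: major type, length-based subtype,
#' tRNA-half call, 5' oligo-G motif, and parent isoacceptor families
#' resolved against the mature reference.
#'
#' @param trfs data.frame from [load_trf_table()].
#' @param ref Optional collapsed reference; when `NULL`, parents are the
#'   declared ones only.
#' @param min_run Oligo-G run length (default 4).
#' @param ... Passed to [subtype_from_length()].
#' @return data.frame with columns `trf_id`, `major_type`, `subtype`,
#'   `is_half`, `has_oligoG`, `parents` (list column), `orphan` (TRUE when
#'   no parent family could be resolved).
#' @export
classify_trfs <- function(trfs, ref = NULL, min_run = 4L, ...) {
  subtype <- subtype_from_length(trfs$type, nchar(trfs$sequence), ...)
  parents <- if (is.null(ref)) lapply(trfs$parents, sort) else
    lapply(seq_len(nrow(trfs)), function(i)
      parent_isoacceptors(trfs[i, , drop = FALSE], ref))
  out <- data.frame(
    trf_id = trfs$trf_id,
    major_type = trfs$type,
    subtype = subtype,
    is_half = subtype == "half",
    has_oligoG = detect_oligoG(trfs$sequence, min_run),
    stringsAsFactors = FALSE
  )
  out$parents <- parents
  out$orphan <- lengths(parents) == 0L
  out
}
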