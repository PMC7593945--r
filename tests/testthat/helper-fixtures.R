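# Deterministic toy fixtures and brute-force oracles. Oracles are written
# straight from the definitions (all-offsets scans, exhaustive breakpoint /
# label enumeration) and never call the code paths they check.

toy_genes <- function() {
  # Two Ala families whose matures share a 3' 18-mer (15 gene nt + CCA);
  # one Gly family with a unique 5' end.
  shared_tail <- "GGTTCGATTCCCGGC"            # 15 nt, mature suffix = this + CCA
  data.frame(
    gene_id = c("tRNA-Ala-TGC-1-1", "tRNA-Ala-CGC-1-1", "tRNA-Gly-GCC-1-1"),
    amino_acid = c("Ala", "Ala", "Gly"),
    anticodon = c("TGC", "CGC", "GCC"),
    sequence = c(
      paste0("GGGGCTATAGCTCAGCTGGGAGAGCGCCTGCTTTGCACGCAGGAGGTCTGCGGTTCGAT",
             shared_tail),
      paste0("GGGGATGTAGCTCAGTGGTAGAGCGCATGCTTCGCATGTATGAGGTCCCGGGTTCGATC",
             shared_tail),
      paste0("GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTC",
             "CCGGCCAATGCA")),
    is_mito = FALSE,
    stringsAsFactors = FALSE
  )
}

toy_reference <- function() {
  collapse_unique(build_mature(toy_genes()))
}

toy_trfs <- function() {
  mat <- build_mature(toy_genes())
  gly <- mat$sequence[mat$family == "Gly-GCC"]
  ala <- mat$sequence[mat$family == "Ala-TGC"]
  data.frame(
    trf_id = c("tRF-5001a", "tRF-3001a", "tRF-1001"),
    type = c("tRF-5", "tRF-3", "tRF-1"),
    sequence = c(substr(gly, 1, 15),
                 substr(ala, nchar(ala) - 17, nchar(ala)),
                 "CTAGCTAGCTAGTT"),
    parents = I(list("Gly-GCC", c("Ala-CGC", "Ala-TGC"), "Gly-GCC")),
    stringsAsFactors = FALSE
  )
}

random_reads <- function(n, len_range = c(20L, 60L)) {
  vapply(sample(len_range[1]:len_range[2], n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Literal range-table oracle for length-based subtyping.
oracle_subtype <- function(type, L) {
  if ((type == "tRF-5" || type == "tRF-3") && L > 30) return("half")
  if (type == "tRF-5") {
    if (L >= 14 && L <= 16) return("5a")
    if (L >= 22 && L <= 24) return("5b")
    if (L >= 28 && L <= 30) return("5c")
    return("unclassified")
  }
  if (type == "tRF-3") {
    if (L >= 17 && L <= 19) return("3a")
    if (L >= 21 && L <= 23) return("3b")
    return("unclassified")
  }
  if (L <= 40) "1" else "unclassified"
}

# All-offsets Hamming scan: which reference entries contain `read` as a
# substring with <= mm mismatches at some offset.
oracle_hamming_hits <- function(read, ref_seqs, mm) {
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(rch)
  which(vapply(ref_seqs, function(s) {
    n <- nchar(s)
    if (L > n) return(FALSE)
    sch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (off in 0:(n - L))
      if (sum(sch[(off + 1):(off + L)] != rch) <= mm) return(TRUE)
    FALSE
  }, logical(1), USE.NAMES = FALSE))
}

# Reference scanner for count_trnas: full per-sample count vector + ledger.
oracle_count_trnas <- function(seqs, ref, min_len, mm) {
  counts <- integer(nrow(ref))
  assigned <- ambiguous <- filtered <- 0L
  for (r in seqs) {
    if (nchar(r) < min_len) { filtered <- filtered + 1L; next }
    hits <- oracle_hamming_hits(r, ref$sequence, mm)
    if (length(hits) == 1L) { counts[hits] <- counts[hits] + 1L; assigned <- assigned + 1L }
    else if (length(hits) >= 2L) ambiguous <- ambiguous + 1L
  }
  list(counts = counts, assigned = assigned, ambiguous = ambiguous,
       filtered = filtered)
}

# Exhaustive two-sample KS statistic: max |F1 - F2| over pooled breakpoints.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Pooled-variance two-sided t, derived independently from the formula.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Exhaustive label-permutation p-value for the two-sample t statistic.
oracle_perm_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x)
  splits <- combn(length(v), n1)
  t_obs <- abs(oracle_student_t(x, y)["t"])
  t_all <- apply(splits, 2, function(i)
    abs(oracle_student_t(v[i], v[-i])["t"]))
  mean(t_all >= t_obs - 1e-12)
}
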