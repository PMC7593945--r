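#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA experiment generator. Defaults
#' emulate the study design the analysis is built for: 3 normal vs 5 tumor
#' libraries; a catalogue of 122 annotated tRFs (22 tRF-1, 48 tRF-3, 52
#' tRF-5); group-level tRF type composition of 7.51 / 52.55 / 39.94 percent
#' (tRF-1/-3/-5) in normal tissue and 1.01 / 24.77 / 74.22 in tumor;
#' log-normal baseline abundances with negative-binomial sampling noise.
#'
#' @param n_trna_families Number of isoacceptor families (one gene each).
#' @param n_trfs Named integer vector: fragments per major type.
#' @param n_mirnas Number of mature miRNAs.
#' @param n_normal,n_tumor Samples per group.
#' @param reads_per_sample Reads per sample within each feature class (the
#'   three classes model separately prepared, gel-excised libraries).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance
#'   parameters (relative scale; only proportions matter).
#' @param dispersion Negative-binomial size `k` (Var = mu + mu^2/k);
#'   larger is closer to Poisson, and `Inf` samples reads straight from the
#'   expected proportions (Poisson limit).
#' @param trf_type_props `list(normal = , tumor = )` of per-type sampling
#'   proportions (named `tRF-1`, `tRF-3`, `tRF-5`, summing to 1), or `NULL`
#'   to leave type mass to the baseline draw.
#' @param planted_effects `NULL` or data.frame with columns `feature_id`,
#'   `log2fc`: deterministic tumor-over-normal effects planted on chosen
#'   features.
#' @param error_rate Per-base substitution probability in emitted reads
#'   (0-0.2).
#' @param seed Integer master seed; every stage derives its stream from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_trna_families = 24L,
                       n_trfs = c("tRF-1" = 22L, "tRF-3" = 48L, "tRF-5" = 52L),
                       n_mirnas = 60L,
                       n_normal = 3L, n_tumor = 5L,
                       reads_per_sample = 100000L,
                       baseline_meanlog = 3, baseline_sdlog = 1.5,
                       dispersion = 10,
                       trf_type_props = list(
                         normal = c("tRF-1" = 0.0751, "tRF-3" = 0.5255,
                                    "tRF-5" = 0.3994),
                         tumor  = c("tRF-1" = 0.0101, "tRF-3" = 0.2477,
                                    "tRF-5" = 0.7422)),
                       planted_effects = NULL,
                       error_rate = 0,
                       seed = 1L) {
  cfg <- list(n_trna_families = as.integer(n_trna_families),
              n_trfs = n_trfs, n_mirnas = as.integer(n_mirnas),
              n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
              reads_per_sample = as.integer(reads_per_sample),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion,
              trf_type_props = trf_type_props,
              planted_effects = planted_effects,
              error_rate = error_rate, seed = as.integer(seed))
  stopifnot(cfg$n_trna_families >= 1L, all(cfg$n_trfs >= 0L),
            all(c("tRF-1", "tRF-3", "tRF-5") %in% names(cfg$n_trfs)),
            cfg$n_normal >= 1L, cfg$n_tumor >= 1L,
            cfg$reads_per_sample >= 1L, cfg$dispersion > 0)
  if (cfg$error_rate < 0 || cfg$error_rate > 0.2)
    stop("error_rate must lie in [0, 0.2]", call. = FALSE)
  if (!is.null(cfg$trf_type_props)) {
    for (g in c("normal", "tumor")) {
      p <- cfg$trf_type_props[[g]]
      stopifnot(!is.null(p), all(c("tRF-1", "tRF-3", "tRF-5") %in% names(p)))
      if (abs(sum(p) - 1) > 1e-6)
        stop("trf_type_props$", g, " must sum to 1", call. = FALSE)
    }
  }
  if (!is.null(cfg$planted_effects))
    stopifnot(is.data.frame(cfg$planted_effects),
              all(c("feature_id", "log2fc") %in% names(cfg$planted_effects)))
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, len) {
  vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic reference
#'
#' Builds a reference the pipeline can consume end-to-end: random tRNA gene
#' bodies (70-90 nt) with real anticodon/amino-acid metadata; tRF-5 records
#' that are prefixes of the mature sequences with lengths drawn from the
#' subtype windows; tRF-3 records that are suffixes (hence end CCA) from
#' their windows; tRF-1 trailer-like random fragments ending in at least two
#' T; and random mature miRNAs. All fragment and miRNA sequences are
#' pairwise distinct, so every generated tRF-5/tRF-3 validates CONSISTENT
#' against the collapsed reference by construction.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return List of class `sim_reference`: `genes`, `matures`, `ref`
#'   (collapsed), `trfs`, `mirnas`, `config`.
#' @export
make_reference <- function(config = sim_config(), seed = config$seed) {
  force(config); force(seed)   # lazy args must not fire after reseeding
  set.seed(stage_seed(seed, 1L))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anticodons <- sample(revcomp(sense), config$n_trna_families)
  aa1 <- unname(Biostrings::GENETIC_CODE[revcomp(anticodons)])
  aa3 <- unname(Biostrings::AMINO_ACID_CODE[aa1])

  repeat {
    bodies <- random_dna(config$n_trna_families,
                         sample(70:90, config$n_trna_families, replace = TRUE))
    if (!anyDuplicated(bodies)) break
  }
  genes <- data.frame(
    gene_id = sprintf("tRNA-%s-%s-1-1", aa3, anticodons),
    amino_acid = aa3, anticodon = anticodons, sequence = bodies,
    is_mito = FALSE, stringsAsFactors = FALSE
  )
  matures <- build_mature(genes)
  ref <- collapse_unique(matures)

  taken <- character(0)
  draw_distinct <- function(n, gen, what, max_tries = 1000L) {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      s <- gen()
      if (!s %in% taken) {
        out <- c(out, s); taken <<- c(taken, s)
      } else {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("requested more distinct ", what, " than realizable",
               call. = FALSE)
      }
    }
    out
  }

  mk_trf <- function(type, n) {
    if (n == 0L)
      return(data.frame(trf_id = character(0), type = character(0),
                        sequence = character(0), length = integer(0)))
    lens_pool <- switch(type,
                        "tRF-5" = c(14:16, 22:24, 28:30),
                        "tRF-3" = c(17:19, 21:23),
                        "tRF-1" = 14:20)
    seqs <- draw_distinct(n, function() {
      L <- sample(lens_pool, 1L)
      if (type == "tRF-1") {
        paste0(random_dna(1L, L - 2L), "TT")
      } else {
        m <- matures$sequence[sample.int(nrow(matures), 1L)]
        if (type == "tRF-5") substr(m, 1L, L)
        else substr(m, nchar(m) - L + 1L, nchar(m))
      }
    }, paste(type, "fragments"))
    L <- nchar(seqs)
    letter <- sub("^([35])", "", subtype_from_length(type, L))
    letter[letter %in% c("1", "unclassified", "half")] <- ""
    data.frame(
      trf_id = sprintf("%s%03d%s", type, seq_len(n), letter),
      type = type, sequence = seqs, length = L, stringsAsFactors = FALSE
    )
  }
  trfs <- rbind(mk_trf("tRF-5", config$n_trfs[["tRF-5"]]),
                mk_trf("tRF-3", config$n_trfs[["tRF-3"]]),
                mk_trf("tRF-1", config$n_trfs[["tRF-1"]]))
  trfs$parents <- lapply(seq_len(nrow(trfs)), function(i) {
    if (trfs$type[i] == "tRF-1")
      return(matures$family[sample.int(nrow(matures), 1L)])
    hit <- if (trfs$type[i] == "tRF-5") startsWith(ref$sequence, trfs$sequence[i])
           else endsWith(ref$sequence, trfs$sequence[i])
    sort(unique(unlist(ref$families[hit], use.names = FALSE)))
  })

  mirna_seqs <- draw_distinct(config$n_mirnas, function()
    random_dna(1L, sample(19:23, 1L)), "miRNAs")
  mirnas <- data.frame(
    mirna_id = sprintf("mir-sim-%03d", seq_len(config$n_mirnas)),
    sequence = mirna_seqs, length = nchar(mirna_seqs),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, matures = matures, ref = ref, trfs = trfs,
                 mirnas = mirnas, config = config),
            class = "sim_reference")
}

#' Draw per-sample molecule counts with group structure
#'
#' Per feature class: a log-normal baseline abundance is drawn once; group
#' means multiply in the planted tumor-over-normal effects (`2^log2fc`) and,
#' for tRFs, are rescaled within each major type so the group's type
#' composition matches `trf_type_props`. Each sample then receives exactly
#' `reads_per_sample` reads allocated by a gamma-Poisson (negative-binomial)
#' scheme: per-sample gamma intensities with shape `dispersion` around the
#' group mean, then a multinomial draw conditioned on the library size.
#'
#' @param simref A `sim_reference` from [make_reference()].
#' @param config Configuration (defaults to the one inside `simref`).
#' @param seed Master seed (defaults to `config$seed`).
#' @return List of class `sim_counts`: `counts` (list of feature x sample
#'   integer matrices for `tRF`, `tRNA`, `miRNA`), `truth` (list of
#'   data.frames with expected per-group proportions and planted log2fc),
#'   `design` (factor from [sample_design()]), `config`.
#' @export
simulate_counts <- function(simref, config = simref$config,
                            seed = config$seed) {
  force(simref); force(config); force(seed)
  set.seed(stage_seed(seed, 2L))
  samples <- c(sprintf("normal_%d", seq_len(config$n_normal)),
               sprintf("tumor_%d", seq_len(config$n_tumor)))
  groups <- rep(c("normal", "tumor"), c(config$n_normal, config$n_tumor))
  design <- sample_design(samples, groups)

  planted <- config$planted_effects
  class_features <- list(
    tRF = list(ids = simref$trfs$trf_id, type = simref$trfs$type),
    tRNA = list(ids = simref$ref$ref_id, type = NULL),
    miRNA = list(ids = simref$mirnas$mirna_id, type = NULL)
  )
  counts <- list(); truth <- list()
  for (cl in names(class_features)) {
    ids <- class_features[[cl]]$ids
    type <- class_features[[cl]]$type
    n <- length(ids)
    if (n == 0L) next
    w <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    l2fc <- rep(0, n)
    if (!is.null(planted)) {
      m <- match(ids, planted$feature_id)
      l2fc[!is.na(m)] <- planted$log2fc[m[!is.na(m)]]
    }
    mu <- list(normal = w, tumor = w * 2^l2fc)
    if (cl == "tRF" && !is.null(config$trf_type_props)) {
      for (g in c("normal", "tumor")) {
        p <- config$trf_type_props[[g]]
        for (tt in names(p)) {
          sel <- type == tt
          tot <- sum(mu[[g]][sel])
          if (tot > 0) mu[[g]][sel] <- mu[[g]][sel] * p[[tt]] / tot
        }
      }
    }
    mu <- lapply(mu, function(v) v / sum(v))
    cm <- matrix(0L, nrow = n, ncol = length(samples),
                 dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      m <- mu[[groups[j]]]
      # dispersion = Inf is the Poisson limit: reads sampled straight from
      # the expected proportions
      lambda <- if (is.infinite(config$dispersion)) m else
        stats::rgamma(n, shape = config$dispersion,
                      rate = config$dispersion / pmax(m, 1e-12))
      lambda[m == 0] <- 0
      cm[, j] <- stats::rmultinom(1L, config$reads_per_sample, lambda)[, 1L]
    }
    counts[[cl]] <- cm
    tr <- data.frame(feature_id = ids, prop_normal = mu$normal,
                     prop_tumor = mu$tumor, log2fc_planted = l2fc,
                     stringsAsFactors = FALSE)
    if (!is.null(type)) tr$type <- type
    truth[[cl]] <- tr
  }
  structure(list(counts = counts, truth = truth, design = design,
                 config = config),
            class = "sim_counts")
}

mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  n_mut <- stats::rbinom(length(seqs), len, error_rate)
  for (i in which(n_mut > 0L)) {
    pos <- sample.int(len[i], n_mut[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Materialize simulated reads in memory
#'
#' Expands a `sim_counts` object into per-sample read sets for each feature
#' class; every read is its source molecule's sequence with iid per-base
#' substitutions at `error_rate`. Source feature ids travel with the read
#' set (field `source`) for ground-truth checks.
#'
#' @param sim `sim_counts` from [simulate_counts()].
#' @param simref The `sim_reference` the counts were drawn for.
#' @param error_rate Per-base substitution rate (defaults to config).
#' @param seed Master seed (defaults to config).
#' @return Nested list: `reads[[class]][[sample_id]]` is a [read_set()].
#' @export
simulate_reads <- function(sim, simref, error_rate = sim$config$error_rate,
                           seed = sim$config$seed) {
  force(sim); force(simref); force(error_rate); force(seed)
  set.seed(stage_seed(seed, 3L))
  seq_of <- list(
    tRF = stats::setNames(simref$trfs$sequence, simref$trfs$trf_id),
    tRNA = stats::setNames(simref$ref$sequence, simref$ref$ref_id),
    miRNA = stats::setNames(simref$mirnas$sequence, simref$mirnas$mirna_id)
  )
  out <- list()
  for (cl in names(sim$counts)) {
    cm <- sim$counts[[cl]]
    out[[cl]] <- lapply(colnames(cm), function(s) {
      src <- rep(rownames(cm), cm[, s])
      rs <- read_set(mutate_seqs(unname(seq_of[[cl]][src]), error_rate), s)
      rs$source <- src
      rs
    })
    names(out[[cl]]) <- colnames(cm)
  }
  out
}

#' Write simulated reads as FASTQ files
#'
#' One file per feature class and sample
#' (`<class>_<sample>.fastq[.gz]`), constant quality, read ids encoding the
#' source molecule (`<sample>:<feature>:<serial>`) so truth is recoverable
#' from the files alone.
#'
#' @param sim `sim_counts` from [simulate_counts()].
#' @param simref Matching `sim_reference`.
#' @param dir Output directory (created if needed).
#' @param error_rate,seed Defaults from the configuration.
#' @param gzip Write gzipped FASTQ (default TRUE).
#' @return data.frame manifest: `class`, `sample_id`, `path`, `n_reads`.
#' @export
emit_fastq <- function(sim, simref, dir, error_rate = sim$config$error_rate,
                       seed = sim$config$seed, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reads <- simulate_reads(sim, simref, error_rate, seed)
  manifest <- NULL
  for (cl in names(reads)) {
    for (s in names(reads[[cl]])) {
      rs <- reads[[cl]][[s]]
      path <- file.path(dir, sprintf("%s_%s.fastq%s", cl, s,
                                     if (gzip) ".gz" else ""))
      x <- Biostrings::DNAStringSet(rs$sequences)
      names(x) <- sprintf("%s:%s:%d", s, rs$source, seq_along(rs$source))
      qual <- Biostrings::BStringSet(strrep("I", nchar(rs$sequences)))
      Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                  compress = gzip)
      manifest <- rbind(manifest, data.frame(
        class = cl, sample_id = s, path = path,
        n_reads = length(rs$sequences), stringsAsFactors = FALSE))
    }
  }
  manifest
}

#' Simulate a transfection-style gene fold-change table
#'
#' Gene-level log2 fold changes for a fragment-transfection experiment:
#' non-targets draw from N(0, sd), the chosen target genes get an
#' additional planted downward shift. Feeds [cdf_shift()].
#'
#' @param n_genes Total genes (default 2000).
#' @param n_targets Target-set size (default 200).
#' @param shift Planted downward shift in log2 units (default 1).
#' @param sd Baseline log2fc standard deviation (default 1).
#' @param seed Integer seed.
#' @return list with `gene_log2fc` (named numeric) and `targets`
#'   (character).
#' @export
simulate_transfection <- function(n_genes = 2000L, n_targets = 200L,
                                  shift = 1, sd = 1, seed = 1L) {
  stopifnot(n_targets < n_genes)
  force(shift); force(sd); force(seed)
  set.seed(stage_seed(seed, 4L))
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  l2fc <- stats::rnorm(n_genes, 0, sd)
  targets <- sample(genes, n_targets)
  l2fc[match(targets, genes)] <- l2fc[match(targets, genes)] - shift
  list(gene_log2fc = stats::setNames(l2fc, genes), targets = targets)
}

#' Generate a complete synthetic experiment on disk
#'
#' Writes the reference files (tRNA gene FASTA, miRNA FASTA, tRF table),
#' the sample design, per-sample FASTQ libraries, ground-truth tables and
#' run metadata into `dir`, in the same formats the pipeline reads.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param gzip Gzip the FASTQ files (default TRUE).
#' @return Invisible list with `paths`, `simref`, `sim`, `manifest`.
#' @export
simulate_experiment <- function(config = sim_config(), dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  simref <- make_reference(config)
  sim <- simulate_counts(simref, config)
  manifest <- emit_fastq(sim, simref, file.path(dir, "fastq"), gzip = gzip)

  paths <- list(
    trna_fasta = file.path(dir, "trna_genes.fa"),
    mirna_fasta = file.path(dir, "mirnas.fa"),
    trf_table = file.path(dir, "trfs.tsv"),
    design = file.path(dir, "design.tsv"),
    truth_dir = file.path(dir, "truth"),
    fastq_manifest = file.path(dir, "fastq_manifest.tsv"),
    metadata = file.path(dir, "run_metadata.yaml")
  )
  g <- Biostrings::DNAStringSet(simref$genes$sequence)
  names(g) <- simref$genes$gene_id
  Biostrings::writeXStringSet(g, paths$trna_fasta)
  m <- Biostrings::DNAStringSet(simref$mirnas$sequence)
  names(m) <- simref$mirnas$mirna_id
  Biostrings::writeXStringSet(m, paths$mirna_fasta)

  trf_out <- simref$trfs[, c("trf_id", "type", "sequence")]
  trf_out$parents <- join_col(simref$trfs$parents)
  write_tsv(trf_out, paths$trf_table)
  write_tsv(data.frame(sample_id = names(sim$design),
                       group = as.character(sim$design)), paths$design)
  dir.create(paths$truth_dir, showWarnings = FALSE)
  for (cl in names(sim$truth))
    write_tsv(sim$truth[[cl]], file.path(paths$truth_dir,
                                         paste0("truth_", cl, ".tsv")))
  write_tsv(manifest, paths$fastq_manifest)
  yaml::write_yaml(list(seed = config$seed,
                        error_rate = config$error_rate,
                        reads_per_sample = config$reads_per_sample,
                        n_normal = config$n_normal,
                        n_tumor = config$n_tumor),
                   paths$metadata)
  invisible(list(paths = paths, simref = simref, sim = sim,
                 manifest = manifest))
}
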