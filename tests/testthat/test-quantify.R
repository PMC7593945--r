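trf_fixture <- function() load_trf_table(toy_trfs())

test_that("exact tRF counting assigns reads equal to annotated sequences", {
  trfs <- trf_fixture()
  s <- trfs$sequence[1]
  rs <- read_set(c(rep(s, 3), "ACGTACGTACGTACGTACGT"), "s1")
  cm <- count_trfs(rs, trfs)
  expect_equal(unname(cm$counts[trfs$trf_id[1], "s1"]), 3L)
  expect_equal(cm$ledger$assigned, 3L)
  expect_equal(cm$ledger$unmatched, 1L)
})

test_that("3' poly-A stripping follows the trim_trailing_a budget", {
  trfs <- trf_fixture()
  s <- trfs$sequence[1]
  rs <- read_set(paste0(s, "AA"), "s1")
  hit0 <- count_trfs(rs, trfs, trim_trailing_a = 0L)
  hit2 <- count_trfs(rs, trfs, trim_trailing_a = 2L)
  expect_equal(sum(hit0$counts), 0L)
  expect_equal(unname(hit2$counts[trfs$trf_id[1], 1]), 1L)
  # stripping stops at non-A characters
  rs2 <- read_set(paste0(s, "GA"), "s1")
  expect_equal(sum(count_trfs(rs2, trfs, trim_trailing_a = 5L)$counts), 0L)
})

test_that("increasing the poly-A budget never decreases a count", {
  set.seed(11)
  trfs <- trf_fixture()
  tails <- vapply(sample(0:3, 40, replace = TRUE),
                  function(k) strrep("A", k), character(1))
  rs <- read_set(paste0(sample(trfs$sequence, 40, replace = TRUE), tails), "s1")
  prev <- count_trfs(rs, trfs, trim_trailing_a = 0L)$counts
  for (k in 1:4) {
    cur <- count_trfs(rs, trfs, trim_trailing_a = k)$counts
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("contained mode resolves nested fragments to the longest match", {
  # a 20-mer fragment and its own 18-mer prefix, both annotated
  long <- "GCATTGGTGGTTCAGTGGTA"
  trfs <- data.frame(
    trf_id = c("tRF-5002a", "tRF-5001a"),
    type = "tRF-5",
    sequence = c(long, substr(long, 1, 18)),
    parents = I(list("Gly-GCC", "Gly-GCC")),
    stringsAsFactors = FALSE)
  read <- paste0("TT", long, "CCAAGG")  # contains both candidates

  # oracle: enumerate every fragment occurring as a substring, pick longest
  cand <- trfs[vapply(trfs$sequence, grepl, logical(1), x = read,
                      fixed = TRUE), ]
  expected <- cand$trf_id[order(-nchar(cand$sequence), cand$trf_id)][1]
  expect_equal(expected, "tRF-5002a")

  cm <- count_trfs(read_set(read, "s1"), trfs, mode = "contained")
  expect_equal(unname(cm$counts[expected, 1]), 1L)
  expect_equal(sum(cm$counts), 1L)   # one read, one count

  # tie on length -> lexicographically smallest id
  tie <- data.frame(trf_id = c("tRF-5009a", "tRF-5002a"), type = "tRF-5",
                    sequence = c("AAAACCCCGGGGTT", "TTGGGGCCCCAAAA"),
                    parents = I(list(character(0), character(0))),
                    stringsAsFactors = FALSE)
  read2 <- paste0(tie$sequence[1], tie$sequence[2])
  cm2 <- count_trfs(read_set(read2, "s1"), tie, mode = "contained")
  expect_equal(unname(cm2$counts["tRF-5002a", 1]), 1L)
})

test_that("duplicate annotation sequences abort counting", {
  trfs <- trf_fixture()
  trfs2 <- rbind(trfs, trfs[1, ])
  trfs2$trf_id[4] <- "tRF-5099a"
  expect_error(count_trfs(read_set("ACGT", "s1"), trfs2), "duplicate")
  m <- data.frame(mirna_id = c("a", "b"),
                  sequence = rep("TAGCTTATCAGACTGATGTTGA", 2))
  expect_error(count_mirnas(read_set("ACGT", "s1"), m), "duplicate")
})

test_that("tRNA counting filters short reads and discards ambiguous ones", {
  ref <- toy_reference()
  gly <- ref$sequence[vapply(ref$families, function(f) "Gly-GCC" %in% f,
                             logical(1))]
  reads <- c(substr(gly, 1, 39),    # one nt short of the intact filter
             substr(gly, 10, 49))   # 40 nt, unique to the Gly entry
  # ambiguity needs a >= 40-nt stretch shared by two entries: build one
  ref2 <- data.frame(ref_id = c("e1", "e2"),
                     sequence = c(paste0(strrep("A", 20), strrep("C", 45)),
                                  paste0(strrep("G", 20), strrep("C", 45))),
                     stringsAsFactors = FALSE)
  ref2$members <- list("e1", "e2")
  ref2$families <- list("Ala-TGC", "Ala-CGC")
  amb <- strrep("C", 45)

  cm <- count_trnas(read_set(reads, "s1"), ref)
  expect_equal(cm$ledger$filtered, 1L)
  expect_equal(cm$ledger$assigned, 1L)
  gly_id <- ref$ref_id[vapply(ref$families, function(f) "Gly-GCC" %in% f,
                              logical(1))]
  expect_equal(unname(cm$counts[gly_id, 1]), 1L)

  cm2 <- count_trnas(read_set(amb, "s1"), ref2)
  expect_equal(cm2$ledger$ambiguous, 1L)
  expect_equal(sum(cm2$counts), 0L)

  expect_error(count_trnas(read_set("A", "s1"), ref2[0, ]), "empty")
})

test_that("tRNA counting matches the brute-force Hamming scanner", {
  set.seed(42)
  for (mm in 0:2) {
    ref_seqs <- random_reads(12, c(60L, 80L))
    ref <- data.frame(ref_id = sprintf("e%02d", seq_along(ref_seqs)),
                      sequence = ref_seqs, stringsAsFactors = FALSE)
    ref$members <- as.list(ref$ref_id)
    ref$families <- as.list(rep("Gly-GCC", nrow(ref)))
    # mix of planted substrings (with noise) and random reads
    planted <- vapply(1:40, function(i) {
      s <- ref_seqs[sample.int(length(ref_seqs), 1)]
      L <- sample(40:55, 1)
      off <- sample.int(nchar(s) - L + 1L, 1)
      r <- substr(s, off, off + L - 1L)
      if (runif(1) < 0.5) {
        p <- sample.int(L, 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    }, character(1))
    seqs <- c(planted, random_reads(20, c(35L, 50L)))
    cm <- count_trnas(read_set(seqs, "s1"), ref, min_read_len = 40L,
                      max_mismatches = mm)
    orc <- oracle_count_trnas(seqs, ref, 40L, mm)
    expect_equal(unname(cm$counts[, 1]), orc$counts)
    expect_equal(cm$ledger$assigned, orc$assigned)
    expect_equal(cm$ledger$ambiguous, orc$ambiguous)
    expect_equal(cm$ledger$filtered, orc$filtered)
  }
})

test_that("the per-sample ledger is conserved exactly", {
  set.seed(3)
  trfs <- trf_fixture()
  reads <- c(sample(trfs$sequence, 30, replace = TRUE), random_reads(20))
  cm <- count_trfs(read_set(reads, "s1"), trfs)
  with(cm$ledger,
       expect_equal(assigned + ambiguous + filtered + unmatched, total))
  ref <- toy_reference()
  cm2 <- count_trnas(read_set(reads, "s1"), ref)
  with(cm2$ledger,
       expect_equal(assigned + ambiguous + filtered + unmatched, total))
})

test_that("miRNA counting is exact by default", {
  m <- data.frame(mirna_id = c("mir-a", "mir-b"),
                  sequence = c("TAGCTTATCAGACTGATGTTGA",
                               "AAGCTGCCAGTTGAAGAACTGT"),
                  stringsAsFactors = FALSE)
  one_off <- paste0("G", substr(m$sequence[1], 2, 22))
  rs <- read_set(c(rep(m$sequence[1], 10), one_off), "s1")
  cm <- count_mirnas(rs, m)
  expect_equal(unname(cm$counts["mir-a", 1]), 10L)
  expect_equal(cm$ledger$unmatched, 1L)
})

test_that("RPM columns sum to one million and honor the denominator policy", {
  trfs <- trf_fixture()
  rs <- list(read_set(c(rep(trfs$sequence[1], 7), random_reads(63)), "s1"),
             read_set(rep(trfs$sequence[2], 5), "s2"))
  cm <- count_trfs(rs, trfs)
  r <- rpm(cm)
  expect_equal(unname(colSums(r$values)), c(1e6, 1e6))
  # count 7 out of a class total of 7 assigned -> 1e6; library total 70 -> 1e5
  expect_equal(unname(r$values[trfs$trf_id[1], "s1"]), 1e6)
  rl <- rpm(cm, denominator = "library")
  expect_equal(unname(rl$values[trfs$trf_id[1], "s1"]), 7 / 70 * 1e6)

  empty <- read_set(random_reads(5), "s3")
  cm0 <- count_trfs(empty, trfs)
  expect_warning(r0 <- rpm(cm0), "zero denominator")
  expect_true(all(r0$values == 0))
})
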