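rpm_fixture <- function(values, features = NULL) {
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  rownames(values) <- features
  colnames(values) <- c(sprintf("n%d", 1:3), sprintf("t%d", 1:5))[seq_len(ncol(values))]
  values
}

design_35 <- function() sample_design(c(sprintf("n%d", 1:3), sprintf("t%d", 1:5)),
                                      rep(c("normal", "tumor"), c(3, 5)))

test_that("fold change is the ratio of plain group means", {
  mat <- rpm_fixture(rbind(c(5, 5, 5, 10, 10, 10, 10, 10)))
  d <- diff_expression(mat, design_35())
  expect_equal(d$mean_normal, 5)
  expect_equal(d$mean_tumor, 10)
  expect_equal(d$fc, 2)
  expect_equal(d$log2fc, 1)
})

test_that("identical groups give t = 0, p = 1, not significant", {
  mat <- rpm_fixture(rbind(rep(7, 8)))
  d <- diff_expression(mat, design_35())
  expect_equal(d$t_stat, 0)
  expect_equal(d$p_value, 1)
  expect_false(d$significant)
})

test_that("the Student t matches an independent pooled-variance derivation", {
  x <- c(8, 10, 12); y <- c(4, 5, 6)
  mat <- matrix(c(y, x), nrow = 1,
                dimnames = list("f1", c("n1", "n2", "n3", "t1", "t2", "t3")))
  des <- sample_design(colnames(mat), rep(c("normal", "tumor"), each = 3))
  d <- diff_expression(mat, des)
  orc <- oracle_student_t(x, y)
  expect_equal(d$t_stat, unname(orc["t"]))
  expect_equal(d$p_value, unname(orc["p"]))
  # and the exhaustive label-permutation reference agrees this is the most
  # extreme split
  expect_equal(oracle_perm_p(x, y), 2 / 20)
})

test_that("t p-values rank like the exhaustive permutation oracle", {
  # growing shifts over a fixed base: both the t p and the exhaustive
  # label-permutation p must order the features identically (permutation p
  # is granular at 1/20, so ties there carry no ordering information)
  base <- c(4, 5.5, 6)
  deltas <- c(0.3, 2, 8)
  mat <- do.call(rbind, lapply(deltas, function(d) c(base, base + d)))
  dimnames(mat) <- list(sprintf("f%d", seq_along(deltas)),
                        c("n1", "n2", "n3", "t1", "t2", "t3"))
  des <- sample_design(colnames(mat), rep(c("normal", "tumor"), each = 3))
  d <- diff_expression(mat, des)
  perm <- apply(mat, 1, function(v) oracle_perm_p(v[4:6], v[1:3]))
  expect_true(all(diff(d$p_value) < 0))       # strictly more significant
  expect_true(all(diff(perm) <= 0))           # permutation p agrees in rank
  for (i in seq_along(deltas)) for (j in seq_along(deltas))
    if (perm[i] < perm[j]) expect_lt(d$p_value[i], d$p_value[j])
})

test_that("zero group means fall back to the pseudo-value ratio", {
  mat <- rpm_fixture(rbind(c(0, 0, 0, 9.5, 9.5, 9.5, 9.5, 9.5)))
  d <- diff_expression(mat, design_35(), pseudo = 0.5)
  expect_equal(d$fc, 10 / 0.5)
  d2 <- diff_expression(mat, design_35(), pseudo = 1)
  expect_equal(d2$fc, 10.5 / 1)
})

test_that("single-sample groups report missing p but keep fold change", {
  mat <- matrix(c(4, 8), nrow = 1, dimnames = list("f1", c("n1", "t1")))
  des <- sample_design(c("n1", "t1"), c("normal", "tumor"))
  d <- diff_expression(mat, des)
  expect_true(is.na(d$p_value))
  expect_false(d$significant)
  expect_equal(d$fc, 2)
})

test_that("swapping group labels negates log2fc and preserves p", {
  set.seed(21)
  mat <- rpm_fixture(matrix(rlnorm(10 * 8, 4, 1), nrow = 10))
  des <- design_35()
  swapped <- sample_design(names(des),
                           ifelse(des == "normal", "tumor", "normal"))
  d1 <- diff_expression(mat, des)
  d2 <- diff_expression(mat, swapped)
  expect_equal(d2$log2fc, -d1$log2fc)
  expect_equal(d2$p_value, d1$p_value)
})

test_that("Welch variant and BH adjustment are available behind flags", {
  set.seed(13)
  mat <- rpm_fixture(matrix(rlnorm(5 * 8, 4, 1), nrow = 5))
  d <- diff_expression(mat, design_35(), test = "welch", p_adjust = TRUE)
  expect_true("p_adj" %in% names(d))
  expect_equal(d$p_adj, p.adjust(d$p_value, "BH"))
  v <- mat[1, ]
  wt <- t.test(v[4:8], v[1:3])
  expect_equal(d$t_stat[1], unname(wt$statistic))
  expect_equal(d$p_value[1], wt$p.value)
})

test_that("heatmap export is log2 over the normal-group mean", {
  mat <- rpm_fixture(rbind(c(10, 10, 10, 20, 20, 20, 20, 20),
                           rep(0, 8)))
  hm <- heatmap_matrix(mat, design_35(), eps = 0.5)
  expect_equal(unname(hm[1, "n1"]), 0)
  expect_equal(unname(hm[1, "t1"]), log2(20.5 / 10.5))
  expect_equal(unname(hm[2, ]), rep(0, 8), ignore_attr = TRUE)
})

test_that("type distribution sums to 100 and matches toy proportions", {
  trfs <- data.frame(
    trf_id = c("tRF-3001a", "tRF-5001a", "tRF-1001"),
    major_type = c("tRF-3", "tRF-5", "tRF-1"), stringsAsFactors = FALSE)
  counts <- matrix(c(5, 4, 1, 50, 40, 10), ncol = 2,
                   dimnames = list(trfs$trf_id, c("n1", "t1")))
  cm <- structure(list(counts = counts, feature_class = "tRF",
                       ledger = NULL), class = "count_matrix")
  des <- sample_design(c("n1", "t1"), c("normal", "tumor"))
  td <- type_distribution(cm, trfs, des)
  expect_equal(td$percent[td$group == "normal"], c(10, 50, 40))
  expect_equal(as.numeric(tapply(td$percent, td$group, sum)), c(100, 100))
  # depth rescaling within a group with fixed proportions changes nothing
  counts2 <- counts; counts2[, "t1"] <- counts2[, "t1"] * 7L
  cm2 <- structure(list(counts = counts2, feature_class = "tRF",
                        ledger = NULL), class = "count_matrix")
  expect_equal(type_distribution(cm2, trfs, des)$percent, td$percent)

  single <- cm
  single$counts[, "n1"] <- c(12L, 0L, 0L)
  expect_equal(type_distribution(single, trfs, des)$percent[
    td$group == "normal"], c(0, 100, 0))
  zero <- cm
  zero$counts[, "n1"] <- 0L
  expect_error(type_distribution(zero, trfs, des), "zero tRF reads")
})

test_that("codon aggregation sums families and calls status by ratio", {
  ref <- data.frame(ref_id = c("g1", "g2", "v1"), stringsAsFactors = FALSE)
  ref$sequence <- c("x", "y", "z")
  ref$members <- list("g1", "g2", "v1")
  ref$families <- list("Gly-GCC", "Gly-GCC", "Val-CAC")
  mat <- matrix(c(10, 6, 5,    # n1: g1, g2, v1
                  30, 2, 6),   # t1
                ncol = 2, dimnames = list(ref$ref_id, c("n1", "t1")))
  des <- sample_design(c("n1", "t1"), c("normal", "tumor"))
  cp <- codon_aggregate(mat, ref, des)
  ggc <- cp[cp$codon == "GGC", ]
  expect_equal(ggc$sum_normal, 16)
  expect_equal(ggc$sum_tumor, 32)
  expect_equal(ggc$status, "up")
  gug <- cp[cp$codon == "GUG", ]          # Val-CAC decodes GUG
  expect_equal(gug$ratio, 1.2)
  expect_equal(gug$status, "unaltered")
  # statuses partition the 64-codon universe; absent codons dominate the toy
  expect_equal(nrow(cp), 64L)
  expect_true(all(cp$status %in% c("up", "down", "unaltered", "absent")))
  expect_equal(sum(cp$status != "absent"), 2L)
  # stop codons can only be absent
  expect_true(all(cp$status[cp$amino_acid == "*"] == "absent"))
})

test_that("2^-ddCt relative quantification", {
  expect_equal(ddct(20, 18, 22, 18), 4)
  expect_equal(ddct(25, 20, 25, 20), 1)
  expect_equal(ddct(25, 20, 24, 20), 0.5)
  expect_error(ddct(NA, 20, 24, 20), "finite")
})
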