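#' Define a two-group sample design
#'
#' Maps sample ids to groups. The first level of `levels` is the reference
#' group (normal / control); fold changes are case over reference.
#'
#' @param sample_ids Character vector.
#' @param groups Character vector, same length.
#' @param levels Group levels, reference first (default
#'   `c("normal", "tumor")`).
#' @return Named factor (names are sample ids).
#' @export
sample_design <- function(sample_ids, groups, levels = c("normal", "tumor")) {
  stopifnot(length(sample_ids) == length(groups))
  if (!all(groups %in% levels))
    stop("groups must be among: ", paste(levels, collapse = ", "), call. = FALSE)
  f <- factor(groups, levels = levels)
  if (any(table(f) == 0L))
    stop("each group needs at least one sample", call. = FALSE)
  names(f) <- sample_ids
  f
}

design_split <- function(mat, design) {
  if (!all(colnames(mat) %in% names(design)))
    stop("samples missing from design: ",
         paste(setdiff(colnames(mat), names(design)), collapse = ", "),
         call. = FALSE)
  g <- design[colnames(mat)]
  list(ref = which(g == levels(design)[1]), case = which(g == levels(design)[2]))
}

#' Group-wise differential representation of RPM values
#'
#' For every feature: arithmetic mean RPM per group, fold change (case over
#' reference), log2 fold change, and a two-sided unpaired t test on the RPM
#' values (Student pooled-variance by default; Welch behind the flag). When
#' either group mean is zero the fold change uses
#' `(mean + pseudo) / (mean + pseudo)` with a pseudo-RPM on both means;
#' otherwise the plain ratio. A p-value requires at least two samples per
#' group, else it is `NA`. Identical values in both groups give `t = 0`,
#' `p = 1`.
#'
#' @param rpm An `rpm_matrix` (or plain features x samples matrix).
#' @param design Factor from [sample_design()].
#' @param test `"student"` (default) or `"welch"`.
#' @param alpha Significance level (default 0.05, on the raw p-value).
#' @param pseudo Pseudo-RPM used when a group mean is zero (default 0.5).
#' @param p_adjust If TRUE, add a Benjamini-Hochberg adjusted column
#'   `p_adj` (significance still uses the raw p, as reported).
#' @return data.frame of class `c("diff_result","data.frame")` with columns
#'   `feature_id`, `mean_normal`, `mean_tumor`, `fc`, `log2fc`, `t_stat`,
#'   `p_value`, `significant`.
#' @export
diff_expression <- function(rpm, design, test = c("student", "welch"),
                            alpha = 0.05, pseudo = 0.5, p_adjust = FALSE) {
  test <- match.arg(test)
  mat <- rpm_values(rpm)
  idx <- design_split(mat, design)
  n1 <- length(idx$ref); n2 <- length(idx$case)
  if (n1 == 0L || n2 == 0L) stop("both groups need samples", call. = FALSE)

  m_ref <- rowMeans(mat[, idx$ref, drop = FALSE])
  m_case <- rowMeans(mat[, idx$case, drop = FALSE])
  fc <- ifelse(m_ref == 0 | m_case == 0,
               (m_case + pseudo) / (m_ref + pseudo),
               m_case / m_ref)

  tp <- t(apply(mat, 1L, function(v)
    t_unpaired(v[idx$case], v[idx$ref], pooled = test == "student")))
  p <- tp[, 2L]
  out <- data.frame(
    feature_id = rownames(mat),
    mean_normal = m_ref, mean_tumor = m_case,
    fc = fc, log2fc = log2(fc),
    t_stat = tp[, 1L], p_value = p,
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "pseudo") <- pseudo
  attr(out, "test") <- test
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_result", "data.frame")
  out
}

# Two-sided unpaired t; returns c(t, p). Degenerate inputs (fewer than 2
# samples in a group -> no test; zero variance -> t of 0 or +/-Inf) are
# resolved here so callers never see stats::t.test()'s constant-data error.
t_unpaired <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L) return(c(NA_real_, NA_real_))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(c(0, 1))
    return(c(sign(mean(x) - mean(y)) * Inf, 0))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  c(unname(ht$statistic), ht$p.value)
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("<diff_result> %d features, %s t test, alpha=%g, %d significant\n",
              nrow(x), attr(x, "test"), attr(x, "alpha"), sum(x$significant)))
  NextMethod()
}

#' Per-sample log2 ratios for heatmap export
#'
#' value(feature, sample) = log2((rpm + eps) / (mean normal rpm + eps)):
#' every sample, normal ones included, is shown against the mean of the
#' normal group.
#'
#' @inheritParams diff_expression
#' @param eps Stabilizer added to numerator and denominator (default 0.5).
#' @return Numeric matrix, features x samples.
#' @export
heatmap_matrix <- function(rpm, design, eps = 0.5) {
  mat <- rpm_values(rpm)
  idx <- design_split(mat, design)
  m_ref <- rowMeans(mat[, idx$ref, drop = FALSE])
  log2((mat + eps) / (m_ref + eps))
}

#' Per-group tRF type distribution
#'
#' Percentage of tRF-assigned reads in each major type (tRF-1 / tRF-3 /
#' tRF-5), computed on read counts summed across each group's samples.
#'
#' @param counts `count_matrix` of tRF counts.
#' @param calls Classification table from [classify_trfs()] (needs
#'   `trf_id`, `major_type`).
#' @param design Factor from [sample_design()].
#' @return data.frame with columns `group`, `type`, `percent`; percentages
#'   sum to 100 within each group.
#' @export
type_distribution <- function(counts, calls, design) {
  stopifnot(inherits(counts, "count_matrix"))
  mat <- counts$counts
  miss <- setdiff(rownames(mat), calls$trf_id)
  if (length(miss) > 0L)
    stop("counted tRFs without a type call: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  type <- calls$major_type[match(rownames(mat), calls$trf_id)]
  g <- design[colnames(mat)]
  types <- c("tRF-1", "tRF-3", "tRF-5")
  out <- do.call(rbind, lapply(levels(design), function(lev) {
    tot <- rowsum(rowSums(mat[, g == lev, drop = FALSE]), type)
    by_type <- tot[match(types, rownames(tot)), 1L]
    by_type[is.na(by_type)] <- 0
    if (sum(by_type) == 0)
      stop("group '", lev, "' has zero tRF reads", call. = FALSE)
    data.frame(group = lev, type = types,
               percent = 100 * by_type / sum(by_type),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate tRNA abundance at the codon level
#'
#' Sums RPM over reference entries whose isoacceptor anticodon decodes the
#' same codon, per group (group means of RPM, summed within the group's
#' codon), and calls each of the 64 codons up / down / unaltered / absent
#' from the case-over-reference ratio of the summed values. The up/down
#' thresholds are explicit tool defaults (1.5-fold), not literature values.
#' Stop codons have no cognate cytoplasmic tRNA and are always reported
#' absent.
#'
#' @param trna_rpm `rpm_matrix` of tRNA abundance (rows = `ref_id` of the
#'   collapsed reference).
#' @param ref Collapsed reference from [collapse_unique()] (provides the
#'   anticodon of each entry's family).
#' @param design Factor from [sample_design()].
#' @param up_fc,down_fc Ratio thresholds (defaults 1.5 and 1/1.5).
#' @return data.frame with one row per codon: `codon` (RNA alphabet),
#'   `amino_acid`, `sum_normal`, `sum_tumor`, `ratio`, `status`.
#' @export
codon_aggregate <- function(trna_rpm, ref, design, up_fc = 1.5,
                            down_fc = 1 / 1.5) {
  mat <- rpm_values(trna_rpm)
  idx <- design_split(mat, design)
  m_ref <- rowMeans(mat[, idx$ref, drop = FALSE])
  m_case <- rowMeans(mat[, idx$case, drop = FALSE])

  # one anticodon per entry: first declared family (multi-family entries
  # share the anticodon by construction of family names)
  fam <- vapply(ref$families[match(rownames(mat), ref$ref_id)],
                `[`, character(1), 1L)
  anticodon <- sub("^.*-", "", fam)
  codon <- anticodon_to_codon(anticodon)$codon

  universe <- data.frame(codon = dna_to_rna(names(Biostrings::GENETIC_CODE)),
                         amino_acid = unname(Biostrings::GENETIC_CODE),
                         stringsAsFactors = FALSE)
  s_ref <- tapply(m_ref, codon, sum)
  s_case <- tapply(m_case, codon, sum)
  out <- data.frame(
    codon = universe$codon, amino_acid = universe$amino_acid,
    sum_normal = unname(s_ref[universe$codon]),
    sum_tumor = unname(s_case[universe$codon]),
    stringsAsFactors = FALSE
  )
  out$sum_normal[is.na(out$sum_normal)] <- 0
  out$sum_tumor[is.na(out$sum_tumor)] <- 0
  out$ratio <- ifelse(out$sum_normal > 0, out$sum_tumor / out$sum_normal,
                      ifelse(out$sum_tumor > 0, Inf, NA_real_))
  out$status <- ifelse(out$sum_normal == 0 & out$sum_tumor == 0, "absent",
                ifelse(out$ratio >= up_fc, "up",
                ifelse(out$ratio <= down_fc, "down", "unaltered")))
  is_stop <- out$amino_acid == "*"
  if (any(is_stop & out$status != "absent"))
    warning("reads assigned to a stop codon (selenocysteine decoding?); ",
            "reported absent", call. = FALSE)
  out$status[is_stop] <- "absent"
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,control -
#' Ct_ref,control); the returned fold change is 2^-ddCt.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (finite numerics; vectors are recycled elementwise).
#' @return Numeric fold change(s).
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
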