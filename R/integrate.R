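#' Intersect detected tRFs with an AGO-association list
#'
#' Returns the detected fragments reported as Argonaute-loaded (putative
#' miRNA-like silencers) and the fraction of detected fragments they
#' represent. The denominator is the full detected set passed in, exposed
#' explicitly rather than assumed.
#'
#' @param detected Character vector of detected tRF ids (or a tRF table /
#'   classification data.frame with a `trf_id` column).
#' @param ago Character vector of AGO-loaded tRF ids.
#' @return list with `subset` (character), `fraction`, `n_detected`,
#'   `n_ago`.
#' @export
filter_ago <- function(detected, ago) {
  if (is.data.frame(detected)) detected <- detected$trf_id
  if (length(ago) == 0L) stop("empty AGO list", call. = FALSE)
  detected <- unique(detected)
  subset <- detected[detected %in% ago]
  list(subset = subset,
       fraction = if (length(detected) == 0L) NA_real_
                  else length(subset) / length(detected),
       n_detected = length(detected), n_ago = length(unique(ago)))
}

#' ECDF shift between target and non-target gene fold changes
#'
#' Two-sample Kolmogorov-Smirnov comparison of the log2 fold-change
#' distributions of a fragment's target genes versus all other genes: the
#' standard readout for miRNA-like repression, where a left-shifted target
#' CDF indicates fragment-mediated downregulation. Medians are always
#' co-reported, and the pooled ECDF coordinates are exported for plotting.
#'
#' @param gene_log2fc Named numeric vector: gene -> log2 fold change.
#' @param targets Character vector of target gene ids; must leave both
#'   strata non-empty after intersection with `names(gene_log2fc)`.
#' @param exact Passed to [stats::ks.test()]; default `FALSE` (asymptotic
#'   p-value).
#' @return Object of class `cdf_shift`: `n_targets`, `n_nontargets`,
#'   `median_targets`, `median_nontargets`, `ks_D`, `p_value`, and `ecdf`
#'   (data.frame `value`, `F_targets`, `F_nontargets`).
#' @export
cdf_shift <- function(gene_log2fc, targets, exact = FALSE) {
  stopifnot(is.numeric(gene_log2fc), !is.null(names(gene_log2fc)))
  is_t <- names(gene_log2fc) %in% targets
  x <- gene_log2fc[is_t]; y <- gene_log2fc[!is_t]
  if (length(x) == 0L) stop("empty target stratum", call. = FALSE)
  if (length(y) == 0L) stop("empty non-target stratum", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  grid <- sort(unique(c(x, y)))
  structure(list(
    n_targets = length(x), n_nontargets = length(y),
    median_targets = stats::median(x), median_nontargets = stats::median(y),
    ks_D = unname(ks$statistic), p_value = ks$p.value,
    ecdf = data.frame(value = grid,
                      F_targets = stats::ecdf(x)(grid),
                      F_nontargets = stats::ecdf(y)(grid))
  ), class = "cdf_shift")
}

#' @export
print.cdf_shift <- function(x, ...) {
  cat(sprintf(paste0("<cdf_shift> %d targets vs %d non-targets: D = %.4f, ",
                     "p = %.3g\n  median log2FC %.3f (targets) vs %.3f ",
                     "(non-targets)\n"),
              x$n_targets, x$n_nontargets, x$ks_D, x$p_value,
              x$median_targets, x$median_nontargets))
  invisible(x)
}

#' Plot a CDF-shift result
#'
#' Empirical CDFs of target and non-target log2 fold changes.
#'
#' @param x A `cdf_shift` object.
#' @param ... Passed to [plot()].
#' @export
plot.cdf_shift <- function(x, ...) {
  plot(x$ecdf$value, x$ecdf$F_nontargets, type = "s", col = "steelblue",
       xlab = "log2 fold change", ylab = "cumulative fraction", ylim = c(0, 1),
       ...)
  graphics::lines(x$ecdf$value, x$ecdf$F_targets, type = "s", col = "darkorange")
  graphics::legend("topleft", legend = c("targets", "non-targets"),
                   col = c("darkorange", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Significantly repressed genes within a fragment's target set
#'
#' Intersects the significantly downregulated genes (p below `alpha` and
#' negative log2 fold change) with the experimentally supported (CLASH)
#' target set of one fragment.
#'
#' @param diff `diff_result` from [diff_expression()] on gene-level data.
#' @param targets Named list: tRF id -> character vector of gene ids.
#' @param trf_id The fragment to interrogate.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of repressed target genes.
#' @export
repressed_target_genes <- function(diff, targets, trf_id, alpha = 0.05) {
  if (!trf_id %in% names(targets))
    stop("unknown trf_id: ", trf_id, call. = FALSE)
  down <- diff$feature_id[!is.na(diff$p_value) & diff$p_value < alpha &
                            diff$log2fc < 0]
  sort(intersect(down, targets[[trf_id]]))
}

#' Reciprocal tRNA-down / tRF-up pairs
#'
#' Emits (isoacceptor family, tRF) pairs where the family-summed tRNA fold
#' change falls at or below `trna_down` while a cognate fragment's fold
#' change is at or above `trf_up`: the signature of fragments accumulating
#' as their parent tRNA declines.
#'
#' @param trna_diff `diff_result` at the isoacceptor-family level
#'   (`feature_id` = family, e.g. from [aggregate_family_rpm()]).
#' @param trf_diff `diff_result` for tRFs.
#' @param parent_map data.frame with columns `trf_id`, `family` (one row
#'   per tRF-family link), e.g. from [parent_map_from_calls()].
#' @param trna_down,trf_up Fold-change thresholds (defaults 1/1.5 and 1.5).
#' @return data.frame `family`, `trf_id`, `trna_fc`, `trf_fc`, sorted by
#'   `trf_fc` descending.
#' @export
reciprocal_pairs <- function(trna_diff, trf_diff, parent_map,
                             trna_down = 1 / 1.5, trf_up = 1.5) {
  stopifnot(all(c("trf_id", "family") %in% names(parent_map)))
  trna_fc <- trna_diff$fc[match(parent_map$family, trna_diff$feature_id)]
  trf_fc <- trf_diff$fc[match(parent_map$trf_id, trf_diff$feature_id)]
  keep <- !is.na(trna_fc) & !is.na(trf_fc) &
    trna_fc <= trna_down & trf_fc >= trf_up
  out <- data.frame(family = parent_map$family[keep],
                    trf_id = parent_map$trf_id[keep],
                    trna_fc = trna_fc[keep], trf_fc = trf_fc[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$trf_fc, out$trf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum tRNA RPM per isoacceptor family
#'
#' tRF parents resolve to isoacceptor families, not loci, so reciprocal
#' analysis works on family-summed abundance. Multi-family entries
#' contribute to each of their families.
#'
#' @param trna_rpm `rpm_matrix` over collapsed reference entries.
#' @param ref Collapsed reference from [collapse_unique()].
#' @return Plain numeric matrix, families x samples.
#' @export
aggregate_family_rpm <- function(trna_rpm, ref) {
  mat <- rpm_values(trna_rpm)
  fams <- ref$families[match(rownames(mat), ref$ref_id)]
  long_i <- rep(seq_len(nrow(mat)), lengths(fams))
  long_f <- unlist(fams, use.names = FALSE)
  rowsum(mat[long_i, , drop = FALSE], long_f)
}

#' Flatten a classification table into a tRF-family link map
#'
#' @param calls data.frame from [classify_trfs()].
#' @return data.frame with columns `trf_id`, `family`.
#' @export
parent_map_from_calls <- function(calls) {
  data.frame(trf_id = rep(calls$trf_id, lengths(calls$parents)),
             family = unlist(calls$parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}
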