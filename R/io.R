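# TSV conventions: tab-separated, '#' metadata headers, no quoting, no row
# names. All pipeline outputs funnel through write_tsv so reruns are
# byte-identical.

#' Write a table as TSV with optional metadata header lines
#'
#' @param df data.frame (list columns are comma-joined).
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` lines.
#' @export
write_tsv <- function(df, path, meta = NULL) {
  for (j in seq_along(df))
    if (is.list(df[[j]])) df[[j]] <- join_col(df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return data.frame (metadata lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

matrix_to_df <- function(mat, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  df
}

#' Read a sample design table
#'
#' Expects columns `sample_id` and `group`.
#'
#' @param path TSV path.
#' @param levels Group levels, reference first.
#' @return Factor from [sample_design()].
#' @export
read_design <- function(path, levels = c("normal", "tumor")) {
  d <- read_tsv(path)
  sample_design(d$sample_id, d$group, levels)
}
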