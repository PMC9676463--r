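# Small in-code fixtures shared across test files.

make_profile <- function(gene_id, log2fc, p_value = 0.01, adj_p = NULL,
                         label = "fixture") {
  df <- tibble::tibble(gene_id = gene_id, log2fc = log2fc, p_value = p_value)
  if (!is.null(adj_p)) df$adj_p <- adj_p
  de_profile(df, condition_label = label)
}

# A reference whose first n_pos genes have positive log2fc and the rest
# negative, all significant.
make_signed_reference <- function(n_pos, n_neg, label = "refline") {
  make_profile(
    gene_id = paste0("R", seq_len(n_pos + n_neg)),
    log2fc = c(seq(2, 1, length.out = n_pos), seq(-1, -2, length.out = n_neg)),
    label = label
  )
}

write_temp_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
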