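#' Read a signature profile table
#'
#' Signatures use the same delimited format as DE tables but only need
#' `gene_id` and `log2fc` columns. The package ships a small synthetic
#' demonstration panel under `system.file("extdata", package = "taindex")`;
#' real signature panels are user-supplied.
#'
#' @param path Path to the table.
#' @param delimiter Field delimiter (default tab).
#' @param signature_label Label; defaults to the file name.
#' @return Tibble with `gene_id` and `log2fc`, labelled via its
#'   `condition_label` attribute.
#' @export
read_signature_table <- function(path, delimiter = "\t",
                                 signature_label = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(raw))) {
    abort_data("signature tables need gene_id and log2fc columns")
  }
  out <- tibble(gene_id = normalize_gene_id(raw$gene_id),
                log2fc = as.numeric(raw$log2fc))
  out <- out[is.finite(out$log2fc), ]
  if (nrow(out) == 0) abort_data("signature table is empty after parsing")
  structure(out, condition_label = signature_label)
}

#' Correlate a query transcriptome with a ROS-source signature
#'
#' Correlates the two fold-change vectors over the genes shared by the query
#' and the signature, on the -1..+1 scale used by signature-comparison heat
#' maps. Genes missing from either profile are dropped pairwise, never
#' imputed.
#'
#' @param query A `de_profile` (or data frame with `gene_id` and `log2fc`).
#' @param signature A signature profile: data frame with `gene_id` and
#'   `log2fc` columns (same delimited-table format as DE tables).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_shared Minimum number of shared genes required (default 10).
#' @return One-row tibble: `query_label`, `signature_label`, `rho`,
#'   `n_shared`, `method`.
#' @export
correlate_profiles <- function(query, signature,
                               method = c("pearson", "spearman"),
                               min_shared = 10) {
  method <- arg_match(method)
  q <- as_tibble(query)[, c("gene_id", "log2fc")]
  s <- as_tibble(signature)[, c("gene_id", "log2fc")]
  shared <- dplyr::inner_join(q, s, by = "gene_id", suffix = c("_q", "_s"))
  shared <- shared[is.finite(shared$log2fc_q) & is.finite(shared$log2fc_s), ]
  if (nrow(shared) < min_shared) {
    abort_data(sprintf("only %d shared genes; min_shared = %d",
                       nrow(shared), min_shared))
  }
  if (stats::sd(shared$log2fc_q) == 0 || stats::sd(shared$log2fc_s) == 0) {
    abort_data("zero variance in a fold-change vector; correlation undefined")
  }
  tibble(
    query_label = condition_label(query),
    signature_label = condition_label(signature),
    rho = cor(shared$log2fc_q, shared$log2fc_s, method = method),
    n_shared = nrow(shared),
    method = method
  )
}

#' Correlation matrix of queries against a signature panel
#'
#' One cell per (query, signature) pair. Pairs that fail (too few shared
#' genes, degenerate variance) are flagged with `ok = FALSE` and the failure
#' message, never silently dropped.
#'
#' @param queries Named list of query profiles.
#' @param signatures Named list of signature profiles.
#' @inheritParams correlate_profiles
#' @return A `signature_cors` tibble: `query_label`, `signature_label`,
#'   `rho`, `n_shared`, `method`, `ok`, `note`. Use [autoplot()] for the
#'   red/green heat map.
#' @export
correlation_matrix <- function(queries, signatures,
                               method = c("pearson", "spearman"),
                               min_shared = 10) {
  method <- arg_match(method)
  if (length(queries) < 1 || length(signatures) < 1) {
    abort_data("need at least one query and one signature")
  }
  if (is.null(names(queries))) {
    names(queries) <- vapply(queries, condition_label, character(1))
  }
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, condition_label, character(1))
  }
  cells <- purrr::map_dfr(names(queries), function(qn) {
    purrr::map_dfr(names(signatures), function(sn) {
      res <- tryCatch(
        correlate_profiles(queries[[qn]], signatures[[sn]],
                           method = method, min_shared = min_shared),
        error = function(e) {
          tibble(query_label = qn, signature_label = sn, rho = NA_real_,
                 n_shared = NA_integer_, method = method)
        }
      )
      res$query_label <- qn
      res$signature_label <- sn
      res$ok <- !is.na(res$rho)
      res$note <- if (res$ok) "" else "failed: too few shared genes or zero variance"
      res
    })
  })
  if (!any(cells$ok)) abort_data("every query/signature pair failed")
  structure(cells, class = c("signature_cors", class(tibble())))
}
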