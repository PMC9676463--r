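#' Match a query gene set against a reference transcriptome
#'
#' Looks up each query gene in the reference profile and returns its reference
#' log2 fold change. Genes absent from the reference are reported as
#' unmatched, never silently dropped.
#'
#' @param query A `gene_set` (direction `"up"`), character vector of gene
#'   identifiers, or data frame with a `gene_id` column.
#' @param reference A `de_profile` (or compatible data frame) to match
#'   against, e.g. a cycloheximide translational-arrest transcriptome.
#' @return A tibble with columns `gene_id`, `ref_log2fc` and logical
#'   `matched`; unmatched genes carry `NA` fold changes.
#' @export
match_to_reference <- function(query, reference) {
  ids <- query_gene_ids(query)
  if (length(ids) == 0) abort_data("query gene set is empty")
  ref <- as_tibble(reference)
  if (nrow(ref) == 0) abort_data("reference profile is empty")
  idx <- match(ids, ref$gene_id)
  tibble(
    gene_id = ids,
    ref_log2fc = ref$log2fc[idx],
    matched = !is.na(idx)
  )
}

query_gene_ids <- function(query) {
  if (is.data.frame(query)) {
    if (inherits(query, "gene_set")) {
      dir <- attr(query, "direction")
      if (!is.null(dir) && identical(dir, "down")) {
        abort_data("TAI is defined for up-regulated query sets")
      }
    }
    unique(as.character(query$gene_id))
  } else {
    unique(as.character(query))
  }
}

#' Compute the Translational Attenuation Index
#'
#' The TAI of an up-regulated query gene set against a reference
#' translational-arrest transcriptome is the fraction of its genes whose
#' reference log2 fold change is strictly positive (a reference fold change of
#' exactly zero counts as non-positive):
#' \deqn{TAI = n_{positive} / n}
#' A query of 100 genes of which 70 have positive reference fold change gives
#' TAI = 70/100 = 0.7; complete overlap with the reference-induced programme
#' gives the theoretical maximum of 1.
#'
#' The denominator depends on how genes absent from the reference are
#' handled. Under `"drop"` (default) the index is restricted to matched genes
#' and `n = n_matched`; under `"count_as_nonpositive"` every query gene
#' counts and `n = n_query`, a conservative lower bound. Coverage
#' (`n_matched / n_query`) is always reported so the choice stays auditable.
#'
#' @inheritParams match_to_reference
#' @param unmatched_policy `"drop"` or `"count_as_nonpositive"`.
#' @param reference_label Label recorded in the result; defaults to the
#'   reference profile's condition label.
#' @return A `tai_result` object with components `tai`, `n_query`,
#'   `n_matched`, `n_positive`, `ranked_fc` (the descending waterfall tibble),
#'   `unmatched`, `unmatched_policy` and `reference_label`. Use [tidy()] for
#'   the waterfall table, [glance()] for a one-row summary, [autoplot()] for
#'   the waterfall plot and [tai_null_test()] for the sign-symmetry null.
#' @examples
#' ref <- de_profile(tibble::tibble(
#'   gene_id = paste0("G", 1:4),
#'   log2fc = c(2.0, 0.5, -1.0, 0.1),
#'   p_value = 0.01
#' ), condition_label = "CHX-like")
#' compute_tai(c("G1", "G2", "G3"), ref)
#' @export
compute_tai <- function(query, reference,
                        unmatched_policy = c("drop", "count_as_nonpositive"),
                        reference_label = NULL) {
  unmatched_policy <- arg_match(unmatched_policy)
  if (is.null(reference_label)) reference_label <- condition_label(reference)
  m <- match_to_reference(query, reference)
  matched <- m[m$matched, , drop = FALSE]
  n_query <- nrow(m)
  n_matched <- nrow(matched)
  n_positive <- sum(matched$ref_log2fc > 0)
  denom <- if (unmatched_policy == "drop") n_matched else n_query
  if (denom == 0) {
    abort_data("no query genes matched the reference; TAI undefined under the drop policy")
  }
  ord <- order(-matched$ref_log2fc, matched$gene_id)
  ranked <- tibble(
    rank = seq_len(n_matched),
    gene_id = matched$gene_id[ord],
    ref_log2fc = matched$ref_log2fc[ord]
  )
  structure(
    list(
      tai = n_positive / denom,
      n_query = n_query,
      n_matched = n_matched,
      n_positive = n_positive,
      ranked_fc = ranked,
      unmatched = m$gene_id[!m$matched],
      unmatched_policy = unmatched_policy,
      query_label = if (is.data.frame(query)) condition_label(query) else "query",
      reference_label = reference_label
    ),
    class = "tai_result"
  )
}

#' @export
print.tai_result <- function(x, ...) {
  cat(sprintf("Translational attenuation index: %s vs %s\n",
              x$query_label, x$reference_label))
  cat(sprintf("  TAI = %.4f (%d positive / %d, policy = %s)\n",
              x$tai, x$n_positive,
              if (x$unmatched_policy == "drop") x$n_matched else x$n_query,
              x$unmatched_policy))
  cat(sprintf("  coverage: %d of %d query genes matched (%.1f%%)\n",
              x$n_matched, x$n_query, 100 * x$n_matched / x$n_query))
  invisible(x)
}

#' Ranked waterfall table behind a TAI value
#'
#' Matched reference log2 fold changes arranged from largest to smallest,
#' ties broken by gene identifier so the ranking is reproducible.
#'
#' @param result A `tai_result` from [compute_tai()].
#' @return Tibble with columns `rank`, `gene_id`, `ref_log2fc`.
#' @export
waterfall_ranking <- function(result) {
  stopifnot(inherits(result, "tai_result"))
  if (result$n_matched < 1) abort_data("no matched genes to rank")
  result$ranked_fc
}

#' Exact binomial test of a TAI against a sign-symmetry null
#'
#' Under a null in which each matched gene is equally likely to carry a
#' positive or non-positive reference fold change, the positive count is
#' Binomial(n, `null_prob`). This computes the exact two-sided p-value
#' (summing all outcome probabilities no larger than the observed one).
#'
#' @param result A `tai_result`, or the number of positive genes (with `n`
#'   supplied).
#' @param null_prob Null probability of a positive reference fold change,
#'   default 0.5.
#' @param n Number of trials; ignored when `result` is a `tai_result`
#'   (the denominator implied by its unmatched policy is used).
#' @return One-row tibble with `n_positive`, `n`, `null_prob`, `tai`,
#'   `p_value`.
#' @export
tai_null_test <- function(result, null_prob = 0.5, n = NULL) {
  if (!(null_prob > 0 && null_prob < 1)) abort_data("null_prob must lie in (0, 1)")
  if (inherits(result, "tai_result")) {
    k <- result$n_positive
    n <- if (result$unmatched_policy == "drop") result$n_matched else result$n_query
  } else {
    k <- as.integer(result)
    if (is.null(n)) abort_data("supply n when result is a count")
  }
  if (n < 1) abort_data("binomial null test requires n >= 1")
  p <- binom.test(k, n, p = null_prob, alternative = "two.sided")$p.value
  tibble(n_positive = k, n = as.integer(n), null_prob = null_prob,
         tai = k / n, p_value = min(p, 1))
}
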