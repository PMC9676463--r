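#' Tidy a TAI result into its ranked waterfall table
#'
#' @param x A `tai_result`.
#' @param ... Unused.
#' @return Tibble with `rank`, `gene_id`, `ref_log2fc`, `positive`.
#' @method tidy tai_result
#' @export
tidy.tai_result <- function(x, ...) {
  out <- x$ranked_fc
  out$positive <- out$ref_log2fc > 0
  out
}

#' One-row summary of a TAI result
#'
#' @param x A `tai_result`.
#' @param ... Unused.
#' @return One-row tibble: `query_label`, `reference_label`, `tai`,
#'   `n_query`, `n_matched`, `n_positive`, `coverage`, `unmatched_policy`,
#'   `p_null` (exact binomial test against the sign-symmetric null).
#' @method glance tai_result
#' @export
glance.tai_result <- function(x, ...) {
  tibble(
    query_label = x$query_label,
    reference_label = x$reference_label,
    tai = x$tai,
    n_query = x$n_query,
    n_matched = x$n_matched,
    n_positive = x$n_positive,
    coverage = x$n_matched / x$n_query,
    unmatched_policy = x$unmatched_policy,
    p_null = tai_null_test(x)$p_value
  )
}

#' Tidy an overlap report into its ordered-pair table
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return The pairs tibble.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$pairs

#' Tidy a standard curve (coefficient table)
#'
#' @param x A `standard_curve`.
#' @param ... Passed to the `lm` tidier when available.
#' @return Coefficient tibble.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"]
  )
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return One-row tibble: `analyte`, `slope`, `intercept`, `r_squared`,
#'   `n_points`, `usable`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(analyte = x$analyte, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_points = nrow(x$points),
         usable = x$usable)
}
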