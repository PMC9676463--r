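#' Waterfall plot of a TAI result
#'
#' Matched reference log2 fold changes ranked from largest to smallest;
#' the fraction of bars above zero is the TAI.
#'
#' @param object A `tai_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tai_result
#' @export
autoplot.tai_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ref_log2fc,
                                   fill = .data$positive)) +
    ggplot2::geom_col(width = 1, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7191c", `FALSE` = "#2c7bb6")) +
    ggplot2::labs(
      x = "rank (reference log2 fold change, descending)",
      y = sprintf("log2 fold change in %s", object$reference_label),
      title = sprintf("%s: TAI = %.2f (%d/%d)", object$query_label,
                      object$tai, object$n_positive,
                      if (object$unmatched_policy == "drop") object$n_matched
                      else object$n_query)
    ) +
    ggplot2::theme_minimal()
}

#' Signature-correlation heat map
#'
#' Queries by signatures, red for +1 and green for -1, matching the usual
#' rendering of ROS-signature comparisons.
#'
#' @param object A `signature_cors` tibble from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot signature_cors
#' @export
autoplot.signature_cors <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$signature_label,
                               y = .data$query_label, fill = .data$rho)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#1a9641", mid = "white",
                                  high = "#d7191c", limits = c(-1, 1),
                                  na.value = "grey80", name = "rho") +
    ggplot2::labs(x = "signature", y = "query") +
    ggplot2::theme_minimal()
}

#' Venn region bar chart for an overlap report
#'
#' Bar chart of the disjoint Venn region counts (works for 2-4 sets; the
#' counts always partition the union of the selected sets).
#'
#' @param object An `overlap_report`.
#' @param ... Unused.
#' @return A ggplot, or `NULL` when the report has more than 4 sets.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  if (is.null(object$venn)) return(NULL)
  df <- object$venn
  df$region <- factor(df$region, levels = df$region[order(-df$count)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "Venn region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Standard-curve plot with the fitted line
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  unit <- if (object$analyte == "8oxoG") "ng/mL" else "ug/mL"
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "#d7191c") +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s concentration (%s)", object$analyte, unit),
                  y = "response",
                  title = sprintf("r2 = %.5f", object$r_squared)) +
    ggplot2::theme_minimal()
}
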