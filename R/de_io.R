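#' Normalize gene identifiers to the AGI locus convention
#'
#' Uppercases, strips surrounding whitespace, and removes a trailing isoform
#' suffix of the form `.<digits>` (so `"AT5G64870.2"` and `"at5g64870"` both
#' normalize to `"AT5G64870"`). No cross-species identifier mapping is
#' attempted.
#'
#' @param raw_id Character vector of raw gene identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_gene_id(c("At3g61190", "AT5G64870.2", "  at2g40300 "))
#' @export
normalize_gene_id <- function(raw_id) {
  if (!is.character(raw_id)) raw_id <- as.character(raw_id)
  out <- toupper(trimws(raw_id))
  out <- sub("\\.[0-9]+$", "", out)
  if (any(!nzchar(out) | is.na(out))) {
    abort_data("gene identifiers must be non-empty after normalization")
  }
  out
}

#' Construct a differential-expression profile
#'
#' A `de_profile` is a tibble with one row per gene and columns `gene_id`,
#' `log2fc`, `p_value` and (optionally `NA`) `adj_p`, carrying the condition
#' label and free-text provenance as attributes. It is the unit every other
#' function in the package passes around.
#'
#' @param x Data frame with columns `gene_id`, `log2fc`, `p_value` and
#'   optionally `adj_p`.
#' @param condition_label Label for the condition (e.g. `"CHX"`).
#' @param source_note Free-text provenance (e.g. an accession string).
#' @param normalize Normalize gene identifiers (default `TRUE`).
#' @param duplicate_policy How to resolve duplicate gene identifiers after
#'   normalization: `"max_abs_lfc"` keeps the record with the largest
#'   `|log2fc|` (isoform collapse needs one representative), `"error"` fails.
#' @return A `de_profile` tibble.
#' @export
de_profile <- function(x, condition_label = "query", source_note = "",
                       normalize = TRUE,
                       duplicate_policy = c("max_abs_lfc", "error")) {
  duplicate_policy <- arg_match(duplicate_policy)
  x <- as_tibble(x)
  required <- c("gene_id", "log2fc", "p_value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_data(paste0("missing required columns: ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!"adj_p" %in% names(x)) x$adj_p <- NA_real_
  x <- x[, c("gene_id", "log2fc", "p_value", "adj_p")]
  x$log2fc <- as.numeric(x$log2fc)
  x$p_value <- as.numeric(x$p_value)
  x$adj_p <- as.numeric(x$adj_p)
  if (normalize) x$gene_id <- normalize_gene_id(x$gene_id)

  bad_p <- !is.na(x$p_value) & (x$p_value < 0 | x$p_value > 1)
  bad_q <- !is.na(x$adj_p) & (x$adj_p < 0 | x$adj_p > 1)
  if (any(bad_p) || any(bad_q)) abort_data("p-values must lie in [0, 1]")

  n_dup <- sum(duplicated(x$gene_id))
  if (n_dup > 0) {
    if (duplicate_policy == "error") {
      abort_data(paste0(n_dup, " duplicate gene_id(s) after normalization"))
    }
    x <- x %>%
      group_by(.data$gene_id) %>%
      slice_max(abs(.data$log2fc), n = 1, with_ties = FALSE) %>%
      ungroup()
  }
  if (nrow(x) == 0) abort_data("profile is empty")

  structure(
    x,
    class = c("de_profile", class(as_tibble(x))),
    condition_label = condition_label,
    source_note = source_note,
    duplicates_resolved = n_dup
  )
}

#' @export
print.de_profile <- function(x, ...) {
  cat("# DE profile:", attr(x, "condition_label"),
      sprintf("(%d genes)\n", nrow(x)))
  note <- attr(x, "source_note")
  if (nzchar(note)) cat("#", note, "\n")
  NextMethod()
}

#' Condition label of a profile or gene set
#' @param x A `de_profile` or `gene_set`.
#' @return Character scalar.
#' @export
condition_label <- function(x) {
  attr(x, "condition_label") %||% attr(x, "label") %||% "unlabelled"
}

#' Read a delimited differential-expression table
#'
#' Reads a delimited text file (TSV by default, CSV accepted) into a
#' [de_profile()]. Column names in the file are mapped onto the profile fields
#' via `column_map`; rows whose mapped numeric fields fail to parse are dropped
#' and counted, never imputed. A parse report (rows read / kept / dropped,
#' duplicates resolved) is appended to the profile's `source_note` attribute
#' and available via `attr(x, "parse_report")`.
#'
#' @param path Path to the table.
#' @param column_map Named character vector mapping profile fields to file
#'   column names; names are a subset of `c("gene_id", "log2fc", "p_value",
#'   "adj_p")` (the first three required).
#' @param delimiter Field delimiter; `"\t"` (default) or `","`.
#' @param condition_label,source_note,duplicate_policy Passed to [de_profile()].
#' @return A `de_profile`.
#' @export
read_de_table <- function(path,
                          column_map = c(gene_id = "gene_id", log2fc = "log2fc",
                                         p_value = "p_value"),
                          delimiter = "\t",
                          condition_label = basename(path),
                          source_note = path,
                          duplicate_policy = "max_abs_lfc") {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  required <- c("gene_id", "log2fc", "p_value")
  if (!all(required %in% names(column_map))) {
    abort_data("column_map must name gene_id, log2fc and p_value columns")
  }
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  # the adjusted-p mapping is optional: ignore it when the column is absent
  if ("adj_p" %in% names(column_map) &&
      !column_map[["adj_p"]] %in% names(raw)) {
    column_map <- column_map[names(column_map) != "adj_p"]
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    abort_data(paste0("mapped column(s) absent from header: ",
                      paste(missing_cols, collapse = ", ")))
  }
  df <- tibble(
    gene_id = raw[[column_map[["gene_id"]]]],
    log2fc = suppressWarnings(as.numeric(raw[[column_map[["log2fc"]]]])),
    p_value = suppressWarnings(as.numeric(raw[[column_map[["p_value"]]]])),
    adj_p = if ("adj_p" %in% names(column_map)) {
      suppressWarnings(as.numeric(raw[[column_map[["adj_p"]]]]))
    } else {
      NA_real_
    }
  )
  n_read <- nrow(df)
  keep <- !is.na(df$gene_id) & nzchar(trimws(df$gene_id)) &
    is.finite(df$log2fc) & !is.na(df$p_value)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) abort_data("table is empty after parsing")

  prof <- de_profile(df, condition_label = condition_label,
                     source_note = source_note,
                     duplicate_policy = duplicate_policy)
  report <- list(rows_read = n_read, rows_kept = nrow(prof),
                 rows_dropped = n_read - nrow(df),
                 duplicates_resolved = attr(prof, "duplicates_resolved"))
  attr(prof, "parse_report") <- report
  attr(prof, "source_note") <- paste0(
    source_note, " [read ", report$rows_read, ", kept ", report$rows_kept,
    ", dropped ", report$rows_dropped, ", duplicates resolved ",
    report$duplicates_resolved, "]")
  prof
}

#' Write a profile back to tab-separated text
#'
#' @param profile A `de_profile` (or compatible data frame).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(profile, path) {
  readr::write_tsv(as_tibble(profile)[, c("gene_id", "log2fc", "p_value", "adj_p")],
                   path, progress = FALSE)
  invisible(path)
}

#' Select significantly regulated genes
#'
#' Applies the standard regulation filter: at least `fold_threshold`-fold
#' change (inclusive, on the linear scale, so the default 2 corresponds to
#' `|log2fc| >= 1`) and tested p-value strictly below `p_threshold`. Up- and
#' down-regulated sets are therefore disjoint for any `fold_threshold > 1`.
#'
#' @param profile A `de_profile` or data frame with `gene_id`, `log2fc`,
#'   `p_value` (and optionally `adj_p`) columns.
#' @param direction `"up"` or `"down"`.
#' @param fold_threshold Minimum absolute fold change on the linear scale;
#'   must be `>= 1`. Default 2.
#' @param p_threshold Significance cutoff in `(0, 1]`; comparison is strict
#'   (`p < p_threshold`). Default 0.05.
#' @param p_column Which p-value to test: `"auto"` uses the adjusted p-value
#'   when the column carries any non-missing values and the raw p-value
#'   otherwise; `"raw"` and `"adjusted"` force the choice. Genes with a
#'   missing tested p-value are never selected.
#' @return A `gene_set`: a tibble with a `gene_id` column and attributes
#'   `label`, `direction`, `selection` (the thresholds used) and `parent_size`.
#' @export
select_regulated <- function(profile, direction = c("up", "down"),
                             fold_threshold = 2, p_threshold = 0.05,
                             p_column = c("auto", "raw", "adjusted")) {
  direction <- arg_match(direction)
  p_column <- arg_match(p_column)
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1)
  if (fold_threshold < 1) abort_data("fold_threshold must be >= 1")
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    abort_data("p_threshold must lie in (0, 1]")
  }
  df <- as_tibble(profile)
  if (nrow(df) == 0) abort_data("profile is empty")
  if (!"adj_p" %in% names(df)) df$adj_p <- NA_real_

  use_adj <- switch(p_column,
                    auto = any(!is.na(df$adj_p)),
                    adjusted = TRUE,
                    raw = FALSE)
  tested_p <- if (use_adj) df$adj_p else df$p_value
  lfc_cut <- log2(fold_threshold)
  pass_fc <- if (direction == "up") df$log2fc >= lfc_cut else df$log2fc <= -lfc_cut
  pass <- pass_fc & !is.na(tested_p) & tested_p < p_threshold

  gene_set(
    members = df$gene_id[pass],
    label = paste0(condition_label(profile), "_", direction),
    direction = direction,
    selection = list(fold_threshold = fold_threshold,
                     p_threshold = p_threshold,
                     p_column = if (use_adj) "adjusted" else "raw"),
    parent_size = nrow(df),
    normalize = FALSE
  )
}

#' Construct a direction-tagged gene set
#'
#' @param members Character vector of gene identifiers (deduplicated).
#' @param label Set label.
#' @param direction `"up"` or `"down"`.
#' @param selection List recording the thresholds that produced the set.
#' @param parent_size Number of genes in the source profile (`NA` if unknown).
#' @param normalize Normalize identifiers via [normalize_gene_id()].
#' @return A `gene_set` tibble with one `gene_id` column.
#' @export
gene_set <- function(members, label = "set", direction = c("up", "down"),
                     selection = list(), parent_size = NA_integer_,
                     normalize = TRUE) {
  direction <- arg_match(direction)
  members <- as.character(members)
  if (normalize && length(members) > 0) members <- normalize_gene_id(members)
  members <- unique(members)
  structure(
    tibble(gene_id = members),
    class = c("gene_set", class(tibble())),
    label = label,
    direction = direction,
    selection = selection,
    parent_size = as.integer(parent_size)
  )
}

#' @export
print.gene_set <- function(x, ...) {
  sel <- attr(x, "selection")
  cat("# Gene set:", attr(x, "label"),
      sprintf("(%s, %d genes", attr(x, "direction"), nrow(x)))
  if (!is.na(attr(x, "parent_size"))) {
    cat(sprintf(" of %d measured", attr(x, "parent_size")))
  }
  cat(")\n")
  if (length(sel) > 0) {
    cat("# selection:", paste(names(sel), unlist(sel), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order and every adjusted value is at least the
#' raw one.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_data("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p_values, method = "BH")
}

#' Write a gene set to plain text
#'
#' One gene per line, preceded by a `#`-prefixed metadata header recording
#' label, direction, selection thresholds and parent size, so the file
#' round-trips losslessly through [read_gene_set()].
#'
#' @param gene_set A `gene_set`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gene_set, path) {
  sel <- attr(gene_set, "selection")
  header <- c(
    paste0("# label: ", attr(gene_set, "label")),
    paste0("# direction: ", attr(gene_set, "direction")),
    paste0("# parent_size: ", attr(gene_set, "parent_size")),
    vapply(names(sel), function(k) paste0("# selection.", k, ": ", sel[[k]]),
           character(1))
  )
  writeLines(c(header, gene_set$gene_id), path)
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#'
#' @param path Path to the gene-set file.
#' @return A `gene_set` with the stored metadata restored.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  members <- trimws(lines[!is_meta])
  members <- members[nzchar(members)]

  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", hit[[1]])
  }
  sel_keys <- grep("^# selection\\.", meta, value = TRUE)
  selection <- list()
  for (line in sel_keys) {
    key <- sub("^# selection\\.([^:]+): .*$", "\\1", line)
    val <- sub("^# selection\\.[^:]+: ", "", line)
    num <- suppressWarnings(as.numeric(val))
    selection[[key]] <- if (is.na(num)) val else num
  }
  gene_set(
    members,
    label = get_meta("label"),
    direction = get_meta("direction"),
    selection = selection,
    parent_size = suppressWarnings(as.integer(get_meta("parent_size"))),
    normalize = FALSE
  )
}
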