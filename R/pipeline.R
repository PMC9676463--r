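#' Run the full comparison pipeline
#'
#' Orchestrates an end-to-end run: read the reference and query DE tables,
#' select up-regulated genes at the configured thresholds, compute each
#' query's TAI against the reference (with waterfall and binomial null test),
#' build the pairwise overlap report, and optionally correlate each query
#' with a signature panel. A query that fails (missing file, no matched
#' genes) is recorded in `$errors` and the run continues; the run only fails
#' when the reference is unreadable or no query succeeds.
#'
#' @param config Named list (or path to a YAML file encoding one) with
#'   elements:
#'   \describe{
#'     \item{reference}{path to the reference DE table, or a data frame /
#'       `de_profile`.}
#'     \item{queries}{named list of query DE tables (paths or data frames).}
#'     \item{column_map, delimiter}{passed to [read_de_table()] for paths.}
#'     \item{fold_threshold, p_threshold, p_column}{selection thresholds
#'       (defaults 2, 0.05, `"auto"`).}
#'     \item{tai_policy}{`"drop"` (default) or `"count_as_nonpositive"`.}
#'     \item{universe_mode}{`"intersection"` (default) or `"union"`.}
#'     \item{signatures}{optional named list of signature tables.}
#'     \item{min_shared}{minimum shared genes for signature correlation
#'       (default 10).}
#'     \item{output_dir}{optional; when set, the report is serialized there
#'       as JSON plus TSV tables.}
#'   }
#' @return A `run_report`: list with `tai` (tibble of per-query [glance()]
#'   rows), `waterfalls` (named list of ranked tables), `overlap`
#'   (an `overlap_report`), `signature` (correlation tibble or `NULL`),
#'   `errors` (named character), `config` (echo) and `timestamp`.
#' @export
run_comparison <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_data("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(fold_threshold = 2, p_threshold = 0.05, p_column = "auto",
                   tai_policy = "drop", universe_mode = "intersection",
                   min_shared = 10, delimiter = "\t",
                   column_map = c(gene_id = "gene_id", log2fc = "log2fc",
                                  p_value = "p_value", adj_p = "adj_p"))
  config <- modifyList(defaults, config)
  if (is.null(config$reference)) abort_data("config must name a reference")
  if (is.null(config$queries) || length(config$queries) == 0) {
    abort_data("config must name at least one query")
  }
  if (is.null(names(config$queries)) || any(!nzchar(names(config$queries)))) {
    abort_data("queries must be uniquely named")
  }
  if (anyDuplicated(names(config$queries)) > 0) {
    abort_data("query labels must be unique")
  }

  load_profile <- function(x, label) {
    if (is.data.frame(x)) {
      if (inherits(x, "de_profile")) return(x)
      return(de_profile(x, condition_label = label))
    }
    read_de_table(x, column_map = config$column_map,
                  delimiter = config$delimiter, condition_label = label)
  }
  reference <- load_profile(config$reference, "reference")

  errors <- character(0)
  tai_results <- list()
  query_profiles <- list()
  for (label in names(config$queries)) {
    res <- tryCatch({
      prof <- load_profile(config$queries[[label]], label)
      qset <- select_regulated(prof, direction = "up",
                               fold_threshold = config$fold_threshold,
                               p_threshold = config$p_threshold,
                               p_column = config$p_column)
      attr(qset, "label") <- label
      tai <- compute_tai(qset, reference, unmatched_policy = config$tai_policy)
      tai$query_label <- label
      list(profile = prof, tai = tai)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[[label]] <- res
    } else {
      query_profiles[[label]] <- res$profile
      tai_results[[label]] <- res$tai
    }
  }
  if (length(tai_results) == 0) {
    abort_data("no query completed successfully")
  }

  overlap <- NULL
  if (length(query_profiles) >= 1) {
    profs <- c(list(reference = reference), query_profiles)
    overlap <- overlap_report(profs, direction = "up",
                              fold_threshold = config$fold_threshold,
                              p_threshold = config$p_threshold,
                              p_column = config$p_column,
                              universe_mode = config$universe_mode)
  }

  signature <- NULL
  if (!is.null(config$signatures) && length(config$signatures) > 0) {
    sigs <- purrr::imap(config$signatures, function(x, label) {
      if (is.data.frame(x)) x else {
        read_signature_table(x, delimiter = config$delimiter,
                             signature_label = label)
      }
    })
    signature <- tryCatch(
      correlation_matrix(query_profiles, sigs, min_shared = config$min_shared),
      error = function(e) {
        errors[["signature_panel"]] <<- conditionMessage(e)
        NULL
      })
  }

  report <- structure(
    list(
      tai = purrr::map_dfr(tai_results, glance),
      waterfalls = purrr::map(tai_results, waterfall_ranking),
      tai_objects = tai_results,
      overlap = overlap,
      signature = signature,
      errors = errors,
      config = config[setdiff(names(config), "output_dir")],
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  queries completed: %d; failed: %d\n",
              nrow(x$tai), length(x$errors)))
  print(x$tai)
  if (length(x$errors) > 0) {
    cat("  errors:\n")
    for (nm in names(x$errors)) cat("   -", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Serialize a run report to disk
#'
#' Writes `report.json` (TAI table, overlap pairs, Venn regions, signature
#' matrix, errors; the timestamp is kept out of the JSON so reruns on
#' identical inputs are byte-identical) plus TSV tables for the TAI summary,
#' each waterfall, and the overlap pairs.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    tai = report$tai,
    overlap_pairs = if (!is.null(report$overlap)) report$overlap$pairs,
    venn = if (!is.null(report$overlap)) report$overlap$venn,
    signature = report$signature,
    errors = as.list(report$errors)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  readr::write_tsv(report$tai, file.path(dir, "tai_summary.tsv"),
                   progress = FALSE)
  for (nm in names(report$waterfalls)) {
    readr::write_tsv(report$waterfalls[[nm]],
                     file.path(dir, paste0("waterfall_", nm, ".tsv")),
                     progress = FALSE)
  }
  if (!is.null(report$overlap)) {
    readr::write_tsv(report$overlap$pairs,
                     file.path(dir, "overlap_pairs.tsv"), progress = FALSE)
  }
  writeLines(paste0("run completed: ", report$timestamp),
             file.path(dir, "run.log"))
  invisible(dir)
}
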