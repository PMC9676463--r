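#' Build a 2x2 contingency table for two gene sets over a universe
#'
#' @param setA,setB `gene_set`s, character vectors, or data frames with a
#'   `gene_id` column. Both must be subsets of `universe`; membership outside
#'   the universe signals inconsistent gene namespaces and is an error.
#' @param universe Character vector of all gene identifiers considered
#'   (typically the genes measured in both parent profiles).
#' @return A `contingency_table`: list with counts `a` (in both), `b` (A
#'   only), `c` (B only), `d` (neither), plus set labels.
#' @export
build_contingency <- function(setA, setB, universe) {
  A <- unique(query_ids_any(setA))
  B <- unique(query_ids_any(setB))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort_data("universe is empty")
  outside <- setdiff(c(A, B), universe)
  if (length(outside) > 0) {
    abort_data(paste0(length(outside),
                      " set member(s) lie outside the universe (first: ",
                      outside[[1]], "); check gene namespaces"))
  }
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  c <- length(setdiff(B, A))
  d <- length(universe) - a - b - c
  structure(
    list(a = a, b = b, c = c, d = d,
         label_A = set_label(setA), label_B = set_label(setB)),
    class = "contingency_table"
  )
}

query_ids_any <- function(x) {
  if (is.data.frame(x)) as.character(x$gene_id) else as.character(x)
}

set_label <- function(x) {
  if (is.data.frame(x)) attr(x, "label") %||% "set" else "set"
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("in B", "not B"), c("in A", "not A")))
  cat(sprintf("2x2 contingency (%s vs %s):\n", x$label_A, x$label_B))
  print(m)
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins: the two-sided p-value sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (probability ties resolved within a relative tolerance of
#' 1e-7). The odds ratio reported is the sample cross-product ratio
#' `(a*d)/(b*c)`, infinite when `b*c = 0` with `a*d > 0`.
#'
#' @param table A `contingency_table` from [build_contingency()], or a list /
#'   named vector with elements `a`, `b`, `c`, `d`.
#' @return One-row tibble with `a`, `b`, `c`, `d`, `p_value`, `odds_ratio`.
#' @export
fisher_exact_two_sided <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_data("contingency counts must be non-negative integers")
  }
  p <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                   alternative = "two.sided")$p.value
  odds <- if (b * c == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c)
  }
  tibble(a = a, b = b, c = c, d = d,
         p_value = min(p, 1), odds_ratio = odds)
}

#' Overlap statistics for one ordered pair of gene sets
#'
#' @inheritParams build_contingency
#' @param universe Universe of gene identifiers over which `d` is counted.
#' @return One-row tibble: labels, contingency counts, `pct_of_A`
#'   (100*a/(a+b), the share of A found in B), `pct_of_B`, `jaccard`,
#'   `fisher_p`, `odds_ratio`, `universe_size`.
#' @export
overlap_pair <- function(setA, setB, universe) {
  ct <- build_contingency(setA, setB, universe)
  ft <- fisher_exact_two_sided(ct)
  tibble(
    set_A = ct$label_A, set_B = ct$label_B,
    a = ct$a, b = ct$b, c = ct$c, d = ct$d,
    pct_of_A = 100 * ct$a / (ct$a + ct$b),
    pct_of_B = 100 * ct$a / (ct$a + ct$c),
    jaccard = ct$a / (ct$a + ct$b + ct$c),
    fisher_p = ft$p_value,
    odds_ratio = ft$odds_ratio,
    universe_size = ct$a + ct$b + ct$c + ct$d
  )
}

#' Venn region counts for 2-4 gene sets
#'
#' Partitions the union of the sets into its disjoint regions and counts each.
#'
#' @param sets Named list of `gene_set`s or character vectors (2 to 4 sets).
#' @return Tibble with one row per non-empty-membership region: one logical
#'   column per set, a `region` label, and `count`. Counts always sum to the
#'   size of the union.
#' @export
venn_regions <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4) {
    abort_data("venn_regions supports 2 to 4 sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  members <- purrr::map(sets, ~ unique(query_ids_any(.x)))
  all_genes <- unique(unlist(members))
  membership <- purrr::map(members, ~ all_genes %in% .x)
  key <- do.call(paste0, purrr::map(membership, as.integer))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  combo_key <- apply(combos, 1, function(r) paste0(as.integer(r), collapse = ""))
  counts <- vapply(combo_key, function(k) sum(key == k), integer(1))
  out <- as_tibble(combos)
  out$region <- apply(combos, 1, function(r) {
    paste(names(sets)[as.logical(r)], collapse = "&")
  })
  out$count <- unname(counts)
  out
}

#' Pairwise overlap report across regulated gene sets
#'
#' Selects regulated genes from each profile at the given thresholds, then
#' computes [overlap_pair()] statistics for every ordered pair and Venn region
#' counts (for up to 4 profiles). For each pair the universe is the set of
#' genes measured in both profiles (`"intersection"`, the defensible
#' background for cross-platform comparisons) or in either (`"union"`); gene
#' sets are restricted to that universe before counting.
#'
#' @param profiles Named list of `de_profile`s (at least 2).
#' @param direction,fold_threshold,p_threshold,p_column Passed to
#'   [select_regulated()].
#' @param universe_mode `"intersection"` (default) or `"union"`.
#' @return An `overlap_report`: list with `pairs` (tibble of ordered-pair
#'   statistics), `venn` (region counts, `NULL` for >4 profiles), and `sets`
#'   (the selected gene sets). `tidy()` returns the pairs tibble.
#' @export
overlap_report <- function(profiles, direction = "up",
                           fold_threshold = 2, p_threshold = 0.05,
                           p_column = "auto",
                           universe_mode = c("intersection", "union")) {
  universe_mode <- arg_match(universe_mode)
  if (length(profiles) < 2) abort_data("need at least 2 profiles")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, condition_label, character(1))
  }
  sets <- purrr::imap(profiles, function(p, nm) {
    s <- select_regulated(p, direction = direction,
                          fold_threshold = fold_threshold,
                          p_threshold = p_threshold, p_column = p_column)
    attr(s, "label") <- nm
    s
  })
  labels <- names(profiles)
  pairs <- purrr::map_dfr(labels, function(la) {
    purrr::map_dfr(setdiff(labels, la), function(lb) {
      measured_a <- profiles[[la]]$gene_id
      measured_b <- profiles[[lb]]$gene_id
      universe <- if (universe_mode == "intersection") {
        intersect(measured_a, measured_b)
      } else {
        union(measured_a, measured_b)
      }
      if (length(universe) == 0) abort_data("empty universe for a profile pair")
      sa <- sets[[la]][sets[[la]]$gene_id %in% universe, , drop = FALSE]
      sb <- sets[[lb]][sets[[lb]]$gene_id %in% universe, , drop = FALSE]
      row <- overlap_pair(sa, sb, universe)
      row$set_A <- la
      row$set_B <- lb
      row$universe_mode <- universe_mode
      row
    })
  })
  venn <- if (length(sets) <= 4) venn_regions(sets) else NULL
  structure(
    list(pairs = pairs, venn = venn, sets = sets,
         selection = list(direction = direction,
                          fold_threshold = fold_threshold,
                          p_threshold = p_threshold, p_column = p_column),
         universe_mode = universe_mode),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report: %d sets (%s-regulated, >=%g-fold, p<%g), universe = %s\n",
              length(x$sets), x$selection$direction, x$selection$fold_threshold,
              x$selection$p_threshold, x$universe_mode))
  print(x$pairs)
  invisible(x)
}
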