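test_that("gene identifiers normalize to the AGI convention", {
  expect_equal(normalize_gene_id("At3g61190"), "AT3G61190")
  expect_equal(normalize_gene_id("AT5G64870.2"), "AT5G64870")
  expect_equal(normalize_gene_id("  at2g40300 "), "AT2G40300")
  expect_error(normalize_gene_id("   "), "non-empty")
})

test_that("read_de_table parses, drops unparseable rows, and collapses isoforms", {
  path <- write_temp_table(c(
    "gene\tlog2fc\tpvalue",
    "at1g01010\t1.5\t0.001",
    "AT1G01020\t-0.4\t0.3",
    "AT1G01030\t2.2\t0.02"
  ))
  cmap <- c(gene_id = "gene", log2fc = "log2fc", p_value = "pvalue")
  prof <- read_de_table(path, column_map = cmap)
  expect_s3_class(prof, "de_profile")
  expect_equal(nrow(prof), 3)
  expect_equal(sort(prof$gene_id), c("AT1G01010", "AT1G01020", "AT1G01030"))

  # one NA log2fc: row dropped and counted
  path2 <- write_temp_table(c(
    "gene\tlog2fc\tpvalue",
    "AT1G01010\tNA\t0.001",
    "AT1G01020\t-0.4\t0.3",
    "AT1G01030\t2.2\t0.02"
  ))
  prof2 <- read_de_table(path2, column_map = cmap)
  expect_equal(nrow(prof2), 2)
  expect_equal(attr(prof2, "parse_report")$rows_dropped, 1)

  # isoform + case duplicates resolve to the max-|log2fc| record
  path3 <- write_temp_table(c(
    "gene\tlog2fc\tpvalue",
    "at3g61190.1\t0.5\t0.2",
    "AT3G61190\t-3.0\t0.001"
  ))
  prof3 <- read_de_table(path3, column_map = cmap)
  expect_equal(nrow(prof3), 1)
  expect_equal(prof3$gene_id, "AT3G61190")
  expect_equal(prof3$log2fc, -3.0)
  expect_error(
    read_de_table(path3, column_map = cmap, duplicate_policy = "error"),
    "duplicate"
  )
})

test_that("read_de_table fails on missing files, columns, and empty tables", {
  expect_error(read_de_table(tempfile()), "not found")
  path <- write_temp_table(c("gene\tlfc", "A\t1"))
  expect_error(
    read_de_table(path, column_map = c(gene_id = "gene", log2fc = "lfc",
                                       p_value = "pvalue")),
    "absent from header"
  )
  path2 <- write_temp_table(c("gene\tlog2fc\tpvalue", "A\tnot_a_number\t0.1"))
  expect_error(
    read_de_table(path2, column_map = c(gene_id = "gene", log2fc = "log2fc",
                                        p_value = "pvalue")),
    "empty"
  )
})

test_that("regulation selection applies inclusive fold and strict p cutoffs", {
  prof <- make_profile(
    gene_id = c("A1", "A2", "A3", "A4", "A5"),
    log2fc = c(1.2, 0.9, 2.5, -1.5, -1.0),
    p_value = c(0.01, 0.001, 0.06, 0.02, 0.0499)
  )
  up <- select_regulated(prof, "up")
  expect_equal(up$gene_id, "A1")   # 1.2 >= 1 & 0.01 < 0.05; A2 below fold; A3 fails p
  down <- select_regulated(prof, "down")
  expect_setequal(down$gene_id, c("A4", "A5"))  # -1.0 <= -1 inclusive, p strict
  expect_equal(attr(up, "parent_size"), 5L)
  expect_equal(attr(up, "selection")$fold_threshold, 2)
})

test_that("selection prefers adjusted p-values when present and is configurable", {
  prof <- make_profile("B1", 2, p_value = 0.01, adj_p = 0.2)
  expect_equal(nrow(select_regulated(prof, "up")), 0)              # auto -> adj
  expect_equal(nrow(select_regulated(prof, "up", p_column = "raw")), 1)
  expect_equal(nrow(select_regulated(prof, "up", p_column = "adjusted")), 0)
})

test_that("up and down selections are disjoint and selection is monotone", {
  set.seed(42)
  prof <- make_profile(
    gene_id = sprintf("M%03d", 1:200),
    log2fc = rnorm(200, 0, 1.5),
    p_value = runif(200)
  )
  for (fold in c(1.5, 2, 4)) {
    up <- select_regulated(prof, "up", fold_threshold = fold)
    down <- select_regulated(prof, "down", fold_threshold = fold)
    expect_length(intersect(up$gene_id, down$gene_id), 0)
  }
  base <- select_regulated(prof, "up")$gene_id
  expect_true(all(select_regulated(prof, "up", fold_threshold = 3)$gene_id %in% base))
  expect_true(all(select_regulated(prof, "up", p_threshold = 0.01)$gene_id %in% base))
})

test_that("bh_adjust matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # outputs bounded and >= input elementwise
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
})

test_that("gene sets and profiles round-trip through their writers", {
  gs <- gene_set(c("AT1G01010", "AT1G01020", "AT1G01030"), label = "demo",
                 direction = "up",
                 selection = list(fold_threshold = 2, p_threshold = 0.05),
                 parent_size = 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_set(gs, path)
  back <- read_gene_set(path)
  expect_setequal(back$gene_id, gs$gene_id)
  expect_equal(attr(back, "label"), "demo")
  expect_equal(attr(back, "direction"), "up")
  expect_equal(attr(back, "parent_size"), 10L)
  expect_equal(attr(back, "selection")$fold_threshold, 2)

  # empty set: header only
  empty <- gene_set(character(0), label = "none", direction = "down",
                    parent_size = 5)
  write_gene_set(empty, path)
  expect_equal(nrow(read_gene_set(path)), 0)

  # profile round-trip
  prof <- make_profile(c("AT1G01010", "AT1G01020"), c(1.5, -2), c(0.01, 0.2))
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(prof, ppath)
  back_prof <- read_de_table(ppath)
  expect_equal(as.data.frame(back_prof)[, 1:3], as.data.frame(prof)[, 1:3])
})
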