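fixture_lines <- c(
  "gene_id\ts1\ts2\ts3\ts4",
  "CLASS\t1\t1\t0\t0",
  "gA\t1.5\t2.5\t0.5\t1.0",
  "gB\t3.0\t2.0\t2.5\t3.5",
  "gC\t0.1\t0.4\t0.2\t0.3")

test_that("expression tables round-trip through TSV with labels intact", {
  path <- write_expr_fixture(fixture_lines)
  ds <- read_expression_table(path)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(ds$gene_ids, c("gA", "gB", "gC"))
  expect_equal(ds$labels, c(1L, 1L, 0L, 0L))
  expect_equal(ds$values["gB", "s3"], 2.5)

  out <- tempfile(fileext = ".tsv")
  write_expression_table(ds, out)
  ds2 <- read_expression_table(out)
  expect_equal(ds2$values, ds$values, tolerance = 1e-9)
  expect_identical(ds2$gene_ids, ds$gene_ids)
  expect_identical(ds2$sample_ids, ds$sample_ids)
  expect_identical(ds2$labels, ds$labels)
})

test_that("missing cells are read as missing and located correctly", {
  lines <- fixture_lines
  lines[3] <- "gA\t1.5\t\t0.5\t1.0"          # blank cell at (gA, s2)
  ds <- read_expression_table(write_expr_fixture(lines))
  expect_equal(n_missing(ds), 1L)
  expect_true(is.na(ds$values["gA", "s2"]))
  lines[3] <- "gA\t1.5\tNA\t0.5\t1.0"        # NA token also accepted
  ds2 <- read_expression_table(write_expr_fixture(lines))
  expect_equal(n_missing(ds2), 1L)
})

test_that("format errors name the offending line or cell", {
  lines <- c(fixture_lines, "gD\t1\t2\t3\t4\t5")
  expect_error(read_expression_table(write_expr_fixture(lines)),
               "ragged row at line 6")
  lines <- fixture_lines
  lines[1] <- "gene_id\ts1\ts1\ts3\ts4"
  expect_error(read_expression_table(write_expr_fixture(lines)),
               "duplicate sample")
  lines <- fixture_lines
  lines[4] <- "gB\t3.0\tabc\t2.5\t3.5"
  expect_error(read_expression_table(write_expr_fixture(lines)),
               "gene 'gB', sample 's2'")
})

test_that("labels can come from a sidecar file with named classes", {
  path <- write_expr_fixture(fixture_lines[-2])
  lab <- tempfile()
  writeLines(c("s1\ttumor", "s2\ttumor", "s3\tnormal", "s4\tnormal"), lab)
  ds <- read_expression_table(path, label_row = NULL, labels_file = lab,
                              case_label = "tumor")
  expect_equal(ds$labels, c(1L, 1L, 0L, 0L))
})

test_that("impute_and_filter drops high-missingness genes and median-imputes", {
  X <- matrix(c(1, NA, 3, 4,
                NA, NA, NA, 5,
                1, 2, 3, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  ds <- expression_dataset(X, c(1, 1, 0, 0))
  out <- impute_and_filter(ds, max_missing_fraction = 0.3)
  expect_equal(out$gene_ids, c("g1", "g3"))           # g2 missing 3/4 > 0.3
  expect_equal(out$values["g1", "s2"], 3)             # median of {1,3,4}
  expect_equal(n_missing(out), 0L)
  # median of an even count of observed values
  X2 <- matrix(c(1, NA, 3, 10), nrow = 1,
               dimnames = list("g", paste0("s", 1:4)))
  ds2 <- expression_dataset(X2, c(1, 1, 0, 0))
  expect_equal(impute_and_filter(ds2, 0.5)$values["g", "s2"], 3)
  # complete matrix returned unchanged; idempotence
  expect_equal(impute_and_filter(out, 0.3)$values, out$values)
  # all-missing gene is an error even at threshold 1
  X3 <- matrix(NA_real_, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  expect_error(impute_and_filter(expression_dataset(X3, c(1, 1, 0, 0)), 1),
               "all values missing")
})

test_that("collapse_probes keeps the max-mean probe with a stable tie-break", {
  X <- matrix(c(5, 5, 5, 5,
                7, 7, 7, 7,
                2, 2, 2, 2,
                2, 2, 2, 2), nrow = 4, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3", "p4"), paste0("s", 1:4)))
  ds <- expression_dataset(X, c(1, 1, 0, 0))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G2")
  out <- collapse_probes(ds, map)
  expect_equal(sort(out$gene_ids), c("G1", "G2"))
  expect_equal(unname(out$values["G1", "s1"]), 7)    # mean 7 beats mean 5
  expect_equal(unname(out$values["G2", "s1"]), 2)    # tie: first probe (p3)
  # single probe per gene: identity up to renaming
  one <- collapse_probes(ds, c(p1 = "A", p3 = "B"))
  expect_equal(unname(one$values["A", ]), unname(X["p1", ]))
  # unmapped probes dropped; output genes all come from the mapping values
  expect_true(all(out$gene_ids %in% map))
  expect_lte(length(out$gene_ids), length(ds$gene_ids))
  expect_error(collapse_probes(ds, character()), "empty")
})

test_that("edge lists deduplicate, drop self-loops, and round-trip", {
  path <- tempfile()
  writeLines(c("A\tB\tpositive", "B\tC\tnegative", "A\tB\tpositive"), path)
  net <- read_edge_list(path)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$nodes, c("A", "B", "C"))

  writeLines(c("A\tA\tpositive", "A\tB"), path)
  expect_message(net2 <- read_edge_list(path), "self-loop")
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$effect, "unspecified")   # missing effect defaults

  writeLines(character(), path)
  empty <- read_edge_list(path)
  expect_equal(length(empty$nodes), 0L)

  writeLines(c("A\tB\tupregulates"), path)
  expect_error(read_edge_list(path), "positive, negative, unspecified")

  out <- tempfile()
  write_edge_list(net, out)
  back <- read_edge_list(out)
  expect_equal(back$edges, net$edges)
  expect_setequal(back$nodes, net$nodes)
})

test_that("gene lists are unique, order-preserving, and comment-aware", {
  path <- tempfile()
  writeLines(c("# downregulated hubs", "FOS", "ESR1", "JUNB", "EGFR",
               "SOCS3", "FOLH1", "IGF1"), path)
  gs <- read_gene_list(path, name = "down7")
  expect_equal(length(gs), 7L)
  expect_equal(gs$genes[1], "FOS")

  writeLines(c("A", "B", "A"), path)
  expect_equal(length(read_gene_list(path)), 2L)

  writeLines(c("# only", "# comments"), path)
  expect_error(read_gene_list(path), "empty")
})

test_that("shipped hub gene list fixtures have the documented sizes", {
  ext <- system.file("extdata", package = "hubclass")
  expect_equal(length(read_gene_list(file.path(ext, "hubs_up10.txt"))), 10L)
  down <- read_gene_list(file.path(ext, "hubs_down7.txt"))
  expect_equal(down$genes,
               c("FOS", "ESR1", "JUNB", "EGFR", "SOCS3", "FOLH1", "IGF1"))
  expect_equal(length(read_gene_list(file.path(ext, "hubs_combined27.txt"))),
               27L)
})
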