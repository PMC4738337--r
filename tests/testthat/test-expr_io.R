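test_that("expression matrices round-trip through TSV unchanged", {
  vals <- matrix(c(1.5, 2.25, -0.5, 3, 0, 7.125), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
  x <- expression_matrix(vals, "mouse")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  y <- load_expression_matrix(path, "mouse")
  expect_identical(gene_ids(y), gene_ids(x))
  expect_identical(sample_ids(y), sample_ids(x))
  expect_equal(unclass(y), unclass(x), ignore_attr = TRUE)
  expect_identical(expr_species(y), "mouse")
})

test_that("malformed matrices are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\t2", "G1\t3\t4"), path)
  expect_error(load_expression_matrix(path, "mouse"), "G1")

  writeLines(c("gene_id\ts1\ts2", "G1\t1\t2", "G2\tNA\t4"), path)
  expect_error(load_expression_matrix(path, "mouse"), "row 2.*column 1")

  writeLines("gene_id\ts1", path)
  expect_error(load_expression_matrix(path, "mouse"), "empty")

  expect_error(expression_matrix(matrix(1:4, 2), "m"), "rownames")
  dup <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(dup, "m"), "duplicate gene")
})

test_that("missing-value policy 'drop' removes affected genes, never imputes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\t2", "G2\tNA\t4", "G3\t5\t6"), path)
  expect_message(x <- load_expression_matrix(path, "h", na_action = "drop"),
                 "dropping 1")
  expect_identical(gene_ids(x), c("G1", "G3"))
})

test_that("sample annotations load and validate against matrices", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tspecies\tgroup\trole",
               "s1\tmouse\tmIC\ttumour",
               "s2\tmouse\tcortex\treference"), path)
  ann <- load_sample_annotation(path)
  expect_identical(ann$role, c("tumour", "reference"))

  writeLines(c("sample_id\tspecies\tgroup\trole",
               "s1\tmouse\tmIC\tcase"), path)
  expect_error(load_sample_annotation(path), "unknown role")

  x <- toy_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2"))), "mouse")
  good <- data.frame(sample_id = "s1", species = "mouse", group = "mIC",
                     role = "tumour")
  expect_identical(check_annotation(x, good)$sample_id, "s1")
  bad <- data.frame(sample_id = "s9", species = "mouse", group = "mIC",
                    role = "tumour")
  expect_error(check_annotation(x, bad), "s9")
})

test_that("ortholog maps load, count their 1:1 core, and reject bad lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A1\tB1", "A2\tB2"), path)
  map <- load_ortholog_map(path)
  expect_identical(nrow(map), 2L)
  expect_identical(attr(map, "n_1to1"), 2L)

  # one gene mapped twice: 2 pairs retained, none 1:1-reducible
  writeLines(c("A1\tB1", "A1\tB2"), path)
  map <- load_ortholog_map(path)
  expect_identical(nrow(map), 2L)
  expect_identical(attr(map, "n_1to1"), 0L)

  writeLines(c("A1\tB1", "A2"), path)
  expect_error(load_ortholog_map(path), "line 2")

  writeLines(character(0), path)
  expect_warning(map <- load_ortholog_map(path), "empty")
  expect_identical(nrow(map), 0L)
})

test_that("to_1to1 drop policy removes every multi-mapped pair", {
  map <- ortholog_map(c("A1", "A2"), c("B1", "B1"))
  expect_identical(nrow(to_1to1(map)), 0L)

  map <- ortholog_map(c("A1", "A2", "A3"), c("B1", "B2", "B2"))
  red <- to_1to1(map)
  expect_identical(red$gene_a, "A1")
  expect_identical(red$gene_b, "B1")

  clean <- ortholog_map(c("A1", "A2"), c("B1", "B2"))
  expect_identical(to_1to1(clean)$gene_a, clean$gene_a)
})

test_that("to_1to1 'first' policy keeps the first pair per identifier and is idempotent", {
  map <- ortholog_map(c("A1", "A1", "A2", "A3"), c("B1", "B2", "B2", "B3"))
  first <- to_1to1(map, policy = "first")
  expect_identical(first$gene_a, c("A1", "A2", "A3"))
  expect_identical(first$gene_b, c("B1", "B2", "B3"))
  for (policy in c("drop", "first")) {
    once <- to_1to1(map, policy = policy)
    expect_identical(to_1to1(once, policy = policy), once)
  }
})

test_that("ortholog maps round-trip through TSV", {
  map <- ortholog_map(c("A1", "A2"), c("B1", "B2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_map(map, path)
  back <- load_ortholog_map(path)
  expect_identical(back$gene_a, map$gene_a)
  expect_identical(back$gene_b, map$gene_b)
})
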