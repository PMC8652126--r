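test_that("reading preserves ids and order and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "gene,c1,c2,c3,c4",
    "g1,1,2,3,4",
    "g2,2,1,0,-1",
    "g3,0.5,0.25,1.5,2"
  ), f)
  x <- read_expression_matrix(f)
  expect_s3_class(x, "expression_matrix")
  expect_identical(dim(x), c(3L, 4L))
  expect_identical(x$gene_ids, c("g1", "g2", "g3"))
  expect_identical(x$condition_ids, c("c1", "c2", "c3", "c4"))
  expect_false(x$standardized)
  expect_equal(x$values["g3", "c2"], 0.25)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2,c3,c4", "g1,1,2,3,4", "g1,4,3,2,1"), dup)
  expect_error(read_expression_matrix(dup), "Duplicate gene id.*g1")

  na <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2,c3,c4", "g1,1,2,3,4", "g2,1,NA,3,4"), na)
  expect_error(read_expression_matrix(na), "gene row 'g2', condition 'c2'")

  narrow <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2,c3", "g1,1,2,3", "g2,4,5,6"), narrow)
  expect_error(read_expression_matrix(narrow), "At least 4 conditions")
})

test_that("TSV input is read via the extension and via an explicit delimiter", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2\tc3\tc4", "g1\t1\t2\t3\t4", "g2\t0\t1\t0\t2"), f)
  x <- read_expression_matrix(f)
  expect_identical(x$gene_ids, c("g1", "g2"))
  y <- read_expression_matrix(f, delimiter = "\t")
  expect_identical(x$values, y$values)
})

test_that("standardize centres and scales with the n-1 denominator and is idempotent", {
  m <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("g1", paste0("c", 1:4)))
  # hand case padded to 4 conditions: mean 2.5, sample sd of (1,2,3,4)
  z <- standardize(expression_matrix(m))
  expect_equal(as.vector(z$values), (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)),
               tolerance = 1e-14)

  x <- random_standardized(10, 8, seed = 11)
  expect_lt(max(abs(rowMeans(x$values))), 1e-12)
  expect_lt(max(abs(apply(x$values, 1, sd) - 1)), 1e-10)
  twice <- standardize(x)
  expect_equal(twice$values, x$values, tolerance = 1e-12)
  expect_true(twice$standardized)
})

test_that("constant genes error by default and can be dropped on request", {
  m <- matrix(rnorm(16), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  m[2, ] <- 7
  x <- expression_matrix(m)
  expect_error(standardize(x), "Constant gene row.*g2")
  expect_warning(z <- standardize(x, drop_constant = TRUE), "Dropping constant gene.*g2")
  expect_identical(z$gene_ids, c("g1", "g3", "g4"))
})

test_that("edge tables round-trip through CSV with deterministic ordering", {
  t <- tibble::tibble(
    gene_a = c("g1", "g1", "g2"),
    gene_b = c("g2", "g3", "g3"),
    score = c(0.5, -0.9, 0.5),
    t = c(1.2, -3.4, 1.1),
    p = c(0.2, 0.001, 0.25),
    fdr = c(0.3, 0.003, 0.3)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  written <- write_edge_table(t, f)
  expect_identical(readLines(f)[1], "gene_a,gene_b,score,t,p,fdr")
  # descending |score|; the |0.5| tie broken lexically by (gene_a, gene_b)
  expect_identical(written$gene_b, c("g3", "g2", "g3"))
  back <- read_edge_table(f)
  expect_identical(back$gene_a, written$gene_a)
  expect_equal(back$score, written$score, tolerance = 1e-12)
  expect_equal(back$p, written$p, tolerance = 1e-12)

  empty <- t[0, ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_edge_table(empty, f2)
  expect_identical(readLines(f2), "gene_a,gene_b,score,t,p,fdr")

  bad <- t; bad$gene_b[1] <- "g1"
  expect_error(write_edge_table(bad, f), "self-pairs")
  dup <- t; dup$gene_a[3] <- "g1"; dup$gene_b[3] <- "g3"
  expect_error(write_edge_table(dup, f), "duplicated gene pairs")
})

test_that("expression write/read round-trip is the identity on the data model", {
  net <- make_planted_network(p = 6, n_edges = 4, strength = 0.5, seed = 3)
  x <- simulate_expression(net, n = 9, seed = 4)
  d <- withr::local_tempdir()
  paths <- write_simulation(net, x, d)
  back <- read_expression_matrix(paths[["expression"]])
  expect_identical(back$gene_ids, x$gene_ids)
  expect_identical(back$condition_ids, x$condition_ids)
  expect_equal(back$values, x$values, tolerance = 1e-12)
})
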