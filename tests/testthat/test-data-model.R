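test_that("csv datasets read back with row sums as default UMI totals", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,gA,gB", "0,0,1,0", "1,0,2,3", "2,0,0,1"), f)
  ds <- read_dataset(f, "csv")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(unname(ds$counts), rbind(c(1, 0), c(2, 3), c(0, 1)))
  expect_equal(ds$umi_totals, c(1, 5, 1))
  expect_equal(ds$gene_names, c("gA", "gB"))
})

test_that("mtx directory and dense csv of the same content agree, and both round-trip", {
  ds0 <- spatial_dataset(rbind(c(1, 0, 4), c(2, 3, 0), c(0, 1, 7)),
                         cbind(c(0, 1, 2), c(5, 5, 6)),
                         gene_names = c("gA", "gB", "gC"))
  csv <- withr::local_tempfile(fileext = ".csv")
  mtx <- withr::local_tempdir()
  write_dataset(ds0, csv, "csv")
  write_dataset(ds0, mtx, "mtx_dir")
  d1 <- read_dataset(csv, "csv")
  d2 <- read_dataset(mtx, "mtx_dir")
  expect_equal(unname(d1$counts), unname(ds0$counts))
  expect_equal(unname(d2$counts), unname(d1$counts))
  expect_equal(d2$coords, d1$coords, ignore_attr = TRUE)
  expect_equal(d2$gene_names, d1$gene_names)
})

test_that("dataset validation names the offending entry and checks shapes", {
  expect_error(spatial_dataset(rbind(c(1, -1), c(0, 2)), cbind(1:2, 1:2)),
               "cell 1, gene 2")
  expect_error(spatial_dataset(rbind(c(1, 0.5), c(0, 2)), cbind(1:2, 1:2)),
               "nonnegative integers")
  expect_error(spatial_dataset(rbind(c(1, 2)), cbind(1:2, 1:2)),
               "dimension mismatch")
  expect_error(spatial_dataset(rbind(c(1, 2), c(3, 4)), cbind(1:2, 1:2),
                               gene_names = c("a", "a")),
               "duplicate gene names")
  expect_error(spatial_dataset(rbind(c(1, 2), c(3, 4)), cbind(1:2, 1:2),
                               umi_totals = c(2, 100)),
               "smaller than")
  ds <- spatial_dataset(rbind(c(1, 2), c(3, 4)), cbind(1:2, 1:2),
                        umi_totals = c(10, 10))
  expect_equal(ds$umi_totals, c(10, 10))
})

test_that("pair lists parse, deduplicate with a warning, and resolve against a dataset", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF1\tG1", "TF1\tG2", "TF1\tG2"), f)
  expect_warning(p <- read_pairs(f), "duplicate")
  expect_equal(nrow(p), 2L)
  expect_true(all(p$pair_type == "tf_target"))

  writeLines(c("regulator\ttarget\ttype", "L1\tR1\tligand_receptor"), f)
  p2 <- read_pairs(f)
  expect_equal(p2$pair_type, "ligand_receptor")

  writeLines(character(0), f)
  expect_error(read_pairs(f), "empty")

  ds <- spatial_dataset(matrix(1, 2, 3), cbind(1:2, 1:2),
                        gene_names = c("TF1", "G1", "G2"))
  p3 <- candidate_pairs(c("TF1", "TF1", "TF9"), c("G1", "G2", "G1"))
  withr::local_options(spagranger.verbose = TRUE)
  expect_message(r <- resolve_pairs(p3, ds), "dropped 1")
  expect_equal(nrow(r), 2L)
  expect_error(resolve_pairs(candidate_pairs("zz", "ww"), ds), "no candidate pair")
})

test_that("log-CPM z-scoring matches hand computation and flags degenerate genes", {
  ds <- spatial_dataset(cbind(g1 = c(1, 1), g2 = c(0, 99), g3 = c(0, 0)),
                        cbind(1:2, 1:2), umi_totals = c(100, 100))
  nm <- suppressMessages(normalize_expression(ds))
  # identical values z-score to zero; a two-point non-constant gene to +/-1
  expect_equal(unname(nm$values[, "g1"]), c(0, 0))
  expect_equal(unname(nm$values[, "g2"]), c(-1, 1))
  expect_equal(unname(nm$values[, "g3"]), c(0, 0))
  expect_equal(unname(nm$constant_genes), c(TRUE, FALSE, TRUE))

  # hand-check of the transform itself on a 2-cell gene
  ds2 <- spatial_dataset(cbind(g = c(1, 1)), cbind(1:2, 1:2), umi_totals = c(10, 20))
  v <- log1p(1e4 * c(1, 1) / c(10, 20))
  sd_pop <- sqrt(mean((v - mean(v))^2))
  nm2 <- normalize_expression(ds2)
  expect_equal(unname(nm2$values[, 1]), unname((v - mean(v)) / sd_pop))
})

test_that("non-constant genes come out with zero mean and unit sd", {
  ds <- benchmark_suite("easy", seed = 3)$dataset
  nm <- normalize_expression(ds)
  ok <- !nm$constant_genes
  expect_lt(max(abs(colMeans(nm$values[, ok]))), 1e-8)
  sd_pop <- sqrt(colMeans(scale(nm$values[, ok], scale = FALSE)^2))
  expect_lt(max(abs(sd_pop - 1)), 1e-6)
})

test_that("zero-UMI cells are dropped by default and can be made fatal", {
  cnt <- rbind(c(2, 1), c(0, 0), c(1, 4))
  ds <- spatial_dataset(cnt, cbind(1:3, 1:3))
  nm <- suppressMessages(normalize_expression(ds))
  expect_equal(nm$kept_cells, c(1L, 3L))
  expect_equal(nrow(nm$values), 2L)
  expect_error(normalize_expression(ds, zero_umi = "error"), "zero total UMI")
})

test_that("gene order permutation permutes normalized output identically", {
  ds <- benchmark_suite("easy", seed = 5)$dataset
  perm <- withr::with_seed(1, sample(ncol(ds$counts)))
  dsp <- spatial_dataset(ds$counts[, perm], ds$coords,
                         gene_names = ds$gene_names[perm],
                         umi_totals = ds$umi_totals)
  a <- normalize_expression(ds)
  b <- normalize_expression(dsp)
  expect_equal(unname(b$values), unname(a$values[, perm]))
  expect_equal(b$constant_genes, a$constant_genes[perm], ignore_attr = TRUE)
})

test_that("interaction tables serialize deterministically and round-trip", {
  tab <- interaction_table(
    regulator = c("B", "A", "C"), target = c("t1", "t1", "t2"),
    pair_type = "tf_target", direction = "forward",
    score = c(1, 1, 0.5), lag = c(2L, 1L, 3L), context = "granular")
  # equal scores: lexicographic tiebreak
  expect_equal(tab$regulator[1:2], c("A", "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(tab, f)
  back <- read_interactions(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # empty table: header only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(interaction_table(), f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_interactions(f2)), 0L)
})

test_that("interaction tables enforce score/lag consistency", {
  expect_error(interaction_table("r", "t", "tf_target", "forward",
                                 score = 0.5, lag = 0L, context = ""),
               "lag must be 0")
  expect_error(interaction_table("r", "t", "tf_target", "forward",
                                 score = 0, lag = 2L, context = ""),
               "lag must be 0")
  expect_error(interaction_table("r", "t", "tf_target", "forward",
                                 score = -1, lag = 1L, context = ""),
               "nonnegative")
})
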