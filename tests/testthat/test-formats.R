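write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("position table parser handles the Biomart column order and bad strands", {
  p <- read_position_table(write_tmp("gA chr2R 100 900 1"))
  expect_identical(p$name, "gA")
  expect_identical(p$chrom, "chr2R")
  expect_identical(p$start, 100)
  expect_identical(p$end, 900)
  expect_identical(p$strand, 1L)

  p2 <- read_position_table(write_tmp("gB\tchr2R\t100\t900\t+1"))
  expect_identical(p2$strand, 1L)
  expect_identical(read_position_table(write_tmp("gC,chrX,5,9,-1"))$strand, -1L)

  expect_error(read_position_table(write_tmp("gB chr2R 100 900 0")), "strand")
  expect_error(read_position_table(write_tmp("gB chr2R 1e2 900 1")), "start")
  expect_error(read_position_table(write_tmp("gB chr2R 100 900")), "5 columns")

  empty <- read_position_table(write_tmp(character(0)))
  expect_identical(nrow(empty), 0L)

  commented <- read_position_table(write_tmp(c("# a comment", "", "gA chr1 1 2 1")))
  expect_identical(nrow(commented), 1L)
})

test_that("expression parser turns blank and non-numeric cells into NaN", {
  e <- read_expression_table(write_tmp("gA 1.5 2.0"))
  expect_identical(e$values[[1]], c(1.5, 2.0))

  # trailing blank cell in a tab-delimited row
  e2 <- read_expression_table(write_tmp("gA\t1.5\t"), dialect = "tab")
  expect_identical(e2$values[[1]][1], 1.5)
  expect_true(is.nan(e2$values[[1]][2]))

  e3 <- read_expression_table(write_tmp("gA x 2.0"))
  expect_true(is.nan(e3$values[[1]][1]))
  expect_identical(e3$values[[1]][2], 2.0)

  # ... and the merge then writes the literal NaN token into the GDF
  pos <- data.frame(name = "gA", chrom = "chr1", start = 1, end = 9, strand = 1L)
  m <- merge_position_expression(pos, e3, "d1")
  f <- tempfile()
  write_gdf(m$table, f)
  expect_match(readLines(f), "\tNaN\t", fixed = TRUE)
})

test_that("GDF lines follow the exact field order with tab separation", {
  gt <- gene_table("d1", "gA", "chr2R", 100, 900, 1L,
                   expr = matrix(c(1.5, NaN), nrow = 1))
  f <- tempfile()
  write_gdf(gt, f)
  expect_identical(readLines(f), "d1\tgA\tchr2R\t100\t900\t1\t1.5\tNaN")
})

test_that("GDF round-trips are field-for-field identities", {
  set.seed(11)
  for (i in 1:20) {
    gt <- rand_gene_table(sample(2:30, 1), n_chrom = sample(1:3, 1),
                          n_expr = sample(0:4, 1))
    if (n_expr(gt) > 0 && runif(1) < 0.5) gt$expr1[1] <- NaN
    f <- tempfile()
    write_gdf(gt, f)
    expect_same_table(gt, read_gdf(f))
  }
  # unscaled doubles round-trip bit-exactly too
  gt <- gene_table("d", "g1", "c", 1, 2, 1L,
                   expr = matrix(c(runif(1), 1/3), nrow = 1))
  f <- tempfile()
  write_gdf(gt, f)
  expect_identical(expr_matrix(read_gdf(f)), expr_matrix(gt))
})

test_that("an unsorted GDF file is read as-is and flagged by validation", {
  f <- write_tmp(c("d\tg1\tchr1\t500\t600\t1", "d\tg2\tchr1\t10\t20\t1"))
  gt <- read_gdf(f)
  expect_identical(gt$name, c("g1", "g2"))
  expect_true(any(grepl("not position-sorted", validate_gene_table(gt))))
})

test_that("GDF reader reports the offending line on ragged input", {
  f <- write_tmp(c("d\tg1\tchr1\t1\t2\t1\t0.5", "d\tg2\tchr1\t5\t6\t1"))
  expect_error(read_gdf(f), "line 2")
})

test_that("CLU layout matches the published listing token for token", {
  cl <- gene_table(c("d1", "d1"), c("gA", "gB"), "chr2R",
                   start = c(100, 2000), end = c(900, 2800),
                   strand = c(1L, -1L), expr = matrix(c(1.5, 2.5), ncol = 1))
  cs <- posclust:::new_posclust(list(cl), threshold_bp = 20000, n_expr = 1L)
  f <- tempfile()
  write_clu(cs, f)
  expect_identical(readLines(f),
                   c("nClusters 1", "1", "beginCluster",
                     "d1 gA chr2R 1 100 900 1.5",   # strand precedes start
                     "d1 gB chr2R -1 2000 2800 2.5",
                     "endCluster"))
})

test_that("an empty cluster set writes only the nClusters header", {
  cs <- posclust:::new_posclust(list(), threshold_bp = 1000, n_expr = 0L)
  f <- tempfile()
  write_clu(cs, f)
  expect_identical(readLines(f), "nClusters 0")
  back <- read_clu(f)
  expect_identical(n_clusters(back), 0L)
})

test_that("CLU round-trips are identities on random cluster sets", {
  set.seed(12)
  for (i in 1:20) {
    cs <- rand_posclust(sample(1:5, 1), n_expr = sample(0:3, 1))
    f <- tempfile()
    write_clu(cs, f)
    back <- read_clu(f, threshold_bp = cs$threshold_bp)
    expect_identical(length(back$clusters), length(cs$clusters))
    for (k in seq_along(cs$clusters))
      expect_same_table(cs$clusters[[k]], back$clusters[[k]])
  }
})

test_that("CLU parser rejects structural corruption", {
  cl <- gene_table("d", c("a", "b"), "c1", c(1, 5), c(2, 6), 1L)
  cs <- posclust:::new_posclust(list(cl), 100, 0L)
  f <- tempfile()
  write_clu(cs, f)

  # header count disagreeing with the block count
  lines <- readLines(f)
  writeLines(c("nClusters 2", lines[-1]), f)
  expect_error(read_clu(f), "declares 2")
  # unbalanced begin/end
  writeLines(lines[-length(lines)], f)
  expect_error(read_clu(f), "endCluster")
  # a 1-member block
  writeLines(lines[-4], f)
  expect_error(read_clu(f), "fewer than 2")
})

test_that("single-character deletions never yield a silently identical object", {
  set.seed(13)
  cs <- rand_posclust(2, n_expr = 1L)
  f <- tempfile()
  write_clu(cs, f)
  content <- paste(readLines(f), collapse = "\n")
  for (i in 1:40) {
    pos <- sample.int(nchar(content), 1)
    corrupted <- paste0(substr(content, 1, pos - 1),
                        substr(content, pos + 1, nchar(content)))
    g <- tempfile()
    writeLines(corrupted, g)
    res <- tryCatch(read_clu(g, threshold_bp = cs$threshold_bp),
                    error = function(e) "parse-error")
    if (!identical(res, "parse-error")) {
      same <- length(res$clusters) == length(cs$clusters) &&
        all(vapply(seq_along(cs$clusters), function(k)
          identical(as.data.frame(res$clusters[[k]]),
                    as.data.frame(cs$clusters[[k]])), logical(1)))
      expect_false(same, label = sprintf("deletion at %d went unnoticed", pos))
    } else {
      succeed()
    }
  }
})

test_that("random-run summary rows reproduce the published table layout", {
  runs <- list(
    list(run = 3L, n_clusters = 3L, n_clustered_genes = 6L,
         sizes = c(2L, 2L, 2L)),
    list(run = 4L, n_clusters = 1L, n_clustered_genes = 2L, sizes = 2L),
    list(run = 5L, n_clusters = 0L, n_clustered_genes = 0L,
         sizes = integer(0)))
  f <- tempfile()
  write_random_summary(runs, f)
  lines <- readLines(f)
  expect_identical(lines[1], "run\tn.clusts\tn.tot.clust.genes\tn.genes per cluster")
  expect_identical(strsplit(lines[2], "[ \t]+")[[1]], c("3", "3", "6", "2", "2", "2"))
  expect_identical(strsplit(lines[3], "[ \t]+")[[1]], c("4", "1", "2", "2"))
  expect_identical(strsplit(lines[4], "[ \t]+")[[1]], c("5", "0", "0"))
})
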