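chain5 <- function() {
  s <- c(0, 15000, 40000, 100000, 118000)
  gene_table("d1", paste0("g", 1:5), "chrA", start = s, end = s + 500,
             strand = 1L)
}

test_that("chaining at the start-distance threshold with singleton elimination", {
  cs <- pos_cluster(chain5(), threshold_bp = 20000)
  expect_identical(n_clusters(cs), 2L)
  expect_identical(cs$clusters[[1]]$name, c("g1", "g2"))
  expect_identical(cs$clusters[[2]]$name, c("g4", "g5"))  # g3 isolated (25 kb gap)

  # a gap exactly equal to the threshold still chains (<=, not <):
  # at D = 25000 the 25 kb gap pulls g3 into the first cluster
  cs_eq <- pos_cluster(chain5(), threshold_bp = 25000)
  expect_identical(partition_of(cs_eq),
                   canon_partition(list(c("g1", "g2", "g3"), c("g4", "g5"))))
})

test_that("cluster identifiers are progressive across chromosomes", {
  s <- c(0, 1000, 50000, 51000)
  gt <- gene_table("d", paste0("a", 1:4), "chrA", s, s + 10, 1L)
  gt2 <- gene_table("d", paste0("b", 1:2), "chrB", c(5, 1005), c(15, 1015), 1L)
  both <- as_gene_table(rbind(as.data.frame(gt), as.data.frame(gt2)))
  cs <- pos_cluster(both, 2000)
  expect_identical(n_clusters(cs), 3L)
  expect_identical(cs$clusters[[3]]$name, c("b1", "b2"))  # chrB starts at id 3
  expect_identical(cs$clusters[[3]]$chrom[1], "chrB")
})

test_that("threshold limit cases collapse or empty the clustering", {
  gt <- chain5()
  span <- max(gt$start) - min(gt$start)
  all_in <- pos_cluster(gt, span)
  expect_identical(n_clusters(all_in), 1L)
  expect_identical(nrow(all_in$clusters[[1]]), 5L)
  expect_identical(n_clusters(pos_cluster(gt, 1)), 0L)
})

test_that("partition equals the single-linkage oracle on random instances", {
  set.seed(31)
  for (i in 1:200) {
    gt <- rand_gene_table(sample(2:50, 1), n_chrom = sample(1:4, 1))
    D <- sample.int(3e5, 1)
    expect_identical(partition_of(pos_cluster(gt, D)), oracle_partition(gt, D))
  }
})

test_that("gap invariants hold inside and between clusters", {
  set.seed(32)
  for (i in 1:25) {
    gt <- rand_gene_table(sample(5:50, 1), n_chrom = 2)
    D <- sample.int(2e5, 1)
    cs <- pos_cluster(gt, D)
    for (cl in cs$clusters)
      if (nrow(cl) > 1) expect_true(all(diff(cl$start) <= D))
    chroms <- vapply(cs$clusters, function(cl) cl$chrom[1], character(1))
    for (ch in unique(chroms)) {
      ids <- which(chroms == ch)
      if (length(ids) > 1) {
        lasts <- vapply(cs$clusters[ids], function(cl) cl$start[nrow(cl)], numeric(1))
        firsts <- vapply(cs$clusters[ids], function(cl) cl$start[1], numeric(1))
        expect_true(all(firsts[-1] - lasts[-length(lasts)] > D))
      }
    }
  }
})

test_that("clustered-gene set grows monotonically with the threshold", {
  set.seed(33)
  for (i in 1:10) {
    gt <- rand_gene_table(30, n_chrom = 2)
    thresholds <- sort(sample.int(5e5, 6))
    prev <- character(0)
    for (D in thresholds) {
      cur <- clustered_genes(pos_cluster(gt, D))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("membership ignores strand and expression values", {
  set.seed(34)
  gt <- rand_gene_table(40, n_chrom = 2, n_expr = 3)
  D <- 1e5
  base <- partition_of(pos_cluster(gt, D))
  flipped <- gt
  flipped$strand <- -flipped$strand
  expect_identical(partition_of(pos_cluster(flipped, D)), base)
  shuffled <- gt
  perm <- sample.int(nrow(gt))
  for (cn in c("expr1", "expr2", "expr3")) shuffled[[cn]] <- gt[[cn]][perm]
  expect_identical(partition_of(pos_cluster(shuffled, D)), base)
})

test_that("add_genes merges, bridges, or creates clusters under the same rules", {
  gt <- gene_table("d1", c("g1", "g2"), "chrA", c(0, 15000), c(10, 15010), 1L)
  cs <- pos_cluster(gt, 20000)
  expect_identical(n_clusters(cs), 1L)

  g3 <- gene_table("new", "g3", "chrA", 30000, 30010, 1L)
  up <- add_genes(cs, g3)
  expect_identical(n_clusters(up), 1L)
  expect_identical(up$clusters[[1]]$name, c("g1", "g2", "g3"))
  expect_identical(up$clusters[[1]]$dset, c("d1", "d1", "new"))  # origin kept

  lone <- gene_table("new", "g4", "chrA", 200000, 200010, 1L)
  up2 <- add_genes(cs, lone)
  expect_false("g4" %in% clustered_genes(up2))

  pair <- gene_table("new", c("g5", "g6"), "chrA", c(300000, 305000),
                     c(300010, 305010), 1L)
  up3 <- add_genes(cs, pair)
  expect_identical(n_clusters(up3), 2L)
  expect_identical(up3$clusters[[2]]$name, c("g5", "g6"))

  expect_error(add_genes(cs, gene_table("new", "g1", "chrA", 7, 8, 1L)),
               "collision.*g1")
  expect_warning(add_genes(cs, g3, threshold_bp = 30000), "differs")
})

test_that("adding an empty set keeps the membership; update() is an alias", {
  set.seed(35)
  gt <- rand_gene_table(30, n_chrom = 2)
  cs <- pos_cluster(gt, 1e5)
  empty <- gene_table(character(0), character(0), character(0),
                      numeric(0), numeric(0), integer(0))
  expect_identical(partition_of(add_genes(cs, empty)), partition_of(cs))
  g_new <- gene_table("n", "zz", "chr1", 1, 2, 1L)
  expect_identical(partition_of(update(cs, g_new)),
                   partition_of(add_genes(cs, g_new)))
})

test_that("find_gene and extract_cluster behave as lookups", {
  cs <- pos_cluster(chain5(), 20000)
  expect_identical(find_gene(cs, "g5"), 2L)
  expect_identical(find_gene(cs, "g3"), NA_integer_)   # eliminated singleton
  expect_identical(find_gene(posclust:::new_posclust(list(), 1, 0L), "g1"),
                   NA_integer_)

  tab <- extract_cluster(cs, 2)
  expect_identical(tab$name, c("g4", "g5"))
  expect_identical(validate_gene_table(tab), character(0))
  # re-clustering an extracted cluster at the same threshold is a fixed point
  re <- pos_cluster(tab, cs$threshold_bp)
  expect_identical(partition_of(re), canon_partition(list(tab$name)))
  expect_error(extract_cluster(cs, 0), "ids run 1")
  expect_error(extract_cluster(cs, 99), "ids run 1")
})
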