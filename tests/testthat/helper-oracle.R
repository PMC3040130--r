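# Shared generators and the independent clustering oracle.
#
# The oracle is deliberately a different algorithm from the package's
# sequential chaining: classical single-linkage agglomeration of start
# coordinates (stats::hclust) cut at height D, followed by removal of
# singleton groups. On one-dimensional positions the two must produce the
# same partition.

rand_gene_table <- function(n_genes, n_chrom = 1L, n_expr = 0L,
                            max_pos = 1e6) {
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE)
  start <- sample.int(max_pos, n_genes, replace = TRUE)
  expr <- if (n_expr > 0L)
    matrix(round(stats::rnorm(n_genes * n_expr), 4), nrow = n_genes) else NULL
  gene_table(dset = sample(c("d1", "d2"), n_genes, replace = TRUE),
             name = sprintf("g%04d", seq_len(n_genes)),
             chrom = chrom, start = start,
             end = start + sample.int(5000, n_genes, replace = TRUE),
             strand = sample(c(1L, -1L), n_genes, replace = TRUE),
             expr = expr)
}

# canonical partition representation: sorted member names joined by ",",
# the whole set of clusters sorted
canon_partition <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

partition_of <- function(cs) {
  canon_partition(lapply(cs$clusters, `[[`, "name"))
}

oracle_partition <- function(table, D) {
  sets <- list()
  for (ch in unique(table$chrom)) {
    sub <- table[table$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2L) next
    grp <- stats::cutree(stats::hclust(stats::dist(sub$start), "single"), h = D)
    for (g in unique(grp)) {
      members <- sub$name[grp == g]
      if (length(members) >= 2L) sets[[length(sets) + 1L]] <- members
    }
  }
  canon_partition(sets)
}

# a random run-summary for format tests
rand_run_summary <- function(run) {
  k <- sample(0:5, 1)
  sizes <- if (k > 0) sample(2:6, k, replace = TRUE) else integer(0)
  list(run = run, n_clusters = k, n_clustered_genes = sum(sizes),
       sizes = as.integer(sizes))
}

# random posclust object built directly (for format round-trips)
rand_posclust <- function(n_clusters = 3L, n_expr = 2L) {
  clusters <- list()
  pos <- 0
  for (i in seq_len(n_clusters)) {
    sz <- sample(2:5, 1)
    start <- sort(pos + cumsum(sample.int(5000, sz)))
    pos <- max(start) + 1e5
    expr <- matrix(round(stats::rnorm(sz * n_expr), 4), nrow = sz)
    if (n_expr > 0 && stats::runif(1) < 0.3) expr[1, 1] <- NaN
    clusters[[i]] <- gene_table(
      dset = sample(c("d1", "d2"), sz, replace = TRUE),
      name = sprintf("c%d_g%d", i, seq_len(sz)),
      chrom = sample(c("chr2R", "chr3L"), 1), start = start,
      end = start + sample.int(3000, sz, replace = TRUE),
      strand = sample(c(1L, -1L), sz, replace = TRUE),
      expr = if (n_expr > 0) expr else NULL)
  }
  posclust:::new_posclust(clusters, threshold_bp = 20000, n_expr = n_expr)
}

expect_same_table <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
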