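# Deterministic synthetic-data generator. Emulates the structure of the
# package's real inputs — a Biomart-style position table plus a
# multi-condition expression table — with positional clusters planted at
# known locations, so clustering recovery can be checked against an exact
# ground truth without any external download.

#' Specify a synthetic dataset with planted positional clusters
#'
#' The default world resembles a mosquito-like genome: four chromosome arms
#' of 40-60 Mbp, two planted clusters per arm (3 and 4 genes) whose
#' consecutive gene starts are 2-10 kbp apart (inside a typical 20 kbp
#' clustering threshold chosen from mean gene density), plus isolated
#' background genes at least 50 kbp away from every other gene, and five
#' expression conditions per gene in which each planted cluster shares one
#' "hot" highly-expressed condition over low background noise (the
#' co-expressed co-localized hot-spot pattern). Any distance threshold
#' between the largest intra-cluster gap and the smallest isolation gap
#' recovers exactly the planted clusters.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param cluster_chrom,cluster_size parallel vectors: chromosome and gene
#'   count (>= 2) of each planted cluster.
#' @param gap_range length-2 numeric, min/max gap in bp between consecutive
#'   gene starts inside a planted cluster.
#' @param n_isolated number of isolated background genes overall.
#' @param isolation_gap minimum bp distance from an isolated gene (or a
#'   planted cluster boundary) to any neighboring gene; must exceed
#'   `max(gap_range)`.
#' @param n_expr number of expression conditions per gene.
#' @param hot_mean,background_mean mean expression of a planted cluster's
#'   hot condition and of everything else.
#' @param nan_rate fraction of expression cells set to the missing marker.
#' @param gene_length_range length-2 numeric, uniform range of gene lengths.
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   spec.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(chromosomes = c(chr2R = 61e6, chr2L = 49e6,
                                           chr3R = 53e6, chr3L = 42e6),
                           cluster_chrom = rep(names(chromosomes), each = 2),
                           cluster_size = rep(c(3L, 4L),
                                              length(chromosomes)),
                           gap_range = c(2000, 10000),
                           n_isolated = 20L,
                           isolation_gap = 50000,
                           n_expr = 5L,
                           hot_mean = 8, background_mean = 1,
                           nan_rate = 0,
                           gene_length_range = c(500, 5000),
                           seed = 1L) {
  stopifnot(length(chromosomes) >= 1L, !is.null(names(chromosomes)),
            all(chromosomes > 0),
            length(cluster_chrom) == length(cluster_size),
            all(cluster_size >= 2L),
            all(cluster_chrom %in% names(chromosomes)),
            length(gap_range) == 2L, gap_range[1L] > 0,
            gap_range[1L] <= gap_range[2L],
            n_isolated >= 0L, n_expr >= 0L,
            nan_rate >= 0, nan_rate <= 1,
            gene_length_range[1L] > 0,
            gene_length_range[1L] <= gene_length_range[2L])
  if (isolation_gap <= gap_range[2L])
    stop("isolation_gap must exceed the largest intra-cluster gap")
  structure(list(chromosomes = chromosomes,
                 cluster_chrom = as.character(cluster_chrom),
                 cluster_size = as.integer(cluster_size),
                 gap_range = gap_range, n_isolated = as.integer(n_isolated),
                 isolation_gap = isolation_gap, n_expr = as.integer(n_expr),
                 hot_mean = hot_mean, background_mean = background_mean,
                 nan_rate = nan_rate,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic position/expression dataset
#'
#' Lays the planted clusters and isolated genes out along each chromosome
#' in random order, separated by at least the isolation gap, and draws
#' expression values: members of a planted cluster share one hot condition
#' with high expression, all other cells are low background noise, and a
#' `nan_rate` fraction of cells is knocked out to the missing marker.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `positions` (data.frame as from
#'   [read_position_table()]), `expressions` (data.frame as from
#'   [read_expression_table()]), and `truth` (list of character vectors:
#'   the planted clusters' member names, in layout order).
#' @examples
#' syn <- generate_synthetic(synthetic_spec(seed = 7))
#' merged <- merge_position_expression(syn$positions, syn$expressions, "syn")
#' cs <- pos_cluster(merged$table, threshold_bp = 20000)
#' n_clusters(cs) == length(syn$truth)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  chrom_names <- names(spec$chromosomes)
  # groups: one per planted cluster, one per isolated gene
  iso_chrom <- if (spec$n_isolated > 0L)
    sample(chrom_names, spec$n_isolated, replace = TRUE) else character(0)
  groups <- data.frame(
    chrom = c(spec$cluster_chrom, iso_chrom),
    size = c(spec$cluster_size, rep(1L, spec$n_isolated)),
    cluster = c(seq_along(spec$cluster_size),
                rep(NA_integer_, spec$n_isolated)),
    stringsAsFactors = FALSE)

  rows <- list()
  gidx <- 0L
  truth_names <- vector("list", length(spec$cluster_size))
  for (ch in chrom_names) {
    g <- groups[groups$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[sample.int(nrow(g)), , drop = FALSE]  # random order along the arm
    cursor <- stats::runif(1, 0, min(1e6, spec$chromosomes[[ch]] / 10))
    for (i in seq_len(nrow(g))) {
      starts <- cursor
      if (g$size[i] > 1L)
        starts <- cursor + c(0, cumsum(stats::runif(g$size[i] - 1L,
                                                    spec$gap_range[1L],
                                                    spec$gap_range[2L])))
      starts <- round(starts)
      lens <- round(stats::runif(g$size[i], spec$gene_length_range[1L],
                                 spec$gene_length_range[2L]))
      names_i <- sprintf("g%05d", gidx + seq_len(g$size[i]))
      gidx <- gidx + g$size[i]
      rows[[length(rows) + 1L]] <- data.frame(
        name = names_i, chrom = ch, start = starts, end = starts + lens,
        strand = sample(c(1L, -1L), g$size[i], replace = TRUE),
        cluster = g$cluster[i], stringsAsFactors = FALSE)
      if (!is.na(g$cluster[i])) truth_names[[g$cluster[i]]] <- names_i
      cursor <- max(starts) +
        stats::runif(1, spec$isolation_gap, 2 * spec$isolation_gap)
    }
    if (cursor > spec$chromosomes[[ch]])
      stop(sprintf("infeasible spec: layout exceeds the length of %s", ch))
  }
  pos <- do.call(rbind, rows)

  expr <- NULL
  if (spec$n_expr > 0L) {
    n <- nrow(pos)
    expr <- matrix(pmax(stats::rnorm(n * spec$n_expr,
                                     spec$background_mean,
                                     spec$background_mean / 4), 0),
                   nrow = n)
    hot_stage <- sample.int(spec$n_expr, length(spec$cluster_size),
                            replace = TRUE)
    for (ci in seq_along(spec$cluster_size)) {
      rows_ci <- which(pos$cluster == ci)
      expr[rows_ci, hot_stage[ci]] <-
        stats::rnorm(length(rows_ci), spec$hot_mean, spec$hot_mean / 10)
    }
    if (spec$nan_rate > 0) {
      knock <- which(stats::runif(length(expr)) < spec$nan_rate)
      expr[knock] <- NaN
    }
  }

  expressions <- data.frame(name = pos$name, stringsAsFactors = FALSE)
  expressions$values <- if (is.null(expr)) rep(list(numeric(0)), nrow(pos))
                        else lapply(seq_len(nrow(pos)), function(i) expr[i, ])
  list(positions = pos[, c("name", "chrom", "start", "end", "strand")],
       expressions = expressions,
       truth = truth_names)
}

#' Write a synthetic dataset to delimited text files
#'
#' @param syn the list returned by [generate_synthetic()].
#' @param dir output directory (created if absent); writes
#'   `positions.tsv`, `expressions.tsv`, `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(syn, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- syn$positions
  writeLines(sprintf("%s\t%s\t%s\t%s\t%d", p$name, p$chrom,
                     fmt_pos(p$start), fmt_pos(p$end), p$strand),
             file.path(dir, "positions.tsv"))
  e <- syn$expressions
  writeLines(vapply(seq_len(nrow(e)), function(i) {
    paste(c(e$name[i], fmt_num(e$values[[i]])), collapse = "\t")
  }, character(1)), file.path(dir, "expressions.tsv"))
  jsonlite::write_json(syn$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
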