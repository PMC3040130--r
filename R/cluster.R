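#' Positional clustering of genes along chromosomes
#'
#' Fits the positional clustering model: each chromosome is traversed in
#' gene start order and a gene joins the cluster of the previous gene
#' whenever the distance between the two start coordinates is smaller than
#' or equal to the distance threshold `threshold_bp`; a larger gap starts a
#' new cluster. Strand plays no role in the distance, and expression values
#' never influence membership — expression is used upstream, to select which
#' genes enter the table (see [filter_by_expression()]). Clusters of a
#' single gene are eliminated during the traversal, and surviving clusters
#' are tagged with progressive numeric identifiers 1, 2, ... across the
#' whole run, chromosomes taken in order of first appearance.
#'
#' The threshold is the model's only parameter. It is a plain base-pair
#' cutoff, typically chosen from the mean gene density of the genome under
#' study (for example 20 kbp for the Anopheles gambiae genome); running the
#' analysis at several thresholds probes regions of different gene density.
#'
#' @param table a valid, position-sorted `gene_table` (see [gene_table()];
#'   an unsorted table is an error — sort with [sort_gene_table()] first).
#' @param threshold_bp positive distance threshold in base pairs.
#' @return An object of class `"posclust"`: a list with elements
#'   `clusters` (list of `gene_table`s, one per cluster, indexed by the
#'   cluster identifier), `threshold_bp`, `n_expr`, `n_input_genes`.
#'   Methods: [print.posclust()], [summary.posclust()], [plot.posclust()],
#'   [update.posclust()].
#' @examples
#' gt <- gene_table("d1", paste0("g", 1:5), "chrA",
#'                  start = c(0, 15000, 40000, 100000, 118000),
#'                  end = c(0, 15000, 40000, 100000, 118000) + 500,
#'                  strand = 1L)
#' cs <- pos_cluster(gt, threshold_bp = 20000)
#' cs             # two clusters: {g1,g2} and {g4,g5}; g3 is isolated
#' find_gene(cs, "g5")
#' @export
pos_cluster <- function(table, threshold_bp) {
  if (!is.numeric(threshold_bp) || length(threshold_bp) != 1L ||
      is.na(threshold_bp) || threshold_bp <= 0)
    stop("threshold_bp must be a positive number of base pairs")
  stop_if_invalid(table)
  clusters <- list()
  for (ch in unique(table$chrom)) {
    sub <- table[table$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) next
    gap_gt <- c(TRUE, diff(sub$start) > threshold_bp)  # TRUE opens a run
    run_id <- cumsum(gap_gt)
    for (r in seq_len(run_id[n])) {
      idx <- which(run_id == r)
      if (length(idx) < 2L) next  # singleton elimination
      cl <- sub[idx, , drop = FALSE]
      rownames(cl) <- NULL
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  new_posclust(clusters, threshold_bp = threshold_bp, n_expr = n_expr(table),
               n_input_genes = nrow(table))
}

new_posclust <- function(clusters, threshold_bp, n_expr,
                         n_input_genes = NA_integer_) {
  structure(list(clusters = clusters,
                 threshold_bp = threshold_bp,
                 n_expr = as.integer(n_expr),
                 n_input_genes = n_input_genes),
            class = "posclust")
}

#' Number of clusters in a clustering result
#' @param cs a `posclust` object.
#' @return integer.
#' @export
n_clusters <- function(cs) length(cs$clusters)

#' Per-cluster gene counts
#' @param cs a `posclust` object.
#' @return integer vector of cluster sizes in cluster-id order.
#' @export
cluster_sizes <- function(cs)
  vapply(cs$clusters, nrow, integer(1))

#' Names of all clustered genes
#' @param cs a `posclust` object.
#' @return character vector, in cluster-id then within-cluster order.
#' @export
clustered_genes <- function(cs)
  unlist(lapply(cs$clusters, `[[`, "name"), use.names = FALSE)

#' Find the cluster containing a gene
#'
#' @param cs a `posclust` object.
#' @param name gene name to look up.
#' @return the numeric cluster identifier, or `NA_integer_` if the gene is
#'   in no cluster.
#' @export
find_gene <- function(cs, name) {
  for (cid in seq_along(cs$clusters))
    if (name %in% cs$clusters[[cid]]$name) return(cid)
  NA_integer_
}

#' Extract one cluster as a gene table
#'
#' Projects the members of a single cluster back into a standalone
#' `gene_table`, suitable for any downstream operation (writing as GDF,
#' re-clustering, viewing). Re-clustering the extracted table at the same
#' threshold yields exactly one cluster with the same membership.
#'
#' @param cs a `posclust` object.
#' @param cid cluster identifier (1-based).
#' @return a `gene_table` with the cluster's members in position order.
#' @export
extract_cluster <- function(cs, cid) {
  if (!is.numeric(cid) || length(cid) != 1L || is.na(cid) ||
      cid != floor(cid) || cid < 1L || cid > length(cs$clusters))
    stop(sprintf("no cluster with id %s (ids run 1..%d)",
                 format(cid), length(cs$clusters)))
  cs$clusters[[cid]]
}

#' Update a clustering with additional genes
#'
#' Adds a new set of genes to an existing clustering result: the union of
#' the current cluster members and the added genes is re-sorted and
#' re-clustered under the same rules, so new genes may merge into existing
#' clusters, bridge them, or form new independent clusters. Cluster
#' identifiers are reassigned by the new traversal. Tag the added genes
#' with a distinct `dset` label to keep their origin recognizable in the
#' result and in CLU output.
#'
#' Genes eliminated as singletons in the original run are no longer part of
#' the `posclust` object and are not reconsidered; to avoid that
#' information loss, merge the full gene tables and rerun [pos_cluster()].
#'
#' @param existing a `posclust` object.
#' @param added a valid `gene_table` of genes to add; names must not
#'   collide with existing cluster members.
#' @param threshold_bp distance threshold; defaults to the one stored in
#'   `existing`. A different value is allowed but warns.
#' @return a new `posclust` object.
#' @export
add_genes <- function(existing, added, threshold_bp = existing$threshold_bp) {
  stopifnot(inherits(existing, "posclust"))
  stop_if_invalid(added, "added gene table")
  if (existing$n_expr != n_expr(added))
    stop(sprintf("added genes carry %d expression value(s) but clusters carry %d",
                 n_expr(added), existing$n_expr))
  if (!is.na(existing$threshold_bp) && threshold_bp != existing$threshold_bp)
    warning(sprintf(
      "threshold_bp (%g) differs from the one used at creation (%g)",
      threshold_bp, existing$threshold_bp))
  old <- do.call(rbind, lapply(existing$clusters, as.data.frame))
  collide <- intersect(old$name, added$name)
  if (length(collide))
    stop("gene name collision between clusters and added genes: ",
         paste(collide, collapse = ", "))
  union_tab <- as_gene_table(rbind(old, as.data.frame(added)), sort = TRUE)
  pos_cluster(union_tab, threshold_bp)
}

#' @rdname add_genes
#' @param object a `posclust` object (for the `update` method).
#' @param ... unused.
#' @export
update.posclust <- function(object, added,
                            threshold_bp = object$threshold_bp, ...) {
  add_genes(object, added, threshold_bp)
}

#' @export
print.posclust <- function(x, ...) {
  cat("Positional clustering\n")
  cat(sprintf("  distance threshold: %s bp\n",
              if (is.na(x$threshold_bp)) "unknown"
              else format(x$threshold_bp, big.mark = ",", scientific = FALSE)))
  sizes <- cluster_sizes(x)
  cat(sprintf("  clusters: %d  (clustered genes: %d%s)\n",
              length(sizes), sum(sizes),
              if (is.na(x$n_input_genes)) ""
              else sprintf(" of %d input genes", x$n_input_genes)))
  if (length(sizes)) {
    chroms <- vapply(x$clusters, function(cl) cl$chrom[1L], character(1))
    for (ch in unique(chroms)) {
      ids <- which(chroms == ch)
      cat(sprintf("  %s: %d cluster(s), sizes %s\n", ch, length(ids),
                  paste(sizes[ids], collapse = " ")))
    }
  }
  invisible(x)
}

#' Summarize a positional clustering result
#'
#' @param object a `posclust` object.
#' @param ... unused.
#' @return an object of class `"summary.posclust"`: cluster count, clustered
#'   gene count, the empirical cluster-size distribution (see
#'   [size_distribution()]), and per-chromosome cluster counts.
#' @export
summary.posclust <- function(object, ...) {
  sizes <- cluster_sizes(object)
  chroms <- vapply(object$clusters, function(cl) cl$chrom[1L], character(1))
  structure(list(
    threshold_bp = object$threshold_bp,
    n_clusters = length(sizes),
    n_clustered_genes = sum(sizes),
    n_input_genes = object$n_input_genes,
    size_distribution = size_distribution(object),
    clusters_per_chrom = if (length(chroms)) table(chroms) else table(character(0))
  ), class = "summary.posclust")
}

#' @export
print.summary.posclust <- function(x, ...) {
  cat("Positional clustering summary\n")
  cat(sprintf("  threshold: %s bp, clusters: %d, clustered genes: %d%s\n",
              format(x$threshold_bp, scientific = FALSE), x$n_clusters,
              x$n_clustered_genes,
              if (is.na(x$n_input_genes)) ""
              else sprintf("/%d", x$n_input_genes)))
  print(x$size_distribution)
  invisible(x)
}

#' Plot a positional clustering result
#'
#' Draws the multiple-cluster view with base graphics: one horizontal line
#' per chromosome spanning its first to last cluster, left-aligned on a
#' shared base-pair scale, one circle per cluster at the start of its first
#' gene with area proportional to the member count. For the editable
#' vector-graphics rendering, see [render_multi_cluster_view()].
#'
#' @param x a `posclust` object with at least one cluster.
#' @param labels draw cluster-id and first-gene kbp labels (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.posclust <- function(x, labels = TRUE, ...) {
  if (length(x$clusters) == 0L) stop("nothing to draw: no clusters")
  chroms <- unique(vapply(x$clusters, function(cl) cl$chrom[1L], character(1)))
  firsts <- vapply(x$clusters, function(cl) cl$start[1L], numeric(1))
  lasts <- vapply(x$clusters, function(cl) cl$start[nrow(cl)], numeric(1))
  sizes <- cluster_sizes(x)
  ymap <- stats::setNames(rev(seq_along(chroms)), chroms)
  span <- vapply(chroms, function(ch) {
    idx <- vapply(x$clusters, function(cl) cl$chrom[1L] == ch, logical(1))
    max(lasts[idx]) - min(firsts[idx])
  }, numeric(1))
  graphics::plot(NA, xlim = c(0, max(span, 1)), ylim = c(0.5, length(chroms) + 0.5),
                 xlab = "position from first cluster (bp)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = ymap, labels = chroms, las = 1)
  for (ch in chroms) {
    idx <- which(vapply(x$clusters, function(cl) cl$chrom[1L] == ch, logical(1)))
    x0 <- min(firsts[idx])
    graphics::segments(0, ymap[ch], max(lasts[idx]) - x0, ymap[ch])
    graphics::symbols(firsts[idx] - x0, rep(ymap[ch], length(idx)),
                      circles = sqrt(sizes[idx] / max(sizes)) * max(span) / 60,
                      inches = FALSE, add = TRUE, bg = "steelblue")
    if (labels)
      graphics::text(firsts[idx] - x0, ymap[ch] + 0.25,
                     sprintf("%d (%.0f kbp)", idx, firsts[idx] / 1000),
                     cex = 0.7)
  }
  invisible(x)
}
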