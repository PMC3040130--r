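# Random-gene-set baseline and the significance test applied to clustering
# summaries. The null sample is built by repeatedly clustering uniformly
# drawn gene subsets from a pool; the observed result is then compared with
# a one-sample t-test, implemented here from the closed form.

#' Cluster random gene sets from a pool
#'
#' Builds the randomization baseline for assessing clustering significance:
#' in each of `runs` repetitions, `n` genes are drawn uniformly without
#' replacement from the pool table, the draw is position-sorted and
#' clustered with [pos_cluster()] at the given threshold, and the run is
#' summarized by its cluster count, total clustered genes, and per-cluster
#' sizes. The pool is typically a large set (e.g. all coding genes of the
#' genome) which may or may not include the genes under study. Fully
#' deterministic given `seed`: per-run substreams are derived from the one
#' seed, so summaries are reproducible run by run.
#'
#' @param pool a valid `gene_table` to draw from.
#' @param n number of genes per draw (`2 <= n <= nrow(pool)`).
#' @param runs number of repetitions (>= 1).
#' @param threshold_bp clustering distance threshold in base pairs.
#' @param seed integer seed for the whole batch.
#' @return an object of class `"random_runs"`: a list of per-run summaries,
#'   each a list with `run`, `n_clusters`, `n_clustered_genes`, `sizes`.
#'   Write it in the tabular exchange format with [write_random_summary()].
#' @seealso [compare_observed_vs_random()] for the significance test.
#' @export
random_clustering_runs <- function(pool, n, runs, threshold_bp, seed = 1L) {
  stop_if_invalid(pool, "pool")
  if (n > nrow(pool))
    stop(sprintf("cannot draw %d genes from a pool of %d", n, nrow(pool)))
  if (n < 1L || runs < 1L) stop("n and runs must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, runs)
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    set.seed(run_seeds[r])
    draw <- sort_gene_table(pool[sample.int(nrow(pool), n), , drop = FALSE])
    cs <- pos_cluster(draw, threshold_bp)
    out[[r]] <- summarize_run(cs, r)
  }
  structure(out, class = "random_runs")
}

summarize_run <- function(cs, run) {
  sizes <- cluster_sizes(cs)
  list(run = as.integer(run), n_clusters = length(sizes),
       n_clustered_genes = sum(sizes), sizes = as.integer(sizes))
}

#' @export
print.random_runs <- function(x, ...) {
  cat(sprintf("Random clustering baseline: %d run(s)\n", length(x)))
  nc <- vapply(x, `[[`, integer(1), "n_clusters")
  ng <- vapply(x, `[[`, integer(1), "n_clustered_genes")
  cat(sprintf("  clusters/run: mean %.2f (range %d-%d); clustered genes/run: mean %.2f\n",
              mean(nc), min(nc), max(nc), mean(ng)))
  invisible(x)
}

#' Empirical distribution of cluster sizes
#'
#' Returns the probability distribution of cluster sizes of a clustering
#' result, together with the derived indicators commonly reported:
#' the fraction of input genes that ended up in clusters, and the
#' proportions of clusters (and of clustered genes) in clusters of exactly
#' two, of three or more, and of four or more genes. Two-gene clusters are
#' often discounted as possible local duplications, so the larger-size
#' breakdown is what identifies transcriptional hot-spots.
#'
#' @param cs a `posclust` object.
#' @return an object of class `"size_distribution"`: list with `probs`
#'   (named numeric vector, size -> probability, empty when there are no
#'   clusters), `n_clusters`, `n_clustered_genes`, `frac_genes_clustered`
#'   (`NA` when the input gene count is unknown), `prop_clusters`
#'   and `prop_genes` (each with elements `eq2`, `ge3`, `ge4`).
#' @examples
#' gt <- gene_table("d", paste0("g", 1:7), "c1",
#'                  start = c(0, 1, 2, 100, 101, 200, 201) * 1000,
#'                  end = c(0, 1, 2, 100, 101, 200, 201) * 1000 + 10,
#'                  strand = 1L)
#' size_distribution(pos_cluster(gt, 5000))  # sizes 3,2,2
#' @export
size_distribution <- function(cs) {
  stopifnot(inherits(cs, "posclust"))
  sizes <- cluster_sizes(cs)
  if (length(sizes) == 0L) {
    probs <- stats::setNames(numeric(0), character(0))
  } else {
    tab <- table(sizes)
    probs <- as.numeric(tab) / length(sizes)
    names(probs) <- names(tab)
  }
  ngenes <- sum(sizes)
  prop <- function(x, tot) if (tot > 0) x / tot else NA_real_
  structure(list(
    probs = probs,
    n_clusters = length(sizes),
    n_clustered_genes = ngenes,
    frac_genes_clustered = if (is.na(cs$n_input_genes)) NA_real_
                           else prop(ngenes, cs$n_input_genes),
    prop_clusters = list(eq2 = prop(sum(sizes == 2L), length(sizes)),
                         ge3 = prop(sum(sizes >= 3L), length(sizes)),
                         ge4 = prop(sum(sizes >= 4L), length(sizes))),
    prop_genes = list(eq2 = prop(sum(sizes[sizes == 2L]), ngenes),
                      ge3 = prop(sum(sizes[sizes >= 3L]), ngenes),
                      ge4 = prop(sum(sizes[sizes >= 4L]), ngenes))
  ), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  if (x$n_clusters == 0L) {
    cat("Cluster size distribution: no clusters\n")
    return(invisible(x))
  }
  cat(sprintf("Cluster size distribution (%d clusters, %d genes):\n",
              x$n_clusters, x$n_clustered_genes))
  for (s in names(x$probs))
    cat(sprintf("  size %s: %.4f\n", s, x$probs[[s]]))
  cat(sprintf("  %% of genes in clusters n=2: %.1f%%, n>=3: %.1f%%, n>=4: %.1f%%\n",
              100 * x$prop_genes$eq2, 100 * x$prop_genes$ge3,
              100 * x$prop_genes$ge4))
  invisible(x)
}

#' Write the size distribution as a text table
#'
#' @param sd a `size_distribution`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(sd, path) {
  stopifnot(inherits(sd, "size_distribution"))
  out <- c("size\tprobability",
           sprintf("%s\t%s", names(sd$probs), fmt_num(unname(sd$probs))))
  writeLines(out, path)
  invisible(path)
}

#' One-sample Student's t-test
#'
#' Tests whether the mean of a sample differs from a hypothesized value
#' `mu`: `t = (mean(x) - mu) / (sd(x) / sqrt(k))` on `k - 1` degrees of
#' freedom, two-sided p-value from the Student's t distribution. This is
#' the test applied to the randomization baseline (the random-run
#' statistics are the sample, the observed clustering statistic is `mu`).
#'
#' @param sample numeric vector, length >= 2, with positive standard
#'   deviation.
#' @param mu hypothesized mean.
#' @return list with `t`, `df`, `p` (two-sided), `mean`, `sd`, `n`.
#' @examples
#' one_sample_t_test(c(1, 2, 3), mu = 0)
#' @export
one_sample_t_test <- function(sample, mu) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L) stop("sample must contain at least 2 values")
  if (anyNA(sample)) stop("sample contains missing values")
  s <- stats::sd(sample)
  if (s == 0)
    stop("zero-variance sample: report the degenerate comparison instead ",
         "(all random runs identical)")
  k <- length(sample)
  t <- (mean(sample) - mu) / (s / sqrt(k))
  df <- k - 1L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean = mean(sample), sd = s, n = k)
}

#' Compare an observed clustering statistic with the random baseline
#'
#' Extracts one summary statistic (`n_clusters`, `n_clustered_genes`, or
#' `mean_cluster_size`) from each randomization run and tests, with
#' [one_sample_t_test()], whether the random sample's mean differs from the
#' observed value. If every random run yields the same value the test is
#' degenerate (zero variance): a flagged report is returned with `t`, `df`,
#' `p` set to `NA`, stating whether the observed value lies outside the
#' (single-valued) random support. Runs with no clusters have no defined
#' mean cluster size and are dropped from that statistic with a warning.
#'
#' @param observed either a `posclust` object or a single observed numeric
#'   value of the chosen statistic.
#' @param randoms a `"random_runs"` object (>= 2 runs).
#' @param statistic which summary to compare (default `"n_clusters"`).
#' @return an object of class `"posclust_test"`: list with `statistic`,
#'   `observed`, `random_mean`, `random_sd`, `n_runs`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
compare_observed_vs_random <- function(observed, randoms,
                                       statistic = c("n_clusters",
                                                     "n_clustered_genes",
                                                     "mean_cluster_size")) {
  statistic <- match.arg(statistic)
  if (length(randoms) < 2L) stop("need at least 2 random runs")
  obs <- if (inherits(observed, "posclust"))
    extract_statistic(summarize_run(observed, 0L), statistic)
  else as.numeric(observed)
  vals <- vapply(randoms, extract_statistic, numeric(1), statistic)
  if (statistic == "mean_cluster_size" && anyNA(vals)) {
    warning(sprintf("%d run(s) with no clusters dropped (undefined mean cluster size)",
                    sum(is.na(vals))))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) stop("fewer than 2 usable random runs")
  }
  if (stats::sd(vals) == 0) {
    res <- list(statistic = statistic, observed = obs,
                random_mean = mean(vals), random_sd = 0,
                n_runs = length(vals), t = NA_real_, df = NA_integer_,
                p = NA_real_, degenerate = TRUE,
                outside_support = obs != vals[1L])
  } else {
    tt <- one_sample_t_test(vals, mu = obs)
    res <- list(statistic = statistic, observed = obs,
                random_mean = tt$mean, random_sd = tt$sd,
                n_runs = tt$n, t = tt$t, df = tt$df, p = tt$p,
                degenerate = FALSE, outside_support = NA)
  }
  structure(res, class = "posclust_test")
}

extract_statistic <- function(run, statistic) {
  switch(statistic,
         n_clusters = as.numeric(run$n_clusters),
         n_clustered_genes = as.numeric(run$n_clustered_genes),
         mean_cluster_size = if (run$n_clusters == 0L) NA_real_
                             else run$n_clustered_genes / run$n_clusters)
}

#' @export
print.posclust_test <- function(x, ...) {
  cat(sprintf("One-sample t-test: observed %s vs %d random runs\n",
              x$statistic, x$n_runs))
  cat(sprintf("  observed = %g, random mean = %g (sd %g)\n",
              x$observed, x$random_mean, x$random_sd))
  if (x$degenerate) {
    cat(sprintf("  degenerate: all random runs identical; observed %s the random value\n",
                if (isTRUE(x$outside_support)) "differs from" else "equals"))
  } else {
    cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$t, x$df, x$p))
  }
  invisible(x)
}
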