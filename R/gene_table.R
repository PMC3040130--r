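#' Construct a gene table
#'
#' A gene table is the package's central in-memory structure: one row per gene
#' carrying a dataset-origin label (`dset`), the gene name, its chromosome,
#' start/end coordinates in base pairs (1-based, inclusive, as exported by
#' Biomart; never rescaled), the strand encoded as +1/-1, and zero or more
#' numeric expression values (`expr1`, `expr2`, ...). A missing expression
#' value is `NaN`. On disk the same structure is the GDF (gene data file)
#' format; see [read_gdf()] / [write_gdf()].
#'
#' Gene and dataset names are whitespace-delimited fields in the GDF/CLU file
#' formats, so neither may contain whitespace. Gene names must be unique
#' within a table. Within each chromosome genes are kept in non-decreasing
#' start order (ties broken by end, then name); chromosomes keep the order of
#' their first appearance.
#'
#' @param dset character vector of dataset labels (no whitespace), recycled.
#' @param name character vector of gene names (no whitespace, unique).
#' @param chrom character vector of chromosome/contig names.
#' @param start,end integer-valued base-pair coordinates, `start <= end`.
#' @param strand integer vector with values in `c(1L, -1L)`.
#' @param expr numeric matrix (genes x conditions) of expression values, or
#'   `NULL` for a table with no expression columns. `NaN` marks missing.
#' @param sort if `TRUE` (default) sort rows into canonical order.
#'
#' @return A `data.frame` of class `"gene_table"` with columns `dset`,
#'   `name`, `chrom`, `start`, `end`, `strand`, `expr1..exprK`.
#' @examples
#' gt <- gene_table("d1", c("gA", "gB"), "chr2R",
#'                  start = c(100, 5000), end = c(900, 5400),
#'                  strand = c(1L, -1L), expr = cbind(c(1.5, 2), c(NaN, 0)))
#' n_expr(gt)
#' @export
gene_table <- function(dset, name, chrom, start, end, strand,
                       expr = NULL, sort = TRUE) {
  n <- length(name)
  df <- data.frame(
    dset = rep_len(as.character(dset), n),
    name = as.character(name),
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.integer(strand), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    if (n > 0L && nrow(expr) != n)
      stop("expr must have one row per gene")
    if (ncol(expr) > 0L) {
      colnames(expr) <- paste0("expr", seq_len(ncol(expr)))
      df <- cbind(df, as.data.frame(expr))
    }
  }
  class(df) <- c("gene_table", "data.frame")
  if (sort) df <- sort_gene_table(df)
  df
}

#' Coerce a data frame to a gene table
#'
#' @param x a data.frame with at least the six positional columns of a gene
#'   table; any columns named `expr<k>` are kept as expression values.
#' @param sort sort rows into canonical order (default `TRUE`).
#' @return a `gene_table`.
#' @export
as_gene_table <- function(x, sort = TRUE) {
  req <- c("dset", "name", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  ecols <- grep("^expr[0-9]+$", names(x), value = TRUE)
  expr <- if (length(ecols)) {
    as.matrix(x[, ecols[order(as.integer(sub("expr", "", ecols)))], drop = FALSE])
  } else NULL
  gene_table(x$dset, x$name, x$chrom, x$start, x$end, x$strand,
             expr = expr, sort = sort)
}

#' Number of expression values per gene
#'
#' @param x a `gene_table` or `posclust` object.
#' @return integer count of expression columns.
#' @export
n_expr <- function(x) {
  if (inherits(x, "posclust")) return(x$n_expr)
  length(expr_cols(x))
}

expr_cols <- function(x) grep("^expr[0-9]+$", names(x), value = TRUE)

#' Expression values as a matrix
#'
#' @param x a `gene_table`.
#' @return numeric matrix, genes x conditions (0 columns when no expression).
#' @export
expr_matrix <- function(x) {
  ec <- expr_cols(x)
  m <- as.matrix(as.data.frame(x)[, ec, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x$name
  m
}

#' Sort a gene table into canonical order
#'
#' Chromosomes keep their first-appearance order; within a chromosome rows
#' are sorted by (start, end, name) ascending. This is the order the
#' clustering traversal and the GDF writer assume.
#'
#' @param x a `gene_table`.
#' @return the sorted `gene_table`.
#' @export
sort_gene_table <- function(x) {
  if (nrow(x) == 0L) return(x)
  chrom_rank <- match(x$chrom, unique(x$chrom))
  o <- order(chrom_rank, x$start, x$end, x$name)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a gene table
#'
#' Checks every structural invariant of the gene table: coordinate ordering
#' (`start <= end`), strand domain, whitespace-free names and dataset labels,
#' name uniqueness, non-negative starts, and per-chromosome position sorting.
#' Validation never throws; it reports.
#'
#' @param x a `gene_table` (or any data.frame with its columns).
#' @return character vector of violation messages, each naming the offending
#'   gene and rule; `character(0)` when the table is valid.
#' @examples
#' gt <- gene_table("d", c("g1", "g2"), "chr1", c(10, 5), c(20, 2),
#'                  c(1L, 1L), sort = FALSE)
#' validate_gene_table(gt)  # reports start>end and unsorted order
#' @export
validate_gene_table <- function(x) {
  v <- character(0)
  if (nrow(x) == 0L) return(v)
  bad <- which(x$start > x$end)
  for (i in bad) v <- c(v, sprintf("start>end %s", x$name[i]))
  bad <- which(!(x$strand %in% c(1L, -1L)))
  for (i in bad) v <- c(v, sprintf("strand not +1/-1 %s", x$name[i]))
  bad <- which(x$start < 0)
  for (i in bad) v <- c(v, sprintf("negative start %s", x$name[i]))
  bad <- which(grepl("[[:space:]]", x$name))
  for (i in bad) v <- c(v, sprintf("whitespace in name %s", x$name[i]))
  bad <- which(grepl("[[:space:]]", x$dset))
  for (i in bad) v <- c(v, sprintf("whitespace in dset %s", x$dset[i]))
  dup <- unique(x$name[duplicated(x$name)])
  for (nm in dup) v <- c(v, sprintf("duplicate name %s", nm))
  # per-chromosome (start, end, name) ordering, chromosomes contiguous in
  # first-appearance order
  chrom_rank <- match(x$chrom, unique(x$chrom))
  o <- order(chrom_rank, x$start, x$end, x$name)
  if (!identical(o, seq_len(nrow(x)))) {
    first_bad <- which(o != seq_len(nrow(x)))[1L]
    v <- c(v, sprintf("not position-sorted (first out-of-order gene %s)",
                      x$name[first_bad]))
  }
  v
}

stop_if_invalid <- function(x, what = "gene table") {
  v <- validate_gene_table(x)
  if (length(v))
    stop(what, " is not valid: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(x)
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("Gene table: %d genes, %d chromosomes, %d expression value(s) per gene\n",
              nrow(x), length(unique(x$chrom)), n_expr(x)))
  NextMethod()
}
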