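#' Merge position and expression tables into a gene table
#'
#' Joins a Biomart-style position table with an expression table on the gene
#' name and produces a position-sorted [gene_table()] tagged with a dataset
#' label. Duplicate gene names in either input keep only their first
#' encountered instance (duplicate handling beyond keep-first-and-warn is
#' deliberately left to the analyst); genes present in only one of the two
#' inputs are dropped with a warning, mirroring the exclusion of genes whose
#' coordinates cannot be retrieved. Missing expression cells become `NaN`,
#' and ragged expression rows are padded with `NaN` to the longest observed
#' row. Passing `expressions = NULL` builds a table with a single all-zero
#' expression column, for clustering on position alone.
#'
#' @param positions data.frame as returned by [read_position_table()].
#' @param expressions data.frame as returned by [read_expression_table()],
#'   or `NULL`.
#' @param dset_label dataset-origin label (non-empty, no whitespace).
#' @return a list with elements `table` (the merged `gene_table`),
#'   `duplicates` (character vector of duplicated names, first-instance
#'   kept) and `dropped` (names present in only one input).
#' @examples
#' pos <- data.frame(name = c("gA", "gB"), chrom = "chr1",
#'                   start = c(100, 50), end = c(500, 300),
#'                   strand = c(1L, -1L))
#' ex <- data.frame(name = c("gA", "gB"))
#' ex$values <- list(1.0, 2.0)
#' merge_position_expression(pos, ex, "d1")$table
#' @export
merge_position_expression <- function(positions, expressions, dset_label) {
  if (!is.character(dset_label) || length(dset_label) != 1L ||
      !nzchar(dset_label) || grepl("[[:space:]]", dset_label))
    stop("dset_label must be a non-empty string without whitespace")
  duplicates <- character(0)

  dup_p <- duplicated(positions$name)
  duplicates <- c(duplicates, unique(positions$name[dup_p]))
  positions <- positions[!dup_p, , drop = FALSE]

  if (is.null(expressions)) {
    expressions <- data.frame(name = positions$name, stringsAsFactors = FALSE)
    expressions$values <- rep(list(0), nrow(positions))
  }
  dup_e <- duplicated(expressions$name)
  duplicates <- c(duplicates, unique(expressions$name[dup_e]))
  expressions <- expressions[!dup_e, , drop = FALSE]
  duplicates <- unique(duplicates)
  if (length(duplicates))
    warning("duplicate gene name(s), first instance kept: ",
            paste(duplicates, collapse = ", "))

  common <- intersect(positions$name, expressions$name)
  if (length(common) == 0L)
    stop("no overlapping genes between position and expression tables")
  dropped <- c(setdiff(expressions$name, positions$name),
               setdiff(positions$name, expressions$name))
  if (length(dropped))
    warning("gene(s) present in only one input were excluded: ",
            paste(dropped, collapse = ", "))

  pos <- positions[positions$name %in% common, , drop = FALSE]
  vals <- expressions$values[match(pos$name, expressions$name)]
  k <- max(lengths(vals), 0L)
  expr <- NULL
  if (k > 0L) {
    expr <- do.call(rbind, lapply(vals, function(v)
      c(v, rep(NaN, k - length(v)))))
  }
  tab <- gene_table(dset_label, pos$name, pos$chrom, pos$start, pos$end,
                    pos$strand, expr = expr, sort = TRUE)
  list(table = tab, duplicates = duplicates, dropped = unique(dropped))
}

#' Replace missing expression values
#'
#' Substitutes every `NaN` expression cell of a gene table with a fixed
#' value, typically ahead of filtering (a `NaN` never passes a filter
#' test). Everything else is untouched.
#'
#' @param table a `gene_table`.
#' @param replacement numeric replacement value. A `NaN` replacement is a
#'   no-op and warns.
#' @return the amended `gene_table`.
#' @export
fix_nan <- function(table, replacement) {
  stopifnot(is.numeric(replacement), length(replacement) == 1L)
  if (is.nan(replacement)) {
    warning("replacement is NaN; table returned unchanged")
    return(table)
  }
  ec <- expr_cols(table)
  for (cn in ec) {
    v <- table[[cn]]
    v[is.nan(v)] <- replacement
    table[[cn]] <- v
  }
  table
}

#' Specify an expression filter
#'
#' @param threshold numeric threshold the selected expression values are
#'   tested against.
#' @param indices 1-based indices of the expression values to test;
#'   `integer(0)` (default) tests all of them.
#' @param combine `"any"` (default): a gene passes if at least one selected
#'   value passes; `"all"`: every selected value must pass.
#' @param direction `"keep_ge"` (default) keeps genes with values `>=`
#'   threshold; `"keep_le"` keeps `<=`.
#' @return an object of class `"filter_spec"`.
#' @seealso [filter_by_expression()]
#' @export
filter_spec <- function(threshold, indices = integer(0),
                        combine = c("any", "all"),
                        direction = c("keep_ge", "keep_le")) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, !is.na(threshold))
  combine <- match.arg(combine)
  direction <- match.arg(direction)
  indices <- as.integer(indices)
  if (any(is.na(indices)) || any(indices < 1L))
    stop("indices must be positive integers")
  structure(list(threshold = threshold, indices = indices,
                 combine = combine, direction = direction),
            class = "filter_spec")
}

#' Filter genes by expression threshold
#'
#' Keeps or discards genes of a gene table by testing selected expression
#' values against a threshold — one, several, or all expression values can
#' be considered. A `NaN` value fails every test (run [fix_nan()] first to
#' keep such genes), so under `combine = "any"` a gene with only `NaN`s in
#' the selected positions is always dropped. Comparison is inclusive
#' (`>=` / `<=`). Row order is preserved.
#'
#' @param table a `gene_table`.
#' @param spec a [filter_spec()]; the indices must lie within
#'   `1..n_expr(table)`.
#' @return the filtered `gene_table`.
#' @export
filter_by_expression <- function(table, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  k <- n_expr(table)
  idx <- if (length(spec$indices) == 0L) seq_len(k) else spec$indices
  if (k == 0L) stop("table has no expression values to filter on")
  if (any(idx > k))
    stop(sprintf("expression index out of range: %d (table has %d)",
                 max(idx), k))
  em <- expr_matrix(table)[, idx, drop = FALSE]
  pass <- if (spec$direction == "keep_ge") em >= spec$threshold
          else em <= spec$threshold
  pass[is.na(pass)] <- FALSE  # NaN fails every test
  keep <- if (spec$combine == "any") rowSums(pass) > 0L
          else rowSums(pass) == ncol(pass)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
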