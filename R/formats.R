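# Text formats: position/expression input tables, GDF, CLU, random-run
# summary. All readers skip blank lines and lines starting with "#", accept
# any run of spaces/tabs as a delimiter (or the stated dialect), and report
# parse errors with 1-based line numbers. Writers are deterministic; numeric
# serialization uses %.17g so write->read round-trips are bit-exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  # shortest representation that still round-trips
  short <- sprintf("%.15g", x)
  ok <- !is.nan(x) & as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

fmt_pos <- function(x) sprintf("%.0f", x)

read_lines_clean <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

split_fields <- function(lines, dialect = "whitespace") {
  sep <- switch(dialect,
                whitespace = "[ \t]+",
                tab = "\t",
                csv = ",",
                stop("unknown dialect: ", dialect))
  lines <- trimws(lines, whitespace = "[\r\n]")
  if (dialect == "whitespace")
    return(lapply(strsplit(lines, sep), function(f) f[nzchar(f)]))
  # keep trailing empty cells (strsplit drops them)
  x <- strsplit(paste0(lines, "\x01"), sep)
  lapply(x, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    trimws(f)
  })
}

detect_dialect <- function(line) {
  if (grepl("\t", line)) "tab" else if (grepl(",", line)) "csv" else "whitespace"
}

parse_strand <- function(tok, lineno) {
  s <- ifelse(tok == "+1", "1", tok)
  val <- suppressWarnings(as.integer(s))
  bad <- is.na(val) | !(val %in% c(1L, -1L))
  if (any(bad))
    stop(sprintf("line %d: strand must be +1 or -1 (got '%s')",
                 lineno[bad][1L], tok[bad][1L]), call. = FALSE)
  val
}

parse_coord <- function(tok, lineno, what) {
  val <- suppressWarnings(as.numeric(tok))
  bad <- !grepl("^[0-9]+$", tok) | is.na(val)
  if (any(bad))
    stop(sprintf("line %d: %s must be a non-negative integer (got '%s')",
                 lineno[bad][1L], what, tok[bad][1L]), call. = FALSE)
  val
}

#' Read a gene position table
#'
#' Parses the five-column position table in the Biomart export column order:
#' gene name, chromosome, start (bp), end (bp), strand (+1/-1, "+1"
#' accepted). Lines that are blank or start with `#` are skipped.
#'
#' @param path path to the file.
#' @param dialect one of `"auto"` (default), `"whitespace"`, `"tab"`,
#'   `"csv"`.
#' @return a data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`, one row per input line in file order.
#' @export
read_position_table <- function(path, dialect = "auto") {
  lc <- read_lines_clean(path)
  if (length(lc$lines) == 0L)
    return(data.frame(name = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = integer(0), stringsAsFactors = FALSE))
  if (dialect == "auto") dialect <- detect_dialect(lc$lines[[1L]])
  fields <- split_fields(lc$lines, dialect)
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop(sprintf("line %d: expected 5 columns (name chrom start end strand), got %d",
                 lc$lineno[nf != 5L][1L], nf[nf != 5L][1L]), call. = FALSE)
  m <- do.call(rbind, fields)
  data.frame(
    name = m[, 1L], chrom = m[, 2L],
    start = parse_coord(m[, 3L], lc$lineno, "start"),
    end = parse_coord(m[, 4L], lc$lineno, "end"),
    strand = parse_strand(m[, 5L], lc$lineno),
    stringsAsFactors = FALSE
  )
}

#' Read a gene expression table
#'
#' Parses a table whose first column is the gene name, followed by one or
#' more expression values. Empty or non-numeric cells become `NaN` (the
#' missing marker); rows may have differing numbers of values — they are
#' reconciled (padded with `NaN`) when merged with a position table.
#'
#' @inheritParams read_position_table
#' @return a data.frame with columns `name` and list-column `values`.
#' @export
read_expression_table <- function(path, dialect = "auto") {
  lc <- read_lines_clean(path)
  if (length(lc$lines) == 0L) {
    out <- data.frame(name = character(0), stringsAsFactors = FALSE)
    out$values <- list()
    return(out)
  }
  if (dialect == "auto") dialect <- detect_dialect(lc$lines[[1L]])
  fields <- split_fields(lc$lines, dialect)
  bad <- lengths(fields) < 1L
  if (any(bad))
    stop(sprintf("line %d: expected a gene name", lc$lineno[bad][1L]),
         call. = FALSE)
  name <- vapply(fields, `[[`, character(1), 1L)
  values <- lapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v[is.na(v)] <- NaN
    v
  })
  out <- data.frame(name = name, stringsAsFactors = FALSE)
  out$values <- values
  out
}

#' Write and read the GDF (gene data file) format
#'
#' GDF is a whitespace-delimited text format with one gene per line and the
#' fixed column order `dset genename chrom start end strand expr1 expr2 ...`.
#' Missing expression values are the literal string `NaN`. The writer emits
#' tab-separated fields; the reader accepts any run of spaces/tabs. Note that
#' the CLU member-line order differs (strand precedes start there).
#'
#' `read_gdf()` does not reorder rows: a positionally unsorted file is read
#' as-is and flagged by [validate_gene_table()].
#'
#' @param table a valid `gene_table`.
#' @param path file path.
#' @return `write_gdf()` returns `path` invisibly; `read_gdf()` returns a
#'   `gene_table`.
#' @seealso [read_clu()] for the cluster file format.
#' @export
write_gdf <- function(table, path) {
  stop_if_invalid(table)
  em <- expr_matrix(table)
  lines <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    f <- c(table$dset[i], table$name[i], table$chrom[i],
           fmt_pos(table$start[i]), fmt_pos(table$end[i]),
           as.character(table$strand[i]),
           if (ncol(em)) fmt_num(em[i, ]))
    lines[i] <- paste(f, collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gdf
#' @export
read_gdf <- function(path) {
  lc <- read_lines_clean(path)
  if (length(lc$lines) == 0L)
    return(gene_table(character(0), character(0), character(0),
                      numeric(0), numeric(0), integer(0)))
  fields <- split_fields(lc$lines, "whitespace")
  k <- length(fields[[1L]]) - 6L
  if (k < 0L)
    stop(sprintf("line %d: expected at least 6 columns, got %d",
                 lc$lineno[1L], length(fields[[1L]])), call. = FALSE)
  nf <- lengths(fields)
  if (any(nf != 6L + k))
    stop(sprintf("line %d: expected %d columns, got %d",
                 lc$lineno[nf != 6L + k][1L], 6L + k,
                 nf[nf != 6L + k][1L]), call. = FALSE)
  m <- do.call(rbind, fields)
  expr <- NULL
  if (k > 0L) {
    expr <- matrix(suppressWarnings(as.numeric(m[, 7L:(6L + k), drop = FALSE])),
                   ncol = k)
    expr[is.na(expr)] <- NaN
  }
  gene_table(m[, 1L], m[, 2L], m[, 3L],
             parse_coord(m[, 4L], lc$lineno, "start"),
             parse_coord(m[, 5L], lc$lineno, "end"),
             parse_strand(m[, 6L], lc$lineno),
             expr = expr, sort = FALSE)
}

#' Write and read the CLU (cluster file) format
#'
#' The CLU format stores one clustering result: a header line `nClusters N`,
#' then the clusters in identifier order, each written as its numeric id on
#' its own line, a `beginCluster` line, one space-separated member line per
#' gene in the order `dset genename chrom strand start stop exp1 exp2 ...`
#' (strand precedes start here, unlike GDF), and an `endCluster` line.
#'
#' @param cs a `posclust` object (see [pos_cluster()]).
#' @param path file path.
#' @param threshold_bp distance threshold to attach to the object read from
#'   `path` (the file does not record it); `NA` by default.
#' @return `write_clu()` returns `path` invisibly; `read_clu()` returns a
#'   `posclust` object.
#' @export
write_clu <- function(cs, path) {
  stopifnot(inherits(cs, "posclust"))
  out <- sprintf("nClusters %d", length(cs$clusters))
  for (i in seq_along(cs$clusters)) {
    cl <- cs$clusters[[i]]
    em <- expr_matrix(cl)
    member <- character(nrow(cl))
    for (j in seq_len(nrow(cl))) {
      f <- c(cl$dset[j], cl$name[j], cl$chrom[j],
             as.character(cl$strand[j]),
             fmt_pos(cl$start[j]), fmt_pos(cl$end[j]),
             if (ncol(em)) fmt_num(em[j, ]))
      member[j] <- paste(f, collapse = " ")
    }
    out <- c(out, as.character(i), "beginCluster", member, "endCluster")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_clu
#' @export
read_clu <- function(path, threshold_bp = NA_real_) {
  lc <- read_lines_clean(path)
  lines <- lc$lines
  lineno <- lc$lineno
  if (length(lines) == 0L)
    stop("empty CLU file (missing nClusters header)", call. = FALSE)
  hdr <- split_fields(lines[1L], "whitespace")[[1L]]
  if (length(hdr) != 2L || hdr[1L] != "nClusters")
    stop(sprintf("line %d: expected header 'nClusters N'", lineno[1L]),
         call. = FALSE)
  n_declared <- suppressWarnings(as.integer(hdr[2L]))
  if (is.na(n_declared) || n_declared < 0L)
    stop(sprintf("line %d: bad cluster count '%s'", lineno[1L], hdr[2L]),
         call. = FALSE)
  clusters <- list()
  i <- 2L
  while (i <= length(lines)) {
    id_tok <- trimws(lines[i])
    cid <- suppressWarnings(as.integer(id_tok))
    if (is.na(cid))
      stop(sprintf("line %d: expected a cluster identifier, got '%s'",
                   lineno[i], id_tok), call. = FALSE)
    if (cid != length(clusters) + 1L)
      stop(sprintf("line %d: cluster ids must run 1..N in order (got %d)",
                   lineno[i], cid), call. = FALSE)
    i <- i + 1L
    if (i > length(lines) || trimws(lines[i]) != "beginCluster")
      stop(sprintf("line %d: expected 'beginCluster'",
                   if (i <= length(lines)) lineno[i] else lineno[i - 1L]),
           call. = FALSE)
    i <- i + 1L
    member_lines <- integer(0)
    while (i <= length(lines) && trimws(lines[i]) != "endCluster") {
      if (trimws(lines[i]) == "beginCluster")
        stop(sprintf("line %d: nested 'beginCluster'", lineno[i]),
             call. = FALSE)
      member_lines <- c(member_lines, i)
      i <- i + 1L
    }
    if (i > length(lines))
      stop(sprintf("unterminated cluster %d: missing 'endCluster'", cid),
           call. = FALSE)
    fields <- split_fields(lines[member_lines], "whitespace")
    nf <- lengths(fields)
    if (length(fields) == 0L)
      stop(sprintf("cluster %d has no member lines", cid), call. = FALSE)
    k <- nf[1L] - 6L
    if (k < 0L || any(nf != nf[1L]))
      stop(sprintf("line %d: bad member line (expected %d columns)",
                   lineno[member_lines[which(nf != nf[1L])[1L]]], nf[1L]),
           call. = FALSE)
    m <- do.call(rbind, fields)
    expr <- NULL
    if (k > 0L) {
      expr <- matrix(suppressWarnings(as.numeric(m[, 7L:(6L + k), drop = FALSE])),
                     ncol = k)
      expr[is.na(expr)] <- NaN
    }
    ml <- lineno[member_lines]
    # CLU member order: dset name chrom STRAND start stop
    clusters[[cid]] <- gene_table(m[, 1L], m[, 2L], m[, 3L],
                                  parse_coord(m[, 5L], ml, "start"),
                                  parse_coord(m[, 6L], ml, "stop"),
                                  parse_strand(m[, 4L], ml),
                                  expr = expr, sort = FALSE)
    i <- i + 1L
  }
  if (length(clusters) != n_declared)
    stop(sprintf("header declares %d clusters but file contains %d",
                 n_declared, length(clusters)), call. = FALSE)
  for (cid in seq_along(clusters)) {
    if (nrow(clusters[[cid]]) < 2L)
      stop(sprintf("cluster %d has fewer than 2 members", cid), call. = FALSE)
    if (length(unique(clusters[[cid]]$chrom)) != 1L)
      stop(sprintf("cluster %d spans more than one chromosome", cid),
           call. = FALSE)
  }
  k <- if (length(clusters)) n_expr(clusters[[1L]]) else 0L
  new_posclust(clusters, threshold_bp = threshold_bp, n_expr = k)
}

#' Write the random-run summary table
#'
#' One row per randomization run in the layout `run  n.clusts
#' n.tot.clust.genes  n.genes per cluster`, the per-cluster sizes
#' space-separated in cluster-id order. This is the text table handed to
#' external statistics software as the null sample.
#'
#' @param runs a list of per-run summaries as returned by
#'   [random_clustering_runs()].
#' @param path file path.
#' @param header write the column-name header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_random_summary <- function(runs, path, header = TRUE) {
  out <- if (header)
    "run\tn.clusts\tn.tot.clust.genes\tn.genes per cluster" else character(0)
  for (r in runs) {
    out <- c(out, sprintf("%d\t%d\t%d\t%s", r$run, r$n_clusters,
                          r$n_clustered_genes,
                          paste(r$sizes, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
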