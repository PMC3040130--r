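# SVG renderers for the two cluster views. Output is a self-contained SVG
# document built as a character string: deterministic, editable in any
# vector-graphics editor (labels are separate text nodes; no collision
# avoidance is attempted). Glyph elements carry class and data-* attributes
# so documents are machine-checkable.

#' Styling options for cluster views
#'
#' @param min_diameter,max_diameter glyph diameter range in drawing units
#'   (`min <= max`). Zero (and `NaN`) expression always renders at zero
#'   diameter regardless of `min_diameter`.
#' @param scaling `"sqrt"` (default; glyph area proportional to the encoded
#'   magnitude) or `"linear"` (diameter proportional).
#' @param glyph `"circle"` (default) or `"diamond"`, used for expression
#'   glyphs in the single-cluster view.
#' @param colors named character vector mapping dataset labels to fill
#'   colors; labels without an entry are assigned from a fixed palette in
#'   order of appearance.
#' @param labels character subset of `c("id", "kbp")`: label clusters with
#'   their numeric identifier and/or the kbp position of their first gene.
#' @param width drawing width in units (default 800).
#' @return an object of class `"view_style"`.
#' @export
view_style <- function(min_diameter = 4, max_diameter = 24,
                       scaling = c("sqrt", "linear"),
                       glyph = c("circle", "diamond"),
                       colors = character(0),
                       labels = c("id", "kbp"),
                       width = 800) {
  stopifnot(min_diameter >= 0, max_diameter >= min_diameter, width > 0)
  scaling <- match.arg(scaling)
  glyph <- match.arg(glyph)
  stopifnot(all(labels %in% c("id", "kbp")))
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 scaling = scaling, glyph = glyph, colors = colors,
                 labels = labels, width = width),
            class = "view_style")
}

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_num <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))

# relative diameter in [0, 1] for a magnitude on [0, vmax]
rel_diameter <- function(v, vmax, scaling) {
  if (vmax <= 0) return(rep(0, length(v)))
  f <- pmax(0, pmin(1, v / vmax))
  if (scaling == "sqrt") sqrt(f) else f
}

dset_palette <- function(dsets, colors) {
  dsets <- unique(dsets)
  need <- setdiff(dsets, names(colors))
  if (length(need)) {
    pal <- grDevices::palette.colors(max(length(need), 2L), "Okabe-Ito")
    colors <- c(colors, stats::setNames(pal[seq_along(need)], need))
  }
  colors[dsets]
}

#' Render the multiple-cluster view as SVG
#'
#' Draws every chromosome that carries at least one cluster as a horizontal
#' line spanning the region from its first (leftmost) to its last
#' (rightmost) cluster; chromosomes are left-aligned and share one
#' base-pair-to-unit scale, so line lengths reflect relative spans. Each
#' cluster is one circle placed at the start coordinate of its first gene,
#' with diameter scaled to the cluster's gene count (area-proportional
#' under the default `sqrt` scaling). Clusters can be labeled with their
#' numeric identifier and the kbp position of their first gene.
#'
#' @param cs a `posclust` object with at least one cluster.
#' @param style a [view_style()].
#' @return the SVG document as a single character string, invisibly
#'   writable with [write_svg()].
#' @export
render_multi_cluster_view <- function(cs, style = view_style()) {
  stopifnot(inherits(cs, "posclust"), inherits(style, "view_style"))
  if (length(cs$clusters) == 0L) stop("nothing to draw: no clusters")
  chroms <- vapply(cs$clusters, function(cl) cl$chrom[1L], character(1))
  firsts <- vapply(cs$clusters, function(cl) cl$start[1L], numeric(1))
  sizes <- cluster_sizes(cs)
  uchrom <- unique(chroms)

  x0 <- vapply(uchrom, function(ch) min(firsts[chroms == ch]), numeric(1))
  span <- vapply(uchrom, function(ch) max(firsts[chroms == ch]) -
                   min(firsts[chroms == ch]), numeric(1))
  margin <- 60
  inner <- style$width - 2 * margin
  scale <- if (max(span) > 0) inner / max(span) else 0  # one shared factor
  row_h <- max(2 * style$max_diameter, 40)
  height <- row_h * (length(uchrom) + 1)
  smax <- max(sizes)

  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    svg_num(style$width), svg_num(height), svg_num(style$width), svg_num(height)))
  for (ci in seq_along(uchrom)) {
    ch <- uchrom[ci]
    y <- row_h * ci
    ids <- which(chroms == ch)
    x_end <- margin + span[ci] * scale
    out <- c(out, sprintf('<g class="chromosome" data-chrom="%s">', svg_esc(ch)),
             sprintf('<line class="chromosome-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                     svg_num(margin), svg_num(y), svg_num(max(x_end, margin + 1)),
                     svg_num(y)),
             sprintf('<text class="chromosome-name" x="%s" y="%s" text-anchor="end" font-size="10">%s</text>',
                     svg_num(margin - 8), svg_num(y + 3), svg_esc(ch)))
    for (cid in ids) {
      x <- margin + (firsts[cid] - x0[ci]) * scale
      d <- max(style$min_diameter,
               style$max_diameter * rel_diameter(sizes[cid], smax, style$scaling))
      out <- c(out, sprintf(
        '<circle class="cluster-glyph" data-cluster="%d" data-size="%d" cx="%s" cy="%s" r="%s" fill="steelblue" fill-opacity="0.7" stroke="black"/>',
        cid, sizes[cid], svg_num(x), svg_num(y), svg_num(d / 2)))
      if ("id" %in% style$labels)
        out <- c(out, sprintf(
          '<text class="label-id" x="%s" y="%s" font-size="9" text-anchor="middle">%d</text>',
          svg_num(x), svg_num(y - style$max_diameter / 2 - 4), cid))
      if ("kbp" %in% style$labels)
        out <- c(out, sprintf(
          '<text class="label-kbp" x="%s" y="%s" font-size="8" text-anchor="middle">%s kbp</text>',
          svg_num(x), svg_num(y + style$max_diameter / 2 + 12),
          svg_num(firsts[cid] / 1000)))
    }
    out <- c(out, "</g>")
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render the single-cluster view as SVG
#'
#' Shows the contents of one cluster across experimental conditions: the
#' cluster's chromosome region is drawn once per expression value (one
#' horizontal track per condition/stage), and on every track each member
#' gene appears at its genomic coordinate as a glyph whose diameter encodes
#' that condition's expression value. Zero expression maps to zero diameter
#' (a point), so a purely positional clustering shows the gene layout
#' alone; a `NaN` value draws a hollow point, distinguishable from a true
#' zero; negative values (e.g. log-ratios of down-regulation) also render
#' as points, with a warning. Glyph fill color is keyed by each gene's
#' dataset label, making the origin of genes visible in iteratively updated
#' clusters. Diamonds may be used instead of circles (see [view_style()]).
#'
#' @param cluster a `gene_table` holding one cluster's members, e.g. from
#'   [extract_cluster()].
#' @param style a [view_style()].
#' @return the SVG document as a single character string.
#' @export
render_single_cluster_view <- function(cluster, style = view_style()) {
  stopifnot(inherits(style, "view_style"))
  if (nrow(cluster) == 0L) stop("nothing to draw: empty cluster")
  em <- expr_matrix(cluster)
  k <- max(ncol(em), 1L)
  if (ncol(em) == 0L) em <- matrix(0, nrow(cluster), 1L)
  if (any(em[is.finite(em)] < 0))
    warning("negative expression values render at point size")
  margin <- 70
  inner <- style$width - 2 * margin
  x0 <- min(cluster$start)
  span <- max(cluster$start) - x0
  scale <- if (span > 0) inner / span else 0
  row_h <- max(2 * style$max_diameter, 40)
  height <- row_h * (k + 1)
  vmax <- suppressWarnings(max(c(0, em[is.finite(em) & em > 0])))
  cols <- dset_palette(cluster$dset, style$colors)

  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
    svg_num(style$width), svg_num(height), svg_num(style$width), svg_num(height)))
  for (s in seq_len(k)) {
    y <- row_h * s
    out <- c(out, sprintf('<g class="stage-track" data-stage="%d">', s),
             sprintf('<line class="track-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="grey"/>',
                     svg_num(margin), svg_num(y),
                     svg_num(max(margin + span * scale, margin + 1)), svg_num(y)),
             sprintf('<text class="stage-name" x="%s" y="%s" text-anchor="end" font-size="10">stage %d</text>',
                     svg_num(margin - 8), svg_num(y + 3), s))
    for (g in seq_len(nrow(cluster))) {
      v <- em[g, s]
      x <- margin + (cluster$start[g] - x0) * scale
      hollow <- is.nan(v)
      d <- if (!is.finite(v) || v <= 0) 0
           else max(style$min_diameter,
                    style$max_diameter * rel_diameter(v, vmax, style$scaling))
      fill <- if (hollow) "none" else unname(cols[cluster$dset[g]])
      attrs <- sprintf(
        'class="expr-glyph%s" data-gene="%s" data-stage="%d" data-dset="%s" data-value="%s" fill="%s" stroke="black"',
        if (hollow) " missing" else "", svg_esc(cluster$name[g]), s,
        svg_esc(cluster$dset[g]), if (hollow) "NaN" else svg_num(v), fill)
      if (style$glyph == "circle") {
        out <- c(out, sprintf('<circle %s cx="%s" cy="%s" r="%s"/>',
                              attrs, svg_num(x), svg_num(y), svg_num(d / 2)))
      } else {
        r <- d / 2
        pts <- sprintf("%s,%s %s,%s %s,%s %s,%s",
                       svg_num(x), svg_num(y - r), svg_num(x + r), svg_num(y),
                       svg_num(x), svg_num(y + r), svg_num(x - r), svg_num(y))
        out <- c(out, sprintf('<polygon %s points="%s"/>', attrs, pts))
      }
      if (s == 1L)
        out <- c(out, sprintf(
          '<text class="label-gene" x="%s" y="%s" font-size="8" text-anchor="middle">%s</text>',
          svg_num(x), svg_num(row_h * 0.4), svg_esc(cluster$name[g])))
    }
    out <- c(out, "</g>")
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Write an SVG document to a file
#'
#' @param doc SVG character string from a renderer.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  writeLines(doc, path)
  invisible(path)
}
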