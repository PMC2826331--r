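#' Compute the layout graph by the relaxed multi-fragment heuristic
#'
#' Adjacency edges are processed in order of decreasing weight (equivalently
#' increasing TSP distance; ties broken lexicographically by connector
#' labels) and greedily inserted into an initially empty layout. An edge is
#' inserted iff its weight exceeds `min_weight` and at least one of its two
#' connectors carries no previously inserted adjacency edge — i.e. counting
#' the structural intra edge, at most one endpoint may exceed the usual tour
#' degree of two. No cycle check is performed, so repeated contigs may close
#' cycles and conflicting adjacencies are kept visible. The result is a
#' subgraph of the adjacency graph and is not necessarily connected.
#'
#' @param graph An `adjacency_graph`.
#' @param min_weight Insert only edges with weight strictly greater than
#'   this (default 0: all strictly positive edges are candidates).
#' @return An object of class `layout_graph`.
#' @export
build_layout <- function(graph, min_weight = 0) {
  edges <- graph_edges(graph, include_zero = FALSE)
  # canonical orientation of each edge, then deterministic processing order
  if (nrow(edges) > 0L) {
    k1 <- paste(edges$contig1, edges$side1)
    k2 <- paste(edges$contig2, edges$side2)
    flip <- k2 < k1
    if (any(flip)) {
      tmp_c <- edges$contig1[flip]; tmp_s <- edges$side1[flip]
      edges$contig1[flip] <- edges$contig2[flip]
      edges$side1[flip] <- edges$side2[flip]
      edges$contig2[flip] <- tmp_c
      edges$side2[flip] <- tmp_s
    }
    edges <- edges[order(-edges$weight, edges$contig1, edges$side1,
                         edges$contig2, edges$side2), , drop = FALSE]
    edges <- edges[edges$weight > min_weight, , drop = FALSE]
  }
  deg <- stats::setNames(integer(length(graph$vertices)), graph$vertices)
  keep <- logical(nrow(edges))
  if (nrow(edges) > 0L) {
    u <- paste0(edges$contig1, ":", edges$side1)
    v <- paste0(edges$contig2, ":", edges$side2)
    for (k in seq_len(nrow(edges))) {
      if (deg[u[k]] == 0L || deg[v[k]] == 0L) {
        keep[k] <- TRUE
        deg[u[k]] <- deg[u[k]] + 1L
        deg[v[k]] <- deg[v[k]] + 1L
      }
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(contig_ids = graph$contig_ids,
                 contig_lengths = graph$contig_lengths,
                 edges = out, min_weight = min_weight,
                 annotations = NULL),
            class = "layout_graph")
}

#' Annotate a layout graph for display
#'
#' Adds per-contig display annotations: the node label (reference-order rank
#' when a reference order is supplied, the contig id otherwise), the contig
#' size, a "small" flag for contigs below `small_cutoff` bases, and a
#' "repeat" flag for contigs of which at least `repeat_fraction` of the bases
#' are covered by two or more matches on at least one reference genome.
#' Edge weights gain a `log_weight` column (log10) for display.
#'
#' @param layout A `layout_graph`.
#' @param contigs Optional named character vector of contig sequences (used
#'   for sizes when the layout carries none).
#' @param matches Optional match table used for repeat detection.
#' @param ref_order Optional `reference_order` used for rank labels.
#' @param small_cutoff Size threshold in bases for the gray "small" flag
#'   (default 3500).
#' @param repeat_fraction Coverage fraction for the repeat flag
#'   (default 0.95).
#' @return The annotated `layout_graph`.
#' @export
annotate_layout <- function(layout, contigs = NULL, matches = NULL,
                            ref_order = NULL, small_cutoff = 3500,
                            repeat_fraction = 0.95) {
  ids <- layout$contig_ids
  len <- unname(layout$contig_lengths[ids])
  if (!is.null(contigs)) len <- unname(nchar(contigs[ids]))
  if (anyNA(len)) stop("contig lengths unknown; supply `contigs`")
  label <- ids
  if (!is.null(ref_order)) {
    ord <- as.data.frame(ref_order)
    rank <- ord$rank[match(ids, ord$contig_id)]
    label <- ifelse(is.na(rank), ids, as.character(rank))
  }
  rep_flag <- rep(FALSE, length(ids))
  if (!is.null(matches) && nrow(matches) > 0L) {
    for (i in seq_along(ids)) {
      mi <- matches[matches$contig_id == ids[i], , drop = FALSE]
      if (nrow(mi) == 0L) next
      for (g in unique(mi$ref_genome)) {
        mg <- mi[mi$ref_genome == g, , drop = FALSE]
        cov <- integer(len[i])
        for (k in seq_len(nrow(mg))) {
          lo <- min(mg$sb[k], mg$se[k]); hi <- max(mg$sb[k], mg$se[k])
          cov[lo:hi] <- cov[lo:hi] + 1L
        }
        if (mean(cov >= 2L) >= repeat_fraction) {
          rep_flag[i] <- TRUE
          break
        }
      }
    }
  }
  layout$annotations <- data.frame(
    contig_id = ids, length = len, label = label,
    small = len < small_cutoff, repeat_flag = rep_flag,
    stringsAsFactors = FALSE)
  if (nrow(layout$edges) > 0L) {
    layout$edges$log_weight <- log10(layout$edges$weight)
  } else {
    layout$edges$log_weight <- numeric(0)
  }
  layout
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a layout graph as Graphviz DOT
#'
#' One node per contig; connector sides appear as edge head/tail labels
#' (`L`/`R`). Small contigs are drawn gray-filled, repeat contigs as boxes,
#' and edge labels give the log10 of the adjacency weight.
#'
#' @param layout A `layout_graph`, ideally after [annotate_layout()].
#' @return The DOT text as a single character string.
#' @export
layout_to_dot <- function(layout) {
  ann <- layout$annotations
  if (is.null(ann)) {
    ann <- data.frame(contig_id = layout$contig_ids,
                      length = unname(layout$contig_lengths[layout$contig_ids]),
                      label = layout$contig_ids, small = FALSE,
                      repeat_flag = FALSE, stringsAsFactors = FALSE)
  }
  lines <- c("graph contig_layout {", "  node [fontsize=10];")
  for (i in seq_len(nrow(ann))) {
    lab <- ann$label[i]
    if (!is.na(ann$length[i])) {
      lab <- sprintf("%s\\n%.1f kb", lab, ann$length[i] / 1000)
    }
    attrs <- c(sprintf("label=\"%s\"", lab),
               sprintf("shape=%s", if (ann$repeat_flag[i]) "box" else "ellipse"))
    if (ann$small[i]) attrs <- c(attrs, "style=filled", "fillcolor=gray")
    lines <- c(lines, sprintf("  %s [%s];", dot_quote(ann$contig_id[i]),
                              paste(attrs, collapse = ", ")))
  }
  e <- layout$edges
  if (nrow(e) > 0L) {
    lw <- if ("log_weight" %in% names(e)) e$log_weight else log10(e$weight)
    lines <- c(lines, sprintf(
      "  %s -- %s [label=\"%.2f\", taillabel=\"%s\", headlabel=\"%s\"];",
      dot_quote(e$contig1), dot_quote(e$contig2), lw, e$side1, e$side2))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Write a layout graph edge list as TSV
#' @param layout A `layout_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.layout_graph <- function(x, ...) {
  cat("Contig layout graph: ", length(x$contig_ids), " contigs, ",
      nrow(x$edges), " adjacency edges (min weight ",
      format(x$min_weight), ")\n", sep = "")
  deg <- table(c(paste0(x$edges$contig1, ":", x$edges$side1),
                 paste0(x$edges$contig2, ":", x$edges$side2)))
  conflicts <- sum(deg > 1L)
  if (conflicts > 0L) {
    cat("  conflicting connectors (degree > 1): ", conflicts, "\n", sep = "")
  }
  invisible(x)
}
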