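#' Construct a reference order object
#'
#' A reference order is the ground-truth signed contig permutation: each
#' placed contig with its orientation and placement interval on the finished
#' genome, sorted by placement start, plus the set of contigs that could not
#' be placed.
#'
#' @param placements `data.frame` with columns `contig_id`, `orientation`
#'   (`"forward"`/`"reverse"`), `start`, `end`.
#' @param excluded Character vector of contigs without a placement.
#' @return An object of class `reference_order` (a `data.frame` with a
#'   `rank` column and an `excluded` attribute).
#' @export
reference_order <- function(placements, excluded = character()) {
  need <- c("contig_id", "orientation", "start", "end")
  stopifnot(all(need %in% names(placements)))
  stopifnot(all(placements$orientation %in% c("forward", "reverse")))
  if (anyDuplicated(placements$contig_id)) {
    stop("each contig may appear only once in a reference order")
  }
  p <- placements[order(placements$start, placements$end,
                        placements$contig_id), need, drop = FALSE]
  p <- cbind(rank = seq_len(nrow(p)), p)
  rownames(p) <- NULL
  structure(p, excluded = excluded,
            class = c("reference_order", "data.frame"))
}

#' @export
print.reference_order <- function(x, ...) {
  sym <- ifelse(x$orientation == "forward", "+", "-")
  cat("Reference order (", nrow(x), " contigs placed, ",
      length(attr(x, "excluded")), " excluded)\n", sep = "")
  cat("  ", paste0(x$contig_id, sym, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Derive the reference order from a finished genome
#'
#' Maps every contig onto the finished genome of its own species and places
#' it on the region where it gains the most matches: candidate placements are
#' clusters of projected matches on one record (split where the projection
#' gap exceeds `cluster_gap`), the winning cluster maximizes the summed
#' q-gram hit count (ties: summed match length, then leftmost position), and
#' the orientation is the strand carrying the majority of matched bases in
#' the winning cluster. Contigs without any match are excluded and reported.
#'
#' @param contigs Named character vector of contig sequences.
#' @param finished_genome Named character vector with the record(s) of the
#'   finished genome.
#' @param params A [match_params()] object.
#' @param matches Optional precomputed match table of the contigs against the
#'   finished genome (skips the matching step).
#' @param cluster_gap Projection gap, in bases, that separates two candidate
#'   placements; defaults to the contig length.
#' @return A `reference_order` object.
#' @export
build_reference_order <- function(contigs, finished_genome,
                                  params = match_params(), matches = NULL,
                                  cluster_gap = NULL) {
  if (is.null(matches)) {
    matches <- match_all(contigs, list(finished = finished_genome), params)
  }
  lens <- stats::setNames(nchar(contigs), names(contigs))
  rows <- list()
  excluded <- character()
  for (cid in names(contigs)) {
    mi <- matches[matches$contig_id == cid, , drop = FALSE]
    if (nrow(mi) == 0L) {
      excluded <- c(excluded, cid)
      next
    }
    gap_max <- if (is.null(cluster_gap)) unname(lens[cid]) else cluster_gap
    proj <- project_match(mi, lens)
    best <- NULL
    for (rec in unique(proj$ref_record)) {
      sel <- proj$ref_record == rec
      P <- proj[sel, , drop = FALSE]
      M <- mi[sel, , drop = FALSE]
      o <- order(P$pb, P$pe)
      P <- P[o, , drop = FALSE]; M <- M[o, , drop = FALSE]
      # split into clusters where the projection gap exceeds gap_max
      new_cluster <- c(TRUE, P$pb[-1L] - cummax(P$pe)[-nrow(P)] - 1 > gap_max)
      cl <- cumsum(new_cluster)
      for (k in unique(cl)) {
        ix <- which(cl == k)
        mlen <- M$te[ix] - M$tb[ix] + 1L
        fwd <- M$sb[ix] < M$se[ix]
        cand <- list(qhits = sum(M$qhits[ix]), mlen = sum(mlen),
                     start = min(P$pb[ix]), end = max(P$pe[ix]),
                     orientation = if (sum(mlen[fwd]) >= sum(mlen[!fwd]))
                       "forward" else "reverse",
                     record = rec)
        if (is.null(best) ||
            cand$qhits > best$qhits ||
            (cand$qhits == best$qhits && cand$mlen > best$mlen) ||
            (cand$qhits == best$qhits && cand$mlen == best$mlen &&
               cand$start < best$start)) {
          best <- cand
        }
      }
    }
    rows[[cid]] <- data.frame(contig_id = cid, orientation = best$orientation,
                              start = best$start, end = best$end,
                              record = best$record, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no contig could be placed on the finished genome")
  reference_order(do.call(rbind, rows), excluded = excluded)
}

# The truth adjacency set of a reference order: one row per consecutive
# contig pair, as canonical connector pairs.
truth_edges <- function(ref_order, circular = FALSE) {
  n <- nrow(ref_order)
  if (n < 2L) {
    return(data.frame(contig1 = character(), side1 = character(),
                      contig2 = character(), side2 = character()))
  }
  i <- seq_len(if (circular) n else n - 1L)
  j <- ifelse(i == n, 1L, i + 1L)
  out_side <- ifelse(ref_order$orientation[i] == "forward", "R", "L")
  in_side <- ifelse(ref_order$orientation[j] == "forward", "L", "R")
  data.frame(contig1 = ref_order$contig_id[i], side1 = out_side,
             contig2 = ref_order$contig_id[j], side2 = in_side,
             stringsAsFactors = FALSE)
}

canonical_edge_key <- function(c1, s1, c2, s2) {
  a <- paste(c1, s1); b <- paste(c2, s2)
  ifelse(a <= b, paste(a, b, sep = " -- "), paste(b, a, sep = " -- "))
}

#' Score predicted adjacencies against a reference order
#'
#' Each predicted connector-level adjacency is a true positive iff its two
#' contigs are consecutive in the reference order *and* the connector sides
#' agree with the reference orientations (a forward contig followed by a
#' forward contig is connected right-to-left, etc.); all other predictions
#' are false positives. Predictions whose contig pair is consecutive but
#' whose sides disagree are flagged `pair-correct, orientation-wrong` in the
#' details. Edges touching contigs excluded from (or unknown to) the
#' reference order are dropped with a warning. `P`, the number of reference
#' connections, is `n - 1` for a linear reference order and `n` for a
#' circular one.
#'
#' @param predicted A `layout_graph`, or a `data.frame` with columns
#'   `contig1`, `side1`, `contig2`, `side2`.
#' @param ref_order A `reference_order`.
#' @param circular Treat the reference order as circular?
#' @return An object of class `eval_result` with elements `TP`, `FP`, `P`,
#'   `TPR`, `PPV` (`NA` when no prediction was scored) and a `details`
#'   `data.frame`.
#' @export
evaluate_adjacencies <- function(predicted, ref_order, circular = FALSE) {
  if (inherits(predicted, "layout_graph")) predicted <- predicted$edges
  need <- c("contig1", "side1", "contig2", "side2")
  stopifnot(all(need %in% names(predicted)))
  known <- ref_order$contig_id
  touch_unknown <- !(predicted$contig1 %in% known) |
    !(predicted$contig2 %in% known)
  if (any(touch_unknown)) {
    warning(sum(touch_unknown),
            " predicted edge(s) touch excluded/unknown contigs; dropped")
    predicted <- predicted[!touch_unknown, , drop = FALSE]
  }
  key <- canonical_edge_key(predicted$contig1, predicted$side1,
                            predicted$contig2, predicted$side2)
  predicted <- predicted[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  tr <- truth_edges(ref_order, circular)
  tkey <- canonical_edge_key(tr$contig1, tr$side1, tr$contig2, tr$side2)
  # contig pairs that are consecutive, regardless of connector sides
  pair_key <- function(c1, c2) {
    ifelse(c1 <= c2, paste(c1, c2, sep = "~"), paste(c2, c1, sep = "~"))
  }
  tpair <- pair_key(tr$contig1, tr$contig2)
  ppair <- pair_key(predicted$contig1, predicted$contig2)
  is_tp <- key %in% tkey
  status <- ifelse(is_tp, "TP",
                   ifelse(ppair %in% tpair, "FP (pair-correct, orientation-wrong)",
                          "FP"))
  TP <- sum(is_tp)
  FP <- sum(!is_tp)
  P <- nrow(tr)
  structure(list(TP = TP, FP = FP, P = P,
                 TPR = if (P > 0L) TP / P else NA_real_,
                 PPV = if (TP + FP > 0L) TP / (TP + FP) else NA_real_,
                 details = data.frame(edge = key, status = status,
                                      stringsAsFactors = FALSE)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  ppv <- if (is.na(x$PPV)) "undef." else sprintf("%.2f", x$PPV)
  cat(sprintf("TP = %d  FP = %d  P = %d  TPR = %.2f  PPV = %s\n",
              x$TP, x$FP, x$P, x$TPR, ppv))
  invisible(x)
}

#' Write an evaluation report as TSV
#' @param result An `eval_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation <- function(result, path) {
  hdr <- data.frame(TP = result$TP, FP = result$FP, P = result$P,
                    TPR = result$TPR, PPV = result$PPV)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(hdr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  utils::write.table(result$details, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' N50 of a set of contig lengths
#'
#' The largest length `L` such that contigs of length at least `L` together
#' cover at least half of the total assembly length.
#'
#' @param lengths Numeric vector of contig lengths (nonempty).
#' @return The N50 value.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
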