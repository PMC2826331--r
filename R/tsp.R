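#' Convert an adjacency graph into a TSP instance
#'
#' Edge weights are flipped into distances `m - w` (with `m` the maximum
#' adjacency weight), intra edges are removed, and an intermediate node is
#' added between the two connectors of each contig with zero-distance edges
#' to both. A shortest Hamiltonian cycle through the 3n nodes then realizes
#' a maximum-weight circular contig order in which each contig appears
#' exactly once, in one orientation.
#'
#' @param graph An `adjacency_graph`.
#' @return A list of class `tsp_instance` with elements `graph`, `n`,
#'   `n_nodes` (3n), `max_weight` and `D` (adjacency distance matrix; `NA`
#'   for removed/intra pairs).
#' @export
to_tsp <- function(graph) {
  n2 <- length(graph$vertices)
  m <- max_adjacency_weight(graph)
  D <- m - graph$W
  D[!adjacency_mask(n2)] <- NA_real_
  structure(list(graph = graph, n = n2 %/% 2L, n_nodes = 3L * (n2 %/% 2L),
                 max_weight = m, D = D),
            class = "tsp_instance")
}

#' @export
print.tsp_instance <- function(x, ...) {
  cat("TSP instance: ", x$n_nodes, " nodes (", 2L * x$n,
      " connectors + ", x$n, " intermediate), max weight m = ",
      format(x$max_weight), "\n", sep = "")
  invisible(x)
}

#' Solve the contig ordering exactly by branch and bound
#'
#' Finds a shortest Hamiltonian cycle of the TSP instance — equivalently a
#' maximum-total-weight circular signed contig order — by depth-first branch
#' and bound over signed contig sequences. The first contig (lexicographically
#' smallest id) is fixed in forward orientation, which canonicalizes rotation
#' and reflection; remaining contigs are explored in lexicographic order with
#' strict improvement, so among equally good tours the lexicographically
#' least signed permutation is returned. The cycle is cut at its
#' lowest-weight realized adjacency (ties: the edge closing the cycle) to
#' report a linear order.
#'
#' @param instance A `tsp_instance` from [to_tsp()].
#' @param time_limit Wall-clock limit in seconds.
#' @param exact_limit Refuse instances with more contigs than this.
#' @return An object of class `signed_ordering`: a `data.frame` with columns
#'   `rank`, `contig_id`, `orientation`, `weight_to_next`, plus attributes
#'   `total_weight` (cycle weight) and `cut_weight`.
#' @export
solve_exact <- function(instance, time_limit = 60, exact_limit = 14L) {
  g <- instance$graph
  ids <- sort(g$contig_ids)
  n <- length(ids)
  if (n > exact_limit) {
    stop("instance has ", n, " contigs, above the exact solver bound (",
         exact_limit, "); use build_layout() for large instances")
  }
  make_ordering <- function(seq_id, seq_or, wnext, total, cutw) {
    df <- data.frame(rank = seq_along(seq_id), contig_id = seq_id,
                     orientation = ifelse(seq_or > 0, "forward", "reverse"),
                     weight_to_next = wnext, stringsAsFactors = FALSE)
    structure(df, total_weight = total, cut_weight = cutw,
              class = c("signed_ordering", "data.frame"))
  }
  if (n == 1L) {
    return(make_ordering(ids, 1L, NA_real_, 0, NA_real_))
  }
  W <- g$W
  # connector row/col index for contig k (position in `ids`), orientation o
  vnum <- function(k, side) vertex_number(g$contig_ids, ids[k], side)
  in_v <- cbind(sapply(seq_len(n), vnum, side = "L"),
                sapply(seq_len(n), vnum, side = "R"))  # [,1] fwd, [,2] rev
  out_v <- cbind(in_v[, 2L], in_v[, 1L])
  mask <- adjacency_mask(2L * n)
  maxw_c <- vapply(seq_len(n), function(k) {
    max(W[in_v[k, ], ][mask[in_v[k, ], ]])
  }, numeric(1L))
  env <- new.env()
  env$best <- -Inf
  env$best_seq <- NULL
  env$nodes <- 0L
  t0 <- Sys.time()
  used <- rep(FALSE, n)
  path_id <- integer(n); path_or <- integer(n)
  path_id[1L] <- 1L; path_or[1L] <- 1L
  used[1L] <- TRUE
  rec <- function(depth, cur, last_out, sum_rem) {
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 4096L == 0L &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      stop("TSP time limit exceeded; use build_layout() for this instance")
    }
    if (depth == n) {
      total <- cur + W[last_out, in_v[1L, 1L]]
      if (total > env$best) {
        env$best <- total
        env$best_seq <- list(id = path_id[1:n], or = path_or[1:n])
      }
      return(invisible())
    }
    if (cur + sum_rem + maxw_c[1L] <= env$best) return(invisible())
    for (j in which(!used)) {
      for (o in 1:2) {
        used[j] <<- TRUE
        path_id[depth + 1L] <<- j
        path_or[depth + 1L] <<- if (o == 1L) 1L else -1L
        rec(depth + 1L, cur + W[last_out, in_v[j, o]], out_v[j, o],
            sum_rem - maxw_c[j])
        used[j] <<- FALSE
      }
    }
    invisible()
  }
  rec(1L, 0, out_v[1L, 1L], sum(maxw_c[-1L]))
  sq <- env$best_seq
  # realized cycle edge weights: w[i] joins position i and i+1 (w[n] closes)
  or_col <- ifelse(sq$or > 0, 1L, 2L)
  wcyc <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    W[out_v[sq$id[i], or_col[i]], in_v[sq$id[j], or_col[j]]]
  }, numeric(1L))
  cut <- max(which(wcyc == min(wcyc)))
  rot <- if (cut == n) seq_len(n) else c((cut + 1L):n, 1L:cut)
  seq_id <- ids[sq$id[rot]]
  seq_or <- sq$or[rot]
  wnext <- c(wcyc[rot][-n], NA_real_)
  make_ordering(seq_id, seq_or, wnext, env$best, wcyc[cut])
}

#' @export
print.signed_ordering <- function(x, ...) {
  cat("Signed contig ordering (", nrow(x), " contigs), cycle weight ",
      format(attr(x, "total_weight")), "\n", sep = "")
  sym <- ifelse(x$orientation == "forward", "+", "-")
  cat("  ", paste0(x$contig_id, sym, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a signed ordering as TSV
#' @param ordering A `signed_ordering`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ordering <- function(ordering, path) {
  utils::write.table(as.data.frame(ordering), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
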