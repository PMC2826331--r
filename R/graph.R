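#' Scoring parameters for contig adjacency weights
#'
#' Parameters of the superimposed two-Gaussian adjacency score. The first
#' (zero-mean) component models insertions/deletions between the species; the
#' second component models lost sequencing fragments of expected size `mu`.
#' `phi` is the mixture weight of the lost-fragment component.
#'
#' @param sigma1 Standard deviation, in bases, of the insertion/deletion
#'   component (default 10000).
#' @param mu Expected lost fragment size in bases (default 2000).
#' @param sigma2 Standard deviation of the lost fragment size (default 1000).
#' @param phi Weight of the lost-fragment component, in `[0, 1]`
#'   (default 0.1).
#' @param tau_scaling If `TRUE` (default), `sigma1` is scaled by
#'   `tau / tau_min` so that more distant references tolerate larger
#'   displacements; the printed `sigma1` then applies to the closest
#'   reference.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(sigma1 = 10000, mu = 2000, sigma2 = 1000,
                           phi = 0.1, tau_scaling = TRUE) {
  stopifnot(sigma1 > 0, sigma2 > 0, phi >= 0, phi <= 1)
  structure(list(sigma1 = sigma1, mu = mu, sigma2 = sigma2, phi = phi,
                 tau_scaling = isTRUE(tau_scaling)),
            class = "scoring_params")
}

#' Project matches onto the reference
#'
#' Extends each match to the placement interval implied for the whole contig
#' on the reference record. Under the default (`"inclusive"`) convention a
#' full-length forward match projects exactly onto its own reference
#' interval; the `"raw"` convention keeps the unshifted begin coordinate
#' (one base to the left of the inclusive one). Projections may run off the
#' ends of the record (`pb < 1` or `pe >` record length).
#'
#' @param matches Match table `data.frame` (one or more rows).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param convention `"inclusive"` (default) or `"raw"`.
#' @return A `data.frame` with columns `contig_id`, `ref_genome`,
#'   `ref_record`, `pb`, `pe`, `orientation`.
#' @export
project_match <- function(matches, contig_lengths,
                          convention = c("inclusive", "raw")) {
  convention <- match.arg(convention)
  L <- unname(contig_lengths[matches$contig_id])
  if (anyNA(L)) stop("missing contig length for: ",
                     paste(unique(matches$contig_id[is.na(L)]), collapse = ", "))
  fwd <- matches$sb < matches$se
  off <- if (convention == "inclusive") 1L else 0L
  pb <- ifelse(fwd,
               matches$tb - matches$sb + off,
               matches$tb - (L - matches$sb) - 1L + off)
  pe <- ifelse(fwd,
               matches$te + L - matches$se,
               matches$te + matches$se - 1L)
  data.frame(contig_id = matches$contig_id, ref_genome = matches$ref_genome,
             ref_record = matches$ref_record, pb = as.numeric(pb),
             pe = as.numeric(pe),
             orientation = ifelse(fwd, "forward", "reverse"),
             stringsAsFactors = FALSE)
}

#' Displacement between two projected contigs
#'
#' Signed gap between two projection intervals on the same reference record:
#' `d = start(later) - end(earlier) - 1`, so abutting intervals give 0 and
#' overlapping intervals give a negative value. The displacement is undefined
#' (returned as `NA`) when the projections lie on different reference genomes
#' or records.
#'
#' @param p,p2 Single-row projection `data.frame`s (see [project_match()]).
#' @return Signed numeric displacement, or `NA` if undefined.
#' @export
displacement <- function(p, p2) {
  if (p$ref_genome != p2$ref_genome || p$ref_record != p2$ref_record) {
    return(NA_real_)
  }
  first_earlier <- (p$pb < p2$pb) || (p$pb == p2$pb && p$pe <= p2$pe)
  if (first_earlier) p2$pb - p$pe - 1 else p$pb - p2$pe - 1
}

#' Phylogeny-weighted adjacency score
#'
#' Likelihood-style score for two contigs being adjacent given the
#' displacement `d` of their projections on a reference at phylogenetic
#' (patristic) distance `tau` from the contig species:
#' \deqn{s(d, \tau) = \frac{1}{\tau}\Big[(1-\varphi)
#'   e^{-d^2 / (2 \sigma_1(\tau)^2)} +
#'   \varphi\, e^{-(d-\mu)^2 / (2 \sigma_2^2)}\Big]}
#' with \eqn{\sigma_1(\tau) = \sigma_1 \tau / \tau_{min}} when `tau_scaling`
#' is on. The Gaussians are unnormalized kernels (value 1 at their mean), so
#' `phi` alone controls the balance of the two components.
#'
#' @param d Displacement(s) in bases (may be a vector).
#' @param tau Patristic distance between contig species and reference
#'   species; must be positive.
#' @param params A [scoring_params()] object.
#' @param tau_min Smallest contig-to-reference distance in the run (defaults
#'   to `tau`).
#' @return Nonnegative score(s), strictly positive and tending to 0 as
#'   `|d|` grows.
#' @export
adjacency_score <- function(d, tau, params = scoring_params(),
                            tau_min = tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a single positive number (the contig species must not ",
         "be its own reference)")
  }
  s1 <- if (params$tau_scaling) params$sigma1 * tau / tau_min else params$sigma1
  (1 / tau) * ((1 - params$phi) * exp(-d^2 / (2 * s1^2)) +
                 params$phi * exp(-(d - params$mu)^2 / (2 * params$sigma2^2)))
}

vertex_labels <- function(contig_ids) {
  as.vector(rbind(paste0(contig_ids, ":L"), paste0(contig_ids, ":R")))
}

vertex_number <- function(contig_ids, contig, side) {
  i <- match(contig, contig_ids)
  if (anyNA(i)) stop("unknown contig id: ",
                     paste(unique(contig[is.na(i)]), collapse = ", "))
  2L * (i - 1L) + ifelse(side == "R", 2L, 1L)
}

new_adjacency_graph <- function(contig_ids, contig_lengths, W, W_ref, tau,
                                tau_min, params, d_cutoff) {
  v <- vertex_labels(contig_ids)
  dimnames(W) <- list(v, v)
  for (r in names(W_ref)) dimnames(W_ref[[r]]) <- list(v, v)
  structure(list(contig_ids = contig_ids, contig_lengths = contig_lengths,
                 vertices = v, W = W, W_ref = W_ref, tau = tau,
                 tau_min = tau_min, params = params, d_cutoff = d_cutoff,
                 overridden = matrix(FALSE, length(v), length(v),
                                     dimnames = list(v, v))),
            class = "adjacency_graph")
}

#' Construct an adjacency graph from precomputed edge weights
#'
#' Builds a contig adjacency graph directly from an edge list, for example
#' from expert knowledge or precomputed scores. Unlisted connector pairs get
#' weight 0; intra edges are always 0.
#'
#' @param contig_ids Character vector of contig ids.
#' @param edges Optional `data.frame` with columns `contig1`, `side1`,
#'   `contig2`, `side2`, `weight` (and optionally `ref`).
#' @param contig_lengths Optional named lengths (defaults to `NA`).
#' @return An `adjacency_graph` object.
#' @export
adjacency_graph <- function(contig_ids, edges = NULL, contig_lengths = NULL) {
  n2 <- 2L * length(contig_ids)
  if (is.null(contig_lengths)) {
    contig_lengths <- stats::setNames(rep(NA_integer_, length(contig_ids)),
                                      contig_ids)
  }
  refs <- if (!is.null(edges) && "ref" %in% names(edges)) {
    sort(unique(edges$ref))
  } else "manual"
  W_ref <- lapply(stats::setNames(refs, refs),
                  function(r) matrix(0, n2, n2))
  if (!is.null(edges) && nrow(edges) > 0L) {
    a <- vertex_number(contig_ids, edges$contig1, edges$side1)
    b <- vertex_number(contig_ids, edges$contig2, edges$side2)
    if (any(edges$contig1 == edges$contig2)) {
      stop("edge weights cannot be assigned to intra contig edges")
    }
    rr <- if ("ref" %in% names(edges)) edges$ref else rep(refs[1L], nrow(edges))
    for (k in seq_len(nrow(edges))) {
      M <- W_ref[[rr[k]]]
      M[a[k], b[k]] <- max(M[a[k], b[k]], edges$weight[k])
      M[b[k], a[k]] <- M[a[k], b[k]]
      W_ref[[rr[k]]] <- M
    }
  }
  W <- Reduce(`+`, W_ref)
  tau <- stats::setNames(rep(NA_real_, length(refs)), refs)
  new_adjacency_graph(contig_ids, contig_lengths, W, W_ref, tau, NA_real_,
                      scoring_params(), Inf)
}

#' Build the contig adjacency graph from matches
#'
#' For every unordered pair of connectors of different contigs and every
#' reference genome, all supporting match-pair combinations on a common
#' reference record are enumerated. A pair of projections supports the edge
#' between the rightward-facing connector of the earlier projection and the
#' leftward-facing connector of the later one (a forward-projected contig
#' faces right with its `R` connector, a reverse-projected one with its `L`
#' connector). Each supporting pair is scored with [adjacency_score()] at the
#' patristic distance of its reference; the per-reference edge weight is the
#' maximum over supporting pairs and the total edge weight the sum over
#' references.
#'
#' @param matches Match table `data.frame`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param tree A `phylo` tree containing contig species and all reference
#'   genomes as leaves.
#' @param contig_species Leaf name of the species the contigs belong to.
#' @param ref_genomes Reference genome names (tree leaves); defaults to the
#'   genomes present in `matches`.
#' @param params A [scoring_params()] object.
#' @param d_cutoff Displacement cutoff in bases; supporting pairs with
#'   `|d| > d_cutoff` are ignored (default 200000).
#' @param convention Projection convention, see [project_match()].
#' @return An `adjacency_graph` object.
#' @export
build_adjacency_graph <- function(matches, contig_lengths, tree,
                                  contig_species,
                                  ref_genomes = sort(unique(matches$ref_genome)),
                                  params = scoring_params(),
                                  d_cutoff = 200000,
                                  convention = "inclusive") {
  contig_ids <- names(contig_lengths)
  n2 <- 2L * length(contig_ids)
  dm <- tree_distance_matrix(tree)
  if (!contig_species %in% rownames(dm)) {
    stop("species not in tree: ", contig_species)
  }
  missing <- setdiff(ref_genomes, rownames(dm))
  if (length(missing) > 0L) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  if (contig_species %in% ref_genomes) {
    stop("the contig species must not be among the reference genomes")
  }
  tau <- stats::setNames(dm[contig_species, ref_genomes], ref_genomes)
  if (any(tau <= 0)) stop("zero phylogenetic distance to reference(s): ",
                          paste(names(tau)[tau <= 0], collapse = ", "))
  tau_min <- min(tau)
  W_ref <- lapply(stats::setNames(ref_genomes, ref_genomes),
                  function(r) matrix(0, n2, n2))
  if (nrow(matches) == 0L) {
    warning("no matches; all adjacency weights are 0")
  } else {
    proj <- project_match(matches, contig_lengths, convention)
    for (g in intersect(ref_genomes, unique(proj$ref_genome))) {
      Wg <- W_ref[[g]]
      pg <- proj[proj$ref_genome == g, , drop = FALSE]
      for (rec in unique(pg$ref_record)) {
        P <- pg[pg$ref_record == rec, , drop = FALSE]
        P <- P[order(P$pb, P$pe, P$contig_id), , drop = FALSE]
        p <- nrow(P)
        if (p < 2L) next
        idx <- which(upper.tri(matrix(NA, p, p)), arr.ind = TRUE)
        i <- idx[, 1L]; j <- idx[, 2L]
        keep <- P$contig_id[i] != P$contig_id[j]
        i <- i[keep]; j <- j[keep]
        if (length(i) == 0L) next
        d <- P$pb[j] - P$pe[i] - 1
        keep <- abs(d) <= d_cutoff
        i <- i[keep]; j <- j[keep]; d <- d[keep]
        if (length(i) == 0L) next
        side_i <- ifelse(P$orientation[i] == "forward", "R", "L")
        side_j <- ifelse(P$orientation[j] == "forward", "L", "R")
        vi <- vertex_number(contig_ids, P$contig_id[i], side_i)
        vj <- vertex_number(contig_ids, P$contig_id[j], side_j)
        s <- adjacency_score(d, unname(tau[g]), params, tau_min)
        a <- pmin(vi, vj); b <- pmax(vi, vj)
        key <- paste(a, b)
        agg <- tapply(s, key, max)
        ab <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
        ai <- as.integer(ab[, 1L]); bi <- as.integer(ab[, 2L])
        cur <- Wg[cbind(ai, bi)]
        upd <- pmax(cur, as.numeric(agg))
        Wg[cbind(ai, bi)] <- upd
        Wg[cbind(bi, ai)] <- upd
      }
      W_ref[[g]] <- Wg
    }
  }
  W <- Reduce(`+`, W_ref)
  new_adjacency_graph(contig_ids, contig_lengths, W, W_ref, tau, tau_min,
                      params, d_cutoff)
}

# Logical mask of adjacency entries (pairs of connectors of different
# contigs) in a 2n x 2n weight matrix.
adjacency_mask <- function(n2) {
  contig_of <- rep(seq_len(n2 / 2L), each = 2L)
  outer(contig_of, contig_of, `!=`)
}

#' Maximum adjacency edge weight of a graph
#' @param graph An `adjacency_graph`.
#' @return The maximum weight over all adjacency edges.
#' @export
max_adjacency_weight <- function(graph) {
  m <- graph$W[adjacency_mask(length(graph$vertices))]
  if (length(m) == 0L) 0 else max(m)
}

#' List the adjacency edges of a graph
#'
#' @param graph An `adjacency_graph`.
#' @param include_zero Include zero-weight adjacency edges?
#' @return `data.frame` with `contig1`, `side1`, `contig2`, `side2`,
#'   `weight`, one `w.<ref>` column per reference, and `overridden`.
#' @export
graph_edges <- function(graph, include_zero = FALSE) {
  n2 <- length(graph$vertices)
  mask <- adjacency_mask(n2) & upper.tri(matrix(NA, n2, n2))
  sel <- which(mask, arr.ind = TRUE)
  w <- graph$W[sel]
  if (!include_zero) {
    keep <- w > 0 | graph$overridden[sel]
    sel <- sel[keep, , drop = FALSE]
    w <- w[keep]
  }
  contig_of <- function(v) graph$contig_ids[(v + 1L) %/% 2L]
  side_of <- function(v) ifelse(v %% 2L == 0L, "R", "L")
  out <- data.frame(contig1 = contig_of(sel[, 1L]), side1 = side_of(sel[, 1L]),
                    contig2 = contig_of(sel[, 2L]), side2 = side_of(sel[, 2L]),
                    weight = w, stringsAsFactors = FALSE)
  for (r in names(graph$W_ref)) out[[paste0("w.", r)]] <- graph$W_ref[[r]][sel]
  out$overridden <- graph$overridden[sel]
  out[order(-out$weight, out$contig1, out$side1, out$contig2, out$side2), ,
      drop = FALSE]
}

#' Apply expert adjacency constraints to a graph
#'
#' `forbid` sets the edge weight to zero; `force` sets it to the maximum
#' adjacency weight of the graph. All forbids are applied before any force,
#' and the force weight is the maximum taken after the forbids. Overridden
#' edges are flagged in the per-reference decomposition.
#'
#' @param graph An `adjacency_graph`.
#' @param constraints `data.frame` with columns `contig1`, `side1`,
#'   `contig2`, `side2`, `action` (see [read_constraints()]).
#' @return The modified `adjacency_graph`.
#' @export
apply_constraints <- function(graph, constraints) {
  if (nrow(constraints) == 0L) return(graph)
  if (any(constraints$contig1 == constraints$contig2)) {
    stop("constraints on intra contig edges are not allowed")
  }
  a <- vertex_number(graph$contig_ids, constraints$contig1, constraints$side1)
  b <- vertex_number(graph$contig_ids, constraints$contig2, constraints$side2)
  set_edge <- function(g, i, j, w) {
    g$W[i, j] <- w; g$W[j, i] <- w
    g$overridden[i, j] <- TRUE; g$overridden[j, i] <- TRUE
    g
  }
  forb <- which(constraints$action == "forbid")
  for (k in forb) {
    graph <- set_edge(graph, a[k], b[k], 0)
    for (r in names(graph$W_ref)) {
      graph$W_ref[[r]][a[k], b[k]] <- 0
      graph$W_ref[[r]][b[k], a[k]] <- 0
    }
  }
  frc <- which(constraints$action == "force")
  if (length(frc) > 0L) {
    m <- max_adjacency_weight(graph)
    for (k in frc) graph <- set_edge(graph, a[k], b[k], m)
  }
  graph
}

#' @export
print.adjacency_graph <- function(x, ...) {
  n <- length(x$contig_ids)
  ne <- sum(graph_edges(x)$weight > 0)
  cat("Contig adjacency graph\n")
  cat("  contigs:    ", n, " (", 2L * n, " connectors, ",
      choose(2L * n, 2L), " edges, ", n, " intra)\n", sep = "")
  cat("  references: ", paste(names(x$tau), collapse = ", "), "\n", sep = "")
  if (!anyNA(x$tau)) {
    cat("  tau:        ", paste(sprintf("%s=%.4g", names(x$tau), x$tau),
                                collapse = ", "), "\n", sep = "")
  }
  cat("  non-zero adjacency edges: ", ne, "\n", sep = "")
  cat("  max adjacency weight:     ", format(max_adjacency_weight(x)),
      "\n", sep = "")
  invisible(x)
}

#' Write an adjacency graph edge list as TSV
#'
#' @param graph An `adjacency_graph`.
#' @param path Output path.
#' @param include_zero Include zero-weight edges?
#' @return Invisibly, `path`.
#' @export
write_graph <- function(graph, path, include_zero = FALSE) {
  utils::write.table(graph_edges(graph, include_zero), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
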