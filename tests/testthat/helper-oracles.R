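# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results from first principles (plain loops,
# closed forms, exhaustive enumeration) rather than calling the package
# internals they are used to check.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_substitutions <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# Substitutions at fixed positions, resampled until the *edit* distance to
# the original equals the substitution count (random base choices can make a
# Levenshtein alignment cheaper than the Hamming count, which would change
# the planted error rate).
plant_mismatches <- function(seq, positions) {
  repeat {
    mut <- mutate_substitutions(seq, positions)
    if (utils::adist(mut, seq)[1, 1] == length(positions)) return(mut)
  }
}

rc_oracle <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Closed-form adjacency score, written out independently.
oracle_score <- function(d, tau, sigma1 = 10000, mu = 2000, sigma2 = 1000,
                         phi = 0.1, tau_scaling = TRUE, tau_min = tau) {
  s1 <- if (tau_scaling) sigma1 * tau / tau_min else sigma1
  (1 / tau) * ((1 - phi) * exp(-d^2 / (2 * s1^2)) +
                 phi * exp(-(d - mu)^2 / (2 * sigma2^2)))
}

# Exhaustive enumeration of all supporting match pairs, straight from the
# definitions: project every match, consider every pair of matches of
# different contigs on the same genome and record, take the per-reference
# maximum score per connector pair and sum over references.
oracle_graph_weights <- function(matches, contig_lengths, tau, params,
                                 d_cutoff) {
  tau_min <- min(tau)
  ids <- names(contig_lengths)
  w_total <- list()
  for (g in names(tau)) {
    mg <- matches[matches$ref_genome == g, , drop = FALSE]
    if (nrow(mg) == 0L) next
    w_g <- list()
    for (i in seq_len(nrow(mg))) {
      for (j in seq_len(nrow(mg))) {
        if (i == j) next
        mi <- mg[i, ]; mj <- mg[j, ]
        if (mi$contig_id == mj$contig_id) next
        if (mi$ref_record != mj$ref_record) next
        pr <- function(m) {
          L <- contig_lengths[[m$contig_id]]
          if (m$sb < m$se) {
            c(pb = m$tb - m$sb + 1, pe = m$te + L - m$se, fwd = 1)
          } else {
            c(pb = m$tb - (L - m$sb) - 1 + 1, pe = m$te + m$se - 1, fwd = 0)
          }
        }
        pi <- pr(mi); pj <- pr(mj)
        # unordered pair handled once, with i the earlier projection
        if (pi[["pb"]] > pj[["pb"]] ||
            (pi[["pb"]] == pj[["pb"]] && pi[["pe"]] > pj[["pe"]]) ||
            (pi[["pb"]] == pj[["pb"]] && pi[["pe"]] == pj[["pe"]] &&
               mi$contig_id > mj$contig_id)) next
        d <- pj[["pb"]] - pi[["pe"]] - 1
        if (abs(d) > d_cutoff) next
        v1 <- paste0(mi$contig_id, ":", if (pi[["fwd"]] == 1) "R" else "L")
        v2 <- paste0(mj$contig_id, ":", if (pj[["fwd"]] == 1) "L" else "R")
        key <- paste(sort(c(v1, v2)), collapse = "|")
        s <- oracle_score(d, tau[[g]], params$sigma1, params$mu,
                          params$sigma2, params$phi, params$tau_scaling,
                          tau_min)
        if (is.null(w_g[[key]]) || s > w_g[[key]]) w_g[[key]] <- s
      }
    }
    for (key in names(w_g)) {
      w_total[[key]] <- (if (is.null(w_total[[key]])) 0 else w_total[[key]]) +
        w_g[[key]]
    }
  }
  w_total
}

# Extract the implementation's nonzero adjacency weights in the same keyed
# form as the oracle.
graph_weight_map <- function(graph) {
  e <- graph_edges(graph)
  e <- e[e$weight > 0, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(e))) {
    key <- paste(sort(c(paste0(e$contig1[k], ":", e$side1[k]),
                        paste0(e$contig2[k], ":", e$side2[k]))),
                 collapse = "|")
    out[[key]] <- e$weight[k]
  }
  out
}

# Random micro-instance: a few contigs, references and arbitrary matches.
random_micro_instance <- function(max_contigs = 3L, max_refs = 2L,
                                  max_matches = 4L) {
  n <- sample(2:max_contigs, 1L)
  ids <- paste0("c", seq_len(n))
  lens <- stats::setNames(sample(50:500, n, TRUE), ids)
  n_refs <- sample(1:max_refs, 1L)
  refs <- paste0("g", seq_len(n_refs))
  nm <- sample(2:max_matches, 1L)
  rows <- lapply(seq_len(nm), function(k) {
    cid <- sample(ids, 1L)
    L <- lens[[cid]]
    a <- sample.int(L, 1L); b <- sample.int(L, 1L)
    while (b == a) b <- sample.int(L, 1L)
    tb <- sample.int(5000, 1L)
    te <- tb + abs(b - a)
    data.frame(contig_id = cid, ref_genome = sample(refs, 1L),
               ref_record = "chr", sb = a, se = b, tb = tb, te = te,
               qhits = sample.int(50, 1L), stringsAsFactors = FALSE)
  })
  list(matches = do.call(rbind, rows), lens = lens, refs = refs)
}

# Newick tree placing the contig species S and references g1..gk at given
# distances (star tree: distance S->gi = 0.1 + extra_i).
star_tree <- function(refs, extra = rep(0.4, length(refs))) {
  tips <- paste0(refs, ":", extra + 0.05)
  read_newick(paste0("(S:0.05,", paste(tips, collapse = ","), ");"))
}

# Exhaustive maximum cycle weight over all signed circular orderings.
# Rotation and reflection invariance let the first contig be fixed in
# forward orientation; orientation combinations are evaluated vectorized.
oracle_tsp_max <- function(graph) {
  ids <- sort(graph$contig_ids)
  n <- length(ids)
  W <- graph$W
  base <- 2L * (match(ids, graph$contig_ids) - 1L)
  lidx <- base + 1L
  ridx <- base + 2L
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  FWD <- cbind(TRUE, as.matrix(expand.grid(rep(list(c(TRUE, FALSE)),
                                               n - 1L))))
  C <- nrow(FWD)
  best <- -Inf
  for (p in perms(seq_len(n)[-1L])) {
    ordp <- c(1L, p)
    Rm <- matrix(ridx[ordp], C, n, byrow = TRUE)
    Lm <- matrix(lidx[ordp], C, n, byrow = TRUE)
    OUT <- ifelse(FWD, Rm, Lm)
    IN <- ifelse(FWD, Lm, Rm)[, c(seq_len(n)[-1L], 1L), drop = FALSE]
    tot <- rowSums(matrix(W[cbind(as.vector(OUT), as.vector(IN))], C, n))
    m <- max(tot)
    if (m > best) best <- m
  }
  best
}

# Random fully specified adjacency graph on n contigs.
random_adjacency_graph <- function(n) {
  ids <- paste0("c", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      for (s1 in c("L", "R")) {
        for (s2 in c("L", "R")) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig1 = ids[i], side1 = s1, contig2 = ids[j], side2 = s2,
            weight = stats::runif(1L), stringsAsFactors = FALSE)
        }
      }
    }
  }
  adjacency_graph(ids, do.call(rbind, rows))
}

# Shared tree for pipeline-scale simulations: one close reference (R1) and
# a more distant pair (R2, R3).
sim_tree <- function() {
  read_newick("((S:0.35,R1:0.35):0.15,(R2:0.30,R3:0.30):0.20);")
}
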