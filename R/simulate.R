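DNA_BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(x) unname(COMP[rev(x)])

#' Simulation parameters
#'
#' Parameters for the synthetic comparative-assembly generator: an ancestral
#' genome is evolved independently down each branch of a tree, and the
#' sequence at one designated leaf (the contig species) is fragmented into
#' contigs separated by lost fragments.
#'
#' Structural event rates (`inv_rate`, `transloc_rate`) are expected events
#' per unit branch length; `indel_rate` and `sub_rate` are per base per unit
#' branch length. Lost fragment sizes follow a Normal distribution truncated
#' at 0, mirroring the lost-fragment component of the adjacency score.
#'
#' @param genome_length Ancestral genome length in bases.
#' @param tree A `phylo` tree (or Newick string) with branch lengths; all
#'   leaves are simulated.
#' @param contig_species Leaf whose genome is fragmented into contigs.
#' @param n_contigs Number of contigs to cut.
#' @param sub_rate Substitutions per base per unit branch length
#'   (default 0.02).
#' @param inv_rate Expected inversions per unit branch length (default 0).
#' @param transloc_rate Expected translocations per unit branch length
#'   (default 0).
#' @param indel_rate Indel events per base per unit branch length
#'   (default 0.001).
#' @param inv_size_mean,transloc_size_mean,indel_size_mean Geometric mean
#'   event sizes in bases.
#' @param lost_fragment_mean,lost_fragment_sd Lost fragment (gap) size
#'   distribution in bases (defaults 2000 and 1000).
#' @param min_contig Minimum contig length in bases (default 1000).
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length, tree, contig_species, n_contigs,
                       sub_rate = 0.02, inv_rate = 0, transloc_rate = 0,
                       indel_rate = 0.001, inv_size_mean = 10000,
                       transloc_size_mean = 10000, indel_size_mean = 3,
                       lost_fragment_mean = 2000, lost_fragment_sd = 1000,
                       min_contig = 1000L, seed = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"), genome_length >= 1, n_contigs >= 1,
            sub_rate >= 0, inv_rate >= 0, transloc_rate >= 0, indel_rate >= 0,
            lost_fragment_mean >= 0, lost_fragment_sd >= 0)
  if (!contig_species %in% tree$tip.label) {
    stop("species not in tree: ", contig_species)
  }
  if ((n_contigs - 1) * lost_fragment_mean + n_contigs * min_contig >
        genome_length) {
    stop("n_contigs x (mean contig + mean gap) exceeds genome_length")
  }
  structure(list(genome_length = as.integer(genome_length), tree = tree,
                 contig_species = contig_species,
                 n_contigs = as.integer(n_contigs), sub_rate = sub_rate,
                 inv_rate = inv_rate, transloc_rate = transloc_rate,
                 indel_rate = indel_rate, inv_size_mean = inv_size_mean,
                 transloc_size_mean = transloc_size_mean,
                 indel_size_mean = indel_size_mean,
                 lost_fragment_mean = lost_fragment_mean,
                 lost_fragment_sd = lost_fragment_sd,
                 min_contig = as.integer(min_contig), seed = seed),
            class = "sim_params")
}

geom_size <- function(mean_size) {
  if (mean_size <= 1) return(1L)
  1L + stats::rgeom(1L, 1 / mean_size)
}

# Evolve a genome (character vector) along one branch. Structural events
# first, substitutions last. Returns list(seq, log).
evolve_branch <- function(x, bl, p, branch_label) {
  log <- list()
  note <- function(type, pos, size) {
    log[[length(log) + 1L]] <<- data.frame(branch = branch_label, type = type,
                                           pos = pos, size = size)
  }
  n_inv <- stats::rpois(1L, p$inv_rate * bl)
  for (k in seq_len(n_inv)) {
    size <- min(length(x) - 1L, geom_size(p$inv_size_mean))
    a <- sample.int(length(x) - size + 1L, 1L)
    b <- a + size - 1L
    x[a:b] <- revcomp_chars(x[a:b])
    note("inversion", a, size)
  }
  n_tr <- stats::rpois(1L, p$transloc_rate * bl)
  for (k in seq_len(n_tr)) {
    size <- min(length(x) %/% 2L, geom_size(p$transloc_size_mean))
    if (size < 1L) next
    a <- sample.int(length(x) - size + 1L, 1L)
    seg <- x[a:(a + size - 1L)]
    x <- x[-(a:(a + size - 1L))]
    ins <- sample.int(length(x) + 1L, 1L)
    x <- append(x, seg, after = ins - 1L)
    note("translocation", a, size)
  }
  n_id <- stats::rpois(1L, p$indel_rate * length(x) * bl)
  for (k in seq_len(n_id)) {
    size <- geom_size(p$indel_size_mean)
    if (stats::runif(1L) < 0.5 && length(x) > size + 1L) {
      a <- sample.int(length(x) - size + 1L, 1L)
      x <- x[-(a:(a + size - 1L))]
      note("deletion", a, size)
    } else {
      a <- sample.int(length(x) + 1L, 1L)
      x <- append(x, sample(DNA_BASES, size, replace = TRUE), after = a - 1L)
      note("insertion", a, size)
    }
  }
  psub <- p$sub_rate * bl
  if (psub > 0) {
    hit <- which(stats::runif(length(x)) < psub)
    if (length(hit) > 0L) {
      old <- x[hit]
      shift <- sample.int(3L, length(hit), replace = TRUE)
      x[hit] <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
      note("substitutions", NA_integer_, length(hit))
    }
  }
  list(seq = x, log = log)
}

#' Simulate a comparative assembly problem with ground truth
#'
#' Draws a random ancestral genome, evolves it independently along every
#' branch of the tree (inversions, translocations, indels, substitutions,
#' Poisson in branch length times rate), cuts the sequence of the contig
#' species into contigs separated by lost fragments drawn from a truncated
#' Normal, and reverse-complements each contig with probability 1/2. The
#' true signed contig order, the gap sizes, and the per-branch event log are
#' returned alongside the sequences.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `contigs` (named character vector),
#'   `references` (named list of single-record genomes, one per non-contig
#'   leaf), `target_genome` (the contig species' full sequence), `tree`,
#'   `truth` (a [reference_order()]), `gaps` (numeric vector of lost
#'   fragment sizes) and `event_log` (`data.frame`).
#' @export
simulate_assembly <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  tr <- p$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  anc <- sample(DNA_BASES, p$genome_length, replace = TRUE)
  seqs <- vector("list", max(tr$edge))
  seqs[[root]] <- anc
  logs <- list()
  # process edges parent-before-child (ape trees are not guaranteed ordered,
  # so iterate until all children are resolved)
  todo <- seq_len(nrow(tr$edge))
  while (length(todo) > 0L) {
    prog <- FALSE
    for (e in todo) {
      par <- tr$edge[e, 1L]; chl <- tr$edge[e, 2L]
      if (is.null(seqs[[par]])) next
      lab <- if (chl <= ntip) tr$tip.label[chl] else paste0("node", chl)
      res <- evolve_branch(seqs[[par]], tr$edge.length[e], p, lab)
      seqs[[chl]] <- res$seq
      logs <- c(logs, res$log)
      todo <- setdiff(todo, e)
      prog <- TRUE
    }
    if (!prog) stop("tree edges do not form a rooted tree")
  }
  leaves <- stats::setNames(lapply(seq_len(ntip), function(i) seqs[[i]]),
                            tr$tip.label)
  target <- leaves[[p$contig_species]]
  L <- length(target)
  n <- p$n_contigs
  # lost fragment sizes: Normal truncated at 0
  draw_gap <- function() {
    if (p$lost_fragment_mean == 0 && p$lost_fragment_sd == 0) return(0)
    repeat {
      g <- stats::rnorm(1L, p$lost_fragment_mean, p$lost_fragment_sd)
      if (g >= 0) return(round(g))
    }
  }
  gaps <- if (n > 1L) vapply(seq_len(n - 1L), function(i) draw_gap(),
                             numeric(1L)) else numeric(0)
  total_contig <- L - sum(gaps)
  if (total_contig < n * p$min_contig) {
    stop("gaps leave less than n_contigs x min_contig bases of contig sequence")
  }
  extra <- total_contig - n * p$min_contig
  props <- diff(c(0, sort(stats::runif(n - 1L)), 1))
  alloc <- floor(props * extra)
  rem <- extra - sum(alloc)
  if (rem > 0L) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  clen <- p$min_contig + alloc
  starts <- cumsum(c(1, clen[-n] + gaps))
  ids <- sprintf("contig_%02d", seq_len(n))
  flip <- stats::runif(n) < 0.5
  contigs <- character(n)
  for (i in seq_len(n)) {
    seg <- target[starts[i]:(starts[i] + clen[i] - 1L)]
    if (flip[i]) seg <- revcomp_chars(seg)
    contigs[i] <- paste(seg, collapse = "")
  }
  names(contigs) <- ids
  truth <- reference_order(data.frame(
    contig_id = ids,
    orientation = ifelse(flip, "reverse", "forward"),
    start = starts, end = starts + clen - 1L, stringsAsFactors = FALSE))
  ref_leaves <- setdiff(tr$tip.label, p$contig_species)
  references <- lapply(stats::setNames(ref_leaves, ref_leaves), function(lf) {
    stats::setNames(paste(leaves[[lf]], collapse = ""),
                    paste0(lf, "_genome"))
  })
  event_log <- if (length(logs) > 0L) do.call(rbind, logs) else
    data.frame(branch = character(), type = character(), pos = integer(),
               size = integer())
  list(contigs = contigs, references = references,
       target_genome = paste(target, collapse = ""), tree = tr,
       truth = truth, gaps = gaps, event_log = event_log)
}

#' Write a simulated assembly problem to disk
#'
#' Writes `contigs.fasta`, one `ref_<leaf>.fasta` per reference,
#' `target.fasta`, `tree.nwk` and `truth.tsv` into a directory.
#'
#' @param sim Result of [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
  for (g in names(sim$references)) {
    write_fasta(sim$references[[g]], file.path(dir, paste0("ref_", g, ".fasta")))
  }
  write_fasta(stats::setNames(sim$target_genome, "target"),
              file.path(dir, "target.fasta"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
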