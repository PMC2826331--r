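#' Read a flat key-value run configuration
#'
#' The configuration format is one `key = value` pair per line, `#` starting
#' a comment. Reference genomes are given as `reference.<species> = <path>`.
#' Recognised keys mirror the command-line flags: `contigs`, `tree`,
#' `contig_species`, `out_dir`, `cache_dir`, `finished_genome`,
#' `constraints`, `q`, `min_length`, `max_error`, `sigma1`, `mu`, `sigma2`,
#' `phi`, `tau_scaling`, `d_cutoff`, `min_weight`, `order`, `exact_limit`,
#' `time_limit`, `circular`, `small_cutoff`, `repeat_fraction`.
#'
#' @param path Path to the configuration file.
#' @return A named list; reference paths are collected into a named
#'   character vector under `references`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, character(1L), 2L))
  vals <- trimws(vapply(kv, `[`, character(1L), 3L))
  cfg <- list()
  refs <- character()
  for (i in seq_along(keys)) {
    if (startsWith(keys[i], "reference.")) {
      refs[sub("^reference\\.", "", keys[i])] <- vals[i]
    } else {
      cfg[[keys[i]]] <- vals[i]
    }
  }
  num_keys <- c("q", "min_length", "max_error", "sigma1", "mu", "sigma2",
                "phi", "d_cutoff", "min_weight", "exact_limit", "time_limit",
                "small_cutoff", "repeat_fraction", "seed")
  for (k in intersect(num_keys, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  lgl_keys <- c("tau_scaling", "order", "circular")
  for (k in intersect(lgl_keys, names(cfg))) {
    cfg[[k]] <- toupper(cfg[[k]]) %in% c("TRUE", "T", "YES", "1", "ON")
  }
  cfg$references <- refs
  cfg
}

load_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    read_fasta(x)
  } else x
}

#' Run the full scaffolding pipeline
#'
#' Orchestrates matching (with cache), adjacency graph construction,
#' optional expert constraints, layout (and optionally exact ordering), and
#' optional evaluation against a finished genome, writing all artifacts to
#' `out_dir`: `matches.tsv`, `graph.tsv`, `layout.tsv`, `layout.dot`, and —
#' when requested/possible — `order.tsv` and `evaluation.tsv`.
#'
#' @param contigs Contig FASTA path or named character vector.
#' @param references Named character vector of reference FASTA paths (names
#'   are the species/tree leaves), or a named list of sequence vectors.
#' @param tree Newick path/string or a `phylo` object.
#' @param contig_species Tree leaf of the contig species.
#' @param out_dir Output directory.
#' @param cache_dir Match cache directory (default: `<out_dir>/cache`).
#' @param match_params A [match_params()] object.
#' @param scoring_params A [scoring_params()] object.
#' @param d_cutoff Displacement cutoff for graph construction.
#' @param min_weight Layout insertion threshold.
#' @param constraints Optional constraint file path or `data.frame`.
#' @param order Also compute the exact TSP ordering?
#' @param exact_limit,time_limit Exact solver bounds (see [solve_exact()]).
#' @param finished_genome Optional finished-genome FASTA path or sequence
#'   vector of the contig species, enabling evaluation.
#' @param circular Score the reference order as circular?
#' @param small_cutoff,repeat_fraction Layout annotation thresholds.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the matches, graph, layout, optional
#'   ordering and evaluation, and per-stage timings.
#' @export
run_pipeline <- function(contigs, references, tree, contig_species, out_dir,
                         cache_dir = file.path(out_dir, "cache"),
                         match_params = phyloscaf::match_params(),
                         scoring_params = phyloscaf::scoring_params(),
                         d_cutoff = 200000, min_weight = 0,
                         constraints = NULL, order = FALSE,
                         exact_limit = 14L, time_limit = 60,
                         finished_genome = NULL, circular = FALSE,
                         small_cutoff = 3500, repeat_fraction = 0.95,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- load_genome(contigs)
  if (is.character(references) && !is.null(names(references))) {
    references <- lapply(as.list(references), read_fasta)
  }
  if (inherits(tree, "phylo")) tr <- tree else tr <- read_newick(tree)
  missing <- setdiff(c(contig_species, names(references)), tr$tip.label)
  if (length(missing) > 0L) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  say("phyloscaf: matching ", length(contigs), " contigs against ",
      length(references), " reference genome(s) [q=", match_params$q,
      ", min_length=", match_params$min_length,
      ", max_error=", match_params$max_error, "]")
  st <- t_stage(match_all(contigs, references, match_params, cache_dir))
  matches <- st$val
  timings <- c(matching = st$secs)
  write_matches(matches, file.path(out_dir, "matches.tsv"))
  say("  ", nrow(matches), " matches (", round(st$secs, 1), " s)")

  lens <- stats::setNames(nchar(contigs), names(contigs))
  say("phyloscaf: building adjacency graph [sigma1=", scoring_params$sigma1,
      ", mu=", scoring_params$mu, ", sigma2=", scoring_params$sigma2,
      ", phi=", scoring_params$phi, "]")
  st <- t_stage(build_adjacency_graph(matches, lens, tr, contig_species,
                                      ref_genomes = sort(names(references)),
                                      params = scoring_params,
                                      d_cutoff = d_cutoff))
  graph <- st$val
  timings["graph"] <- st$secs
  if (!is.null(constraints)) {
    if (is.character(constraints)) constraints <- read_constraints(constraints)
    graph <- apply_constraints(graph, constraints)
  }
  write_graph(graph, file.path(out_dir, "graph.tsv"))
  say("  ", sum(graph_edges(graph)$weight > 0), " non-zero adjacency edges (",
      round(st$secs, 1), " s)")

  ordering <- NULL
  if (order) {
    say("phyloscaf: exact ordering (branch and bound)")
    st <- t_stage(solve_exact(to_tsp(graph), time_limit = time_limit,
                              exact_limit = exact_limit))
    ordering <- st$val
    timings["order"] <- st$secs
    write_ordering(ordering, file.path(out_dir, "order.tsv"))
  }

  say("phyloscaf: layout heuristic [min_weight=", min_weight, "]")
  st <- t_stage(build_layout(graph, min_weight))
  layout <- st$val
  timings["layout"] <- st$secs

  evaluation <- NULL
  ref_ord <- NULL
  if (!is.null(finished_genome)) {
    say("phyloscaf: evaluation against finished genome")
    fin <- load_genome(finished_genome)
    st <- t_stage(build_reference_order(contigs, fin, match_params))
    ref_ord <- st$val
    timings["reference_order"] <- st$secs
    evaluation <- evaluate_adjacencies(layout, ref_ord, circular)
    write_evaluation(evaluation, file.path(out_dir, "evaluation.tsv"))
    if (!quiet) print(evaluation)
  }
  layout <- annotate_layout(layout, contigs, matches, ref_ord,
                            small_cutoff, repeat_fraction)
  write_layout(layout, file.path(out_dir, "layout.tsv"))
  writeLines(layout_to_dot(layout), file.path(out_dir, "layout.dot"))
  say("phyloscaf: done (",
      paste(sprintf("%s %.1fs", names(timings), timings), collapse = ", "),
      ")")
  invisible(list(matches = matches, graph = graph, layout = layout,
                 ordering = ordering, reference_order = ref_ord,
                 evaluation = evaluation, timings = timings))
}

#' Run the pipeline from a configuration file
#'
#' @param config Path to a configuration file (see [read_config()]) or a
#'   list as returned by it.
#' @param overrides Named list of config values that take precedence.
#' @return See [run_pipeline()].
#' @export
run_pipeline_from_config <- function(config, overrides = list()) {
  if (is.character(config)) config <- read_config(config)
  for (k in names(overrides)) config[[k]] <- overrides[[k]]
  need <- c("contigs", "tree", "contig_species", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop("config lacks required key(s): ", paste(missing, collapse = ", "))
  }
  if (length(config$references) == 0L) stop("config names no reference genomes")
  mp <- match_params(
    q = config$q %||% 11L,
    min_length = config$min_length %||% 64L,
    max_error = config$max_error %||% 0.08)
  sp <- scoring_params(
    sigma1 = config$sigma1 %||% 10000, mu = config$mu %||% 2000,
    sigma2 = config$sigma2 %||% 1000, phi = config$phi %||% 0.1,
    tau_scaling = config$tau_scaling %||% TRUE)
  run_pipeline(
    contigs = config$contigs, references = config$references,
    tree = config$tree, contig_species = config$contig_species,
    out_dir = config$out_dir,
    cache_dir = config$cache_dir %||% file.path(config$out_dir, "cache"),
    match_params = mp, scoring_params = sp,
    d_cutoff = config$d_cutoff %||% 200000,
    min_weight = config$min_weight %||% 0,
    constraints = config$constraints,
    order = config$order %||% FALSE,
    exact_limit = config$exact_limit %||% 14L,
    time_limit = config$time_limit %||% 60,
    finished_genome = config$finished_genome,
    circular = config$circular %||% FALSE,
    small_cutoff = config$small_cutoff %||% 3500,
    repeat_fraction = config$repeat_fraction %||% 0.95)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
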