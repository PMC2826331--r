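#' Read a multi-FASTA file of nucleotide sequences
#'
#' Reads a (multi-record) FASTA file and returns the sequences as a named
#' character vector in file order. Sequence identifiers are the first
#' whitespace-delimited token of each header line. Lowercase bases are
#' uppercased; only the characters `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a contig", "acgt", "ACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(seqs) < 1L)) stop("empty sequence in ", path)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a phylogenetic tree in Newick format
#'
#' Parses a Newick tree with branch lengths. Branch lengths are required
#' because they drive the phylogeny weighting of adjacency scores; a tree
#' without them is rejected.
#'
#' @param path Path to a Newick file (or a Newick string ending in `;`).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE) && !file.exists(path)) {
    ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("could not parse Newick tree")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("branch lengths are required on every edge of the Newick tree")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label))) {
    stop("every leaf must be named")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Patristic distance between two leaves of a tree
#'
#' Sum of branch lengths on the unique path between two named leaves.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param leaf_a,leaf_b Leaf names.
#' @return Nonnegative numeric distance; 0 when `leaf_a == leaf_b`.
#' @export
tree_distance <- function(tree, leaf_a, leaf_b) {
  d <- tree_distance_matrix(tree)
  for (x in c(leaf_a, leaf_b)) {
    if (!x %in% rownames(d)) stop("unknown leaf name: ", x)
  }
  unname(d[leaf_a, leaf_b])
}

# Full patristic distance matrix (leaves only).
tree_distance_matrix <- function(tree) {
  stats::cophenetic(tree)
}

match_table_columns <- c("contig_id", "ref_genome", "ref_record",
                         "sb", "se", "tb", "te", "qhits")

empty_match_table <- function() {
  df <- data.frame(contig_id = character(), ref_genome = character(),
                   ref_record = character(), sb = integer(), se = integer(),
                   tb = integer(), te = integer(), qhits = integer(),
                   stringsAsFactors = FALSE)
  df
}

# Normalize raw (possibly descending) coordinates to the internal convention:
# reference coordinates always ascending (tb < te); a reverse match is encoded
# by descending contig coordinates (sb > se).
normalize_match_coords <- function(qs, qe, ss, se) {
  rev_q <- qs > qe
  rev_s <- ss > se
  reverse <- xor(rev_q, rev_s)
  sb <- pmin(qs, qe)
  sE <- pmax(qs, qe)
  tb <- pmin(ss, se)
  te <- pmax(ss, se)
  data.frame(sb = ifelse(reverse, sE, sb), se = ifelse(reverse, sb, sE),
             tb = tb, te = te)
}

#' Read a table of contig-to-reference matches
#'
#' Supports three dialects: `blast-tab6` (BLAST `-outfmt 6`, 12 standard
#' columns), `nucmer-coords` (`show-coords -rclT` output), and `native-tsv`
#' (the table written by [write_matches()]). Coordinates are normalized so
#' that reference coordinates ascend (`tb < te`) and reverse matches carry
#' descending contig coordinates (`sb > se`).
#'
#' For imported BLAST/nucmer rows no q-gram hit count is available; it is
#' synthesized as `max(1, round(identity_fraction * aligned_length) - q + 1)`.
#'
#' @param path Path to the match table.
#' @param dialect One of `"blast-tab6"`, `"nucmer-coords"`, `"native-tsv"`.
#' @param q q-gram size used for the synthesized hit count (default 11).
#' @param record_to_genome Optional named character vector mapping reference
#'   record ids to reference genome names; by default each record is its own
#'   genome.
#' @return A match table `data.frame` with columns `contig_id`, `ref_genome`,
#'   `ref_record`, `sb`, `se`, `tb`, `te`, `qhits`.
#' @export
read_match_table <- function(path, dialect = c("native-tsv", "blast-tab6", "nucmer-coords"),
                             q = 11L, record_to_genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  genome_of <- function(rec) {
    if (is.null(record_to_genome)) return(rec)
    out <- unname(record_to_genome[rec])
    if (anyNA(out)) stop("no genome mapping for record(s): ",
                         paste(unique(rec[is.na(out)]), collapse = ", "))
    out
  }
  if (dialect == "native-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(match_table_columns, names(df))
    if (length(missing) > 0L) {
      stop("native match table lacks column(s): ", paste(missing, collapse = ", "))
    }
    df <- df[, match_table_columns, drop = FALSE]
    for (col in c("sb", "se", "tb", "te", "qhits")) df[[col]] <- as.integer(df[[col]])
    return(validate_match_table(df, path))
  }
  if (dialect == "blast-tab6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(empty_match_table())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 12L)) {
      stop("malformed blast-tab6 row at line ", which(nf < 12L)[1L])
    }
    m <- do.call(rbind, lapply(parts, function(p) p[1:12]))
    num <- function(j, line_check = TRUE) {
      v <- suppressWarnings(as.numeric(m[, j]))
      if (anyNA(v)) stop("malformed blast-tab6 row at line ", which(is.na(v))[1L])
      v
    }
    pident <- num(3); alen <- num(4)
    qs <- as.integer(num(7)); qe <- as.integer(num(8))
    ss <- as.integer(num(9)); se <- as.integer(num(10))
    cc <- normalize_match_coords(qs, qe, ss, se)
    df <- data.frame(contig_id = m[, 1], ref_genome = genome_of(m[, 2]),
                     ref_record = m[, 2], sb = cc$sb, se = cc$se,
                     tb = cc$tb, te = cc$te,
                     qhits = pmax(1L, as.integer(round(pident / 100 * alen)) - as.integer(q) + 1L),
                     stringsAsFactors = FALSE)
    return(validate_match_table(df, path))
  }
  # nucmer show-coords -rclT: numeric rows are
  # S1 E1 S2 E2 LEN1 LEN2 %IDY LENR LENQ COVR COVQ REFID QRYID
  lines <- readLines(path)
  keep <- grepl("^\\s*[0-9]", lines)
  if (!any(keep)) return(empty_match_table())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 13L)) {
    stop("malformed nucmer-coords row at line ", which(keep)[which(nf < 13L)[1L]])
  }
  m <- do.call(rbind, lapply(parts, function(p) p[1:13]))
  numcol <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop("malformed nucmer-coords row at line ",
                       which(keep)[which(is.na(v))[1L]])
    v
  }
  s1 <- as.integer(numcol(1)); e1 <- as.integer(numcol(2))
  s2 <- as.integer(numcol(3)); e2 <- as.integer(numcol(4))
  idy <- numcol(7); len1 <- as.integer(numcol(5))
  cc <- normalize_match_coords(s2, e2, s1, e1)
  df <- data.frame(contig_id = m[, 13], ref_genome = genome_of(m[, 12]),
                   ref_record = m[, 12], sb = cc$sb, se = cc$se,
                   tb = cc$tb, te = cc$te,
                   qhits = pmax(1L, as.integer(round(idy / 100 * len1)) - as.integer(q) + 1L),
                   stringsAsFactors = FALSE)
  validate_match_table(df, path)
}

validate_match_table <- function(df, origin = "match table") {
  if (nrow(df) == 0L) return(df)
  bad <- df$tb >= df$te | df$sb < 1L | df$se < 1L | df$tb < 1L | df$qhits < 1L
  if (any(bad)) stop("invalid match coordinates in ", origin,
                     " (row ", which(bad)[1L], ")")
  rownames(df) <- NULL
  df
}

#' Write a match table in the native TSV dialect
#'
#' @param matches Match table as returned by [find_matches()] or
#'   [read_match_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matches <- function(matches, path) {
  stopifnot(all(match_table_columns %in% names(matches)))
  utils::write.table(matches[, match_table_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expert adjacency constraint file
#'
#' A constraint file is a TSV with columns `contig1`, `side1`, `contig2`,
#' `side2`, `action` where sides are `L`/`R` and action is `forbid` or
#' `force`.
#'
#' @param path Path to the constraint file.
#' @return A `data.frame` of constraints.
#' @export
read_constraints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig1", "side1", "contig2", "side2", "action")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("constraint file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(df$side1 %in% c("L", "R")) || !all(df$side2 %in% c("L", "R"))) {
    stop("constraint sides must be 'L' or 'R'")
  }
  if (!all(df$action %in% c("forbid", "force"))) {
    stop("constraint action must be 'forbid' or 'force'")
  }
  df[, need, drop = FALSE]
}

# Reverse complement of an ACGTN string.
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}
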