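#' Matching parameters
#'
#' Thresholds and filter settings for the q-gram seeded matcher. A reported
#' match must span at least `min_length` bases on the reference and have a
#' unit-cost edit error rate of at most `max_error` over the matched region.
#'
#' @param q q-gram size used for seeding (default 11).
#' @param min_length Minimum match length in bases on the reference
#'   (default 64).
#' @param max_error Maximum edit error rate over the matched region
#'   (default 0.08).
#' @param max_chain_gap Maximum reference gap, in bases, between successive
#'   seeds of one chain.
#' @param diag_band Maximum diagonal drift, in bases, between successive seeds
#'   of one chain (absorbs small indels).
#' @param full_ext_min_qhits Minimum seed count of a chain before the
#'   whole-contig extension is attempted; chains below it are still verified
#'   through the cheaper greedy per-end extension.
#' @return A list of class `match_params`.
#' @export
match_params <- function(q = 11L, min_length = 64L, max_error = 0.08,
                         max_chain_gap = 200L, diag_band = 20L,
                         full_ext_min_qhits = 8L) {
  q <- as.integer(q); min_length <- as.integer(min_length)
  stopifnot(q >= 4L, min_length >= q, max_error > 0, max_error < 1,
            max_chain_gap >= 1L, diag_band >= 0L, full_ext_min_qhits >= 1L)
  structure(list(q = q, min_length = min_length, max_error = max_error,
                 max_chain_gap = as.integer(max_chain_gap),
                 diag_band = as.integer(diag_band),
                 full_ext_min_qhits = as.integer(full_ext_min_qhits)),
            class = "match_params")
}

# Encode A/C/G/T as 0..3; anything else (N) as NA.
encode_dna <- function(seq) {
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
  map[utf8ToInt(seq)]
}

# Numeric codes of all q-grams (base-4); NA where the window contains N.
# Codes fit exactly in a double for q <= 26.
qgram_codes <- function(seq, q) {
  code <- encode_dna(seq)
  n <- length(code)
  m <- n - q + 1L
  if (m < 1L) return(numeric(0))
  acc <- numeric(m)
  for (k in 0:(q - 1L)) acc <- acc * 4 + code[(1L + k):(m + k)]
  acc
}

# q-gram index of a reference record: q-gram codes sorted ascending, with
# their start positions.
qgram_index <- function(seq, q) {
  codes <- qgram_codes(seq, q)
  pos <- which(!is.na(codes))
  cd <- codes[pos]
  o <- order(cd, method = "radix")
  list(codes = cd[o], pos = pos[o], q = q)
}

# Greedy colinear chaining of seed hits. Seeds are processed in reference
# order; a seed joins the chain with the nearest diagonal among those whose
# last seed is within max_chain_gap on the reference and within diag_band in
# diagonal. Returns a data.frame of chains (seed extents + counts).
chain_seeds <- function(spos, tpos, q, params) {
  o <- order(tpos, spos, method = "radix")
  m <- chain_seeds_cpp(as.integer(spos[o]), as.integer(tpos[o]),
                       as.integer(params$max_chain_gap),
                       as.integer(params$diag_band))
  if (nrow(m) == 0L) {
    return(data.frame(sb = integer(), se = integer(), tb = integer(),
                      te = integer(), qhits = integer()))
  }
  data.frame(sb = m[, 1L], se = m[, 2L] + q - 1L, tb = m[, 3L],
             te = m[, 4L] + q - 1L, qhits = m[, 5L])
}

# Banded edit distance with escalating band widths: a narrow band gives an
# upper bound on the distance, which suffices whenever it already passes the
# error-rate check; only rejections are re-checked with the full band.
edit_errors <- function(a, b, max_error, escalate = TRUE) {
  n <- max(nchar(a), nchar(b))
  diff <- abs(nchar(a) - nchar(b))
  full <- max(16L, as.integer(ceiling(max_error * n)) + diff + 8L)
  narrow <- max(32L, as.integer(ceiling(0.02 * n)) + diff + 8L)
  if (narrow < full) {
    d <- banded_edit_distance(a, b, narrow)
    if (d >= 0L && d <= max_error * n) return(d)
    if (!escalate) return(if (d < 0L) n else d)
  }
  d <- banded_edit_distance(a, b, full)
  if (d < 0L) d <- n  # no within-band alignment
  d
}

# Greedy same-diagonal extension of a verified core towards one side.
# Returns the number of bases the region can be grown while keeping the
# overall error rate within budget; the extension always ends on a match.
# The walk proceeds in chunks and is abandoned (X-drop style) once the
# mismatch count exceeds the budget by `drop` errors, so extensions into
# unrelated sequence stop quickly.
extend_budget <- function(ct, rf, s_edge, t_edge, dir, core_len, core_err,
                          max_error, chunk = 256L, drop = 25) {
  K <- if (dir < 0L) min(s_edge - 1L, t_edge - 1L) else
    min(length(ct) - s_edge, length(rf) - t_edge)
  if (K <= 0L) return(0L)
  best <- 0L
  cum <- 0
  off <- 0L
  while (off < K) {
    kk <- (off + 1L):min(off + chunk, K)
    if (dir < 0L) {
      a <- ct[s_edge - kk]; b <- rf[t_edge - kk]
    } else {
      a <- ct[s_edge + kk]; b <- rf[t_edge + kk]
    }
    mism <- (a != b) | a == "N" | b == "N"
    cumk <- cum + cumsum(mism)
    slack <- max_error * (core_len + kk) - core_err - cumk
    ok <- which(!mism & slack >= 0)
    if (length(ok) > 0L) best <- kk[max(ok)]
    if (min(slack) < -drop) break
    cum <- cumk[length(cumk)]
    off <- off + length(kk)
  }
  best
}

# Verify one candidate chain; returns a one-row data.frame (forward contig
# coordinates) or NULL.
verify_candidate <- function(contig, reference, ct, rf, cand, params) {
  L <- nchar(contig); N <- nchar(reference)
  sb <- cand$sb; se <- cand$se; tb <- cand$tb; te <- cand$te
  # 1. whole-contig extension: project the full contig through the seed core.
  # This speculative (and relatively expensive) attempt is only worthwhile
  # when the chain has solid seed support and already covers most of the
  # contig; a failed attempt falls through to the greedy path, so only the
  # cheap narrow verification band is used here.
  if (cand$qhits >= params$full_ext_min_qhits &&
      (max(sb, se) - min(sb, se) + 1L) >= 0.6 * L) {
    ftb <- tb - (sb - 1L); fte <- te + (L - se)
    fs <- 1L; fe <- L
    if (ftb < 1L) { fs <- fs + (1L - ftb); ftb <- 1L }
    if (fte > N) { fe <- fe - (fte - N); fte <- N }
    if (fte - ftb + 1L >= params$min_length && fe > fs) {
      err <- edit_errors(substr(contig, fs, fe), substr(reference, ftb, fte),
                         params$max_error, escalate = FALSE)
      if (err / (fte - ftb + 1L) <= params$max_error) {
        return(data.frame(sb = fs, se = fe, tb = ftb, te = fte,
                          qhits = cand$qhits))
      }
    }
  }
  # 2. greedy per-end extension of the seed core
  core_len <- te - tb + 1L
  core_err <- edit_errors(substr(contig, sb, se), substr(reference, tb, te),
                          params$max_error)
  kL <- extend_budget(ct, rf, sb, tb, -1L, core_len, core_err, params$max_error)
  core_len <- core_len + kL
  core_err <- core_err + sum((ct[(sb - kL):sb] != rf[(tb - kL):tb])[seq_len(kL)])
  kR <- extend_budget(ct, rf, se, te, 1L, core_len, core_err, params$max_error)
  sb2 <- sb - kL; tb2 <- tb - kL; se2 <- se + kR; te2 <- te + kR
  len <- te2 - tb2 + 1L
  if (len < params$min_length) return(NULL)
  err <- edit_errors(substr(contig, sb2, se2), substr(reference, tb2, te2),
                     params$max_error)
  if (err / len > params$max_error) return(NULL)
  data.frame(sb = sb2, se = se2, tb = tb2, te = te2, qhits = cand$qhits)
}

scan_strand <- function(contig, reference, index, params, ct, rf) {
  q <- params$q
  cg <- qgram_codes(contig, q)
  valid <- which(!is.na(cg))
  if (length(valid) == 0L) return(NULL)
  cv <- cg[valid]
  lo <- findInterval(cv - 0.5, index$codes) + 1L
  hi <- findInterval(cv + 0.5, index$codes)
  nh <- hi - lo + 1L
  hit <- which(nh > 0L)
  if (length(hit) == 0L) return(NULL)
  spos <- rep(valid[hit], nh[hit])
  tpos <- index$pos[sequence(nh[hit], from = lo[hit])]
  chains <- chain_seeds(spos, tpos, q, params)
  if (nrow(chains) == 0L) return(NULL)
  out <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) {
    out[[i]] <- verify_candidate(contig, reference, ct, rf, chains[i, ], params)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Drop candidates that substantially duplicate a better candidate (same
# region found through overlapping chains). Ties: larger qhits, then longer,
# then smaller tb.
dedupe_matches <- function(df) {
  if (nrow(df) <= 1L) return(df)
  len <- df$te - df$tb + 1L
  o <- order(-df$qhits, -len, df$tb)
  df <- df[o, , drop = FALSE]
  c_lo <- pmin(df$sb, df$se); c_hi <- pmax(df$sb, df$se)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ov_t <- min(df$te[i], df$te[j]) - max(df$tb[i], df$tb[j]) + 1L
      ov_c <- min(c_hi[i], c_hi[j]) - max(c_lo[i], c_lo[j]) + 1L
      small_t <- min(df$te[i] - df$tb[i], df$te[j] - df$tb[j]) + 1L
      small_c <- min(c_hi[i] - c_lo[i], c_hi[j] - c_lo[j]) + 1L
      if (ov_t > 0.5 * small_t && ov_c > 0.5 * small_c) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' Find matching regions between one contig and one reference record
#'
#' Seeds candidate regions with exact q-gram hits, chains colinear seeds,
#' extends each candidate (whole-contig extension first, then greedy per-end
#' extension), and verifies every candidate by banded unit-cost edit distance
#' against the `min_length` and `max_error` thresholds. Both strands are
#' searched; reverse-strand matches are reported with descending contig
#' coordinates (`sb > se`). Reference coordinates always ascend.
#'
#' @param contig Contig sequence (single character string).
#' @param reference Reference record sequence (single character string).
#' @param params A [match_params()] object.
#' @param contig_id,ref_record,ref_genome Identifiers recorded in the output.
#' @return A match table `data.frame` (possibly empty) with columns
#'   `contig_id`, `ref_genome`, `ref_record`, `sb`, `se`, `tb`, `te`, `qhits`.
#' @export
find_matches <- function(contig, reference, params = match_params(),
                         contig_id = "contig", ref_record = "ref",
                         ref_genome = ref_record, .index = NULL,
                         .rf = NULL) {
  stopifnot(length(contig) == 1L, length(reference) == 1L)
  L <- nchar(contig)
  if (L < params$min_length) return(empty_match_table())
  index <- if (is.null(.index)) qgram_index(reference, params$q) else .index
  rf <- if (is.null(.rf)) strsplit(reference, "", fixed = TRUE)[[1L]] else .rf
  ct_f <- strsplit(contig, "", fixed = TRUE)[[1L]]
  fwd <- scan_strand(contig, reference, index, params, ct_f, rf)
  rc <- revcomp(contig)
  ct_r <- strsplit(rc, "", fixed = TRUE)[[1L]]
  rev <- scan_strand(rc, reference, index, params, ct_r, rf)
  if (!is.null(rev) && nrow(rev) > 0L) {
    # map coordinates on the reverse complement back to the original contig;
    # encode the reverse orientation as sb > se
    sb_orig <- L - rev$sb + 1L
    se_orig <- L - rev$se + 1L
    rev$sb <- sb_orig
    rev$se <- se_orig
  }
  df <- rbind(fwd, rev)
  if (is.null(df) || nrow(df) == 0L) return(empty_match_table())
  df <- dedupe_matches(df)
  df <- df[order(df$tb, df$te, df$sb), , drop = FALSE]
  out <- data.frame(contig_id = contig_id, ref_genome = ref_genome,
                    ref_record = ref_record, sb = df$sb, se = df$se,
                    tb = df$tb, te = df$te, qhits = df$qhits,
                    stringsAsFactors = FALSE)
  validate_match_table(out, "find_matches")
}

match_cache_key <- function(contigs, records, params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(names(contigs), unname(contigs), names(records),
               unname(records),
               sprintf("%d %d %g %d %d", params$q, params$min_length,
                       params$max_error, params$max_chain_gap,
                       params$diag_band)), tf)
  unname(tools::md5sum(tf))
}

#' Match every contig against every reference genome
#'
#' Computes (or loads from cache) the matches of each contig against each
#' record of each reference genome. The cache stores one native-TSV match
#' table per reference genome, keyed by a digest of the sequences and the
#' matching parameters, so re-running later pipeline stages with different
#' scoring parameters does not trigger a re-match.
#'
#' @param contigs Named character vector of contig sequences.
#' @param references Named list (one element per reference genome) of named
#'   character vectors of record sequences.
#' @param params A [match_params()] object.
#' @param cache_dir Optional directory for the match cache.
#' @return A combined match table `data.frame`.
#' @export
match_all <- function(contigs, references, params = match_params(),
                      cache_dir = NULL) {
  stopifnot(is.character(contigs), !is.null(names(contigs)),
            is.list(references), !is.null(names(references)))
  all_rec <- unlist(lapply(references, names))
  if (anyDuplicated(c(names(contigs), all_rec))) {
    stop("contig and reference record ids must be unique across the run")
  }
  short <- names(contigs)[nchar(contigs) < params$min_length]
  if (length(short) > 0L) {
    warning("contig(s) shorter than min_length skipped: ",
            paste(short, collapse = ", "))
  }
  out <- list()
  for (g in sort(names(references))) {
    recs <- references[[g]]
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      key <- match_cache_key(contigs, recs, params)
      cache_file <- file.path(cache_dir, sprintf("matches_%s_%s.tsv", g, key))
      if (file.exists(cache_file)) {
        hit <- tryCatch(read_match_table(cache_file, "native-tsv"),
                        error = function(e) NULL)
        if (!is.null(hit)) {
          out[[g]] <- hit
          next
        }
        warning("corrupt match cache for genome ", g, "; recomputing")
      }
    }
    rows <- list()
    for (rid in names(recs)) {
      idx <- qgram_index(recs[[rid]], params$q)
      rfc <- strsplit(recs[[rid]], "", fixed = TRUE)[[1L]]
      for (cid in names(contigs)) {
        rows[[paste(cid, rid)]] <-
          find_matches(contigs[[cid]], recs[[rid]], params,
                       contig_id = cid, ref_record = rid, ref_genome = g,
                       .index = idx, .rf = rfc)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (!is.null(cache_file)) write_matches(tab, cache_file)
    out[[g]] <- tab
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_match_table()
  rownames(res) <- NULL
  res
}
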