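test_that("an exact substring yields one full-length match with L-q+1 seeds", {
  set.seed(42)
  ref <- random_dna(1000)
  ctg <- substr(ref, 201, 300)
  m <- find_matches(ctg, ref, contig_id = "c1", ref_record = "chr")
  expect_equal(nrow(m), 1L)
  expect_equal(m$sb, 1L)
  expect_equal(m$se, 100L)
  expect_equal(m$tb, 201L)
  expect_equal(m$te, 300L)
  expect_equal(m$qhits, 100L - 11L + 1L)
})

test_that("reverse-complement input gives the same region with sb > se", {
  set.seed(43)
  ref <- random_dna(1000)
  ctg <- rc_oracle(substr(ref, 201, 300))
  m <- find_matches(ctg, ref)
  expect_equal(nrow(m), 1L)
  expect_gt(m$sb, m$se)
  expect_equal(m$sb, 100L)
  expect_equal(m$se, 1L)
  expect_equal(m$tb, 201L)
  expect_equal(m$te, 300L)
})

test_that("64 bp at 5 mismatches (7.8%) is kept, 6 mismatches (9.4%) is dropped", {
  set.seed(44)
  ref <- random_dna(2000)
  planted <- substr(ref, 501, 564)
  keep <- plant_mismatches(planted, c(2, 4, 6, 8, 10))
  drop <- plant_mismatches(planted, c(2, 4, 6, 8, 10, 12))
  mk <- find_matches(keep, ref)
  expect_gte(nrow(mk), 1L)
  expect_gte(max(mk$te - mk$tb + 1L), 64L)
  # independent re-verification of the kept match with utils::adist
  best <- mk[which.max(mk$te - mk$tb), ]
  err <- utils::adist(substr(keep, min(best$sb, best$se), max(best$sb, best$se)),
                      substr(ref, best$tb, best$te))[1, 1]
  expect_lte(err / (best$te - best$tb + 1L), 0.08)
  md <- find_matches(drop, ref)
  expect_equal(nrow(md), 0L)
})

test_that("random contigs never match a random reference", {
  for (s in 1:20) {
    set.seed(1000 + s)
    ref <- random_dna(100000)
    ctg <- random_dna(1000)
    expect_equal(nrow(find_matches(ctg, ref)), 0L)
  }
})

test_that("planted homologs at 5% substitutions are recovered nearly fully", {
  for (s in 1:20) {
    set.seed(2000 + s)
    ref <- random_dna(20000)
    start <- sample(1000:15000, 1L)
    ctg_len <- 2000L
    positions <- sample(ctg_len, round(0.05 * ctg_len))
    ctg <- mutate_substitutions(substr(ref, start, start + ctg_len - 1L),
                                positions)
    if (s %% 2L == 0L) ctg <- rc_oracle(ctg)
    m <- find_matches(ctg, ref)
    expect_gte(nrow(m), 1L)
    cov <- max(abs(m$se - m$sb) + 1L)
    expect_gte(cov, 0.9 * ctg_len)
    # every reported match independently satisfies both thresholds
    for (k in seq_len(nrow(m))) {
      sub_c <- substr(ctg, min(m$sb[k], m$se[k]), max(m$sb[k], m$se[k]))
      if (m$sb[k] > m$se[k]) sub_c <- rc_oracle(sub_c)
      err <- utils::adist(sub_c, substr(ref, m$tb[k], m$te[k]))[1, 1]
      len <- m$te[k] - m$tb[k] + 1L
      expect_gte(len, 64L)
      expect_lte(err / len, 0.08)
    }
  }
})

test_that("matching is strand-symmetric", {
  set.seed(77)
  ref <- random_dna(5000)
  ctg <- paste0(substr(ref, 1001, 1500),
                random_dna(100),
                rc_oracle(substr(ref, 3001, 3400)))
  m1 <- find_matches(ctg, ref)
  m2 <- find_matches(rc_oracle(ctg), ref)
  L <- nchar(ctg)
  # mapping contig coordinates through the reverse complement flips strands
  remap <- m2
  remap$sb <- L - m2$sb + 1L
  remap$se <- L - m2$se + 1L
  key <- function(m) {
    sort(paste(pmin(m$sb, m$se), pmax(m$sb, m$se), m$tb, m$te,
               sign(m$se - m$sb)))
  }
  expect_equal(key(remap), key(m1))
})

test_that("match_all covers every contig-genome pair and caches bytewise", {
  set.seed(55)
  g1 <- stats::setNames(random_dna(3000), "g1_chr")
  g2 <- stats::setNames(random_dna(3000), "g2_chr")
  contigs <- c(c1 = substr(g1[[1]], 101, 800), c2 = rc_oracle(substr(g2[[1]], 1001, 1900)))
  refs <- list(g1 = g1, g2 = g2)
  cache <- withr::local_tempdir()
  m1 <- match_all(contigs, refs, cache_dir = cache)
  expect_true(all(c("g1", "g2") %in% m1$ref_genome))
  expect_setequal(unique(m1$contig_id), c("c1", "c2"))
  m2 <- match_all(contigs, refs, cache_dir = cache)
  expect_identical(m1, m2)
  # corrupt cache triggers recomputation with a warning
  cf <- list.files(cache, full.names = TRUE)[1]
  writeLines("garbage", cf)
  expect_warning(m3 <- match_all(contigs, refs, cache_dir = cache), "corrupt")
  expect_equal(m3, m1)
})

test_that("contigs shorter than min_length are skipped with a warning", {
  set.seed(56)
  ref <- stats::setNames(random_dna(1000), "chr")
  contigs <- c(tiny = "ACGTACGT", ok = substr(ref[[1]], 11, 210))
  expect_warning(m <- match_all(contigs, list(g = ref)), "tiny")
  expect_false("tiny" %in% m$contig_id)
  expect_true("ok" %in% m$contig_id)
})
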