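test_that("per-base scores follow the capped run-length rule", {
  expect_identical(g4_base_scores("GGGG"), c(4L, 4L, 4L, 4L))
  expect_identical(g4_base_scores("GGGGG"), rep(4L, 5))
  expect_identical(g4_base_scores("AGGTCC"), c(0L, 2L, 2L, 0L, -2L, -2L))
  # telomeric 25-mer: four GGG runs plus a single G, sum 37 over 25 bases
  telo <- "GGGTTAGGGTTAGGGTTAGGGTTAG"
  expect_equal(mean(g4_base_scores(telo)), 37 / 25)
  # N scores zero and breaks runs
  expect_identical(g4_base_scores("GGNGG"), c(2L, 2L, 0L, 2L, 2L))
  # case-insensitive by default; lowercase treated as N when masking
  expect_identical(g4_base_scores("gGcC"), c(2L, 2L, -2L, -2L))
  expect_identical(g4_base_scores("ggGG", mask_lowercase = TRUE),
                   c(0L, 0L, 2L, 2L))
  # a custom run cap changes saturation
  expect_identical(g4_base_scores("GGGGG", run_cap = 2L), rep(2L, 5))
  expect_error(g4_base_scores("ACGXG"), "position 4")
  expect_error(g4_base_scores("ACG", run_cap = 0), "run_cap")
})

test_that("window means are arithmetic means with the stated length", {
  expect_equal(g4_window_means(rep(0L, 25), 25), 0)
  expect_equal(g4_window_means(rep(4L, 25), 25), 4)
  telo <- "GGGTTAGGGTTAGGGTTAGGGTTAG"
  expect_equal(g4_window_means(g4_base_scores(telo), 25), 1.48)
  expect_message(out <- g4_window_means(rep(1L, 10), 25), "shorter than window")
  expect_length(out, 0)
  set.seed(11)
  sc <- oracle_base_scores(random_dna(300))
  expect_equal(g4_window_means(sc, 25), oracle_window_means(sc, 25))
  expect_length(g4_window_means(sc, 25), 300 - 25 + 1)
})

test_that("detection selects, merges, refines and signs hits", {
  expect_length(g4_detect(strrep("A", 100)), 0)
  h <- g4_detect(strrep("G", 25))
  expect_equal(GenomicRanges::start(h), 1)
  expect_equal(GenomicRanges::end(h), 25)
  expect_equal(as.character(GenomicRanges::strand(h)), "+")
  expect_equal(h$score, 4)
  # C-rich tract reports the minus strand with a negated score
  hc <- g4_detect(strrep("C", 25))
  expect_equal(as.character(GenomicRanges::strand(hc)), "-")
  expect_equal(hc$score, -4)
  # two overlapping above-threshold window sets merge into one hit
  s <- paste0(strrep("A", 30), strrep("G", 20), "TT", strrep("G", 20),
              strrep("A", 30))
  hm <- g4_detect(s)
  expect_length(hm, 1)
  expect_equal(GenomicRanges::start(hm), 31)
  expect_equal(GenomicRanges::end(hm), 72)
  # raising the threshold never increases the hit count
  set.seed(21)
  for (i in 1:10) {
    sq <- random_dna(1500, probs = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15))
    n_lo <- length(g4_detect(sq, threshold = 1.2))
    n_hi <- length(g4_detect(sq, threshold = 1.5))
    expect_lte(n_hi, n_lo)
  }
})

test_that("cleaning flags control N-dropping and deduplication", {
  # an N inside a zero-scoring loop leaves scores unchanged but marks the hit
  s <- paste0(strrep("A", 10), "GGGTTAGGGTTANGGGTTAGGGTTAGGG", strrep("A", 10))
  kept <- g4_detect(s, drop_n = FALSE)
  expect_length(kept, 1)
  expect_match(kept$sequence, "N")
  expect_length(g4_detect(s, drop_n = TRUE), 0)
})

test_that("genome scan summarises sequences and validates input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1 first", strrep("G", 25), ">s2", strrep("AT", 500)), fa)
  sc <- g4_scan(fa)
  expect_equal(sc$summary$seq_id, c("s1", "s2"))
  expect_equal(sc$summary$n_hits, c(1L, 0L))
  expect_equal(sc$summary$density_per_kbp, c(1 / (25 / 1000), 0))
  expect_equal(sc$summary$gc_percent, c(100, 0))
  expect_length(sc$hits, 1)

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(g4_scan(dup), "duplicate")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(g4_scan(empty), "empty|no sequences")
})

test_that("hit and summary exports round-trip through BED and TSV", {
  h <- g4_detect("GGGTTAGGGTTAGGGTTAGGGTTAG", seq_id = "chrT")
  bed <- tempfile(fileext = ".bed")
  export_hits_bed(h, bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 0)           # 0-based start
  expect_equal(b$V3, 25)          # half-open end
  expect_equal(b$V5, 148)         # |score| * 100 rounded
  expect_equal(b$V6, "+")
  tsv <- tempfile(fileext = ".tsv")
  export_hits_tsv(h, tsv)
  d <- read.delim(tsv)
  expect_equal(d$score, 1.48)
  expect_equal(d$length, 25)
})
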