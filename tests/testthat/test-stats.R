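test_that("density arithmetic matches published chromosome profiles", {
  expect_equal(round(g4_density(26041, 27822162), 2), 0.94)
  expect_equal(round(g4_density(1092, 774663), 2), 1.41)
  expect_equal(g4_density(0, 5000), 0)
  expect_warning(d <- g4_density(3, 0), "zero span")
  expect_true(is.na(d))
})

test_that("strand fold difference uses the max/min convention", {
  r <- strand_fold(0.2, 0.6)
  expect_equal(r$g4sdf, 3)
  expect_equal(r$dominant, "template")
  r <- strand_fold(0.5, 0.5)
  expect_equal(r$g4sdf, 1)
  expect_equal(r$dominant, "tie")
  r <- strand_fold(0.9, 0.3)
  expect_equal(r$g4sdf, 3)
  expect_equal(r$dominant, "coding")
  # one-sided and degenerate records are flagged
  r <- strand_fold(0.4, 0)
  expect_true(is.infinite(r$g4sdf) && r$flagged && r$dominant == "coding")
  r <- strand_fold(0, 0)
  expect_true(is.na(r$g4sdf) && r$flagged)
  # symmetry: swapping arguments flips the dominant strand only
  a <- strand_fold(0.2, 0.7); b <- strand_fold(0.7, 0.2)
  expect_equal(a$g4sdf, b$g4sdf)
  expect_true(a$dominant != b$dominant)
})

test_that("exact binomial strand test matches closed forms", {
  expect_equal(strand_bias_test(10, 10), 1)
  expect_equal(strand_bias_test(8, 0), 2 * 0.5^8)
  # brute-force two-sided tail for (60, 20)
  p_direct <- sum(dbinom(0:80, 80, 0.5)[dbinom(0:80, 80, 0.5) <=
                                          dbinom(60, 80, 0.5) * (1 + 1e-7)])
  expect_equal(strand_bias_test(60, 20), p_direct, tolerance = 1e-9)
  expect_lt(strand_bias_test(60, 20), 1e-5)
  expect_warning(p <- strand_bias_test(0, 0), "undefined")
  expect_true(is.na(p))
})

test_that("gene classification bins, cutoffs and proportions are exact", {
  counts <- c(g1 = 0L, g2 = 11L, g3 = 3L)
  cl <- classify_genes(counts, cutoff = 10)
  expect_equal(cl$above_cutoff, "g2")
  expect_equal(cl$prop_above, 1 / 3)
  expect_equal(cl$n_with_any, 2L)
  expect_equal(sum(cl$bins$proportion), 1)
  zero <- classify_genes(c(a = 0L, b = 0L), cutoff = 5)
  expect_length(zero$above_cutoff, 0)
  expect_equal(zero$prop_above, 0)
  # cutoff is strict: a gene at exactly the cutoff is not selected
  edge <- classify_genes(c(x = 10L), cutoff = 10)
  expect_length(edge$above_cutoff, 0)
  expect_error(classify_genes(integer(0)), "empty")
})

test_that("region densities split by context and respect denominators", {
  ann <- load_annotation(write_tiny_gff())
  reg <- derive_regions(ann)
  # all hits on each gene's own strand: template context empty everywhere
  hits <- make_hits(c("chr1", "chr1", "chr2"), c(1050, 1600, 1500),
                    strands = c("+", "+", "-"))
  dens <- region_densities(hits, reg, classes = c("gene", "exon"))
  tpl <- dens[dens$context == "template", ]
  expect_true(all(tpl$hit_count == 0))
  dbl <- dens[dens$context == "double" & dens$region_class == "gene", ]
  expect_equal(dbl$hit_count, 3L)
  # union denominator: the two 1 kb genes overlap nothing, span 2 kb + g3
  expect_equal(dbl$span_bp, 2000L + 100L)
  # per-gene denominator sums each gene's own span
  pg <- region_densities(hits, reg, classes = "gene", denominator = "per_gene")
  expect_equal(unique(pg$span_bp), 2000L + 100L)
  expect_identical(dens$hit_count[dens$context == "double"],
                   dens$hit_count[dens$context == "coding"] +
                     dens$hit_count[dens$context == "template"])
})

test_that("gene-set counting totals member genes and flags unknown IDs", {
  fx <- shared_fixture()
  tg <- fx$sim$truth$per_gene
  body <- tg[tg$region_class == "gene", ]
  picked <- body$gene_id[order(-body$double)][1:4]
  gs <- data.frame(gene_id = c(picked, "NOT_A_GENE"),
                   category = c("hi", "hi", "lo", "lo", "lo"))
  expect_warning(res <- geneset_counts(gs, fx$scan$hits, fx$regions),
                 "NOT_A_GENE")
  expect_equal(res$unknown, "NOT_A_GENE")
  # per-category totals equal the sum of planted member-gene counts
  expected_hi <- sum(body$double[body$gene_id %in% picked[1:2]])
  expect_equal(res$per_category$gene[res$per_category$category == "hi"],
               expected_hi)
  # per-gene counts recover the planted truth exactly
  m <- merge(res$per_gene, body, by = "gene_id")
  expect_equal(m$gene, m$double)
  # an empty category contributes zero rows, a zero-count gene counts zero
  zero_gene <- body$gene_id[body$double == 0][1]
  res0 <- geneset_counts(data.frame(gene_id = zero_gene, category = "none"),
                         fx$scan$hits, fx$regions)
  expect_equal(res0$per_category$gene, 0L)
})

test_that("chromosome correlations recover planted association strength", {
  # perfectly proportional tracks
  cs <- data.frame(g4_density = 1:10 / 10, gc_percent = 30 + 1:10)
  out <- chromosome_correlations(cs, features = "gc_percent")
  expect_equal(out$r, 1)
  expect_lt(out$p_value, 1e-6)
  # constant feature: undefined correlation, flagged
  cs$gene_density <- 5
  out <- chromosome_correlations(cs, features = "gene_density")
  expect_true(out$flagged && is.na(out$r))
  expect_error(chromosome_correlations(cs[1:2, ]), "at least 3")
  # simulated 19-chromosome summary at target r = 0.8: each estimate falls
  # inside the analytic Fisher-z 95% interval around the target
  cs <- synth_chrom_summary(n_chrom = 19, target_r = 0.8, seed = 5)
  out <- chromosome_correlations(cs)
  expect_equal(nrow(out), 4L)
  halfwidth <- 1.96 / sqrt(19 - 3)
  expect_true(all(abs(atanh(out$r) - atanh(0.8)) <= halfwidth))
})

test_that("windowed tracks conserve counts and smooth with window size", {
  # no hits: all-zero track
  empty <- make_hits("chr1", integer(0))
  tr <- windowed_track(empty, window_bp = 1000)
  expect_true(all(tr$count == 0))
  # one hit lands in exactly one tiling window
  one <- make_hits("chr1", 2500)
  tr <- windowed_track(one, window_bp = 1000)
  expect_equal(sum(tr$count > 0), 1L)
  expect_equal(tr$count[tr$start == 2001], 1L)
  # tiling windows conserve the total; variance shrinks as windows grow
  set.seed(31)
  hits <- make_hits("chr1", sort(sample(9900, 200)), width = 10)
  fine <- windowed_track(hits, window_bp = 100)
  coarse <- windowed_track(hits, window_bp = 1000)
  expect_equal(sum(fine$count), 200L)
  expect_equal(sum(coarse$count), 200L)
  expect_lt(var(coarse$density_per_kbp), var(fine$density_per_kbp))
  # bedGraph export is 0-based half-open
  bg <- tempfile(fileext = ".bedgraph")
  export_bedgraph(coarse, bg)
  b <- read.delim(bg, header = FALSE)
  expect_equal(b$V2[1], 0)
  expect_equal(b$V3[1], 1000)
})

test_that("interval subsets (centromere-style) are intersected correctly", {
  hits <- make_hits("chr1", c(100, 200, 5000))
  cen <- data.frame(seq_id = "chr1", start = 1, end = 1000)
  out <- interval_densities(hits, cen)
  expect_equal(out$hit_count, 2L)
  expect_equal(out$density_per_kbp, 2)
})
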