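test_that("generation is byte-identical under a fixed seed", {
  spec <- synth_spec(n_chrom = 1L, genes_per_chrom = 8L,
                     n_up = 2L, n_down = 2L,
                     n_promoter_rich = 1L, n_tss_rich = 1L)
  d1 <- tempfile("synthA"); d2 <- tempfile("synthB")
  s1 <- synth_generate(spec, seed = 9L, dir = d1)
  s2 <- synth_generate(spec, seed = 9L, dir = d2)
  for (f in c("fasta", "gff", "deg")) {
    expect_identical(unname(tools::md5sum(s1$paths[[f]])),
                     unname(tools::md5sum(s2$paths[[f]])))
  }
  # a different seed changes the sequence
  s3 <- synth_generate(spec, seed = 10L)
  expect_false(identical(as.character(s1$sequences), as.character(s3$sequences)))
})

test_that("a background with no planted motifs yields zero hits", {
  spec <- synth_spec(n_chrom = 1L, genes_per_chrom = 6L,
                     plant_density = list(promoter2000 = c(coding = 0, template = 0)),
                     n_promoter_rich = 0L, n_tss_rich = 0L,
                     n_up = 0L, n_down = 0L)
  sim <- synth_generate(spec, seed = 3L)
  expect_equal(nrow(sim$truth$hits), 0L)
  sc <- g4_scan(sim$sequences)
  expect_length(sc$hits, 0)
})

test_that("planted motifs are recovered one-for-one with exact coordinates", {
  fx <- shared_fixture()
  th <- fx$sim$truth$hits
  h <- fx$scan$hits
  got <- paste(as.character(GenomicRanges::seqnames(h)),
               GenomicRanges::start(h), GenomicRanges::end(h),
               as.character(GenomicRanges::strand(h)))
  want <- paste(th$chrom, th$start, th$end, th$strand)
  expect_setequal(got, want)
  expect_equal(length(h), nrow(th))
  # every planted motif scores the telomeric mean, signed by strand
  expect_true(all(abs(abs(h$score) - 1.48) < 1e-12))
})

test_that("a promoter planting of known count recovers its density exactly", {
  # 10 motifs across five 2 kb promoters = 1.0 per kbp
  spec <- synth_spec(n_chrom = 1L, genes_per_chrom = 5L,
                     plant_density = list(promoter2000 = c(coding = 0.6,
                                                           template = 0.4)),
                     n_promoter_rich = 0L, n_tss_rich = 0L,
                     n_up = 0L, n_down = 0L)
  sim <- synth_generate(spec, seed = 12L, dir = tempfile("prom"))
  sc <- g4_scan(sim$paths$fasta)
  ann <- load_annotation(sim$paths$gff)
  reg <- derive_regions(ann)
  dens <- region_densities(sc$hits, reg, classes = "promoter2000")
  expect_equal(dens$hit_count[dens$context == "double"], 10L)
  expect_equal(dens$density_per_kbp[dens$context == "double"], 1.0)
})

test_that("infeasible planting densities fail naming the limiting region", {
  spec <- synth_spec(n_chrom = 1L, genes_per_chrom = 4L,
                     plant_density = list(TSS500 = c(coding = 50, template = 50)),
                     n_promoter_rich = 0L, n_tss_rich = 0L,
                     n_up = 0L, n_down = 0L)
  expect_error(synth_generate(spec, seed = 1L), "TSS500")
  expect_error(synth_spec(plant_density = list(bogus = c(coding = 1,
                                                         template = 1))),
               "unsupported planting class")
})

test_that("central-G perturbation lowers scores without breaking detection", {
  fx <- shared_fixture()
  sim <- fx$sim
  # fraction 0 is the identity
  p0 <- synth_perturb(sim, 0)
  expect_identical(as.character(p0$sequences), as.character(sim$sequences))
  # fraction 1: every motif's central run is broken; the refined score drops
  # from 37/25 to the value the scoring oracle gives the mutated motif
  p1 <- synth_perturb(sim, 1, seed = 8L)
  mut <- strsplit(sim$spec$motif, "")[[1]]
  mut[13] <- "T"
  expected <- mean(oracle_base_scores(paste(mut, collapse = "")))
  sc1 <- g4_scan(p1$sequences)
  expect_true(all(abs(abs(sc1$hits$score) - expected) < 1e-12))
  expect_lt(expected, 37 / 25)
  # hit count is non-increasing in the mutated fraction
  n_half <- length(g4_scan(synth_perturb(sim, 0.5, seed = 8L)$sequences)$hits)
  expect_lte(length(sc1$hits), n_half)
  expect_lte(n_half, length(fx$scan$hits))
})

test_that("the emitted DEG table satisfies the direction thresholds exactly", {
  fx <- shared_fixture()
  d <- filter_degs(fx$sim$deg)
  m <- merge(d[, c("gene_id", "direction")], fx$sim$truth$deg, by = "gene_id")
  expect_equal(m$direction.x, m$direction.y)
})
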