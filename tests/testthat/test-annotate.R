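test_that("GFF3 loading builds the gene store with intron inference", {
  ann <- load_annotation(write_tiny_gff())
  g1 <- ann$genes[ann$genes$gene_id == "g1"]
  expect_equal(GenomicRanges::start(g1), 1001)
  expect_equal(GenomicRanges::end(g1), 2000)
  expect_equal(as.character(GenomicRanges::strand(g1)), "+")
  # intron = gap between the two exons
  intr <- ann$introns[["g1"]]
  expect_equal(GenomicRanges::start(intr), 1201)
  expect_equal(GenomicRanges::end(intr), 1500)
  # single-exon gene has no introns
  expect_true(!"g2" %in% names(ann$introns) || length(ann$introns[["g2"]]) == 0)
})

test_that("genes without strand are rejected with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t100\t200\t.\t+\t.\tID=ok",
               "chr1\tt\tgene\t300\t400\t.\t.\t.\tID=nostrand"), gff)
  expect_warning(ann <- load_annotation(gff), "without strand")
  expect_equal(ann$genes$gene_id, "ok")
  expect_error(load_annotation("/no/such/file.gff3"), "cannot read")
})

test_that("promoters and TSS windows are strand-aware and clipped", {
  ann <- load_annotation(write_tiny_gff())
  reg <- derive_regions(ann)
  pick <- function(gid, cls) {
    reg[reg$gene_id == gid & reg$region_class == cls]
  }
  # + gene at 1001..2000: promoter2000 nominally reaches -999, clipped to 1..1000
  p2k <- pick("g1", "promoter2000")
  expect_equal(GenomicRanges::start(p2k), 1)
  expect_equal(GenomicRanges::end(p2k), 1000)
  # - gene at 1001..2000: promoter500 lies downstream-in-genome, 2001..2500
  p5 <- pick("g2", "promoter500")
  expect_equal(GenomicRanges::start(p5), 2001)
  expect_equal(GenomicRanges::end(p5), 2500)
  # TSS window: 250 bp each side of the + TSS at 1001 -> 751..1250
  tss <- pick("g1", "TSS500")
  expect_equal(GenomicRanges::start(tss), 751)
  expect_equal(GenomicRanges::end(tss), 1250)
  expect_equal(GenomicRanges::width(tss), 500)
  # mirrored for the - gene: TSS at 2000 -> 1751..2250
  tss2 <- pick("g2", "TSS500")
  expect_equal(GenomicRanges::start(tss2), 1751)
  expect_equal(GenomicRanges::end(tss2), 2250)
  # promoters of the gene at the contig start are clipped away and logged
  expect_length(pick("g3", "promoter2000"), 0)
  expect_true(any(grepl("^g3:promoter", attr(reg, "clipped"))))
  # every region lies within its contig
  expect_true(all(GenomicRanges::start(reg) >= 1))
  expect_true(all(GenomicRanges::end(reg) <= 10000))
})

test_that("promoter windows nest and their per-gene counts are monotone", {
  fx <- shared_fixture()
  reg <- fx$regions
  proms <- paste0("promoter", c(500, 1000, 1500, 2000))
  ids <- fx$ann$genes$gene_id
  counts <- sapply(proms, function(cls) {
    count_hits_by_gene(fx$scan$hits, reg, cls, gene_ids = ids)$double
  })
  # containment: for every gene, each promoter lies inside the next longer one
  for (k in 1:3) {
    a <- reg[reg$region_class == proms[k]]
    b <- reg[reg$region_class == proms[k + 1]]
    m <- match(a$gene_id, b$gene_id)
    keep <- !is.na(m)
    expect_true(all(GenomicRanges::start(a)[keep] >= GenomicRanges::start(b)[m[keep]]))
    expect_true(all(GenomicRanges::end(a)[keep] <= GenomicRanges::end(b)[m[keep]]))
    expect_true(all(counts[, k] <= counts[, k + 1]))
  }
})

test_that("strand context resolves coding vs template", {
  expect_equal(strand_context("+", "+"), "coding")
  expect_equal(strand_context("-", "+"), "template")
  expect_equal(strand_context("-", "-"), "coding")
  expect_equal(strand_context("+", "-"), "template")
  expect_equal(strand_context(c("+", "-"), "+"), c("coding", "template"))
  expect_error(strand_context("*", "+"), "strands")
})

test_that("per-gene context counts partition and swap under strand flips", {
  fx <- shared_fixture()
  ids <- fx$ann$genes$gene_id
  for (cls in c("gene", "CDS", "TSS500", "promoter2000")) {
    cnt <- count_hits_by_gene(fx$scan$hits, fx$regions, cls, gene_ids = ids)
    expect_identical(cnt$double, cnt$coding + cnt$template)
  }
  # flipping every gene's strand annotation swaps coding and template exactly
  flipped <- fx$regions
  flipped$gene_strand <- ifelse(flipped$gene_strand == "+", "-", "+")
  a <- count_hits_by_gene(fx$scan$hits, fx$regions, "CDS", gene_ids = ids)
  b <- count_hits_by_gene(fx$scan$hits, flipped, "CDS", gene_ids = ids)
  expect_identical(a$coding, b$template)
  expect_identical(a$template, b$coding)
})
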