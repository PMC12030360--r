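# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# The default synthetic genome with its scan, annotation and regions;
# expensive enough (a few seconds) to cache across test files.
shared_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "g4scape-shared-sim")
    sim <- synth_generate(synth_spec(), seed = 101L, dir = dir)
    scan <- g4_scan(sim$paths$fasta)
    ann <- load_annotation(sim$paths$gff)
    regions <- derive_regions(ann)
    .fixture_env$sim <- sim
    .fixture_env$scan <- scan
    .fixture_env$ann <- ann
    .fixture_env$regions <- regions
  }
  list(sim = .fixture_env$sim, scan = .fixture_env$scan,
       ann = .fixture_env$ann, regions = .fixture_env$regions)
}

# Small hand-written GFF3 with known structure:
#  g1 (+, chr1 1001..2000): two exons 1001..1200 / 1501..2000 -> one intron
#  g2 (-, chr2 1001..2000): single exon -> no introns
#  g3 (+, chr1 1..100): promoters fully clipped at the contig start
write_tiny_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "##sequence-region chr2 1 10000",
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t1001\t1200\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\texon\t1501\t2000\t.\t+\t.\tParent=g1.t1",
    "chr2\ttest\tgene\t1001\t2000\t.\t-\t.\tID=g2",
    "chr2\ttest\tmRNA\t1001\t2000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\ttest\texon\t1001\t2000\t.\t-\t.\tParent=g2.t1",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g3",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=g3.t1"
  ), path)
  path
}

# Hand-built hits GRanges for counting tests.
make_hits <- function(seq_id, starts, width = 25L, strands = "+",
                      seqlen = 10000L) {
  n <- length(starts)
  seq_id <- rep_len(seq_id, max(n, 1L))
  strands <- rep_len(strands, n)
  chroms <- unique(seq_id)
  GenomicRanges::GRanges(
    seqnames = seq_id[seq_len(n)],
    ranges = IRanges::IRanges(starts, width = width),
    strand = strands,
    score = ifelse(strands == "+", 1.5, -1.5),
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms,
                                    seqlengths = rep_len(seqlen,
                                                         length(chroms)))
  )
}
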