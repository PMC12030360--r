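#!/usr/bin/env Rscript

# Thin command-line wrapper over the g4scape package.
#
#   g4scape scan  --fasta F [--window 25] [--threshold 1.2] --out DIR
#   g4scape synth [--seed 1] --out DIR
#   g4scape run   --fasta F --gff G [--deg TSV] [--seed 1] --out DIR
#
# 'run' applies the default parameterization throughout: window 25,
# threshold 1.2, promoters 2000/1500/1000/500, TSS half-width 250,
# |log2FC| >= 1, padj <= 0.05, strand-fold cutoff 3, burden cutoffs 10/5.

suppressMessages(library(g4scape))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: g4scape <scan|synth|run> [options]")
cmd <- argv[1L]
opts <- list(window = 25, threshold = 1.2, seed = 1)
i <- 2L
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  opts[[key]] <- argv[i + 1L]
  i <- i + 2L
}
if (is.null(opts$out)) stop("--out DIR is required")

if (cmd == "scan") {
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  res <- g4_scan(opts$fasta, window = as.integer(opts$window),
                 threshold = as.numeric(opts$threshold))
  export_hits_bed(res$hits, file.path(opts$out, "hits.bed"))
  export_hits_tsv(res$hits, file.path(opts$out, "hits.tsv"))
  export_scan_summary_tsv(res, file.path(opts$out, "sequence_summary.tsv"))
  print(res)
} else if (cmd == "synth") {
  sim <- synth_generate(synth_spec(), seed = as.integer(opts$seed),
                        dir = opts$out)
  print(sim)
} else if (cmd == "run") {
  res <- run_pipeline(opts$fasta, opts$gff, opts$out,
                      deg_table = opts$deg,
                      window = as.integer(opts$window),
                      threshold = as.numeric(opts$threshold))
  cat(sprintf("pipeline complete: %d hits, outputs in %s\n",
              res$manifest$summary$n_hits, opts$out))
} else {
  stop("unknown command: ", cmd)
}
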