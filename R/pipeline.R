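#' Run the full G4 analysis pipeline on a genome
#'
#' @description Orchestrates scan -> annotate -> stats -> DEG overlay as one
#' reproducible run: detects hits on the genome FASTA, derives strand-aware
#' regions from the GFF3, writes densities, strand-bias tables, gene
#' classifications, windowed tracks and (when a DEG table is given)
#' per-direction densities and strand-fold selections, together with a JSON
#' manifest recording the parameters and the MD5 checksum of every output.
#' Re-running with an identical configuration reproduces identical outputs;
#' any stage failure aborts with the stage name and the offending input.
#'
#' @param fasta Genome FASTA path.
#' @param gff GFF3 annotation path.
#' @param out_dir Output directory (created; stage subfolders inside).
#' @param deg_table Optional DEG results TSV (columns `gene_id`,
#'   `log2FoldChange`, `padj`) or data.frame.
#' @param genesets Optional gene-set table (`gene_id`, `category`) or TSV
#'   path for per-category counting.
#' @param centromeres Optional centromere coordinate TSV (`seq_id`,
#'   `start`, `end`, 1-based inclusive) or data.frame.
#' @param tandem_repeats,transposable_elements Optional repeat annotations
#'   (GFF3/BED paths or `GRanges`) for chromosome-level correlations.
#' @param window,threshold,run_cap Scan parameters (defaults 25 / 1.2 / 4).
#' @param promoter_lengths,tss_halfwidth Region parameters (defaults
#'   2000/1500/1000/500 and 250).
#' @param lfc_cut,padj_cut DEG thresholds (defaults 1 and 0.05).
#' @param fold_cutoff Strand-fold selection cutoff (default 3).
#' @param promoter_cutoff,tss_cutoff Gene-classification burden cutoffs
#'   (defaults 10 and 5).
#' @param track_window Window for the bedGraph density track (default
#'   100 kbp).
#' @param drop_n,dedupe Hit-cleaning flags (recorded in the manifest).
#' @return Invisibly, a list with the in-memory results (`scan`,
#'   `annotation`, `regions`, `densities`, `strand_bias`,
#'   `classification`, `degs`, `selections`, ...) and `manifest`.
#' @export
run_pipeline <- function(fasta, gff, out_dir,
                         deg_table = NULL, genesets = NULL,
                         centromeres = NULL, tandem_repeats = NULL,
                         transposable_elements = NULL,
                         window = 25L, threshold = 1.2, run_cap = 4L,
                         promoter_lengths = c(2000L, 1500L, 1000L, 500L),
                         tss_halfwidth = 250L,
                         lfc_cut = 1, padj_cut = 0.05, fold_cutoff = 3,
                         promoter_cutoff = 10L, tss_cutoff = 5L,
                         track_window = 100000L,
                         drop_n = TRUE, dedupe = TRUE) {
  stage <- function(name, input, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed on %s: %s", name, input,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  for (f in c(fasta, gff)) {
    if (!is.character(f) || !file.exists(f)) {
      stop(sprintf("cannot read input file: %s", as.character(f)))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("scan", "regions", "stats", "degs")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  outputs <- character(0)
  emit <- function(writer, obj, rel, ...) {
    path <- file.path(out_dir, rel)
    writer(obj, path, ...)
    outputs <<- c(outputs, rel)
    path
  }
  write_tsv <- function(obj, path) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_lines_file <- function(obj, path) writeLines(obj, path)

  ## ---- scan ----
  scan <- stage("scan", fasta,
                g4_scan(fasta, window = window, threshold = threshold,
                        run_cap = run_cap, drop_n = drop_n, dedupe = dedupe))
  hits <- scan$hits
  emit(function(o, p) export_hits_bed(o, p), hits, "scan/hits.bed")
  emit(function(o, p) export_hits_tsv(o, p), hits, "scan/hits.tsv")
  emit(function(o, p) export_scan_summary_tsv(o, p), scan,
       "scan/sequence_summary.tsv")

  ## ---- annotate ----
  ann <- stage("annotate", gff, load_annotation(gff))
  seqlen <- stats::setNames(scan$summary$length_bp, scan$summary$seq_id)
  regions <- stage("annotate", gff,
                   derive_regions(ann, contig_lengths = seqlen,
                                  promoter_lengths = promoter_lengths,
                                  tss_halfwidth = tss_halfwidth))
  for (cls in unique(regions$region_class)) {
    reg <- regions[regions$region_class == cls]
    bed <- data.frame(as.character(GenomicRanges::seqnames(reg)),
                      GenomicRanges::start(reg) - 1L,
                      GenomicRanges::end(reg),
                      reg$gene_id, 0L, reg$gene_strand)
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE, col.names = FALSE),
         bed, file.path("regions", paste0("regions_", cls, ".bed")))
  }

  ## ---- stats ----
  dens_union <- stage("stats", fasta, region_densities(hits, regions))
  dens_gene <- region_densities(hits, regions, denominator = "per_gene")
  sb <- strand_bias(hits, regions)
  emit(write_tsv, dens_union, "stats/region_densities_union.tsv")
  emit(write_tsv, dens_gene, "stats/region_densities_per_gene.tsv")
  emit(write_tsv, sb, "stats/strand_bias.tsv")

  gene_ids <- ann$genes$gene_id
  tss_class <- paste0("TSS", 2L * as.integer(tss_halfwidth))
  prom_counts <- count_hits_by_gene(hits, regions, "promoter2000",
                                    gene_ids = gene_ids)
  tss_counts <- count_hits_by_gene(hits, regions, tss_class,
                                   gene_ids = gene_ids)
  cls_prom <- classify_genes(stats::setNames(prom_counts$double,
                                             prom_counts$gene_id),
                             cutoff = promoter_cutoff)
  cls_tss <- classify_genes(stats::setNames(tss_counts$double,
                                            tss_counts$gene_id),
                            cutoff = tss_cutoff)
  emit(write_tsv, cls_prom$bins, "stats/gene_classification_promoter2000.tsv")
  emit(write_tsv, cls_tss$bins,
       file.path("stats", paste0("gene_classification_", tss_class, ".tsv")))
  emit(write_lines_file, cls_prom$above_cutoff,
       sprintf("stats/genes_promoter2000_gt%d.txt", promoter_cutoff))
  emit(write_lines_file, cls_tss$above_cutoff,
       sprintf("stats/genes_%s_gt%d.txt", tss_class, tss_cutoff))

  track <- windowed_track(hits, window_bp = track_window)
  emit(function(o, p) export_bedgraph(o, p), track, "stats/g4_density.bedgraph")

  correlations <- NULL
  if (!is.null(tandem_repeats) || !is.null(transposable_elements)) {
    cs <- chrom_feature_summary(scan$summary, genes = ann$genes,
                                tandem_repeats = tandem_repeats,
                                transposable_elements = transposable_elements)
    correlations <- stage("stats", "chromosome summaries",
                          chromosome_correlations(cs))
    emit(write_tsv, correlations, "stats/chromosome_correlations.tsv")
  }
  centromere_stats <- NULL
  if (!is.null(centromeres)) {
    centromere_stats <- stage("stats", "centromere table",
                              interval_densities(hits, centromeres))
    emit(write_tsv, centromere_stats, "stats/centromere_densities.tsv")
  }
  geneset_stats <- NULL
  if (!is.null(genesets)) {
    if (is.character(genesets)) genesets <- utils::read.delim(genesets)
    geneset_stats <- stage("stats", "gene sets",
                           geneset_counts(genesets, hits, regions,
                                          classes = c("gene", tss_class,
                                                      "promoter2000")))
    emit(write_tsv, geneset_stats$per_gene, "stats/geneset_per_gene.tsv")
    emit(write_tsv, geneset_stats$per_category, "stats/geneset_per_category.tsv")
  }

  ## ---- DEG overlay ----
  degs <- NULL; selections <- list()
  if (!is.null(deg_table)) {
    degs <- stage("degs",
                  if (is.character(deg_table)) deg_table else "DEG table",
                  filter_degs(deg_table, lfc_cut = lfc_cut,
                              padj_cut = padj_cut))
    lists <- deg_lists(degs)
    emit(write_lines_file, lists$up, "degs/up_genes.txt")
    emit(write_lines_file, lists$down, "degs/down_genes.txt")
    for (dirn in c("up", "down")) {
      ids <- lists[[dirn]]
      if (!length(ids)) next
      gd <- group_densities(ids, hits, regions)
      emit(write_tsv, gd, sprintf("degs/deg_densities_%s.tsv", dirn))
      pg <- per_gene_strand_densities(hits, regions, tss_class, gene_ids = ids)
      sel <- select_by_fold(pg, fold_cutoff = fold_cutoff,
                            region_class = tss_class, direction = dirn)
      selections[[dirn]] <- sel
      emit(write_tsv, sel$table, sprintf("degs/selection_table_%s.tsv", dirn))
      emit(write_lines_file, sel$selected,
           sprintf("degs/selected_%s_fold_gt%g.txt", dirn, fold_cutoff))
    }
  }

  ## ---- manifest ----
  manifest <- list(
    tool = "g4scape",
    version = as.character(utils::packageVersion("g4scape")),
    parameters = list(window = as.integer(window), threshold = threshold,
                      run_cap = as.integer(run_cap),
                      promoter_lengths = as.integer(promoter_lengths),
                      tss_halfwidth = as.integer(tss_halfwidth),
                      lfc_cut = lfc_cut, padj_cut = padj_cut,
                      fold_cutoff = fold_cutoff,
                      promoter_cutoff = as.integer(promoter_cutoff),
                      tss_cutoff = as.integer(tss_cutoff),
                      track_window = as.integer(track_window),
                      drop_n = drop_n, dedupe = dedupe),
    inputs = list(fasta = unname(tools::md5sum(fasta)),
                  gff = unname(tools::md5sum(gff))),
    summary = list(n_sequences = nrow(scan$summary),
                   n_hits = length(hits),
                   n_genes = length(gene_ids),
                   n_regions = length(regions),
                   n_deg_up = if (is.null(degs)) NA else sum(degs$direction == "up"),
                   n_deg_down = if (is.null(degs)) NA else sum(degs$direction == "down")),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scan = scan, annotation = ann, regions = regions,
                 densities = list(union = dens_union, per_gene = dens_gene),
                 strand_bias = sb,
                 classification = list(promoter2000 = cls_prom,
                                       tss = cls_tss),
                 correlations = correlations,
                 centromeres = centromere_stats,
                 genesets = geneset_stats,
                 degs = degs, selections = selections,
                 track = track, manifest = manifest, out_dir = out_dir))
}
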