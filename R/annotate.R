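#' Load a GFF3 gene annotation into a hierarchical interval store
#'
#' @description Reads gene / mRNA / exon / CDS / UTR features from a GFF3
#' file (1-based inclusive coordinates, kept as such in the returned
#' `GRanges` objects) and organises them per gene. Exon, CDS and UTR
#' intervals are unioned over a gene's transcripts; introns are computed per
#' transcript as the transcript span minus its exons, then unioned per gene.
#' Genes without a strand are rejected with a warning.
#'
#' @param gff Path to a GFF3 file.
#' @return An object of class `g4_annotation`: a list with `genes` (a
#'   `GRanges` with a `gene_id` column), per-gene `GRangesList`s `exons`,
#'   `cds`, `introns`, `utr5`, `utr3`, and the `seqinfo` taken from the
#'   file's `##sequence-region` pragmas when present.
#' @export
load_annotation <- function(gff) {
  if (!is.character(gff) || length(gff) != 1L || !file.exists(gff)) {
    stop(sprintf("cannot read GFF annotation: %s",
                 if (is.character(gff)) gff else "<not a path>"))
  }
  gr <- rtracklayer::import(gff, format = "gff3")
  type <- as.character(gr$type)

  genes <- gr[type == "gene"]
  if (!length(genes)) stop("GFF contains no gene features")
  gene_id <- genes$ID
  if (is.null(gene_id) || anyNA(gene_id)) stop("gene features must carry an ID attribute")
  no_strand <- as.character(GenomicRanges::strand(genes)) == "*"
  if (any(no_strand)) {
    warning(sprintf("dropping %d gene(s) without strand: %s",
                    sum(no_strand),
                    paste(utils::head(gene_id[no_strand], 5), collapse = ", ")))
    genes <- genes[!no_strand]
    gene_id <- gene_id[!no_strand]
  }
  genes$gene_id <- gene_id
  names(genes) <- gene_id

  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_parent <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                      character(1))
  tx2gene <- stats::setNames(tx_parent, tx$ID)

  ## map a Parent attribute (gene or transcript ID) to its gene and its
  ## transcript (NA when attached directly to the gene)
  expand_parts <- function(part_type) {
    p <- gr[type == part_type]
    if (!length(p)) {
      return(list(gr = GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(gr)),
                  gene = character(0), tx = character(0)))
    }
    np <- lengths(p$Parent)
    p <- rep(p, np)
    parent <- unlist(p$Parent)
    tx_id <- ifelse(parent %in% names(tx2gene), parent, NA_character_)
    gene <- ifelse(is.na(tx_id), parent, unname(tx2gene[tx_id]))
    keep <- gene %in% gene_id
    if (any(!keep)) {
      warning(sprintf("dropping %d %s record(s) with unresolvable Parent",
                      sum(!keep), part_type))
    }
    list(gr = p[keep], gene = gene[keep], tx = tx_id[keep])
  }

  by_gene <- function(parts) {
    if (!length(parts$gr)) {
      return(GenomicRanges::GRangesList())
    }
    GenomicRanges::reduce(GenomicRanges::split(GenomicRanges::granges(parts$gr),
                                               factor(parts$gene)))
  }

  ex <- expand_parts("exon")
  cds <- expand_parts("CDS")
  u5 <- expand_parts("five_prime_UTR")
  u3 <- expand_parts("three_prime_UTR")

  ## introns: per transcript span minus exons, then per-gene union;
  ## exons attached directly to a gene are treated as a single transcript
  introns <- GenomicRanges::GRangesList()
  if (length(ex$gr)) {
    tx_key <- ifelse(is.na(ex$tx), ex$gene, ex$tx)
    ex_by_tx <- GenomicRanges::split(GenomicRanges::granges(ex$gr), factor(tx_key))
    spans <- unlist(range(ex_by_tx))
    intr_by_tx <- GenomicRanges::psetdiff(spans, ex_by_tx)
    key2gene <- stats::setNames(ex$gene, tx_key)[names(intr_by_tx)]
    intr <- unlist(intr_by_tx, use.names = FALSE)
    intr_gene <- rep(unname(key2gene), lengths(intr_by_tx))
    if (length(intr)) {
      introns <- GenomicRanges::reduce(
        GenomicRanges::split(intr, factor(intr_gene)))
    }
  }

  structure(
    list(genes = genes, exons = by_gene(ex), cds = by_gene(cds),
         introns = introns, utr5 = by_gene(u5), utr3 = by_gene(u3),
         seqinfo = GenomeInfoDb::seqinfo(gr)),
    class = "g4_annotation"
  )
}

#' @export
print.g4_annotation <- function(x, ...) {
  cat(sprintf("g4_annotation: %d genes on %d sequence(s); exon sets: %d, CDS sets: %d\n",
              length(x$genes), length(GenomeInfoDb::seqnames(x$seqinfo)),
              length(x$exons), length(x$cds)))
  invisible(x)
}

#' Derive strand-aware feature regions from a loaded annotation
#'
#' @description Builds the per-gene region set used throughout the density
#' and strand-bias statistics: the gene body, exon/CDS/intron/UTR unions,
#' upstream promoters of several lengths, and a window centred on the
#' transcription start site (TSS). `promoterN` is the N bp immediately
#' upstream of the gene start in gene orientation; the TSS window covers
#' `tss_halfwidth` bp on each side of the TSS (the TSS base itself lies in
#' the downstream half). Regions are clipped to `[1, contig length]`;
#' regions clipped to zero width are dropped and recorded in the
#' `"clipped"` attribute.
#'
#' @param ann A `g4_annotation` from [load_annotation()].
#' @param contig_lengths Optional named vector of contig lengths, overriding
#'   the seqlengths stored in the annotation.
#' @param promoter_lengths Integer vector of upstream promoter lengths in bp
#'   (default `c(2000, 1500, 1000, 500)`).
#' @param tss_halfwidth Half-width in bp of the TSS window (default 250,
#'   i.e. a 500 bp "TSS500" window).
#' @return A `GRanges` (1-based) with metadata columns `gene_id`,
#'   `region_class` and `gene_strand`. Region classes are `gene`, `exon`,
#'   `CDS`, `intron`, `five_prime_UTR`, `three_prime_UTR`, `promoterN` for
#'   each requested N, and `TSS<2*tss_halfwidth>`.
#' @export
derive_regions <- function(ann, contig_lengths = NULL,
                           promoter_lengths = c(2000L, 1500L, 1000L, 500L),
                           tss_halfwidth = 250L) {
  stopifnot(inherits(ann, "g4_annotation"))
  genes <- ann$genes
  si <- ann$seqinfo
  if (!is.null(contig_lengths)) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(contig_lengths),
                                seqlengths = unname(contig_lengths))
  }
  seqlen <- stats::setNames(GenomeInfoDb::seqlengths(si),
                            GenomeInfoDb::seqnames(si))

  clipped <- character(0)
  rows <- list()
  add <- function(gr, gene_id, class) {
    if (!length(gr)) return(invisible(NULL))
    ## clip to contig bounds; drop (and log) regions clipped away entirely
    sl <- seqlen[as.character(GenomicRanges::seqnames(gr))]
    st <- pmax(GenomicRanges::start(gr), 1L)
    en <- GenomicRanges::end(gr)
    en <- ifelse(is.na(sl), en, pmin(en, sl))
    keep <- st <= en
    if (any(!keep)) {
      clipped <<- c(clipped, paste0(gene_id[!keep], ":", class))
    }
    if (!any(keep)) return(invisible(NULL))
    out <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(gr))[keep],
      ranges = IRanges::IRanges(st[keep], en[keep]),
      strand = as.character(GenomicRanges::strand(gr))[keep]
    )
    out$gene_id <- gene_id[keep]
    out$region_class <- class
    out$gene_strand <- as.character(GenomicRanges::strand(gr))[keep]
    rows[[length(rows) + 1L]] <<- out
    invisible(NULL)
  }

  add(GenomicRanges::granges(genes), genes$gene_id, "gene")
  add_list <- function(grl, class) {
    if (!length(grl)) return(invisible(NULL))
    flat <- unlist(grl, use.names = FALSE)
    gid <- rep(names(grl), lengths(grl))
    gstr <- as.character(GenomicRanges::strand(genes))[match(gid, genes$gene_id)]
    GenomicRanges::strand(flat) <- gstr
    add(flat, gid, class)
  }
  add_list(ann$exons, "exon")
  add_list(ann$cds, "CDS")
  add_list(ann$introns, "intron")
  add_list(ann$utr5, "five_prime_UTR")
  add_list(ann$utr3, "three_prime_UTR")

  for (N in as.integer(promoter_lengths)) {
    prom <- suppressWarnings(GenomicRanges::flank(genes, width = N, start = TRUE))
    add(GenomicRanges::granges(prom), genes$gene_id, paste0("promoter", N))
  }
  tssw <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = as.integer(tss_halfwidth),
                             downstream = as.integer(tss_halfwidth)))
  add(GenomicRanges::granges(tssw), genes$gene_id,
      paste0("TSS", 2L * as.integer(tss_halfwidth)))

  out <- do.call(c, rows)
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(si)
  GenomeInfoDb::seqinfo(out) <- si
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  if (length(clipped)) {
    message(sprintf("%d region(s) clipped away at contig edges", length(clipped)))
  }
  attr(out, "clipped") <- clipped
  out
}

#' Strand context of a hit relative to its host gene
#'
#' A hit whose G-rich strand equals the gene strand lies on the coding
#' (sense) strand of that gene; otherwise it lies on the template strand.
#'
#' @param hit_strand,gene_strand Character vectors of "+"/"-" strands
#'   (recycled to a common length).
#' @return Character vector of `"coding"` / `"template"`.
#' @export
strand_context <- function(hit_strand, gene_strand) {
  hit_strand <- as.character(hit_strand)
  gene_strand <- as.character(gene_strand)
  if (!all(hit_strand %in% c("+", "-")) || !all(gene_strand %in% c("+", "-"))) {
    stop("strands must be '+' or '-'")
  }
  ifelse(hit_strand == gene_strand, "coding", "template")
}

#' Per-gene hit counts in one region class, split by strand context
#'
#' Counts distinct hits overlapping (>= 1 bp) each gene's regions of the
#' given class. A hit overlapping several genes is counted once per gene.
#' `double = coding + template` for every gene, since each hit carries one
#' strand.
#'
#' @param hits `GRanges` of detected hits (strand = G-rich strand).
#' @param regions `GRanges` from [derive_regions()].
#' @param region_class Single region class name, e.g. `"promoter2000"`.
#' @param gene_ids Gene universe for the output (default: every gene seen in
#'   `regions`); genes without overlap get zero counts.
#' @return data.frame with `gene_id`, `coding`, `template`, `double` and the
#'   per-gene region span `span_bp`.
#' @export
count_hits_by_gene <- function(hits, regions, region_class, gene_ids = NULL) {
  reg <- regions[regions$region_class == region_class]
  if (is.null(gene_ids)) gene_ids <- unique(regions$gene_id)
  spans <- tapply(GenomicRanges::width(reg), factor(reg$gene_id, levels = gene_ids),
                  sum, default = 0L)
  ov <- GenomicRanges::findOverlaps(hits, reg, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    ctx <- strand_context(as.character(GenomicRanges::strand(hits))[q],
                          reg$gene_strand[s])
    d <- unique(data.frame(hit = q, gene_id = reg$gene_id[s], ctx = ctx,
                           stringsAsFactors = FALSE))
    tab <- table(factor(d$gene_id, levels = gene_ids),
                 factor(d$ctx, levels = c("coding", "template")))
    coding <- as.integer(tab[, "coding"])
    template <- as.integer(tab[, "template"])
  } else {
    coding <- template <- integer(length(gene_ids))
  }
  data.frame(gene_id = gene_ids, coding = coding, template = template,
             double = coding + template,
             span_bp = as.integer(spans), row.names = NULL)
}
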