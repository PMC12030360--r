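#' Specification for a synthetic genome with planted G4 motifs
#'
#' @description Describes a small multi-chromosome genome with
#' non-overlapping genes on both strands, a quadruplex-free background, and
#' G4 motifs planted at controlled densities and strand contexts in
#' promoter, TSS and CDS regions, plus up/down differential-expression
#' groups with opposite planted strand-bias ratios in their TSS windows.
#' The defaults emulate the regulatory-region statistics observed in a
#' grapevine-scale genome: total promoter2000 density 0.54/kbp with a 2:1
#' coding bias, TSS500 density 1.00/kbp with no strand bias, and a 2.45-fold
#' coding-strand excess in CDS; up- and downregulated gene groups carry a
#' 3:1 template- and coding-dominant TSS500 ratio respectively.
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome (non-overlapping slots).
#' @param gene_length Gene length in bp (two exons with a central intron;
#'   300 bp 5' UTR, 150 bp 3' UTR).
#' @param gc Background GC fraction (before run-breaking).
#' @param p_plus Probability that a gene lies on the "+" strand.
#' @param motif Planted quadruplex motif; the default telomeric 25-mer has
#'   a window-25 mean score of 37/25 = 1.48, above the 1.2 threshold.
#' @param plant_density Named list of per-kbp planted densities per region
#'   class, each a `c(coding=, template=)` pair; supported classes:
#'   `promoter2000` (planted upstream of the TSS window so promoter counts
#'   stay unconfounded), `TSS500` (planted in the downstream half for the
#'   same reason) and `CDS`.
#' @param n_promoter_rich,promoter_rich_count Genes planted with a high
#'   promoter burden (to exceed the >10 classification cutoff).
#' @param n_tss_rich,tss_rich_count Genes planted with a high TSS burden
#'   (to exceed the >5 cutoff).
#' @param n_up,n_down Sizes of the up/down differential-expression groups.
#' @param deg_tss500_hits Planted TSS500 hits per DEG gene (on average).
#' @param up_template_ratio Template:coding ratio planted in up-gene TSS
#'   windows (default 3).
#' @param down_coding_ratio Coding:template ratio planted in down-gene TSS
#'   windows (default 3).
#' @param window,threshold Scan parameters the background is sanitised
#'   against (no background window reaches `|mean| >= threshold`).
#' @return A list of class `g4_synth_spec`.
#' @export
synth_spec <- function(n_chrom = 3L, genes_per_chrom = 60L, gene_length = 3000L,
                       gc = 0.4, p_plus = 0.5,
                       motif = "GGGTTAGGGTTAGGGTTAGGGTTAG",
                       plant_density = list(
                         promoter2000 = c(coding = 0.36, template = 0.18),
                         TSS500 = c(coding = 0.5, template = 0.5),
                         CDS = c(coding = 1.22, template = 1.22 / 2.45)),
                       n_promoter_rich = 5L, promoter_rich_count = 12L,
                       n_tss_rich = 4L, tss_rich_count = 7L,
                       n_up = 25L, n_down = 25L, deg_tss500_hits = 6L,
                       up_template_ratio = 3, down_coding_ratio = 3,
                       window = 25L, threshold = 1.2) {
  stopifnot(n_chrom >= 1L, genes_per_chrom >= 1L, gene_length >= 1500L,
            gc > 0, gc < 1, p_plus >= 0, p_plus <= 1,
            nchar(motif) >= 1L, window >= 1L, threshold > 0)
  if (any(unlist(plant_density) < 0)) stop("planted densities must be >= 0")
  bad <- setdiff(names(plant_density), c("promoter2000", "TSS500", "CDS"))
  if (length(bad)) {
    stop(sprintf("unsupported planting class(es): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(n_chrom = as.integer(n_chrom),
         genes_per_chrom = as.integer(genes_per_chrom),
         gene_length = as.integer(gene_length), gc = gc, p_plus = p_plus,
         motif = toupper(motif), plant_density = plant_density,
         n_promoter_rich = as.integer(n_promoter_rich),
         promoter_rich_count = as.integer(promoter_rich_count),
         n_tss_rich = as.integer(n_tss_rich),
         tss_rich_count = as.integer(tss_rich_count),
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         deg_tss500_hits = as.integer(deg_tss500_hits),
         up_template_ratio = up_template_ratio,
         down_coding_ratio = down_coding_ratio,
         window = as.integer(window), threshold = threshold,
         flank = 13L),
    class = "g4_synth_spec"
  )
}

.revcomp_chars <- function(chars) {
  rev(chartr("ACGTN", "TGCAN", chars))
}

## background: iid bases at the requested GC, then break any G/C run of
## length >= 3 and finally mutate until no scan window reaches the
## detection threshold (the run rule alone does not bound window means).
.synth_background <- function(n, gc, window, threshold) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), n, replace = TRUE, prob = p)
  r <- rle(chars)
  long <- which(r$lengths >= 3L & r$values %in% c("G", "C"))
  if (length(long)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in long) {
      idx <- seq.int(starts[i] + 2L, ends[i])
      chars[idx] <- if (r$values[i] == "G") "A" else "T"
    }
  }
  repeat {
    sc <- .base_scores_chars(chars)
    wm <- suppressMessages(g4_window_means(sc, window))
    bad <- which(abs(wm) >= threshold)
    if (!length(bad)) break
    for (b in bad) {
      win <- b:(b + window - 1L)
      pos <- win[which.max(abs(sc[win]))]
      chars[pos] <- if (sc[pos] > 0) "A" else "T"
      sc <- .base_scores_chars(chars)  # scores shift only locally; recompute cheaply enough
    }
  }
  chars
}

## slot positions (0-based motif starts) inside a planting window [a, b)
.slot_positions <- function(a, b, footprint, flank) {
  n_slot <- (b - a) %/% footprint
  if (n_slot <= 0L) return(integer(0))
  a + (seq_len(n_slot) - 1L) * footprint + flank
}

#' Generate a synthetic genome, annotation and DEG table with ground truth
#'
#' @description Builds the dataset described by a [synth_spec()]: FASTA
#' sequences whose background cannot produce a detection at the spec's
#' window/threshold, a GFF3 annotation of non-overlapping genes on both
#' strands, a DEG table satisfying the direction thresholds exactly, and a
#' ground-truth record of every planted motif (coordinates, strand,
#' context, host gene, planting group) plus per-gene expected counts per
#' region class. Each planted motif is flanked by score-zero bases so it
#' yields exactly one detected hit with a refined interval equal to the
#' planted interval.
#'
#' @param spec A `g4_synth_spec`.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `degs.tsv` and `truth_hits.tsv` and records the
#'   paths in the result.
#' @return A list of class `g4_synth`: `sequences` (DNAStringSet),
#'   `gff_lines`, `deg` (data.frame), `truth` (list with `hits`,
#'   `per_gene`, `groups`, `deg`), `genes` (layout table), `spec`, and
#'   `paths` when written.
#' @export
synth_generate <- function(spec, seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "g4_synth_spec"))
  set.seed(as.integer(seed))
  L <- spec$gene_length
  e1 <- round(0.4 * L)
  utr5 <- 300L; utr3 <- 150L
  if (e1 <= utr5 + 60L) stop("gene_length too short for the exon/UTR layout")
  intr <- L - 2L * e1
  up_space <- 3000L; down_space <- 2000L
  slot <- L + up_space + down_space
  chrom_len <- spec$genes_per_chrom * slot + 1000L
  mlen <- nchar(spec$motif)
  flank <- spec$flank
  footprint <- mlen + 2L * flank
  n_genes <- spec$n_chrom * spec$genes_per_chrom

  ## gene layout (0-based half-open genomic coordinates)
  genes <- data.frame(
    gene_id = sprintf("SYNG%04d", seq_len(n_genes)),
    chrom = rep(paste0("chr", seq_len(spec$n_chrom)), each = spec$genes_per_chrom),
    slot = rep(seq_len(spec$genes_per_chrom) - 1L, times = spec$n_chrom),
    stringsAsFactors = FALSE
  )
  genes$gs <- genes$slot * slot + up_space
  genes$ge <- genes$gs + L
  genes$strand <- ifelse(stats::runif(n_genes) < spec$p_plus, "+", "-")

  n_special <- spec$n_up + spec$n_down + spec$n_promoter_rich + spec$n_tss_rich
  if (n_special > n_genes) {
    stop("not enough genes for the requested DEG and burden groups")
  }
  special <- sample(n_genes, n_special)
  genes$group <- "bulk"
  grp_sizes <- c(up = spec$n_up, down = spec$n_down,
                 rich_promoter = spec$n_promoter_rich,
                 rich_tss = spec$n_tss_rich)
  off <- 0L
  for (g in names(grp_sizes)) {
    if (grp_sizes[[g]] > 0L) {
      genes$group[special[(off + 1L):(off + grp_sizes[[g]])]] <- g
    }
    off <- off + grp_sizes[[g]]
  }

  ## per-gene planting windows and derived-region intervals (0-based)
  prom_win <- cbind(ifelse(genes$strand == "+", genes$gs - 2000L, genes$ge + 250L),
                    ifelse(genes$strand == "+", genes$gs - 250L, genes$ge + 2000L))
  tssdown_win <- cbind(ifelse(genes$strand == "+", genes$gs, genes$ge - 250L),
                       ifelse(genes$strand == "+", genes$gs + 250L, genes$ge))
  tssfull_win <- cbind(ifelse(genes$strand == "+", genes$gs - 250L, genes$ge - 250L),
                       ifelse(genes$strand == "+", genes$gs + 250L, genes$ge + 250L))
  cds_win <- lapply(seq_len(n_genes), function(i) {
    gs <- genes$gs[i]; ge <- genes$ge[i]
    if (genes$strand[i] == "+") {
      rbind(c(gs + utr5, gs + e1), c(gs + e1 + intr, ge - utr3))
    } else {
      rbind(c(gs + utr3, gs + e1), c(ge - e1, ge - utr5))
    }
  })

  ## enumerate plantable slots for a set of gene indices and window matrix
  slots_for <- function(idx, win) {
    out <- lapply(idx, function(i) {
      pos <- .slot_positions(win[i, 1L], win[i, 2L], footprint, flank)
      if (!length(pos)) return(NULL)
      data.frame(gene = i, pos0 = pos)
    })
    do.call(rbind, out)
  }
  slots_cds <- function(idx) {
    out <- lapply(idx, function(i) {
      pos <- unlist(lapply(seq_len(nrow(cds_win[[i]])), function(k) {
        .slot_positions(cds_win[[i]][k, 1L], cds_win[[i]][k, 2L], footprint, flank)
      }))
      if (!length(pos)) return(NULL)
      data.frame(gene = i, pos0 = pos)
    })
    do.call(rbind, out)
  }

  plants <- list()
  add_plants <- function(tab, pick, ctx, class) {
    if (!length(pick)) return(invisible(NULL))
    d <- tab[pick, , drop = FALSE]
    d$context <- ctx
    d$class <- class
    plants[[length(plants) + 1L]] <<- d
    invisible(NULL)
  }

  bulk_idx <- which(genes$group == "bulk")
  n_bulk <- length(bulk_idx)
  class_windows <- list(
    promoter2000 = list(tab = slots_for(bulk_idx, prom_win),
                        span_bp = 2000 * n_bulk),
    TSS500 = list(tab = slots_for(bulk_idx, tssdown_win),
                  span_bp = 500 * n_bulk),
    CDS = list(tab = slots_cds(bulk_idx),
               span_bp = (2L * e1 - utr5 - utr3) * n_bulk)
  )
  for (cls in names(spec$plant_density)) {
    dens <- spec$plant_density[[cls]]
    cw <- class_windows[[cls]]
    k_c <- round(dens[["coding"]] * cw$span_bp / 1000)
    k_t <- round(dens[["template"]] * cw$span_bp / 1000)
    if (k_c + k_t == 0L) next
    if (is.null(cw$tab) || k_c + k_t > nrow(cw$tab)) {
      stop(sprintf("planted density infeasible for region class %s", cls))
    }
    pick <- sample(nrow(cw$tab), k_c + k_t)
    add_plants(cw$tab, pick[seq_len(k_c)], "coding", cls)
    add_plants(cw$tab, pick[seq_len(k_t) + k_c], "template", cls)
  }

  for (i in which(genes$group == "rich_promoter")) {
    tab <- slots_for(i, prom_win)
    k <- spec$promoter_rich_count
    if (k > nrow(tab)) stop("planted density infeasible for region class promoter2000 (rich gene)")
    pick <- sample(nrow(tab), k)
    half <- ceiling(k / 2)
    add_plants(tab, pick[seq_len(half)], "coding", "promoter2000")
    add_plants(tab, pick[-seq_len(half)], "template", "promoter2000")
  }
  for (i in which(genes$group == "rich_tss")) {
    tab <- slots_for(i, tssfull_win)
    k <- spec$tss_rich_count
    if (k > nrow(tab)) stop("planted density infeasible for region class TSS500 (rich gene)")
    pick <- sample(nrow(tab), k)
    half <- ceiling(k / 2)
    add_plants(tab, pick[seq_len(half)], "coding", "TSS500")
    add_plants(tab, pick[-seq_len(half)], "template", "TSS500")
  }

  for (grp in c("up", "down")) {
    idx <- which(genes$group == grp)
    if (!length(idx)) next
    tab <- slots_for(idx, tssfull_win)
    total <- length(idx) * spec$deg_tss500_hits
    ratio <- if (grp == "up") spec$up_template_ratio else spec$down_coding_ratio
    k_major <- round(total * ratio / (ratio + 1))
    k_minor <- total - k_major
    major_ctx <- if (grp == "up") "template" else "coding"
    minor_ctx <- if (grp == "up") "coding" else "template"
    if (total > nrow(tab)) {
      stop(sprintf("planted density infeasible for region class TSS500 (%s group)", grp))
    }
    pick <- sample(nrow(tab), total)
    add_plants(tab, pick[seq_len(k_major)], major_ctx, "TSS500")
    add_plants(tab, pick[seq_len(k_minor) + k_major], minor_ctx, "TSS500")
  }

  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(gene = integer(0), pos0 = integer(0),
               context = character(0), class = character(0),
               gene_id = character(0), chrom = character(0),
               gene_strand = character(0), strand = character(0),
               group = character(0))

  ## build sequences: clean background, then overwrite planted footprints
  motif_chars <- strsplit(spec$motif, "", fixed = TRUE)[[1L]]
  seqs <- vector("list", spec$n_chrom)
  names(seqs) <- paste0("chr", seq_len(spec$n_chrom))
  for (ci in seq_len(spec$n_chrom)) {
    seqs[[ci]] <- .synth_background(chrom_len, spec$gc, spec$window, spec$threshold)
  }
  if (nrow(plants)) {
    plants$gene_id <- genes$gene_id[plants$gene]
    plants$chrom <- genes$chrom[plants$gene]
    plants$gene_strand <- genes$strand[plants$gene]
    plants$strand <- ifelse(plants$context == "coding",
                            plants$gene_strand,
                            ifelse(plants$gene_strand == "+", "-", "+"))
    plants$group <- genes$group[plants$gene]
    for (k in seq_len(nrow(plants))) {
      p0 <- plants$pos0[k]
      body <- if (plants$strand[k] == "+") motif_chars else .revcomp_chars(motif_chars)
      idx <- (p0 - flank + 1L):(p0 + mlen + flank)
      seqs[[plants$chrom[k]]][idx] <- c(rep("A", flank), body, rep("A", flank))
    }
  }
  sequences <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))

  truth_hits <- data.frame(
    gene_id = plants$gene_id, chrom = plants$chrom,
    start = plants$pos0 + 1L, end = plants$pos0 + mlen,
    strand = plants$strand, context = plants$context,
    planted_class = plants$class, group = plants$group,
    stringsAsFactors = FALSE
  )
  truth_hits <- truth_hits[order(truth_hits$chrom, truth_hits$start), , drop = FALSE]
  rownames(truth_hits) <- NULL

  ## expected per-gene counts per derived region class, by direct interval
  ## arithmetic on the planted coordinates (0-based half-open)
  region_iv <- function(i, cls) {
    gs <- genes$gs[i]; ge <- genes$ge[i]; s <- genes$strand[i]
    tss <- if (s == "+") gs else ge - 1L
    switch(cls,
      gene = rbind(c(gs, ge)),
      CDS = cds_win[[i]],
      TSS500 = rbind(c(tss - 250L + (s == "-"), tss + 250L + (s == "-"))),
      promoter2000 = if (s == "+") rbind(c(gs - 2000L, gs)) else rbind(c(ge, ge + 2000L)),
      promoter1500 = if (s == "+") rbind(c(gs - 1500L, gs)) else rbind(c(ge, ge + 1500L)),
      promoter1000 = if (s == "+") rbind(c(gs - 1000L, gs)) else rbind(c(ge, ge + 1000L)),
      promoter500 = if (s == "+") rbind(c(gs - 500L, gs)) else rbind(c(ge, ge + 500L))
    )
  }
  truth_classes <- c("gene", "CDS", "TSS500", "promoter2000", "promoter1500",
                     "promoter1000", "promoter500")
  per_gene <- expand.grid(gene_id = genes$gene_id, region_class = truth_classes,
                          stringsAsFactors = FALSE)
  per_gene$coding <- 0L; per_gene$template <- 0L
  if (nrow(plants)) {
    m0 <- plants$pos0; m1 <- plants$pos0 + mlen
    for (r in seq_len(nrow(per_gene))) {
      i <- match(per_gene$gene_id[r], genes$gene_id)
      iv <- region_iv(i, per_gene$region_class[r])
      sel <- plants$gene == i
      if (!any(sel)) next
      hit <- rep(FALSE, sum(sel))
      for (k in seq_len(nrow(iv))) {
        hit <- hit | (m0[sel] < iv[k, 2L] & m1[sel] > iv[k, 1L])
      }
      per_gene$coding[r] <- sum(hit & plants$context[sel] == "coding")
      per_gene$template[r] <- sum(hit & plants$context[sel] == "template")
    }
  }
  per_gene$double <- per_gene$coding + per_gene$template

  ## DEG table satisfying the direction thresholds exactly
  deg <- data.frame(gene_id = genes$gene_id, log2FoldChange = NA_real_,
                    padj = NA_real_, stringsAsFactors = FALSE)
  up_i <- genes$group == "up"; down_i <- genes$group == "down"
  ns_i <- !(up_i | down_i)
  deg$log2FoldChange[up_i] <- stats::runif(sum(up_i), 1.5, 4)
  deg$padj[up_i] <- stats::runif(sum(up_i), 1e-6, 0.01)
  deg$log2FoldChange[down_i] <- -stats::runif(sum(down_i), 1.5, 4)
  deg$padj[down_i] <- stats::runif(sum(down_i), 1e-6, 0.01)
  deg$log2FoldChange[ns_i] <- stats::runif(sum(ns_i), -0.9, 0.9)
  deg$padj[ns_i] <- stats::runif(sum(ns_i), 0, 1)
  ## some non-significant genes with large fold change but padj above the
  ## cutoff, and a few NA padj, to exercise both filter arms
  big_ns <- utils::head(which(ns_i), 10L)
  deg$log2FoldChange[big_ns] <- stats::runif(length(big_ns), 1.5, 3) *
    sample(c(-1, 1), length(big_ns), replace = TRUE)
  deg$padj[big_ns] <- stats::runif(length(big_ns), 0.06, 0.5)
  na_ns <- utils::tail(which(ns_i), 5L)
  deg$log2FoldChange[na_ns] <- 2
  deg$padj[na_ns] <- NA_real_
  deg_truth <- data.frame(gene_id = genes$gene_id,
                          direction = ifelse(up_i, "up",
                                             ifelse(down_i, "down", "ns")),
                          stringsAsFactors = FALSE)

  gff <- .synth_gff_lines(genes, chrom_len, e1, intr, utr5, utr3,
                          names(seqs))

  out <- structure(
    list(sequences = sequences, gff_lines = gff, deg = deg,
         truth = list(hits = truth_hits, per_gene = per_gene,
                      groups = genes[, c("gene_id", "group")],
                      deg = deg_truth),
         genes = genes, chrom_len = chrom_len, spec = spec,
         seed = as.integer(seed), paths = NULL),
    class = "g4_synth"
  )
  if (!is.null(dir)) out <- synth_write(out, dir)
  out
}

.synth_gff_lines <- function(genes, chrom_len, e1, intr, utr5, utr3, chroms) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", chroms, chrom_len))
  feat <- function(chrom, type, a0, b0, strand, attrs) {
    sprintf("%s\tg4synth\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, a0 + 1L, b0, strand,
            if (type == "CDS") "0" else ".", attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    gs <- g$gs; ge <- g$ge
    ex <- rbind(c(gs, gs + e1), c(ge - e1, ge))
    if (g$strand == "+") {
      u5 <- c(gs, gs + utr5); cds <- rbind(c(gs + utr5, gs + e1),
                                           c(ge - e1, ge - utr3))
      u3 <- c(ge - utr3, ge)
    } else {
      u5 <- c(ge - utr5, ge); cds <- rbind(c(ge - e1, ge - utr5),
                                           c(gs + utr3, gs + e1))
      u3 <- c(gs, gs + utr3)
    }
    lines <- c(lines,
      feat(g$chrom, "gene", gs, ge, g$strand, paste0("ID=", g$gene_id)),
      feat(g$chrom, "mRNA", gs, ge, g$strand,
           paste0("ID=", tid, ";Parent=", g$gene_id)),
      feat(g$chrom, "exon", ex[1, 1], ex[1, 2], g$strand, paste0("Parent=", tid)),
      feat(g$chrom, "exon", ex[2, 1], ex[2, 2], g$strand, paste0("Parent=", tid)),
      feat(g$chrom, "five_prime_UTR", u5[1], u5[2], g$strand, paste0("Parent=", tid)),
      feat(g$chrom, "CDS", cds[1, 1], cds[1, 2], g$strand, paste0("Parent=", tid)),
      feat(g$chrom, "CDS", cds[2, 1], cds[2, 2], g$strand, paste0("Parent=", tid)),
      feat(g$chrom, "three_prime_UTR", u3[1], u3[2], g$strand, paste0("Parent=", tid)))
  }
  lines
}

#' Write a synthetic dataset to disk
#'
#' @param sim A `g4_synth` from [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return The `g4_synth` with `paths` filled in.
#' @export
synth_write <- function(sim, dir) {
  stopifnot(inherits(sim, "g4_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    deg = file.path(dir, "degs.tsv"),
    truth = file.path(dir, "truth_hits.tsv")
  )
  Biostrings::writeXStringSet(sim$sequences, paths$fasta)
  writeLines(sim$gff_lines, paths$gff)
  utils::write.table(sim$deg, paths$deg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$hits, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sim$paths <- paths
  sim
}

#' @export
print.g4_synth <- function(x, ...) {
  cat(sprintf("g4_synth: %d chromosome(s) x %d bp, %d genes, %d planted motifs\n",
              length(x$sequences), x$chrom_len, nrow(x$genes),
              nrow(x$truth$hits)))
  invisible(x)
}

#' Perturb planted motifs by central point mutation
#'
#' Mutates the central base of a fraction of the planted motifs (G -> T on
#' the forward-strand motif, C -> A on the reverse-complement plant),
#' breaking the central G run and lowering each mutated motif's refined
#' score.
#'
#' @param sim A `g4_synth`.
#' @param fraction Fraction of planted motifs to mutate, in `[0, 1]`.
#' @param seed Seed for choosing which motifs are mutated.
#' @return The `g4_synth` with mutated `sequences` and a logical `mutated`
#'   column added to `truth$hits`.
#' @export
synth_perturb <- function(sim, fraction, seed = 1L) {
  stopifnot(inherits(sim, "g4_synth"), fraction >= 0, fraction <= 1)
  hits <- sim$truth$hits
  hits$mutated <- FALSE
  k <- round(fraction * nrow(hits))
  if (k > 0L) {
    set.seed(as.integer(seed))
    pick <- sample(nrow(hits), k)
    hits$mutated[pick] <- TRUE
    mlen <- nchar(sim$spec$motif)
    center_off <- ceiling(mlen / 2) - 1L
    chars_by_chrom <- list()
    for (r in pick) {
      ch <- hits$chrom[r]
      if (is.null(chars_by_chrom[[ch]])) {
        chars_by_chrom[[ch]] <- strsplit(as.character(sim$sequences[[ch]]),
                                         "", fixed = TRUE)[[1L]]
      }
      pos <- hits$start[r] + center_off  # 1-based central base
      chars_by_chrom[[ch]][pos] <- if (hits$strand[r] == "+") "T" else "A"
    }
    for (ch in names(chars_by_chrom)) {
      sim$sequences[[ch]] <- Biostrings::DNAString(
        paste(chars_by_chrom[[ch]], collapse = ""))
    }
  }
  sim$truth$hits <- hits
  sim
}

#' Simulate a chromosome feature summary with a target correlation
#'
#' Draws per-chromosome G4 densities and four genomic feature tracks (GC
#' content, gene / tandem-repeat / transposable-element densities) from a
#' bivariate-normal construction so that each feature correlates with G4
#' density at the requested level; useful for exercising
#' [chromosome_correlations()] at a known truth.
#'
#' @param n_chrom Number of chromosomes (default 19).
#' @param target_r Target Pearson correlation of each feature with G4
#'   density.
#' @param seed Optional seed.
#' @return data.frame with `seq_id`, `length_bp`, `gc_percent`,
#'   `g4_density`, `gene_density`, `tandem_repeat_density`, `te_density`.
#' @export
synth_chrom_summary <- function(n_chrom = 19L, target_r = 0.8, seed = NULL) {
  stopifnot(n_chrom >= 3L, abs(target_r) <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- stats::rnorm(n_chrom)
  mix <- function() target_r * z + sqrt(1 - target_r^2) * stats::rnorm(n_chrom)
  data.frame(
    seq_id = paste0("chr", seq_len(n_chrom)),
    length_bp = 25e6,
    gc_percent = 35 + 0.6 * mix(),
    g4_density = 0.95 + 0.08 * z,
    gene_density = 0.030 + 0.004 * mix(),
    tandem_repeat_density = 0.05 + 0.012 * mix(),
    te_density = 0.30 + 0.05 * mix()
  )
}
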