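#' Hit density per kilobase
#'
#' @param hit_count Integer vector of hit counts.
#' @param span_bp Integer vector of spans in bp (recycled).
#' @return `hit_count * 1000 / span_bp`; `NA` (with a warning) where
#'   `span_bp` is zero.
#' @examples
#' g4_density(26041, 27822162)  # 0.94 at 2 dp
#' @export
g4_density <- function(hit_count, span_bp) {
  bad <- span_bp == 0
  if (any(bad)) warning("density undefined for zero span; returning NA")
  out <- hit_count * 1000 / span_bp
  out[bad] <- NA_real_
  out
}

#' Region-class densities by strand context
#'
#' @description For every region class, computes the hit count, span and
#' density per kbp in three strand contexts: `double` (both strands),
#' `coding` (hits whose G-rich strand matches the host gene strand) and
#' `template` (the opposite). With the default `"union"` denominator the
#' span is the total bp of the interval union of the class (avoiding
#' double-counted bp where promoters overlap) and counts are distinct hits
#' overlapping that union; with `"per_gene"` the span is the sum of each
#' gene's own region spans and a hit is counted once per overlapped gene.
#' Coding and template contexts share the double-strand span: both strands
#' of a region have identical exposure.
#'
#' @param hits `GRanges` of detected hits.
#' @param regions `GRanges` from [derive_regions()].
#' @param classes Region classes to report (default: all present).
#' @param denominator `"union"` (default) or `"per_gene"`.
#' @return data.frame with `region_class`, `context`, `hit_count`,
#'   `span_bp`, `density_per_kbp`, `denominator`, `flagged` (zero span).
#' @export
region_densities <- function(hits, regions, classes = NULL,
                             denominator = c("union", "per_gene")) {
  denominator <- match.arg(denominator)
  if (is.null(classes)) classes <- unique(regions$region_class)
  rows <- lapply(classes, function(cls) {
    reg <- regions[regions$region_class == cls]
    if (denominator == "union") {
      u <- GenomicRanges::reduce(GenomicRanges::granges(reg), ignore.strand = TRUE)
      span <- sum(GenomicRanges::width(u))
      ov <- GenomicRanges::findOverlaps(hits, reg, ignore.strand = TRUE)
      q <- S4Vectors::queryHits(ov)
      ctx <- strand_context(as.character(GenomicRanges::strand(hits))[q],
                            reg$gene_strand[S4Vectors::subjectHits(ov)])
      n_dbl <- length(unique(q))
      n_cod <- length(unique(q[ctx == "coding"]))
      n_tpl <- length(unique(q[ctx == "template"]))
    } else {
      per <- count_hits_by_gene(hits, regions, cls)
      span <- sum(per$span_bp)
      n_dbl <- sum(per$double)
      n_cod <- sum(per$coding)
      n_tpl <- sum(per$template)
    }
    data.frame(region_class = cls,
               context = c("double", "coding", "template"),
               hit_count = c(n_dbl, n_cod, n_tpl),
               span_bp = span,
               density_per_kbp = if (span > 0) c(n_dbl, n_cod, n_tpl) * 1000 / span
                                 else NA_real_,
               denominator = denominator,
               flagged = span == 0)
  })
  do.call(rbind, rows)
}

#' Strand-bias fold difference (G4SDF)
#'
#' The fold difference in G4 density between the coding and template
#' strands of a region set, by the max/min convention with the dominant
#' strand recorded. One zero density gives an infinite fold (flagged); both
#' zero gives an undefined, flagged record.
#'
#' @param coding_density,template_density Non-negative densities.
#' @return One-row data.frame with `coding_density`, `template_density`,
#'   `g4sdf`, `dominant` (`"coding"`, `"template"` or `"tie"`), `flagged`.
#' @examples
#' strand_fold(0.2, 0.6)  # g4sdf 3, dominant template
#' @export
strand_fold <- function(coding_density, template_density) {
  cd <- coding_density; td <- template_density
  if (length(cd) != 1L || length(td) != 1L || cd < 0 || td < 0) {
    stop("densities must be single non-negative numbers")
  }
  if (cd == 0 && td == 0) {
    return(data.frame(coding_density = cd, template_density = td,
                      g4sdf = NA_real_, dominant = NA_character_, flagged = TRUE))
  }
  dominant <- if (cd > td) "coding" else if (td > cd) "template" else "tie"
  g4sdf <- if (min(cd, td) == 0) Inf else max(cd, td) / min(cd, td)
  data.frame(coding_density = cd, template_density = td, g4sdf = g4sdf,
             dominant = dominant, flagged = !is.finite(g4sdf))
}

#' Exact binomial test for coding/template strand bias
#'
#' Under equal exposure of the two strands (spans are identical by
#' construction), the number of coding-strand hits among all stranded hits
#' is Binomial(n, 1/2) when there is no bias; the two-sided exact binomial
#' p-value is returned.
#'
#' @param coding_count,template_count Non-negative integer counts.
#' @return Two-sided p-value; `NA` (with a warning) when both are zero.
#' @examples
#' strand_bias_test(8, 0)  # 2 * 0.5^8
#' @export
strand_bias_test <- function(coding_count, template_count) {
  n <- coding_count + template_count
  if (n == 0) {
    warning("strand bias test undefined for zero total count")
    return(NA_real_)
  }
  stats::binom.test(coding_count, n, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Strand-bias summary per region class
#'
#' Combines [region_densities()], [strand_fold()] and [strand_bias_test()]
#' into one table.
#'
#' @inheritParams region_densities
#' @return data.frame with one row per class: context counts and densities,
#'   `g4sdf`, `dominant`, `p_value`, `flagged`.
#' @export
strand_bias <- function(hits, regions, classes = NULL) {
  dens <- region_densities(hits, regions, classes = classes)
  rows <- lapply(split(dens, dens$region_class), function(d) {
    cd <- d$density_per_kbp[d$context == "coding"]
    td <- d$density_per_kbp[d$context == "template"]
    cc <- d$hit_count[d$context == "coding"]
    tc <- d$hit_count[d$context == "template"]
    if (d$flagged[1L] || is.na(cd)) {
      return(data.frame(region_class = d$region_class[1L], coding_count = cc,
                        template_count = tc, coding_density = NA_real_,
                        template_density = NA_real_, g4sdf = NA_real_,
                        dominant = NA_character_, p_value = NA_real_,
                        flagged = TRUE))
    }
    sf <- strand_fold(cd, td)
    p <- if (cc + tc > 0) strand_bias_test(cc, tc) else NA_real_
    data.frame(region_class = d$region_class[1L], coding_count = cc,
               template_count = tc, coding_density = cd,
               template_density = td, g4sdf = sf$g4sdf,
               dominant = sf$dominant, p_value = p,
               flagged = sf$flagged | is.na(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genes by G4 burden in a region class
#'
#' @description Bins every annotated gene by its hit count and reports the
#' genes whose count strictly exceeds a cutoff, with proportions over the
#' full gene universe (zero-count genes included).
#'
#' @param counts Named integer vector of per-gene hit counts covering every
#'   annotated gene (see [count_hits_by_gene()]).
#' @param cutoff Burden cutoff; genes with `count > cutoff` (strict) are
#'   reported (default 10, the promoter convention; use 5 for TSS windows).
#' @param bin_breaks Increasing internal break points for the histogram
#'   (default `c(0, 5, 10)` giving bins 0, 1-5, 6-10, >10).
#' @return A list of class `g4_gene_classification`: `bins` (data.frame
#'   `bin`, `n_genes`, `proportion`; proportions sum to 1), `above_cutoff`
#'   (gene IDs), `n_above`, `prop_above`, `n_with_any`, `prop_with_any`,
#'   `n_genes`, `cutoff`.
#' @export
classify_genes <- function(counts, cutoff = 10L, bin_breaks = c(0L, 5L, 10L)) {
  if (!length(counts)) stop("empty gene universe")
  if (is.null(names(counts)) || anyNA(names(counts))) {
    stop("'counts' must be named by gene_id")
  }
  breaks <- c(-Inf, bin_breaks, Inf)
  labs <- c(as.character(bin_breaks[1L]),
            paste0(utils::head(bin_breaks, -1L) + 1L, "-", bin_breaks[-1L]),
            paste0(">", bin_breaks[length(bin_breaks)]))
  binned <- cut(counts, breaks = breaks, labels = labs, right = TRUE)
  tab <- table(binned)
  bins <- data.frame(bin = names(tab), n_genes = as.integer(tab),
                     proportion = as.integer(tab) / length(counts),
                     row.names = NULL)
  above <- names(counts)[counts > cutoff]
  structure(
    list(bins = bins, above_cutoff = above,
         n_above = length(above), prop_above = length(above) / length(counts),
         n_with_any = sum(counts > 0),
         prop_with_any = sum(counts > 0) / length(counts),
         n_genes = length(counts), cutoff = cutoff),
    class = "g4_gene_classification"
  )
}

#' @export
print.g4_gene_classification <- function(x, ...) {
  cat(sprintf("%d / %d genes (%.2f%%) with any hit; %d (%.2f%%) with > %d hits\n",
              x$n_with_any, x$n_genes, 100 * x$prop_with_any,
              x$n_above, 100 * x$prop_above, x$cutoff))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' G4 counts for curated gene sets
#'
#' Counts hits per member gene (double-strand) in the requested region
#' classes and totals them per category; useful for pathway gene lists such
#' as sugar-acid metabolism enzymes.
#'
#' @param genesets data.frame with columns `gene_id` and `category`.
#' @param hits,regions As in [region_densities()].
#' @param classes Region classes to count (default gene body, TSS window,
#'   promoter2000).
#' @return List with `per_gene` (one row per member gene, one count column
#'   per class), `per_category` (category totals) and `unknown` (gene IDs
#'   absent from the annotation; reported with a warning).
#' @export
geneset_counts <- function(genesets, hits, regions,
                           classes = c("gene", "TSS500", "promoter2000")) {
  stopifnot(is.data.frame(genesets),
            all(c("gene_id", "category") %in% names(genesets)))
  known <- unique(regions$gene_id)
  unknown <- setdiff(genesets$gene_id, known)
  if (length(unknown)) {
    warning(sprintf("%d gene ID(s) not found in annotation: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
  }
  gs <- genesets[genesets$gene_id %in% known, , drop = FALSE]
  per_gene <- gs[, c("gene_id", "category"), drop = FALSE]
  for (cls in classes) {
    cnt <- count_hits_by_gene(hits, regions, cls, gene_ids = unique(gs$gene_id))
    per_gene[[cls]] <- cnt$double[match(per_gene$gene_id, cnt$gene_id)]
  }
  per_category <- stats::aggregate(per_gene[classes],
                                   by = list(category = per_gene$category), sum)
  list(per_gene = per_gene, per_category = per_category, unknown = unknown)
}

#' Chromosome-level Pearson correlations with genomic features
#'
#' Correlates per-chromosome G4 density with GC content and with gene,
#' tandem-repeat and transposable-element densities (counts per kbp), as a
#' genome-landscape association screen.
#'
#' @param chrom_summary data.frame with one row per chromosome, a
#'   `g4_density` column and any of `gc_percent`, `gene_density`,
#'   `tandem_repeat_density`, `te_density`.
#' @param features Feature columns to test (default: all four, when
#'   present).
#' @return data.frame with `feature`, `r`, `p_value`, `n`, `flagged`
#'   (zero-variance feature: undefined r).
#' @export
chromosome_correlations <- function(chrom_summary,
                                    features = c("gc_percent", "gene_density",
                                                 "tandem_repeat_density",
                                                 "te_density")) {
  stopifnot(is.data.frame(chrom_summary), "g4_density" %in% names(chrom_summary))
  if (nrow(chrom_summary) < 3L) stop("need at least 3 chromosomes")
  features <- intersect(features, names(chrom_summary))
  if (!length(features)) stop("no feature columns found")
  y <- chrom_summary$g4_density
  rows <- lapply(features, function(f) {
    x <- chrom_summary[[f]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(feature = f, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), flagged = TRUE))
    }
    ct <- stats::cor.test(y[ok], x[ok], method = "pearson")
    data.frame(feature = f, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Hit densities over user-supplied coordinate subsets (e.g. centromeres)
#'
#' @param hits `GRanges` of detected hits.
#' @param intervals data.frame with `seq_id`, `start`, `end` (1-based,
#'   inclusive) or a path to such a TSV.
#' @return data.frame with per-interval `hit_count`, `span_bp`,
#'   `density_per_kbp`.
#' @export
interval_densities <- function(hits, intervals) {
  if (is.character(intervals)) {
    intervals <- utils::read.delim(intervals, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  gr <- GenomicRanges::GRanges(intervals$seq_id,
                               IRanges::IRanges(intervals$start, intervals$end))
  cnt <- GenomicRanges::countOverlaps(gr, hits, ignore.strand = TRUE)
  span <- GenomicRanges::width(gr)
  data.frame(seq_id = intervals$seq_id, start = intervals$start,
             end = intervals$end, hit_count = cnt, span_bp = span,
             density_per_kbp = g4_density(cnt, span))
}

#' Windowed G4 density track
#'
#' Tiles each sequence into windows and assigns every hit to the window
#' containing its start coordinate, so that with `step == window_bp` the
#' window counts conserve the total hit count.
#'
#' @param hits `GRanges` with seqlengths set (as returned by [g4_scan()]),
#'   or supply `seqlengths` explicitly.
#' @param window_bp Window width in bp.
#' @param step Step between window starts (default `window_bp`: tiling).
#' @param seqlengths Optional named vector of sequence lengths.
#' @return data.frame with `seq_id`, `start`, `end` (1-based inclusive),
#'   `count` and `density_per_kbp`.
#' @export
windowed_track <- function(hits, window_bp, step = window_bp,
                           seqlengths = NULL) {
  if (window_bp <= 0 || step <= 0) stop("'window_bp' and 'step' must be positive")
  if (is.null(seqlengths)) {
    seqlengths <- GenomeInfoDb::seqlengths(hits)
  }
  if (!length(seqlengths) || anyNA(seqlengths)) {
    stop("sequence lengths are required (set seqlengths on 'hits' or pass them)")
  }
  starts1 <- GenomicRanges::start(hits)
  chrom <- as.character(GenomicRanges::seqnames(hits))
  rows <- lapply(names(seqlengths), function(sq) {
    len <- seqlengths[[sq]]
    st <- seq.int(1L, len, by = step)
    en <- pmin(st + window_bp - 1L, len)
    hs <- starts1[chrom == sq]
    cnt <- vapply(seq_along(st),
                  function(i) sum(hs >= st[i] & hs <= en[i]), integer(1))
    data.frame(seq_id = sq, start = st, end = en, count = cnt,
               density_per_kbp = g4_density(cnt, en - st + 1L))
  })
  do.call(rbind, rows)
}

#' Write a windowed track as bedGraph
#'
#' Coordinates are converted to the 0-based half-open bedGraph convention.
#'
#' @param track data.frame from [windowed_track()].
#' @param path Output file path.
#' @param value Which column to write as the track value.
#' @export
export_bedgraph <- function(track, path, value = c("density_per_kbp", "count")) {
  value <- match.arg(value)
  d <- data.frame(track$seq_id, track$start - 1L, track$end, track[[value]])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a chromosome feature summary from scan results and feature tracks
#'
#' @param scan_summary The `summary` data.frame of a [g4_scan()] result.
#' @param genes Optional `GRanges` of genes (from [load_annotation()]).
#' @param tandem_repeats,transposable_elements Optional `GRanges` (or
#'   GFF3/BED paths) of repeat annotations.
#' @return data.frame with `seq_id`, `length_bp`, `gc_percent`,
#'   `g4_density` and one count-per-kbp column per supplied track.
#' @export
chrom_feature_summary <- function(scan_summary, genes = NULL,
                                  tandem_repeats = NULL,
                                  transposable_elements = NULL) {
  out <- data.frame(seq_id = scan_summary$seq_id,
                    length_bp = scan_summary$length_bp,
                    gc_percent = scan_summary$gc_percent,
                    g4_density = scan_summary$density_per_kbp)
  per_kbp <- function(x) {
    if (is.character(x)) x <- rtracklayer::import(x)
    cnt <- table(factor(as.character(GenomicRanges::seqnames(x)),
                        levels = out$seq_id))
    as.integer(cnt) * 1000 / out$length_bp
  }
  if (!is.null(genes)) out$gene_density <- per_kbp(genes)
  if (!is.null(tandem_repeats)) out$tandem_repeat_density <- per_kbp(tandem_repeats)
  if (!is.null(transposable_elements)) out$te_density <- per_kbp(transposable_elements)
  out
}
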