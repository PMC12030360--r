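#' Filter a differential-expression results table into up/down/ns genes
#'
#' @description Applies the usual DESeq2-style thresholds to a results
#' table: a gene is `up` when `log2FoldChange >= lfc_cut` and
#' `padj <= padj_cut`, `down` when `log2FoldChange <= -lfc_cut` and
#' `padj <= padj_cut`, otherwise `ns`. Missing `padj` (NA, as DESeq2 emits
#' for independent-filtering casualties) is treated as not significant. The
#' partition is exhaustive and exclusive.
#'
#' @param x data.frame with columns `gene_id`, `log2FoldChange`, `padj`
#'   (`log2FC`/`lfc` and `p_adj`/`FDR` are accepted aliases), or a path to
#'   such a TSV.
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param padj_cut Adjusted-p threshold (default 0.05).
#' @param timepoint Optional label attached to the output (e.g. "D2").
#' @return data.frame of class `g4_deg` with the input columns plus
#'   `direction` and `timepoint`.
#' @export
filter_degs <- function(x, lfc_cut = 1, padj_cut = 0.05, timepoint = NA_character_) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  alias <- c(log2FC = "log2FoldChange", lfc = "log2FoldChange",
             p_adj = "padj", FDR = "padj", gene = "gene_id")
  for (a in names(alias)) {
    if (a %in% names(x) && !alias[[a]] %in% names(x)) {
      names(x)[names(x) == a] <- alias[[a]]
    }
  }
  need <- c("gene_id", "log2FoldChange", "padj")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$gene_id)) {
    stop(sprintf("duplicate gene_id(s): %s",
                 paste(utils::head(unique(x$gene_id[duplicated(x$gene_id)]), 5),
                       collapse = ", ")))
  }
  sig <- !is.na(x$padj) & x$padj <= padj_cut & !is.na(x$log2FoldChange)
  x$direction <- "ns"
  x$direction[sig & x$log2FoldChange >= lfc_cut] <- "up"
  x$direction[sig & x$log2FoldChange <= -lfc_cut] <- "down"
  x$timepoint <- timepoint
  class(x) <- c("g4_deg", class(x))
  x
}

#' Split a filtered DEG table into direction gene lists
#'
#' @param degs data.frame from [filter_degs()].
#' @return List with character vectors `up`, `down`, `ns`.
#' @export
deg_lists <- function(degs) {
  stopifnot("direction" %in% names(degs))
  list(up = degs$gene_id[degs$direction == "up"],
       down = degs$gene_id[degs$direction == "down"],
       ns = degs$gene_id[degs$direction == "ns"])
}

#' Region densities restricted to a gene list
#'
#' Computes [region_densities()] over only the listed genes' regions, so
#' denominators are the listed genes' spans; with the full gene universe it
#' reproduces the genome-wide table.
#'
#' @param gene_ids Character vector of gene IDs.
#' @param hits,regions,classes,denominator As in [region_densities()].
#' @return data.frame as [region_densities()] (empty, with a warning, for
#'   an empty gene list).
#' @export
group_densities <- function(gene_ids, hits, regions, classes = NULL,
                            denominator = "union") {
  if (!length(gene_ids)) {
    warning("empty gene list; returning no density records")
    return(region_densities(hits, regions[0], classes = character(0),
                            denominator = denominator))
  }
  reg <- regions[regions$gene_id %in% gene_ids]
  if (!length(reg)) {
    warning("no regions found for the listed genes")
  }
  region_densities(hits, reg, classes = classes, denominator = denominator)
}

#' Per-gene coding/template densities in one region class
#'
#' @param hits,regions As in [region_densities()].
#' @param region_class Single region class, e.g. `"TSS500"`.
#' @param gene_ids Optional gene subset (default: all genes in `regions`).
#' @return data.frame with per-gene `coding`/`template` counts, the gene's
#'   region `span_bp` (identical exposure for both strands) and
#'   `coding_density`/`template_density` per kbp.
#' @export
per_gene_strand_densities <- function(hits, regions, region_class,
                                      gene_ids = NULL) {
  cnt <- count_hits_by_gene(hits, regions, region_class, gene_ids = gene_ids)
  cnt$coding_density <- ifelse(cnt$span_bp > 0,
                               cnt$coding * 1000 / cnt$span_bp, NA_real_)
  cnt$template_density <- ifelse(cnt$span_bp > 0,
                                 cnt$template * 1000 / cnt$span_bp, NA_real_)
  cnt
}

#' Select genes by strand-bias fold cutoff
#'
#' @description Selects genes whose per-gene fold difference between
#' coding- and template-strand densities (max/min convention) strictly
#' exceeds `fold_cutoff` in the given region class. Genes with hits on one
#' strand only have an infinite fold: they are selected and flagged. Genes
#' with no hits on either strand are excluded. With `pooled = TRUE` the
#' fold is instead computed on the pooled densities of the whole gene set
#' and the selection is all-or-none.
#'
#' @param per_gene data.frame from [per_gene_strand_densities()].
#' @param fold_cutoff Strict fold threshold (default 3).
#' @param region_class Label recorded in the result.
#' @param direction,timepoint Optional labels recorded in the result.
#' @param pooled Use pooled group densities instead of per-gene folds.
#' @return List of class `g4_deg_selection`: `selected` (gene IDs), `table`
#'   (per-gene folds with `dominant` and `flagged`), `fold_cutoff`,
#'   `pooled`, `pooled_g4sdf` (when pooled), plus the labels.
#' @export
select_by_fold <- function(per_gene, fold_cutoff = 3, region_class = NA_character_,
                           direction = NA_character_, timepoint = NA_character_,
                           pooled = FALSE) {
  stopifnot(all(c("gene_id", "coding", "template") %in% names(per_gene)))
  d <- per_gene[per_gene$coding + per_gene$template > 0, , drop = FALSE]
  cd <- d$coding; td <- d$template
  fold <- ifelse(pmin(cd, td) == 0, Inf, pmax(cd, td) / pmin(cd, td))
  dominant <- ifelse(cd > td, "coding", ifelse(td > cd, "template", "tie"))
  tab <- data.frame(gene_id = d$gene_id,
                    coding = cd, template = td,
                    coding_density = d$coding_density,
                    template_density = d$template_density,
                    fold = fold, dominant = dominant,
                    flagged = !is.finite(fold))
  pooled_g4sdf <- NA_real_
  if (pooled) {
    sf <- strand_fold(sum(cd) / max(sum(d$span_bp), 1) * 1000,
                      sum(td) / max(sum(d$span_bp), 1) * 1000)
    pooled_g4sdf <- sf$g4sdf
    selected <- if (isTRUE(pooled_g4sdf > fold_cutoff)) tab$gene_id else character(0)
  } else {
    selected <- tab$gene_id[tab$fold > fold_cutoff]
  }
  structure(
    list(selected = selected, table = tab, fold_cutoff = fold_cutoff,
         pooled = pooled, pooled_g4sdf = pooled_g4sdf,
         region_class = region_class, direction = direction,
         timepoint = timepoint),
    class = "g4_deg_selection"
  )
}

#' @export
print.g4_deg_selection <- function(x, ...) {
  cat(sprintf("%d gene(s) with strand fold > %g%s%s\n",
              length(x$selected), x$fold_cutoff,
              if (!is.na(x$region_class)) paste0(" in ", x$region_class) else "",
              if (x$pooled) sprintf(" (pooled g4sdf = %.3g)", x$pooled_g4sdf) else ""))
  invisible(x)
}
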