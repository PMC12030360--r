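#' @title G4Hunter-style per-base scoring
#'
#' @description Scores every base of a nucleotide sequence by the run-length
#' rule used for G-quadruplex propensity: each base in a maximal run of k
#' consecutive G's scores `+min(k, run_cap)`, each base in a run of k C's
#' scores `-min(k, run_cap)`, and A/T/N score 0. Scanning is
#' case-insensitive; N breaks G/C runs.
#'
#' @param sequence A single nucleotide string (character scalar or
#'   [Biostrings::DNAString]) over A/C/G/T/N, any case.
#' @param run_cap Integer >= 1, the saturation value of the run-length score
#'   (default 4, the conventional cap: runs of four or more guanines are
#'   already sufficient to stack a tetrad core).
#' @param mask_lowercase If `TRUE`, soft-masked (lowercase) bases are treated
#'   as N (score 0, run-breaking) instead of being scanned normally.
#'   Only meaningful for character input; default `FALSE`.
#' @return Integer vector of per-base scores, same length as the sequence.
#' @examples
#' g4_base_scores("GGGG")    # 4 4 4 4
#' g4_base_scores("AGGTCC")  # 0 2 2 0 -2 -2
#' @export
g4_base_scores <- function(sequence, run_cap = 4L, mask_lowercase = FALSE) {
  chars <- .seq_chars(sequence, mask_lowercase = mask_lowercase)
  .base_scores_chars(chars, run_cap = run_cap)
}

## split/validate a sequence into an uppercase character vector
.seq_chars <- function(sequence, mask_lowercase = FALSE) {
  if (methods::is(sequence, "XString") || methods::is(sequence, "XStringSet")) {
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("'sequence' must be a single nucleotide string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (mask_lowercase) {
    chars[chars %in% c("a", "c", "g", "t", "n")] <- "N"
  }
  chars <- toupper(chars)
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  }
  chars
}

.base_scores_chars <- function(chars, run_cap = 4L) {
  run_cap <- as.integer(run_cap)
  if (is.na(run_cap) || run_cap < 1L) stop("'run_cap' must be an integer >= 1")
  if (!length(chars)) return(integer(0))
  r <- rle(chars)
  v <- integer(length(r$lengths))
  is_g <- r$values == "G"
  is_c <- r$values == "C"
  v[is_g] <- pmin(r$lengths[is_g], run_cap)
  v[is_c] <- -pmin(r$lengths[is_c], run_cap)
  rep.int(v, r$lengths)
}

#' Sliding-window mean of per-base scores
#'
#' @param scores Numeric/integer vector of per-base scores
#'   (see [g4_base_scores()]).
#' @param window Integer window width in bp (>= 1).
#' @return Numeric vector of length `length(scores) - window + 1` with the
#'   arithmetic mean of each window; empty (with a message) when the
#'   sequence is shorter than the window.
#' @export
g4_window_means <- function(scores, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("'window' must be an integer >= 1")
  n <- length(scores)
  if (n < window) {
    message(sprintf("sequence of length %d is shorter than window %d; no windows scored",
                    n, window))
    return(numeric(0))
  }
  cs <- c(0, cumsum(as.numeric(scores)))
  (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
}

#' Detect G-quadruplex-forming intervals in one sequence
#'
#' @description Runs the full detection on a single sequence: per-base
#' run-length scores, sliding-window means, selection of windows whose mean
#' is `>= threshold` (G-rich, reported on the "+" strand) or
#' `<= -threshold` (C-rich, i.e. a G tract on the "-" strand), merging of
#' overlapping or adjacent same-sign windows, and refinement of each merged
#' candidate: ends are extended to include any complete G run (positive) or
#' C run (negative) crossing the boundary, then terminal zero-scoring bases
#' are trimmed. The reported `score` is the mean per-base score over the
#' refined interval (signed on the forward strand); the most extreme window
#' mean among the selected windows is retained as `max_window_mean`.
#'
#' @inheritParams g4_base_scores
#' @param window Sliding window width in bp (default 25).
#' @param threshold Positive window-mean threshold (default 1.2); the
#'   comparison is inclusive.
#' @param seq_id Sequence name used for the returned ranges.
#' @param drop_n Drop hits whose refined interval contains an N
#'   (default `TRUE`; part of the post-detection cleaning).
#' @param dedupe Remove duplicated (start, end, strand) intervals
#'   (default `TRUE`).
#' @return A [GenomicRanges::GRanges] (1-based, closed intervals) sorted by
#'   start, with strand and metadata columns `score`, `max_window_mean` and
#'   `sequence` (forward-strand nucleotides of the interval).
#' @examples
#' g4_detect(strrep("G", 25))
#' g4_detect("GGGTTAGGGTTAGGGTTAGGGTTAG")
#' @export
g4_detect <- function(sequence, window = 25L, threshold = 1.2, run_cap = 4L,
                      seq_id = "seq", drop_n = TRUE, dedupe = TRUE,
                      mask_lowercase = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single positive number")
  }
  chars <- .seq_chars(sequence, mask_lowercase = mask_lowercase)
  sc <- .base_scores_chars(chars, run_cap = run_cap)
  n <- length(sc)
  si <- GenomeInfoDb::Seqinfo(seqnames = seq_id, seqlengths = n)
  empty <- GenomicRanges::GRanges(seqinfo = si)
  empty$score <- numeric(0); empty$max_window_mean <- numeric(0)
  empty$sequence <- character(0)
  wm <- suppressMessages(g4_window_means(sc, window))
  if (!length(wm)) return(empty)

  ## run bookkeeping for O(1) boundary refinement
  r <- rle(sc)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_of <- rep.int(seq_along(r$lengths), r$lengths)

  refine_one <- function(s, e, sgn) {
    if (sgn * sc[s] > 0) s <- run_start[run_of[s]]
    if (sgn * sc[e] > 0) e <- run_end[run_of[e]]
    while (s <= e && sc[s] == 0) s <- run_end[run_of[s]] + 1L
    while (e >= s && sc[e] == 0) e <- run_start[run_of[e]] - 1L
    if (s > e) return(NULL)
    c(s, e)
  }

  out <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) which(wm >= threshold) else which(wm <= -threshold)
    if (!length(sel)) next
    cand <- IRanges::reduce(IRanges::IRanges(start = sel, width = window))
    for (k in seq_along(cand)) {
      s0 <- IRanges::start(cand)[k]
      e0 <- IRanges::end(cand)[k]
      in_cand <- sel[sel >= s0 & sel <= e0 - window + 1L]
      mwm <- if (sgn > 0) max(wm[in_cand]) else min(wm[in_cand])
      se <- refine_one(s0, e0, sgn)
      if (is.null(se)) next
      score <- mean(sc[se[1L]:se[2L]])
      if (score == 0) next
      out[[length(out) + 1L]] <- data.frame(
        start = se[1L], end = se[2L],
        strand = if (sgn > 0) "+" else "-",
        score = score, max_window_mean = mwm
      )
    }
  }
  if (!length(out)) return(empty)
  d <- do.call(rbind, out)
  d$sequence <- substr(paste(chars, collapse = ""), d$start, d$end)
  if (drop_n) d <- d[!grepl("N", d$sequence, fixed = TRUE), , drop = FALSE]
  if (dedupe) d <- d[!duplicated(d[, c("start", "end", "strand")]), , drop = FALSE]
  d <- d[order(d$start, d$end, d$strand), , drop = FALSE]
  if (!nrow(d)) return(empty)
  GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(d$start, d$end),
    strand = d$strand,
    score = d$score,
    max_window_mean = d$max_window_mean,
    sequence = d$sequence,
    seqinfo = si
  )
}

#' Scan a genome for G-quadruplex-forming sequences
#'
#' @description Applies [g4_detect()] to every sequence of a FASTA file (or
#' an in-memory [Biostrings::DNAStringSet]) and summarises each sequence by
#' length, GC content, hit count and hit density per kbp.
#'
#' @param x Path to a FASTA file (optionally gzipped) or a
#'   [Biostrings::DNAStringSet] / named character vector.
#' @inheritParams g4_detect
#' @return An object of class `g4_scan_result`: a list with `hits` (a
#'   [GenomicRanges::GRanges] over all sequences) and `summary` (a
#'   data.frame with `seq_id`, `length_bp`, `gc_percent`, `n_hits`,
#'   `density_per_kbp`; densities at full precision, rounded only in file
#'   reports) plus the scan `parameters`.
#' @export
g4_scan <- function(x, window = 25L, threshold = 1.2, run_cap = 4L,
                    drop_n = TRUE, dedupe = TRUE, mask_lowercase = FALSE) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- if (mask_lowercase) {
      Biostrings::readBStringSet(x)
    } else {
      Biostrings::readDNAStringSet(x)
    }
  }
  seqs <- if (methods::is(x, "XStringSet")) {
    stats::setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    stop("'x' must be a FASTA path, an XStringSet or a named character vector")
  }
  if (!length(seqs)) stop("no sequences found (empty FASTA?)")
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence ID(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lens <- nchar(seqs)
  si <- GenomeInfoDb::Seqinfo(seqnames = ids, seqlengths = unname(lens))
  hit_list <- vector("list", length(seqs))
  gc <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- .seq_chars(seqs[[i]], mask_lowercase = mask_lowercase)
    gc[i] <- if (length(chars)) 100 * mean(chars %in% c("G", "C")) else 0
    h <- g4_detect(seqs[[i]], window = window, threshold = threshold,
                   run_cap = run_cap, seq_id = ids[i], drop_n = drop_n,
                   dedupe = dedupe, mask_lowercase = mask_lowercase)
    GenomeInfoDb::seqlevels(h) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(h) <- si
    hit_list[[i]] <- h
  }
  hits <- do.call(c, hit_list)
  n_hits <- as.integer(table(factor(as.character(GenomicRanges::seqnames(hits)),
                                    levels = ids)))
  summary <- data.frame(
    seq_id = ids,
    length_bp = as.integer(lens),
    gc_percent = gc,
    n_hits = n_hits,
    density_per_kbp = g4_density(n_hits, as.integer(lens)),
    row.names = NULL
  )
  structure(
    list(hits = hits, summary = summary,
         parameters = list(window = as.integer(window), threshold = threshold,
                           run_cap = as.integer(run_cap), drop_n = drop_n,
                           dedupe = dedupe, mask_lowercase = mask_lowercase)),
    class = "g4_scan_result"
  )
}

#' @export
print.g4_scan_result <- function(x, ...) {
  cat(sprintf("G4 scan: %d hits on %d sequence(s) (window %d, threshold %.2f)\n",
              length(x$hits), nrow(x$summary),
              x$parameters$window, x$parameters$threshold))
  s <- x$summary
  s$gc_percent <- round(s$gc_percent, 1)
  s$density_per_kbp <- round(s$density_per_kbp, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write detected hits as BED6
#'
#' Coordinates are converted to the 0-based half-open BED convention; the
#' BED score column is `round(|score| * 100)` and the name column a
#' sequential hit identifier.
#'
#' @param hits `GRanges` of hits from [g4_detect()]/[g4_scan()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_hits_bed <- function(hits, path) {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    name = sprintf("g4_%06d", seq_along(hits)),
    score = round(abs(hits$score) * 100),
    strand = as.character(GenomicRanges::strand(hits))
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write detected hits as a full-precision TSV
#'
#' @inheritParams export_hits_bed
#' @export
export_hits_tsv <- function(hits, path) {
  d <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    strand = as.character(GenomicRanges::strand(hits)),
    score = hits$score,
    max_window_mean = hits$max_window_mean,
    length = GenomicRanges::width(hits),
    sequence = hits$sequence
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-sequence scan summary (densities reported at 2 dp)
#'
#' @param scan A `g4_scan_result` from [g4_scan()].
#' @param path Output file path.
#' @export
export_scan_summary_tsv <- function(scan, path) {
  s <- scan$summary
  s$gc_percent <- round(s$gc_percent, 1)
  s$density_per_kbp <- round(s$density_per_kbp, 2)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
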