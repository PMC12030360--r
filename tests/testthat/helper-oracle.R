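# Naive reference implementation of the run-length scoring and detection,
# kept deliberately independent of the package internals: scores are walked
# base by base, every window mean is recomputed directly, and merging /
# refinement are done with plain position loops.

oracle_base_scores <- function(seq_str, run_cap = 4) {
  chars <- toupper(strsplit(seq_str, "", fixed = TRUE)[[1L]])
  n <- length(chars)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    b <- chars[i]
    if (b == "G" || b == "C") {
      j <- i
      while (j < n && chars[j + 1L] == b) j <- j + 1L
      val <- min(j - i + 1L, run_cap)
      out[i:j] <- if (b == "G") val else -val
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

oracle_window_means <- function(sc, window) {
  n <- length(sc)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1L),
         function(i) mean(sc[i:(i + window - 1L)]), numeric(1))
}

oracle_detect <- function(seq_str, window = 25L, threshold = 1.2, run_cap = 4) {
  window <- as.integer(window)
  sc <- oracle_base_scores(seq_str, run_cap)
  wm <- oracle_window_means(sc, window)
  n <- length(sc)
  rows <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) which(wm >= threshold) else which(wm <= -threshold)
    if (!length(sel)) next
    grp <- cumsum(c(1, diff(sel) > window))
    for (g in split(sel, grp)) {
      s <- min(g)
      e <- max(g) + window - 1L
      while (s > 1L && sgn * sc[s] > 0 && sgn * sc[s - 1L] > 0) s <- s - 1L
      while (e < n && sgn * sc[e] > 0 && sgn * sc[e + 1L] > 0) e <- e + 1L
      while (s <= e && sc[s] == 0) s <- s + 1L
      while (e >= s && sc[e] == 0) e <- e - 1L
      if (s > e) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, strand = if (sgn > 0) "+" else "-",
        score = mean(sc[s:e]))
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  d <- do.call(rbind, rows)
  d <- d[!duplicated(d[c("start", "end", "strand")]), , drop = FALSE]
  d <- d[order(d$start, d$end, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

random_dna <- function(n, probs = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

hits_as_df <- function(gr) {
  d <- data.frame(start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  score = gr$score)
  d <- d[order(d$start, d$end, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}
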