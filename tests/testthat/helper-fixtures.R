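# Shared fixture builders: everything is generated in code at test time.

# Write a minimal coordinate-sortable SAM file of read pairs.
# `pairs` is a data.frame with columns: qname, chrom, pos1, pos2 (1-based
# leftmost positions of the two mates), mapq1, mapq2, and optional
# logicals dup, improper. Reads are 50 bp (50M).
write_sam_pairs <- function(path, pairs, chroms = c(chr1 = 10000L)) {
  rl <- 50L
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  recs <- character(0)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    dup <- isTRUE(p$dup)
    improper <- isTRUE(p$improper)
    f1 <- 0x1L + 0x20L + 0x40L
    f2 <- 0x1L + 0x10L + 0x80L
    if (!improper) { f1 <- f1 + 0x2L; f2 <- f2 + 0x2L }
    if (dup) { f1 <- f1 + 0x400L; f2 <- f2 + 0x400L }
    tlen <- p$pos2 + rl - p$pos1
    seq1 <- paste(rep("A", rl), collapse = "")
    recs <- c(recs,
      paste(p$qname, f1, p$chrom, p$pos1, p$mapq1, paste0(rl, "M"),
            "=", p$pos2, tlen, seq1, "*", sep = "\t"),
      paste(p$qname, f2, p$chrom, p$pos2, p$mapq2, paste0(rl, "M"),
            "=", p$pos1, -tlen, seq1, "*", sep = "\t"))
  }
  pos <- as.integer(vapply(strsplit(recs, "\t"), `[`, "", 4))
  writeLines(c(hdr, recs[order(pos)]), path)
  path
}

simple_targets <- function(chrom = "chr1", starts, ends,
                           ids = paste0("T", seq_along(starts))) {
  data.frame(chrom = chrom, start = starts, end = ends, target_id = ids,
             stringsAsFactors = FALSE)
}

# Brute-force copy-state argmax: scalar loop, independent of the
# vectorized implementation (uses dnbinom/dpois directly).
brute_force_state <- function(c, f, mu, phi, states = c(0.001, 0.5, 1, 1.5, 2)) {
  ll <- vapply(states, function(s) {
    m <- f * s * mu
    d <- phi / f
    if (d <= 0) dpois(c, m, log = TRUE)
    else dnbinom(c, size = 1 / d, mu = m, log = TRUE)
  }, numeric(1))
  best <- max(ll)
  cand <- states[ll == best]
  if (1 %in% cand) return(1)
  cand[which.min(abs(cand - 1))]
}

# Independent Benjamini-Hochberg step-up, written as the textbook loop.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- min(1, running)
  }
  adj
}
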