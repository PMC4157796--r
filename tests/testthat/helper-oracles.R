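# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# two-sided two-library exact p-value through stats::pnbinom (the conditional
# distribution y | x is NegBinom(size = x + 1, prob = N1/(N1+N2));
# conditioning is on the larger count, as in the implementation's contract)
oracle_ac_pvalue <- function(x, y, N1, N2) {
  if (y > x) { t <- x; x <- y; y <- t; t <- N1; N1 <- N2; N2 <- t }
  q <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = q)
  upper <- 1 - pnbinom(y - 1, size = x + 1, prob = q)
  min(1, 2 * min(lower, upper))
}

# direct summation of the conditional pmf (log-space factorials)
oracle_ac_pmf <- function(y, x, N1, N2) {
  exp(lchoose(x + y, y) + (x + 1) * (log(N1) - log(N1 + N2)) +
        y * (log(N2) - log(N1 + N2)))
}

# brute-force substring search for transcript mapping
oracle_scan_tag <- function(tag, transcripts) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  out <- list()
  for (tx in names(transcripts)) {
    for (pat in c("+" = tag, "-" = rc)) {
      p <- gregexpr(pat, transcripts[[tx]], fixed = TRUE)[[1]]
      # gregexpr misses overlapping matches; step through manually
      hits <- integer(0)
      from <- 1
      while (from <= nchar(transcripts[[tx]])) {
        h <- regexpr(pat, substr(transcripts[[tx]], from,
                                 nchar(transcripts[[tx]])), fixed = TRUE)
        if (h < 0) break
        hits <- c(hits, from + h - 1)
        from <- from + h
      }
      if (length(hits))
        out[[length(out) + 1]] <- data.frame(
          tag = tag, transcript = tx, start = hits,
          strand = if (pat == tag) "+" else "-", stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# minimal Hamming distance of tag against a reference allowing the tag to
# slide along references up to 2 nt longer
oracle_min_mismatch <- function(tag, refs) {
  best <- Inf; best_id <- NA
  for (id in sort(names(refs))) {
    r <- chartr("Uu", "Tt", toupper(refs[[id]]))
    lt <- nchar(tag); lr <- nchar(r)
    if (lr < lt || lr > lt + 2) next
    for (off in 0:(lr - lt)) {
      mm <- sum(strsplit(toupper(tag), "")[[1]] !=
                  strsplit(substr(r, off + 1, off + lt), "")[[1]])
      if (mm < best) { best <- mm; best_id <- id }
    }
  }
  list(id = best_id, mismatches = best)
}

# reverse complement shorthand
rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# random ACGT sequence
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
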