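#' Collapsed small-RNA tag library
#'
#' Container for a library of unique 18-30 nt small-RNA tags with counts and
#' the library's clean-read total. The clean total is recorded independently
#' of the retained tag counts: it is the denominator of the reads-per-million
#' normalisation and generally exceeds the sum of retained miRNA tag counts.
#'
#' @param name Library name.
#' @param counts Named integer vector: tag sequence -> count (>= 1).
#' @param clean_total Total clean reads of the library (> 0).
#' @return An object of class `tag_library`: a list with elements `name`,
#'   `tags` (named integer vector) and `clean_total`.
#' @export
#' @examples
#' tag_library("demo", c(TGACAGAAGAGAGTGAGCACA = 3L), clean_total = 10)
tag_library <- function(name, counts, clean_total) {
  counts <- counts[order(names(counts))]
  stopifnot(is.numeric(counts), all(counts >= 1),
            length(clean_total) == 1, clean_total > 0)
  lens <- nchar(names(counts))
  if (length(counts) && (any(lens < 18) || any(lens > 30)))
    stop("tag lengths must be within [18, 30]")
  if (length(counts)) .check_nt(names(counts))
  structure(list(name = name,
                 tags = setNames(as.integer(counts), names(counts)),
                 clean_total = as.integer(clean_total)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d unique tags, %s tagged reads, clean total %s\n",
              x$name, length(x$tags),
              format(sum(x$tags), big.mark = ","),
              format(x$clean_total, big.mark = ",")))
  invisible(x)
}

# locate the 3' adapter in one read; the adapter prefix is matched against
# every read suffix with <= max_mismatch mismatches and overlap >= min_overlap.
# Returns the 1-based position where the adapter starts, or 0L if absent.
.find_adapter <- function(seq, adapter, min_overlap = 6L, max_mismatch = 1L) {
  n <- nchar(seq); la <- nchar(adapter)
  sv <- strsplit(seq, "")[[1]]; av <- strsplit(adapter, "")[[1]]
  for (p in seq_len(n)) {
    ov <- min(n - p + 1L, la)
    if (ov < min_overlap) break
    mm <- sum(sv[p:(p + ov - 1L)] != av[seq_len(ov)])
    if (mm <= max_mismatch) return(p)
  }
  0L
}

#' Clean raw small-RNA reads
#'
#' Applies the standard small-RNA cleaning cascade: 3' adapter trimming, then
#' rejection of adapter-contaminated reads (adapter at the read start, a 5'
#' adapter hit, or nothing left after trimming), low-quality reads (mean
#' Phred below `min_mean_qual`; skipped when no qualities are available, as
#' for FASTA input), reads containing N, poly(A) reads, and reads outside the
#' 18-30 nt length window. Checks are applied in that order and each read is
#' rejected for the first failing rule, so the rejection tally plus the
#' retained count partitions the input.
#'
#' @param reads Data.frame with columns `id`, `seq` and optionally `qual`
#'   (Sanger Phred+33 strings), as returned by [read_fastq()].
#' @param adapter3 3' adapter sequence to trim; `NULL` disables trimming.
#' @param adapter5 Optional 5' adapter; reads starting with it are rejected.
#' @param min_mean_qual Minimum mean Phred quality over the trimmed read.
#' @param polya_frac Reject when at least this fraction of the trimmed read
#'   is A.
#' @param min_len,max_len Retained length window after trimming.
#' @param min_overlap,max_mismatch Adapter matching parameters: minimum
#'   read/adapter overlap and mismatches tolerated in the overlap.
#' @return A list with `reads` (the surviving reads, trimmed, input order)
#'   and `tally`, a named integer vector with elements `low_quality`,
#'   `poly_a`, `oversize`, `undersize`, `adapter_contaminated`, `n_bases`
#'   and `retained`.
#' @export
filter_raw_reads <- function(reads,
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             adapter5 = NULL,
                             min_mean_qual = 20,
                             polya_frac = 0.8,
                             min_len = 18L, max_len = 30L,
                             min_overlap = 6L, max_mismatch = 1L) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (!is.null(adapter3) && !nzchar(adapter3))
    stop("empty adapter sequence; pass NULL to disable trimming")
  if (!is.null(adapter5) && !nzchar(adapter5))
    stop("empty adapter sequence; pass NULL to disable trimming")
  tally <- setNames(integer(7),
                    c("low_quality", "poly_a", "oversize", "undersize",
                      "adapter_contaminated", "n_bases", "retained"))
  n <- nrow(reads)
  if (n == 0)
    return(list(reads = reads, tally = tally))
  has_qual <- "qual" %in% names(reads)
  seqs <- toupper(reads$seq)
  quals <- if (has_qual) reads$qual else rep(NA_character_, n)
  keep <- logical(n)
  out_seq <- character(n); out_qual <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[i]; q <- quals[i]
    if (!is.null(adapter3)) {
      p <- .find_adapter(s, toupper(adapter3), min_overlap, max_mismatch)
      if (p == 1L) { tally["adapter_contaminated"] <- tally["adapter_contaminated"] + 1L; next }
      if (p > 1L) {
        s <- substr(s, 1L, p - 1L)
        if (!is.na(q)) q <- substr(q, 1L, p - 1L)
      }
    }
    if (!is.null(adapter5) && startsWith(s, toupper(adapter5))) {
      tally["adapter_contaminated"] <- tally["adapter_contaminated"] + 1L; next
    }
    if (!is.na(q) && nzchar(q)) {
      if (mean(utf8ToInt(q) - 33L) < min_mean_qual) {
        tally["low_quality"] <- tally["low_quality"] + 1L; next
      }
    }
    nc <- nchar(s)
    if (grepl("N", s, fixed = TRUE)) { tally["n_bases"] <- tally["n_bases"] + 1L; next }
    if (nc > 0 &&
        lengths(regmatches(s, gregexpr("A", s, fixed = TRUE))) / nc >= polya_frac) {
      tally["poly_a"] <- tally["poly_a"] + 1L; next
    }
    if (nc < min_len) { tally["undersize"] <- tally["undersize"] + 1L; next }
    if (nc > max_len) { tally["oversize"] <- tally["oversize"] + 1L; next }
    keep[i] <- TRUE
    out_seq[i] <- s; out_qual[i] <- q
  }
  tally["retained"] <- sum(keep)
  res <- data.frame(id = reads$id[keep], seq = out_seq[keep],
                    stringsAsFactors = FALSE)
  if (has_qual) res$qual <- out_qual[keep]
  list(reads = res, tally = tally)
}

#' Collapse clean reads to unique tags
#'
#' @param reads Character vector of clean read sequences, or a data.frame
#'   with a `seq` column (the output of [filter_raw_reads()]).
#' @param name Library name.
#' @param clean_total Clean-read total to record; defaults to the number of
#'   input reads. Supply the library's full clean total when the input reads
#'   are only the retained subset.
#' @return A [tag_library()].
#' @export
collapse_tags <- function(reads, name, clean_total = NULL) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (is.null(clean_total)) clean_total <- length(seqs)
  counts <- table(seqs)
  tag_library(name, setNames(as.integer(counts), names(counts)), clean_total)
}

#' Length distribution of a tag library
#'
#' @param lib A [tag_library()].
#' @return Data.frame with columns `length`, `reads` (total read count at
#'   that length) and `unique` (unique tags), restricted to lengths present.
#' @export
length_distribution <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  if (!length(lib$tags))
    return(data.frame(length = integer(), reads = integer(),
                      unique = integer()))
  len <- nchar(names(lib$tags))
  agg <- rowsum(data.frame(reads = unname(lib$tags), unique = 1L), len)
  data.frame(length = as.integer(rownames(agg)),
             reads = as.integer(agg$reads),
             unique = as.integer(agg$unique))
}

#' Write a cleaning report
#'
#' @param tally Named tally from [filter_raw_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(tally, path) {
  write.table(data.frame(reason = names(tally), reads = unname(tally)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
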