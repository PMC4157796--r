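#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector, uppercase with U normalised to T. Headers are truncated
#' at the first whitespace (miRBase-style `>id description` headers are
#' tolerated).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # read as B (not DNA) strings so U-containing miRBase references survive
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  out <- .norm_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read reads from a FASTQ file
#'
#' Reads a Sanger (Phred+33) FASTQ file into the raw-read data.frame used by
#' [filter_raw_reads()].
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id`, `seq` and `qual` (quality string).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = toupper(as.character(ss)),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Write a FASTQ file
#'
#' @param reads Data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Write a tag library as collapsed FASTA
#'
#' One entry per unique tag with headers `>tag<i>_x<count>`, the conventional
#' collapsed small-RNA format.
#'
#' @param lib A [tag_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  seqs <- names(lib$tags)
  hdr <- sprintf("tag%d_x%d", seq_along(seqs), unname(lib$tags))
  write_fasta(setNames(seqs, hdr), path)
}

#' Write a tag library as a two-column TSV
#'
#' Columns `sequence` and `count`; the clean-read total is stored on a
#' `# clean_total=` comment line so the file round-trips.
#'
#' @param lib A [tag_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# clean_total=%d", lib$clean_total), con)
  writeLines("sequence\tcount", con)
  if (length(lib$tags))
    writeLines(paste(names(lib$tags), unname(lib$tags), sep = "\t"), con)
  invisible(path)
}

#' Read a tag library from a two-column TSV
#'
#' @param path Path written by [write_tag_tsv()].
#' @param name Library name; defaults to the file base name.
#' @return A [tag_library()].
#' @export
read_tag_tsv <- function(path, name = NULL) {
  lines <- readLines(path)
  total <- NA_integer_
  hdr <- grep("^# clean_total=", lines)
  if (length(hdr))
    total <- as.integer(sub("^# clean_total=", "", lines[hdr[1]]))
  df <- read.delim(text = lines[!grepl("^#", lines)],
                   stringsAsFactors = FALSE)
  counts <- setNames(as.integer(df$count), df$sequence)
  if (is.na(total)) total <- sum(counts)
  tag_library(if (is.null(name)) basename(path) else name, counts, total)
}

#' Load a reference sequence set
#'
#' Reads a FASTA reference (structural ncRNA or mature miRNA set), normalises
#' U to T and checks identifier uniqueness.
#'
#' @param path Path to a FASTA file.
#' @param name Set name, e.g. `"rRNA"` or `"mature_miRNA"`.
#' @return Named character vector with attribute `set_name`.
#' @export
read_reference_set <- function(path, name) {
  seqs <- read_fasta(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate identifiers in reference set '", name, "'")
  if (any(nchar(seqs) == 0))
    stop("empty sequence in reference set '", name, "'")
  attr(seqs, "set_name") <- name
  seqs
}
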