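#' Map tags to transcripts by exact full-length match
#'
#' Finds every exact, full-length occurrence of each tag in a transcript set,
#' on either strand. Coordinates are 1-based and always refer to the leftmost
#' transcript position of the match on the forward strand.
#'
#' @param tags Character vector of tag sequences.
#' @param transcripts Named character vector of transcript sequences (or a
#'   `DNAStringSet`).
#' @return Data.frame with columns `tag`, `transcript`, `start`, `strand`.
#' @export
map_tags_to_transcripts <- function(tags, transcripts) {
  if (!methods::is(transcripts, "DNAStringSet")) {
    stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  tags <- unique(.norm_seq(tags))
  hit <- function(tag, strand) {
    pat <- if (strand == "+") tag else .revcomp(tag)
    m <- Biostrings::vmatchPattern(pat, transcripts)
    st <- Biostrings::startIndex(m)
    idx <- which(lengths(st) > 0)
    if (!length(idx)) return(NULL)
    do.call(rbind, lapply(idx, function(i) {
      data.frame(tag = tag, transcript = names(transcripts)[i],
                 start = st[[i]], strand = strand,
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, c(lapply(tags, hit, strand = "+"),
                          lapply(tags, hit, strand = "-")))
  if (is.null(res))
    res <- data.frame(tag = character(), transcript = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  res[order(res$tag, res$transcript, res$start), , drop = FALSE]
}

#' Classify a tag against structural ncRNA references
#'
#' A tag matching a reference entry (exact substring, either strand) is
#' assigned that reference set's class. Sets are checked in precedence order
#' `rRNA > tRNA > snRNA > snoRNA > other_ncRNA`; the first matching set wins.
#'
#' @param tags Character vector of tag sequences.
#' @param ref_sets Named list of reference sets (named character vectors, as
#'   from [read_reference_set()]); list names are the class labels.
#' @return Character vector of classes, `"unannotated"` where nothing
#'   matched.
#' @export
classify_ncrna <- function(tags,
                           ref_sets) {
  order_pref <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_ncRNA")
  sets <- intersect(order_pref, names(ref_sets))
  sets <- c(sets, setdiff(names(ref_sets), order_pref))
  tags <- .norm_seq(tags)
  out <- rep("unannotated", length(tags))
  for (cls in sets) {
    refs <- .norm_seq(ref_sets[[cls]])
    todo <- which(out == "unannotated")
    if (!length(todo)) break
    for (i in todo) {
      tg <- tags[i]
      if (any(grepl(tg, refs, fixed = TRUE)) ||
          any(grepl(.revcomp(tg), refs, fixed = TRUE)))
        out[i] <- cls
    }
  }
  out
}

# minimum Hamming distance between tag and a reference, sliding the tag along
# references up to 2 nt longer; same-length references compared end to end
.best_offset_mismatch <- function(tag, ref) {
  lt <- nchar(tag); lr <- nchar(ref)
  if (lr < lt || lr > lt + 2L) return(Inf)
  tv <- strsplit(tag, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  best <- Inf
  for (off in 0:(lr - lt))
    best <- min(best, sum(tv != rv[(off + 1L):(off + lt)]))
  best
}

#' Match a tag against a mature miRNA reference set
#'
#' Ungapped comparison of the tag against every reference mature sequence of
#' identical length, or longer by at most 2 nt (the tag slides along the
#' longer reference; no indels). U/T equivalence is applied. Returns the
#' minimum-mismatch hit when it has at most `max_mismatch` mismatches, ties
#' broken by the lexicographically smallest reference identifier.
#'
#' @param tag A single tag sequence.
#' @param mature_ref Named character vector of mature miRNA sequences.
#' @param max_mismatch Mismatch allowance (default 2).
#' @return A list with `id` and `mismatches`, or `NULL` when no reference is
#'   within the allowance.
#' @export
match_conserved_mirna <- function(tag, mature_ref, max_mismatch = 2L) {
  tag <- .norm_seq(tag)
  refs <- .norm_seq(mature_ref)
  keep <- nchar(refs) >= nchar(tag) & nchar(refs) <= nchar(tag) + 2L
  refs <- refs[keep]
  if (!length(refs)) return(NULL)
  mm <- vapply(refs, .best_offset_mismatch, numeric(1), tag = tag)
  best <- min(mm)
  if (best > max_mismatch) return(NULL)
  ids <- sort(names(refs)[mm == best])
  list(id = ids[1], mismatches = as.integer(best))
}

#' Annotate a tag library through the classification cascade
#'
#' Applies the annotation cascade to every tag: structural ncRNA matching
#' first (Rfam/GenBank-style reference sets), then conserved-miRNA matching
#' against the mature reference with the mismatch allowance; the residue is
#' left `unannotated` for hairpin discovery. Transcript mapping is
#' annotational only and does not affect the class.
#'
#' @param lib A [tag_library()].
#' @param transcripts Named character vector of transcripts (optional; when
#'   supplied, per-tag transcript hit counts are reported).
#' @param ncrna_sets Named list of structural ncRNA reference sets.
#' @param mature_ref Named character vector of mature miRNA references.
#' @param max_mismatch Conserved-matching mismatch allowance (default 2).
#' @return Data.frame with one row per tag: `tag`, `count`, `class`,
#'   `best_match`, `mismatches`, `n_transcript_hits`.
#' @export
annotate_tags <- function(lib, transcripts = NULL, ncrna_sets = list(),
                          mature_ref = character(), max_mismatch = 2L) {
  stopifnot(inherits(lib, "tag_library"))
  tags <- names(lib$tags)
  cls <- if (length(ncrna_sets)) classify_ncrna(tags, ncrna_sets)
         else rep("unannotated", length(tags))
  best <- rep(NA_character_, length(tags))
  mm <- rep(NA_integer_, length(tags))
  if (length(mature_ref)) {
    todo <- which(cls == "unannotated")
    for (i in todo) {
      hit <- match_conserved_mirna(tags[i], mature_ref, max_mismatch)
      if (!is.null(hit)) {
        cls[i] <- "conserved_miRNA"
        best[i] <- hit$id
        mm[i] <- hit$mismatches
      }
    }
  }
  nhits <- rep(NA_integer_, length(tags))
  if (!is.null(transcripts)) {
    hits <- map_tags_to_transcripts(tags, transcripts)
    tab <- table(hits$tag)
    nhits <- as.integer(ifelse(tags %in% names(tab), tab[tags], 0L))
  }
  data.frame(tag = tags, count = unname(lib$tags), class = cls,
             best_match = best, mismatches = mm,
             n_transcript_hits = nhits, stringsAsFactors = FALSE)
}

# parse a miRNA family name (e.g. "ath-miR166a-5p" -> "MIR166")
.mirna_family <- function(ids) {
  pos <- regexpr("[mM][iI][rR]-?([0-9]+)", ids)
  out <- rep("UNKNOWN", length(ids))
  ok <- pos > 0
  if (any(ok)) {
    m <- regmatches(ids, pos)
    out[ok] <- paste0("MIR", sub("[mM][iI][rR]-?", "", m))
  }
  if (any(!ok))
    warning("unparseable miRNA family name(s): ",
            paste(unique(ids[!ok]), collapse = ", "))
  out
}

#' Aggregate conserved miRNA hits into families
#'
#' Family names are parsed from the reference identifiers (e.g. `pas-miR166a`
#' belongs to `MIR166`); unparseable identifiers go to family `UNKNOWN` with
#' a warning. Family totals are sums over member counts, and per-library
#' family shares (percent of all conserved reads) are reported.
#'
#' @param hits Data.frame with columns `mirna` (or `best_match`) and one or
#'   more count columns.
#' @param count_cols Names of the count columns (default: all numeric
#'   columns).
#' @param family Optional character vector of pre-assigned family names; when
#'   absent, families are parsed from the identifiers.
#' @return A list with `members` (input plus a `family` column) and
#'   `families` (per-family totals and `share_<col>` percentages).
#' @export
assign_families <- function(hits, count_cols = NULL, family = NULL) {
  if (!nrow(hits))
    return(list(members = cbind(hits, family = character(0)),
                families = data.frame(family = character(0))))
  idcol <- if ("mirna" %in% names(hits)) "mirna" else "best_match"
  if (is.null(count_cols))
    count_cols <- names(hits)[vapply(hits, is.numeric, logical(1))]
  fam <- if (is.null(family)) .mirna_family(hits[[idcol]]) else family
  members <- cbind(hits, family = fam, stringsAsFactors = FALSE)
  agg <- rowsum(hits[count_cols], fam)
  families <- data.frame(family = rownames(agg), agg, row.names = NULL,
                         stringsAsFactors = FALSE)
  for (cc in count_cols)
    families[[paste0("share_", cc)]] <-
      100 * families[[cc]] / sum(families[[cc]])
  list(members = members, families = families)
}
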