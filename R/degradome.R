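#' Target-site scoring weights
#'
#' Penalty weights of the plant miRNA:target complementarity score:
#' Watson-Crick pair 0, G:U wobble 0.5, mismatch 1, gapped position 2. Only
#' the total-score cap and the strict Watson-Crick requirement at miRNA
#' positions 10-11 (the cleavage site) are fixed rules; the weights follow
#' the dominant plant target-scoring convention and are configurable.
#'
#' @param gu,mismatch,gap Penalties per position.
#' @param max_score Maximum admissible total score.
#' @return Named list of weights.
#' @export
site_weights <- function(gu = 0.5, mismatch = 1, gap = 2, max_score = 4) {
  list(gu = gu, mismatch = mismatch, gap = gap, max_score = max_score)
}

#' Map degradome tags to transcript 5'-end signature profiles
#'
#' Each degradome tag (a ~20-21 nt 5'-end fragment tag) is matched perfectly
#' against the transcript sense strands; its count is added at the transcript
#' position of its 5'-most aligned base. Multi-mapping tags contribute to
#' every locus and are flagged.
#'
#' @param tags Named integer vector (tag sequence -> count) or character
#'   vector of tag sequences (counts of 1 each).
#' @param transcripts Named character vector of transcripts.
#' @return List of signature profiles, one per transcript with signal: each a
#'   data.frame with `pos`, `count`, `multimapped`.
#' @export
map_degradome_tags <- function(tags, transcripts) {
  if (is.null(names(tags))) {
    tb <- table(tags)
    tags <- setNames(as.integer(tb), names(tb))
  }
  txset <- Biostrings::DNAStringSet(transcripts)
  prof <- new.env(parent = emptyenv())
  for (tag in names(tags)) {
    m <- Biostrings::vmatchPattern(.norm_seq(tag), txset)
    st <- Biostrings::startIndex(m)
    idx <- which(lengths(st) > 0)
    nloci <- sum(lengths(st))
    for (i in idx) {
      key <- names(transcripts)[i]
      cur <- if (!is.null(prof[[key]])) prof[[key]] else
        data.frame(pos = integer(), count = integer(),
                   multimapped = logical())
      for (p in st[[i]]) {
        j <- match(p, cur$pos)
        if (is.na(j)) {
          cur <- rbind(cur, data.frame(pos = p, count = unname(tags[tag]),
                                       multimapped = nloci > 1L))
        } else {
          cur$count[j] <- cur$count[j] + unname(tags[tag])
          cur$multimapped[j] <- cur$multimapped[j] || nloci > 1L
        }
      }
      prof[[key]] <- cur
    }
  }
  out <- lapply(ls(prof), function(k) {
    df <- prof[[k]]
    df[order(df$pos), , drop = FALSE]
  })
  names(out) <- ls(prof)
  out
}

#' Score a miRNA against a target site
#'
#' The miRNA (5'->3') is aligned against the site (transcript sense strand)
#' read 3'->5', so miRNA position i faces the site base i positions from the
#' site 3' end. Aligned inputs may contain `-` for gaps (equal string
#' lengths); ungapped inputs must be the same length. The pairing string
#' marks Watson-Crick pairs `|`, G:U wobbles `o`, mismatches `x` and gaps
#' `-`. The site is rejected (returns `NULL`) when the total penalty exceeds
#' `weights$max_score` or when miRNA positions 10 or 11 are not strict
#' Watson-Crick pairs.
#'
#' @param mirna miRNA sequence, 5'->3' (may contain `-` when pre-aligned).
#' @param site Site sequence on the transcript sense strand, 5'->3'.
#' @param weights A [site_weights()] list.
#' @return List with `score` and `pairing` (5'->3' along the miRNA), or
#'   `NULL` when rejected.
#' @export
#' @examples
#' score_site("TGACAGAAGAGAGTGAGCACA",
#'            as.character(Biostrings::reverseComplement(
#'              Biostrings::DNAString("TGACAGAAGAGAGTGAGCACA"))))
score_site <- function(mirna, site, weights = site_weights()) {
  mirna <- gsub("U", "T", toupper(mirna)); site <- gsub("U", "T", toupper(site))
  .check_gap_nt <- function(x) {
    if (!grepl("^[ACGTN-]*$", x))
      stop("sequence contains non-nucleotide characters")
  }
  .check_gap_nt(mirna); .check_gap_nt(site)
  mv <- strsplit(mirna, "")[[1]]
  sv <- rev(strsplit(site, "")[[1]])   # 3'->5' along the site
  if (length(mv) != length(sv))
    stop("ungapped scoring requires equal lengths; align with '-' for gaps")
  score <- 0
  pairing <- character(length(mv))
  mpos <- 0L
  for (i in seq_along(mv)) {
    m <- mv[i]; t <- sv[i]
    if (m == "-" || t == "-") {
      score <- score + weights$gap
      pairing[i] <- "-"
      if (m != "-") mpos <- mpos + 1L
      if (m != "-" && mpos %in% c(10L, 11L)) return(NULL)
      next
    }
    mpos <- mpos + 1L
    cls <- if ((m == "A" && t == "T") || (m == "T" && t == "A") ||
               (m == "G" && t == "C") || (m == "C" && t == "G")) "|"
           else if ((m == "G" && t == "T") || (m == "T" && t == "G")) "o"
           else "x"
    if (mpos %in% c(10L, 11L) && cls != "|") return(NULL)
    score <- score + switch(cls, "|" = 0, "o" = weights$gu,
                            "x" = weights$mismatch)
    pairing[i] <- cls
  }
  if (score > weights$max_score) return(NULL)
  list(score = score, pairing = paste(pairing, collapse = ""))
}

#' Scan a transcript for admissible miRNA target sites
#'
#' Ungapped scan of every window of miRNA length along the transcript,
#' scored as in [score_site()]. Implemented in C++ for speed; agrees with a
#' window-by-window [score_site()] loop.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence (sense strand).
#' @param weights A [site_weights()] list.
#' @return Data.frame with `start`, `end`, `score`, `pairing`.
#' @export
scan_target_sites <- function(mirna, transcript, weights = site_weights()) {
  mirna <- .norm_seq(mirna); transcript <- .norm_seq(transcript)
  .check_nt(c(mirna, transcript), allow_n = TRUE)
  res <- .scan_sites_cpp(mirna, transcript, weights$max_score, weights$gu,
                         weights$mismatch)
  res$end <- if (nrow(res)) res$start + nchar(mirna) - 1L else integer(0)
  res[c("start", "end", "score", "pairing")]
}

#' Predicted slice position of a target alignment
#'
#' The cleavage position is the transcript coordinate of the base paired to
#' miRNA position 10 (counting from the miRNA 5' end); the phosphodiester
#' bond between the bases facing miRNA positions 10 and 11 is cut. For an
#' ungapped site `[s, s + L - 1]` and an L-nt miRNA this is `s + L - 10`.
#' Gapped alignments are resolved by walking the aligned strings.
#'
#' @param alignment List with `site_start` (1-based transcript start of the
#'   site) and either `mirna_len` (ungapped) or aligned strings
#'   `mirna_aligned` / `site_aligned` containing `-` for gaps (both 5'->3';
#'   the site string is walked from its 3' end, which faces miRNA position
#'   1).
#' @return 1-based transcript position.
#' @export
#' @examples
#' predict_slice_position(list(site_start = 101, mirna_len = 21))  # 112
predict_slice_position <- function(alignment) {
  s <- alignment$site_start
  if (!is.null(alignment$mirna_len) && is.null(alignment$mirna_aligned))
    return(s + alignment$mirna_len - 10L)
  mv <- strsplit(alignment$mirna_aligned, "")[[1]]
  sv <- rev(strsplit(alignment$site_aligned, "")[[1]])
  site_len <- sum(strsplit(alignment$site_aligned, "")[[1]] != "-")
  mpos <- 0L; spos <- 0L     # consumed miRNA / site bases from the site 3' end
  for (i in seq_along(mv)) {
    if (sv[i] != "-") spos <- spos + 1L
    if (mv[i] != "-") {
      mpos <- mpos + 1L
      if (mpos == 10L) {
        if (sv[i] == "-") stop("gap at miRNA position 10 is not allowed")
        return(s + site_len - spos)
      }
    }
  }
  stop("alignment shorter than 10 miRNA positions")
}

#' Classify a cleavage event by its t-plot category
#'
#' Category I: the slice-site abundance equals the transcript's maximum
#' signature (ties allowed). Category II: above the transcript's median
#' signature but below the maximum. Category III: at or below the median.
#' The median is computed over positions with at least one signature read.
#'
#' @param slice_pos Predicted slice position.
#' @param profile Signature profile of the transcript (data.frame `pos`,
#'   `count` as from [map_degradome_tags()]).
#' @return `"I"`, `"II"`, `"III"`, or `NA` when the profile has no read at
#'   the slice position (no event).
#' @export
categorize_event <- function(slice_pos, profile) {
  j <- match(slice_pos, profile$pos)
  if (is.na(j) || profile$count[j] < 1) return(NA_character_)
  ab <- profile$count[j]
  if (ab >= max(profile$count)) return("I")
  if (ab > median(profile$count)) return("II")
  "III"
}

#' Call miRNA cleavage targets from degradome profiles
#'
#' Scans every transcript for admissible sites of every miRNA
#' ([scan_target_sites()]), predicts each site's slice position and emits a
#' cleavage event when the degradome profile carries at least `min_reads` at
#' that position. At most one event is kept per (miRNA, transcript, slice
#' position); overlapping alternatives resolve to the lowest score, then the
#' leftmost site. Events are sorted by category then descending slice
#' abundance.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcripts.
#' @param profiles Signature profiles from [map_degradome_tags()].
#' @param weights A [site_weights()] list.
#' @param min_reads Minimum degradome reads at the slice position.
#' @return Data.frame of events: `mirna`, `transcript`, `site_start`,
#'   `site_end`, `score`, `pairing`, `slice_pos`, `slice_abundance`,
#'   `category`.
#' @export
call_targets <- function(mirnas, transcripts, profiles,
                         weights = site_weights(), min_reads = 1L) {
  rows <- list()
  for (mi in names(mirnas)) {
    L <- nchar(mirnas[[mi]])
    for (tx in names(profiles)) {
      if (is.null(transcripts[[tx]])) next
      sites <- scan_target_sites(mirnas[[mi]], transcripts[[tx]], weights)
      if (!nrow(sites)) next
      prof <- profiles[[tx]]
      sites$slice_pos <- sites$start + L - 10L
      j <- match(sites$slice_pos, prof$pos)
      ab <- ifelse(is.na(j), 0L, prof$count[j])
      keep <- ab >= min_reads
      if (!any(keep)) next
      sites <- sites[keep, , drop = FALSE]
      sites$slice_abundance <- ab[keep]
      # one event per slice position: lowest score, then leftmost site
      sites <- sites[order(sites$slice_pos, sites$score, sites$start), ,
                     drop = FALSE]
      sites <- sites[!duplicated(sites$slice_pos), , drop = FALSE]
      sites$category <- vapply(sites$slice_pos, categorize_event,
                               character(1), profile = prof)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, transcript = tx,
        site_start = sites$start, site_end = sites$end,
        score = sites$score, pairing = sites$pairing,
        slice_pos = sites$slice_pos,
        slice_abundance = sites$slice_abundance,
        category = sites$category, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), transcript = character(),
               site_start = integer(), site_end = integer(),
               score = numeric(), pairing = character(),
               slice_pos = integer(), slice_abundance = integer(),
               category = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(match(out$category, c("I", "II", "III")),
            -out$slice_abundance), , drop = FALSE]
}

#' T-plot series of a transcript
#'
#' The full signature profile of one transcript with the slice position(s)
#' flagged, ready for plotting or TSV export.
#'
#' @param profile Signature profile (data.frame `pos`, `count`).
#' @param slice_pos Integer vector of slice positions to flag.
#' @return Data.frame `pos`, `count`, `is_slice`.
#' @export
tplot_series <- function(profile, slice_pos = integer(0)) {
  data.frame(pos = profile$pos, count = profile$count,
             is_slice = profile$pos %in% slice_pos)
}

#' Draw a t-plot
#'
#' Degradome signature abundance along one transcript, with predicted slice
#' positions highlighted.
#'
#' @param profile Signature profile of the transcript.
#' @param slice_pos Slice positions to highlight.
#' @param main Plot title.
#' @return The [tplot_series()] data.frame, invisibly.
#' @export
plot_tplot <- function(profile, slice_pos = integer(0), main = "t-plot") {
  ser <- tplot_series(profile, slice_pos)
  graphics::plot(ser$pos, ser$count, type = "h", lwd = 2,
                 col = ifelse(ser$is_slice, "red", "grey40"),
                 xlab = "transcript position", ylab = "degradome reads",
                 main = main)
  if (any(ser$is_slice))
    graphics::points(ser$pos[ser$is_slice], ser$count[ser$is_slice],
                     col = "red", pch = 17)
  invisible(ser)
}

#' Render an alignment text block for a cleavage event
#'
#' Target site over miRNA with `|` (Watson-Crick), `o` (G:U) and `x`
#' (mismatch) marks; the miRNA is written 3'->5' under the site so
#' complementary bases line up.
#'
#' @param event One row of [call_targets()] output.
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcripts.
#' @return Character vector of three lines.
#' @export
format_alignment <- function(event, mirnas, transcripts) {
  site <- substr(transcripts[[event$transcript]], event$site_start,
                 event$site_end)
  marks <- paste(rev(strsplit(event$pairing, "")[[1]]), collapse = "")
  mseq <- paste(rev(strsplit(.norm_seq(mirnas[[event$mirna]]), "")[[1]]),
                collapse = "")
  c(sprintf("target 5'-%s-3'  (%s:%d-%d, slice %d, category %s)",
            site, event$transcript, event$site_start, event$site_end,
            event$slice_pos, event$category),
    sprintf("          %s", marks),
    sprintf("miRNA  3'-%s-5'  (%s, score %.1f)", mseq, event$mirna,
            event$score))
}
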