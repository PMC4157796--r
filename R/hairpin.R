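#' Hairpin acceptance thresholds
#'
#' Numeric criteria a candidate precursor must satisfy, following the
#' community's strict annotation conventions for plant miRNAs: mature length
#' 20-23 nt, at most 4 duplex mismatches and 2 bulged nucleotides in the
#' miRNA/miRNA* duplex, folding energy at most -18 kcal/mol, precursor
#' length 60-300 nt, and a single major (hairpin) loop. All configurable.
#'
#' @param mature_len Length window for the mature sequence.
#' @param max_mismatch Maximum miRNA/miRNA* duplex mismatches.
#' @param max_bulge Maximum bulged (asymmetric unpaired) nucleotides.
#' @param max_mfe Maximum (least negative) folding energy, kcal/mol.
#' @param precursor_len Precursor length window, nt.
#' @return Named list of thresholds.
#' @export
hairpin_thresholds <- function(mature_len = c(20L, 23L), max_mismatch = 4,
                               max_bulge = 2, max_mfe = -18,
                               precursor_len = c(60L, 300L)) {
  list(mature_len = mature_len, max_mismatch = max_mismatch,
       max_bulge = max_bulge, max_mfe = max_mfe,
       precursor_len = precursor_len)
}

#' Excise candidate precursor windows around a transcript hit
#'
#' Two windows per hit, covering the cases where the tag sits near the 5' end
#' of its precursor (downstream flank) or near the 3' end (upstream flank),
#' clipped to the transcript bounds and deduplicated.
#'
#' @param hit List or one-row data.frame with `transcript`, `start`, `end`
#'   (1-based, inclusive, on the transcript forward strand).
#' @param transcripts Named character vector of transcript sequences.
#' @param flank Flanking length in nt (default 150).
#' @param pad Extra padding on the tag-proximal side of each window (default
#'   0), so the stem below the miRNA/miRNA* duplex is captured even when the
#'   tag sits at the precursor edge.
#' @return Data.frame with columns `transcript`, `start`, `end`.
#' @export
#' @examples
#' tx <- c(t1 = strrep("ACGT", 250))
#' excise_precursor_windows(list(transcript = "t1", start = 200, end = 220),
#'                          tx, flank = 150)
excise_precursor_windows <- function(hit, transcripts, flank = 150L,
                                     pad = 0L) {
  n <- nchar(transcripts[[hit$transcript]])
  if (is.null(n) || is.na(n)) stop("unknown transcript: ", hit$transcript)
  if (hit$start < 1 || hit$end > n || hit$start > hit$end)
    stop("hit coordinates outside transcript bounds")
  w <- rbind(c(max(1L, hit$start - pad), min(n, hit$end + flank)),
             c(max(1L, hit$start - flank), min(n, hit$end + pad)))
  w <- unique(w)
  data.frame(transcript = hit$transcript, start = as.integer(w[, 1]),
             end = as.integer(w[, 2]), stringsAsFactors = FALSE)
}

# ---- structure bookkeeping -------------------------------------------------

# nearest paired position at or inside the mature, scanning from `from`
# towards `towards`
.nearest_paired <- function(pt, from, towards) {
  step <- if (towards >= from) 1L else -1L
  for (i in seq(from, towards, by = step)) if (pt[i] > 0) return(i)
  NA_integer_
}

# star interval under the 2-nt 3' overhang rule: the star 5' end pairs with
# mature position m2-2 and the star 3' end extends 2 nt beyond the partner of
# m1.  Unpaired anchor positions fall back to the nearest paired mature
# position with the offset carried over.
.star_interval <- function(pt, m1, m2, n) {
  a <- .nearest_paired(pt, m2 - 2L, m1)
  b <- .nearest_paired(pt, m1, m2)
  if (is.na(a) || is.na(b)) return(NULL)
  lo <- pt[a] - ((m2 - 2L) - a)
  hi <- pt[b] + (b - m1) + 2L
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  lo <- max(1L, lo); hi <- min(n, hi)
  c(lo, hi)
}

# number of hairpin loops (innermost base pairs) within [lo, hi]
.n_hairpin_loops <- function(pt, lo, hi) {
  cnt <- 0L
  for (i in lo:hi) {
    j <- pt[i]
    if (j > i && j <= hi) {
      inner <- if (j - i > 1) pt[(i + 1):(j - 1)] else integer(0)
      if (all(inner == 0)) cnt <- cnt + 1L
    }
  }
  cnt
}

# duplex statistics between the mature [m1, m2] and its pairing region:
# symmetric unpaired positions count as mismatches (one per position pair),
# the asymmetric excess as bulged nucleotides
.duplex_stats <- function(pt, m1, m2) {
  part <- pt[m1:m2]
  paired <- part[part > 0]
  if (!length(paired))
    return(list(arm = NA_character_, mismatches = Inf, bulges = Inf,
                span = NULL))
  arm <- if (all(paired > m2)) "5p" else if (all(paired < m1)) "3p" else NA
  smin <- min(paired); smax <- max(paired)
  u_m <- sum(part == 0)
  u_s <- (smax - smin + 1L) - length(paired)
  list(arm = arm, mismatches = min(u_m, u_s), bulges = abs(u_m - u_s),
       span = c(smin, smax))
}

# extend [lo, hi] outwards along the enclosing stem: repeatedly absorb the
# nearest enclosing base pair while the unpaired gap stays small, so the
# walk follows the stem below the duplex but stops at multiloop junctions
.enclosing_stem <- function(pt, lo, hi, max_gap = 8L) {
  repeat {
    k <- 0L
    if (lo > 1L) for (t in (lo - 1L):1L) if (pt[t] > hi) { k <- t; break }
    if (k == 0L) break
    gap <- (lo - 1L - k) + (pt[k] - hi - 1L)
    if (gap > max_gap) break
    lo <- k; hi <- pt[k]
  }
  c(lo, hi)
}

# ---- candidate evaluation --------------------------------------------------

#' Evaluate a precursor window as a miRNA hairpin candidate
#'
#' Folds the window, locates the mature tag, derives the miRNA* (star)
#' partner under the 2-nt 3' overhang rule, trims the window to the enclosing
#' stem-loop, refolds the trimmed precursor, and applies the acceptance
#' criteria of [hairpin_thresholds()]. The candidate passes iff all flags are
#' true.
#'
#' @param window_seq Window sequence.
#' @param mature_start 1-based start of the mature tag within the window.
#' @param mature_len Length of the mature tag.
#' @param thresholds A [hairpin_thresholds()] list.
#' @param engine Folding engine, see [fold_rna()].
#' @param transcript,window_start Provenance: transcript identifier and the
#'   window's 1-based start on it (for reporting precursor coordinates).
#' @return An object of class `hairpin_candidate`: list with `transcript`,
#'   `precursor` (start/end on the transcript, sequence), `fold`
#'   ([fold_rna()] result of the precursor), `mature` (sequence, arm,
#'   start within the precursor), `star` (sequence and interval, or `NULL`),
#'   `stats` (duplex mismatches, bulged nucleotides), `flags` (named
#'   logicals) and `pass`.
#' @export
evaluate_candidate <- function(window_seq, mature_start, mature_len,
                               thresholds = hairpin_thresholds(),
                               engine = "auto",
                               transcript = NA_character_,
                               window_start = 1L) {
  window_seq <- .norm_seq(window_seq)
  stopifnot(mature_start >= 1,
            mature_start + mature_len - 1 <= nchar(window_seq))
  seq <- window_seq
  off <- 0L          # offset of `seq` within the original window
  fold <- star <- stats <- NULL
  for (pass_i in 1:2) {
    fold <- fold_rna(seq, engine = engine)
    pt <- pair_table(fold$structure)
    n <- nchar(seq)
    m1 <- mature_start - off
    m2 <- m1 + mature_len - 1L
    stats <- .duplex_stats(pt, m1, m2)
    star_iv <- if (!is.na(stats$arm)) .star_interval(pt, m1, m2, n) else NULL
    if (pass_i == 2 || is.null(star_iv)) break
    lo <- min(m1, star_iv[1]); hi <- max(m2, star_iv[2])
    stem <- .enclosing_stem(pt, lo, hi)
    if (stem[1] == 1L && stem[2] == n) break    # nothing to trim
    if (stem[2] <= stem[1]) break
    seq <- substr(seq, stem[1], stem[2])
    off <- off + stem[1] - 1L
  }
  pt <- pair_table(fold$structure)
  n <- nchar(seq)
  m1 <- mature_start - off
  m2 <- m1 + mature_len - 1L
  star_iv <- if (!is.na(stats$arm)) .star_interval(pt, m1, m2, n) else NULL
  star_seq <- if (!is.null(star_iv) &&
                  (star_iv[2] < m1 || star_iv[1] > m2))
    substr(seq, star_iv[1], star_iv[2]) else NULL
  loops <- if (!is.na(stats$arm)) .n_hairpin_loops(pt, 1L, n) else NA_integer_
  th <- thresholds
  flags <- c(
    mature_length = mature_len >= th$mature_len[1] &&
                    mature_len <= th$mature_len[2],
    arm = !is.na(stats$arm),
    duplex_mismatches = is.finite(stats$mismatches) &&
                        stats$mismatches <= th$max_mismatch,
    duplex_bulges = is.finite(stats$bulges) && stats$bulges <= th$max_bulge,
    mfe = fold$mfe <= th$max_mfe,
    single_loop = !is.na(loops) && loops == 1L,
    precursor_length = n >= th$precursor_len[1] && n <= th$precursor_len[2],
    star_defined = !is.null(star_seq)
  )
  structure(list(
    transcript = transcript,
    precursor = list(start = window_start + off,
                     end = window_start + off + n - 1L,
                     sequence = seq),
    fold = fold,
    mature = list(sequence = substr(seq, m1, m2),
                  arm = stats$arm, start = m1),
    star = if (!is.null(star_seq))
      list(sequence = star_seq, start = star_iv[1], end = star_iv[2])
      else NULL,
    stats = list(mismatches = stats$mismatches, bulges = stats$bulges,
                 n_loops = loops),
    flags = flags,
    pass = all(flags)
  ), class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("hairpin_candidate %s:%d-%d (%s arm, mfe %.1f, %s)\n",
              x$transcript, x$precursor$start, x$precursor$end,
              if (is.na(x$mature$arm)) "?" else x$mature$arm, x$fold$mfe,
              if (x$pass) "PASS" else paste("fail:",
                paste(names(x$flags)[!x$flags], collapse = ","))))
  invisible(x)
}

#' Star (miRNA*) read evidence for a candidate
#'
#' Looks up the candidate's star sequence in the tag libraries. A star count
#' of zero does not invalidate the candidate; candidates whose star was
#' actually sequenced carry the stronger 3p:5p evidence.
#'
#' @param candidate A [evaluate_candidate()] result.
#' @param libs List of [tag_library()] objects.
#' @return A list with `sequence` and per-library `counts`, or `NULL` when
#'   the candidate has no valid duplex partner.
#' @export
detect_star <- function(candidate, libs) {
  if (is.null(candidate$star)) return(NULL)
  seqs <- candidate$star$sequence
  counts <- vapply(libs, function(l) {
    cnt <- l$tags[seqs]
    ifelse(is.na(cnt), 0L, cnt)
  }, integer(1))
  names(counts) <- vapply(libs, `[[`, character(1), "name")
  list(sequence = seqs, counts = counts)
}

#' Discover novel miRNA candidates from unannotated transcript-mapped tags
#'
#' For every transcript hit of every unannotated tag, excises the two
#' precursor windows, evaluates each as a hairpin and keeps passing
#' candidates. When both windows around a hit pass, the window with the
#' higher |mfe| per nucleotide is kept; candidates are deduplicated by
#' (transcript, precursor interval).
#'
#' @param hits Data.frame of transcript hits (`tag`, `transcript`, `start`,
#'   `strand`) as from [map_tags_to_transcripts()]; only forward-strand hits
#'   are considered (transcripts are sense-oriented contigs).
#' @param transcripts Named character vector of transcripts.
#' @param libs List of [tag_library()] objects for mature/star counts.
#' @param flank Window flank, nt.
#' @param pad Tag-proximal window padding, nt (see
#'   [excise_precursor_windows()]).
#' @param thresholds A [hairpin_thresholds()] list.
#' @param engine Folding engine.
#' @return Data.frame report (one row per candidate: mature sequence and
#'   arm, precursor coordinates and mfe, star sequence, per-library mature
#'   and star counts, flags, pass) with the full `hairpin_candidate` objects
#'   in `attr(, "candidates")`.
#' @export
discover_hairpins <- function(hits, transcripts, libs = list(),
                              flank = 150L, pad = 30L,
                              thresholds = hairpin_thresholds(),
                              engine = "auto") {
  hits <- hits[hits$strand == "+", , drop = FALSE]
  cands <- list()
  for (k in seq_len(nrow(hits))) {
    tag <- hits$tag[k]
    hit <- list(transcript = hits$transcript[k], start = hits$start[k],
                end = hits$start[k] + nchar(tag) - 1L)
    wins <- excise_precursor_windows(hit, transcripts, flank, pad)
    best <- NULL
    for (w in seq_len(nrow(wins))) {
      cand <- evaluate_candidate(
        substr(transcripts[[wins$transcript[w]]], wins$start[w], wins$end[w]),
        mature_start = hit$start - wins$start[w] + 1L,
        mature_len = nchar(tag),
        thresholds = thresholds, engine = engine,
        transcript = wins$transcript[w], window_start = wins$start[w])
      if (!cand$pass) next
      if (is.null(best) ||
          abs(cand$fold$mfe) / nchar(cand$precursor$sequence) >
          abs(best$fold$mfe) / nchar(best$precursor$sequence))
        best <- cand
    }
    if (!is.null(best)) cands[[length(cands) + 1L]] <- best
  }
  .hairpin_report(.dedupe_candidates(cands, libs), libs)
}

# one candidate per locus: overlapping precursors on the same transcript
# (e.g. the mature- and star-arm views of one hairpin) collapse to the
# candidate whose mature has the highest library support, ties broken by
# |mfe| per nucleotide, then by coordinates
.dedupe_candidates <- function(cands, libs, min_overlap_frac = 0.5) {
  if (length(cands) < 2) return(cands)
  support <- vapply(cands, function(cand) {
    sum(vapply(libs, function(l) {
      cnt <- l$tags[cand$mature$sequence]
      ifelse(is.na(cnt), 0L, cnt)
    }, integer(1)))
  }, numeric(1))
  dens <- vapply(cands, function(cand)
    abs(cand$fold$mfe) / nchar(cand$precursor$sequence), numeric(1))
  starts <- vapply(cands, function(cand) cand$precursor$start, numeric(1))
  txs <- vapply(cands, function(cand) cand$transcript, character(1))
  ends <- vapply(cands, function(cand) cand$precursor$end, numeric(1))
  ord <- order(-support, -dens, txs, starts)
  kept <- list()
  for (i in ord) {
    clash <- FALSE
    for (kc in kept) {
      if (cands[[kc]]$transcript != txs[i]) next
      ov <- min(ends[i], cands[[kc]]$precursor$end) -
            max(starts[i], cands[[kc]]$precursor$start) + 1
      shorter <- min(ends[i] - starts[i], cands[[kc]]$precursor$end -
                       cands[[kc]]$precursor$start) + 1
      if (ov >= min_overlap_frac * shorter) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  cands[sort(unlist(kept))]
}

.hairpin_report <- function(cands, libs) {
  libnames <- vapply(libs, `[[`, character(1), "name")
  rows <- lapply(cands, function(cand) {
    mat <- cand$mature$sequence
    mcounts <- vapply(libs, function(l) {
      cnt <- l$tags[mat]; ifelse(is.na(cnt), 0L, cnt)
    }, integer(1))
    star <- detect_star(cand, libs)
    row <- data.frame(
      mature = mat, arm = cand$mature$arm, transcript = cand$transcript,
      precursor_start = cand$precursor$start,
      precursor_end = cand$precursor$end,
      mfe = cand$fold$mfe,
      mismatches = cand$stats$mismatches, bulges = cand$stats$bulges,
      star = if (is.null(star)) NA_character_ else star$sequence,
      pass = cand$pass, stringsAsFactors = FALSE)
    for (i in seq_along(libs)) {
      row[[paste0("count_", libnames[i])]] <- mcounts[i]
      row[[paste0("star_count_", libnames[i])]] <-
        if (is.null(star)) 0L else star$counts[i]
    }
    row
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mature = character(), arm = character(),
               transcript = character(), precursor_start = integer(),
               precursor_end = integer(), mfe = numeric(),
               mismatches = numeric(), bulges = numeric(),
               star = character(), pass = logical(),
               stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  if (nrow(rep)) rep$id <- sprintf("nov-mir%d", seq_len(nrow(rep)))
  attr(rep, "candidates") <- unname(cands)
  rep
}

#' Summary statistics over a candidate report
#'
#' @param report Output of [discover_hairpins()].
#' @return List with `n`, `mean_precursor_length` and `mean_mfe`.
#' @export
hairpin_summary <- function(report) {
  list(n = nrow(report),
       mean_precursor_length =
         mean(report$precursor_end - report$precursor_start + 1),
       mean_mfe = mean(report$mfe))
}
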