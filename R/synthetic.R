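# Synthetic data generator: a fully specified stand-in for a two-genotype
# small-RNA + degradome experiment, with a machine-readable truth table. All
# generators are pure functions of (parameters, seed); the caller's RNG
# state is left untouched.

#' Generate a synthetic transcriptome
#'
#' Random uppercase ACGT transcripts with configurable GC content,
#' reproducible given the seed.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Integer range of transcript lengths (uniform draw).
#' @param gc GC fraction.
#' @param seed Random seed.
#' @return Named character vector (`TX0001`, ...), with a `truth` attribute
#'   holding the skeleton truth table (list with `seed` and empty slots for
#'   hairpins, miRNA levels and cleavage sites).
#' @export
generate_transcriptome <- function(n_transcripts, length_range = c(800L, 2000L),
                                   gc = 0.5, seed = 1L) {
  stopifnot(n_transcripts >= 0, all(length_range > 0), gc >= 0, gc <= 1)
  tx <- .with_seed(.scramble_seed(seed, "transcriptome"), {
    lens <- if (n_transcripts) sample(length_range[1]:length_range[2],
                                      n_transcripts, replace = TRUE)
            else integer(0)
    .rand_seq(lens, gc)
  })
  names(tx) <- sprintf("TX%04d", seq_len(n_transcripts))
  attr(tx, "truth") <- list(seed = seed, hairpins = NULL, mirnas = NULL,
                            cleavage_sites = NULL, contamination = NULL)
  tx
}

# build one ideal precursor: a perfect inverted repeat [stem5 | arm | loop |
# revcomp(arm) | revcomp(stem5)] carrying the mature on the requested arm;
# under the perfect fold pt(i) = n+1-i the star (2-nt 3' overhang rule) is
# prec[n+3-m2 .. n+3-m1] for a mature at [m1, m2]
.make_precursor <- function(mature, stem_ext = 15L, loop_len = 8L,
                            arm = "5p") {
  stem5 <- .rand_seq(stem_ext)
  loop <- .rand_seq(loop_len)
  arm5 <- paste0(stem5, if (arm == "5p") mature else .revcomp(mature))
  prec <- paste0(arm5, loop, .revcomp(arm5))
  n <- nchar(prec)
  m1 <- if (arm == "5p") stem_ext + 1L
        else nchar(arm5) + loop_len + 1L
  m2 <- m1 + nchar(mature) - 1L
  star <- substr(prec, n + 3L - m2, n + 3L - m1)
  list(precursor = prec, mature_offset = m1, star = star, arm = arm)
}

#' Plant hairpin precursors into a transcriptome
#'
#' Inserts ideal stem-loop precursors (perfect miRNA/miRNA* duplex with a
#' 2-nt 3' overhang, flanking stem extension, short terminal loop) at random
#' positions, replacing transcript sequence so coordinates stay stable.
#' Mature sequences are rejection-sampled to be unique and mutually distant
#' (pairwise Hamming distance > 2 among equal-length matures), so downstream
#' truth labels are unambiguous. Inserted precursors fold into hairpins that
#' pass [evaluate_candidate()] at default thresholds.
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @param n_hairpins Number of hairpins to plant (at most one per
#'   transcript).
#' @param mature_len Mature miRNA length (20-23).
#' @param stem_ext,loop_len Stem extension beyond the duplex and terminal
#'   loop length, nt.
#' @param max_mismatch Duplex mismatches requested (only 0 is generated;
#'   values above the community limit of 4 are refused).
#' @param seed Random seed.
#' @return The transcriptome with planted precursors; `attr(, "truth")$hairpins`
#'   is a data.frame (`mirna`, `transcript`, `precursor_start`,
#'   `precursor_end`, `mature`, `star`, `mature_start`).
#' @export
plant_hairpins <- function(transcriptome, n_hairpins = 20L, mature_len = 21L,
                           stem_ext = 15L, loop_len = 8L, max_mismatch = 0L,
                           seed = 1L) {
  stopifnot(mature_len >= 20, mature_len <= 23)
  if (max_mismatch > 4)
    stop("duplex spec outside the valid range (mismatches must be <= 4)")
  truth <- attr(transcriptome, "truth")
  tx <- as.vector(transcriptome); names(tx) <- names(transcriptome)
  plen <- 2L * (stem_ext + mature_len) + loop_len
  eligible <- which(nchar(tx) >= plen + 20L)
  rows <- list()
  tx <- .with_seed(.scramble_seed(seed, "plant_hairpins"), {
    slots <- sample(eligible, min(n_hairpins, length(eligible)))
    if (length(slots) < n_hairpins)
      warning("only ", length(slots), " transcripts long enough; planted ",
              length(slots), " hairpins")
    matures <- character(0)
    for (k in seq_along(slots)) {
      i <- slots[k]
      # mature distinct from all previous ones (Hamming > 2)
      repeat {
        mat <- .rand_seq(mature_len)
        if (!length(matures) ||
            all(vapply(matures, .hamming, numeric(1), a = mat) > 2)) break
      }
      matures <- c(matures, mat)
      hp <- .make_precursor(mat, stem_ext, loop_len,
                            arm = if (k %% 2) "5p" else "3p")
      start <- sample(seq_len(nchar(tx[i]) - plen + 1L), 1)
      substr(tx[i], start, start + plen - 1L) <- hp$precursor
      rows[[k]] <- data.frame(
        mirna = sprintf("syn-mir%d", k), transcript = names(tx)[i],
        precursor_start = start, precursor_end = start + plen - 1L,
        mature = mat, star = hp$star, arm = hp$arm,
        mature_start = start + hp$mature_offset - 1L,
        stringsAsFactors = FALSE)
    }
    tx
  })
  truth$hairpins <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(tx, "truth") <- truth
  tx
}

#' Plant miRNA cleavage sites into a transcriptome
#'
#' Inserts the reverse complement of planted mature miRNAs at random
#' transcript positions (outside planted precursors), defining true slice
#' positions under the position-10 rule.
#'
#' @param transcriptome Transcriptome (after [plant_hairpins()]).
#' @param mirnas Named character vector of miRNA sequences; defaults to the
#'   planted hairpins' matures.
#' @param n_sites Number of sites to plant.
#' @param seed Random seed.
#' @return The transcriptome; `attr(, "truth")$cleavage_sites` is a
#'   data.frame (`mirna`, `transcript`, `site_start`, `slice_pos`).
#' @export
plant_target_sites <- function(transcriptome, mirnas = NULL, n_sites = 20L,
                               seed = 1L) {
  truth <- attr(transcriptome, "truth")
  if (is.null(mirnas)) {
    stopifnot(!is.null(truth$hairpins))
    mirnas <- setNames(truth$hairpins$mature, truth$hairpins$mirna)
  }
  tx <- as.vector(transcriptome); names(tx) <- names(transcriptome)
  hp <- truth$hairpins
  rows <- list()
  occupied <- if (!is.null(hp))
    data.frame(transcript = hp$transcript, start = hp$precursor_start,
               end = hp$precursor_end, stringsAsFactors = FALSE)
  else data.frame(transcript = character(), start = integer(),
                  end = integer(), stringsAsFactors = FALSE)
  tx <- .with_seed(.scramble_seed(seed, "plant_target_sites"), {
    for (k in seq_len(n_sites)) {
      mi <- names(mirnas)[(k - 1L) %% length(mirnas) + 1L]
      L <- nchar(mirnas[[mi]])
      repeat {
        i <- sample(length(tx), 1)
        # keep >= 20 nt downstream of the slice so the degradome tag fits
        hi <- nchar(tx[i]) - L - 12L
        if (hi < 1L) next
        start <- sample(hi, 1)
        clash <- any(occupied$transcript == names(tx)[i] &
                     start <= occupied$end + 25L &
                     start + L - 1L >= occupied$start - 25L)
        if (!clash) break
      }
      substr(tx[i], start, start + L - 1L) <- .revcomp(mirnas[[mi]])
      occupied <- rbind(occupied,
                        data.frame(transcript = names(tx)[i], start = start,
                                   end = start + L - 1L,
                                   stringsAsFactors = FALSE))
      rows[[k]] <- data.frame(
        mirna = mi, transcript = names(tx)[i], site_start = start,
        slice_pos = start + L - 10L, stringsAsFactors = FALSE)
    }
    tx
  })
  truth$cleavage_sites <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(tx, "truth") <- truth
  tx
}

#' Simulate two-condition tag libraries
#'
#' Draws per-miRNA counts independently per condition under a Poisson law
#' with mean `rpm * depth / 1e6` (condition 1) and `rpm * 2^fc * depth / 1e6`
#' (condition 2). Star tags are sequenced at `star_frac` of the mature level.
#' Background tags are random 18-30 nt sequences (length mode at 24 nt, then
#' 21 nt, as in leaf small-RNA libraries) rejection-sampled to stay more
#' than 2 mismatches away from every planted mature, so truth labels remain
#' unambiguous. Negative-binomial noise is available behind `dispersion`
#' (the single-library design identifies no overdispersion, so Poisson is
#' the default).
#'
#' @param transcriptome Transcriptome with planted hairpins (its truth table
#'   is updated), or a truth list.
#' @param depth Length-2 clean-read totals of the two libraries.
#' @param rpm Per-miRNA RPM levels in condition 1; recycled over the planted
#'   miRNAs. Defaults to cycling 5000/10000/20000/40000, the mid range
#'   observed for conserved plant miRNA families.
#' @param fc True log2 fold-changes; recycled. Defaults to cycling
#'   0, +1, -1, +2.5, -2.5.
#' @param star_frac Star-to-mature sequencing ratio.
#' @param n_background Number of background tags per library.
#' @param dispersion NB dispersion (size = 1/dispersion); 0 keeps Poisson.
#' @param seed Random seed.
#' @param lib_names Library names.
#' @return List with `libs` (two [tag_library()] objects) and `truth` (the
#'   updated truth table: per-miRNA `rpm1`, `rpm2`, `true_log2fc`, realized
#'   `count1`, `count2`).
#' @export
simulate_libraries <- function(transcriptome, depth = c(1e6, 1e6),
                               rpm = c(5000, 10000, 20000, 40000),
                               fc = c(0, 1, -1, 2.5, -2.5),
                               star_frac = 0.05, n_background = 500L,
                               dispersion = 0, seed = 1L,
                               lib_names = c("cond1", "cond2")) {
  if (any(depth <= 0)) stop("depth must be positive")
  truth <- attr(transcriptome, "truth")
  stopifnot(!is.null(truth$hairpins))
  hp <- truth$hairpins
  n <- nrow(hp)
  rpm1 <- rep_len(rpm, n)
  lfc <- rep_len(fc, n)
  rpm2 <- rpm1 * 2^lfc
  draw <- function(mu) {
    if (dispersion > 0) stats::rnbinom(length(mu), mu = mu,
                                       size = 1 / dispersion)
    else rpois(length(mu), mu)
  }
  res <- .with_seed(.scramble_seed(seed, "simulate_libraries"), {
    c1 <- draw(rpm1 * depth[1] / 1e6)
    c2 <- draw(rpm2 * depth[2] / 1e6)
    s1 <- draw(star_frac * rpm1 * depth[1] / 1e6)
    s2 <- draw(star_frac * rpm2 * depth[2] / 1e6)
    bg <- character(0)
    if (n_background > 0) {
      lens <- sample(18:30, n_background, replace = TRUE,
                     prob = c(1, 1, 2, 6, 2, 2, 10, 2, 1, 1, 1, 1, 1))
      bg <- unique(.rand_seq(lens))
      ok <- vapply(bg, function(b) {
        same <- hp$mature[nchar(hp$mature) == nchar(b)]
        !length(same) || all(vapply(same, .hamming, numeric(1), a = b) > 2)
      }, logical(1))
      bg <- bg[ok]
    }
    bgc1 <- if (length(bg)) 1L + rpois(length(bg), 2) else integer(0)
    bgc2 <- if (length(bg)) 1L + rpois(length(bg), 2) else integer(0)
    list(c1 = c1, c2 = c2, s1 = s1, s2 = s2, bg = bg, bgc1 = bgc1,
         bgc2 = bgc2)
  })
  mk <- function(nm, mc, sc, bgc) {
    counts <- c(setNames(mc, hp$mature), setNames(sc, hp$star),
                setNames(bgc, res$bg))
    counts <- counts[counts > 0]
    counts <- tapply(counts, names(counts), sum)  # mature==star collisions
    tag_library(nm, setNames(as.integer(counts), names(counts)),
                clean_total = depth[match(nm, lib_names)])
  }
  libs <- list(mk(lib_names[1], res$c1, res$s1, res$bgc1),
               mk(lib_names[2], res$c2, res$s2, res$bgc2))
  truth$mirnas <- data.frame(
    mirna = hp$mirna, mature = hp$mature, rpm1 = rpm1, rpm2 = rpm2,
    true_log2fc = lfc, count1 = res$c1, count2 = res$c2,
    star_count1 = res$s1, star_count2 = res$s2, stringsAsFactors = FALSE)
  truth$depth <- depth
  list(libs = libs, truth = truth)
}

#' Simulate a degradome tag set
#'
#' Planted-site tags are 20-nt transcript substrings starting exactly at the
#' true slice position, at abundance `peak_height`. Background tags are
#' 20-nt substrings at uniformly random transcript positions, each at
#' abundance `round(peak_height * bg_fraction)`, with `bg_per_kb` background
#' positions per kb of transcript.
#'
#' @param transcriptome Transcriptome with planted cleavage sites.
#' @param peak_height Reads at each planted slice position.
#' @param bg_fraction Background abundance as a fraction of the peak.
#' @param bg_per_kb Background positions per kb of transcript.
#' @param seed Random seed.
#' @return Named integer vector: degradome tag sequence -> count.
#' @export
simulate_degradome <- function(transcriptome, peak_height = 50L,
                               bg_fraction = 0.1, bg_per_kb = 2,
                               seed = 1L) {
  truth <- attr(transcriptome, "truth")
  stopifnot(!is.null(truth$cleavage_sites))
  sites <- truth$cleavage_sites
  tx <- transcriptome
  tags <- integer(0)
  add <- function(tags, seq, count) {
    if (count < 1 || nchar(seq) < 20) return(tags)
    cur <- if (seq %in% names(tags)) tags[[seq]] else 0L
    tags[[seq]] <- cur + as.integer(count)
    tags
  }
  .with_seed(.scramble_seed(seed, "simulate_degradome"), {
    if (peak_height >= 1) {
      for (k in seq_len(nrow(sites))) {
        s <- substr(tx[[sites$transcript[k]]], sites$slice_pos[k],
                    sites$slice_pos[k] + 19L)
        tags <- add(tags, s, peak_height)
      }
    }
    bg_h <- round(peak_height * bg_fraction)
    if (bg_h >= 1 && bg_per_kb > 0) {
      for (i in seq_along(tx)) {
        nb <- rpois(1, bg_per_kb * nchar(tx[i]) / 1000)
        if (nb < 1) next
        pos <- sample(seq_len(max(1L, nchar(tx[i]) - 19L)), nb,
                      replace = TRUE)
        for (p in pos) tags <- add(tags, substr(tx[i], p, p + 19L), bg_h)
      }
    }
    tags
  })
}

#' Wrap clean tags into contaminated raw reads
#'
#' Expands a tag library (or tag count vector) into per-read records with a
#' 3' adapter appended, high base qualities, and injected contaminants:
#' adapter-only reads, low-quality reads, poly(A) reads, sub-18-nt inserts,
#' oversized (>30 nt) inserts and reads containing N. The truth table
#' records the contamination counts by class.
#'
#' @param tags Named integer vector (sequence -> count).
#' @param adapter3 3' adapter appended to each insert.
#' @param read_len Output read length (insert + adapter, truncated).
#' @param contam Named integer vector with any of `adapter_only`,
#'   `low_quality`, `poly_a`, `undersize`, `oversize`, `n_bases`.
#' @param seed Random seed.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and
#'   `contamination` (the tally planted).
#' @export
simulate_raw_reads <- function(tags,
                               adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                               read_len = 45L,
                               contam = c(adapter_only = 20L,
                                          low_quality = 20L, poly_a = 20L,
                                          undersize = 20L, oversize = 20L,
                                          n_bases = 20L),
                               seed = 1L) {
  mkread <- function(insert, qual_char = "I") {
    s <- substr(paste0(insert, adapter3, strrep("A", read_len)), 1, read_len)
    list(seq = s, qual = strrep(qual_char, nchar(s)))
  }
  .with_seed(.scramble_seed(seed, "simulate_raw_reads"), {
    seqs <- rep(names(tags), tags)
    seqs <- sample(seqs)
    reads <- lapply(seqs, mkread)
    extra <- list()
    for (cls in names(contam)) {
      for (k in seq_len(contam[[cls]])) {
        extra[[length(extra) + 1L]] <- switch(cls,
          adapter_only = mkread(""),
          low_quality = { r <- mkread(.rand_seq(21L)); r$qual <-
            strrep("#", nchar(r$seq)); r },
          poly_a = mkread(strrep("A", 22L)),
          undersize = mkread(.rand_seq(sample(10:17, 1))),
          oversize = mkread(.rand_seq(sample(31:36, 1))),
          n_bases = mkread(paste0(.rand_seq(10L), "NN", .rand_seq(9L))))
      }
    }
    all <- c(reads, extra)
    ord <- sample(length(all))
    list(reads = data.frame(
           id = sprintf("read%06d", seq_along(all)),
           seq = vapply(all, `[[`, character(1), "seq")[ord],
           qual = vapply(all, `[[`, character(1), "qual")[ord],
           stringsAsFactors = FALSE),
         contamination = contam)
  })
}

#' Write a truth table as JSON
#'
#' @param truth Truth list (as carried in `attr(transcriptome, "truth")` or
#'   returned by [simulate_libraries()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
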