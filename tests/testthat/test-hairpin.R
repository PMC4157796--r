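# a planted two-arm test bundle shared across blocks
make_bundle <- function(seed = 61, n_tx = 12, n_hp = 6) {
  tx <- generate_transcriptome(n_tx, c(900, 1500), 0.5, seed = seed)
  tx <- plant_hairpins(tx, n_hairpins = n_hp, seed = seed + 1)
  tx
}

test_that("precursor windows are excised with the documented arithmetic", {
  tx <- c(t1 = strrep("ACGT", 250))
  w <- excise_precursor_windows(list(transcript = "t1", start = 200,
                                     end = 220), tx, flank = 150)
  expect_equal(w$start, c(200L, 50L))
  expect_equal(w$end, c(370L, 220L))
  # boundary clipping
  wb <- excise_precursor_windows(list(transcript = "t1", start = 1,
                                      end = 21), tx, flank = 150)
  expect_true(all(wb$start >= 1))
  expect_equal(sort(wb$start)[1], 1L)
  expect_error(excise_precursor_windows(list(transcript = "t1", start = 990,
                                             end = 1010), tx),
               "outside transcript bounds")
})

test_that("windows around a planted hairpin contain the full precursor", {
  tx <- make_bundle()
  h <- attr(tx, "truth")$hairpins[1, ]
  w <- excise_precursor_windows(list(transcript = h$transcript,
                                     start = h$mature_start,
                                     end = h$mature_start + 20),
                                tx, flank = 150, pad = 30)
  covers <- any(w$start <= h$precursor_start & w$end >= h$precursor_end)
  expect_true(covers)
})

test_that("ideal planted hairpins pass all acceptance flags on both arms", {
  tx <- make_bundle()
  truth <- attr(tx, "truth")$hairpins
  for (k in seq_len(nrow(truth))) {
    h <- truth[k, ]
    win <- excise_precursor_windows(list(transcript = h$transcript,
                                         start = h$mature_start,
                                         end = h$mature_start + 20),
                                    tx, flank = 150, pad = 30)
    passed <- FALSE
    for (w in seq_len(nrow(win))) {
      cand <- evaluate_candidate(
        substr(tx[[h$transcript]], win$start[w], win$end[w]),
        mature_start = h$mature_start - win$start[w] + 1, mature_len = 21,
        transcript = h$transcript, window_start = win$start[w])
      if (cand$pass) {
        passed <- TRUE
        expect_equal(cand$mature$arm, h$arm)
        expect_equal(cand$mature$sequence, h$mature)
        expect_equal(cand$star$sequence, h$star)
        expect_equal(cand$stats$mismatches, 0)
        expect_equal(cand$stats$bulges, 0)
      }
    }
    expect_true(passed, label = sprintf("hairpin %d passes", k))
  }
})

test_that("a mature straddling the terminal loop fails arm containment", {
  tx <- make_bundle()
  h <- attr(tx, "truth")$hairpins[1, ]
  prec <- substr(tx[[h$transcript]], h$precursor_start, h$precursor_end)
  # centre the "mature" on the loop (precursor midpoint)
  mid <- nchar(prec) %/% 2 - 10
  cand <- evaluate_candidate(prec, mature_start = mid, mature_len = 21)
  expect_false(cand$flags[["arm"]])
  expect_false(cand$pass)
})

test_that("weak stems fail the energy criterion", {
  # 8 A:U pairs: pseudo-energy -16 kcal/mol under the fallback engine
  stem <- strrep("AT", 4)
  hp <- paste0(strrep("A", 8), "CCCC", strrep("T", 8))
  cand <- evaluate_candidate(paste0(hp, strrep("C", 50)), 1, 20,
                             engine = "nussinov")
  expect_false(cand$flags[["mfe"]])
  expect_false(cand$pass)
})

test_that("star evidence is looked up per library, zero counts allowed", {
  tx <- make_bundle()
  sim <- simulate_libraries(tx, seed = 63)
  truth <- attr(tx, "truth")$hairpins
  h <- truth[1, ]
  win <- excise_precursor_windows(list(transcript = h$transcript,
                                       start = h$mature_start,
                                       end = h$mature_start + 20),
                                  tx, flank = 150, pad = 30)
  cand <- NULL
  for (w in seq_len(nrow(win))) {
    cc <- evaluate_candidate(
      substr(tx[[h$transcript]], win$start[w], win$end[w]),
      mature_start = h$mature_start - win$start[w] + 1, mature_len = 21,
      transcript = h$transcript, window_start = win$start[w])
    if (cc$pass) cand <- cc
  }
  star <- detect_star(cand, sim$libs)
  expect_equal(star$sequence, h$star)
  tm <- sim$truth$mirnas
  expect_equal(unname(star$counts["cond1"]),
               tm$star_count1[tm$mirna == h$mirna])
  # a candidate whose star was never sequenced still reports, with zeros
  empty_lib <- tag_library("empty", setNames(1L, rand_nt(21)), 100)
  star0 <- detect_star(cand, list(empty_lib))
  expect_equal(unname(star0$counts), 0L)
})

test_that("discovery recovers planted hairpins with high precision and recall", {
  tx <- make_bundle(seed = 65, n_tx = 15, n_hp = 8)
  truth <- attr(tx, "truth")$hairpins
  sim <- simulate_libraries(tx, n_background = 150, seed = 66)
  # discovery input: everything unannotated that maps, as in the pipeline
  tags <- unique(c(names(sim$libs[[1]]$tags), names(sim$libs[[2]]$tags)))
  hits <- map_tags_to_transcripts(tags, tx)
  rep <- discover_hairpins(hits, tx, sim$libs)
  # a candidate is true when its precursor overlaps a planted precursor
  # (the star arm of a planted hairpin is a legitimate detection too)
  is_tp <- vapply(seq_len(nrow(rep)), function(i) {
    any(truth$transcript == rep$transcript[i] &
          truth$precursor_start <= rep$precursor_end[i] &
          truth$precursor_end >= rep$precursor_start[i])
  }, logical(1))
  found <- vapply(seq_len(nrow(truth)), function(k) {
    any(rep$transcript == truth$transcript[k] &
          rep$precursor_start <= truth$precursor_end[k] &
          rep$precursor_end >= truth$precursor_start[k])
  }, logical(1))
  expect_gte(mean(found), 0.9)    # recall over planted hairpins
  expect_gte(mean(is_tp), 0.9)    # precision over reported candidates
  # every reported candidate re-folds into the declared duplex
  for (cand in attr(rep, "candidates")) {
    refold <- fold_rna(cand$precursor$sequence, engine = cand$fold$engine)
    expect_equal(refold$structure, cand$fold$structure)
    m1 <- cand$mature$start
    pt <- pair_table(refold$structure)
    part <- pt[m1:(m1 + nchar(cand$mature$sequence) - 1)]
    expect_true(all(part[part > 0] >= cand$star$start - 2 &
                      part[part > 0] <= cand$star$end + 2))
  }
  # summary statistics equal direct recomputation
  s <- hairpin_summary(rep)
  expect_equal(s$mean_mfe, mean(rep$mfe))
  expect_equal(s$mean_precursor_length,
               mean(rep$precursor_end - rep$precursor_start + 1))
})
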