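test_that("degradome tags register their 5' ends, multi-mapping flagged", {
  set.seed(81)
  tx <- c(t1 = rand_nt(400), t2 = rand_nt(300))
  tag <- substr(tx["t1"], 101, 120)
  prof <- map_degradome_tags(setNames(7L, tag), tx)
  expect_equal(names(prof), "t1")
  expect_equal(prof$t1$pos, 101L)
  expect_equal(prof$t1$count, 7L)
  expect_false(prof$t1$multimapped)
  expect_equal(length(map_degradome_tags(rand_nt(20), tx)), 0L)
  # a tag present in both transcripts contributes to every locus, flagged
  tx2 <- c(a = paste0(rand_nt(50), tag, rand_nt(30)),
           b = paste0(rand_nt(10), tag, rand_nt(70)))
  mm <- map_degradome_tags(setNames(3L, tag), tx2)
  expect_setequal(names(mm), c("a", "b"))
  expect_true(all(c(mm$a$multimapped, mm$b$multimapped)))
})

test_that("site scoring applies the weight table and the cleavage-site rule", {
  set.seed(82)
  mir <- rand_nt(21)
  perfect <- rc(mir)
  s <- score_site(mir, perfect)
  expect_equal(s$score, 0)
  expect_equal(s$pairing, strrep("|", 21))
  # one G:U at miRNA position 5 adds 0.5 (flip the site base facing pos 5)
  flip_site <- function(site, mpos, base) {
    i <- nchar(site) - mpos + 1
    paste0(substr(site, 1, i - 1), base, substr(site, i + 1, nchar(site)))
  }
  mv <- strsplit(mir, "")[[1]]
  wob <- c(A = NA, C = NA, G = "T", T = "G")[[mv[5]]]
  if (is.na(wob)) {       # pos 5 is A/C: mutate the miRNA copy instead
    mir5 <- mir; substr(mir5, 5, 5) <- "G"
    site5 <- flip_site(rc(mir5), 5, "T")
    s5 <- score_site(mir5, site5)
  } else {
    s5 <- score_site(mir, flip_site(perfect, 5, wob))
  }
  expect_equal(s5$score, 0.5)
  expect_equal(substr(s5$pairing, 5, 5), "o")
  # a mismatch at position 10 is rejected regardless of total score
  bad10 <- flip_site(perfect, 10, setdiff(c("A", "C", "G", "T"),
                                          c(rc(mv[10]), mv[10]))[1])
  expect_null(score_site(mir, bad10))
  # total score above 4 is rejected
  v <- strsplit(perfect, "")[[1]]
  for (mpos in c(1:5)) {
    i <- 21 - mpos + 1
    v[i] <- setdiff(c("A", "C", "G", "T"), c(v[i], mv[mpos]))[1]
  }
  expect_null(score_site(mir, paste(v, collapse = "")))
  expect_error(score_site("ACGTQ", "ACGTT"), "non-nucleotide")
})

test_that("the compiled scanner agrees with a window-by-window score_site loop", {
  set.seed(83)
  tx <- rand_nt(2000)
  mir <- rand_nt(21)
  # plant a few imperfect sites so matches exist
  for (p in c(200, 900, 1500)) {
    site <- rc(mir)
    j <- sample(c(1:7, 14:21), 1)          # keep positions 10/11 intact
    substr(site, j, j) <- sample(c("A", "C", "G", "T"), 1)
    substr(tx, p, p + 20) <- site
  }
  got <- scan_target_sites(mir, tx, site_weights(max_score = 6))
  want <- list()
  for (s in 1:(nchar(tx) - 20)) {
    r <- score_site(mir, substr(tx, s, s + 20), site_weights(max_score = 6))
    if (!is.null(r))
      want[[length(want) + 1]] <- data.frame(start = s, score = r$score,
                                             pairing = r$pairing)
  }
  want <- do.call(rbind, want)
  expect_equal(got[c("start", "score", "pairing")], want,
               ignore_attr = TRUE)
})

test_that("slice position arithmetic matches the pairing-walk oracle", {
  expect_equal(predict_slice_position(list(site_start = 101, mirna_len = 21)),
               112)
  expect_equal(predict_slice_position(list(site_start = 1, mirna_len = 20)),
               11)
  # gapped toy alignment: site has a deletion facing miRNA position 15
  mir <- "ACGTACGTACGTACGTACGTA"        # 21 nt
  mir_al <- mir                          # no gaps on the miRNA
  site <- rc(mir)
  site_al <- paste0(substr(site, 1, 6), "-", substr(site, 8, 21))
  al <- list(site_start = 301, mirna_aligned = mir_al,
             site_aligned = site_al)
  # pairing walk: miRNA position 10 faces the 10th site base from the 3' end
  # (site is 20 nt after the deletion), i.e. transcript position 301+20-10
  expect_equal(predict_slice_position(al), 311)
  # ungapped alignment through the aligned-string path agrees with arithmetic
  expect_equal(predict_slice_position(list(site_start = 101,
                                           mirna_aligned = mir,
                                           site_aligned = rc(mir))),
               predict_slice_position(list(site_start = 101, mirna_len = 21)))
})

test_that("t-plot categories follow the declared maximum/median rule", {
  single <- data.frame(pos = 50L, count = 9L)
  expect_equal(categorize_event(50, single), "I")
  prof <- data.frame(pos = c(10L, 20L, 30L), count = c(5L, 10L, 1L))
  expect_equal(categorize_event(10, prof), "III")  # 5 = median, not above
  expect_equal(categorize_event(20, prof), "I")
  prof2 <- data.frame(pos = c(1L, 2L, 3L, 4L), count = c(2L, 5L, 10L, 1L))
  expect_equal(categorize_event(2, prof2), "II")   # 5 > median 3.5, < max
  expect_true(is.na(categorize_event(99, prof)))
  # categories are stable under uniform scaling of abundances
  for (f in c(2, 10, 100)) {
    sc <- prof2; sc$count <- sc$count * f
    expect_equal(categorize_event(2, sc), "II")
    expect_equal(categorize_event(4, sc), "III")
    expect_equal(categorize_event(3, sc), "I")
  }
})

test_that("target calling recovers planted cleavage events exactly at zero noise", {
  tx <- generate_transcriptome(15, c(900, 1500), 0.5, seed = 84)
  tx <- plant_hairpins(tx, n_hairpins = 8, seed = 85)
  tx <- plant_target_sites(tx, n_sites = 12, seed = 86)
  truth <- attr(tx, "truth")
  mirnas <- setNames(truth$hairpins$mature, truth$hairpins$mirna)
  dtags <- simulate_degradome(tx, peak_height = 50, bg_fraction = 0,
                              seed = 87)
  prof <- map_degradome_tags(dtags, tx)
  ev <- call_targets(mirnas, tx, prof)
  key_t <- with(truth$cleavage_sites, paste(mirna, transcript, slice_pos))
  key_e <- with(ev, paste(mirna, transcript, slice_pos))
  expect_setequal(key_e, key_t)                       # recall 1, 0 false calls
  expect_true(all(ev$category == "I"))
  expect_true(all(ev$slice_abundance == 50))
  # every emitted event re-scores to its stored score
  for (i in seq_len(nrow(ev))) {
    site <- substr(tx[[ev$transcript[i]]], ev$site_start[i], ev$site_end[i])
    r <- score_site(mirnas[[ev$mirna[i]]], site)
    expect_equal(r$score, ev$score[i])
    expect_equal(r$pairing, ev$pairing[i])
    # pairing-string penalties sum to the score
    pr <- strsplit(ev$pairing[i], "")[[1]]
    expect_equal(sum((pr == "o") * 0.5 + (pr == "x") * 1), ev$score[i])
  }
})

test_that("sites above the score cap and miRNAs with no site produce no events", {
  set.seed(88)
  tx <- c(t1 = rand_nt(600))
  mir <- rand_nt(21)
  site <- rc(mir)
  # plant a site with 4 mismatches plus one G:U -> score 4.5, over the cap
  mv <- strsplit(mir, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  for (mpos in c(2, 4, 6, 18)) {
    i <- 21 - mpos + 1
    sv[i] <- setdiff(c("A", "C", "G", "T"), c(sv[i], mv[mpos]))[1]
  }
  gu <- if (mv[16] %in% c("G", "T")) c(G = "T", T = "G")[[mv[16]]] else NA
  if (is.na(gu)) { mv[16] <- "G"; mir <- paste(mv, collapse = ""); gu <- "T" }
  sv[21 - 16 + 1] <- gu
  substr(tx["t1"], 200, 220) <- paste(sv, collapse = "")
  prof <- list(t1 = data.frame(pos = 211L, count = 50L))
  ev <- call_targets(c(m1 = mir), tx, prof)
  expect_equal(nrow(ev), 0L)
  # no complementary window anywhere
  ev2 <- call_targets(c(m2 = strrep("A", 21)), c(t2 = strrep("A", 300)),
                      list(t2 = data.frame(pos = 100L, count = 5L)))
  expect_equal(nrow(ev2), 0L)
})

test_that("t-plot series flags slice positions and the plot renders", {
  prof <- data.frame(pos = c(10L, 20L), count = c(5L, 50L))
  ser <- tplot_series(prof, 20L)
  expect_equal(ser$is_slice, c(FALSE, TRUE))
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path)
  out <- plot_tplot(prof, 20L)
  grDevices::dev.off()
  expect_equal(out, ser)
  expect_true(file.exists(png_path))
})
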