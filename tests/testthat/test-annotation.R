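test_that("transcript mapping reports exact full-length hits on both strands", {
  set.seed(41)
  tx <- c(tx1 = rand_nt(200), tx2 = rand_nt(150))
  tag <- substr(tx["tx1"], 11, 31)
  hits <- map_tags_to_transcripts(tag, tx)
  expect_equal(hits$start[hits$strand == "+"], 11L)
  expect_equal(hits$transcript[hits$strand == "+"], "tx1")
  # reverse-strand hit reports the leftmost forward-strand coordinate
  rctag <- rc(substr(tx["tx2"], 50, 70))
  rhits <- map_tags_to_transcripts(rctag, tx)
  expect_equal(rhits$start, 50L)
  expect_equal(rhits$strand, "-")
  expect_equal(nrow(map_tags_to_transcripts(strrep("ACGT", 6), tx)), 0L)
})

test_that("mapping agrees with a naive substring-scan oracle on planted tags", {
  set.seed(42)
  tx <- setNames(replicate(10, rand_nt(500)), sprintf("t%02d", 1:10))
  tags <- character(0)
  for (k in 1:100) {
    i <- sample(10, 1); p <- sample(480, 1)
    tags <- c(tags, substr(tx[[i]], p, p + 20))
  }
  tags <- unique(tags)
  got <- map_tags_to_transcripts(tags, tx)
  want <- do.call(rbind, lapply(tags, oracle_scan_tag, transcripts = tx))
  want <- want[order(want$tag, want$transcript, want$start), ]
  got <- got[order(got$tag, got$transcript, got$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[c("tag", "transcript", "start")],
               want[c("tag", "transcript", "start")])
})

test_that("structural ncRNA classification follows the precedence order", {
  set.seed(43)
  shared <- rand_nt(21)
  refs <- list(rRNA = c(r1 = paste0(rand_nt(40), shared, rand_nt(40))),
               tRNA = c(t1 = paste0(rand_nt(10), shared, rand_nt(10))),
               snRNA = c(s1 = rand_nt(80)))
  expect_equal(classify_ncrna(shared, refs), "rRNA")
  expect_equal(classify_ncrna(rand_nt(21), refs), "unannotated")
  sn_frag <- substr(refs$snRNA[["s1"]], 5, 26)
  expect_equal(classify_ncrna(sn_frag, refs), "snRNA")
  # reverse-strand fragments match too
  expect_equal(classify_ncrna(rc(shared), refs["rRNA"]), "rRNA")
})

test_that("conserved matching honours the two-mismatch allowance and tie-breaks", {
  set.seed(44)
  base <- rand_nt(21)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in sample(length(v), k))
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  refs <- c(zmi_b = base, ami_a = base)   # tie: both exact
  hit <- match_conserved_mirna(base, refs)
  expect_equal(hit, list(id = "ami_a", mismatches = 0L))
  expect_equal(match_conserved_mirna(mut(base, 2), c(m1 = base))$mismatches, 2L)
  expect_null(match_conserved_mirna(mut(base, 3), c(m1 = base)))
  # U-containing references (miRBase dialect) and sliding over longer refs
  longer <- chartr("T", "U", paste0("GG", base))
  expect_equal(match_conserved_mirna(base, c(m1 = longer))$mismatches, 0L)
  expect_null(match_conserved_mirna(base, c(m1 = paste0("GGG", base))))
})

test_that("conserved matching agrees with a brute-force Hamming oracle", {
  set.seed(45)
  refs <- setNames(replicate(30, rand_nt(sample(20:23, 1))),
                   sprintf("ref%02d", 1:30))
  for (k in 1:50) {
    tag <- rand_nt(sample(20:22, 1))
    want <- oracle_min_mismatch(tag, refs)
    got <- match_conserved_mirna(tag, refs)
    if (want$mismatches > 2) {
      expect_null(got)
    } else {
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(oracle_min_mismatch(tag, refs[got$id])$mismatches,
                   want$mismatches)
    }
  }
})

test_that("family aggregation reproduces published family totals", {
  tab <- pa_mirna_counts()
  cons <- tab[tab$set == "conserved", ]
  fam <- assign_families(cons[, c("mirna", "pa2", "pa4")],
                         count_cols = c("pa2", "pa4"))
  f <- fam$families
  expect_equal(f$pa4[f$family == "MIR166"], 1422532)
  expect_equal(f$pa4[f$family == "MIR171"], 26)
  expect_equal(sum(f$share_pa2), 100)
  expect_equal(sum(f$share_pa4), 100)
  # members of the same identifier stem share a family
  expect_true(all(fam$members$family[grepl("miR166", fam$members$mirna)] ==
                    "MIR166"))
  empty <- assign_families(cons[0, c("mirna", "pa2", "pa4")])
  expect_equal(nrow(empty$families), 0L)
  expect_warning(assign_families(data.frame(mirna = "odd-name", pa2 = 1,
                                            pa4 = 2)), "unparseable")
})

test_that("the annotation cascade assigns exactly one class per tag", {
  set.seed(46)
  tx <- c(tx1 = rand_nt(400))
  rref <- c(rrna1 = rand_nt(120))
  mat <- c(`xxx-miR9990` = rand_nt(21))
  tags <- c(substr(rref[[1]], 10, 30),      # rRNA fragment
            unname(mat),                    # conserved
            rand_nt(21), rand_nt(24))       # unannotated
  lib <- collapse_tags(rep(tags, c(5, 4, 3, 2)), "lib")
  ann <- annotate_tags(lib, tx, list(rRNA = rref), mat)
  expect_equal(nrow(ann), 4L)
  expect_equal(sort(table(ann$class), decreasing = TRUE),
               sort(table(c("rRNA", "conserved_miRNA", "unannotated",
                            "unannotated")), decreasing = TRUE))
  expect_equal(ann$best_match[ann$class == "conserved_miRNA"], "xxx-miR9990")
  # classes partition the library: every tag has exactly one class
  expect_false(any(is.na(ann$class)))
})
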