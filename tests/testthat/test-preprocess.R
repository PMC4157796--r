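adapter <- "TGGAATTCTCGGGTGCCAAGG"
hi_q <- function(s) strrep("I", nchar(s))

mkreads <- function(seqs, quals = vapply(seqs, hi_q, character(1))) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

test_that("cleaning cascade applies each rule in order on a hand-enumerated toy set", {
  set.seed(11)
  good <- replicate(3, rand_nt(21))
  reads <- mkreads(c(
    adapter,                                   # adapter-only
    rand_nt(31),                               # 31 nt, no adapter: oversize
    paste0(substr(good[1], 1, 13), "NNNNNNNN"),# 8/21 N bases
    paste0(good, adapter)                      # three valid 21-nt inserts
  ))
  res <- filter_raw_reads(reads, adapter3 = adapter)
  expect_equal(unname(res$tally["retained"]), 3L)
  expect_setequal(res$reads$seq, good)
  expect_equal(unname(res$tally["adapter_contaminated"]), 1L)
  expect_equal(unname(res$tally["oversize"]), 1L)
  expect_equal(unname(res$tally["n_bases"]), 1L)
  # a read of length 17 after trimming is undersize
  res17 <- filter_raw_reads(mkreads(paste0(rand_nt(17), adapter)),
                            adapter3 = adapter)
  expect_equal(unname(res17$tally["undersize"]), 1L)
  # low-quality and poly(A) rules
  resq <- filter_raw_reads(mkreads(c(paste0(good[1], adapter),
                                     paste0(strrep("A", 22), adapter)),
                                   quals = c(strrep("#", 42),
                                             strrep("I", 43))),
                           adapter3 = adapter)
  expect_equal(unname(resq$tally["low_quality"]), 1L)
  expect_equal(unname(resq$tally["poly_a"]), 1L)
})

test_that("empty input, FASTA input and configuration errors behave as specified", {
  empty <- filter_raw_reads(mkreads(character(0)))
  expect_equal(nrow(empty$reads), 0L)
  expect_true(all(empty$tally == 0L))
  # FASTA input (no qualities) skips the quality filter instead of erroring
  fa <- data.frame(id = "r1", seq = paste0(strrep("ACG", 7), adapter),
                   stringsAsFactors = FALSE)
  expect_equal(unname(filter_raw_reads(fa)$tally["retained"]), 1L)
  expect_error(filter_raw_reads(fa, adapter3 = ""), "adapter")
})

test_that("filtering is idempotent and the tally partitions the input", {
  tags <- setNames(rep(5L, 30), replicate(30, rand_nt(sample(18:30, 1))))
  sim <- simulate_raw_reads(tags, seed = 3)
  res1 <- filter_raw_reads(sim$reads)
  expect_equal(sum(res1$tally), nrow(sim$reads) + 0L)  # rejected + retained
  res2 <- filter_raw_reads(res1$reads)
  expect_equal(res2$reads, res1$reads)
  expect_equal(unname(res2$tally["retained"]), nrow(res1$reads))
})

test_that("planted contaminants are tallied under their own classes", {
  tags <- setNames(rep(3L, 20), replicate(20, rand_nt(21)))
  contam <- c(adapter_only = 7L, low_quality = 5L, poly_a = 4L,
              undersize = 6L, oversize = 3L, n_bases = 2L)
  sim <- simulate_raw_reads(tags, contam = contam, seed = 4)
  res <- filter_raw_reads(sim$reads)
  expect_equal(unname(res$tally["adapter_contaminated"]), 7L)
  expect_equal(unname(res$tally["low_quality"]), 5L)
  expect_equal(unname(res$tally["poly_a"]), 4L)
  expect_equal(unname(res$tally["undersize"]), 6L)
  expect_equal(unname(res$tally["oversize"]), 3L)
  expect_equal(unname(res$tally["n_bases"]), 2L)
  expect_equal(unname(res$tally["retained"]), sum(tags))
})

test_that("collapse_tags counts exact duplicates and is order invariant", {
  a <- strrep("A", 10); s1 <- paste0(a, rand_nt(11)); s2 <- rand_nt(21)
  lib <- collapse_tags(c(s1, s1, s1, s2), "demo")
  expect_equal(length(lib$tags), 2L)
  expect_equal(unname(lib$tags[s1]), 3L)
  expect_equal(unname(lib$tags[s2]), 1L)
  expect_equal(lib$clean_total, 4L)
  lib2 <- collapse_tags(c(s2, s1, s1, s1), "demo")
  expect_equal(lib2, lib)
})

test_that("collapsing then expanding yields the input multiset (generator truth)", {
  set.seed(21)
  planted <- unique(replicate(50, rand_nt(sample(18:30, 1))))
  draws <- sample(planted, 10000, replace = TRUE)
  lib <- collapse_tags(draws, "big")
  expect_equal(length(lib$tags), length(planted))
  expect_equal(lib$clean_total, 10000L)
  expanded <- rep(names(lib$tags), lib$tags)
  expect_equal(sort(expanded), sort(draws))
  expect_equal(unname(lib$tags[planted]),
               as.integer(table(draws)[planted]))
})

test_that("length_distribution totals match the library and find the planted mode", {
  one <- tag_library("one", setNames(5L, rand_nt(21)), 5)
  expect_equal(length_distribution(one),
               data.frame(length = 21L, reads = 5L, unique = 1L))
  empty <- tag_library("none", setNames(integer(0), character(0)), 1)
  expect_equal(nrow(length_distribution(empty)), 0L)
  set.seed(31)
  lens <- sample(c(21, 24), 200, TRUE, prob = c(0.3, 0.7))
  tags <- setNames(rep(2L, 200), vapply(lens, rand_nt, character(1)))
  lib <- tag_library("planted", tags, sum(tags))
  ld <- length_distribution(lib)
  expect_equal(sum(ld$reads), sum(lib$tags))
  expect_equal(sum(ld$unique), length(lib$tags))
  expect_equal(ld$length[which.max(ld$reads)], 24)
})

test_that("tag libraries round-trip through the TSV and collapsed FASTA formats", {
  tags <- setNames(c(3L, 1L), c(rand_nt(21), rand_nt(24)))
  lib <- tag_library("rt", tags, clean_total = 1000)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tag_tsv(lib, tsv)
  expect_equal(read_tag_tsv(tsv, "rt"), lib)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(lib, fa)
  seqs <- read_fasta(fa)
  expect_setequal(unname(seqs), names(tags))
  expect_true(all(grepl("^tag[0-9]+_x[0-9]+$", names(seqs))))
})
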