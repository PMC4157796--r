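# internal helpers shared across modules

.BASES <- c("A", "C", "G", "T")

# normalise a nucleotide vector: uppercase, U -> T
.norm_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.check_nt <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop("sequence contains non-nucleotide characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(TRUE)
}

# derive a stage-specific seed from a user seed, so that the same user seed
# used across different generator stages yields independent RNG streams
# (kept below 2^31 - 1)
.scramble_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) %% 44488 * 48271 + h * 30269) %% 2147483647)
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# random sequences of given lengths
.rand_seq <- function(lengths, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(lengths, function(l) {
    paste(sample(.BASES, l, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Hamming distance between equal-length strings
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
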