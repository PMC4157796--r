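#' RNA secondary structure prediction
#'
#' Predicts the minimum-free-energy secondary structure of a sequence and
#' returns it in dot-bracket notation with the folding energy (kcal/mol).
#' The engine is pluggable: `"vienna"` calls the ViennaRNA `RNAfold` binary
#' (a thermodynamic nearest-neighbour engine), `"nussinov"` uses the
#' package's deterministic base-pair-maximisation engine with pseudo-energies
#' (G:C -3, A:U -2, G:U -1 per pair, minimum loop 3 nt; lower fidelity but
#' dependency-free), and the default `"auto"` picks `RNAfold` when it is on
#' the PATH and the fallback otherwise.
#'
#' @param seq A nucleotide sequence (A/C/G/T/U, case-insensitive).
#' @param engine `"auto"`, `"vienna"` or `"nussinov"`.
#' @return An object of class `fold_result`: list with `sequence` (input,
#'   normalised), `structure` (dot-bracket), `mfe` (kcal/mol, <= 0) and
#'   `engine`.
#' @export
#' @examples
#' fold_rna(strrep("A", 20), engine = "nussinov")
fold_rna <- function(seq, engine = c("auto", "vienna", "nussinov")) {
  fold_batch(seq, engine)[[1]]
}

#' @rdname fold_rna
#' @param seqs Character vector of sequences (batched folding; one external
#'   process for the whole batch under the `"vienna"` engine).
#' @export
fold_batch <- function(seqs, engine = c("auto", "vienna", "nussinov")) {
  engine <- match.arg(engine)
  seqs <- .norm_seq(seqs)
  .check_nt(seqs)
  if (engine == "auto")
    engine <- if (.has_rnafold()) "vienna" else "nussinov"
  res <- if (engine == "vienna") .fold_vienna(seqs) else .fold_nussinov(seqs)
  lapply(seq_along(seqs), function(i) {
    structure(list(sequence = seqs[i], structure = res$structure[i],
                   mfe = res$mfe[i], engine = engine),
              class = "fold_result")
  })
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.2f kcal/mol, %s)\n",
                                             x$mfe, x$engine), sep = "")
  invisible(x)
}

.has_rnafold <- function() nzchar(Sys.which("RNAfold"))

.fold_nussinov <- function(seqs) {
  out <- lapply(seqs, .nussinov_fold)
  list(structure = vapply(out, `[[`, character(1), "structure"),
       mfe = vapply(out, `[[`, numeric(1), "mfe"))
}

.fold_vienna <- function(seqs) {
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin))
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fin)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", shQuote(fin)), stdout = TRUE))
  st <- grep("^[.()]+\\s+\\(", out, value = TRUE)
  if (length(st) != length(seqs))
    stop("unexpected RNAfold output (", length(st), " structures for ",
         length(seqs), " sequences)")
  structure_s <- sub("\\s.*$", "", st)
  mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", st))
  list(structure = structure_s, mfe = mfe)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure Dot-bracket string (balanced `(`/`)`, `.` unpaired).
#' @return Integer vector: position of the pairing partner, 0 when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("invalid character in dot-bracket string")
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}
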