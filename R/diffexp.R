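#' Reads-per-million normalisation
#'
#' `rpm = count / clean_total * 1e6`, at full floating precision. The
#' denominator is the library's clean-read total, not the sum of retained
#' miRNA counts.
#'
#' @param count Read count(s), >= 0.
#' @param clean_total Clean-read total of the library (> 0).
#' @return Normalised expression in reads per million.
#' @export
#' @examples
#' normalize_rpm(1475, 10691271)
normalize_rpm <- function(count, clean_total) {
  if (any(clean_total <= 0)) stop("clean_total must be positive")
  count / clean_total * 1e6
}

#' Log2 fold-change with zero flooring
#'
#' `log2(rpm2 / rpm1)` after replacing any zero RPM by `floor`, so the
#' fold-change of a count of zero is finite. The default floor of 0.01 RPM is
#' the value uniquely recoverable from published zero-count fold-changes
#' (e.g. a 244-versus-0 pair at ~10.7M reads/library gives -11.16 only with
#' a 0.01 floor). Rounding is left to reporting time.
#'
#' @param rpm1,rpm2 Normalised expressions (library 1, library 2).
#' @param floor Replacement value for a zero RPM.
#' @return log2 fold-change (library 2 over library 1), unrounded.
#' @export
#' @examples
#' log2_fold_change(normalize_rpm(244, 10691271), normalize_rpm(0, 10712733))
log2_fold_change <- function(rpm1, rpm2, floor = 0.01) {
  stopifnot(all(rpm1 >= 0), all(rpm2 >= 0))
  log2(pmax(rpm2, floor) / pmax(rpm1, floor))
}

# log pmf of the conditional distribution of the library-2 count y given the
# library-1 count x:  p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)),
# i.e. Y | x ~ NegBinom(size = x + 1, prob = N1/(N1+N2))
.ac_logpmf <- function(y, x, N1, N2) {
  lq <- log(N1) - log(N1 + N2)
  l1q <- log(N2) - log(N1 + N2)
  lchoose(x + y, y) + (x + 1) * lq + y * l1q
}

#' Exact two-library tag-count p-value (Audic-Claverie test)
#'
#' Conditional on the count `x` observed in library 1, the count in library 2
#' follows the negative-binomial-form distribution
#' `p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`,
#' where `N1`, `N2` are the clean-read totals. The two-sided p-value is
#' `min(1, 2 * min(P(Y <= y), P(Y >= y)))`, both tails including the point
#' mass. The test conditions on the larger of the two counts (the pair is
#' swapped when `y > x`), which makes the p-value exactly symmetric in the
#' two libraries and is the convention that reproduces published tag-count
#' tables. Tails are computed by log-space summation: the tail on the side
#' of `y` relative to the conditional mode is accumulated directly (the far
#' tail is truncated under a geometric-series bound once terms decay), and
#' the complementary tail follows from normalisation, so the computation is
#' stable for `x + y` up to well beyond 1e6 counts.
#'
#' @param x,y Tag counts in libraries 1 and 2.
#' @param N1,N2 Clean-read totals of libraries 1 and 2.
#' @return Two-sided p-value in `[0, 1]`. Vectorised over `x`, `y`.
#' @export
#' @examples
#' audic_claverie_pvalue(252, 142, 10691271, 10712733)  # ~2.3e-08
audic_claverie_pvalue <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), N1 > 0, N2 > 0)
  if (length(x) > 1 || length(y) > 1) {
    k <- max(length(x), length(y))
    x <- rep_len(x, k); y <- rep_len(y, k)
    return(vapply(seq_len(k), function(i)
      audic_claverie_pvalue(x[i], y[i], N1, N2), numeric(1)))
  }
  if (y > x) { tmp <- x; x <- y; y <- tmp; tmp <- N1; N1 <- N2; N2 <- tmp }
  lq <- log(N1) - log(N1 + N2)     # log P(success)
  l1q <- log(N2) - log(N1 + N2)
  # conditional mode of y | x
  mode_y <- floor((x + 1) * N2 / (N1 + N2) / (N1 / (N1 + N2)))
  if (y <= mode_y) {
    # lower tail summed directly: log p(0..y)
    yy <- 0:y
    logp <- lchoose(x + yy, yy) + (x + 1) * lq + yy * l1q
    lower <- exp(.logsumexp(logp))
    upper <- 1 - lower + exp(logp[length(logp)])
  } else {
    # upper tail summed forward from y in chunks; geometric truncation once
    # the term ratio r = (x+y'+1)/(y'+1) * N2/(N1+N2) falls below 1
    chunk <- 10000L
    logterms <- c()
    y0 <- y
    log_acc <- -Inf
    repeat {
      yy <- y0:(y0 + chunk - 1L)
      lp <- lchoose(x + yy, yy) + (x + 1) * lq + yy * l1q
      log_acc <- .logsumexp(c(log_acc, lp))
      ylast <- yy[chunk]
      r <- exp(l1q) * (x + ylast + 1) / (ylast + 1)
      if (r < 1) {
        # remaining mass < last term * r / (1 - r)
        log_rem <- lp[chunk] + log(r) - log1p(-r)
        if (log_rem < log_acc + log(1e-16)) break
      }
      y0 <- y0 + chunk
    }
    upper <- exp(log_acc)
    lower <- 1 - upper + exp(.ac_logpmf(y, x, N1, N2))
  }
  min(1, 2 * min(lower, upper))
}

#' Differential-expression status of one miRNA
#'
#' `up` when the unrounded log2 fold-change is at least `fc_threshold` and
#' the p-value at most `p_threshold`; `down` symmetrically; otherwise
#' `not_significant`. Thresholds are inclusive.
#'
#' @param log2fc Unrounded log2 fold-change.
#' @param pvalue Two-sided p-value.
#' @param fc_threshold Fold-change threshold (default 1.0).
#' @param p_threshold P-value threshold (default 0.05).
#' @return `"up"`, `"down"` or `"not_significant"` (vectorised).
#' @export
classify_de <- function(log2fc, pvalue, fc_threshold = 1.0,
                        p_threshold = 0.05) {
  ifelse(pvalue <= p_threshold & log2fc >= fc_threshold, "up",
         ifelse(pvalue <= p_threshold & log2fc <= -fc_threshold, "down",
                "not_significant"))
}

#' Two-library differential expression table
#'
#' Computes RPM, floored log2 fold-change, the exact two-library p-value and
#' the significance status for each row of a count table. No
#' multiple-testing correction is applied by default (single-library designs
#' are conventionally reported with raw exact p-values); Benjamini-Hochberg
#' adjusted p-values can be added with `adjust = TRUE` and are then used for
#' the status call.
#'
#' @param counts Data.frame with a `mirna` column and two count columns.
#' @param totals Length-2 numeric: clean-read totals of the two libraries.
#' @param count_cols Names of the two count columns.
#' @param floor Zero-RPM floor, see [log2_fold_change()].
#' @param fc_threshold,p_threshold Significance thresholds.
#' @param adjust Apply Benjamini-Hochberg correction (non-default).
#' @return The input data.frame plus columns `rpm1`, `rpm2`, `log2fc`,
#'   `pvalue` (and `padj` if adjusted) and `status`.
#' @export
diff_expression <- function(counts, totals,
                            count_cols = c("pa2", "pa4"), floor = 0.01,
                            fc_threshold = 1.0, p_threshold = 0.05,
                            adjust = FALSE) {
  stopifnot(length(totals) == 2, all(count_cols %in% names(counts)))
  x <- counts[[count_cols[1]]]; y <- counts[[count_cols[2]]]
  counts$rpm1 <- normalize_rpm(x, totals[1])
  counts$rpm2 <- normalize_rpm(y, totals[2])
  counts$log2fc <- log2_fold_change(counts$rpm1, counts$rpm2, floor)
  counts$pvalue <- audic_claverie_pvalue(x, y, totals[1], totals[2])
  p_use <- counts$pvalue
  if (adjust) p_use <- counts$padj <- p.adjust(counts$pvalue, "BH")
  counts$status <- classify_de(counts$log2fc, p_use, fc_threshold,
                               p_threshold)
  counts
}

#' Up/down summary of a differential-expression table
#'
#' @param results Output of [diff_expression()], with a `set` column
#'   labelling each row `conserved` or `novel` (optional).
#' @return Data.frame of counts: rows `up`, `down`, `total_significant`;
#'   columns `all` plus one per `set` level when available.
#' @export
de_summary <- function(results) {
  tally <- function(df) c(up = sum(df$status == "up"),
                          down = sum(df$status == "down"),
                          total_significant = sum(df$status != "not_significant"))
  out <- data.frame(all = tally(results))
  if ("set" %in% names(results))
    for (s in unique(results$set))
      out[[s]] <- tally(results[results$set == s, , drop = FALSE])
  out
}
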