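---
title: "Methods: small-RNA and degradome analysis with srnadeg"
author: "srnadeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA and degradome analysis with srnadeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnadeg)
```

srnadeg re-implements, as tested reusable functions, the classical
single-replicate plant miRNA workflow: two small-RNA libraries from two
genotypes (here: a diploid, PA2, and its autotetraploid, PA4, of *Paulownia
australis*), a unigene transcript assembly in place of a genome, and paired
degradome (PARE) libraries that catch the uncapped 5' ends left by
miRNA-guided cleavage. This vignette explains each model and the choices
behind its defaults; nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Read cleaning and tag collapsing

Raw reads are trimmed of their 3' adapter (exact prefix/suffix match,
minimum overlap 6 nt, up to 1 mismatch) and then rejected, in order, as
adapter-contaminated (adapter at the read start or nothing left after
trimming), low-quality (mean Phred < 20; skipped for FASTA input),
N-containing, poly(A) (>= 80% A), or outside the 18-30 nt window. The
source protocol names these filter classes without quantifying them, so the
thresholds are configuration with standard Illumina-era defaults, not
fidelity claims. The cascade order makes the rejection tally a partition of
the input, and filtering is idempotent. Collapsing to unique tags keeps the
library's clean-read total as an independent quantity: it is the
normalisation denominator and is not the sum of retained miRNA counts.

## Annotation cascade

Tags are first matched (exact substring, either strand) against structural
ncRNA reference sets with precedence rRNA > tRNA > snRNA > snoRNA >
other ncRNA; survivors are compared with a mature-miRNA reference
(miRBase-style, U tolerated) by ungapped Hamming comparison, sliding along
references up to 2 nt longer, with a <= 2 mismatch allowance — the
"allowing two mismatches" convention under which published conserved-miRNA
tables are built. Ties go to the lexicographically smallest identifier.
Everything left is `unannotated` and feeds hairpin discovery. Each tag
receives exactly one class, so class counts partition the library.

## Hairpin discovery

For every transcript hit of an unannotated tag, two precursor windows are
excised — tag near the 5' end with a 150 nt downstream flank, and tag near
the 3' end with the flank upstream — padded by 30 nt on the tag-proximal
side so the stem below the miRNA/miRNA* duplex is captured when the tag
sits at the precursor edge. Windows are folded, trimmed to the stem-loop
enclosing the mature (walking outward along enclosing base pairs, stopping
at multiloop junctions), refolded, and judged against the community's
strict annotation criteria: mature length 20-23 nt, mature wholly within
one arm, <= 4 duplex mismatches (symmetric unpaired positions) and <= 2
bulged nucleotides (asymmetric excess), folding energy <= -18 kcal/mol,
precursor 60-300 nt, and a single major loop. The numeric limits are the
accepted community defaults (the source protocol cites the criteria
without numbers) and all are configurable via `hairpin_thresholds()`.

The star (miRNA\*) is derived from the fold under the 2-nt 3' overhang
rule: the star 5' end pairs with mature position `len - 2` and its 3' end
extends two nucleotides beyond the partner of the mature 5' end, with
nearest-paired fallback at unpaired anchors. Star counts of zero do not
invalidate a candidate — observed star reads are graded-up evidence, as in
published novel-miRNA tables. When the mature- and star-arm views of one
locus both pass, overlapping candidates collapse to the arm with the higher
library support.

Folding is a pluggable contract (`fold_rna()`): the default uses the
ViennaRNA `RNAfold` binary when on the PATH, otherwise a deterministic
base-pair-maximisation engine (Rcpp; pair pseudo-energies G:C -3, A:U -2,
G:U -1 kcal/mol, minimum loop 3 nt). The fallback is lower fidelity — it
has no stacking or loop entropies — but is deterministic, dependency-free,
and its pseudo-energies are scaled so that the -18 kcal/mol acceptance
threshold discriminates the same ideal-versus-weak hairpins; all tests hold
under either engine. When both windows around a hit pass, the higher
|MFE|-per-nucleotide window is kept (a deterministic tie-break the source
protocol does not specify).

## Differential expression

Counts are normalised to reads per million of the clean total
(`rpm = count / clean_total * 1e6`) and compared as
`log2(rpm2 / rpm1)` with zero RPMs floored at 0.01. The floor value is not
stated in the source table but is uniquely recoverable from its zero-count
rows (244 vs 0 at ~10.7 M reads/library prints -11.16, which only a 0.01
floor yields); it is a configurable default here.

Significance uses the exact two-library tag-count test: conditional on the
count `x` in one library, the count in the other follows

\[ p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
   \frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}} , \]

a negative-binomial form in the two clean totals \(N_1, N_2\). The
two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`, both tails
including the point mass. Two numerical choices matter:

* **Conditioning direction.** The test conditions on the *larger* of the
  two counts. This is the convention that reproduces published tables
  (e.g. 30 vs 40 prints 2.38E-01, the condition-on-40 value; 252 vs 142
  prints 2.27E-08, the condition-on-252 value) and it makes the p-value
  exactly symmetric in the two libraries.
* **Tails in log space.** The tail on `y`'s side of the conditional mode is
  accumulated directly by log-space summation, truncated once the term
  ratio falls below 1 under a geometric-series remainder bound of 1e-16
  relative; the far tail follows by normalisation. This keeps the
  computation exact-to-double for counts beyond 1e6 with no factorial
  overflow.

The filter is inclusive — `|log2fc| >= 1.0` and `p <= 0.05` — matching the
parenthetical form in the source's results. No multiple-testing correction
is applied by default (none was applied in the source; Benjamini-Hochberg
is available behind `adjust = TRUE`).

`table_reproduction()` recomputes every row of the bundled printed count
table. Three reproduction facts are worth stating precisely, because the
tests assert them: (i) strict round-to-nearest agreement of fold-changes
holds for 75 of 76 rows — the pas-miR156a row prints 0.51 while its own
counts (2251/3231) recompute to 0.5185, consistent instead with the
neighbouring pas-miR156b counts; all 76 rows agree within one unit in the
last printed place. (ii) The printed family shares (89.44% / 86.35% for
the dominant family) are truncations of 89.4433 / 86.3563, not roundings.
(iii) The published "15 down-regulated" is not reproducible under the
stated thresholds: exactly three of the claimed rows (pas-mir3,
pas-mir8a-3p, pas-mir8b-3p) carry printed p-values above 0.05, and the
report flags exactly those rather than reverse-engineering them. The
pas-mir8a-3p printed value (4.57E-01 for 29 vs 0) is irreconcilable with
any exact two-library convention (~1.8E-09 recomputed) and is treated as a
table typo.

## Degradome target calling

Degradome tags are matched perfectly to transcript sense strands; each tag
adds its count at the position of its 5'-most base, multi-mapping tags
counting at every locus (flagged, not fractionally split — determinism and
transparency over elegance). Candidate sites are scanned ungapped with the
dominant plant scoring convention: Watson-Crick 0, G:U wobble 0.5, mismatch
1, gap 2 (gapped alignments are supported in `score_site()` via pre-aligned
strings; the scanner itself is ungapped), total score <= 4, and strict
Watson-Crick pairing — G:U excluded — at miRNA positions 10 and 11, since
the source's own figure legend labels G:U a mismatch. The slice position is
the transcript base paired to miRNA position 10; an event is emitted only
when the degradome profile carries at least one read there (configurable).

T-plot categories follow a declared convention (the source does not print
its definitions): category I — slice abundance equals the transcript
maximum (ties allowed); II — above the median but below the maximum; III —
at or below the median, with the median computed over positions having at
least one read (matching t-plot practice of plotting observed signatures).
Categories are scale-invariant. At most one event is kept per (miRNA,
transcript, slice position); alternatives resolve to the lowest score, then
the leftmost site.

## Synthetic data: what it emulates, and what it does not

The generator is first-class, tested code and defines the study conditions
for every stochastic test:

* **Transcriptome** — uniform random ACGT contigs (default 0.5 GC,
  0.8-2 kb), standing in for a unigene assembly.
* **Hairpins** — ideal inverted repeats: perfect miRNA/miRNA* duplex with
  2-nt 3' overhangs, 15 nt stem extension, 8 nt loop, matures alternating
  between the 5p and 3p arms, mutually > 2 mismatches apart so truth labels
  stay unambiguous under the conserved-matching allowance.
* **Libraries** — per-miRNA counts drawn independently per condition as
  Poisson with mean `rpm * depth / 1e6`; default RPM levels cycle
  5000/10000/20000/40000 (the mid range of conserved plant miRNA families,
  whose published counts span roughly 1 to 53,000 RPM) and true log2
  fold-changes cycle 0, +1, -1, +2.5, -2.5 at 1e6 reads per library.
  Poisson, not negative binomial, because a single library per condition
  identifies no overdispersion (NB is available behind `dispersion`).
  Background tags are random sequences rejection-sampled away from planted
  matures. Each generator stage derives an independent RNG stream from the
  one user seed.
* **Degradome** — 20 nt tags starting exactly at true slice positions at
  peak height 50, over uniform background positions at 10% of the peak.

The Poisson error of a log2 fold-change estimate is roughly
\(\sqrt{1/x + 1/y}/\ln 2\); at the default levels the smallest expected
count (~880 at fold-change -2.5 from 5000 RPM) gives a standard error near
0.06, so recovery within ±0.2 log2 units is a >3-sigma statement — the
test suite asserts it for all planted miRNAs at or above 50 RPM. What the
generator does *not* emulate: sequencing error, quality-score realism
beyond what the filters need, expression heterogeneity within a family,
imperfect duplexes (planted hairpins are ideal), or degradation background
correlated with expression. Passing tests therefore demonstrate that the
implementation recovers a cleanly planted truth, not that thresholds are
optimal for noisy field data.

Problem sizes used by the deterministic checks and the end-to-end
recovery run (40 transcripts, 20 hairpins, 20 cleavage sites, 1e6 reads
per library) were chosen as the smallest sizes at which the Poisson
arguments above have comfortable margins.

## Degenerate inputs and tie-breaks

Empty read sets, empty libraries and empty hit tables flow through every
stage as empty results, not errors; a transcript absent from the degradome
yields no profile; a slice position with no reads is a signal ("no
event"), not an error. Deliberate errors: zero or negative clean totals,
adapter trimming requested with an empty adapter string, hit coordinates
outside a transcript, and non-nucleotide characters where sequence is
required. All tie-breaks are deterministic and documented at the function
level (lexicographic reference ids, lowest-score-then-leftmost sites,
higher |MFE|/nt windows, higher-support arms).

## Known limitations

* The conserved matcher is a direct Hamming scan — appropriate for
  reference sets of a few thousand matures, not for genome-scale search.
* The ungapped site scanner cannot emit gapped target alignments (the
  scoring function itself can evaluate them when given pre-aligned
  strings); plant cleavage sites with internal bulges are missed.
* The fallback folding engine maximises weighted pairs; its "MFE" is a
  pseudo-energy. Candidate energies should be compared across engines only
  qualitatively.
* Transcript mapping treats unigenes as sense-oriented; hairpin discovery
  considers forward-strand hits only.
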