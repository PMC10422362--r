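---
title: "Quality-symbol stratified evaluation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-symbol stratified evaluation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualstrat)
```

## The question

Every base a nanopore basecaller emits carries a quality symbol: the
printable ASCII character on the fourth line of its FASTQ record, encoding
under the Sanger convention a Phred score Q = ordinal − 33 and hence a
claimed error probability 10^(−Q/10). `qualstrat` treats that claim as a
testable hypothesis. Given reads and their alignments, it groups every read
base by its symbol and classifies it from the alignment as matched,
mismatched, inserted or clipped, so each symbol's empirical error rate can
be placed next to its theoretical one. A separate harness asks the
complementary question: do downstream tools consume the symbols at all?

## Quality-score models

Two published scoring schemes are implemented.

* `chironQuality(p1, p2)` = 10·log₁₀(p1/p2), the score used by basecallers
  that compare the two most probable nucleotide calls. It is zero on ties,
  grows with the odds ratio, and is invariant under common rescaling of
  (p1, p2) — properties the tests assert directly.
* `scaledQuality(p, coeffs)` = −10·(y·log₁₀(1−p) + log₁₀ x), the scaled
  Phred-style score with model-specific coefficients. Six coefficient sets
  are built in; two of them (x = y = 1) reduce the formula to the plain
  Phred transform −10·log₁₀(1−p), which the tests verify as an exact
  identity. Coefficient selection for the Nanonet family depends on the
  read kind and, for template reads, on p, with the boundary p = 0.1
  assigned to the "p ≤ 0.1" set, reading the set labels literally.

Scores are returned as unrounded reals. The rounding a basecaller applies
before emitting a symbol is not published, so a separate helper
(`clampPhred()`) rounds half-up and clamps to the printable Phred range
[0, 93]; keeping this outside the formulas leaves both behaviours
inspectable.

One conflict worth recording: some published per-symbol probability
figures do not agree exactly with Phred+33 arithmetic (e.g. a symbol at
Q = 20 implies a 0.99 correct-call probability, while accompanying prose
sometimes quotes slightly different values). The package follows standard
Phred+33 arithmetic everywhere.

## Stratified evaluation

The unit of computation is one primary alignment walked operator by
operator:

* `=` → matched, `X` → mismatched, `I` → inserted, `S`/`H` → clipped;
* `M` (alignment match of unspecified identity) is resolved to
  matched/mismatched through the MD tag when present, else by direct
  comparison against a supplied reference; with neither the run aborts
  rather than guess — silent misclassification would corrupt every
  downstream rate. Under reference resolution, a column whose reference
  base is 'N' counts as mismatched.
* `D` consumes no read base. A deleted base has no quality symbol, so
  deletions are excluded from the per-symbol panels and tallied once at
  set level, where they enter the read-set summary's deletion percentage.

Secondary (flag 256) and supplementary (flag 2048) alignments are skipped:
each read contributes exactly once, which is what makes the conservation
identity — matched + mismatched + inserted + clipped equals each symbol's
base count in mapped reads — exact rather than approximate. Reads present
in the SAM but absent from the FASTQ are an error, not a skip, because a
silent id mismatch shifts denominators invisibly.

Reverse-strand records store SEQ and QUAL in reference orientation;
positions are mapped back to original read coordinates (index i ↔
L − 1 − i) so the classification table always covers the read as the
basecaller emitted it. Hard-clipped bases, absent from SEQ, are recovered
from the original read by id and counted as clipped.

Two denominator conventions needed a decision:

* **Mapped fraction per symbol** = (matched + mismatched + inserted) /
  (all bases of that symbol in the FASTQ). Soft- and hard-clipped bases
  count as unmapped. Aligned-base semantics were chosen because they make
  the expected increase of mapped fraction with Q meaningful; counting
  clipped bases as "mapped" would flatten the curve by construction.
* **Read-set summary percentages** use alignment columns
  (matched + mismatched + inserted + deleted) as the denominator for the
  match/substitution/deletion/insertion split, and all FASTQ bases for the
  mapped percentage. Other mapping-statistics tools use slightly different
  conventions, so absolute values on real data can differ by fractions of
  a percent; the convention here is fixed and printed with the outputs.

Percentages are rounded half-up to two decimals; fractions and rates in
the per-symbol table are left unrounded.

## The simulator and what passing tests show

Real long-read data with known per-base truth does not exist, so the
package carries a generator that produces the statistical structure the
analysis assumes, together with the truth labels the analysis must
recover:

* each emitted base draws a symbol from a configurable profile
  (`defaultSymbolProfile()`: a unimodal negative-binomial shape over
  Q = 5..30 peaking at Q = 12, resembling the per-symbol distributions of
  basecalled read sets);
* conditional on a symbol with Phred Q, the base is substituted with
  probability f·10^(−Q/10), followed by an insertion with probability
  f·insFraction·10^(−Q/10); the next reference base is deleted with
  probability f·delFraction·10^(−Q/10). The three draws are independent
  Bernoullis, so the mismatch rate among aligned bases of a symbol equals
  its substitution rate exactly in expectation. The defaults
  insFraction = delFraction = 0.5 give the roughly 2:1:1
  substitution:insertion:deletion balance typical of nanopore data;
  f = `miscalibrationFactor` (default 1) models a basecaller whose symbols
  are systematically off by a constant factor;
* clip flanks of uniform random sequence with geometric length (mean
  `clipFlankMean` per end, default 0, 20–25 in the shipped experiments)
  exercise the clipped category with labels known by construction rather
  than via a real mapper's behaviour;
* insertions are placed after the current base and inherit a
  profile-drawn symbol; errors are i.i.d. per base given the symbol.

The emitted truth SAM uses `=`/`X` CIGARs, both strands, and SAM
orientation conventions, so the evaluation consumes it through exactly the
same code path as a mapper-produced file.

What this does and does not establish: the exact-oracle tests show the
CIGAR walk, strand handling, clipping and bookkeeping are correct, and the
calibration tests show the estimator recovers known per-symbol error rates
and a known miscalibration factor within binomial sampling error. The
simulator deliberately omits homopolymer and k-mer context effects,
signal-level artefacts, chimeras and mapping ambiguity — the analysis is
symbol-marginal, so context effects change what real data look like but
not whether the tally is computed correctly. Conclusions about any
particular basecaller still require real reads and a real mapper.

## Invariance harness

`makeVariants()` derives from one FASTQ the three inputs of the identity
experiment — real qualities, constant '?' (Phred 30) qualities, and FASTA
with qualities removed — and re-validates from the written files that ids
and sequences are byte-identical before returning. `runAndCompare()` runs
a downstream command on each variant and compares outputs pairwise. The
command is an opaque template (or R function); no downstream tool is
bundled or re-implemented, because the contribution is the comparison
design, and the two built-in toy commands (one that never reads quality
lines, one that sums quality ordinals) exercise both verdicts in
milliseconds.

Output identity granularity was an open choice: the harness exposes both
byte-level and record-level comparators and defaults to record-level,
since headers and timestamps differ between runs without the records
differing (VCF `##` lines and SAM `@PG`/`@CO` lines are ignored by the
respective comparators). Verdicts are only meaningful for deterministic
commands; fixed-seed flags belong inside the template.

## Masking

`maskReference()` consumes BED intervals (0-based half-open) rather than
discovering repeats: repeat discovery is a solved upstream problem and its
output formats all map to BED. Intervals are merged before counting so
overlapping annotations are not double-counted; bases already 'N' inside
intervals are included in the masked count but reported separately, since
published masked-bp figures do not state how pre-masked bases were
treated. Masking is idempotent and length-preserving, and case outside
intervals is untouched (soft-masked references survive a round trip).

## Problem sizes and numerical choices

The shipped experiments use a 60 kb reference with 1,000 reads of mean
1 kb for the oracle-equivalence check, and a 100 kb reference with 2,000
such reads per calibration run — sizes at which every symbol in the
profile's bulk accumulates well over 500 aligned bases, making the
3-binomial-sigma criteria sharp while keeping a full run in tens of
seconds. Statistical tests are pinned to fixed seeds: they are exact
regression tests of a stochastic pipeline, not flaky approximations.
Degenerate inputs (empty FASTQ, unmapped-only SAM, zero-length interval
lists) are all defined and tested rather than left to crash.

## Known limitations

* Only strict 4-line FASTQ is accepted; wrapped FASTQ is ambiguous ('@'
  is a valid quality character) and no basecaller emits it.
* Text SAM is the contract; BAM/CRAM inputs should be converted with
  `samtools view` first.
* The evaluation trusts the mapper's alignment; systematic mapping bias
  (e.g. in repeats, hence the masking stage) shifts empirical rates in
  ways the package reports but cannot correct.
* Duplicate read ids are disambiguated by suffixing, with a warning.
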