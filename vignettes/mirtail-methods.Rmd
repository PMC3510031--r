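---
title: "Calling 3' terminal tailing of mature miRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 3' terminal tailing of mature miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtail)
```

## The analysis in one paragraph

Mature miRNAs can receive untemplated 3' uridines or adenines from
non-canonical poly(A) polymerases. In sequencing data such an addition is a
read that extends past the annotated mature 3' terminus, and the added base
sits at the *+1 position* — one nucleotide beyond the terminus. Three
confounders must be controlled. A sequencing error can mimic an addition,
so every called base must pass a quality filter. The genomic sequence
downstream of the miRNA locus can itself begin with T or A, in which case a
longer read may be alternative processing rather than enzymatic addition;
the catalog therefore carries each miRNA's genomic 3' flank and a +1 base
equal to the templated flank base is never called an addition. Finally, the
strongest evidence — *unambiguous uridylation* — is a terminal U over a
templated base that is not T, which can only arise enzymatically.
`mirtail` implements this calling pipeline together with the paired
wild-type/knockout statistics used to show that an enzyme knockout
depletes uridylation, and a fully seeded simulator that provides per-read
ground truth so each stage is verifiable at desk scale.

## Coordinates

All offsets beyond the mature 3' terminus are 1-based into the genomic
flank: offset 1 is the +1 position, offset k is the k-th flank base. The
mature terminus itself is offset 0 and is not a flank position;
`templated_base_at()` rejects it. A read's `terminal_read_offset` is its
length minus the mature length: 0 for a read ending exactly at the
terminus, k > 0 for a k-base overhang, k < 0 for a read ending short of
the terminus. This convention is asserted in tests against the simulator's
own flank bookkeeping to prevent off-by-one drift.

## Demultiplexing and trimming

Libraries are multiplexed with four 3' adapters that differ in a leading
barcode. A read is assigned to a sample iff exactly one sample's adapter
matches; the match rule is the leftmost exact occurrence of an adapter
prefix of at least 8 nt (the full adapter whenever the read is long
enough). Adapter matching is exact — no mismatches — because the protocol
this models trims only perfectly matched adapters; the 8-nt floor handles
adapter run-off at the end of a fixed-length read. Reads matching no
adapter (`unrecognizable`), several adapters (`ambiguous`), or whose
trimmed insert falls outside [`min_insert`, `max_insert`] = [16, 30] nt
are discarded with a reason code. The 30-nt ceiling mirrors the size
selection of the library prep (<30 nt inserts); the 16-nt floor removes
fragments too short to assign. Both bounds are arguments. The 5' adapter
is assumed absent from the sequenced read (sequencing starts at the
insert); reads containing N are passed through and left to the aligner
and quality filter.

## Alignment under an internal / 3'-end mismatch budget

Reads are 5'-anchored to each mature sequence with no offset — the
analysis interrogates only 3' variation, and anchoring makes "internal"
versus "3' end" well defined. Positions are compared to the mature body
and, beyond the terminus, to the genomic flank. A mismatching position
counts to the 3'-end class when it lies in the read's terminal 5 nt or
beyond the mature terminus, otherwise to the internal class. A candidate
is feasible with at most 2 internal and 5 3'-end mismatches; a budget of
5 at the 3' end is read as a 5-nt window, which also bounds the maximum
overhang at 5 nt. Overhang bases that mismatch the flank still count
against the 3'-end budget but are retained verbatim — they are the tails
being studied. Among feasible candidates the winner has the fewest total
mismatches, then fewest internal, then longest overlap, then the
lexicographically smallest catalog name (radix/C-locale order, so the
tie-break is total and platform independent). A tie surviving the first
three keys flags the read `ambiguous`: it keeps its deterministic
assignment for quantification but is excluded from tail calling, so that
sequence-family cross-talk cannot inflate modification calls. N bases
count as mismatches wherever compared. The implementation is a small C++
kernel over the unique read sequences; an independent brute-force
enumerator in the test suite checks it exhaustively over all 4^8 length-8
reads against a two-entry catalog.

## NQS filtering and variant calling

A called base must pass the neighborhood quality score: Phred >= 20 at
the call site and mean Phred >= 15 over a 5-base window centered there,
truncated at read ends. The original NQS formulation used larger
neighborhoods; "window length 5" is implemented as the centered +/-2
window and both thresholds and the window width are arguments
(`nqs_params()`). The filter is applied at the variant position only (the
+1 base, or the terminal base for unambiguous-uridylation calls), not to
every aligned base.

A +1 nucleotide becomes a *retained variant* iff its count over all reads
of the miRNA reaches `min_variant_freq` = 1/1000 and it differs from the
templated flank base at offset 1. The threshold comparator is `>=` ("1 or
more per 1,000"), with a strict `>` available, since the two phrasings of
the rule differ; the boundary case is pinned in a test. Excluding the
templated base keeps the headline percentages consistent with the
complementary unambiguous analysis: a +1 base equal to the flank is
alternative processing, not addition. Percent adenylated/uridylated is
100 x retained count / total reads, 0 when the variant is not retained,
and NA — never 0 — when the miRNA has no reads, so downstream filters
see missing data rather than a fake zero. Unambiguous uridylation counts
NQS-passing reads whose terminal base is T over a non-T template; when
several catalog entries share a mature sequence (multi-locus miRNAs) the
non-T condition must hold for every entry's flank, a conservative reading
of "non-genomic U". A species is called uridylated in a library when it
has >= 1 such read (`min_events`, configurable), the weaker of the two
plausible rules; the 1/1000 threshold variant is available through the
same argument.

## Comparative statistics

**RPM.** Reads per million aligned miRNA reads per library; every RPM
column sums to 10^6 by construction and the invariant is tested.

**Genotype correlation.** Pearson correlation of mean WT vs mean KO RPM
over miRNAs detected (>= 1 read) in at least one library of each
genotype, computed on log10(RPM + 1) because abundances span orders of
magnitude; a linear-scale option exists.

**Read-length ANOVA.** Per-library length fractions over 15-30 nt enter a
two-way fixed-effects ANOVA (genotype x length). Per-length genotype
contrasts use the pooled residual variance and are Bonferroni-corrected
across the number of lengths tested — the correction actually used for
this figure-style analysis; no FDR is applied anywhere else. With fewer
than two libraries per genotype the test is skipped with a warning and
the descriptive histogram still returned.

**Waterfall.** Fold changes are computed within manifest-defined library
pairs (the sex/littermate matching of the design), then combined by
geometric mean, matching "per-pair ratio, geometric mean over the three
libraries". Inclusion requires > 10,000 summed WT reads and > 0.1 %
pooled (read-weighted) WT modification — the filters are applied to the
pooled wild type because the per-library aggregation is otherwise
ambiguous; per-library filtering would only shrink the included set. When
a pair's percent is zero on either side, half the minimum detectable
percent in that library (100 x 0.5 / total reads) is added to numerator
and denominator — a standard half-count continuity correction that keeps
the geometric mean defined without biasing non-zero ratios. The summary
is a one-sample t-test of log2 ratios against 0 with a 95 % CI
(t distribution, df = n - 1); the log scale is the natural one for ratios
and makes "no effect" exactly 0.

**Species counts.** Restricted to miRNAs seen in every library of both
genotypes, the number of species uridylated in *all* WT libraries is
compared to the KO analogue by a 2-category chi-squared goodness of fit
against equal proportions. The exact construction of the published test
is not recoverable, so a 2 x 2 contingency alternative over the shared
universe is provided behind the `test` argument. `chisq_gof()` is a thin
wrapper over `stats::chisq.test()`; its agreement with an exact mid-p
binomial oracle is property-tested, but only in the approximation's
validity regime (expected counts >= 10, tolerance 0.03) — outside that
regime the chi-squared approximation genuinely departs from exact
binomial tails by far more than any test tolerance, which is a property
of the statistic, not of the implementation.

## The simulator

`simulation_config()` describes a paired WT/KO multiplexed experiment:
three library pairs, four barcode-bearing 3' adapters, miRNA-dominated
inserts below 30 nt, and U/A tails of length 1-4. Defaults chosen where
the modeled design is silent, with rationale:

* **Reads** are fixed 36-nt single-end (a GAIIx-era read length), built as
  mature + tail + barcode + adapter core, truncated.
* **Abundance** is log-normal (sdlog 1.2), giving the several-decade
  dynamic range typical of liver miRNA content.
* **Tailing** is per-miRNA: WT U- and A-tail probabilities uniform on
  [0.01, 0.10] (modification levels of a few percent, as observed for
  the more heavily modified species), at most one tail type per read,
  homopolymeric tails with geometric length decay 0.35 over 1-4 nt so
  mono-additions dominate.
* **The knockout effect** is multiplicative on the U-tail probability
  (`ko_u_factor`, default 0.3) with A tailing untouched
  (`ko_a_factor` = 1), reproducing the observed signature of a skewed U
  waterfall and a centred A waterfall.
* **Templated flanks**: a configurable fraction (default 0.25) of flanks
  begins with T, creating the templated +1 U calls the caller must
  refuse.
* **Errors** are substitutions only, at `per_base_error_rate` (default
  0.001). Correct bases draw Phred ~ N(32, 4) clipped to [2, 40];
  erroneous bases draw from N(14, 4), tying low quality to error so the
  NQS filter is exercised meaningfully rather than vacuously. Error
  positions and substituted bases are recorded per read, and a test
  reconstructs every emitted read exactly from its truth annotation.
* **Reference hygiene**: fabricated matures are pairwise Hamming >= 3
  over their common prefix (unless ambiguous families are requested) and
  are screened so that no error-free read built from them produces an
  adapter match other than the true one — without the screen, a catalog
  sequence embedding an adapter-like 8-mer would send all its reads to
  the ambiguous bin. Real catalogs can contain such sequences; their
  reads are correctly discarded as ambiguous, which is the intended
  behaviour, but the simulator excludes them so that round-trip tests
  can assert exact recovery.

The simulator does *not* model ligation bias, PCR duplicates, 5'
isomiRs (an option exists to disable the pairwise-distance guarantee but
5' ends are always exact), indels, non-miRNA small RNAs, or precursor
uridylation. Consequently, passing tests demonstrate that the pipeline's
logic is correct under its stated error model — they do not certify
performance on real libraries, where adapter chemistry and content are
substantially messier.

## Planted effects and problem sizes

Test and acceptance runs use sizes chosen to keep the whole suite in
minutes on one CPU; they are stated here as the package's choices.

* *End-to-end recovery*: 3 pairs x 50 miRNAs x 2 x 10^5 reads/library,
  `ko_u_factor` 0.3 — the U waterfall CI must cover log2 0.3 and the A
  waterfall CI must cover 0.
* *Null calibration*: 200 replicates at 25 miRNAs x 10^4 reads/library
  with both knockout factors 1; waterfall t-test p-values are tested for
  uniformity (KS, alpha 0.01). At this depth the paper-scale 10,000-read
  inclusion filter is unattainable, so the read filter scales to 500
  while the percent filter is unchanged.
* *Length effect*: the 23-nt deficit is planted directly on the length
  distribution — per-library multinomial draws (10^5 reads) from a
  realistic 15-30 nt profile peaked at 22 nt, with the KO 23-nt mass
  scaled by 0.7 and renormalised. Planting via reduced tailing cannot
  make 23 nt the *uniquely* strongest contrast: fraction mass is
  conserved, so the loss at 23 nt reappears as an equal-magnitude gain at
  the mature length, and the 22-nt contrast ties or beats it by
  construction. The direct plant isolates what the statistic must
  detect; the tailing-driven length shift is still exercised (and its
  direction checked) in the pipeline tests.
* *Species thinning*: 120 miRNAs at 5 x 10^4 reads/library put many
  species near the one-event detection margin, where a 70 % uridylation
  loss measurably thins the knockout species set. At high depth the
  >= 1-event rule saturates for every abundant species and the counts
  cannot differ — marginal species carry this statistic.

## Degenerate inputs and numerical conventions

Zero-depth simulations return empty, well-typed tables. Zero-read miRNAs
yield NA percentages flagged by `defined`. Libraries with zero aligned
reads abort RPM quantification explicitly. An empty waterfall (nothing
passes the filters) warns and returns an NA summary rather than failing.
All randomness is seeded; identical configurations produce byte-identical
FASTQ files, manifests and result tables, and per-library seeds derive
deterministically from the experiment seed. Ties in every ranking are
broken by radix (C-locale) name order.

## Limitations

The catalog substitutes precomputed per-miRNA genomic flanks for
whole-genome alignment; this is equivalent for +1..+5 templated checks
but cannot discover modifications of unannotated loci. Internal editing,
5' variation and quality-aware alignment scoring are out of scope. The
unambiguous-uridylation rule is conservative for multi-locus miRNAs and
will undercount when only some loci have T-starting flanks.
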