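# mirtail

Detection and quantification of 3′ terminal tailing (uridylation and
adenylation) of mature miRNAs from multiplexed small RNA sequencing, with
paired wild-type / knockout comparative statistics and a seeded simulator
that provides ground truth for every stage.

## The problem

Non-canonical poly(A) polymerases such as the uridyltransferase Zcchc11
(TUT4) add untemplated U or A residues to the 3′ terminus of mature
miRNAs. These additions do not change miRNA abundance but tune silencing
activity, so detecting them reliably from small RNA-seq is the analytical
core of studying this regulatory layer. The signal is subtle: a tailed read
is a read extending one or more bases past the annotated mature 3′
terminus (the **+1 position**), and a genuine enzymatic addition must be
distinguished from sequencing error (via base-quality filtering), from
genomically templated downstream bases (via the genomic 3′ flank), and
from alternative precursor processing (via **unambiguous uridylation**: a
terminal U where the templated base is not T).

`mirtail` implements that analysis end to end for paired wild-type (WT)
vs knockout (KO) library designs:

1. **simulate** — seeded generation of multiplexed FASTQ library pairs
   with per-read ground truth (`simulation_config()`,
   `simulate_experiment()`);
2. **trim** — 3′-adapter barcode demultiplexing with exact-match trimming
   (`demultiplex_and_trim()`), discarding ambiguous or unrecognizable
   reads;
3. **align** — 5′-anchored assignment to a mature-miRNA catalog allowing
   at most 2 internal mismatches and 5 in the read's 3′-end region
   (`align_library()`), recording the 3′ overhang of every read;
4. **call** — +1-position A/U calling under the neighborhood quality
   score (NQS) filter (central Phred ≥ 20, window-of-5 mean ≥ 15) with a
   ≥ 1/1000 variant-frequency threshold, plus unambiguous-uridylation
   counting (`build_profiles()`);
5. **stats** — reads-per-million quantification and WT/KO correlation,
   read-length two-way ANOVA with Bonferroni contrasts, the
   geometric-mean fold-change **waterfall** analysis, and χ² goodness-of-
   fit tests (`quantify_rpm()`, `length_histogram_test()`, `waterfall()`,
   `chisq_gof()`, `species_uridylation_counts()`).

The waterfall statistic for miRNA *x* with libraries paired
(WT<sub>i</sub>, KO<sub>i</sub>) is

&nbsp;&nbsp;&nbsp;&nbsp;R<sub>x</sub> = ( ∏<sub>i</sub> pct<sub>KO,i</sub>(x) / pct<sub>WT,i</sub>(x) )<sup>1/n</sup>

the geometric mean across pairs of the percent of reads end-modified in
the knockout over the wild type, restricted to miRNAs with > 10,000 summed
WT reads and > 0.1 % WT modification; the per-nucleotide summary is a
one-sample t-test of log₂ R<sub>x</sub> against 0 with a 95 % confidence
interval.

## Worked example

```r
library(mirtail)

cfg <- simulation_config(n_mirnas = 30, depth_per_library = 50000,
                         ko_u_factor = 0.3, seed = 42)
report <- run_all(cfg, min_reads = 2000)
report
#> mirtail pipeline report
#>   libraries: 6 (3 pairs), 30 miRNAs, depth 50000
#>   aligned reads: 295551 (100.0% of demultiplexed)
#>   WT/KO abundance correlation r = 0.999 (30 miRNAs)
#>   U waterfall: mean log2 FC -1.731 [-1.867, -1.596], n = 14
#>   A waterfall: mean log2 FC -0.012 [-0.076, 0.051], n = 17
#>   unambiguous-U species: WT 26 vs KO 26 (p = 1)

glance(report$waterfall_u)
#> # A tibble: 1 × 7
#>   nucleotide n_mirnas mean_log2_fc ci_low ci_high statistic  p_value
#>   <chr>         <int>        <dbl>  <dbl>   <dbl>     <dbl>    <dbl>
#> 1 U                14        -1.73  -1.87   -1.60     -27.6 6.32e-13
```

The simulation planted a 70 % loss of U tailing in the knockout
(`ko_u_factor = 0.3`, true log₂ fold-change log₂ 0.3 ≈ −1.74) while
leaving A tailing untouched. The report shows exactly that signature: the
U waterfall is centred on −1.73 with the confidence interval covering the
truth, the A waterfall is centred on 0, and miRNA *quantities* remain
almost perfectly correlated between genotypes (r = 0.999) because tailing
affects sequence composition, not abundance. Per-miRNA ratios are in
`tidy(report$waterfall_u)`; `autoplot(report$waterfall_u)` draws the
sorted waterfall bars.

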