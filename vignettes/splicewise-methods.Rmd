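---
title: "Models and methods in splicewise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in splicewise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicewise)
```

splicewise predicts the splicing impact of single-nucleotide variants by
individual information theory and confronts the predictions with three
kinds of expression evidence. This vignette is the package's own account
of the models, the tunable parameters, the synthetic world the tests run
in, and the design decisions taken where the design was genuinely open.

## 1. The information model

An information weight matrix is built from an alignment of verified
functional splice sites. With per-position base counts over `n` sites
and pseudocount `c`,

$$f(b,l) = \frac{\mathrm{count}(b,l) + c}{n + 4c}, \qquad
R_{iw}(b,l) = 2 + \log_2 f(b,l) - e(n) \;\text{bits},$$

and a candidate window scores
$R_i = \sum_l R_{iw}(\text{window}[l], l)$. Bits are the natural unit
here: each bit corresponds to a twofold change in predicted
protein–RNA binding affinity, so a variant changing a site from
$R_{i,\mathrm{initial}}$ to $R_{i,\mathrm{final}}$ implies a minimum
affinity fold change of $2^{|\Delta R_i|}$. `fold_change()` reports this
quantity rounded to one decimal, the convention used in report tables.

**Window geometry.** The underlying site models do not impose a unique
window, so windows are fully configurable and carried in the matrix
header. Defaults: donors span offsets $-3..+5$ around the exon|intron
junction (9 nt), acceptors $-25..+2$ around the intron|exon junction
(28 nt) — the span of the polypyrimidine tract plus the invariant AG and
the first exonic bases. Junction coordinates are 0-based; the junction
is the *first intronic base* for donors and the *first exonic base* for
acceptors, a convention tested by coordinate round-trips on both
strands.

**Zero frequencies.** With pseudocount 0, a base never seen in training
has weight $-\infty$, and any window containing it scores $-\infty$: an
undefined logarithm is never replaced by a silently finite number. The
recommended analysis setting is `pseudocount = 0.25` (one prior
observation split across the four bases), which keeps every weight
finite while barely moving well-sampled columns.

**Small-sample correction.** `correction = "analytic"` subtracts
$e(n) = 3/(2 n \ln 2)$ bits per column, the leading-order bias of the
plug-in entropy estimator. It is off by default so the closed-form test
identities (column normalization, the `rsequence()` mean-score identity)
hold exactly; at the training sizes used here ($n \ge 1000$) it is
below $2\times10^{-3}$ bits per column either way.

**Convention caveat.** Published fold changes for sites crossing 0 bits
are not always plain $2^{|\Delta R_i|}$ (different tools clamp
negative-strength endpoints differently, and the convention is not
recoverable from printed tables). splicewise reports plain
$2^{|\Delta R_i|}$ and its acceptance checks use only worked examples
where that convention matches the printed value.

## 2. Variant evaluation and classification

`evaluate_variant()` rescores, under both alleles, every natural site
whose window covers the variant, and scans `cryptic_window` nt
(default 300, configurable; 600 covers the most distant validated
activation we model) on each side of nearby natural junctions for
cryptic sites under both alleles.

Classification against `criteria_config()`:

| class | rule |
|---|---|
| `inactivating` | natural site, $\Delta R_i < 0$, $R_{i,\mathrm{final}} < R_{i,\min}$ |
| `leaky_weakened` | natural site, $\Delta R_i \le -\delta_{\min}$, $R_{i,\mathrm{final}} \ge R_{i,\min}$ |
| `strengthened` | $\Delta R_i \ge +\delta_{\min}$ |
| `cryptic_activated` | functional cryptic site ($R_{i,\mathrm{final}} \ge R_{i,\min}$) that is strengthened, or reaches the weakened natural site's final strength |
| `pseudoexon_candidate` | intronic cryptic site crossing $R_{i,\min}$ from below, more than `pseudoexon_dist` nt from the natural junction |

Defaults: $R_{i,\min} = 1.6$ bits (the minimum functional site strength
— weakened sites above it still produce normal product, i.e. leaky
splicing), $\delta_{\min} = 0.1$ bits (the smallest change treated as an
effect), `comparable_margin` = 1.0 bit (one bit = twofold affinity, the
natural flagging unit), `sp_flag` = −1.0 bit with `het_min` = 0.10 (the
common-variant screen: a site weakened by more than a bit in a variant
with average heterozygosity above 10%).

`pseudoexon_dist` (default 200 nt) is this package's own cut: it
separates the exon-extension pattern (an intronic cryptic donor ~140 nt
out, splicing an extended exon) from the deep-intronic pseudo-exon
pattern (~220 nt and beyond). The boundary is tunable because the
biology is a continuum.

**Exon definition.** `exon_definition_total()` combines an exon's
acceptor and donor information, optionally penalized by an exon-length
term: the self-information of the exon's length bin relative to the
modal bin of a supplied length histogram, so a typical-length exon pays
nothing and unusual lengths pay $-\log_2 \hat p(\text{len}) + \log_2
\hat p(\text{mode})$ bits. The histogram form is a documented stand-in:
the exact length penalty used by existing exon-definition servers is not
published, and under the null model (no histogram) the total is simply
additive.

## 3. The splicing-index screen

`splicing_index()` computes SI = probeset intensity / gene intensity
from pre-normalized intensities (normalization itself, e.g. PLIER, is
out of scope; gene-level summaries are the preferred input, and the
fallback — the mean of the gene's probesets — announces itself loudly).
SI is scale-free per sample, which the tests assert.

`stepwise_filter()` implements the genotype-stepwise criterion exactly
as quoted: rare-homozygote and heterozygote group means `< 90%` of the
common-homozygote mean (strict at 90%), with the heterozygote mean
strictly *between* the homozygote means (a tie at either end fails —
"in between" is read as strict interior ordering). With no rare
homozygotes the two-group reduction (het < 90% of common) applies and
the result is labelled *partial*. A `direction = "increase"` mirror
(on reciprocals) supports probesets that gain signal, e.g. one that
detects an intronic cryptic site. No minimum group size is imposed by
default (`min_group_n = 1`): the screen is a criterion, not a
significance test.

## 4. qPCR relative expression

Expression is $\propto E^{-C_t}$ for amplification efficiency $E$
(default 2.0, perfect doubling — per-assay efficiencies are
configurable; none were stated for the assays we model). Replicates are
averaged within samples first; group ratios are

$$\mathrm{ratio} = \frac{E_\mathrm{target}^{\Delta C_t^\mathrm{target}}}
{E_\mathrm{ref}^{\Delta C_t^\mathrm{ref}}},\qquad
\Delta C_t = \overline{C_t}(\text{group a}) - \overline{C_t}(\text{group b}),$$

so a ratio above 1 means the reference-normalized target is higher in
group b (the direction is documented and tested; with $E=2$ this is the
classic $2^{-\Delta\Delta C_t}$). Significance comes from
fixed-reallocation randomization: group labels are permuted over *whole
samples* — a sample's target and reference measurements travel together,
which is what makes the test valid under per-sample scale effects — and
the two-sided empirical p is $(1 + \#\{|\log r_\pi| \ge |\log
r_\mathrm{obs}|\})/(B+1)$ with $B = 2000$ iterations by default (the
published tool's iteration count is not stated; 2000 keeps Monte-Carlo
error below 0.012 at $p = 0.05$ and the tests verify agreement with
exhaustive enumeration on 3v3 tables). `isoform_relative_abundance()`
reports $100\cdot E^{-(\overline{C_t}^\mathrm{iso} -
\overline{C_t}^\mathrm{ref})}$ with values at or above 100 formatted
"~100" (the isoform is at least as abundant as the reference; the raw
value is retained).

## 5. RNA-seq junction evidence

Input is a simplified spliced-alignment table (read id, contig, aligned
blocks, base observed at the variant); an adapter from BAM only needs to
emit those columns, which keeps the test suite free of binary fixtures.
Each read is assigned to exactly one category by its junction structure
at the affected exon: joining the flanking exons = skipping; any
unannotated junction in the region = cryptic use (keyed by exact
coordinates); an annotated adjacent junction = wildtype. Intron
retention is operationalized as a junction-free read running at least
`k = 10` nt past the exon boundary, or lying fully within a flanking
intron — published descriptions of retention are visual, so the numeric
rule is this package's, exposed as a parameter. Interpretation is gated
on `exon_reads >= 5` (inclusive).

Against a control cohort, `evidence_significance()` computes a one-sided
empirical p on counts normalized by `exon_reads`:
$p = (1 + \#\{\text{controls} \ge \text{case}\})/(N+1)$. The exact
statistic used by the published web resource is defined in its companion
work, not restated here; the empirical p is the documented stand-in, and
the tests verify its two key properties — monotonicity in the case count
and approximate uniformity under the null (Kolmogorov–Smirnov).

## 6. The synthetic world

The generator's defaults are a single stated world, fixed before any
test outcome was seen:

* **Site models:** donor frequencies peak at the invariant GT
  (+0/+1 ≈ 0.99) with consensus-weighted flanks; acceptors carry a
  21-column pyrimidine tract (C+T ≈ 0.81 per column) ahead of the
  invariant AG. These give mean model information of roughly 8 (donor)
  and 11 (acceptor) bits — the realistic order for mammalian sites.
* **Locus geometry:** 3 exons of 80–200 nt, introns of 600–1200 nt
  (long enough that the default ±300 nt cryptic scan of one junction
  never touches the next), uniform ACGT background.
* **Planting:** natural junctions are overwritten with windows
  rejection-sampled from the truth frequencies until $R_i \ge 8$ bits;
  cryptic specs land within 0.5 bits of their target. Windows
  overlapping a planted site cannot be rejection-sampled independently
  (each would overwrite part of the other), so naturals are planted
  first and everything is rescored into the manifest, which records
  achieved — not just intended — strengths.
* **Background guarantee:** after planting, any background window away
  from planted sites that scores at or above the 8-bit natural floor is
  resampled. Weak background sites of a few bits *remain*, exactly as in
  real sequence — random DNA contains a splice-site-lookalike above
  1.6 bits every few hundred nt, so "no background site above the leaky
  threshold" would be an unrealistic (and unattainable) guarantee. A
  green background-control test therefore establishes that planted sites
  dominate their locus, not that weak decoys are absent. Shifted copies
  of a strong planted site (e.g. tandem acceptor AGs two nt apart) are
  deliberately left alone: they are real biology, the same geometry as
  validated cryptic acceptors a few nt from a natural site.
* **Cohort:** genotype dose ~ Binomial(2, maf) (Hardy–Weinberg), maf
  0.3 so 60–90 samples populate all three groups; affected-probeset
  intensity $I_0\, s^{\mathrm{dose}}\, e^{\mathcal N(0,\sigma)}$ with
  $s = 0.6$, $\sigma = 0.1$, $I_0 = 100$ — a clearly stepwise effect at
  cohort scale.
* **qPCR:** $C_t = C_t^\mathrm{ref} - \log_E(\text{proportion}\times
  \text{expression}) + \mathcal N(0, 0.2)$, in triplicate; zero
  proportions are censored at exactly cycle 40. A per-sample lognormal
  expression factor (`expr_sd = 0.1`) is shared by the within-gene
  assays but not the external reference — it is cancelled by internal-
  reference normalization only. The ratio-recovery test runs with
  `expr_sd = 0` because its stated tolerance (20% at Ct sd 0.2, three
  samples per group) budgets only for Ct noise.
* **Junction reads:** multinomial over isoform categories with
  per-genotype proportions (wildtype 0.94/0.70/0.40 across dose 0/1/2);
  in heterozygotes aberrant reads carry the alt allele with probability
  0.9. Reads get exact block structures per category, so the classifier
  must recover the drawn counts *exactly* — the round-trip is
  bookkeeping, not approximation.
* **Seeding:** one master seed fans out to fixed per-stage child seeds
  (`seed * 131 + stage * 1000003 mod 2^31−1`), so stages are
  independently reproducible and all child seeds stay in 32-bit range.

What the generator does **not** emulate: sequencing error, alignment
ambiguity, GC or coverage bias, isoform-length effects on read sampling,
probe cross-hybridization, PCR efficiency drift, population structure.
A green pipeline test therefore establishes correctness of the
*computations* under the assumed statistical structure, not robustness
to real-data artefacts.

## 7. Numerical and degenerate-input policy

* $-\infty$ sentinels propagate through scores and are serialized
  losslessly; matrix TSV round-trips are bit-exact (17 significant
  digits).
* Windows containing N are skipped and counted, never scored.
* A sequence shorter than the window yields an empty scan, not an error.
* Zero gene intensity excludes that sample for that gene with a warning;
  empty genotype groups reduce the stepwise test to its partial form.
* Ties: SNP-probeset linking breaks distance ties by smaller start
  coordinate; `plant_variant` keeps the first-found substitution among
  equals (column-major order). Both are deterministic and tested.
* Randomization p-values use the +1-corrected estimator, so $p \in
  (0, 1]$ and never 0.

## 8. Known limitations

* Branch-point and polypyrimidine-specific models, RNA secondary
  structure and splicing-regulatory-element discovery are out of scope;
  a user-supplied matrix (e.g. an RNA-binding-protein model) can be
  scored by the same engine via the matrix TSV interface.
* Multi-nucleotide variants are rejected at the `variant()` boundary.
* The exon-definition length term and the control-cohort significance
  statistic are documented stand-ins for unpublished formulations (see
  sections 2 and 5).
* Printed one-decimal site strengths from proprietary matrices cannot be
  reproduced exactly; acceptance therefore checks the fold-change and
  difference *arithmetic* on the printed values, where seven of
  twenty-four published rows are internally inconsistent by one unit in
  the last decimal (the printed endpoints are themselves rounded) — the
  tests document rather than hide this.
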