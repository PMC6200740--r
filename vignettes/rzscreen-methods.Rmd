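---
title: "Methods: robust Z-score screening signatures and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust Z-score screening signatures and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rzscreen)
```

This vignette documents the statistical model behind each stage of the
package, the conventions adopted where the published descriptions of such
pipelines leave the details open, and what the bundled synthetic-screen
generator does and does not emulate.

## The signature model

A screen is a log2-normalized expression matrix (genes × wells) joined to a
plate annotation: every well belongs to a plate, a screening phase, and a
cell line; each cell line belongs to one of three groups — cancer cell
lines (`CCL`), control neural progenitor lines (`NPC_control`), or patient
lines (`NPC_SZ`). Each plate hosts one cell line and carries its own
vehicle (DMSO) wells, so every treated well has plate- and cell-matched
controls.

The robust Z-score of a drug on a plate is, per gene,

$$\mathrm{RZS}_g = \frac{x_g^{\text{treated}} - \mathrm{median}\big(x_g^{\text{vehicle}}\big)}{\mathrm{MAD}\big(x_g^{\text{vehicle}}\big)},$$

where the vehicle statistics are computed within the (plate, cell line)
stratum. Conventions:

- **Raw MAD.** The denominator is the bare median absolute deviation, with
  no 1.4826 normal-consistency constant; `mad_constant = "normal"` enables
  the constant for sensitivity analysis. On the toy plate with vehicle
  values 1…5 and a treated value of 5, the MAD is 1 and the RZS is 2.
- **MAD floor.** A gene whose vehicle MAD is exactly zero would produce an
  infinite score; such genes take the smallest positive MAD of the stratum
  (fallback 1e-6) and are flagged. This preserves the ranking while
  keeping every signature finite.
- **Replicates.** Multiple treated wells of one drug on one plate are
  averaged *before* the transform; signatures of the same (drug, cell
  line) across plates/phases are collapsed *after* it, to the per-gene
  median. The ordering matters: the transform is plate-local, the collapse
  is not.
- **Vehicle wells ≥ 3.** The median/MAD need support; the layout default
  of 12 vehicle wells per plate per cell line is the screening design this
  package targets.
- **Probe collapsing.** When several probes map to one gene, the probe
  with the highest mean expression across all samples is retained; exact
  ties go to the lexicographically smaller probe id, so the result never
  depends on input order.

The RZS transform is invariant to plate-wide additive shifts (the median
moves with the data) and to plate-wide positive rescaling (numerator and
MAD scale together) — exactly in real arithmetic, and to ~1e-9 relative in
floating point, where genes with near-zero vehicle MAD amplify rounding by
several orders of magnitude. Batch-effect cancellation is quantified by
`batch_variance_fraction()`, a per-gene one-way random-effects ANOVA whose
between-level variance component uses the method-of-moments estimator
`(MSB − MSW)/n0` clipped at zero; unlike a raw R², it reports ≈ 0 (rather
than `(k−1)/(N−1)`) when a factor carries no signal. On vehicle-well
pseudo-signatures the plate and phase fractions fall below 1% even when
the simulated batch scale is ten times the noise scale, while the same
wells' uncorrected expression is > 90% plate-attributable. Drug signatures
retain a ~10% plate-attributable component from a different source: all
signatures on a plate share the same vehicle median/MAD estimate, so
control-sampling noise is correlated within plate. This is a property of
any shared-control design, not a failure of batch cancellation.

## DE accounting and group responsiveness

A drug–gene pair is DE within a group when the absolute median RZS across
the group's cell lines is ≥ `de_threshold` (default 2, inclusive), and
differentially DE between groups when the group medians differ by ≥
`diff_threshold` (default 2) in absolute value — a pair can be
differentially DE with neither group individually DE.

Pairs DE in at least one of two groups are partitioned into four disjoint
response categories: `opposite_de` (DE in both, opposite signs),
`opposite_subthreshold` (DE in one, the other of opposite sign below the
DE threshold), `single_group` (DE in one, the other negligible), and
`same_direction_magnitude` (same sign, both non-negligible). The boundary
between the last two is genuinely open in threshold-based accounting; we
fix it with `negligible_threshold` (default 0.5 RZS units, a quarter of
the DE threshold) and expose it as a parameter rather than hard-coding a
convention.

Group responsiveness is compared with a stratified 2×2 test: each stratum
is one drug–gene pair, rows are groups, columns are per-cell-line DE
status (a line is DE for a pair when its own |RZS| ≥ threshold); strata
with an empty column margin are dropped. The common odds ratio is the
Mantel–Haenszel estimate Σ(aᵢdᵢ/nᵢ)/Σ(bᵢcᵢ/nᵢ). For the chi-square we use
the **Cochran form** of the stratified statistic (per-stratum variance
m₁m₀n₁n₀/n³, no continuity correction): on a single stratum it reduces
exactly to the Pearson chi-square, whereas the hypergeometric-variance
variant would give ((n−1)/n)·X². The two differ negligibly at the strata
sizes this test is meant for (tens of cell lines, tens of thousands of
strata), and `stats::mantelhaen.test` serves as an independent
cross-check in the test suite. Bonferroni correction across the declared
family of group comparisons is applied on request. Note that comparing
*group-median* DE counts between groups of unequal size is biased (a
median over more lines suppresses noise more); the stratified per-line
test is the unbiased instrument, which is why it exists.

## Gene-set enrichment

For one drug and two cell groups, each gene set is tested with an unpaired
two-sample t comparison of the groups' RZS. Two variants are exposed:

- **v1 (default).** Each cell line is summarized to its mean RZS over the
  set's genes; a Welch t compares the group summaries. The cell line is
  the biological replication unit, so this is the variant used everywhere
  downstream; it needs ≥ 2 lines per group.
- **v2.** The per-(cell line, gene) RZS values of the set are pooled per
  group and compared with a Student t — a literal "compare the matrices"
  reading, exposed for sensitivity analysis. Its effective sample size is
  inflated by within-line correlation, so its p-values are optimistic.

Sets are intersected with an expressed-gene background (genes with ≥ 10
reads in ≥ half of the cell lines of a reference counts matrix) before
testing; sets smaller than 5 genes after intersection are reported
`tested = FALSE`, never zero-filled. FDR is Benjamini–Hochberg within each
(comparison, set-collection) family — deterministic on small families,
unlike density-estimated q-values, and monotone in p by construction.
`landmark_consistency()` checks that enrichment statistics computed from a
measured-probe subset correlate with the full-transcriptome statistics
(Pearson, two-sided p).

## Connectivity and reversal screening

Genes are ranked by descending RZS (exact ties broken lexicographically by
gene id, for determinism). For a tag set of size $t$ in a universe of $n$
with sorted ranks $r_j$, the signed KS extremum is

$$a = \max_j\left(\frac{j}{t} - \frac{r_j - j}{n - t}\right),\qquad
  b = \max_j\left(\frac{r_j - j}{n - t} - \frac{j-1}{t}\right),$$

with es = a if a > b, −b if b > a, and 0 on an exact tie. The running sum
steps by 1/t on tag genes and 1/(n−t) on non-tag genes, so a tag set
leading the ranking scores exactly +1 and one trailing it exactly −1.
Comparisons between a and b are made on integer numerators (scaled by
t(n−t)), so ties are detected exactly; mapping a tie to 0 — equal evidence
in both directions — is what makes sign antisymmetry (negating the
signature negates every nonzero score) hold exactly. The connectivity
score combines the up- and down-tag enrichments as (es_up − es_down)/2
when they disagree in sign and 0 otherwise, so +1 is perfect concordance
with the disease signature and −1 a perfect reversal.

The reversal screen's null model re-samples random tag sets of the
observed sizes from the gene universe — for a fixed signature with
distinct values this is exactly a uniform draw of rank sets, so one null
distribution serves every entry. Two-sided p-values use the standard
permutation form (1 + #{|null| ≥ |obs|})/(B + 1); BH is applied within
each column (cell line or group); a drug is *reversing* when its score is
negative with q below the FDR target (default 0.1). A seed is required —
the screen refuses to run on an unseeded RNG. Group aggregation takes the
per-gene median RZS across a group's cell lines before scoring, matching
the pipeline's median conventions. Cell-line similarity is embedded with
classical (Torgerson) MDS on Euclidean distances between drug-score
profiles; coordinates are centered and deterministic up to axis sign.
`prioritize_drugs()` ranks a library by each drug's strongest absolute
single-tag-set enrichment, ties broken by drug id.

## Chemogenomic enrichment

The testing universe for an annotation class is the set of screened drugs
carrying at least one annotation of that class — side effects are only
meaningful for drugs used clinically, and the same logic is applied
uniformly to every class. Results are therefore invariant to adding drugs
with no annotations in the tested class. Over-representation of a feature
among a drug group is the one-sided Fisher exact p — computed as the
hypergeometric upper tail, which is the same quantity — with the sample
odds ratio ad/bc reported, and BH within each (set, class) family. Drug
groups are formed per set from the enrichment results at q < 0.1 (strict)
and kept only when ≥ 3 drugs qualify. Target-overlap prioritization runs
the same machinery per (drug, set) over a gene universe.

## Motif analysis

Motifs are strings over the RNA alphabet plus IUPAC degenerate codes
(K, W, R, Y, S, M, N); DNA input is accepted with T ≡ U; an N in a
*sequence* matches only the motif code N. Scanning tests every start
position, so overlapping occurrences all count. Motif density is
occurrences per kilobase of the provided sequence (the transcript/UTR
choice belongs to the caller), compared between groups with a two-sided
Welch t; if both groups have zero density variance the comparison is
refused rather than reported as t = 0. A variant lies "in" a motif when a
*full* occurrence within its reference window spans the variant offset —
occurrences truncated by the window edge never count. Cohort enrichment is
the same one-sided Fisher machinery, with BH across the tested
(motif × cohort) family. The catalog preloads ACUK — the one pattern of
the RNA-binding-protein motif family that is publicly named — and takes
further patterns from a YAML file rather than hard-coding guesses.

## The synthetic-screen generator

The generator is first-class, tested code; it defines the study
conditions under which every property of the pipeline is verified.

**Expression model.** Additive Gaussian on the log2 scale:
baseline(gene) + cell-line offset + plate offset + phase offset + drug
effect + noise. The screens this package targets arrive log2-normalized,
so no count model is simulated. Plate/phase offsets are gene-independent
scalars by default (`per_gene_batch = TRUE` draws them per gene) — enough
to exercise the RZS cancellation property, which holds for any additive
plate-wide structure. Defaults: noise sd 0.3, batch sd 1.0, cell sd 1.0
(log2 units), baseline N(7, 1.5²).

**Layout.** Each plate hosts one cell line: one empty well, 12 vehicle
wells, 4 positive-control wells (two controls in duplicate), and the rest
test compounds; drugs overflow onto further plates, and every cell line is
re-screened in each of 2 phases, giving each (drug, cell line) one
replicate per phase.

**Planted effects.** `n_effect_pairs` drug–gene pairs receive ±3 log2
shifts in every group; an additional 15/85 of that count are NPC-only
(cell-type modifiers), making the CCL group 15% less responsive among
planted pairs; a further 10% are NPC_SZ-only (diagnosis modifiers).
Reverser drugs shift the disease signature's up genes down and down genes
up by the same magnitude. Set-level regulation is planted by
`simulate_gene_sets()` and realized as per-gene drug-induced shifts in the
designated group. Note the planted set shift is specified in log2
expression units; after the RZS transform its magnitude in score units is
roughly shift/MAD ≈ 5× larger at the default noise scale.

**Sequences and variants.** Backgrounds are generated motif-free (any
chance occurrence is mutated away) and a Poisson number of concrete
occurrences is implanted per sequence, so the planted per-kb rate *is* the
sequence's total density — with a fully random background the ACUK motif
alone would contribute ~7.8/kb and swamp any planted difference. Variant
windows (±10 nt) contain an occurrence spanning the offset with exactly
the configured per-cohort probability.

**What it does not emulate.** Bead-level measurement error and
probe-imputation error of the L1000 assay; sequencing counts; dose
response (one dose per drug, carried but never modeled); gene–gene
correlation structure; non-additive batch effects. Passing tests
demonstrate the pipeline's statistical machinery under the stated additive
model, not the vendor-side normalization upstream of it.

## Problem sizes and runtime choices

The scaled-down conditions used by the test suite and the acceptance
script are 20 drugs × 500 genes × (3 CCL + 3 control NPC + 2 SZ NPC)
lines × 2 phases; the `preset = "full"` configuration (135 drugs,
8 + 12 + 12 lines, 96-well plates) is used where a check is only powered
at the published screen's size — the stratified responsiveness comparison
detects the planted 15% deficit at Bonferroni p ≪ 0.001 there. Monte-Carlo
checks use 50–200 replicates with fixed seeds; the enrichment calibration
builds score-space tensors directly (12 vs 8 lines, unit noise, sets of
50 from a universe of 1000), which is the natural scale for a shift
specified in RZS units.

## Known limitations

- DE calling is purely threshold-based, as in the accounting it
  reproduces; no standard errors accompany the calls.
- The v2 enrichment variant's pooled t ignores within-line correlation
  (see above); it exists for comparability, not inference.
- The connectivity permutation null permutes gene labels, not wells; it
  tests tag-set structure given the signature, not signature stability
  across replicates.
- The common odds ratio is undefined (infinite) when every informative
  stratum is concordant; at realistic noise levels this does not occur.
- `collapse_probes()` assumes a many-to-one probe→gene map; probes mapped
  to multiple genes must be resolved upstream.
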