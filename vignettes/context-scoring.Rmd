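---
title: "Quantitative modeling of microRNA targeting efficacy with contextpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative modeling of microRNA targeting efficacy with contextpp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextpp)
```

## The model

Animal microRNAs (miRNAs) repress mRNAs mainly through Watson–Crick
pairing between the miRNA seed (nucleotides 2–7/2–8) and short sites in
3' UTRs.  `contextpp` implements a quantitative model of this canonical
targeting: every seed-matched site receives a *context score* (CS), the
predicted log2 mRNA fold change attributable to that one site,

> CS = min(cap, b0 + sum over features of b_f · x_f)

where the `x_f` are fourteen scaled features of the site, the mRNA and the
small RNA, and `b0`, `b_f` are site-type-specific linear-regression
parameters.  Four canonical site types are scored — 8mer, 7mer-m8,
7mer-A1 and 6mer — with per-type caps of −0.03, −0.02, −0.01 and 0 that
bound each score away from predicting enhancement, making the model
piece-wise linear.  Offset-6mer sites (match to miRNA nucleotides 3–8)
are detected and counted as a context feature but are not scored
themselves.

Site classification is hierarchical: a seed-core match extended by an m8
pair and followed by an A is an 8mer; with only the m8 extension a
7mer-m8; with only the A a 7mer-A1; otherwise a 6mer.  Overlapping
distinct loci are resolved by keeping the higher-priority type, breaking
ties toward the 5' site — the published filtering removes overlapping
sites without stating the rule, so this deterministic choice is our own.
Sites overlapping the first 15 nt of the 3' UTR (the region traversed by
the terminating ribosome) are excluded from scoring by default.

### The fourteen features

| feature | meaning | scaled |
|---|---|---|
| `TA_3UTR` | log10 transcriptome-wide seed-match count (target-site abundance; titration of the silencing complex) | yes |
| `SPS` | seed-pairing stability: nearest-neighbor free energy of the perfect seed:target helix (nt 2–8 for m8-paired types, nt 2–7 otherwise) | yes |
| `local_AU` | AU fraction of the 30-nt flanks, weighted 1/k by distance from the site edge | yes |
| `threep_score` | supplementary pairing between miRNA nt ≥9 and the 16 nt upstream of the seed match | yes |
| `SA` | log10 probability that the 14-nt segment over the match to miRNA nt 7–8 is unpaired under local folding | yes |
| `min_dist` | log10 distance from the closest 3'-UTR terminus (isoform-weighted) | yes |
| `P_CT` | probability of conserved targeting (consumed as an input; 0 when absent or the family is not broadly conserved) | yes |
| `len_ORF`, `len_3UTR` | log10 lengths (3'-UTR length isoform-weighted) | yes |
| `off6m` | number of offset-6mer sites in the 3' UTR (isoform-weighted) | no |
| `ORF8m` | number of 8mer sites in the ORF | no |
| `sRNA1`, `sRNA8`, `site8` | nucleotide identities of sRNA positions 1 and 8 and of the target nucleotide opposite position 8, encoded as A/C/G indicators with U as reference | no |

Continuous features are normalized by *trimmed scaling*: subtract the
5th percentile, divide by the 95th−5th percentile gap, do **not** clip.
The packaged table (`default_scaling_table()`) reproduces the published
per-site-type percentiles; values outside [0, 1] are expected for
out-of-range inputs and are deliberate — clipping would distort the
linear model near the tails.

### Isoform weighting and the cumulative score

Tandem 3'-UTR isoforms are quantified from 3P-seq cleavage/poly(A)
clusters (`build_profile()`): per-dataset tag counts are upper-quartile
normalized (factor = 75th percentile of per-transcript totals, linear
interpolation, factors rescaled to geometric mean 1 so a lone dataset
keeps its raw scale), summed per cluster, and given two pseudocounts —
0.1 tag on the longest tandem isoform and 5 tags on the longest
annotated isoform.  A site's AIR (affected isoform ratio) is the summed
abundance of isoforms whose end lies at or beyond the site's end; a site
must be fully contained to count.  Features that vary with the isoform
end (`min_dist`, `len_3UTR`, `off6m`) are abundance-weighted means over
the site-containing isoforms.

Per-site scores combine across all sites of one family on one transcript
through the cumulative recursion, processing sites from the distal end:

> C_i = C_(i−1) + (1 − 2^CS_i)(AIR_i − C_(i−1)),  C_0 = 0,
> CWCS = log2(1 − C_n).

`cumulative_weighted_score()` enforces the nondecreasing-AIR ordering
and is tested against an independent oracle: the log2 of the
abundance-weighted mean over isoform classes of the product of per-site
remaining fractions, to which the recursion is algebraically equivalent.
With all AIR = 1 the CWCS reduces to the plain sum of context scores
(independent site action).  Per family, the member with the most
repressive CWCS represents the family; per gene, the stop-codon isoform
with the most 3P-seq tags represents the gene.  Targets whose only sites
are 6mers contribute to scores but are hidden from ranked listings.

## Training pipeline

### Compendium normalization

Fold-change compendia from small-RNA perturbation experiments carry
strong sRNA-independent structure (batch effects tied to, e.g., 3'-UTR
length and AU content).  `normalize_compendium()` removes it per
experiment: (i) predictor cells whose gene carries a canonical 7–8 nt
site to the predictor experiment's sRNA are masked, so genuine
repression measured twice is never treated as batch structure; (ii)
genes missing in the response or in more than half the predictors are
dropped (exactly half is kept); (iii) remaining holes are imputed by
k-nearest neighbors (k = 20, Euclidean distance over jointly observed
columns rescaled by the shared-column fraction — the cited imputation
routine does not document its distance, so this is our choice); (iv) the
response is residualized on the predictors by partial least squares.
PLS is implemented as NIPALS; the component count minimizes 10-fold
cross-validated error under a one-standard-error rule (the source
pipeline says only "an appropriate number"), with 0 components allowed
so that unpredictable responses pass through unchanged.  Columns are
finally centered on the median of their no-site genes.  Residualization
precedes centering; the original ordering is not stated, and the choice
is configurable in effect because centering is an affine shift.

### Feature selection and fitting

Candidate features are selected by bidirectional stepwise regression
from an intercept-only start, minimizing AIC = −2 ln L + 2k (the text
accompanying the original definition says "maximized"; the definition
given is minimized, and we minimize).  Selection runs on 1000 bootstrap
samples (100 in scaled-down runs), each holding 70% of every
experiment's rows drawn without replacement, with the held-out 30%
providing test r².  The robust feature set contains features selected
with frequency ≥ 0.99 for at least two site types.  Final per-site-type
models are ordinary least squares on the full data with the site-type
caps attached and 95% confidence intervals recorded.  Near-noiseless
responses make AIC degenerate (the likelihood diverges), so selections
whose residual sum of squares is at numerical zero are pruned back to
the minimal set — this only triggers in synthetic noise-free settings.

## The synthetic-data generator

`simulate_transcriptome()`, `simulate_profiles()` and
`simulate_compendium()` generate every input format with the statistical
structure the method assumes.  Defaults define the study conditions used
throughout the test suite and were fixed once, by design:

* 3'-UTR lengths log-normal with median ≈ 600 nt (`sdlog` 0.45), GC
  content 0.40 — typical of mammalian UTR catalogs; 30–150 nt 5' UTRs,
  300–1200 nt ORFs.
* At most one canonical site planted per transcript (probability 0.8,
  uniform over the four types); flanking bases are fixed so the planted
  locus classifies as intended, and accidental seed matches are mutated
  away, so discovery recovers the emitted registry exactly.
* 1–4 tandem isoform ends per UTR with Dirichlet(2) abundances, 70% of
  transcripts single-isoform, ≈200 tags per transcript split over two
  datasets.
* Fold changes: sum of generating per-site scores (intercepts −0.50 /
  −0.35 / −0.20 / −0.08 by site type; coefficients −0.35 on `local_AU`,
  +0.30 on `min_dist`, +0.30 on `len_3UTR`; all other features null) +
  optional low-rank batch component tied to 3'-UTR length and AU content
  + iid Gaussian noise (SD 0.15) + 3% missing cells.  Effect sizes sit
  in the upper range of the published coefficient magnitudes and were
  chosen by power analysis so that ~300 single-site rows per site type
  identify each planted feature (|t| ≳ 4.5); the noise SD matches
  typical residual microarray variability on the log2 scale.
* An optional derepression artifact (positive offset for genes carrying
  sites of designated "endogenous" families) emulates competition with
  endogenous miRNAs.

What the generator does *not* emulate: realistic sequence composition
beyond GC content (no repeats, no UTR motif structure), correlated
feature distributions of real transcriptomes, probe-level measurement
artifacts, or non-canonical sites.  Tests passing on this generator
therefore demonstrate the correctness of the implementation and the
internal consistency of the pipeline, not the biological accuracy of any
particular coefficient value.

## Structural accessibility backend

The default backend is a simplified McCaskill-style partition function
over non-crossing structures (compiled, `src/partition.cpp`): admissible
pairs are Watson–Crick plus G:U, each pair contributes a single free
energy (−3.0 GC, −2.0 AU, −1.0 GU kcal/mol at 37 °C), loops of fewer
than 3 nt are forbidden, the maximal pair span is 40 nt, and the folding
universe is an 80-nt window centered on the queried segment.  The
unpaired probability of a segment is the ratio of the constrained to the
unconstrained partition function, which on sequences short enough for
exhaustive enumeration is verified to agree with a structure-by-structure
sum to < 1e-9.  This model intentionally omits loop entropies and
stacking context, so its probabilities are systematically lower than a
full Turner-model fold; the trimmed scaling absorbs the shift in
location/scale, and a reader for RNAplfold `_lunp` files
(`accessibility_provider("lunp")`) gives bit-compatible reproduction of
precomputed profiles when exact agreement with the reference tool is
needed.  Seed-pairing stability likewise uses an embedded Watson–Crick
nearest-neighbor stack table without an initiation term; an AU-only
7-pair helix sums to −5.58 kcal/mol and GC-rich seeds to below −17,
bracketing the published percentile anchors.

## The packaged model

There is no published coefficient table inside this package, so the
shipped default model (`default_context_model()`) is trained by the
package's own pipeline on its synthetic compendium
(`scripts/build_shipped_model.R`; eight families engineered so the
sRNA-1 and sRNA-8 identity indicators have support) and is labelled
*synthetic* in its filename and documentation.  It carries all fourteen
features per site type; structurally aliased terms — the site-8 identity
of 8mer/7mer-m8 sites, which perfect m8 pairing makes a deterministic
function of the sRNA-8 identity, and features constant in the synthetic
data (`P_CT`, `off6m`) — receive coefficient 0.  Substitute a real
coefficient table via `read_context_model()` for production scoring; the
caps, scaling and recursion are independent of which coefficients are
loaded.

## Numerical choices and degenerate inputs

* Percentile computations use linear interpolation (R quantile type 7);
  the interpolation convention of the source pipelines is unstated.
* `min_dist` measures from the site edge closest to each terminus and
  clamps distances at 1 nt before the log; `SA` windows truncate at UTR
  ends; flanks truncated by UTR ends renormalize the `local_AU` weights.
* Any window containing `N` yields a missing feature value and flags the
  site unscorable; `N` never matches a site signature.
* The CWCS recursion rejects AIR sequences that decrease distal to
  proximal (a symptom of mis-sorted sites) rather than reordering
  silently.
* Score percentiles in ranked output are 100 × the fraction of
  same-family scores not more repressive, so the best target of a family
  sits at percentile 100; ties share percentiles, and equal scores are
  ordered lexicographically by transcript id.

## Scaled-down problem sizes

The suite exercises the full pipeline at sizes a laptop handles in
minutes, chosen as the smallest sizes at which the statistical
properties under test are comfortably identified: normalization runs on
a 250-gene × 20-experiment compendium with one unique seed per
experiment (shared-seed experiments would retain genuine repression
correlation that no batch-removal step should erase); selection runs 100
bootstrap samples over ~300 single-site rows per site type; coefficient
recovery uses 50 noise replicates on a fixed design.  Full-scale runs
(B = 1000, compendium-scale matrices) use the same code paths with
different arguments.

## Known limitations

* Stepwise-AIC selection admits any pure-noise candidate with marginal
  probability P(χ²₁ > 2) ≈ 0.16, and conditional on a realized dataset
  the bootstrap selection frequency of such a candidate is strongly
  overdispersed — a noise feature that happens to correlate with the
  response in the full sample is selected in most subsamples.  Bootstrap
  selection frequencies for null features should therefore be read as
  heavy-tailed diagnostics, not calibrated error rates; only the
  ≥ 0.99-in-≥ 2-site-types robust-set rule is used to build models.
* The built-in folding model is a deliberate simplification (see above).
* `P_CT` is consumed, never computed: conservation scoring from genome
  alignments is out of scope, as are non-canonical (3'-compensatory,
  centered, cleavage) sites, CLIP processing, and genome-coordinate
  lifting.
* Scoring mouse or other species with human-trained parameters is
  supported by simply loading the corresponding tables; no species logic
  is hard-coded.
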