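---
title: "Species-resolved expression from mixed-culture RNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-resolved expression from mixed-culture RNA-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultureseq)
```

## The problem

When several fungi grow together on a shared substrate (say, wheat straw),
a single bulk RNA-seq library contains transcripts from all of them.  Two
questions then have to be answered before any expression analysis can
start: *which species did each read come from*, and *how much of each
species is actually in the flask*.  `cocultureseq` implements a complete
desk-scale version of the strategy used for dual RNA-seq of fungal
co-cultures:

1. reads are attributed to species against a **composite reference**
   (all member genomes concatenated), keeping only reads unique to one
   species;
2. expression is normalised as **per-species FPKM**, so each species is
   quantified against its own uniquely assigned read total;
3. differential expression, CAZy-set aggregation, clustering and term
   enrichment run downstream per species;
4. in parallel, species abundance is measured by absolute qPCR: a
   multi-copy rRNA marker (a 5.8S analogue) proxies total RNA and predicts
   read yield, and a single-copy genomic locus converts gDNA to mycelial
   dry weight.

Every stage is exercised end to end on a synthetic generator with planted
truth, so the package's guarantees are stated as measured properties, not
assumptions.

## Species assignment on a composite reference

The original pipeline mapped reads with a spliced aligner to a
concatenated tri-species genome and kept uniquely mapping reads (MAPQ >=
20).  Re-implementing a spliced aligner is neither necessary nor
desirable here; what matters is the *uniqueness semantics*.  The package
re-expresses it as an exact k-mer vote:

* the composite index records every k-mer (default k = 31) of every
  contig, both strands, tagged `species|contig`;
* each read pair contributes all its k-mers (both mates); a query k-mer
  adds at most one hit per species;
* the pair is `unique(s)` iff `hits(s) >= min_hits` (default 2) and
  `hits(s') <= margin * hits(s)` for every other species; `unmapped` if
  every species is below `min_hits`; otherwise `ambiguous`.

The default `margin = 0` is the zero-tolerance reading of "unique to a
particular species": a single shared k-mer voids uniqueness.  This is
deliberately conservative.  At 10 % pairwise divergence a 2 x 75 bp pair
has a sizeable chance of containing at least one run of 31 identical
sites, so roughly half of all pairs are discarded as ambiguous at
`margin = 0`; misassignment, however, is essentially zero (measured
<= 0.1 % at 10 % divergence, 10,000 pairs).  Users who prefer
aligner-like tolerance can set `margin` to, say, 0.3, which recovers
>= 95 % of pairs uniquely and correctly in the same simulation; the
trade-off is documented rather than hidden in the default.

Two details are worth stating.  First, the verdict rule is *oracle
testable*: on small genomes the package's verdicts are compared
one-for-one against a brute-force all-substring search, which is how the
test suite guards the index and vote logic.  Second, the inferred locus
of a unique pair is the span of its matched k-mers on the modal contig,
and the reported strand is the reference strand matched by mate 1.  The
synthetic library is directional (dUTP-style, read 1 antisense), so the
default counting mode is `reverse`: a fragment is compatible with a gene
on the strand opposite its mate-1 strand.

Fragment-to-gene counting follows the conservative union rule: a
fragment is counted once for a gene if it overlaps exons of that gene
only; fragments touching two genes are discarded as gene-ambiguous, and
intergenic fragments are left uncounted.

## Per-species FPKM

For gene $g$ with summed exon length $L_g$ (bp) and $C_{gs}$ fragments in
sample $s$:

$$\mathrm{FPKM}_{gs} = \frac{C_{gs} \cdot 10^9}{L_g \cdot M_s},$$

where $M_s$ is **that species' own** gene-model-counted fragment total in
the sample, never the whole-sample total.  Intergenic unique fragments
are excluded from $M_s$ (the definition speaks of fragments counted onto
gene models; including intergenic reads would make the denominator depend
on annotation completeness in an uninterpretable way).  A direct
consequence used as an exactness check throughout the tests:
$\sum_g \mathrm{FPKM}_{gs} \cdot L_g / 10^3 = 10^6$ for every
species-sample with $M_s > 0$.

FPKM is retained because the downstream rules are stated in FPKM units
(the >= 1 FPKM expression filter); no claim of between-species
comparability is attached to it.

## Differential expression

The DESeq2 stage of the original pipeline is replaced by a self-contained
two-group negative-binomial Wald test, validated by calibration rather
than by concordance with any external tool:

* size factors are median-of-ratios: $s_j = \mathrm{median}_g\,
  C_{gj} / (\prod_j C_{gj})^{1/n}$ over genes with nonzero counts in all
  samples;
* per-gene dispersion $\alpha_g$ comes from the pooled within-group
  variance of normalised counts by method of moments, floored at
  $10^{-8}$, then **moderated toward the across-gene median** with prior
  weight `prior_df = 20`;
* the Wald statistic on the log2 difference of group means uses the NB
  variance $\mu + \alpha\mu^2$ via the delta method and is referred to a
  t distribution with `prior_df + n1 + n2 - 2` degrees of freedom;
* fold changes use a pseudo-mean of 0.5 so zero counts stay finite.

The moderation is the load-bearing design choice.  With three replicates
per group a purely per-gene dispersion makes the Wald statistic exactly a
pooled two-sample t statistic: referred to a normal it rejects ~12 % of
null genes at nominal 5 %, and referred to t(4) it is calibrated but
recovers only ~64 % of 8-fold effects at p < 10^-3.  Sharing dispersion
information across genes — the same idea that underlies the established
count-based DE tools — resolves the dilemma: measured on 20,000 null NB
genes (mu = 100, alpha = 0.1, 3 vs 3) the rejection rate at p < 0.05 is
~0.06, and 8-fold effects are recovered with essentially full
sensitivity.  The cost is the usual one: when true dispersions vary
wildly across genes, moderation with a global prior misfits the extremes.

DE calls implement the published filters verbatim: fold change >= 2 **on
normalised counts** (not FPKM), BH-adjusted p < 0.05, and mean FPKM >= 1
in the test condition for up-calls / the control condition for
down-calls.  Benjamini–Hochberg adjustment is implemented in the package
and cross-checked against the reference step-up implementation on random
vectors.

## Clustering and enrichment

Heatmap-style gene selection keeps genes with a significant change from
their glucose control (p_adj < 0.05 in at least one straw-vs-glucose
comparison) and FPKM >= 1 in at least one straw condition, optionally
restricted to an annotation set (e.g. CAZy genes).  Values are
log2(x + 1)-transformed; base 2 and offset 1 are the package's choice
(neither is pinned by the published description) because they preserve
zeros and are the de facto standard for FPKM heatmaps.

The distance is the **uncentered correlation** similarity
$r_u = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ with $d = 1 - r_u$.
Unlike Pearson it does not subtract means, so profile magnitude matters:
two genes with proportional (not merely correlated) profiles are at
distance 0, and anti-correlated profiles can reach $d$ up to 2 — a
documented property, not a defect.  Rows of all zeros have no direction
and are rejected by name.

Complete-linkage agglomeration is implemented directly (inter-cluster
distance = max pairwise, ties broken by the lexicographically smallest
active-cluster pair) and returns an `hclust`-compatible object, so
`cutree`, `plot` and Newick export via `ape` all work.  The
implementation uses the Lance–Williams max-update; the test suite checks
its merge heights against a brute-force oracle that recomputes every
inter-cluster maximum from the original matrix, and against
`stats::hclust`.

Term enrichment replaces the original GO-tool stage (whose internal
statistic is not specified in the published description) with the
upper-tail hypergeometric test over a flat term map plus BH adjustment,
exact against enumeration of all draws for small backgrounds.  No DAG
propagation is attempted.

## Absolute qPCR quantification

Standard curves are log-linear least-squares fits
$C_t = b + m \log_{10}(\text{copies})$, with amplification efficiency
$E = 10^{-1/m} - 1$ ($E = 1$ at the perfect-doubling slope
$-1/\log_{10} 2 \approx -3.3219$).  The default simulated dilution series
is 10 five-fold dilutions from $5 \times 10^7$ copies.  No-amplification
wells are excluded from fits and flagged below detection downstream;
inversions outside the fitted dynamic range are flagged out of range.
Only the log-linear regime is modelled — no sigmoid fitting, no melt
curves.

**Mixture shares and read yield.**  Species-specific rRNA marker copies
are normalised to shares; multiplying by the planned sequencing depth
(e.g. 100 M fragments for a mixed sample vs 30 M for a monoculture)
predicts per-species read yield.  The proportional-share model is the
package's formalisation of the qualitative published prediction.  Its
validation is the end-to-end property that marker-predicted shares track
realized unique-read shares across simulated mixtures (r^2 ~ 0.98 at low
qPCR noise in the acceptance run).  This is deliberately a property check
under controlled noise, not a claim about real cultures, where biological
and technical variation make the correlation substantially weaker.

**Biomass from gDNA.**  Standards are gDNA extractions from known dry
weights spanning 2-50 mg, measured (like the samples) at a 1/500 gDNA
dilution; the curve is fitted as Ct vs log10(mg), so inversion gives
aliquot dry weight directly and a sample measured at a different dilution
is rescaled by the dilution ratio.  Flask totals divide by the fraction
of recovered solids used for extraction.  On noiseless simulations the
round trip is exact to numerical precision.

## The synthetic generator

The generator emulates the study design rather than any particular
dataset: three fungal species, glucose and straw monocultures plus mixed
straw cultures, three biological replicates, paired 2 x 75 bp reads, and
a mono:mixed depth ratio of 30:100 (defaults 30,000 and 100,000 fragments
— the real design's ~30 M/~100 M scaled by 10^3 to desk scale; the
validation runs below use 50,000 fragments per sample throughout).

Key modelling choices:

* **Substitution-only divergence.**  Each species derives from one
  ancestral genome by independent per-site substitution; the per-site
  rate is solved from $p = 2q - \tfrac{4}{3}q^2$ so that the *pairwise*
  mismatch fraction equals the configured divergence.  No indels: shared
  coordinates isolate the question the composite-reference strategy
  poses (when is a read unique?) from alignment bookkeeping.
* **Gene models** are single-exon (the counting code still implements the
  general multi-exon union rule, exercised with constructed fixtures);
  no reads span splice junctions, matching the stated non-goal.
* **Markers.**  The rRNA marker is multi-copy (default 50 identical
  copies per genome, mimicking rDNA repeats); the single-copy locus
  appears once.  Both carry forced species-discriminating positions —
  the sites a species-specific hydrolysis probe would target — even at
  zero background divergence, so marker assays always discriminate; at
  `divergence = 0` the genomes are identical everywhere else.
* **Expression** baselines are log-normal (default meanlog 0, sdlog 1.2,
  a realistic heavy tail for transcript fractions), with log-normal
  replicate noise (sdlog 0.1) and renormalisation to fractions.
* **Planted effects.**  Straw media multiply the straw-induced
  degradative CAZy genes (default fold 5, half of the GH/CE/PL/AA
  genes).  Mixed cultures divide a planted subset by the mixed-down fold
  (default 4); this subset is drawn *from the straw-induced genes*,
  because the biomass-degrading transcripts repressed by co-cultivation
  are the substrate-induced ones — planting repression on un-induced
  genes would test recovery of effects the emulated biology does not
  produce.  A small non-CAZy subset is mixed-culture-induced (fold 3).
  The effect sizes are configuration, not claims about real cultures,
  which state no such numbers.
* **Reads.**  Fragment lengths are N(180, 20) truncated at the read
  length and resampled when longer than the transcript; placement is
  uniform within the transcript; the library is directional (mate 1
  antisense); errors are fixed-rate substitutions (default 0.1 %);
  quality strings are constant Q30 and are never used by assignment.

What the generator does **not** model — and hence what passing tests do
not show about real data: indels and rearrangements between genomes,
splice junctions, repeat families beyond the rDNA-like marker, GC and
positional coverage bias, quality-dependent error profiles, library-prep
batch effects, and any real-genome content.  Conclusions from the
synthetic validation are about the *procedures* (uniqueness semantics,
normalisation identities, test calibration, curve inversion), not about
biological effect sizes.

## Numerical conventions and degenerate inputs

* k-mer vote: `k = 31`, `min_hits = 2` (one chance collision never makes
  a read unique), `margin = 0`; empty read sets return empty tables with
  a warning; reads shorter than k are an error.
* FPKM: a species-sample with $M_s = 0$ (e.g. a species absent from a
  monoculture) becomes an all-NA column with a warning, not zeros.
* NB test: dispersion floor $10^{-8}$; genes with zero variance in both
  groups and equal means get p = 1 exactly; `eps = 0.5` pseudo-mean.
* BH: stable ties, monotone by construction, capped at 1.
* Clustering: merge ties broken lexicographically; duplicate rows merge
  at height 0; a 1 x 1 input is an error.
* qPCR: copies <= 0 never amplify (NA Ct); below-detection wells are
  excluded from fits and propagate as flags, never as zeros; negative
  DNS-corrected sugars are reported negative with a flag, never clamped.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run, per invocation: one
tri-species study (100 kb genomes, 200 genes/species, 21 samples of
50,000 pairs, 3 replicates); a four-level divergence sweep (0, 1, 5,
10 %) at 10,000 pairs each; 500 brute-force oracle read pairs on <= 2 kb
genomes; 21,000 simulated NB genes for calibration and power; 20
simulated mixtures for the marker validation; and exact-oracle batches
for BH (1,000 vectors), complete linkage (n <= 8) and the hypergeometric
test (N <= 12).  These sizes are the package's chosen desk-scale study
conditions; all thresholds quoted above are measured at them.

## Known limitations

* The k-mer vote is a stand-in for aligner MAPQ semantics, not an
  equivalent: near-identical paralogues and multi-mapping interact with
  MAPQ in aligner-specific ways that an exact-match vote cannot imitate.
* FPKM values are not comparable across species (different $M_s$), and
  no between-species testing is offered.
* The NB test covers two-group designs only: no multi-factor models, no
  outlier refitting, no independent filtering.
* The enrichment test uses a flat term map; terms related by a hierarchy
  are tested independently.
* qPCR modelling is log-linear only; probe cross-reactivity is a boolean
  matrix, not a chemistry model.
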