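---
title: "Methods: lncRNA array analysis and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA array analysis and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lncarray)
```

This vignette explains the models and procedures the package
implements, the choices made where the method description leaves room,
and what the synthetic-data generator does and does not establish.

## The analysis problem

Custom expression arrays can tile the non-coding genome — intergenic
space, introns, and the antisense strand of coding exons — alongside
protein-coding exons. Given log2 intensities for a small clinical
cohort (here the study shape is 5 normal and 26 tumor samples spread
over the five PAM50 subtypes), the questions are: which probes change
between conditions; which of those report genuinely non-coding
transcription; where does regulated non-coding transcription sit
relative to genomic annotation and to neighbouring protein-coding
genes; do chromatin-associated lncRNA regions (CARs) move coherently;
and how much of the non-coding expression variation is a trivial
consequence of DNA copy-number change.

## Coordinates and interval semantics

All intervals live in `GRanges` (1-based, closed) — the container the
field's R stack is built on; BED input/output is converted by
rtracklayer, so files on disk are ordinary 0-based half-open BED. A
probe "overlaps" an annotation for enrichment counting when at least
90% of its length lies inside a **single** annotation interval
(`overlap_fraction`, maximum over intervals, not the union — two
abutting intervals each covering half a probe give 0.5). The union
interpretation is available via `union = TRUE`. Any-nucleotide overlap
(`overlaps_any_nt`) is used where the rule is "at least one
nucleotide" (filter step 1, CARs, protein hits). Strand `*` means
unknown and is compatible with either strand in strand-filtered
queries, because the underlying platform targets both strands when the
strand of a locus is unknown.

Nearest-gene distances are gap lengths in bases (0 for any overlap);
`tss` mode measures to the strand-aware transcription start. Ties break
to the lexicographically smallest `gene_id` so results are
deterministic.

`sample_matched_intervals` draws random intervals uniformly over the
genome minus an exclusion track, with lengths resampled from a template
set, optionally rejection-sampling until the candidate's repeat-base
fraction is within ±0.1 (absolute) of its template's. The tolerance is
a package choice — the method description fixes no value; ±0.1 is tight
enough that a "repeat-matched" null is meaningfully matched and loose
enough that sampling terminates on a toy genome.

## Preprocessing and moderated statistics

Quantile normalisation (via `limma::normalizeQuantiles`, ties averaged)
forces every array to the common sorted-mean distribution. The
nonspecific filter retains a probe if it exceeds the per-array
background — mean + 3·SD of that array's negative-control spots — on at
least 4 arrays, and its IQR across arrays reaches `iqr_min`. The IQR
threshold is not legible in the method source; the function default is
0.5, and the pipeline default is 0.3. The pipeline value is chosen
relative to the design: with 5 normals among 31 arrays, a pure
two-group shift moves only the tails, so a probe's IQR stays near the
null value ≈ 1.35 × noise SD (≈ 0.40 at the stated 0.3 noise); a gate
above that would remove true positives wholesale, a gate just below
keeps the rule active against flat probes.

Per-probe linear models (group contrast, optional additive batch
covariate) yield residual variances s² with df degrees of freedom. The
empirical Bayes prior assumes s² ~ s₀²·F(df, d₀); matching the mean and
variance of log s² gives closed forms: with
e = log s² − ψ(df/2) + log(df/2),
`evar = var(e) − ψ′(df/2)`; if positive, d₀ = 2·ψ′⁻¹(evar) and
s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2)); otherwise d₀ = ∞ and s₀² is
the pooled mean variance (the homoskedastic MLE). The moderated t uses
the posterior variance (d₀·s₀² + df·s²)/(d₀+df) with d₀+df degrees of
freedom; the moderated F compares subtype-model and reduced-model
residual sums of squares against the same posterior variance. The
limits are exact: d₀ = 0 reproduces the ordinary t, d₀ = ∞ the pooled
t, and with two groups F = t². The independent cross-check against the
established empirical Bayes implementation agrees to numerical
precision; it is a test oracle only, never the implementation.

Default FDR cutoffs: 0.05 for the two-group contrasts, 0.10 for the
subtype F-test — deliberately less stringent because each subtype holds
only ~5 samples. All cutoffs are parameters.

## The three-step non-coding filter

Step 1 removes probes overlapping a protein-coding exon by ≥ 1 nt on
either strand; a probe whose only exon overlap is antisense **and** that
carries no significant same-strand coding segment forms the separate
antisense non-coding set. Step 2 removes remaining probes covered by a
significant coding-potential segment (p < 0.05). Segment p-values are
intentionally not multiplicity-adjusted: the filter's job is to
minimise regions falsely called non-coding, not to certify coding
regions. Because the upstream coding scan evaluates all six reading
frames, the default step-2 rule disqualifies on either-strand overlap
(conservative); `step2_strand = "same"` restricts it. Step 3 applies
only where the coding scan had no alignment coverage (outside the
coverage mask): there, a translated protein-similarity hit (≥ 1 nt)
removes the probe. Survivors are bona fide intronic (inside a
protein-coding span) or intergenic. `calibrate_coding_threshold`
reports sensitivity against known coding exons and specificity against
length- and repeat-matched sampled intervals across a p-cutoff grid;
both are monotone in the cutoff by construction.

## Enrichment, pairs, CARs, copy number

Enrichment builds the 2×2 table of overlap (90% single-interval rule)
for a DE set against the full array background — which, as defined,
contains the DE probes; an exclusive-background mode exists for
sensitivity analysis. Reported are the observed odds a/(n_DE − a), the
background odds, their ratio, the exact conditional MLE odds ratio, the
exact 95% CI, and the two-sided exact p (sum of tables at most as
probable as observed). The legible method text defines the odds through
the relative overlaps; the exact algebra of its displayed equations is
not recoverable from the source, so the prose definition is what is
implemented, with both odds-ratio variants reported.

Pairing: the nearest protein-coding gene is found among **all**
protein-coding genes and the pair is then kept only if that gene is
itself DE (the alternative — searching only among DE genes — is noted
as ambiguous in the source; the implemented order is the literal
reading of "closest … retained if DE"). A gene's fold change is the
signed log2FC of its maximum-|log2FC| significant exonic probe.
Same-strand pairs must be converse (opposite signs) to be accepted —
this guards against unannotated distal exons of the coding gene
masquerading as lncRNAs; opposite- or unknown-strand pairs are accepted
regardless of sign. Quadrant counts are per unique gene: a gene counts
in a quadrant if at least one accepted pair places it there.

CAR calls use every significant probe overlapping the CAR by ≥ 1 nt on
either strand (CAR strand is unknown): all negative → consistent_down,
all positive → consistent_up, mixed → inconsistent (a zero fold change
among significant probes counts as inconsistent), none significant →
not_significant; CARs without probes are not_represented and excluded
from denominators.

Copy number: piecewise-constant per-sample profiles are interpolated at
probe positions — segment value inside a segment, base-weighted average
across a boundary, nearest-segment value in gaps (mean of the two at an
exact tie; the source says only "interpolation of the piecewise
constant function", so the gap rule is a package choice). "Explained by
copy number" is operationalised as a per-probe OLS slope significant at
BH FDR < 0.05 across tumor samples — the headline fraction — with the
mean per-probe R² emitted alongside as the variance-decomposition
summary, since the source does not state which of the two its "6%"
refers to.

## The synthetic world

`sim_config()` defaults state the world the tests run in: 2 chromosomes
× 1 Mb; 100 protein-coding genes with log-normal exon (~150 bp) and
intron (~700 bp) lengths; 2,000 expression probes of 60 bp
(600/600/600/200 across coding-exonic/intronic/intergenic/antisense)
plus 100 negative controls; 5 normals and 26 tumors cycled over five
subtype labels with two additive batches; planted two-group effects of
±2 log2 units on 25% of uncommitted probes; 20 planted converse pairs
(probe and anchor-gene fold changes of opposite sign, probe placed
nearer its anchor than any other gene); a CAR pattern of 43
consistent-down, 17 consistent-up, 4 inconsistent and 24 quiet CARs
(placed ~10% in introns, ~45% spanning an exon, ~45% intergenic,
mirroring the reported composition); 5%/3% of intronic+intergenic
probes planted to fail filter steps 2/3; a 6% copy-number-driven
fraction with unit slope against segment values of SD 0.6; and log2
noise of SD 0.3 over N(8, 1) baselines. Sample counts, probe length,
the CAR pattern, the pair count, and the 6%/slope/noise values mirror
the study design; the genome scale and length distributions are toy
values chosen so the structure (multi-exon genes, real intergenic
space) exists at desk size.

Generator choices worth knowing:

* **Exonic and antisense probes may overlap each other** (independent
  uniform placement), as probes on dense tiling arrays do;
  intronic/intergenic probes keep ≥ 24 bp separation so that planted
  per-probe evidence segments (probe ± 20 bp) can never touch a
  neighbouring probe, keeping the planted filter truth exact.
* **Probes never straddle commitments**: exonic/antisense probes avoid
  CAR intervals, stratum probes avoid CARs and gene spans with margins
  wider than any evidence padding — so classification truth and CAR
  truth are exact by construction, not approximately.
* **Quiet CARs are unexpressed.** CARs planted "not significant" get
  probes at negative-control background; the nonspecific filter removes
  them, and the planted consistency pattern is deterministically
  recoverable. This mirrors the biological reading that
  chromatin-associated lncRNAs without expression change in a tissue
  are mostly not expressed there at all. Without this, Benjamini–
  Hochberg false positives (expected ≈ 1 among ~50 quiet-CAR probes
  when hundreds of true effects are present) would flip a quiet CAR's
  call in a sizeable fraction of runs.
* **Committed probes draw baselines from the upper half** of the
  baseline distribution so planted patterns are expressed above
  background — a planted effect on an unexpressed probe would be
  removed by the filter by design.

What a green test does **not** establish: the generator plants additive
Gaussian effects on the log2 scale with a single effect size, no
between-array intensity distortions, no spatial or dye artifacts, no
correlation structure between probes beyond the planted commitments,
and no mixture of effect sizes. In particular, quantile normalisation
is a no-op in expectation on this world; on the planted world where 25%
of probes shift by ±2 in the tumor group only, quantile normalisation
demonstrably distorts null probes (measured null |log2FC| ≈ 0.4 on the
default world) because the equal-distribution assumption is broken by
the asymmetric signal mass. Recovery tests therefore evaluate the
statistics on the generated log2 matrix, while normalisation is
verified against its defining property and hand-computed references and
runs inside the full pipeline. Real-data analyses should be aware that
heavy asymmetric differential expression biases quantile-normalised
fold changes toward the probe's rank position.

## Numerical and degenerate-input choices

* Trigamma inversion for d₀ uses damped Newton iteration with the
  standard large/small-argument shortcuts; probes with zero residual
  variance are excluded from the moment fit and shrink fully to the
  prior.
* Fisher tables with a zero margin report 0/∞ odds with the exact
  one-sided CI from the conditional test; proportional tables give an
  odds ratio of exactly 1 and p = 1.
* Constant expression or copy-number vectors yield `NA` correlations;
  zero-variance copy number excludes a probe from the explained-fraction
  denominator.
* Probes on chromosomes absent from a track simply do not overlap it
  (fraction 0); probes on chromosomes absent from the supplied genome
  are an error at classification.
* Unique DE loci collapse probes with *identical* coordinates only;
  overlapping-but-distinct probes stay distinct. The probe→locus rule
  is not stated in the method source; exact-coordinate collapsing is
  the most conservative deterministic choice.
* All randomised procedures take explicit seeds; a pipeline run is a
  pure function of (config, seed) and reruns are byte-identical.

## Known limitations

The generator's placement uses rejection sampling: extremely dense
configurations (probe counts approaching the available stratum space
divided by probe length + padding) fail with a placement error rather
than degrading silently. The moderated-F batch adjustment assumes the
batch is not confounded with subtype. The enrichment type-I calibration
holds for the exact test's discrete p-values at the default world's
count sizes; for very sparse tracks the exact test is conservative, as
expected. No liftover, sequence handling, peak calling, segmentation or
clustering is provided; those are inputs or out of scope.
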