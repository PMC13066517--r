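---
title: "Methods: profiling protein composition with aptamer library sequencing"
author: "aptaprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling protein composition with aptamer library sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaprofile)
```

## The measurement model

In branched selection, a single SELEX-enriched RNA aptamer library is
presented in parallel to many individual biofluid samples (here: human milk
collected longitudinally from mothers).  Library molecules that bind sample
proteins are recovered and sequenced, so each sample yields a vector of read
counts over library sequences.  Because binding depends on which proteins
are present and at what concentrations, the per-sample read distribution is
a quantitative proxy for the sample's global protein composition — without
ever identifying the proteins directly.  Downstream, selected candidate
aptamers are used as affinity baits in pull-downs, and mass spectrometry of
the captured fractions links sequence families back to proteins.

`aptaprofile` implements the dry half of this design: everything from raw
barcoded reads to validated condition-specific sequence panels, motif
families, and pull-down relative-abundance profiles.

## Pipeline stages and their assumptions

### Demultiplexing

Reads are fixed-structure amplicons: `barcode + 5' flank + variable region +
3' flank`.  Barcodes are matched exactly by default; a 1-mismatch tolerance
is available, with ambiguous assignments discarded rather than guessed.
Flanks are stripped by literal prefix/suffix match.  Reads failing any part
of the structure are counted as unassigned, and assigned + unassigned always
equals the total — no read is silently lost.  Quality trimming and adapter
discovery are deliberately out of scope: the amplicon structure is known.

### Family joining (Damerau–Levenshtein, d_max = 3)

PCR and sequencing errors scatter a true library sequence ("ancestor") into
a halo of near-identical derived sequences.  Sequences within
Damerau–Levenshtein distance 3 of a more abundant sequence are therefore
joined into its family.  Two variants of the metric are provided:

* **unrestricted** (default): substitutions, insertions, deletions and
  adjacent transpositions, with transposed pairs free to be edited again.
  This is a true metric (it satisfies the triangle inequality), computed
  with the Lowrance–Wagner dynamic program in C++.
* **restricted / OSA** (`restricted = TRUE`): the optimal-string-alignment
  variant many libraries compute, which forbids re-editing a transposed
  pair.  The two differ on cases like `CA → ABC` (2 vs 3).

Which variant an upstream analysis used is often unclear; both are exposed
and both are oracle-tested.

The joining algorithm is a greedy abundance-anchored pass: sequences are
visited in descending total count (ties broken lexicographically), each
becoming a new family representative unless an existing representative lies
within `d_max`, in which case its counts move to the *nearest*
representative (ties to the more abundant one).  The rationale is the
ancestor semantics itself — high-abundance parents absorb low-abundance
derivatives, not the other way round.  A single-linkage connected-components
alternative is available (`method = "components"`); it merges chains that
greedy assignment keeps separate, and is provided for sensitivity analysis
rather than as the default.  Joining moves counts and never drops them, so
total reads are conserved, and the visiting order makes the result invariant
to input row order.

For speed, candidates are screened with a banded, capped Levenshtein bound
before the full metric is computed: since each transposition can be emulated
by two substitutions, `Lev ≤ 2·DL`, so `Lev > 2·d_max` proves
`DL > d_max`.  The screen is exact, not heuristic, as is the
length-difference prefilter `|len(a) − len(b)| > d_max`.

### Detection filter (c_min = 3)

After joining, a sequence is retained only if it has at least 3 reads in
*every* sample (`presence_mode = "all_samples"`).  The per-sample reading of
the rule follows its stated purpose — minimizing bias from missing values
caused by limited detection sensitivity; `any_sample` and `mean` modes are
available for exploration.  Joining precedes filtering.

### Normalization

Counts are converted to percent-of-total per sample (compositional closure;
read depth varies per sample), then each percent value is divided by that
sequence's mean percent across the cohort's samples.  A scaled value of 1
means "at this sequence's average relative binding"; values below/above 1
mean reduced/increased binding.  Two invariants are enforced to 1e-9:
percent columns sum to 100, and per-sequence scaled means equal 1.  Scaled
values are invariant to per-sample depth rescaling.  The scaling scope is
per cohort — discovery means for discovery samples, validation means for
validation samples — because the two cohorts are analyzed independently and
freezing discovery means into the validation branch would leak information
across the split.

### Differential profiling

For each contrast (each later sampling time vs the first; elevated vs
normal BMI; primiparous vs multiparous), each sequence's scaled values are
fit by OLS on a study-group indicator over the union of the two groups.
With a binary predictor the coefficient *is* the group-mean difference, and
its two-sided p value equals the pooled-variance two-sample t-test
(df = n − 2) — an algebraic identity the tests verify against `lm()` and
`t.test()` to machine precision.  P values are Benjamini–Hochberg adjusted
within each contrast (contrast counts are reported separately, so pooling
across contrasts would misstate the per-contrast FDR).  A sequence is
**descriptive** when `p_adj ≤ 0.05` *and* `|beta| ≥ δ`, with δ = 1 for
sampling time (maturation changes are profound) and δ = 0.2 for BMI group
and parity (subtler, heterogeneous conditions searched more broadly).
Degenerate zero-residual-variance fits get p = 1 with a warning — never NaN.
Raising δ can only shrink the descriptive set (a monotonicity the suite
checks).

Repeated measures are deliberately not modeled: contrasts are simple
two-group comparisons without participant random effects or covariates.
This matches the analysis the package reproduces; a mixed-model extension
would change the meaning of every threshold.

### Panel validation

Descriptive panels discovered on the discovery cohort are frozen, then
tested on an independent validation cohort: the validation scaled matrix is
restricted to the panel, sequences are mean-centered (no unit-variance
scaling — scaled values already share the mean-1 scale, and rescaling would
up-weight noisy low-variance sequences), and PC1 scores are computed by
SVD.  The PC1 sign is fixed by orienting the study group's median score to
be at least the reference group's, making runs bit-identical.  Group
separation is tested by two-sided Wilcoxon rank-sum on PC1 scores — exact
when both groups have ≤ 25 observations and no ties, otherwise the normal
approximation with tie and continuity corrections.  Per-group medians and
unbiased (n − 1) variances are reported alongside, since group dispersion
differences are themselves of interest.  Panel coverage (fraction of panel
sequences present in the validation matrix) is always recorded; missing
sequences trigger a warning, not silent subsetting.

### Motif families

"Global homology" among descriptive sequences is operationalized as k-mer
containment enrichment (default k = 7): for each k-mer occurring in the
panel, the number of panel sequences containing it is tested against its
empirical containment frequency in the full retained library (SELEX
libraries are sequence-biased, so an i.i.d.-base background would be wrong)
with a one-sided binomial tail.  Two design points matter:

* **Multiplicity is taken over all 4^k possible k-mers**, not just the
  observed ones.  Observed k-mers are a selected subset — every k-mer in a
  panel occurs at least once — and adjusting only over them makes chance
  singletons "significant" under the null.  With the full universe, null
  panels yield no enrichments while an implanted motif (present in all
  panel members, essentially absent from background) is detected with
  overwhelming strength.
* A pseudocount (0.5 background occurrences) keeps never-seen motifs
  testable without producing p = 0.

Enriched motifs are merged transitively when they are a single shift apart
(k − 1 character overlap) or share at least 50% of member sequences
(relative to the smaller set), giving motif families; the representative is
the member with the largest summed read count across both cohorts, ties
lexicographic.  Candidates are then the top representatives per model
group, each flagged on the three selection criteria (read count, conserved
motif, model representation).  No attempt is made to reproduce any specific
published motif count: the homology method, k and statistic are the
package's own concrete choices for an otherwise under-specified step.

### Pull-down profiles

Protein intensities from pull-down mass spectrometry are expressed per
sample as `L = log2(100 · I / ΣI)`; zero-intensity cells are "not detected"
and masked rather than imputed, so per-sample detected relative abundances
always sum to 100 before the log.  Proteins detected in any negative
control are classified background (highly abundant matrix proteins bind
nucleic acids nonspecifically and appear everywhere); proteins detected
only in one model group's pull-downs are unique to that group; detections
across several groups without negatives are shared.  Detection is raw
intensity > 0 by default — a configurable floor is available because MS
noise floors vary, but no soft threshold is imposed silently.

## The synthetic-cohort generator

Every stage above is benchmarked against a generator that emulates the
statistical structure the analysis assumes, providing ground truth that no
deposited dataset can:

* a library of `n_ancestors` random 36-nt RNA variable regions with
  log-normal baseline abundances (`abundance_sigma = 1.5` by default, giving
  the ~4 orders of magnitude of relative abundance typical of enriched
  libraries);
* a longitudinal two-cohort design — one sample per participant per
  timepoint (3 days, 1, 2, 3 months), 86 discovery participants by default
  with ~63% in the elevated-BMI group and balanced parity;
* planted multiplicative condition effects on chosen ancestors, applied to
  latent proportions before compositional renormalization (reads are
  compositional, matching the percent-of-total normalization downstream),
  with optional per-sample log-normal biological noise;
* multinomial reads at Poisson depth (desk-scale default 1e5 per sample);
* per-read edit noise: with probability `mutation_rate`, a read acquires
  1–3 uniform edits among substitution, insertion, deletion and *adjacent
  transposition* — the last included precisely so the Damerau–Levenshtein
  metric, not plain Levenshtein, is exercised;
* RNA alphabet internally (U), DNA (T) on FASTQ export, losslessly.

With `well_separated = TRUE`, ancestors are rejection-sampled to pairwise
distance > 2·d_max, which makes family recovery identifiable: every derived
read is nearer its own ancestor than any other, so joining must reconstruct
the pre-mutation tallies exactly — an exact, not approximate, oracle.

Timepoint effects are modeled as fold changes relative to the 3-day level,
mirroring the reference structure of the contrasts.  Planted fold-change
defaults (1.5–2×) are the package's own benchmark choice; per-sequence
condition effect sizes are not published quantities.

What the generator does *not* emulate: SELEX round-to-round enrichment
dynamics, PCR amplification bias correlated with sequence content,
position-dependent sequencing error profiles, participant-level covariance
beyond the planted effects, or mass spectra.  Passing benchmarks therefore
demonstrates correctness of the algorithms under the stated statistical
model, not robustness to every artifact of real sequencing data.

## Benchmark designs and numerical choices

The test suite and `scripts/acceptance.R` use desk-scale problem sizes
chosen to finish in minutes while keeping the statistics meaningful: 1000
well-separated ancestors at depth 1e5 over 20 samples for exact family
recovery; 60–200 null cohorts of 500 sequences with 40-vs-40 balanced
groups for false-positive calibration (the `balanced` generator flag fixes
group sizes exactly); 10–20 replicates with 20 planted effects among 1000
sequences at fold 1.5 and biological noise 0.3 for sensitivity/FDP; 20–50
implanted-motif panels against a 1500-sequence background.

One benchmark choice deserves its own paragraph: planted effects are placed
on sequences above the detection floor implied by the ≥ 3-reads-per-sample
filter (expected per-sample count ≥ 15, which makes at least 3 reads in
every sample of the cohort near-certain).  With a realistic abundance
spread, a sizeable fraction of library sequences sits at expected counts of
1–10 reads per sample, where multinomial noise swamps a 1.5× effect; such
sequences are exactly what the detection filter exists to exclude from the
analyzed library, and effects planted there are unrecoverable by any
method at that depth.  The benchmark measures what the pipeline claims:
recovery of condition effects on the robustly detected library.

Other numerical conventions: all randomness flows from explicit integer
seeds (sub-seeds stay below 2^31); canonical row order everywhere is
descending total count with lexicographic ties, making every output
order-stable; zero-total samples, zero-mean sequences, empty groups and
all-removed filters are hard errors naming the offending entity; the
zero-residual-variance OLS case warns and reports p = 1.  Run manifests
contain the config hash (MD5 of the canonical JSON, excluding the output
path), seed, package version and per-stage row counts — and no timestamps,
so identical configurations reproduce runs bit-identically.

## Known limitations

* The greedy join is a contract, not a globally optimal clustering; at
  d_max = 3 with well-separated ancestors the two coincide, but for dense
  sequence clouds single-linkage components can differ (both are provided).
* Simple two-group OLS ignores the repeated-measures structure of
  longitudinal designs; p values for sampling-time contrasts are
  anti-conservative to the extent that within-participant correlation
  matters.
* k-mer containment is a coarse notion of homology: motifs with internal
  indels or degenerate positions are fragmented across several k-mers and
  only partially rescued by the merge rules.
* The Wilcoxon normal approximation is used for groups larger than 25; for
  very small validation subgroups the exact test is automatic, but heavily
  tied score vectors (possible with degenerate panels) fall back to the
  approximation.
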