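---
title: "Longitudinal tumor evolution from serial exomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal tumor evolution from serial exomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`longevol` analyzes serial tumor exomes from one patient — typically a
primary tumor and one or more recurrences — to describe how the clonal
composition of the tumor changes under treatment, and screens tumor
cohorts for chromothripsis and hypermutation. This vignette describes the
underlying models, the tunable parameters, the synthetic-data generator
used for validation, and the numerical choices the implementation makes.

```{r setup}
library(longevol)
```

## Clonality (cancer cell fraction) model

The fraction of tumor cells that carry a somatic mutation — its cancer
cell fraction (CCF), or clonality rate — is not directly observed. What is
observed is the variant allele frequency (VAF): the fraction of sequencing
reads at the site that carry the alternate allele. The two are linked by
the sample's tumor purity $\rho$ (one minus the admixture rate of normal
cells), the local total copy number in tumor cells $c_T$, the local copy
number in normal cells $c_N$ (2 for autosomes), and the mutation
multiplicity $m$ (mutant-allele copies per mutated tumor cell):

$$
\mathbb{E}[\mathrm{VAF}] \;=\;
\frac{\rho\, m\, \mathrm{CCF}}{\rho\, c_T + (1-\rho)\, c_N}.
$$

`ccf_from_vaf()` inverts this relation per variant. Multiplicity is
estimated first (`estimate_multiplicity()`) under the clonal assumption
$\mathrm{CCF} = 1$:

$$
\hat m = \mathrm{round}\!\left(\mathrm{VAF}\cdot
\frac{\rho c_T + (1-\rho) c_N}{\rho}\right),
\qquad \hat m \in [1,\; \max(1, \mathrm{round}(c_T))],
$$

with ties at $x.5$ rounded half away from zero. Estimating $m$ per variant
rather than jointly is deliberate: at exome depths the per-site likelihood
rarely distinguishes neighboring multiplicities, and a joint model would
couple errors across sites.

Numerical conventions:

* Raw CCF estimates above 1 signal inconsistency between the observed VAF
  and the assumed copy state. Values are capped at `ccf_cap = 1.5` before
  reporting and clustering, and values above 1.2 are flagged
  (`flagged_inconsistent`). The cap preserves the signal that something is
  off without letting a handful of outliers dominate the mixture fit.
* Purity is an input, not estimated from the data. Sex chromosomes use
  $c_N = 2$ by default (appropriate for XX patients; override `normal_cn`
  otherwise).
* At purity 1, $c_T = 2$, $m = 1$ the model reduces to
  $\mathrm{CCF} = 2\,\mathrm{VAF}$ exactly, a useful sanity check.

## The multi-timepoint CCF matrix

`assemble_ccf_matrix()` builds the clustering substrate: rows are the
union of unique somatic mutations across timepoints, columns are
timepoints. A mutation not called at some timepoint may be genuinely
absent or merely uncovered, and the two must not be conflated. The rule:

* called — `observed`, with its estimated CCF;
* uncalled, site depth $\ge$ `min_depth` (default 20) in that sample —
  `absent_confident`, CCF exactly 0;
* uncalled, depth unknown or below `min_depth` — `absent_lowdepth`.

Rows containing any `absent_lowdepth` cell are excluded from clustering
(`clustering_rows()`): a trajectory with an unverifiable zero would be
assigned to a clone on fabricated evidence. Site depths at uncalled
positions come from an optional per-timepoint coverage table (`depths`
argument), as produced by a pileup over the union of mutated sites; when
no coverage is supplied every absence is treated as low-depth, which is
conservative.

## Mixture clustering and BIC model selection

Mutation trajectories (rows of the CCF matrix, points in $\mathbb{R}^T$
for $T$ timepoints) are clustered with a finite Gaussian mixture fitted by
EM (`fit_mixture()`). Three covariance families span the volume/shape
spectrum that matters for low-dimensional CCF data: spherical
($\sigma_k^2 I$), diagonal (per-component axis-aligned), and full
(unconstrained per-component). The number of components $k$ and the
family are selected (`select_model()`) by minimizing

$$
\mathrm{BIC} = p \ln n - 2\,\ell,
$$

where $p$ is the parameter count and $\ell$ the log-likelihood; ties break
to smaller $k$, then spherical < diagonal < full. This is the standard BIC
convention stated once to avoid sign errors (model-based clustering
packages sometimes maximize its negative).

Numerical choices, each of which matters in practice:

* **Initialization.** k-means++ seeding with 10 restarts; restart seeds
  are derived deterministically from the user seed, so fits are exactly
  reproducible. (Hierarchical-agglomeration initialization, as used by
  some model-based clustering packages, is not replicated.)
* **Convergence.** Relative log-likelihood change below $10^{-6}$ or 500
  iterations; the per-iteration log-likelihood trace is retained and is
  non-decreasing, which the test suite asserts.
* **Variance floor.** Covariance diagonals are floored at $10^{-6}$.
  Confidently-absent cells are exactly zero, so entire coordinates of a
  component can be constant; the floor keeps such components proper
  without materially biasing them.
* **Degeneracy guards.** With $k > 1$, any component whose effective
  membership falls below $d + 1$ aborts that restart: such components
  collapse onto single points and the likelihood spikes without bound (the
  classic unbounded-likelihood pathology of Gaussian mixtures). Model
  selection also skips combinations with $p \ge n$, which are not
  identifiable. Without both guards BIC can prefer spurious spike
  solutions on small noisy inputs.
* **Hard assignments** are maximum-posterior, ties to the lowest component
  id.
* `k_max` defaults to 6, comfortably above the four clone classes the
  validation plants while keeping the fit grid (18 models) cheap; raise it
  for richer cohorts (hypermutated recurrences can support many emerged
  subclones).

## Clone trajectory classification

Each fitted component's mean CCF trajectory is classified
(`classify_clusters()`, `trajectory_class()`) using a single presence
threshold (default 0.10; the choice is a convention, since "present at
very low clonality" and "absent" cannot be distinguished at exome depth):

* **preserved** — present at every timepoint;
* **lost** — present at the first, absent at the final timepoint;
* **emerged@t** — absent before $t$, present from $t$ onward ($t > 1$);
* **transient** — anything else.

The classes are deliberately coarse: they describe what a clinician reads
off a clonal-evolution plot (a founding clone that persists, a clone
eradicated by therapy, a resistant subclone appearing at recurrence)
without asserting a phylogeny. Tree reconstruction is out of scope.

## Substitution spectra, hypermutation, MMR screening

`mutation_spectrum()` computes 6-class and 96-class (trinucleotide
context) spectra under the standard pyrimidine-strand convention:
purine-reference SNVs are reverse-complemented (G>A in context `TGA`
becomes C>T in `T[C>T]A`). The C>T transition fraction — the signature of
alkylating-agent exposure and of MMR-deficient hypermutation — is reported
over SNVs only, rounded to integer percent for display. Contexts are taken
from annotation (`TNC` INFO key) or from the generator; the package never
requires a reference FASTA.

`flag_hypermutation()` counts coding SNVs against a fixed threshold,
default 500. Observed burdens separate cleanly — hypermutated tumors carry
thousands of coding mutations where typical exomes carry tens — so any
threshold in the wide gap between those regimes gives the same answer; 500
sits near its middle on a log scale. `screen_mmr()` returns
non-synonymous variants in the core mismatch-repair genes (MLH1, MSH2,
MSH6, PMS2 by default); deleteriousness prediction is out of scope, so the
effect class comes from annotation.

## Chromothripsis detection

Chromothripsis — catastrophic shattering and reassembly of a chromosome —
leaves two joint footprints in exome data: oscillation between few copy
states, and dense structural-variant breakpoints with strong read support,
co-located on the affected chromosome. `chromosome_features()` computes
per-chromosome evidence; `call_chromothripsis()` applies the gate:

| parameter | default | meaning |
|---|---|---|
| `support_min` | 100 reads | breakpoint support to count at all |
| `switch_min` | 10 | copy-state switches (oscillation) |
| `break_min` | 10 | supported breakpoints on the chromosome |
| `amp_min` | 20 copies | high-amplification state (amplifying type) |
| `del_frac_min` | 0.3 | covered length at CN $\le 1$ (deleting type) |
| `merge_tol` | 10 kb | breakpoint-end ↔ segment matching slack |

Copy numbers are rounded to integers before oscillation counting, so
segmentation noise around a state does not create spurious switches. The
two anchored thresholds are the printed hallmarks of the phenotype —
amplified segments above 20 copies and breaks supported by more than 100
reads; the remaining three operationalize "many switches, many breaks,
large-scale deletion" and are configurable. Positive chromosomes joined by
at least one supported inter-chromosomal breakpoint merge into one
multi-chromosome event. The lesser-allele-frequency shift (length-weighted
mean $|0.5 - \mathrm{LAF}|$) is reported as supporting evidence but never
gates a call, since no quantitative threshold for it is established.

`dm_candidates()` extracts double-minute candidates: connected components
of the graph whose nodes are segments at or above `amp_min` copies and
whose edges are supported breakpoints landing inside (or within
`merge_tol` of) two such segments. An isolated high-copy segment is not a
candidate — without a junction there is no evidence the amplicon is a
self-contained circular element. Sequencing alone cannot distinguish a
double minute from a homogeneously staining region (that requires FISH),
hence "candidates".

## Cohort summarization and percent rendering

`summarize_cohort()` tallies per-subtype positive fractions.
`format_percent()` renders them to two significant digits: at or above 10%,
nearest integer; below 10%, one decimal truncated toward zero. Truncation
in the decimal regime is intentional — 1/57 renders as "1.7%" (100/57 =
1.754), matching how such screen fractions are conventionally reported —
and the same rule renders 16/52 as "31%" and 1/52 as "1.9%".

## The synthetic-data generator

No patient exome data ship with the package; validation rests on
generators (`simulate_patient()`, `simulate_chromothripsis_chrom()`,
`simulate_spectrum()`, `simulate_cohort()`) that are pure functions of a
specification and a seed, each emitting a truth table covering every
record.

`simulate_patient()` emulates a three-timepoint serial tumor. The default
clone set plants the four canonical trajectories: a preserved founding
clone (CCF 0.95 throughout), a clone lost after the first timepoint (0.6,
0, 0) — the fate of a treatment-sensitive subclone under targeted therapy
— a subclone emerging at the first recurrence (0, 0.5, 0.5) and a late
subclone (0, 0, 0.45) carrying a 97%-C>T alkylator-type spectrum; 50
mutations per clone, depth Poisson(200), purity 0.5 at every timepoint,
multiplicity 1 on a diploid background. Reads are drawn binomially from
the expected VAF, and a mutation with fewer than 3 alt reads at a
timepoint is dropped from that timepoint's calls, emulating caller dropout
without modeling a caller. Coverage tables at all union sites are emitted
so absence classification can be exercised. With `hypermutated = TRUE`
the late clone instead carries 2079 all-coding mutations including an MSH6
missense — the scale of an MMR-deficient recurrence versus the tens of
coding mutations at earlier timepoints.

Under these defaults the matrix-wide mean absolute CCF error is dominated
by irreducible binomial read sampling: roughly 0.05 given depth 200 and
purity 0.5 (high-CCF cells carry per-cell noise near 0.1; confident-absent
cells are exact). The clustering recovers the four planted clones and
their classes essentially always at this separation-to-noise ratio.

`simulate_chromothripsis_chrom()` builds amplifying chromosomes
(20–60 segments alternating between copy 2 and a high state ≥ 20, one
supported junction per boundary), deleting chromosomes (≥ 35% of length at
CN ≤ 1, optionally inter-linked to a partner), and quiet chromosomes
(single diploid segment, at most 2 low-support breakpoints). The
constructions sit above the detector's gates by design, so detection
checks measure the gate logic, not borderline luck. `simulate_cohort()`
plants exactly `round(rate × n)` positive samples per subtype — positives
are planted deterministically rather than drawn binomially, so cohort
recovery checks are exact.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: germline contamination and caller
artifacts; subclonal copy-number change under a mutation (the local CN is
known and clean, so CCF accuracy on real tumors will be worse wherever the
copy model is wrong); mutation multiplicities above 1 by default;
overdispersed (non-binomial) read counts; indel signatures; and the
continuum of partial chromothripsis phenotypes between the planted
"obvious event" and "quiet chromosome" extremes. Detector sensitivity on
borderline real events is not established by the simulation.

## Validation problem sizes

The shipped tests fit mixtures on matrices of 200 mutations × 3
timepoints across 20 seeded patients, estimate CCF accuracy on 100 such
patients, and screen a 109-sample simulated cohort plus 100 simulated
chromosomes — sizes chosen so the full suite completes in a few minutes
while keeping every estimate's Monte-Carlo error well below the margins
being tested.

## Known limitations

* Purity and local copy number are inputs; errors in either propagate
  directly into CCF (the model cannot detect a wrong purity).
* Per-variant multiplicity rounding is unstable exactly at multiplicity
  boundaries (VAF near the midpoint between two integers).
* The mixture model treats trajectories as Gaussian; CCFs are bounded in
  [0, cap] and absence zeros are point masses, so components at the
  boundary are approximations. The variance floor absorbs the point
  masses but a truncated or zero-inflated model would be more faithful.
* Chromothripsis calling is a threshold gate, not a statistical test of
  breakpoint randomness; it is tuned for screening, and borderline events
  need manual review of the per-chromosome features it reports.
* Evolution classes describe mean cluster trajectories; they do not order
  clusters into a clone tree.
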