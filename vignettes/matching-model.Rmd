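---
title: "The nrpslink matching model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nrpslink matching model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpslink)
```

## The problem and the probabilistic model

An NRPS assembly line incorporates one residue per module, so a cluster's
module annotations predict a *sequence* of residues (with methylation and
epimerization states), while retro-biosynthesis of a peptide yields a
*graph* of residues. `nrpslink` reduces both sides to monomer sequences and
asks: how much more likely is the observed compound under the cluster's
predictions than under no genomic information at all?

Formally, an NRP monomer is $(a, m, e)$ with residue $a$ in the extended
alphabet $\bar{A} = A \cup \{\varnothing\}$ ($\varnothing$ pools every
unsupported residue; two unsupported residues are never considered equal),
methylation $m \in \{-1, +1\}$ and stereo $e \in \{-1, 0, +1\}$ ($0$ =
undetermined or achiral). A BGC monomer adds the specificity score
$s \in [0, 100]$ of the adenylation-domain prediction; the *undefined*
monomer $(0, \varnothing, 0, 0)$ carries no information. For a global
alignment $(\mathrm{NRP}', \mathrm{BGC}')$ the score is the log-odds

$$\mathrm{Score} = \sum_i \log P(\mathrm{NRP}'[i] \mid \mathrm{BGC}'[i])
  - \sum_i \log P(\mathrm{NRP}[i] \mid \text{undefined}),$$

with aligned columns independent, and residue / methylation / stereo
contributions independent within a column. Residue matches contribute
$P_{\mathrm{match}A}(\mathrm{level}(s))$ — the match probability depends on
the discretized specificity level only, not on the residue, which keeps the
parameter count proportional to the number of levels rather than
$|\bar{A}|^2$ — and mismatches contribute
$(1 - P_{\mathrm{match}A}) \, P_A(a_{\mathrm{NRP}}) / (1 -
P_A(a_{\mathrm{BGC}}))$, i.e. the background frequency renormalized over
the non-predicted residues. The same match/mismatch/background pattern
applies to $m$ and $e$ with explicit per-state tables; an undetermined NRP
stereo state is uninformative by construction ($P(0 \mid e_{BGC}) = 1$,
contributing zero). Insertions (a monomer without a module) cost
$P_{\mathrm{ins}} P_A(a) P_M(m) P_E(e)$ and deletions (a skipped module) a
flat $P_{\mathrm{del}}$. Two consequences are useful as self-checks, and
the test suite asserts both numerically: a gap-free alignment against an
all-undefined line scores exactly zero, and each insertion column's *net*
contribution reduces algebraically to the monomer-independent constant
$\log(P_{\mathrm{ins}} (1 - P_A(\varnothing)))$.

The optimal alignment is computed with Needleman–Wunsch under this linear
(per-column) gap model; since the null term does not depend on the
alignment, maximizing the summed column log-probabilities maximizes the
score. All logarithms are natural, so the default reporting threshold
(`min_score = 6`) is on the natural-log-odds scale.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `level_boundaries` | 60, 70, 80, 90 | cut points splitting scores 1–100 into 5 levels (level 0 is reserved for $s = 0$, an unreliable prediction, where the match probability is 0 by convention) |
| `min_score` | 6.0 | natural-log-odds threshold below which matches are discarded (strictly below: an exact tie survives) |
| `max_bgc_dist` | 10,000 nt | inter-gene gap (next start minus previous end) beyond which a cluster is split |
| `min_supported` | 2 | minimum alphabet-supported monomers for a backbone component to be retained |
| `max_copies` | 3 | copy cap per deficient module (stuttering) and per sole-PCP terminal module (gene iteration); 1 copy is the unexpanded strip |
| `max_permuted` | 3 | maximum number of acyclic components whose permutations are added as candidates |
| `max_sequences` | 720 | assembly-line cap per cluster; gene counts whose factorial exceeds it skip the permutation stage |
| `k_best` | 1 | reciprocal rank cutoff for the combined report (1 = strict reciprocal best) |

The five-level discretization with boundaries at 60/70/80/90 concentrates
resolution in the upper range where adenylation-domain predictors actually
discriminate; the boundaries are a configuration value, not a modelling
commitment. The shipped alphabet (58 residues: the 20 proteinogenic amino
acids plus common nonribosomal monomers such as ornithine,
hydroxyphenylglycine, pipecolate) and the shipped probability file are
replaceable defaults — the parameter values are realistic placeholders
meant to be re-learned from curated alignments with
`estimate_alignment_params()` / `bootstrap_params()` on the user's own
data.

## Training

Every probability is a plug-in frequency: $P_{\mathrm{match}A}$ per level
from residue-matched versus all non-indel columns at that level;
methylation events over all non-indel columns; stereo events over non-indel
columns whose NRP stereo is determined. These tables are *joint* event
frequencies over their documented denominators — the scoring formulas use
them as conditionals, which is the same estimation shortcut the frequency
counting implies, and doubling every alignment leaves all point estimates
unchanged (asserted in the tests). The indel denominators are not forced by
the counting scheme, so the package normalizes insertions per NRP monomer
and deletions per BGC monomer, matching the roles the two probabilities
play in the score's two sums. Bootstrap resampling draws whole alignments
(not columns), preserving within-cluster correlation; the point estimate is
the per-parameter mean (median available). Zero-event estimates are floored
rather than left at zero (below).

## Numerical choices

* **Probability floor `1e-9`.** Applied before every logarithm and to
  zero-event estimates; unobserved events in small curated datasets must
  not produce $-\infty$ columns.
* **Traceback tie-breaking.** match/mismatch over deletion over insertion;
  deterministic and biologically biased toward using modules.
* **Candidate tie-breaking.** The best (candidate, assembly line) pair is
  the first index pair attaining the maximum; ranked reports break score
  ties lexicographically on (compound, genome, cluster).
* **Specificity rounding.** The Stachelhaus/SVM mean is rounded half-up
  (`floor(x + 0.5)`) for platform-stable integer scores.
* **Degenerate inputs.** Components with no directed Hamiltonian path are
  dropped with a warning rather than failing the compound; genes with no
  typical module yield no strip; clusters with no consistent strip
  permutation fall back to the collinear order with a warning; an empty
  match set still writes valid, headered reports.

## Open design points and how they were resolved

* **Edge direction.** Backbone edges are traversed source-to-target only;
  reversed traversal of a Hamiltonian path is not attempted. This is the
  conservative reading of a directed monomer graph; a user wanting both
  directions can supply reversed edges.
* **Multiple Hamiltonian paths.** All found paths are kept (up to
  `max_candidates = 100` per component), not just one — the scoring stage,
  not the linearizer, is the right place to pick a winner.
* **Component permutation for k = 1.** Adding the identity permutation
  would duplicate the singleton candidate, so permutations are only added
  for 2–3 acyclic components.
* **CS/TE repair.** When the collinear order violates only the
  CS-first/TE-last conditions, the single offending strip is moved to the
  corresponding end; both moves compose when both conditions fail on
  different strips. Middle-module CS/TE placement is treated at gene
  granularity (the annotations carry gene-level flags).
* **Stutter x iteration composition.** Multiple deficient modules in one
  gene expand multiplicatively and independently, bounded by
  `max_copies^d`.
* **Cyclic candidates.** Each rotation of a cycle is scored as an
  independent linear candidate; no wrap-around bonus is added.

## What the synthetic fixtures emulate — and what they do not

The generator draws residues, methylation and stereo states from the
background tables, plants them into 1–3 genes with high-specificity
predictions (85–100) plus lower-scoring decoy predictions, and perturbs
the compound side with residue mismatches, indels, stuttering, tailoring
edges, cyclization, or gene-order shuffling (with CS/TE flags left intact
so consistency constraints can recover the order). Decoy compounds are
resampled from the same background, so discrimination difficulty scales
with the entropy of $P_A$; training sets are drawn from the scoring
model's own generative form, which is exactly what makes plug-in
estimation consistent for the generating values.

Real data differ in ways the fixtures deliberately do not model:
predictor errors are correlated with residue identity (the model assumes
level-only match probabilities), curated alignment columns are not
independent, clusters contain non-NRPS genes and hybrid polyketide
modules, and monomer graphs from real retro-biosynthesis carry
mis-fragmented or unrecognized monomers. Passing the planted-pair tests
therefore demonstrates internal consistency of the pipeline and scoring
algebra, not field accuracy on biological data — that requires curated
benchmarks outside this package's scope.

## Problem sizes used in the validation suite

The test and acceptance workloads are sized for a single CPU: alignment
oracle checks enumerate all global alignments for 500 random pairs of
lengths at most 4; linearization and assembly-line oracles brute-force
permutations up to 7 nodes / 5 strips; parameter recovery uses 60
synthetic alignments of 40 columns (2,400 columns) against a ±0.05
tolerance; end-to-end recovery runs 100 replicates of one planted pair
(length 8, mismatch rate 0.1, indel rate 0.05) against 20 decoys and
requires the planted compound to be the reciprocal best hit in at least
95% of replicates.

## Known limitations

* Linear gap costs only; no affine extension, and no local or glocal
  modes.
* Match probabilities depend on the specificity level only — promiscuous
  adenylation domains with residue-specific error profiles are averaged
  over.
* COM-domain pairing partners are not predicted; docking constraints are
  positional only.
* Minus-strand genes are taken in annotated (translation) order; the
  package does not re-orient.
* The permutation stage is capped (`max_sequences`); pathological clusters
  with many strips fall back to collinear and repaired orders.
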