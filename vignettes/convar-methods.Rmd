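---
title: "Methods: detecting convergent cis-regulatory evolution in hibernators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting convergent cis-regulatory evolution in hibernators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convar)
```

`convar` asks whether lineages that independently evolved hibernation
accumulated parallel changes — accelerated substitution or outright
deletion — in non-coding elements that remain conserved across background
homeotherms. This vignette documents the models, the tunable parameters
and their defaults, the synthetic-data generators that stand in for real
alignments and functional genomics data, the numerical choices, and the
limits of what the test suite can certify.

## Phylogenetic substrate

Likelihoods use an HKY-style reversible nucleotide model: equilibrium
frequencies $\pi$ (4-vector), transition/transversion ratio $\kappa$, rate
matrix $Q$ normalised to one expected substitution per unit branch length
at equilibrium. $\kappa = 1$ with uniform $\pi$ reduces to the equal-rate
model, whose closed forms ($P_{same}(t) = \tfrac14 + \tfrac34 e^{-4t/3}$)
anchor the unit tests. $P(t) = e^{Qt}$ is computed exactly by
eigendecomposition of the symmetrised $Q$ — exact for this reversible
class, no Padé approximation needed.

Column likelihoods are Felsenstein-pruning sums implemented in C++ (the
calibration and convergence studies perform tens of thousands of
per-region optimisations). Gap and unknown characters are treated
identically as missing data: a leaf partial-likelihood vector of ones.
Deletion evidence is deliberately *not* expressed through the
substitution model; it is handled by a separate caller (below), so gap
runs cannot masquerade as rate acceleration. The test suite verifies
pruning against brute-force enumeration over all internal-state
assignments (≤ 5 leaves, 10⁻¹⁰ relative tolerance), invariance to child
order and to rerooting (reversibility), and the scale identity
$L(c \cdot t, s/c) = L(t, s)$.

Branch lengths are inputs, not estimates. The neutral model and its
branch lengths on real alignments would come from an external fit; the
package documents this assumption rather than re-deriving neutral models
from data (out of scope).

## Conserved-region calling

A two-state phylo-HMM emits each alignment column under a neutral state
(branch scale 1) or a conserved state (all branches scaled by
$\rho \in (0, 1]$). Transition probabilities $\mu$ (conserved→neutral) and
$\nu$ (neutral→conserved) default to an expected element length of
$1/\mu = 45$ bp at stationary coverage $\nu/(\mu+\nu) = 5\%$ — chosen
because the convergent elements of interest are short (the parallel-AR
length mode sits near 40 bp), and configurable. $\rho$ defaults to 0.3;
when unset it is estimated by maximising the HMM likelihood over a coarse
grid (0.1–0.9) with golden-section refinement.

Decoding defaults to the posterior rule (conserved when the
forward–backward posterior is ≥ 0.5, ties conserved), which produces
smoother segments than Viterbi at these element lengths; Viterbi is
available. All recursions run in log space, so arbitrarily long
alignments cannot underflow. Maximal conserved runs are mapped to
reference coordinates — columns where the reference row is gapped carry no
coordinate, and a run spanning them is emitted as the containing
reference interval — and filtered to a minimum length of 20 bp. A
region-level option requires a minimum mean fraction of non-missing
leaves (off by default; the demonstration alignments are dense).

Two design points deserve emphasis:

* **Conservation is assessed on background homeotherms only.** The CR
  universe is defined from the background species of each clade, not from
  the tested foreground lineages. This mirrors the logic of the
  comparative design — a hibernator's acceleration must not erode the
  evidence that the element is constrained in homeotherms — and it
  measurably rescues short, strongly accelerated elements that an
  all-species HMM misses.
* **FDR control by neutral simulation.** `estimate_cr_fdr()` simulates a
  neutral alignment under the same model, calls candidate regions
  identically, and returns the smallest score threshold at which the
  null-region count (scaled to the observed footprint) over the observed
  count is at most the target. It is monotone in the target by
  construction.

## Acceleration and deletion

For each CR and lineage, the null model scales every branch by the CR's
maximum-likelihood conserved scale $\hat\rho$ (fitted per region by
bounded optimisation, tolerance 10⁻⁶; a global-ρ fast mode exists). The
alternative additionally scales the foreground *terminal* branch by
$\hat\rho \cdot r$ with $r$ optimised over $[1, 1000]$ (on $\log r$, with
explicit boundary comparison so $\Lambda = 2(L_1 - L_0) \ge 0$ exactly).
Because $r = 1$ lies on the boundary of the alternative, the null
distribution of $\Lambda$ is the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the test is one-sided for
acceleration (the convergent signal of interest is loss of constraint,
not increased conservation), and two-sided users can recalibrate from the
reported $\Lambda$.

Calibration: at 200-bp regions the empirical type-I error at
$p < 0.05$ sits inside [0.035, 0.065] (2,000 null regions; the acceptance
suite re-runs this). At very short regions (40 bp) the test is
*conservative* (rejection ≈ 0.02), because the boundary mass exceeds ½ in
small samples — it never overstates significance. Power at 40 bp rises
steeply with the planted multiplier (≈ 0.2 / 0.7 / 0.99 at r = 2/4/8 on
the fixture tree).

Regions whose foreground row is ≥ 80% gapped are flagged untestable and
excluded from the BH correction: such regions belong to the deletion
caller, keeping AR and DEL calls mutually exclusive per lineage. BH runs
within each lineage separately, mirroring per-lineage AR counts.

Deletions are called when ≥ 80% of a CR's reference columns are
gapped/unaligned for the lineage *and* ≥ 50% of the columns in each
500-bp flank are aligned for it. The flank requirement is what separates
deletion from missing data (an unaligned contig fails it); truncated
flanks at contig edges are evaluated on the available bases and flagged.
These three thresholds are declared package choices — no published
deletion-calling rule exists for this design — and all are arguments.

## Convergence and the bootstrap null

A parallel element is a CR carrying same-class calls (AR or DEL) in at
least `min_lineages = 2` lineages of one group — hibernator foregrounds or
matched homeotherm controls, processed by the same code path. "Same
element" is defined at CR identity, not base-pair intersection: ARs are
sub-regions of CRs and the CR is the natural unit of the comparison.

The null model redraws, independently per lineage, that lineage's number
of calls uniformly *without replacement* from the background CR universe,
and counts CRs drawn in ≥ `min_lineages` lineages. The p-value uses the
add-one estimator $(1 + \#\{null \ge obs\})/(B + 1)$ (never exactly 0;
default $B = 1000$, explicit seed logged in the result). The test suite
checks the bootstrap against exhaustive enumeration on a 5-CR toy, its
calibration under a fully null generator (fraction of $p < 0.05$ within
[0.01, 0.12] over 100 datasets — slightly conservative by the add-one
estimator and count ties), and its saturation at $p = 1/(B+1)$ under
planted convergence. A length-stratified sampling mode is not provided;
the demonstration universe has homogeneous CR lengths, and stratification
under heterogeneous lengths is noted as a limitation.

## Regulatory integration

Contacts arrive as called, binned pairs (BEDPE with count,
observed/expected and q-value). Significance is conjunctive — count ≥ 12,
obs/exp > 2, q ≤ 0.01 — with symmetric pairs stored once. Promoters
default to TSS ± 2 kb (configurable; no published definition is assumed),
and a promoter window straddling a bin boundary annotates both bins.
Elements map to 10-kb bins by any-overlap; an element spanning two bins
inherits the union of their contacts (conservative for gene assignment).
Classes: **P-P** (element bin has a promoter and significantly contacts
another promoter bin), **E-P** (no promoter in the element's bins, but a
significant contact to ≥ 1 promoter bin), **no-P** otherwise — with a
subclass separating "no significant contacts at all" from "contacts only
non-promoter bins", since published figures do not distinguish them. The
three classes partition any element set.

Enrichment statistics: 2×2 odds ratios with the Haldane–Anscombe +0.5
correction on zero cells (flagged), CIs from the normal approximation on
log OR, two-sided Fisher exact p (point-probability method); the Woolf
heterogeneity test over strata with inverse-variance weights
$w_i = (1/a + 1/b + 1/c + 1/d)^{-1}$; exact upper-tail hypergeometric set
overlap; LOLA-style per-region-set enrichment with BH; consensus peaks as
base pairs covered by ≥ 4 of 8 replicates, merged, with a 50-bp minimum
width suppressing single-bp artifacts at jittered edges (consensus is
idempotent by construction). The cross-species comparison merges peaks
within species, classifies any-overlap pairs as shared (1 bp suffices),
and tests ARs against background CRs in each partition class; inputs are
assumed pre-mapped to one coordinate system — liftover is explicitly out
of scope.

## Co-expression modules and hubs

The network is unsigned WGCNA-style: adjacency $a_{ij} = |cor|^\beta$
with $\beta = 6$ (defaults chosen as the field's standard; no published
parameter set is assumed), topological overlap
$TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$, and
average-linkage clustering on $1 - TOM$ with a **flat cut at height
0.9**. The flat cut replaces dynamic tree cut as a deliberate
simplification; its default height reflects the actual scale of TOM
dissimilarities, where unrelated genes sit essentially at 1 and co-module
genes well below it even at moderate noise (a cut far below that scale
finds no modules at all). Clusters under 20 genes become label 0.

Module eigengenes are the first right-singular directions of the
gene-standardised module submatrices (unit norm, sign-aligned to the mean
module profile); kME is each gene's correlation with its eigengene. Hubs
follow the two-step rule: rank module genes by intramodular connectivity
$k_i = \sum_{j \in module} a_{ij}$ ("connection weights to all other
genes in a module"), take the top $\lceil 10\% \rceil$ (so small modules
keep one candidate), and retain those with kME > 0.8 (strict, on the
signed value after sign alignment, so anti-correlated genes never
qualify). Ties in $k$ break by kME, then gene id.

## Motif scanning and differential enrichment

PWMs are JASPAR-style count matrices with a 0.25 pseudocount per cell;
log-odds are in bits against the background composition. The scanner
scores every window on both strands and reports hits at ≥ 80% of the
maximum attainable score, in forward coordinates, without overlap
masking; it is verified against a brute-force all-window scorer by exact
hit-set equality. Group-level enrichment replaces an affinity-model
statistic with a per-sequence binary "has ≥ 1 hit" 2×2 test (Fisher + BH
across the motif panel) — simpler, exactly testable, and directionally
equivalent for the claim at stake (relative motif loss in hibernator
orthologues); this substitution is a declared divergence, not a
reconstruction. The per-pairing summary is a chi-square of
homeotherm-vs-hibernator enrichment counts against an equal split.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (parameters, seed), byte-identical
across calls, with planted truth in machine-readable form:

* **Alignments** (`simulate_alignment`): segments of classes
  neutral / conserved ($\rho$ on all branches) / accelerated ($\rho$ on
  background branches, $\rho r$ on the named foreground terminals) /
  deleted (conserved background, gap rows for the named lineages, with
  layouts keeping ≥ 500-bp aligned flanks). The shipped fixture tree has
  12 leaves in 4 clades — one hibernator, one matched control, one
  background homeotherm each — at mammal-like neutral branch lengths.
  Defaults: $\rho = 0.3$, planted $r \in \{2, 4, 8\}$ grids, 40-bp
  accelerated elements (matching the parallel-element length mode),
  100-bp conserved and 60-bp deleted segments, 600-bp neutral spacers.
* **Contacts** (`simulate_contacts`): overdispersed negative-binomial
  background counts; planted contacts are element-bin/promoter-bin pairs
  at `enrichment_factor` times the background contact probability, with
  counts shifted above the significance thresholds; q-values are BH over
  negative-binomial upper tails, so the downstream filter recovers the
  planted graph with a small, quantified noise floor. The generator
  records the analytic true odds ratio of "bin has ≥ 1 significant
  promoter contact", which is the quantity the CI-coverage study checks.
* **Expression** (`simulate_expression`): one latent factor per module,
  expression = loading × factor + Gaussian noise (sd 0.3 by default at
  60 samples). The planted hub tier (top 10% of each module) carries
  loading 0.95; remaining genes grade from 0.7 down to 0.4. The gap
  exists so that "planted hub" is a statistically identifiable label —
  with near-touching loadings, top-connectivity rankings are noise-driven
  and no detector could recover the tier.
* **Peaks / motifs**: per-replicate Bernoulli dropout with Gaussian
  boundary jitter; motif instances sampled from the PWM at recorded
  positions and strands, inserted into background-composition sequence.

What passing tests on these generators show: the estimators are unbiased
and calibrated where they claim to be, planted effects of realistic size
are recovered, and every file format round-trips. What they do not show:
robustness to alignment error, indel evolution beyond block deletions,
GC-biased gene conversion (which can mimic acceleration), non-Gaussian
expression noise, contact-map normalisation artifacts, or
phylogenetically correlated foregrounds — the bootstrap null treats
lineage calls as exchangeable draws, which real shared ancestry violates.
Conclusions on real data need those caveats.

## Problem sizes and numerical choices

The acceptance studies run at: 2,000 null regions (calibration), 3 × 300
regions (power), 5,000-CR universe with 50 planted parallel elements
(convergence, ~20,000 LRTs), 100 null datasets (bootstrap calibration),
20 replicate alignments (deletions), 2 × 100 contact maps (CI coverage),
20 expression matrices (hub recovery), 100 motif datasets (detection) —
sizes chosen so the full suite completes in a few minutes on one CPU
while keeping Monte-Carlo error well inside the asserted margins.
Optimisers are `stats::optimize` with tolerance 10⁻⁶ and explicit
boundary comparison; ties at the posterior threshold decode conserved;
degenerate inputs (empty alignments, single-gene modules, empty partition
classes, all-gap columns) return empty or flagged results rather than
errors wherever the empty case is scientifically meaningful.

## Known limitations

Single-branch (terminal) acceleration tests only — no subtree tests, no
joint conservation/acceleration scores; no rate variation across sites;
flat tree cut instead of dynamic; the bootstrap ignores CR length
structure and phylogenetic non-exchangeability; the motif statistic is
hit-based, not affinity-based; cross-genome coordinates are assumed
pre-mapped. Each is an explicit scope decision documented where the
corresponding function is defined.
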