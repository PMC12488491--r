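---
title: "Inferring clone-level allele-specific copy numbers on a fixed tumour phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clone-level allele-specific copy numbers on a fixed tumour phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecn)
```

## The problem

Bulk DNA sequencing of a tumour sample measures a mixture: each genomic
segment's *fractional* allele-specific copy number is the clone-proportion
weighted average of the integer copy numbers of the clones in the sample.
Given (i) a fixed clone tree whose root is the normal diploid clone, (ii) the
proportion $u_{i,r}$ of every clone $i$ in every sample $r$, and (iii)
per-segment fractional copy-number estimates $\hat f^A_{s,r}, \hat f^B_{s,r}$
with interval bounds, `clonecn` deconvolves the mixture into integer
allele-specific copy numbers $c^A_{s,i}, c^B_{s,i}$ for every clone,
including unsampled ancestral ones. It does not infer the tree, the number
of clones, or the proportions; those come from SNV-based reconstruction
tools upstream.

Throughout the package, fractional copy numbers are on the scale
$f^A_{s,r} = \sum_{i \ge 1} c^A_{s,i}\,u_{i,r}$ — a sum over tumour clones
with proportions measured against all cells. The diploid clone contributes
nothing to this sum, and no division by purity is applied; an all-diploid
tumour at purity 0.6 therefore has $f^A = 0.6$. The simulator, the solver
objective and the TVD benchmark all use this one convention.

## The evolutionary model

Copy numbers evolve along the clone tree by unit gains and losses per
segment and allele. Three assumptions restrict the labellings:

* **LOH persistence.** An allele lost completely ($c = 0$) can never be
  regained by a descendant.
* **Bounded alternation.** Along any root-to-clone path, the per-edge
  copy-number deltas of one allele may switch sign at most once (at most two
  maximal same-sign runs of nonzero deltas, zeros being transparent). One
  direction of change may recur; oscillation is considered overfitting.
* **Parsimony.** Among labellings that explain the data equally well, the
  one with the fewest events (total $|\Delta c|$ over edges and alleles) is
  preferred.

A homozygous deletion $(0,0)$ is additionally only permitted where the
segment is shorter than 50 Mb and the clone or a descendant is present in a
sample whose fractional copy number falls below $h = 1$ on both alleles —
this prevents small clones from absorbing long spurious deletions.

## The per-segment optimization

Each segment is solved independently. For a fixed event budget $\lambda$,
the solver finds integer copy numbers minimizing, lexicographically:

1. the number of samples in which the predicted mixture leaves the observed
   interval $[f^-, f^+]$ for either allele;
2. the Manhattan distance between predicted and observed estimates;
3. the total event count.

The third criterion is not an extra objective so much as the parsimony
assumption made operational: it pins down the many labellings that tie on
the first two (in particular, clones absent from every sample inherit their
parent's state), which makes the output deterministic without any post-hoc
canonicalization.

The optimization is carried out exactly by a depth-first branch-and-bound
over clone assignments in tree preorder. Two lower bounds prune the search:
an interval bound (each unassigned clone is confined to
$[\max(0, a - B), \min(c_{\max}, a + B)]$ around its nearest assigned
ancestor value $a$, with $B$ the remaining budget), and a displacement bound
(the all-inherit completion's deviation can be reduced by at most the
largest remaining subtree proportion mass per budget unit — one event moves
exactly one subtree). Candidate states are enumerated in order of increasing
event cost, so good incumbents appear early; each budget is warm-started
from the previous optimum, which also guarantees the reported objective
curve is monotone. Solves are exact; a wall-clock cap per solve (default
2 s) returns the best incumbent with a `timeout` flag, and the solve that
produces the reported profile is retried with a ten-fold longer cap if it
was truncated. The oracle-equivalence tests run the solver against
exhaustive enumeration with no recorded timeouts.

`cmax` defaults to an automatic per-segment rule,
$\min(40, \max(2, \lceil \max f^+ / \max(0.05, u_{\min}) \rceil))$ with
$u_{\min}$ the smallest positive clone proportion: a high amplification
carried by a small clone must be admissible, but the search must stay
bounded.

## Model selection over the event budget

The true number of events per segment is unknown, so the solver sweeps
$\lambda = 0, 1, 2, \dots$ (up to $4|E|$), stopping after three consecutive
budgets bring no meaningful improvement. The budget is then chosen by the
Kneedle elbow rule on the (budget, Manhattan-distance) curve, clamped to the
smallest budget achieving the minimal objective 1, with two refinements:

* **Exact-fit parsimony.** If some budget fits the data exactly, the
  smallest such budget is selected outright. This is what makes noise-free
  reconstructions exact.
* **Noise floor.** A selected budget is walked back while the last budget
  step improved the distance by less than a floor $\delta$. With interval
  half-width $w$ and mean allele level $\ell$ on the segment,
  $\delta = \tfrac{w}{2}\sqrt{\max(1, \ell)}$: half the stated measurement
  uncertainty, inflated for high copy numbers because read-count noise
  grows roughly as $\sqrt{f}$ while pipelines often report fixed-width
  intervals. The same floor defines "meaningful improvement" for the sweep's
  early stopping.

The noise-floor refinement is deliberately one-sided. We examined a
symmetric variant that also *extends* the budget while the next step buys at
least $\delta$; it recovered a few concealed events in ordinary tumours but
systematically corrupted genome-doubled ones, where many clones give the
exact solver enough freedom to harvest noise in $\ge\delta$ increments. The
asymmetry of errors decides the design: a missed sub-noise event leaves a
clone on its parent's (usually correct) state, while a spurious event
corrupts other clones' entries, so conservative selection is the better
default.

## The simulator

`simulate_tumour()` generates the study conditions end to end: a random
rooted clone tree; interval SCNA events placed per edge (Poisson counts,
mean 6 truncal and 2 per subclonal edge, each spanning a geometric-like run
of segments, gains with probability 0.55); an optional truncal whole-genome
doubling (probability 0.3); segment lengths log-normal around 5 Mb across up
to 22 chromosomes. The generated profiles satisfy LOH persistence, the
alternation bound and the homozygous-deletion length rule by construction —
an event that would violate them is skipped, mimicking evolution under the
model rather than rejection sampling.

Clone proportions are lineage-biased: each sample keeps a clone with
probability $1-\mathrm{sparsity}$ if its parent is present (half that
otherwise), the MRCA is always present, Dirichlet weights are scaled by a
per-sample purity drawn from $[0.4, 0.9]$, and every clone is forced to be
present in at least one sample — clone trees obtained from SNV clustering
only contain clones that were detected somewhere.

Observation noise follows a read-count model. With per-sample coverage
parameter $\gamma = 1000$ and $\rho$ the length-weighted all-cell ploidy,
total reads are $t \sim \mathrm{Pois}(f/\rho\cdot\gamma)$ and the observed
BAF is $\hat\beta = \mathrm{Binom}(\gamma, y/f)/\gamma$; the observed
fractional copy numbers are reconstructed as $\hat F = (t/\gamma)\rho$,
$\hat x = \hat F (1-\hat\beta)$, $\hat y = \hat F \hat\beta$. (A
`literal_scaling` flag reproduces the variant without the $1/\gamma$
normalization, which inflates estimates by the coverage and is retained for
compatibility only.) Interval bounds are the estimates
$\pm 1.96 \times 0.1$, floored at zero. Homozygously deleted segments
($f = 0$) receive a small Poisson floor (mean copy number 0.02) so that
observed values near zero still carry noise.

What the simulator does **not** emulate: GC and mappability bias,
segmentation error (segments are known and shared across samples),
SNP-phasing error in the BAF, correlated noise between samples, and
uncertainty in the tree and clone proportions themselves. Recovery rates on
these simulations therefore measure the deconvolution step in isolation,
not a full pipeline on real data.

## Scale of the built-in experiments

The packaged tests and the acceptance script run a cohort of 20 simulated
tumours with 5–15 clones, 3–9 samples and 100 segments each (roughly
40,000–45,000 clone- and allele-specific entries), chosen to mirror a
multi-region whole-exome study while keeping a complete run in the minutes
range on a single core. Oracle-equivalence checks use up to 4 tumour clones
and copy numbers up to 4, the largest instances for which exhaustive
enumeration is comfortable; identifiability in the noise-free recovery
tests is certified per segment by the enumeration oracle returning a unique
optimum.

## Numerical choices and degenerate inputs

* Objective-2 ties are resolved at $10^{-9}$; interval membership uses the
  same slack.
* "Nearest integer" operations round halves to even, everywhere.
* Objective 1 counts a sample once when either allele misses its interval;
  per-allele counting is available behind `per_allele_obj1`.
* Clones with zero proportion everywhere are driven to their parent's state
  by the parsimony tie-break.
* A constant model-selection curve yields $\hat\lambda = 0$; curves with no
  Kneedle knee fall back to the smallest budget within $10^{-6}$ of the
  minimal distance.
* Segments whose replicate tables are too small to test are flagged
  `untestable` and treated as clonal/balanced by the preprocessing rules;
  allele rebalancing skips (and logs) rows where one allele sits above and
  the other below its nearest integer, a case the reassignment rule leaves
  undefined.
* `detect_wgd` excludes segments with parent total copy number 0 from the
  weighted ratio (LOH persistence forces the child to 0 there too, and 0/0
  is undefined); the MRCA is compared against the diploid root and has no
  grandparent, so only the direct rule applies to it.

## Known limitations

* Errors concentrate in clones with small proportions in all samples; their
  entries are only weakly identified and the conservative model selection
  leaves them on ancestral states. This matches the intended failure mode.
* Parsimony can invert genome-doubling histories per segment: the true
  "gain on the MRCA, loss in a subclone" (three events including the other
  allele's doubling step) and the inverted "no MRCA gain, gain in the
  complementary subclade" (two events) predict mixtures that differ only by
  the subclade's proportion mass, so when that difference is within noise
  the cheaper inverted labelling wins. Alleles are modelled independently
  per segment, so the doubling evident on one allele cannot constrain the
  other.
* Tumours combining whole-genome doubling with many clones and few samples
  are the hardest regime: deep budgets with wide copy-number ranges both
  slow the exact search and offer the most room to fit noise.
* The per-segment independence assumption means no information is shared
  across breakpoints; the SCNA counting utilities partially reconstruct
  multi-segment events after the fact, but the solver itself does not.
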