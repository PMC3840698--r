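---
title: "Methods: lineage rates and branch-site selection tests in grasses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage rates and branch-site selection tests in grasses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Pooideae grasses (wheat, barley, ryegrass, fescue, *Brachypodium*) are the
major temperate grass lineage, while their relatives rice, maize and
sorghum retain the family's ancestral warm-climate niche. If adaptation to
cold habitats drove molecular adaptation early in Pooideae history, genes
induced by low temperature (LTI genes) should show stronger signatures of
positive selection on the ancestral Pooideae branches than the genome-wide
background. `grasselect` implements the full comparative machinery needed
to test this on a fixed eight-taxon species tree: ortholog-set hygiene and
quality control, lineage substitution rates against the PACMAD outgroups,
branch-site likelihood-ratio tests on two ancestral branches, and
subset-versus-background resampling tests — together with a codon
simulator that generates study-like data with known ground truth, since
the package's statistical behaviour is validated entirely on synthetic
data.

The two candidate branches are named throughout:

* `BP_ancestral` — the stem of Pooideae after the split from rice, before
  the *Brachypodium* divergence;
* `CP_stem` — the stem of the core Pooideae (wheat, barley, *Lolium*,
  *Festuca*) after the *Brachypodium* divergence.

## Models

### Nucleotide level

Gene trees are estimated under GTR+Γ: neighbour-joining on pairwise
maximum-likelihood GTR distances gives the topology, then all branch
lengths, the five free exchangeabilities and the gamma shape (four
discrete, mean-one categories, median discretisation) are optimised
jointly by bounded quasi-Newton maximisation of the Felsenstein-pruning
log-likelihood. Base frequencies are fixed at their empirical values.
Gaps and ambiguous symbols are missing data (partial likelihood one over
all states). Because every retained gene tree must match the known
species topology anyway, no heuristic topology search is performed beyond
neighbour-joining; the congruence filter discards the rest. "GTR+Γ"
without an invariant-sites component is used throughout.

Lineage rates are cophenetic (path-length) distances from each species
tip to the outgroup tips, averaged when both outgroups are present.

### Codon level

The codon model is GY94-style over the 61 sense codons of the universal
code: a single-position change has rate proportional to the target codon
frequency times 1, κ, ω or κω according to whether it is a synonymous
transversion, synonymous transition, nonsynonymous transversion or
nonsynonymous transition; rates into stop codons are zero. Codon
frequencies are F3×4, computed from each gene's alignment.

For a single-ω process the rate matrix is scaled to one expected
substitution per codon at stationarity. The pairwise dN/dS estimator
maximises the two-sequence likelihood over (t, κ, ω) and decomposes the
distance with the flux identity
`dS = t·ρS/(3·fS)`, `dN = t·(1−ρS)/(3·(1−fS))`, where ρS is the
synonymous fraction of substitution flux under the fitted process and fS
the same fraction at ω = 1 (the "synonymous site" fraction); the identity
dN/dS = ω̂ then holds exactly and is asserted in the tests.

**Mixture scaling.** For site-class mixtures (the simulator, the mixture
likelihood, and the branch-site fits) all class matrices share a single
flux scale — the stationary flux of the background mixture — instead of
each class being normalised separately. This is the convention of the
standard codon-model tools: a branch length t means t expected
substitutions per codon under the background process, and a positively
selected class genuinely substitutes faster on the foreground branch.
Normalising each class separately would reduce positive selection to a
pure composition shift with no rate elevation, which both misrepresents
the biology and empirically destroys the power of the likelihood-ratio
test.

### The branch-site test

The branch-site model (Model A) has four site classes: purifying (ω0 on
all branches), neutral (1 everywhere), and two selected classes that use
ω2 ≥ 1 on the designated foreground branch only (ω0 or 1 elsewhere).
Class proportions are constrained to
(p0, p1, p2a, p2b) with p2a = (1−p0−p1)·p0/(p0+p1) and
p2b = (1−p0−p1)·p1/(p0+p1). The null model fixes ω2 = 1; the test is the
χ²₁ upper tail of 2ΔlnL, clamped at zero, with Benjamini–Hochberg FDR
across genes (per foreground branch).

Numerical strategy, in order of the leverage each choice has:

* **Profiled weights.** The class proportions factorise as
  (q·r, (1−q)·r, q·(1−r), (1−q)·(1−r)) with q = p0/(p0+p1), r = p0+p1,
  so for fixed (ω0, ω2, κ) the weights are a smooth two-parameter inner
  problem over fixed class-conditional site likelihoods; profiling them
  out reduces the expensive outer optimisation to two or three
  dimensions.
* **Branch lengths.** A preliminary one-ratio codon fit estimates a
  single scale factor on the nucleotide gene tree's branch proportions
  (×3 for codon units); those lengths are then held fixed for both
  hypotheses — except the foreground branch, whose length is re-optimised
  under each hypothesis through one multiplier parameter. Keeping it
  fully fixed lets a substitution burst on the foreground branch be
  absorbed into the shared estimate, and planted-selection genes came out
  with likelihood ratios near zero; freeing this one length restores the
  expected power while preserving the nesting of the null inside the
  alternative.
* **Multi-start ω2.** The alternative is run from starting values 0.5, 1,
  1.5 and 2 (values below the ω2 ≥ 1 bound are projected just above 1)
  and the best likelihood kept, so the reported optimum dominates every
  single start. κ is maximised in the null and carried into the
  alternative starts (ω2 and κ are near-orthogonal); when the ratio is
  non-trivial the null is re-polished from the alternative's parameters,
  which removes spurious ratios caused by asymmetric optimiser stopping.
* **Pruning kernels.** All pruning is compiled (RcppArmadillo) with
  per-node scaling against underflow; the Model A classes share work
  (classes 0/2a and 1/2b differ only on the foreground edge, handled by
  an above/below decomposition at that edge), and the fast path is
  asserted equal to the plain per-class path and to brute-force
  enumeration in the tests.

Selected sites are reported by **naive empirical Bayes**: the per-site
posterior of the selected classes evaluated at the alternative MLE, with
the conventional 0.9 cutoff. Full Bayes empirical Bayes (averaging over
parameter uncertainty) is out of scope; NEB keeps the same decision
surface and the output metadata says so. NEB posteriors are conservative
detectors: a selected site with no realized foreground substitution
cannot be recovered, and sites whose background evidence is weak plateau
below high cutoffs, so site lists should be read as high-confidence
subsets, not inventories.

## Resampling tests

Subset-versus-background comparisons draw `n_resamples` subsets of the
LTI-subset size uniformly without replacement from the full gene pool
(subset included) and report the one-sided proportion of resamples whose
statistic is equal to or more extreme than the observed one — plain
proportion, no +1 correction (a `plus_one` flag exposes the corrected
variant). Statistics: median (rate differences), third quartile
(likelihood ratios), and proportion significant (enrichment).
Significance calls for enrichment are made once over all genes (global
FDR) and inherited by the resampled subsets; recomputing FDR inside each
resample is available as an option but makes the null depend on
subset-specific rank structure, so it is not the default.

## The synthetic-data generator

The generator is the package's study-conditions definition, not a
convenience fixture. Defaults:

* **Topology and branch lengths** — the eight-taxon grass tree; lengths
  (substitutions per codon) chosen once so tip-to-outgroup distances fall
  around 0.2–0.26 nucleotide substitutions per site, the range of
  published median grass divergences. No empirical branch lengths exist
  for this exact setting; these are the package's own defaults and are
  configurable.
* **LTI fraction 0.09** — mirroring a 388-of-4330 labelled subset.
* **400 codons per gene** (~1200 bp), matching reported mean alignment
  lengths; configurable as a scalar or range.
* **Site classes** p0 = 0.6, p1 = 0.25 (so ~15% of sites selected in LTI
  genes), ω0 = 0.1, ω2 = 8 on the foreground branch of LTI genes
  (published foreground estimates for such genes exceed 7); background
  genes have ω2 = 1. Classes are drawn i.i.d. per codon.
* **κ = 2.5** and mildly GC3-rich F3×4 base frequencies, typical of grass
  coding sequence.
* **Dropout** per species set from the relative per-species coverage of
  the 4330-tree collection (e.g. *Festuca* missing most often); the
  anchor *B. distachyon* and rice never drop out.
* **Contaminants** — with probability 0.02 one non-anchor taxon is
  replaced by a sequence independently re-evolved from the same ancestral
  node along a branch 3.5× the longest branch of the tree, which
  guarantees the long-branch rule can fire on it. (Scaling relative to
  the taxon's own terminal branch turned out not to trip a 3× rule when
  that terminal branch is short — the replacement is still orthologous
  enough to pass RBH, exactly the failure mode the QC exists for.)

What the generator does *not* emulate: alignment error and trimming
(alignments are exact, no indels), assembly/ORF-prediction noise,
among-site nucleotide rate variation beyond the selection classes, gene
family turnover, and expression-based LTI mislabelling. Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions — they do not certify robustness to misalignment or
annotation error in real data.

Substitutions are realized by a per-site jump chain (Gillespie) along
each branch, so the ground truth contains exact per-branch synonymous and
nonsynonymous counts; the tests compare those against closed-form flux
expectations derived independently from the rate matrix.

## Degenerate inputs and tie-breaks

* RBH ties are broken by lexicographic gene id; output is invariant to
  score-table row order. Self-hits are not scored. The minimum
  taxon-composition rule is re-checked after any QC taxon drop.
* The long-branch rule uses strict `>` at factor 3 (a ratio of exactly 3
  is kept); external offenders drop the taxon and re-enter the tree loop
  (capped at 5 iterations), internal offenders discard the tree.
* Outlier rates are removed on strict `>` bounds (dS > 2, dN > 0.5).
* A pairwise fit hitting the divergence upper bound is flagged
  `saturated` and survives to the outlier filter, which removes it.
* Genes whose foreground branch is unidentifiable after taxon loss
  (no *Brachypodium*, or fewer than two core Pooideae for `CP_stem`) are
  skipped for that branch with a logged reason.
* Zero-length alignments, ω0 > 1, and probabilities outside [0, 1] are
  rejected at configuration time.

## Problem sizes used in the shipped tests

The validation suite runs on a single CPU, so the statistical checks use
deliberately chosen sizes: likelihood-oracle comparisons use 3–4 taxa and
5–10 sites (small enough for exact enumeration); the Jukes–Cantor
closed-form check uses 50 000 sites; null calibration of the branch-site
LRT uses 200 genes of 150 codons; the end-to-end recovery experiment runs
five replicate pipelines of 64 genes × 400 codons with 9% LTI genes and
ω2 = 8 on `BP_ancestral` (15% of sites), with 2000 resamples per test;
NEB site recovery uses eight replicates in a strong-signal regime (long
foreground branch, ω2 = 20). These sizes are the package's choices for a
desk-scale validation; all of them grow gracefully if more compute is
available, and the acceptance script accepts any seed.

## Known limitations

* NEB instead of BEB for site identification (see above).
* The branch-site fit fixes non-foreground branch lengths at the
  preliminary estimate; only the foreground length is re-optimised per
  hypothesis. With very short genes this can leave residual
  branch-length misfit that the mixture weights partially absorb.
* ω̂2 is noisily estimated and upward-biased when the selected-class
  weight is small — standard for Model A; the LRT and the site posteriors
  are the reliable outputs, the ω2 point estimate is descriptive.
* The RBH scorer is protein identity, adequate for the synthetic data's
  divergence range; it is not a substitute similarity search for real
  proteomes.
* P-values from resampling have resolution 1/n_resamples and can be
  exactly zero under the plain-proportion definition.
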