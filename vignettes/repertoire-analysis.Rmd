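---
title: "Methods: clonotype-level repertoire comparison across selection conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype-level repertoire comparison across selection conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalholes)
```

## The problem

A perturbation of thymic positive selection — here modelled as a two-genotype
comparison between a control and a mutant condition — can remove specific
TCRα clonotypes from the mature CD4⁺ repertoire and admit others that are
normally absent. `clonalholes` quantifies this at the clonotype level from
bulk UMI-annotated rearrangement data (replicated per condition) and from
paired single-cell clonotype tables. The analysis is deliberately
set-theoretic: the question is not *how much* a clone's abundance shifts but
*whether* a reproducibly detected clone is present at all under each
condition.

## Data model and aggregation

One UMI corresponds to one cDNA molecule, and clonotype abundance is the
number of UMIs; raw read multiplicity never enters any statistic. A bulk
clonotype is the exact triple (V gene, J gene, CDR3 amino-acid sequence)
after normalising gene names (upper case, allele suffixes stripped). Gene
calls that hit several paralogs are kept in the abundance table under their
sorted comma-joined call string — presence/absence classification is
unaffected by the ambiguity — but are excluded from gene-position and
junction analyses, where the identity of the single germline segment
matters.

UMI collapse is by exact `(sample, umi)` string match. When reads within one
UMI group disagree on the clonotype, the majority wins and an exact tie goes
to the lexicographically smallest (V, J, CDR3) tuple; the conflict rate is
reported so a user can see when this rule is doing real work. Error-tolerant
UMI clustering is intentionally out of scope: it belongs upstream, in the
read processor that produced the annotated reads.

Paired single-cell clonotypes are defined at the amino-acid level of both
chains and retained only when both chains are in frame. Within a mouse a
clonotype is counted once, so all multiplicities downstream are counts of
mice, not cells — publicness is a property of individuals, not of sorting
depth.

## Diversity, rarefaction and coverage

Diversity uses Hill numbers with molecules as individuals and clonotypes as
species; the default order `q = 1` (Shannon diversity, the exponential of
Shannon entropy) weights clones by abundance without being dominated by
either singletons (`q = 0`) or the largest clones (`q = 2`). `0·log 0 := 0`.

Rarefaction is by simulation: `reps` (default 100) subsamples of exactly `m`
molecules drawn without replacement (multivariate hypergeometric), returning
the mean and Monte-Carlo standard error. The tests verify this estimator
against an exhaustive-enumeration oracle that averages the diversity of all
C(n, m) subsamples for every abundance shape up to n = 12 — the oracle works
on explicit individual labels and shares no code with the sampler.
Extrapolation beyond the observed depth and asymptotic richness estimators
are omitted by design: the workflow is built for deeply sequenced samples
whose Good–Turing coverage

$$\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2}$$

is close to 1, and in that regime observed diversities are used directly,
normalised per study by the mean of a reference (control) sample set
(`relative_diversity()`). With singletons but no doubletons the coverage
formula degrades continuously to `1 − f₁/n`; with no singletons it is 1.
Bootstrap confidence bands around rarefaction curves are not drawn; the
Monte-Carlo SE per grid point is reported instead.

## Repertoire overlap

Pairwise similarity is the abundance-weighted Morisita–Horn index on the
union clonotype set. It is scale invariant in each argument, equals 1 only
for proportionally identical repertoires, and is 0 for disjoint ones. The
module reports the full matrix plus the within-group and between-group value
lists (a 3+3 design yields 3/3/9 pairs, a 4+4 design 6/6/16); significance
testing on those lists is left to the caller's favourite test, since the
interesting output here is the effect structure, not a p-value.

## Classification

Presence means at least `min_umi` molecules (default 1) in a sample; the
threshold is configurable because no abundance floor is intrinsic to the
definition. A clonotype is **recurrent** when present in at least
`min_samples` (default 3) of all samples regardless of condition — with
three replicates per condition this requires detection beyond a single
replicate set. Recurrent clonotypes partition into **dependent** (present in
≥ 1 condition-A sample, absent from every condition-B sample), **newcomer**
(the mirror image) and **shared** (present in both). "Present in a
condition" is detection in at least one sample of that condition; this
reading is forced by the requirement that the within-condition recurrent
inventories satisfy |A| + |B| − |shared| = |recurrent|, which the test suite
asserts on every input.

The natural-CD5 classifier applies the same logic to samples sorted from the
two extremes of the CD5 spectrum: membership in one extreme requires
detection in ≥ 3 of its 4 samples and absence from all 4 of the other, so
the two classes are disjoint by construction and everything else is
unassigned. `cross_assign()` projects any clonotype set onto a dependence
inventory by exact key match and reports class fractions over **both**
denominators — matched clones and all query clones — because when part of a
query set is absent from the inventory the choice of denominator is a
genuine analytical decision, and reporting both keeps it explicit.

`top_expanded()` ranks clones of an expanded (e.g. antigen-specific,
post-immunisation) repertoire by the mean of per-sample relative
frequencies, treating each replicate mouse equally; pooled ranking, which
weights mice by sequencing depth, is available behind `pooled = TRUE`. Ties
at the cut break to the lexicographically smallest key so results are
reproducible.

## Junction and positional features

The junction edit count is the sum of four nonnegative annotation fields: V
deletions, J deletions, P additions, N additions. A missing field is an
error, not a zero — silent zero-filling would bias group comparisons
downward. The positional index of a V or J segment defaults to the primary
number parsed from its IMGT-style name; a user-supplied order map (gene →
index) overrides the parse and is the right tool when true chromosomal
coordinates are available. Which end of the locus counts as "distal" is a
convention carried by the map; with the default parse, larger indices are
read as farther from the recombination-proximal end.

Group comparisons use a permutation test on the difference of means rather
than a named parametric test: the distributions are discrete, skewed and of
unequal size, and permutation needs none of the corresponding assumptions.
The null is built by label permutation on the sorted pooled values, always
resampling the smaller group, which makes the two-sided p-value (with +1
smoothing) exactly invariant under a group swap; the test suite checks this
exchangeability along with seeded determinism.

## The synthetic generator

`simulate_study()` draws a clonotype pool whose availability labels (shared
/ dependent / newcomer) partition it, then samples every replicate as a
multinomial draw of `reads` molecules from its condition's
availability-restricted abundance vector. Defaults encode the study design
the classifiers target: 3+3 bulk replicates, 4+4 CD5-sorted replicates, a
1,000-clonotype pool with 500 dependent and 100 newcomer clones, and 50,000
molecules per sample. Remaining choices, fixed once on field judgement:

* **Clone sizes** are log-normal (sdlog 1.5) on the relative-abundance
  scale — heavy-tailed, matching the qualitative skew of real repertoires; no
  abundance model is being inferred, the generator is a stand-in.
* **CD5 class** is a latent Bernoulli(0.5) property fixed per clonotype and
  never redrawn per sample, encoding the assumption that CD5 partitioning is
  specified by TCR identity rather than stochastic; CD5-sorted samples draw
  only from condition-A clonotypes of the matching class.
* **Junction edits** are Poisson with mean 4, split evenly over the four
  annotation fields, with newcomers shifted by +2; **positional indices**
  are 1 + Poisson(7) with newcomers shifted by +2. These place planted
  effects at realistic magnitudes for the permutation tests to recover.
* **Paralog ambiguity** marks 25% of clonotypes, in the range reported for
  the duplicated region of the mouse *Tcra* locus.
* All randomness flows from one master seed through named per-sample
  substreams, so adding or reordering samples never changes another sample's
  draw, and the same seed is bit-reproducible.

`emit_airr()` expands a table back to one annotated read per molecule
(optionally with duplicate-UMI reads), closing the loop: aggregating the
emitted file reproduces the table exactly. `simulate_paired()` plants an
exact number of public paired clonotypes in at least one mouse of each
genotype while private clones never cross genotypes, so `public_paired()`
must recover exactly the planted set.

What the generator does **not** emulate: sequence-level realism (no germline
reference, no realistic CDR3 composition), PCR/sequencing error, UMI
collisions between distinct molecules (a duplicate-read knob exercises the
collapse path instead), inter-mouse biological variance beyond multinomial
sampling, and any correlation between clone size and dependence class.
Passing tests therefore demonstrate correctness of the estimators and
classifiers under the stated sampling model, not robustness to upstream
annotation error.

## Numerical choices and problem sizes

The Hill computation drops zero counts before forming proportions and
branches to the entropy limit only at `q = 1` exactly; continuity at the
branch is tested. Degenerate inputs fail loudly: empty abundance vectors,
zero-total samples, empty clonotype subsets, `m` outside `(0, n]` and empty
permutation groups are all errors rather than NaNs. JSON summaries from
`run_pipeline()` serialise numbers at 12 significant digits so a rerun with
the same config and seed is bit-identical.

Test and verification problem sizes are chosen to exercise every code path
well inside a minute per file: the enumeration oracle runs on all abundance
shapes with n ≤ 9 plus n = 12 cases at 2,000 Monte-Carlo replicates; the
partition identity is checked on 1,000 randomly configured small studies;
parameter recovery uses the full default design (1,000-clone pool, 50,000
molecules/sample) over 10 seeds plus a depth grid of 1k/5k/25k/50k
molecules; junction recovery uses 500 clones per group.

## Known limitations

Clonotype matching is exact-key only — no clustering of near-identical CDR3s
— so sequencing errors surviving upstream QC inflate singleton counts.
Dependence classification is presence-based and inherits the detection limit
of the assay: a "dependent" call means undetected under condition B at the
achieved depth, which is why the false-dependent-rate-versus-depth curve is
part of the acceptance checks. The CD5 cross-assignment denominators differ
when query clones are missing from the inventory; both are reported, and
downstream interpretation should say which one it uses.
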