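# clonalholes

Clonotype-level analysis of TCRα repertoire selection.

When thymic positive selection is perturbed — for example by removing a
protease that shapes the peptide–MHC-II ligandome of cortical thymic
epithelial cells — some T cell receptor clonotypes disappear from the mature
CD4⁺ repertoire ("clonal holes") while others appear only under the
perturbation ("newcomers"). `clonalholes` is an R package for quantifying
these effects from UMI-annotated TCRα rearrangement data: it aggregates
annotated reads into clonotype abundance tables, measures diversity and
sampling saturation, compares repertoires between replicates and conditions,
classifies clonotypes by their detection pattern across conditions, and
characterises the V–J junctions and gene positions of the clones that change.
A seeded synthetic generator with planted ground truth makes every stage
testable end to end.

## The statistics at the core

* **Clonotype** (bulk): the unique combination of a *Trav* gene, a *Traj*
  gene and an in-frame CDR3 amino-acid sequence; abundance is the number of
  clonotype-encoding unique cDNA molecules (UMIs). Paired single-cell
  clonotypes additionally carry the β chain and are counted once per mouse.
* **Hill diversity of order q**: with clonotype proportions *pᵢ*,
  ᵠD = (Σᵢ pᵢᵠ)^{1/(1−q)}, the effective number of equally abundant
  clonotypes; q = 1 (the limit exp(−Σ pᵢ log pᵢ), Shannon diversity) is the
  default, q = 0 is richness, q = 2 inverse Simpson. Depth saturation is
  assessed by Monte-Carlo rarefaction (subsampling m molecules without
  replacement) and Good–Turing sample coverage
  Ĉ = 1 − (f₁/n)·(n−1)f₁/((n−1)f₁ + 2f₂).
* **Morisita–Horn similarity**: C = 2Σpᵢqᵢ / (Σpᵢ² + Σqᵢ²) between two
  repertoires on their union clonotype set; 0 = disjoint, 1 = proportionally
  identical.
* **Dependence classification**: a clonotype detected in ≥ 3 of all samples
  is *recurrent*; a recurrent clonotype detected only in condition-A samples
  is *dependent*, only in condition-B samples a *newcomer*, otherwise
  *shared*. The partition satisfies |A| + |B| − |shared| = |recurrent|.
  Natural CD5-extreme clonotypes are defined analogously on 4+4 CD5-sorted
  samples (≥ 3 of 4 in one extreme, 0 in the other).
* **Junction features**: the V–J edit count is the sum of germline V and J
  deletions plus P and N additions; group differences in edit counts and in
  V/J positional (distality) indices are tested by label permutation.

## Worked example

```r
library(clonalholes)

study <- simulate_study(sim_config(include_cd5 = TRUE), seed = 1)
study$table
#> abundance_table: 995 clonotypes x 6 samples (300000 molecules)
#>   groups: ctrl=3, mut=3

rec <- recurrent_clonotypes(study$table, min_samples = 3)
dep <- classify_dependence(study$table, rec, "ctrl", "mut")
dep
#> dependence_labels: 958 recurrent = 465 dependent + 397 shared + 96 newcomer

diversity_summary(study$table)$summary
#>   sample_id     n S_obs D_obs coverage
#> 1    ctrl_1 50000   872 327.8   0.9995
#> 2    ctrl_2 50000   873 329.8   0.9994
#> 3    ctrl_3 50000   872 330.1   0.9995
#> 4     mut_1 50000   493 187.3   0.9998
#> 5     mut_2 50000   496 185.5   0.9999
#> 6     mut_3 50000   494 184.6   0.9997

pairwise_overlap(study$table)
#> overlap_matrix: 6 samples, 15 pairs
#>   mean between = 0.6666
#>   mean within:ctrl = 0.9964
#>   mean within:mut = 0.9981
```

The generator planted 500 dependent and 100 newcomer clonotypes in a
1,000-clonotype pool; at 50,000 molecules per sample the classifier recovers
465 and 96 of them among 958 recurrent clonotypes, coverage is effectively 1
(sampling is saturated), the condition-B repertoire has roughly half the
effective number of clonotypes of the control, and replicates within a
genotype are far more similar (Morisita–Horn ≈ 0.997) than samples across
genotypes (≈ 0.667).

For real data, start from `read_rearrangements()` on an AIRR-style
rearrangement TSV and `aggregate_bulk()`, or drive everything from a YAML
config with `run_pipeline()` / the CLI wrapper in `inst/cli/clonalholes.R`:

```sh
Rscript inst/cli/clonalholes.R run --config config.yaml --out out/
```

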