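# amylocnv

Coverage-based copy-number genotyping of the human amylase locus
(*AMY1*, *AMY2A*, *AMY2B*) and the statistical machinery to relate those
copy numbers to adiposity in family-structured cohorts.

The amylase cluster is one of the most copy-number variable regions of
the human genome — diploid *AMY1* counts run from 2 to over 20 — and its
near-identical ~20-kb repeat units defeat breakpoint-based callers.
`amylocnv` implements the read-depth approach used in population studies
of the locus, end to end:

- **Counting** (`count_reads`, `locus_counts`, `alignability_report`):
  per-interval read counts from indexed BAMs with per-locus MAPQ
  policies, plus alignability QC (properly-paired unique-mapping
  fractions, Phred error bounds).
- **Calling** (`raw_cn`, `conditional_round`, `call_genotypes`,
  `filter_for_association`): density-ratio copy numbers
  `CN = 2 · (target reads / L_unit) / (reference reads / L_ref)`
  against a copy-invariant diploid reference region, then
  **parity-conditional rounding** — *AMY2A* is rounded half-up and
  *AMY1* is rounded to the nearest integer of matching even/odd parity,
  exploiting the loci's shared structural haplotypes.
- **ddPCR validation** (`ddpcr_cn`, `average_replicates`,
  `reconcile_amy1`, `concordance`): droplet-count estimators with
  optional Poisson occupancy correction `λ = −log(1 − k/N)`, two-probe
  *AMY1* reconciliation against the *AMY2A* parity, and WGS–ddPCR
  concordance summaries.
- **Association** (`preprocess_trait`, `threshold_kinship`, `lmm_fit`,
  `heritability`, `associate_cn`, `logistic_fit`, `polychoric`):
  3-SD outlier removal and rank inverse-normal transforms, then the
  variance-component mixed model `y = Xβ + g + ε`,
  `Var(g) = 2Φσ²g`, fitted by eigendecomposition REML with kinship
  thresholded at 0.05; heritability `h² = σ²g/(σ²g+σ²e)`; logistic
  models for obesity/dietary restraint; polychoric correlation for the
  ordinal CN distributions.
- **Ancestry** (`variant_qc`, `ld_prune`, `pca_genotypes`,
  `assign_ancestry`, `sliding_windows`, `windowed_association`):
  variant QC (MAF > 0.01, call rate > 0.9, HWE exact p > 1e-6), greedy
  50-kb LD pruning at r² 0.05, PCA, nearest-centroid ancestry calls with
  an admixture margin, and 750-individual sliding windows along PC1
  (step 85) for stratified association.
- **Simulation** (`sim_config`, `simulate_cohort`, `simulate_cn`,
  `simulate_counts`, `simulate_phenotypes`, `simulate_ddpcr`,
  `simulate_genotype_matrix`, `simulate_bam_fixture`): seeded,
  replayable generators for every input the pipeline takes — pedigreed
  cohorts with expected kinship, ancestry-specific haplotype tables,
  Poisson coverage at 30×, droplet counts, drifted genotype matrices,
  and miniature indexed BAM fixtures.

Individual-level amylase cohort data are access-controlled, so the
package's statistical validation is built entirely on parameter-recovery
experiments against its own simulator truth.

## Worked example

Simulate a 1,000-sample family cohort at 30× depth, genotype it from the
simulated coverage, and test the CN–trait association with the kinship
mixed model:

```r
library(amylocnv)

cfg     <- sim_config(seed = 7, n_samples = 1000)
cohort  <- simulate_cohort(cfg)
truth   <- simulate_cn(cfg, cohort)
regions <- amylase_regions()          # GRCh37 locus definitions (YAML)

counts <- rbind(
  simulate_counts(truth$amy1,  regions$AMY1,  depth = cfg$depth,
                  sample_ids = truth$sample_id, seed = 8),
  simulate_counts(truth$amy2a, regions$AMY2A, depth = cfg$depth,
                  sample_ids = truth$sample_id, seed = 9))

calls <- call_genotypes(counts)
head(calls[, c("sample_id", "raw_amy1", "raw_amy2a", "amy1", "amy2a")], 3)
#>   sample_id raw_amy1 raw_amy2a amy1 amy2a
#> 1  F0001_I1 4.012718 2.0050887    4     2
#> 2  F0001_I2 5.009822 0.9677736    5     1
#> 3  F0001_I3 6.171731 1.9883915    6     2
```

The continuous estimates sit tight around integers and the
parity-conditional calls match the simulated truth for all 1,000 samples
at this depth.  Association against the simulated adiposity trait:

```r
geno  <- filter_for_association(
  data.frame(sample_id = truth$sample_id, amy1 = truth$amy1,
             amy2a = truth$amy2a))
pheno <- simulate_phenotypes(cohort, truth, cfg)

associate_cn(geno, pheno, as.matrix(cohort$kinship),
             traits = "trait", covars = c("sex", "age"))
#>   predictor trait   n     beta     se     p   method
#> 1      amy1 trait 997 -0.00502 0.0131 0.701 lmm_reml
#> 2     amy2a trait 997  0.01799 0.0581 0.757 lmm_reml
```

Each row is one predictor–trait test: `beta` is the effect per copy in
SD units of the inverse-normalised trait, with its Wald SE and p-value.
The simulated per-copy effect is −0.02, well inside this single
cohort's sampling error (SE 0.013 at n ≈ 1000); demonstrating unbiased
recovery takes the replicated experiment in the acceptance script.
The heritability of the same trait, from the predictor-free REML fit:

```r
heritability(preprocess_trait(pheno$trait), cbind(pheno$sex, pheno$age),
             K = threshold_kinship(as.matrix(cohort$kinship)))
#>   trait sigma2_g sigma2_e    h2
#> 1 trait    0.268    0.708 0.274
```

consistent with the generator's `h2 = 0.3`.

A thin CLI over the same functions ships in `inst/cli/amylocnv.R`
(`count`, `qc`, `call`, `validate`, `associate`, `simulate`).

## Layout

```
R/                      counting, calling, ddPCR, association, ancestry,
                        simulation modules
inst/extdata/           GRCh37 amylase region config (YAML);
                        synthetic haplotype tables (TSV)
inst/cli/amylocnv.R     command-line wrapper
tests/testthat/         unit, property and acceptance tests
scripts/acceptance.R    reproduction script (JSON output)
vignettes/              methods vignette
```
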