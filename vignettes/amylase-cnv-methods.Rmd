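---
title: "Methods: coverage-based amylase CN genotyping and kinship-aware association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based amylase CN genotyping and kinship-aware association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylocnv)
```

# The problem

The human amylase cluster on chromosome 1 carries the salivary gene *AMY1*
and the pancreatic genes *AMY2A*/*AMY2B* inside a tandem repeat structure
that is among the most copy-number variable regions of the genome: diploid
*AMY1* counts commonly range from 2 to over 20.  Because the repeat units are
nearly identical, short-read callers cannot genotype the locus by
breakpoints; the practical approach is read *depth*: count reads over the
repeat units, compare with a nearby copy-invariant region, and convert the
density ratio into a discrete copy number.  `amylocnv` implements this
pipeline — counting, calling, ddPCR validation — together with the
downstream statistical layer used to relate amylase CN to adiposity in a
consanguineous cohort: rank-normalised traits, a kinship variance-component
mixed model, heritability, ancestry stratification by PCA and
sliding-window analyses along PC1.

The individual-level data this kind of study uses are access-controlled, so
every statistical claim in this package is exercised on synthetic data.
The simulation module is first-class, tested code: its generators encode
the study conditions (depth, cohort structure, effect sizes) and every
acceptance check is a parameter-*recovery* experiment against simulator
truth, not a reproduction of the original cohort estimates.

# Copy-number model

For a locus with target intervals of combined content equivalent to
repeat units of length $L_u$, and a diploid reference region of length
$L_r$, the estimate is

$$\widehat{CN} = 2 \cdot
  \frac{\text{target reads} / L_u}{\text{reference reads} / L_r}.$$

**Unit-length normalisation.** *AMY1* is counted over three near-identical
~20-kb units (~60 kb in total) but normalised by the length of *one* unit
(20 kb).  A genome with true diploid copy number $C$ scatters reads from
all $C$ copies across the three reference-genome units, so the summed
count has expectation $C \cdot d \cdot L_u$ for per-haploid-copy read
density $d$; dividing by a single unit length (and by the diploid
reference density $2d$) makes the estimator's expectation exactly $C$.
Normalising by the full 60-kb span would compress the estimates three-fold
and could not reproduce the observed 2–22 range — this is the only scaling
consistent with a density-ratio estimator at this locus, and the constant
is exposed in the region configuration for sensitivity analysis.

**MAPQ policy.** The repeat structure depresses mapping quality inside
*AMY1*, so *AMY1* counting applies no MAPQ filter; *AMY2A*/*AMY2B* use
MAPQ ≥ 20 (error probability at most $10^{-20/10} = 0.01$).  These
policies are data (the YAML region config), not code.

**Flag policy.** The default counts every primary mapped record
(duplicates included), matching plain `samtools view -c` behaviour; a
stricter duplicate-excluding preset is available.  A record counts for an
interval if its aligned span overlaps it by at least one base.

**Coordinates.** Internally everything is 0-based half-open.  Region
strings (`"chr1:104190000-104210000"`) are ingested as 1-based inclusive;
BED is read natively.  One internal convention removes off-by-one drift
between the two input styles.

# Parity-conditional rounding

*AMY1* and *AMY2A* lie on shared structural haplotypes, so their diploid
copy numbers share even/odd parity.  The caller exploits this: *AMY2A*
(and *AMY2B*) are rounded half-up; *AMY1* is rounded to the nearest
integer of matching parity.  This halves the worst-case rounding error
that matters (a parity-violating ±1 miscall) at the cost of at most one
copy of absolute rounding distance ($|\hat{a}_1 - a_1^{raw}| \le 1$,
$|\hat{a}_{2A} - a_{2A}^{raw}| \le 0.5$, both property-tested).  When the
raw *AMY1* value is exactly equidistant between the two admissible
integers, the larger is taken — a deterministic, documented tie rule for
a case the estimator hits with probability zero.

At 30× coverage the Poisson counting error of the density ratio has SD
well below 0.2 copies across the observed CN range, so integer calls are
essentially always exact; the suite asserts ≥ 99% accuracy on 1,000
simulated samples and observes ~100%.

Association preprocessing removes *AMY1* = 0 samples and winsorises rare
calls above 14 copies to 14.  *AMY2A* is not capped: the stated filtering
rule concerns *AMY1* only, and the *AMY2A* zero-copy class is a genuine
genotype; a cap can be applied through the same function if wanted.
*AMY2B* is genotyped but excluded from association by default — its calls
agree with *AMY2A* in ~90% of samples and, when discordant, it is almost
always *AMY2B* that sits at the invariant 2 copies, so it carries little
independent signal.

# ddPCR validation

With ~20,000 droplets per reaction, the plain estimator is
`control_copies × FAM⁺/HEX⁺` (reference ploidy 2).  The positive-droplet
ratio understates high occupancies, so an optional Poisson correction
converts counts to mean molecules per droplet,
$\lambda = -\log(1 - k/N)$, before taking the ratio.  The plain form is
the default to mirror standard QuantaSoft practice; the corrected form is
recommended (it is unbiased to within ±0.02 copies at $\lambda = 0.5$ in
the acceptance check) and the two agree within 1% below 10% occupancy.

Two independent FAM probes target *AMY1*.  Reconciliation uses the
*AMY2A* call as a parity oracle: probe calls are rounded, tested for
parity concordance with *AMY2A*, and (both concordant → average; one →
keep it; none → average), with averaged values re-rounded under the
parity rule so the output always shares *AMY2A* parity.  "Concordant" is
interpreted as *parity*-concordant — the stated purpose of the check is
that the *AMY2A* call vouches for the *AMY1* call's parity; an
integer-equality interpretation of probe agreement is available behind a
flag.  Concordance of final integer calls defines the validation summary
(two calls per sample, one per locus).

# Trait preprocessing and the mixed model

Traits are cleaned in a single pass — values beyond 3 SD of the full
sample's mean are removed (not iterated, per the stated order of
operations) — then rank inverse-normal transformed with offset
$(r - 0.5)/n$ and average ranks for ties.  The Blom offset is available;
the two differ negligibly at cohort sizes and the choice is documented
rather than consequential.

Association uses the variance-component model
$y = X\beta + g + \varepsilon$, $\mathrm{Var}(g) = 2\Phi\sigma^2_g$,
$\mathrm{Var}(\varepsilon) = \sigma^2_e I$, with $\Phi$ the kinship
matrix after thresholding: pairs with $\varphi < 0.05$ are set to 0
(exactly 0.05 is retained — a strict reading of "lower than").  The
kinship-to-covariance factor 2 is a configuration constant, since mixed
model software differs in whether it expects kinship or relationship
matrices; all recovery experiments are self-consistent with the
simulator, which uses the same convention.

REML is computed by eigendecomposition: rotating by the eigenvectors of
$2\Phi$ diagonalises the covariance, leaving a one-dimensional profile
likelihood in $\delta = \sigma^2_e/\sigma^2_g$, maximised on the log
scale (coarse grid then Brent refinement, relative tolerance $10^{-8}$;
deterministic given inputs).  A thresholded family kinship is
block-diagonal, so the decomposition is performed per family block and
stored sparse — fits on a 3,000-sample cohort take milliseconds once the
decomposition is cached, which is what makes 1,000-replicate calibration
experiments affordable.  With no relatedness the model provably collapses
to OLS, and the tests assert equality to $10^{-6}$.  Heritability is
$h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$ from the predictor-free fit.
Wald tests use the normal approximation, adequate at the cohort sizes
simulated here (type-I error is checked against its binomial interval at
$n = 1500$).

Binary outcomes (obesity defined as BMI ≥ 30 vs < 25 controls; dietary
restraint) use ordinary logistic regression with Wald intervals;
separation is detected and raised rather than silently returning a
divergent estimate.

The polychoric correlation between the two ordinal CN distributions is a
two-step ML estimator: thresholds from the margins via $\Phi^{-1}$, then
the latent correlation maximising the bivariate-normal cell likelihood.
The bivariate normal CDF uses the standard one-dimensional reduction
$\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \int_0^\rho \phi_2(h,k,r)\,dr$ with
a cached 48-node Gauss–Legendre rule (~$10^{-12}$ accuracy); the test
suite verifies the ML maximum against a $10^{-3}$-step grid search.

# Ancestry stratification

Variant QC applies MAF > 0.01, call rate > 0.9 and HWE exact $p >
10^{-6}$ (the exact test is the standard conditional enumeration, checked
against an independent log-factorial oracle on 1,000 random tables).
LD pruning is greedy within 50-kb windows (drop the lower-MAF member of
any pair with $r^2 > 0.05$, ties to the later position), sliding by 5
variants, followed by a global cleanup sweep so the *final* retained set
contains no violating pair within any 50-kb span — the stepped sweep
alone can miss a long-range pair that no anchored window covers jointly.
PCA mean-imputes missing dosages per variant (PLINK-like), standardises
columns, and fixes each component's sign by its largest-magnitude
loading.

Ancestry assignment is nearest-centroid in PC space with an admixture
margin: samples whose nearest/second-nearest centroid distance ratio
exceeds 0.5 are labelled Admixed.  The 0.5 default was calibrated once on
the simulator's geometry — pure samples in a clearly structured cohort
sit below ~0.2 while 50/50 admixed draws sit above ~0.5 — and is
deliberately conservative toward the Admixed label for ambiguous samples.
The published analyses assign ancestry from a fixed panel of
ancestry-informative markers whose identities are not public; this module
therefore implements the generic mechanism and treats the marker list as
input data.  Post-hoc outlier re-exclusion after a region-restricted PCA
uses an explicit distance rule (> 6 MAD from the own-group centroid),
since the original rule is not specified.

**Sliding windows.** Windows of 750 individuals along the PC1 ranking
advancing by 85 are used for stratified association.  A literal "overlap
of 85" cannot produce 10 windows over 1,518 individuals; a *step* of 85
yields exactly 10 windows there and exactly 3 over 948, matching both
stated counts simultaneously, so the step interpretation is adopted (the
parameters remain configurable).  Within each window the trait is
re-cleaned and re-transformed by default — the stated preprocessing
sentence sits inside the window-analysis description — with a switch to
use globally transformed values instead.

# The simulator

Generators are pure functions of (config, seed); identical seeds replay
bit-identically.

*Haplotypes.* Diploid CNs are sums of two haplotypes drawn from
per-ancestry tables (children inherit one haplotype per parent).  The
tables are synthetic — haplotype frequencies are not public — and were
constructed to reproduce the reported diploid means exactly in
expectation (*AMY1* 6.92/7.60, *AMY2A* 2.06/2.27 for Arab/Persian), to
couple *AMY1* and *AMY2A* parity at the haplotype level (so diploid
parity always agrees, matching the observed pattern), and to keep *AMY2B*
nearly invariant at 1 copy per haplotype.  They live in a versioned data
file, not code.

*Coverage.* Target counts are Poisson with mean
$CN \cdot d \cdot L_u$ and reference counts Poisson with mean
$2 d L_r$, where $d = 0.15$ reads/bp per haploid copy corresponds to 30×
diploid coverage at 100-bp reads.  A shared per-sample gamma multiplier
(CV 0.1) mimics library-size variation and cancels in the density ratio;
an optional independent per-region gamma (CV 0 by default) does not
cancel and exists to stress-test calling accuracy.

*Phenotypes.* $y = \beta_{CN} CN + \beta_{sex} sex + \beta_{age} age_z +
g + \varepsilon$ with $g \sim N(0, 2K\sigma^2_g)$ drawn per family
block, $\sigma^2_g = h^2$, $\sigma^2_e = 1 - h^2$ (unit residual scale).
Defaults: $\beta_{CN} = -0.02$ SD/copy (the reported trunk-fat effect),
$h^2 = 0.3$ (between the reported Arab 19–23% and Persian 42–44%
regimes, which the recovery experiments probe at 0.2 and 0.45), sex
effect 0.3 SD (adiposity higher in women), age effect 0.1 SD per SD.
Ages are normal (39.11, 12.03) truncated to [18, 80]; sex is
Bernoulli(0.5).  Obesity is drawn from a logistic model with per-copy OR
0.93 around a 41% baseline; restraint is defined for overweight/obese
individuals (BMI ≥ 25 on the derived raw-BMI scale) with per-ancestry
baseline prevalence 54%/60%.

*ddPCR.* Droplet occupancy is Poisson: positives are binomial with
probability $1 - e^{-\lambda}$ (reference) and $1 - e^{-\lambda CN/2}$
(target), $\lambda = 0.5$, 20,000 droplets, three replicates, two *AMY1*
probes and one *AMY2A* probe.

*Genotype matrices.* Balding–Nichols drift around a uniform ancestral
frequency at a target $F_{st}$ (realised within ±0.01 at 5,000 variants,
checked with a Weir–Cockerham estimator), optional AR(1) latent-Gaussian
LD, optional missingness.

*Alignment fixtures.* Miniature BAMs on a 100-kb toy contig realise a
draw of the coverage model with controlled MAPQ values and XA/SA tags;
they carry placeholder bases and exist for testing the counting and QC
layer, not sequence-level realism.

**What passing tests do and do not show.** The simulator captures the
statistical structure that drives the methods — Poisson depth, pedigree
covariance, ancestry-shifted haplotype frequencies, logistic outcomes.
It does not model GC bias, reference bias, batch effects in depth,
genotyping error in the kinship source, or assortative mating; recovery
on simulated data therefore validates the estimators' correctness and
calibration under the stated model, not robustness to every artefact of
real sequencing data.

# Problem sizes and numerical choices

The recovery experiments run at deliberate desk scale: effect-size
recovery uses 200 phenotype replicates on a fixed 3,000-sample cohort
(the fixed cohort lets the kinship eigendecomposition be reused; the
Monte-Carlo SE of the mean effect is ~0.0005, comfortably inside the
±0.005 band), type-I calibration uses 1,000 nulls at $n = 1500$,
heritability recovery averages 8 replicates at $n = 2000$ per regime
(single-fit SE ~0.06 with nuclear-family kinship, so averaging is needed
to test a ±0.07 band meaningfully), and estimator checks use 1,000
tables/reactions or $n = 5000$ observations as appropriate.

Degenerate inputs are handled explicitly rather than silently: zero
reference coverage, saturated ddPCR channels, all-tied traits,
zero-variance PCA input, constant-CN windows, empty margin categories and
non-PSD kinship all raise or flag with informative messages.

# Known limitations

- The CN model assumes the reference region is GC-matched and truly
  copy-invariant; no GC re-estimation is attempted.
- Calling is locus-level: no breakpoints, no per-exon CN, no haplotype
  phasing.
- The mixed model fits one variance component; dominance, shared
  environment and inbreeding-adjusted self-kinship are out of scope.
- Logistic fits stop at separation rather than switching to a penalised
  estimator.
- The admixture margin is a geometric heuristic, not a model-based
  admixture estimate.
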