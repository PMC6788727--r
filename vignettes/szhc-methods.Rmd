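---
title: "Methods: from risk-gene SNPs to grey-matter hot clusters and patient subtypes"
author: "szhc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from risk-gene SNPs to grey-matter hot clusters and patient subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis this package implements

`szhc` implements a multi-scale analysis strategy for first-episode
schizophrenia imaging genetics. The chain of reasoning runs: (i) individual
risk-gene SNPs are screened for association with voxel-level grey-matter
volume (GMV); (ii) the genes surviving the screen are checked for
biological coherence — do they co-express more strongly than chance in
specific brain regions and developmental windows?; (iii) the voxels they
hit are aggregated, corrected for linkage disequilibrium, smoothed and
segmented into connected "hot clusters" (HCs) — brain territories
collectively associated with the candidate genes; and (iv) patients are
subtyped by their GMV profile over the HCs and the subtypes are
characterized clinically on the PANSS symptom scale.

The clinical cohort such an analysis would consume is not publicly
deposited, so the package is organised around a synthetic-data generator
with planted, recoverable ground truth. Every stage is exercised, and every
statistical guarantee tested, against data whose correct answer is known by
construction.

## Stage models and their assumptions

### Voxel-wise association screen

For SNP $s$ (additive minor-allele coding $g_s \in \{0,1,2\}$) and voxel
$v$, the model is ordinary least squares:

$$\mathrm{GMV}_v = \beta_0 + \beta_1 g_s + \beta_2\,\mathrm{age} +
\beta_3\,\mathrm{sex} + \beta_4\,\mathrm{edu} + \varepsilon,$$

with a two-sided $t$ test on $\beta_1$ at $n_{\mathrm{used}} - 5$ degrees
of freedom. Subjects with a missing call at $s$ are dropped from that
SNP's fits only (per-test complete cases; no imputation). A gene is a
candidate when any of its SNPs reaches $p < 10^{-6}$ at any voxel — a fixed
screen, deliberately uncorrected for multiplicity, whose per-gene minimum
p-values are reported so the reader can apply any correction they prefer.
Cases and controls are pooled by default; the caller controls the subject
set, so a cases-only screen is a subsetting step, not a package option.

Genotype QC precedes the screen: subjects below a 97% call rate, markers
with more than 5% missingness, minor allele frequency at or below 0.05
(computed over all retained subjects), or an exact Hardy–Weinberg
equilibrium p at or below $10^{-6}$ are excluded. The HWE test enumerates
heterozygote counts conditional on the allele count (exact at the extreme
threshold, where the $\chi^2$ approximation is unreliable); a $\chi^2$
variant is available via `hwe_method = "chisq"`.

### Co-expression interconnectedness

Expression samples are stratified into four brain regions (FC, SC, SM, TP)
by three developmental stages. Within a stratum, the network weight between
two genes is their absolute Pearson correlation $|r|$ if it strictly
exceeds 0.8, else 0; unweighted variants binarise surviving edges. The
*interconnectedness* of a gene set is the sum of edge weights among its
members, each unordered pair counted once. Significance comes from
resampling: `n_resamples` (default 10000) equally sized gene sets are drawn
uniformly without replacement from the risk-gene pool, and

$$p = \frac{\#\{\text{null} \ge \text{observed}\} + 1}{n + 1}.$$

The add-one correction keeps $p$ away from an impossible exact zero; ties
count toward the tail (conservative). Both choices are configurable
(`add_one`, `ties`). The merged network (all strata pooled) is the
robustness control: signal confined to one (region, stage) stratum is
diluted roughly by the number of strata when samples are pooled, so a
stratum-specific module should be invisible there.

### Hot-cluster construction

Each voxel is first weighted by the number of distinct SNPs significantly
associated with its GMV. Because SNPs on one chromosome can be nearly
redundant through LD, the count is replaced per chromosome by the Li–Ji
effective number of independent SNPs,
$m_\mathrm{eff} = \sum_i f(\lambda_i)$ with
$f(\lambda) = \mathbf{1}[\lambda \ge 1] + (\lambda - \lfloor\lambda\rfloor)$,
computed from the eigenvalues of the SNPs' genotype correlation matrix.
This estimator satisfies the two boundary conditions any such correction
must: perfectly correlated SNPs count once, independent SNPs count fully.
The exact correction formula used in the original analysis is not public;
Li–Ji is this package's documented reconstruction, implemented as a
swappable step. Eigenvalues are rounded to 8 decimals before applying
$f$, so analytically integer eigenvalues (duplicated SNPs) are not split
by floating-point jitter — $f$ is discontinuous at integers, and without
rounding a $\lambda = 2 - 10^{-15}$ would absurdly count as two SNPs.

Corrected weights are smoothed with an isotropic Gaussian kernel
(FWHM 8 mm; $\sigma_{\mathrm{vox}} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) /
\text{voxel size} \approx 2.2649$ at 1.5 mm), separably, truncated at
$4\sigma$, unit-normalised, with zero padding — mass is preserved away
from the image boundary and never created. Voxels strictly above the
threshold 0.2304 are merged under 18-connectivity: "sharing at least one
edge or side" is read literally as face-or-edge adjacency, excluding
corner-only contact (6 and 26 are available). The threshold is kept as the
published operating point but treated as data-dependent; a percentile of
the smoothed map is the natural alternative when porting to other grids
(e.g. `quantile(map$smoothed, 0.995)`). Clusters are ranked HC1, HC2, …
by maximum voxel weight (ties broken by smallest voxel index), annotated
with every gene whose significant voxels intersect them, and located by
the modal atlas label with the full label composition retained.

### Subtyping and clinical characterization

Patients are represented by their mean GMV over each HC and clustered by
K-means under the correlation distance $d(x, y) = 1 - r(x, y)$: assignment
to the centroid at minimal $d$, centroids updated as the mean of members'
row-standardised (zero-mean, unit-norm) features — the construction under
which correlation distance is a monotone function of Euclidean distance,
making Lloyd iterations well behaved. Each K runs `n_replicates` (default
1000) random restarts seeded from K distinct patients; the minimal
within-group distance sum wins. An emptied group is re-seeded from the
point farthest from its centroid.

K is chosen over 2..10 by maximizing the mean in-group proportion (IGP):
per group, the fraction of members whose nearest neighbour (under the same
distance; ties to the lowest patient index) shares their label, averaged
unweighted over groups. Ties in mean IGP resolve to the smallest K. Note
that IGP rewards coarse clusterings — any union of well-separated groups
scores 1 — so K = 3 wins only when the data punish the two-group solution;
see the generator design below.

PANSS subscales are P (7 items), N (7 items), G (16 items), TT = P + N + G
and the composite PN = P − N, validated against the instrument's 1–7 item
range. Group contrasts use label permutations (default 10000) with group
sizes fixed: per-group means and pairwise mean differences are referenced
to their permutation distributions, two-tailed by doubling the smaller
tail (add-one corrected, capped at 1). The published description of the
percentile rule is one-tailed/ambiguous; the two-tailed reading matches
the two quantile lines drawn in the original figures, and a one-tailed
mode is available. Because it is unclear whether the original group-mean
statistic was tested per group or jointly, both the per-group p-values and
an omnibus max-|difference| statistic are emitted. Per-(group, HC) GMV
contrasts use two-sided Wilcoxon rank-sum tests of a group against all
remaining patients, flagged at the Bonferroni level $0.05 / \#\mathrm{HC}$
(exactly $0.003125$ at 16 HCs).

## The synthetic study design

The generator (`sim_config()` defaults) emulates the study conditions the
pipeline was built for:

* **Cohort**: 72 cases + 73 controls; age ~ U(16, 45) years, sex 0/1,
  education ~ U(6, 18) years, drawn identically for cases and controls (a
  matched design).
* **Genotypes**: 200 risk genes × 5 SNPs. A gene's SNPs share a base MAF
  drawn from U(0.1, 0.4) (±0.02 per-SNP jitter) — variants on a common
  haplotype background have similar allele frequencies — and are coupled
  through a latent-Gaussian threshold copula with exchangeable correlation
  0.95, cut at Hardy–Weinberg genotype frequencies. This produces genotype
  correlations around 0.85–0.9, i.e. a Li–Ji effective count near 2 for a
  5-SNP block: strong LD, exactly the regime the correction exists for.
  There is no recombination map, ancestry structure or genotyping-error
  model.
* **Images**: 24³ voxels at 1.5 mm — a desk-scale stand-in for a brain
  volume (the real analysis had ~4 × 10⁵ in-brain voxels). Eight causal
  genes each drive one sphere of radius 2.5 voxels (β = 1 GMV unit per
  minor allele) at the (6|18)³ corners; 12-voxel spacing keeps the
  smoothed clusters disjoint at the default kernel and threshold. Gaussian
  voxel noise has sd 0.2; covariate effects are small global offsets.
  Baseline GMV is 2.5 arbitrary units and values are floored at zero
  (the floor is essentially never reached at the defaults).
* **Expression**: 4 regions × 3 stages × 30 samples. One 20-gene module
  (containing the causal genes) is generated from a one-factor model with
  within-module correlation 0.95 in (FC, stage 2) only; everything else is
  independent noise. Real expression data have correlated backgrounds,
  batch structure and mean–variance coupling; none of that is emulated, so
  passing tests demonstrate correctness of the statistics, not robustness
  to those artefacts.
* **Subgroups**: sizes (14, 29, 29). The two large groups are internally
  homogeneous with strong GMV increases on disjoint sphere pairs (5–6 and
  7–8, shift 2.5) — a positive-dominant subtype (+2 per P item) and a
  negative-dominant subtype (+2 per N item). The small group carries a
  moderate shift (1.5) on spheres 1–4 plus per-patient regional
  variability (sd 0.6 on every sphere): a clinically heterogeneous group.
  This asymmetry is deliberate and load-bearing: with three equally tight,
  well-separated groups, the two-group K-means solution simply merges two
  of them, every nearest neighbour stays within its own group, and mean
  IGP ties at 1.0 for K = 2 and K = 3 — the smallest-K tie rule would then
  report K = 2. A heterogeneous group whose stray members' nearest
  neighbours cross into other groups penalises the two-group average
  (weight 1/2) harder than the three-group average (weight 1/3), making
  K = 3 the genuine IGP maximum. In replicate simulations at these
  defaults K = 3 is selected in roughly 90% of datasets and the K = 3
  labelling agrees with the planted groups at ≥ 0.97; recovery tests
  therefore assert a majority over five replicate datasets rather than a
  single draw.
* **PANSS**: items are 1 + rounded half-normal noise (scale 1.5) + the
  group shift, clipped to 1–7.

No effect sizes linking SNPs to GMV are published for the original cohort;
β = 1 at noise 0.2 was chosen so that planted effects sit far above the
10⁻⁶ screen (per-voxel t ≈ 40) while null SNPs behave exactly uniformly —
the regime in which recovery and calibration can both be asserted.

## Numerical and procedural choices

* All boundary rules are strict as documented: call rate `< 0.97` removes,
  MAF `<= 0.05` removes, HWE `p <= 1e-6` removes, association `p < 1e-6`
  selects, network edges `|r| > 0.8`, cluster voxels `weight > 0.2304`.
* Degenerate regressions (constant genotype, non-positive degrees of
  freedom, singular design) yield missing statistics, never a crash or a
  fabricated p.
* Zero-variance genes keep their network node (warning) so the resampling
  pool size is preserved.
* At realistic voxel counts the full SNP × voxel p matrix does not fit in
  memory; per-pair records are retained only below `p_keep` (default
  1e-4 ≫ the 1e-6 screen), while per-SNP and per-gene minima are always
  kept. `keep_full = TRUE` retains everything on small problems.
* Determinism: one global seed; every stage and every replicate derives a
  counter-based sub-seed (`stage_seed()`), so re-running one stage never
  shifts another's randomness, and the pipeline's output tables are
  byte-identical across runs with the same seed. Permutation tests
  canonicalise patient order before drawing permutations, so row order
  does not leak into p-values.
* The uniform-p arithmetic of a fixed 10⁻⁶ screen implies ~1 false
  SNP–voxel pair per 10⁶ true-null tests. At the full default scale
  (1.4 × 10⁷ tests) a handful of false pairs is *expected*; they are
  isolated single voxels that vanish under smoothing (peak ≈ 0.006 ≪
  0.2304) but can occasionally fall inside a cluster's footprint and add a
  spurious gene to its annotation. The focused cluster-recovery experiment
  therefore runs on the causal panel (8 genes × 5 SNPs), where the
  expected number of in-cluster false pairs is ≈ 0.08.

## Problem sizes used by the tests

The test suite runs the full study scale (145 subjects, 1000 SNPs,
13824 voxels) for the association-recovery and end-to-end determinism
checks — recovery at the stated effect conditions (β = 1, voxel noise
sd 0.2, no subgroup pathology variance), determinism on the full default
design — a 10³-voxel no-effect panel (10⁵ tests) for type-I calibration,
500 replicates × 200 resamples for interconnectedness null uniformity,
five replicate datasets for subtyping recovery, and 300 replicate
datasets × 150 permutations for PANSS null uniformity. These sizes were
chosen so each check has the statistical resolution its assertion needs
(e.g. 3 binomial standard errors at α = 0.001 requires ≥ 10⁵ tests) while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The LD correction and the 0.2304 cluster threshold reconstruct
  non-public details of the original analysis; both are explicit,
  swappable strategies, and conclusions drawn from them should be
  robustness-checked (the percentile threshold, 6/26-connectivity and the
  χ² HWE variant exist for exactly that purpose).
* The generator's planted effects are spherical, additive and
  homoscedastic; real VBM effects are none of these. Recovery results
  quantify the pipeline's correctness, not its field performance.
* IGP-based model selection inherits IGP's bias toward coarse clusterings;
  on data without the kind of asymmetric group structure discussed above,
  expect K below the truth rather than above it.
* Subgroup pathology is unmodelled noise for the association screen: the
  planted GMV shifts contribute ≈ 1.0 sd of extra residual variance at
  shifted spheres — five times the baseline voxel noise — so at the
  default design a low-MAF causal SNP sits near the 10⁻⁶ screen
  (per-voxel t ≈ 5) and can miss it in some datasets. Recovery guarantees
  are therefore stated, and tested, at the effect conditions without
  subgroup shifts; the full default pipeline's own recovery rate is
  reported alongside, unfiltered.
* No population-stratification correction, genotype imputation or mixed
  models: the association screen assumes an unstructured cohort, as the
  original single-site design did.
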