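---
title: "Pathway imaging genetics of low-frequency BOLD fluctuations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway imaging genetics of low-frequency BOLD fluctuations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffnet)
```

## The analysis in one paragraph

`alffnet` implements a pathway-based imaging-genetics pipeline for
resting-state fMRI. Each subject's 4D BOLD series is reduced to a voxelwise
**ALFF** map — the mean single-sided spectral amplitude over 0.01–0.08 Hz —
after discarding initial volumes and removing a linear trend. For each SNP
of a 33-SNP / 12-gene cholesterol-metabolism panel, a mass-univariate
general linear model tests the **SNP-by-diagnosis interaction** on ALFF at
every voxel, adjusting for age, gender, education and the voxelwise
grey-matter probability. Family-wise error over the imaging space is
controlled by Monte-Carlo (AlphaSim-style) **cluster-extent thresholds**,
followed by a two-stage Bonferroni ledger: within each gene the per-SNP
alpha is divided by the gene's SNP count, and across genes the single-voxel
threshold is divided by the number of SNPs that survived stage 1. Surviving
clusters become nodes of an ROI network whose edges are Fisher-z
transformed Pearson correlations of mean ROI time series; the package
computes node strength $S_i = \sum_{j \ne i} w_{ij}$, edge-wise two-sample
tests between diagnostic groups, hemispheric laterality, and correlations
of node strength with behavioural scores. A synthetic-data generator with
known ground truth makes every stage testable end to end.

## Statistical model

At voxel $v$ the full model for subject $i$ is

$$y_{iv} = \beta_0 + \beta_g\,\mathrm{group}_i + \boldsymbol{\beta}_s^\top
\mathbf{c}(d_i) + \boldsymbol{\beta}_{gs}^\top\,
\mathrm{group}_i\,\mathbf{c}(d_i) + \beta_a\,\mathrm{age}_i +
\beta_x\,\mathrm{gender}_i + \beta_e\,\mathrm{edu}_i +
\beta_m\,\mathrm{GM}_{iv} + \varepsilon_{iv},$$

where $d_i \in \{0,1,2\}$ is the minor-allele dosage and
$\mathbf{c}(\cdot)$ the genetic-model coding. The interaction is tested by
the partial F comparing this model against the one without the
$\mathrm{group}\times\mathbf{c}(d)$ column(s): df1 is the rank gained by
the interaction columns, df2 the residual degrees of freedom. This
regression-based partial F is the standard operationalisation of a
"group × genotype ANOVA with covariates"; voxels where a genotype class is
missing in one group lose the aliased column through pivoted QR and df1
shrinks accordingly rather than failing.

**Genetic-model selection.** The genotypic model (orthogonal polynomial
contrasts, `contr.poly(3)`, 2 df) needs a populated rare-homozygote class.
The cutoff is derived as the largest two-decimal frequency $q$ with
$q^2 \le 0.10$ — i.e. at most 10% rare homozygotes — which gives **0.31**.
SNPs with MAF $\ge$ 0.31 use the genotypic model; the boundary itself is
genotypic, because the recessive rule applies strictly below the cutoff.
Rarer SNPs use a carrier indicator merging heterozygotes with rare
homozygotes (1 df).

**Quality control.** SNPs are excluded when the observed MAF is below 0.05
or when their dosage vector is in complete LD with an earlier panel SNP.
Complete LD is operationalised as $r^2 = 1$ between dosage vectors (this
also catches allele-flipped duplicates); the first SNP in panel order is
kept. Hardy–Weinberg equilibrium is tested by a 1-df Pearson chi-square
against the $q^2, 2pq, p^2$ proportions at the estimated allele frequency;
a monomorphic SNP returns p = 1 by convention since it carries no
information about equilibrium.

**Demographics.** Continuous variables are compared with both a
pooled-variance t-test and a Mann–Whitney U; the gender split with a 2×2
chi-square in two variants — plain Pearson and the $(N-1)/N$-scaled
(Mantel–Haenszel style) statistic, which is what several clinical packages
print. On the 27:16 vs 17:13 split the two give p = 0.599 and p = 0.601.
Neuropsychological variables are handled on the z scale; the generator
standardises them against the stated group means and SDs directly, since no
reference population is specified for the published z-scores.

## ALFF computation

The series is detrended (per-voxel linear fit) after dropping the first 8
volumes; subjects whose motion summary exceeds 3 mm displacement or 3°
rotation are flagged for exclusion (realignment itself is out of scope —
the summary is an input). The spectral amplitude uses a plain DFT of the
full retained series (no taper, length = series length); the single-sided
amplitude $2|X_k|/N$ is averaged over the bins with
$0.01 \le f_k \le 0.08$ Hz, both edges inclusive. Band-passing is
implemented as Fourier-coefficient masking, so "band-pass, then transform"
and "average the in-band amplitudes directly" are identical by
construction; a Parseval identity
($\sum_k a_k^2 / 2 = \overline{y^2}$ for the band-passed series $y$) is
asserted in the tests at $10^{-8}$ relative tolerance.

Two numerical caveats are documented rather than hidden. First, a sinusoid
whose frequency does not fall on a DFT bin leaks into neighbouring bins
(rectangular window); out-of-band rejection is therefore exact only for
bin-aligned components, and the spectral tests use scan durations that make
the probe frequencies bin-aligned. Second, smoothing: Gaussian smoothing is
implemented as circular FFT convolution with a unit-sum kernel, which
conserves total intensity exactly; wrap-around is negligible because the
brain mask is an interior ellipsoid with a clear border. Whether to smooth
the 4D data or the ALFF map is left to the caller; the synthetic generator
already produces spatially smooth signal (below), so the packaged pipeline
does not smooth twice.

## Cluster inference

`simulate_cluster_threshold()` draws Gaussian white noise on the grid,
smooths it to the assumed FWHM (default 8 mm, the smoothness the data were
processed at; a residual-autocorrelation FWHM estimator is provided for
reporting only), thresholds the in-mask values at the empirical upper-tail
`voxel_p` quantile and records the largest connected cluster, under
18-connectivity by default (faces + edges, matching a 5 mm adjacency radius
at 3 mm voxels; 6 and 26 are selectable). The returned extent is the
smallest $k$ with $P(\max \text{cluster} \ge k) \le \alpha$. The Monte
Carlo is stationary; the published analyses describe non-stationary
cluster-size inference but parameterise a stationary simulation, so the
stationary form is the default and any local-smoothness rescaling is
regarded as an approximation outside the package's scope.

When simulation is skipped, the packaged fixed extent is **48 voxels =
1296 mm³** at 3 mm isotropic voxels with voxel p < 0.005 — the published
operating point. On the desk-scale validation mask the simulated extent is
smaller (the search space is much smaller than a whole brain), which is
why the fixed default is reproduced as a unit conversion, not by
re-simulation.

The correction ledger has two stages. Stage 1 (`pass_S`): a cluster
survives the extent rule; with a Monte-Carlo null distribution available,
its family-wise corrected p is compared against $\alpha / m_g$ with $m_g$
the number of panel SNPs in the cluster's gene (APOE's five SNPs give
0.01). Stage 2 (`pass_SG`): with $k$ SNPs carrying stage-1 clusters, the
single-voxel threshold tightens to $0.005 / k$ (for $k = 15$:
$3.3\times10^{-4}$, printed as 0.0003) and clusters are re-extracted under
the same extent rule; stage-1 clusters containing a surviving stage-2 peak
gain `pass_SG`, and `pass_SG` implies `pass_S` by construction.

## Network stage

The 31 published interaction clusters ship as a plain-text ROI fixture
(peak MNI coordinates, labels, hemisphere tags, cluster sizes, peak F
values, correction flags). In-session ROIs use the actual cluster voxel
masks; fixture-only ROIs are realised as 6 mm spheres around the peaks.
Edges are Fisher-z transformed Pearson correlations of mean ROI series,
with r clipped to $\pm(1 - 10^{-7})$ so weights stay finite. "Unidirectional
weighted network" is read as an undirected weighted complete graph —
$\binom{31}{2} = 465$ edges confirms that reading. Correlation thresholds
(0.3/0.5/0.7) are applied on the r scale with magnitude
(negative edges retained with sign, since node strength sums signed
weights); edge-wise group tests are pooled two-sample t-tests on z at four
uncorrected thresholds (0.05/0.01/0.005/0.001), with a Bonferroni column
added for reference but not used for selection, mirroring the published
four-threshold sweep. Behaviour correlations are Pearson (or partial, via
residualisation on covariates) between node strength and cognitive scores,
with both uncorrected and Bonferroni-adjusted p-values. The hemispheric
summary quantifies lateralisation as $(L - R)/(L + R)$ over summed node
strengths, a package addition used to express the "left-lateralised global
connectivity" observation numerically.

## The synthetic-data generator

The generator emulates the study conditions: 43 aMCI and 30 control
subjects; demographics and neuropsychological z-scores drawn from the
published group means and SDs (`phenotype_parameters()`); genotypes drawn
in Hardy–Weinberg equilibrium at panel MAFs; a 24×28×24 grid of 3 mm
voxels with an interior ellipsoid mask (a full MNI grid adds nothing to
validation); TR 3 s, 142 volumes, 8 discarded. Panel MAFs are not published,
so the fixture carries plausible synthetic defaults (`sim_maf`), fixed once
— e.g. 0.15 for the APOE ε4-defining SNP, in the range reported for
elderly East-Asian samples — and never tuned.

Each subject's baseline fluctuation is a mixture of 10 sinusoids with
frequencies uniform in 0.01–0.08 Hz and random phases, combined with
spatially smooth (8 mm FWHM) mixing weights and normalised to unit temporal
variance per voxel, which guarantees energy in the analysed band. Inside an
effect blob the amplitude is scaled by
$1 + \text{effect size} \times \mathrm{group}_i \times c_i$, where $c_i$ is
exactly the genotype design code the mapping stage will fit (carrier
indicator or linear contrast), so the injected signal is a pure interaction
and recovery is an identity test. A per-subject linear scanner drift is
added (removed exactly by detrending) plus spatially **white** measurement
noise. Smoothing the structured baseline while leaving the thermal-like
noise white is a deliberate design choice: it is physically reasonable
(thermal noise is spatially white; structure comes from physiology and
processing), it keeps the generator fast enough that the full 73-subject
study can be re-simulated dozens of times inside the test suite, and it
does not weaken the cluster-inference validation, which is performed
against explicitly smoothed null maps at the FWHM the thresholds assume.
Grey-matter maps are smooth probability fields in [0, 1]
(probit-transformed smoothed Gaussian fields); a flag can withhold one
aMCI subject's map to exercise the mean-imputation path for the missing
anatomical scan. Effect sizes are free parameters of the configuration —
the study does not report the amplitude of its real effects, so no attempt
is made to estimate them.

All randomness flows from one master seed through named sub-streams
(`stream_seed()`), so any subject's series can be regenerated in isolation;
the pipeline exploits this to avoid holding 73 4D volumes in memory at
once. Determinism is asserted byte-for-byte in the tests.

What passing tests show — and what they do not: the generator contains no
head motion, slice-timing structure, physiological noise, spatial
inhomogeneity or registration error, and its spatial covariance is
idealised. Passing the recovery and calibration suites demonstrates that
the statistical machinery is correct and calibrated under the stated
model, not that the pipeline is robust to the full complexity of real
resting-state data.

## Validation suite and problem sizes

The test suite pairs every non-trivial computation with an independent
oracle: an $O(N^2)$ DFT for the spectral amplitude; explicit
normal-equations least squares for the partial F (agreement at $10^{-8}$
relative on 100 random voxels); stack-based flood fill for component
labelling (exact partition agreement); an independent-voxel oracle for the
Monte-Carlo extent at FWHM 0 (exact at matched seeds); row sums for node
strength; residualisation for partial correlations.

Calibration and power runs use the study's own scale: the voxelwise null
(group main effect, no interaction) uses 2000 simulated voxels at
n = 43/30; the cluster-level family-wise rate uses a 1000-iteration
Monte-Carlo threshold and 200 replicate pure-noise statistic maps on the
24×28×24 grid; parameter recovery re-simulates the full 73-subject study
20 times with a radius-4 blob at effect size 1.0 and requires the F peak
inside the true blob plus a stage-1-surviving cluster in at least 90% of
runs. Smaller grids (e.g. 14×16×14, 16 subjects, 40 volumes) are used for
structural and determinism tests where statistical scale is irrelevant.

## Known limitations

- No Gaussian-random-field analytic cluster p-values, TFCE or permutation
  FWE; inference is Monte-Carlo extent only.
- No haplotype phasing, imputation, LD estimation beyond exact duplication,
  or population-structure correction.
- Graph analysis stops at node strength; no clustering coefficient, path
  length or modularity.
- The published subject-level results (peak F values, the 15/33 surviving
  SNPs, specific behaviour correlations) depend on raw data that were never
  deposited and are not reproduction targets; the package reproduces the
  analytic worked examples and validates the procedures on synthetic ground
  truth instead.
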