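---
title: "Models and methods in magicgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in magicgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicgs)
```

`magicgs` implements a genomic-selection analysis for an inbred MAGIC
population phenotyped for drought-related traits across sequential
experiments. This vignette documents the models, the numerical choices
behind them, the design decisions that were genuinely open, and what the
bundled simulator does and does not emulate.

## 1. Derived phenotypes

Raw data are plant-level records: organ fresh and dry weights, leaf number
and stem length, optical pigment indices, and proline, each plant tagged by
line, experiment, role (MAGIC line vs parent) and stage (destructive
baseline at stress onset vs final harvest).

Water content is computed on a fresh-weight basis,
$\mathrm{WC} = 100\,(\mathrm{FW}-\mathrm{DW})/\mathrm{FW}$. This is the
only formulation bounded by $[0, 100]$ and consistent with plant tissue
values of roughly 70–90 %; a dry-weight basis would exceed 100 and was
rejected. Aggregate water contents (aerial, total) are computed from the
*summed* fresh and dry weights, not by averaging organ percentages —
percentages do not add, masses do.

Growth during the stress period is a difference against destructive
baselines: for a MAGIC line, final plant minus the single baseline plant of
the same line in the same experiment; for a parent, final replicate minus
the experiment-specific mean of that parent's baseline plants. A final
plant without a matched baseline gets a missing growth value and is
reported. Growth defined this way is invariant to adding a constant to both
stages, and re-deriving an already-derived table is a no-op; both
properties are tested.

The gravimetric watering helper is plain proportionality: the water mass at
a target fraction of field capacity is the fraction times the mass held at
100 % FC (pot and dry substrate already subtracted), e.g. 30 % of 780 g is
234 g.

## 2. Genotypes and the relationship matrix

Genotypes are alternate-allele dosages in $\{0,1,2\}$ with a 1-based
physical map. The loader requires complete data — the intended inputs are
imputed SNP panels — with opt-in per-marker mean imputation for partial
data. Marker filtering retains MAF strictly greater than the cutoff
(default 0.04; a marker exactly at the cutoff is removed), and distance
thinning is greedy left-to-right within chromosome: keep the first marker,
then every marker at least `min_bp` (default 2,000) beyond the last kept
one. The greedy rule is deterministic and standard; whether thinning runs
before or after MAF filtering is the caller's choice — the shipped pipeline
filters MAF first.

The genomic relationship matrix is the VanRaden form
$G = WW' / (2\sum_j p_j(1-p_j))$ with $W$ the dosage matrix centred at
$2p_j$. Monomorphic markers contribute nothing to numerator or denominator,
so removing them beforehand changes nothing (tested). Two structural facts
matter downstream:

* Column centring makes $G\mathbf{1} = 0$: $G$ always has a zero eigenvalue
  along the all-ones vector, so it is singular by construction.
* For fully inbred lines the diagonal approaches $1 + F \approx 2$ under
  the Hardy–Weinberg scaling of the denominator.

If $G$ fails positive semi-definiteness beyond tolerance (minimum
eigenvalue below $-10^{-8}$), the smallest $\varepsilon \in \{10^{-8},
10^{-6}, 10^{-4}\}$ restoring it is added to the diagonal and recorded.

## 3. The GBLUP model and its REML fit

The central model, fitted by `gblup()`, is

$$\mathbf{y} = X\boldsymbol\beta + Z\mathbf{u}_a + Z\mathbf{u}_n +
\mathbf{e}, \qquad
\mathbf{u}_a \sim N(0, \sigma^2_a G),\;
\mathbf{u}_n \sim N(0, \sigma^2_n I),\;
\mathbf{e} \sim N(0, \sigma^2_e I),$$

with fixed experiment effects (reference coding, first experiment as
reference) and both random terms sharing the line-incidence matrix $Z$. The
additive effects $\mathbf{u}_a$ are the genomic estimated breeding values;
$\mathbf{u}_n$ captures line-level genetic variation the markers do not
track. The default interface is plant-level data, as the model is defined;
an adjusted-means mode (one observation per line) exists mainly to make
cross-validation cheap — on means, $\sigma^2_n$ and $\sigma^2_e$ are
confounded, so that mode drops the partition.

### Numerical strategy

Variance components are estimated by average-information REML with EM
fallback steps. Because both random terms share $Z$, every quantity of the
restricted likelihood, its score and the AI matrix reduces to
$q$-dimensional algebra (lines, not plants) through the Woodbury identity
$V^{-1} = (I - ZAZ')/\sigma^2_e$ with
$A = (\sigma^2_e H^{-1} + Z'Z)^{-1}$ and $H = \sigma^2_a G + \sigma^2_n I$.
Since $G$ is singular (Section 2), $A$ is computed through the push-through
identity $A = L(\sigma^2_e I + L'Z'Z L)^{-1}L'$ with $H = LL'$ from the
eigen-decomposition of $G$ — exact for singular $H$ and numerically stable
when $\sigma^2_n = 0$.

Convergence is declared when the largest relative component change falls
below $10^{-8}$ or the restricted log-likelihood change below $10^{-9}$
(at most 200 iterations). Components are constrained non-negative. A
genetic component that sits at the zero bound *with a non-positive score*
is a genuine boundary optimum: it is pruned, the reduced model refitted,
and the estimate reported as exactly zero. The score condition matters — an
aggressive AI step can overshoot a component to the bound even when the
optimum is interior, and pruning on position alone was observed to lock in
a local boundary solution several log-likelihood units below the optimum.
A component that overshoots keeps a positive score and climbs back.

BLUPs and their prediction error variances are computed without ever
inverting $G$:
$\hat{\mathbf{u}}_a = \sigma^2_a G Z'P\mathbf{y}$,
$\mathrm{PEV}_a = \sigma^2_a G - \sigma^4_a\, G (Z'PZ) G$, and for the
total genotypic value $g = u_a + u_n$,
$\mathrm{PEV}_g = H - H (Z'PZ) H$.

### Heritabilities and gCV

Following the Cullis prediction-error-variance form,

$$H^2 = 1 - \frac{\overline{\mathrm{PEV}}_g}{\sigma^2_g}, \qquad
h^2 = 1 - \frac{\overline{\mathrm{PEV}}_a}{\sigma^2_a}, \qquad
\sigma^2_g = \sigma^2_a + \sigma^2_n,$$

each using the mean diagonal of the corresponding PEV matrix. Values are
clamped to $[0,1]$ with clamping recorded; a zero variance denominator
yields a missing heritability. When $\sigma^2_n$ is estimated at zero the
two coincide exactly — the expected situation for most traits in an inbred
population where markers track nearly all genetic variance. The classical
variant based on the mean variance of pairwise BLUP differences (with its
factor 2) is available via `cullis_vd = TRUE`; the plain PEV form is the
default because it is the form the downstream accuracy calculation expects.

The genetic coefficient of variation is reported by default as
$100\,\sigma_g/\mu$ — the genetic SD as a percentage of the trait mean,
the scale on which gCV is comparable across traits. A literal
variance-over-mean mode ($\sigma^2_g/\mu$) is also shipped; it is
dimensionally a variance divided by a mean and not comparable across
traits, so it is not the default. Neither mode is asserted to be the
uniquely correct definition.

### Prediction of unphenotyped lines

`predict()` on a fit uses the conditional expectation
$\hat{u}_{new} = G_{new,train} G_{train,train}^{-1} \hat{u}_{train}$,
with a small recorded ridge if the training block resists inversion. The
algebraically identical joint-equations route
$\sigma^2_a G_{new,train} Z'P\mathbf{y}$ is implemented independently
(`method = "joint"`) and the two are required to agree to $10^{-8}$ in the
tests.

## 4. GWAS

The scan is a per-SNP ordinary least squares fit of the adjusted line mean
on an intercept, the first three genotype principal components (population
structure), and the SNP dosage, with a two-sided t test on the dosage
coefficient. It is implemented by Frisch–Waugh–Lovell residualisation, so
the whole scan is two matrix products. The reported $R^2$ is the partial
$R^2$ of the SNP term given the covariates, $t^2/(t^2 + \mathrm{df})$. PCA
centres dosages without scaling by default; unit-variance scaling is a
flag, since either convention is defensible and the choice is recorded.
A t test on the additive dosage term was adopted rather than a multi-df
genotype-factor F test; for additive coding they coincide.

Significance uses the Bonferroni threshold $-\log_{10}(\alpha/n)$ with
$\alpha = 0.05$ over the tested markers. Associated regions are delimited
around a significant peak: members are markers within half the physical
window (default 4 Mb, i.e. ±2 Mb; a flag widens to ±4 Mb) that are in LD
with the peak ($r^2 \ge 0.4$ by default — the bound is a package choice,
always recorded in the output) and supported by the scan
($-\log_{10} p > 5$, or themselves significant). A peak with no supporting
neighbours collapses to a zero-length region. Traits are scanned
independently with per-scan Bonferroni control only — no cross-trait
adjustment.

## 5. Smith–Hazel selection index

For traits $x$ with phenotypic covariance $P$ (computed over adjusted
means) and genetic covariance $G_c$ (over GEBVs), with economic weights
$a$ (all 1 by default), the index weights are $b = P^{-1} G_c a$ and the
per-line index is $I = b'x$ evaluated on the GEBVs. This $b$ maximises the
correlation between $I$ and the aggregate merit $a'g$; the tests verify
the exact 2-trait solutions and that the index beats 1,000 random weight
vectors on simulated multivariate-normal data. Near-singular $P$ can be
ridged by a recorded fraction of its mean diagonal. Ranking is descending
(most tolerant first); top-$k$ and bottom-$k$ classification breaks ties
lexicographically by line ID and records boundary ties. The index for
unphenotyped lines reuses $b$ estimated on the phenotyped set — weights are
never re-estimated from predictions.

Phenotypic values entering $P$ are adjusted means by construction of the
pipeline; raw line means can be supplied instead, since the definition of
"phenotypic values" is a modelling choice.

## 6. Cross-validation

Folds always partition *lines*, never individual plants — the prediction
target is the line's genetic value, and splitting a line's replicates
across folds would leak it. Plant-level input is first reduced to adjusted
means. Predictive ability is one Pearson correlation per repeat over the
*pooled* held-out predictions of all folds (not an average of per-fold
correlations), and the repeated-k-fold summary is the mean ± SE over
repeats. Variance components are re-estimated within every training fold by
default; a fixed-components fast mode exists for large runs. A single seed
drives all fold assignments, which are returned for audit. With $k = n$ and
one repeat, k-fold reduces to leave-one-out exactly (tested bitwise).

Prediction accuracy divides predictive ability by $\sqrt{h^2}$ using the
$h^2$ of the complete-data fit, never per-fold values; the sign of $r$ is
carried through.

## 7. The simulator: what it emulates, and what it does not

`simulate_magic_study()` generates the full study design with a known truth
set:

* **Founders.** Eight fully homozygous inbreds; seven drawn from a common
  allele-frequency spectrum and one from a diverged spectrum (each marker's
  frequency flipped with probability 0.5) to mimic a wild relative.
* **Population.** A balanced 8-way funnel (pairs, four-ways, final cross),
  founder order permuted per line, followed by 5 generations of
  single-seed-descent selfing. Meioses use the Haldane map function
  (no interference) on a uniform 1 cM/Mb map. Residual per-locus
  heterozygosity is the final-cross heterozygosity scaled by $2^{-5}$ in
  expectation, and each founder contributes ≈ 1/8 of the genome; both are
  tested against their Mendelian expectations. The real crossing scheme of
  any particular MAGIC population, line attrition, and selection during
  development are *not* reproduced — only the population class.
* **Trial.** Three sequential experiments; per experiment one stressed and
  one destructive baseline plant per phenotyped MAGIC line, three of each
  per parent (so 6 plants per MAGIC line and 18 per parent in total),
  completely randomised.
* **Traits.** Six drought traits (total DW, total DW growth, root DW,
  flavonol index, total WC, proline) with means, line-mean phenotypic SDs
  and heritabilities set to values typical of a water-stressed eggplant
  trial (e.g. total DW mean 4.75 g, h² 0.44; proline mean 108 µmol g⁻¹ DW,
  h² 0.31), a positive-definite genetic correlation matrix encoding the
  biomass/water-content antagonism, and residual-genetic shares of 0.30 to
  0.35 for the two traits modelled as imperfectly marker-tracked (flavonols
  and water content, matching the observation that most traits carry none).
  Causal markers are shared across traits with effects drawn multivariate
  normal; true breeding values are rescaled so the realised additive
  variance over lines matches the target exactly. `h2` in a trait
  configuration is the line-mean heritability
  $\sigma^2_a/(\sigma^2_a+\sigma^2_n+\sigma^2_e/3)$; with genomic
  information the Cullis $h^2$ estimator centres near this value, which is
  what the parameter-recovery test asserts (±0.1 over 20 replicates).
* **Raw records.** Organ weights are back-constructed from the trait
  targets — total DW split into leaf/stem/root (Dirichlet-like proportions
  centred on realistic ratios, root share clamped to [0.05, 0.6]), a single
  per-plant water content converting dry to fresh weight for every organ
  (which makes the aggregate WC reproduce the target exactly, at the cost
  of no organ-level WC variation), and baselines placed at final value
  minus the simulated growth (clamped at a small positive floor). The
  phenotype-derivation pipeline applied to these records reproduces the
  simulated targets, which is the end-to-end test of the phenotypes module.

What passing tests on this simulator shows — and does not show. The
generator produces clean MVN effects, no genotyping error, no
genotype-by-experiment interaction, balanced designs and exactly matched
baselines. Passing parameter-recovery, calibration and power tests under
these conditions validates the estimators and the machinery, not the
behaviour of the pipeline under field-data pathologies (outliers, missing
baselines, structured residuals).

## 8. Problem sizes and other fixed choices

The test suite runs the simulator at desk scale: 4 chromosomes × 500 SNPs
and 150–325 lines for the heavier checks, 20 replicate simulations for
parameter recovery (300 lines, 2,000 SNPs) and GWAS calibration/power (200
lines, 2,000 SNPs) — sizes at which the LD structure of a MAGIC population
is present but a full run stays in the minutes range. The acceptance script
uses the emulated trial scale itself: 325 lines, 184 phenotyped, 2,000
SNPs, 100 repeats of 5-fold cross-validation.

Known limitations: single-trait REML only (the index combines single-trait
fits); no dominance or epistatic kernels; no mixed-model (kinship-corrected)
GWAS — the scan relies on PC covariates, which under strong structure is
less conservative; the LD `r²` region bound (0.4) and the ±2 Mb window
interpretation are recorded package defaults rather than community
standards.
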