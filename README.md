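# magicgs

Genomic selection and association analysis for multi-parent advanced
generation inter-cross (MAGIC) populations evaluated under water stress.

## The problem

Drought tolerance in crops such as eggplant is polygenic and expensive to
phenotype: organ biomass requires destructive sampling, growth during a
stress period needs baseline plants, and trials span several sequential
experiments. Genomic selection sidesteps repeated phenotyping by training a
whole-genome prediction model on a phenotyped subset of a population and
predicting the breeding values of the rest from markers alone.

`magicgs` implements that workflow end to end for an inbred MAGIC
population genotyped with biallelic SNPs:

* **Genotypes** — VCF / dosage-CSV import, strict MAF filtering, distance
  thinning, and the VanRaden genomic relationship matrix (GRM)
  `G = W W' / (2 Σ pⱼ(1−pⱼ))` with column-centred dosages `W`.
* **Phenotypes** — derivation of drought traits from raw plant records:
  fresh-weight-based water content `100 (FW − DW)/FW`, organ aggregates,
  aerial/root ratio, growth against destructive same-experiment baselines,
  and the gravimetric field-capacity watering arithmetic.
* **GBLUP** — the mixed model `y = Xβ + Z u_a + Z u_n + e` with
  `u_a ~ N(0, σ²_a G)` (GEBVs), `u_n ~ N(0, σ²_n I)` (residual genetic
  effects) and fixed experiment effects, fitted by average-information REML
  with EM fallback; Cullis heritabilities `H² = 1 − PEV/σ²_g`,
  `h² = 1 − PEV/σ²_a`, genetic coefficients of variation, and prediction of
  unphenotyped lines via `u_new = G_{new,train} G⁻¹_{train} û`.
* **GWAS** — per-SNP general linear model with principal-component
  covariates, Bonferroni threshold `−log₁₀(α/n_SNPs)`, and LD-based
  (`r²`) delimitation of associated regions within a 4 Mb window.
* **Selection index** — Smith–Hazel weights `b = P⁻¹ G a` over a panel of
  drought traits, per-line index values `I = b'x`, tolerant/susceptible
  classification, genetic correlations and PCA of genetic values.
* **Cross-validation** — leave-one-out and repeated k-fold predictive
  ability (Pearson `r` of adjusted means vs predicted GEBVs) and prediction
  accuracy `r/√h²`.
* **Simulator** — a MAGIC population generator (8 founders including one
  divergent wild-relative, balanced funnel, Haldane recombination, selfing)
  with correlated traits, the full trial layout, and a known truth set, so
  the whole pipeline is testable without external data.

## Worked example

```r
library(magicgs)

cfg <- sim_config(seed = 7, n_magic_lines = 120, n_phenotyped = 80,
                  snps_per_chrom = 200)
sim <- simulate_magic_study(cfg)

gm  <- thin_markers(filter_maf(sim$genotypes, 0.04), 2000)
G   <- vanraden_grm(gm)
ph  <- derive_all_traits(sim$phenotypes)
fit <- gblup(ph[ph$role == "magic", ], G, trait = "total_dw")
print(fit)
```

```
GBLUP fit for trait 'total_dw'
  240 observations, 80 lines
  sigma_a^2 = 0.1302  sigma_n^2 = 0.1474  sigma_e^2 = 1.253
  H2 = 0.330  h2 = 0.000   REML logLik = -176.6322 (8 iterations)
```

The three variance components are the additive (marker-tracked), residual
genetic and residual variances of the plant-level model; `H2`/`h2` are the
Cullis heritabilities computed from the mean prediction error variance of
the total-genotypic and additive BLUPs. Cross-validated predictive ability
and accuracy:

```r
am <- adjusted_means(ph[ph$role == "magic", ], "total_dw")
loocv(am, G)
```

```
loocv cross-validation
  predictive ability r = 0.205
```

`prediction_accuracy(r, h2)` rescales predictive ability by `1/sqrt(h2)`;
for example `prediction_accuracy(0.24, 0.44)` is `0.36` (2 dp).

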