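# coexmeta

Cross-cohort persistence analysis for panel-based molecular abundance data.
Given feature-by-sample matrices from several case/control cohorts (the
motivating application is serum proteomics in PTSD cohorts scored with the
CAPS and PCL instruments), `coexmeta` asks which features are altered
*persistently* — supported at once by co-expression network structure,
per-cohort differential abundance, formal meta-analysis, and directional
agreement — and then characterizes the survivors by pathway
over-representation, activation scoring, and cis-pQTL mapping.

## The method

For each cohort an unsigned weighted network is built from the adjacency
`a_ij = |cor(x_i, x_j)|^β` (soft power β = 4) and transformed to the
topological overlap matrix

```
TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),
L_ij   = Σ_{u≠i,j} a_iu a_uj,   k_i = Σ_{u≠i} a_iu
```

The consensus network is the component-wise minimum of the cohort TOMs.
Modules (≥ 30 features) come from average-linkage clustering of 1 − TOM;
each is summarized by its eigengene (first principal component of the
standardized member profiles) and correlated with severity. Module
preservation in every other cohort is quantified by permutation Z scores
for density and connectivity, summarized as `Z_summary = median(Z_density,
Z_connectivity)` over 300 permutations (> 10 high, 5–10 moderate).

Differential abundance per cohort is OLS of the standardized feature on the
case indicator plus covariates. Cross-cohort evidence is combined two ways:
Stouffer's weighted Z (`w_k = √n_k`) with Benjamini–Yekutieli correction,
and a DerSimonian–Laird random-effects pool of Cohen's d with Cochran's Q
and τ². The **persistent set** is the intersection of four routes: members
of preserved and severity-correlated modules; training-cohort FDR q < 0.1;
meta-analytic support (Stouffer BY q < 0.05 or random-effects p < 0.05);
and an identical effect sign with p < 0.1 in every cohort.

Because the real cohort data this design targets are access-restricted, the
package ships a synthetic-data module that plants known truth — modules
driven by latent factors, case shifts with a sign-inconsistent fraction,
severity scores mapped into the printed CAPS/PCL ranges, and cis genetic
effects — so every stage can be validated against ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic fixture (three cohorts of 100/100, 500 features, three planted
modules of 100). Running them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
affected features: 60 (48 direction-consistent)
planted cis pairs: 5

$ Rscript analysis/02_network_modules.R
scale-free fit at power 4: 0.929 (power 1: 0.235)
detected 3 modules of sizes 100, 100, 100 with 200 unassigned features
modules correlated with severity at p < 0.01: ME1, ME2, ME3

$ Rscript analysis/03_preservation.R
cohort2: module 1 Z=14.1 (high); module 2 Z=20.8 (high); module 3 Z=12.4 (high)
cohort3: module 1 Z=18.9 (high); module 2 Z=15.5 (high); module 3 Z=12.3 (high)

$ Rscript analysis/04_diffmeta.R
features with Stouffer BY q < 0.05: 55
direction-consistent (p < 0.1 everywhere): 48
persistent set: 48 features; recall 1.00, precision 1.00 vs planted truth

$ Rscript analysis/05_enrichment.R
sets enriched at Bonferroni q < 0.05: planted_affected

$ Rscript analysis/06_pqtl.R
candidate cis pairs within 1 Mb: 1277
planted cis pairs recovered at q < 0.05: 5 of 5 (beta 0.88-1.09 vs planted 1.0)
```

Module detection recovers the planted partition exactly (ARI = 1), all
planted modules are highly preserved, the persistent set equals the 48
direction-consistent affected features, and all five planted cis effects
are recovered with estimated betas near the planted 1 SD per allele. The
same computations are available programmatically through `run_pipeline()`;
see the vignette in `vignettes/` for the model, its assumptions, and the
design decisions.

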