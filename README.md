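# structkit

Statistics for fine-scale population structure inferred from haplotype
sharing. When a cohort has been painted with a haplotype-copying model
(ChromoPainter-style chunklength matrices) and screened for pairwise
identity-by-descent (RefinedIBD-style segment lists), a set of bespoke
statistics turns those outputs into population-genetic conclusions:
are the inferred clusters real, where do ancestry components come from
geographically, and how old is the structure? `structkit` implements that
layer as a tested, reusable R package, together with a synthetic
structured-cohort generator so the whole pipeline can be exercised and
validated without access-controlled genotype data.

It is aimed at statistical and population geneticists working with
painting/IBD toolchains who need the downstream statistics — not the
painting, phasing or IBD detection themselves, which remain the job of the
dedicated tools whose output formats are read here.

## What it computes

**Cluster validation (TVD).** For clusters *A*, *B* with normalised copying
vectors *v_A*, *v_B* (average cM donated to members of a cluster by every
cluster, scaled to sum 1), total variation distance

> TVD(A, B) = ½ Σ_k | v_{A,k} − v_{B,k} | ∈ [0, 1]

measures distinctness in haplotype-sharing space (a `raw_l1` flag returns
the unhalved sum). Significance comes from permuting individuals between
the pair (preserving sizes) and recomputing: p = #(TVD\* ≥ TVD)/n_perm,
enumerated exhaustively when feasible. A TVD tree summarises cluster
relations by k−1 successive lowest-TVD merges with recomputation at every
step.

**Ancestry profiles (NNLS).** Each target's copying vector **Y**_p over G
donor groups is modelled as **Y**_p = β₁**X**₁ + … + β_G**X**_G with
**X**_g the donor groups' own average copying vectors, solved by
non-negative least squares with β ≥ 0, Σβ = 1; groups contributing < 5%
are pruned and the model refit. Country-aggregated shares are scanned over
compass bearings (0–359°, 1° steps) for the axis maximising the regression
r² — the direction of the ancestry gradient — and spatial autocorrelation
is quantified by Moran's I and a Mantel test, both with permutation
p-values.

**Time-stratified IBD.** Pairwise sharing matrices restricted to segment
length bins [L₁, L₂) cM are dated by the large-population closed form

> E[T] = 75 (1/L₁ + 1/L₂) generations,

converted to years at 28 years/generation; each binned matrix is clustered
by PCA plus a Gaussian mixture model with BIC model selection, and
within/between-group mean sharing uses the exact pair-count denominators
(N² − N)/2 and NM. A Monte-Carlo oracle (uniform coalescence times,
Erlang(2, t/50) segment lengths) independently validates the closed form.

**Confounding.** Nagelkerke pseudo-R² of a binary phenotype against
structure covariates (e.g. coancestry PCs) measures the stratification a
GWAS would inherit.

**Synthetic cohorts.** `scenario_config()`/`generate_cohort()` draw
cohorts with known truth: block-structured chunklength matrices with
spatial decay, Poisson/Erlang IBD with deme-dependent coalescence-time
distributions, linear spatial ancestry gradients, and deme-stratified
phenotypes — each from its own seed substream, byte-reproducible.

## Worked example

```r
library(structkit)

cfg <- scenario_config(seed = 42)     # 3 demes x 15 individuals
cohort <- generate_cohort(cfg)
#> Synthetic cohort: 45 individuals in 3 demes, 4827 IBD segments
clusters <- setNames(cohort$individuals$deme, cohort$individuals$id)

## are the demes distinct in haplotype-sharing space?
tvd_permutation_test(cohort$coancestry, clusters, "deme1", "deme2",
                     n_perm = 1000, seed = 1)
#> TVD(deme1, deme2) = 0.8286; p < 0.001 (0/1000 Monte Carlo permutations)

## ancestry mixtures and their geographic axis
profiles <- ancestry_profiles(cohort$targets, cohort$donor_matrix)
round(head(profiles, 3), 3)
#>          EAST  WEST  BASE
#> ind0001 0.369 0.425 0.206
#> ind0002 0.342 0.452 0.206
#> ind0003 0.355 0.458 0.187
gradient_axis_scan(profiles[, "EAST"], cohort$individuals)
#> Ancestry gradient: bearing 74 deg (N74E), r2 = 0.985, p = 8.83e-41

## dating a segment-length bin and clustering its sharing matrix
expected_tmrca(segment_bin(3, 5))
#> $generations
#> [1] 40
#> $years
#> [1] 1120
long_bin <- binned_sharing_matrix(cohort$ibd, segment_bin(5, 7),
                                  roster = cohort$individuals$id)
cl <- pca_gmm_cluster(long_bin, seed = 1)
mclust::adjustedRandIndex(cl$assignment, clusters)
#> [1] 0.7119476
```

The TVD of 0.83 with p < 0.001 says the two demes' copying vectors differ
far more than any permutation of their members; the profile rows are each
individual's mixture over the three synthetic ancestry sources (the EAST
share climbs along its injected 73° bearing, recovered here at 74° with
r² = 0.99); 3–5 cM segments date to 40 generations ≈ 1120 years; and the
5–7 cM sharing matrix clusters back onto the demes with adjusted Rand
index 0.71 (the long-bin signal; the 1–3 cM bin carries almost none by
design of this scenario).

## Documentation

The methods vignette (`vignettes/structure-statistics.Rmd`) describes the
models, their assumptions, the generator's design and its limits, and the
numerical choices. Every exported function carries full roxygen
documentation.
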