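---
title: "Haplotype-sharing statistics for fine-scale population structure: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-sharing statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`structkit` implements the statistics that sit *between* a haplotype
painting / IBD-detection toolchain and population-genetic conclusions.
This vignette explains each model, its assumptions and tunable parameters,
what the synthetic cohort generator does and does not emulate, and the
numerical and design choices made where conventions were genuinely open.

## 1. Copying vectors and total variation distance

A chunklength (coancestry) matrix records, for each recipient, the total
genetic map length (cM) donated by every other individual under a
haplotype-copying model. The copying vector of a cluster $A$ has one
component per cluster $k$: the mean over recipients $i \in A$ of the total
length donated to $i$ by the members of $k$. Donations from $A$'s own
members are included; only self-copying is excluded (the matrix diagonal is
structurally zero). After normalisation each vector is a probability
distribution over donor clusters, and cluster distinctness is the total
variation distance

$$\mathrm{TVD}(A,B) = \tfrac12 \sum_k |v_{A,k} - v_{B,k}| \in [0,1].$$

**The ½ factor.** The literature describes the statistic as the *sum* of
absolute differences; standard total variation distance is half that. We
return the metric (halved) convention so values live in $[0,1]$, and expose
`raw_l1 = TRUE` for the unhalved sum. The permutation p-value is invariant
to the choice, so nothing downstream depends on it.

**Permutation test.** Under the null that the pair's memberships are
arbitrary, individuals of $A \cup B$ are reassigned to pseudo-clusters of
the original sizes and the TVD recomputed. Memberships of all other
clusters are unchanged by this permutation, so only the components and
recipient sets touching $A$ and $B$ are recomputed (the result equals a
full recomputation; the restriction is purely for speed). The p-value is
the plain ratio $\#\{\mathrm{TVD}^* \ge \mathrm{TVD}\}/n_{\mathrm{perm}}$
with *greater than or equal* (the convention adopted here among the two
phrasings in circulation). When $\binom{|A|+|B|}{|A|} \le n_{\mathrm{perm}}$
all distinct memberships are enumerated, the observed one among them, so
exhaustive p-values are exact and strictly positive. In Monte-Carlo mode a
zero count is reported as $1/n_{\mathrm{perm}}$ ("less than"), never 0; an
optional add-one smoothing exists but is off by default to match the plain
ratio.

**A finite-size caveat.** Because recipients cannot copy from themselves,
a cluster's own column is computed over one fewer donor for its own members
than for outsiders. Even in a perfectly unstructured cohort this leaves a
residual TVD of order $1/(n-1)$ between equal-sized clusters — visible in
the generator's no-structure limit (≈ 0.02 at $n = 24$) and an order of
magnitude below any structured value. The permutation test is unaffected
(the bias is identical under every membership).

**TVD tree.** Cluster relations are summarised by $k-1$ successive merges
of the lowest-TVD pair, with copying vectors and TVD recomputed over the
reduced cluster set after every merge; the tree is therefore not
ultrametric and heights need not increase. Ties are broken by lexicographic
order of the joined label pair (the sources are silent; a deterministic
rule keeps output reproducible), and merged clusters are labelled by
joining their sorted leaf labels with `+`. Newick branch lengths are the
merge TVD values.

## 2. NNLS ancestry profiles

Each target's normalised copying vector $\mathbf{Y}_p$ over $G$ donor
groups is modelled as a mixture of the donor groups' own average copying
vectors $\mathbf{X}_g$ (rows of the donor copy matrix, each summing to 1,
including self-copying):

$$\mathbf{Y}_p = \beta_1\mathbf{X}_1 + \dots + \beta_G\mathbf{X}_G,
\qquad \beta_g \ge 0,\ \textstyle\sum_g \beta_g = 1.$$

The non-negative least squares problem is solved by Lawson–Hanson
(`pracma::lsqnonneg`) and the sum-to-one constraint enforced by post-hoc
renormalisation — the approach of the originating ancestry-profile
literature. An alternative penalty-row formulation (a heavily weighted
pseudo-observation forcing $\sum\beta = 1$ inside the solver) is provided;
the two agree to ~1e-3 on well-posed problems and a test asserts it.

**The 5% prune.** Groups contributing less than 5% are discarded and the
model refit "to eliminate noise". Whether the original rule was applied
per individual or cohort-wide, and whether the refit was iterated, is not
determinate; we implement a per-individual rule iterated to convergence
(drop all below-threshold groups, refit on survivors, repeat until every
retained share clears the threshold or one group remains). Per-individual
iteration is the strictly local reading of the rule and is idempotent.

**Conditioning.** Recovery error scales with the conditioning of the donor
copy matrix: with strongly distinct donor groups (diagonal ≈ 0.95) the
full fit recovers generator truth with mean L1 error ≈ 0.019 at target
noise sd 0.005 ($n = 200$, $G = 5$), while the generator's softer default
mixing (diagonal 0.7) roughly doubles that, ≈ 0.027. Profiles against
closely related donor groups should be interpreted accordingly.

## 3. Ancestry gradients and spatial autocorrelation

Geography is treated as the plane of longitude/latitude in raw degrees —
no great-circle or cos-latitude correction by default, matching the flat
treatment in the source analyses at country scale (a `cos_lat` flag applies
the correction). For each integer compass bearing $\theta \in
\{0,\dots,359\}$ the coordinates are projected on
$p_i = \mathrm{lon}_i \sin\theta + \mathrm{lat}_i \cos\theta$ and the share
regressed on $p$; the reported axis maximises $r^2$ among bearings with
positive slope, so it is the direction of *increasing* share ($\theta$ and
$\theta + 180$ have equal $r^2$ and opposite slopes). Bearings are compass
degrees clockwise from north; a quadrant formatter (e.g. `S66W`) is
display-only. Regression p-values are reported raw, not adjusted for
spatial autocorrelation — which is precisely why Moran's I and the Mantel
test accompany them.

Moran's I uses
$I = (n/S_0)\,\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ with centred values
$z$ and, by default, inverse Euclidean degree-distance weights with zero
diagonal (the sources do not state their weights; k-nearest-neighbour
(k = 5, symmetrised) and Gaussian-kernel alternatives are provided, and the
choice is recorded in the result). Coincident coordinates make
inverse-distance weights infinite and raise an error pointing at the knn
option. Significance is by permuting values over locations, two-sided
around the permutation mean. The Mantel test correlates upper triangles of
two distance matrices with one-sided joint row/column permutation
significance. Both default to 10,000 permutations; permutation p-values
carry the same $1/n_{\mathrm{perm}}$ floor as the TVD test. `ape::Moran.I`
and `vegan::mantel` serve as independent cross-checks of the observed
statistics in the test suite.

## 4. Length-binned IBD sharing and segment dating

IBD segment lengths carry time: longer segments coalesce more recently.
Sharing matrices restricted to a length bin $[L_1, L_2)$ cM are therefore
snapshots of structure at different time depths. Bins are half-open so a
partition of $(0,\infty)$ yields matrices summing exactly to the total
sharing matrix (the usual "1–3, 3–5, 5–7 cM" notation does not state
boundary handling; a test pins the convention).

**Dating.** Under a population large enough that the coalescence-time
prior is effectively flat, the expected coalescence time of segments with
length in the bin is

$$E[T \mid L_1 \le l < L_2] = 75\left(\frac{1}{L_1} + \frac{1}{L_2}\right)
\ \text{generations},$$

converted to years at 28 years per generation. The package returns pure
durations (years before present); anchoring to a calendar epoch (e.g. a
cohort's mean birth year) is left to the caller. Thus $[3,5)$ cM → 40
generations → 1120 years and $[5,7)$ → 25.71 → 720 years. Note that direct
substitution for $[1,3)$ gives 100 generations = 2800 years, whereas a
time depth of "~2700 years" is sometimes quoted for this bin; the rounding
or generation-time assumption behind the smaller figure is unstated, and
the package always reports the formula value.

**Why Erlang(2, t/50).** The closed form is exact when, conditional on
coalescence $t$ generations ago, segment length in cM is Erlang with shape
2 and rate $t/50$: with an (improper) flat prior on $t$, the posterior
density of $t$ given $l \in [L_1, L_2]$ is proportional to
$\int_{L_1}^{L_2} t^2\, l\, e^{-tl/50}\,dl$, whose mean evaluates to
$150\,\frac{1/L_1^2 - 1/L_2^2}{2(1/L_1 - 1/L_2)} = 75(1/L_1 + 1/L_2)$.
The generator uses exactly this length law, so the Monte-Carlo oracle
(`tmrca_mc_oracle`: $t \sim U(0, T_{\max})$, $l \sim$ Erlang(2, $t/50$))
must converge to the closed form; a 2% agreement at $10^6$ draws is
asserted, and $T_{\max} < 100 \cdot 50/L_1$ is rejected because truncating
the flat prior visibly biases the retained mean.

**Clustering.** Each binned matrix is projected on its leading principal
components — column-centred, unscaled, with each component's sign fixed so
its largest-magnitude loading is positive (whether the original analyses
centred rows, columns or both is unstated; column-centring is the default
convention of the painting toolchain's PCA utilities) — and clustered with
a Gaussian mixture over $k = 1..k_{\max}$ (default 9) and the covariance
families {diagonal `VVI`, full `VVV`}, selected by BIC via `mclust`. The
original analyses used `mclust`'s larger family search; two families keep
selection deterministic and cover the spherical-to-correlated range the
PC scores exhibit. Defaults: 10 PCs, deterministic hierarchical EM
initialisation.

**Group means.** Mean pairwise sharing uses the exact denominators:
$(N^2-N)/2$ within a group of size $N$, $NM$ between groups of sizes $N$
and $M$; a brute-force pair enumeration cross-checks it in the tests.
Within-group means for singleton groups are errors, not zeros. The count
statistic is the default for group means (the "mean number of segments"
phrasing) and total cM for matrices ("total length of IBD"); both are
available everywhere via a flag.

## 5. Phenotype confounding

Nagelkerke's pseudo-$R^2$,
$R^2 = \dfrac{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}}{1 - \exp\{(2/n)\ell_0\}}$,
compares intercept-only and covariate logistic fits of a binary phenotype.
Marginal (each covariate alone) and cumulative (left-to-right) values are
reported. Perfect separation makes the likelihood unbounded; `glm` may
stop before its own warning fires, so a perfectly classifying fit with
near-zero deviance is additionally flagged and $R^2$ capped at 1.

## 6. The synthetic cohort generator

The generator emulates the *statistical structure the downstream methods
consume*, not the biology that produces it:

* **Coancestry**: recipient rows have expectation proportional to
  $e^{-d_{ij}/\rho}(1 + \kappa\,[\text{same deme}])$ over donors, realised
  as a Dirichlet draw with concentration $\alpha \times$ expectation and
  scaled to the genome length (default 3500 cM). The Dirichlet-decay model
  is an artifact choice — no generative model for chunklengths is given in
  the source literature — chosen because it reproduces the features the
  statistics rely on: fixed row mass, within-deme blocks, distance decay
  and tunable row noise.
* **IBD**: per pair, event counts are Poisson (within/between rates), each
  event draws a coalescence time from a class Gamma (structured mode) or
  $U(0, T_{\max})$ (validation mode — the dating formula's own assumption;
  the two modes are never mixed), lengths are Erlang(2, $t/50$), and a
  detection floor (default 1 cM) discards short segments. Chromosomes are
  assigned proportionally to map length with uniform starts, at 1 cM = 1 Mb
  — real genetic maps are deliberately not modelled; synthetic segment
  files only need format validity.
* **Ancestry**: true shares follow `intercept + slope × projection` of
  centred coordinates on a per-source bearing, clipped at 0 and
  renormalised; targets mix the truth through the donor copy matrix plus
  optional clipped Gaussian noise. Projections are centred at the cohort
  centroid so intercepts are mean shares (raw lon/lat projections have
  magnitude ~50 at European latitudes). The default sources are two
  antipodal gradients of equal slope plus a flat background with intercepts
  summing to 1, making raw shares sum to 1 exactly, so the truth is exactly
  linear along the injected bearing and the recovery oracle is sharp.
* **Phenotype**: $P(\text{case} \mid \text{deme } d) =
  \mathrm{logit}^{-1}(b_0 + s_d)$.

A single master seed expands into fixed per-component substreams
(geography, coancestry, IBD, ancestry, phenotype), so regenerating one
component never shifts another's draws, and identical configuration + seed
reproduce the cohort byte for byte.

**Default scenario.** Three demes of 15 at Netherlands-like coordinates;
$\kappa = 8$, $\rho = 1.5°$, $\alpha = 100$; within-deme pairs share 8
expected events with recent coalescence (Gamma(4, 5), mean 20 generations)
and between-deme pairs 25 events with ancient coalescence (Gamma(8, 25),
mean 200 generations). These values realise the qualitative regime the
statistics target: long (> 7 cM) segments almost exclusively within demes,
short (1–3 cM) segments dominated by between-deme sharing, so long-bin
sharing matrices recover demes far better than short-bin ones — the
generator-level analogue of time-stratified structure. Null-calibration
scenarios instead use $\kappa = 0$ *and* a very large $\rho$: with
$\kappa = 0$ alone, isolation by distance persists and individuals are not
exchangeable.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage and the correlation between a pair's
segments (events are independent Poisson draws); genuine coalescent
genealogies (no shared ancestry across pairs, no variance inflation from
pedigree structure); phasing or detection error in IBD calls (the floor is
a hard threshold, real detectors lose power gradually and mis-estimate
lengths); painting noise correlated across recipients; non-planar
geography. Tests on generated cohorts validate the *statistics* —
calibration, recovery, exactness of arithmetic — under a model whose
assumptions they state; they do not validate the upstream inference tools.

## 7. Problem sizes and numerical choices in the test suite

The suite is sized to run comfortably on a single CPU: null calibrations
use 200 replicate cohorts of 10 individuals (permutation p-values
enumerated exhaustively over all 252 splits), the Monte-Carlo dating oracle
uses $10^6$ draws (standard error ≈ 0.25 generations on a mean of 40), the
NNLS/gradient recovery suite uses 200 individuals and 5 sources, and the
long-vs-short-bin comparison averages 20 replicate 45-individual cohorts.
Tolerances follow the quantity: exact arithmetic is asserted to machine
precision, closed-form values exactly, Monte-Carlo agreements within 2% or
3 binomial standard errors, and distributional calibration by KS or
chi-square at the 1% level.

Other conventions fixed for determinism: ids are case-sensitive exact
strings; cluster labels sort lexicographically; PCA has no randomness and a
fixed sign rule; all permutation procedures take explicit seeds; the
all-pairs TVD table derives per-pair seeds from the caller's seed.

## 8. Known limitations

* TVD carries the $1/(n-1)$ self-exclusion bias described above; comparing
  TVD between cluster pairs of very different sizes should rely on the
  permutation p-values, not raw TVD.
* The dating formula assumes a large, unstructured population and a flat
  time prior; in structured or recently expanded populations the per-bin
  expected ages are guides, not estimates with uncertainty. Bin-age
  distributions are wide.
* NNLS profiles are only as identifiable as the donor copy matrix is
  well-conditioned (section 2).
* The gradient scan fits a single global linear axis; curved or local
  gradients will be summarised, not captured.
* Moran's I and Mantel p-values are conditional on the chosen weight
  scheme; the default inverse-distance weights are one reasonable choice,
  recorded in the output.
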