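---
title: "Statistical epistasis networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical epistasis networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senet)
```

# The problem

Single-locus association scans explain only part of the heritability of
complex traits such as obesity. Statistical epistasis — a joint effect of
two SNPs on a phenotype beyond their independent effects — is one candidate
for the remainder, but an exhaustive pairwise scan of even a candidate-gene
panel produces hundreds of thousands of interaction scores that are hard to
interpret one at a time. `senet` implements a network view of such a scan:
SNPs become nodes, strongly interacting pairs become edges, and the global
and local structure of the resulting graph is what gets analyzed.

# The model

## Information-theoretic screening

For a SNP $A$ (a 3-level categorical variable: 0, 1 or 2 copies of the
minor allele) and a dichotomous phenotype $C$, the main effect is measured
by mutual information

$$I(A;C) = H(C) - H(C \mid A), \qquad
  H(X) = -\sum_x p(x)\log_2 p(x),$$

and the epistatic (synergistic) effect of a pair $(A, B)$ by the
information gain

$$IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C),$$

where $I(A,B;C)$ treats the pair as a single 9-level variable. $IG > 0$
indicates synergy: the pair explains more of the phenotype than its parts.
$IG < 0$ indicates redundancy (e.g. two SNPs in tight LD). A perfectly
balanced XOR relation attains $IG = 1$ bit; a duplicated, perfectly
predictive SNP attains $IG = -1$ bit. Both extremes are exact test cases
in the suite.

All estimators are maximum-likelihood plug-ins over contingency tables
(3×2 per SNP, 3×3×2 per pair), with no small-sample bias correction —
significance is assessed by permutation, not asymptotics, so the bias is
common to observed and null statistics. Genotypes are treated as unordered
categories, not dosages: pure epistasis lives in the full 3×3 table and
would be invisible to an additive encoding. Quantities are reported in
bits (log base 2) by default; `log_base = exp(1)` rescales to nats, which
changes every score and threshold by the constant factor $\ln 2$ and
nothing else.

`pairwise_ig_scan()` computes all $m(m-1)/2$ pair tables at once from two
indicator-matrix cross-products (one per phenotype class), so the scan is
a pair of BLAS calls plus block sums rather than an explicit pair loop.

## From scores to a network

`build_network()` keeps every pair with $IG$ strictly above a threshold;
nodes are the endpoints of surviving edges (node weight = MI, edge weight
= IG). Sweeping the threshold downward produces a nested series of
networks. The working threshold is the *percolation threshold*: the
largest threshold at which the largest connected component (LCC) first
exceeds half the nodes, after which connectivity grows rapidly.

Two choices here were genuinely open and are exposed as options:

* **Candidate thresholds.** Candidates are the midpoints between
  consecutive distinct IG values (plus one below the minimum). Every
  network realizable by any cutoff appears exactly once in the sweep, and
  the choice of strict versus non-strict comparison becomes immaterial.
* **"Half the nodes".** The default denominator is *all* scanned SNPs
  (`denominator = "all"`); the self-referential alternative — half the
  nodes present at that threshold — is nearly always satisfied by a
  two-node network and is provided (`"present"`) only for comparison.

## Permutation significance

Shuffling the phenotype vector destroys every genotype–phenotype
association while preserving the genotype correlation structure, giving an
exact null for MI, IG and whole-network statistics. For each of $R$
replicates the full scan is recomputed and networks are rebuilt *at the
fixed real-data thresholds*; upper-tail empirical p-values are reported as
$r/R$ with ties counted as exceedances (conservative) and displayed as
`"< 1/R"` when no null value reaches the observed one, matching the
`"<0.001"` convention at $R = 1000$. The $(r+1)/(R+1)$ variant is
available via `method = "add_one"`. Replicate seeds are fanned out from
one root seed by a counter scheme (`fan_seed()`), so results are invariant
to execution order and any replicate can be reproduced in isolation.

## Dyadicity and heterophilicity

Given a binary node property (here: membership of a gene), each edge is a
1–1, 1–0 or 0–0 dyad. With $n_1$ labels placed uniformly at random on $N$
slots in a graph with $M$ edges,

$$\bar m_{11} = M\,\frac{n_1(n_1-1)}{N(N-1)}, \qquad
  \bar m_{10} = M\,\frac{2 n_1 (N-n_1)}{N(N-1)},$$

and dyadicity and heterophilicity are the ratios $D = m_{11}/\bar m_{11}$,
$H = m_{10}/\bar m_{10}$. $D > 1$ means same-gene SNPs interact more than
chance; $H > 1$ means a gene's SNPs preferentially interact outside the
gene. Significance uses structure-preserving label permutation: the graph
and $n_1$ stay fixed, labels are reassigned uniformly, and the observed
dyad counts are compared with the permuted ones.

The **label universe** $N$ deserves a note. The obvious default is the
node set of the analyzed network (`universe = "network"`). But because
gene windows are padded (500 kb on each side by default) and may overlap,
a SNP can carry several gene labels, and a reference twelve-gene analysis
whose arithmetic this package reproduces exactly (see
`inst/extdata/obesity_gene_dyads.tsv`) uses $N = \sum_g n_1(g) = 2139$ —
the total number of gene-membership *slots*, nodes counted once per label
— with $M = 1241$. Both alternatives (`"snps"`, `"slots"`) are
implemented; analyses that must reproduce slot-based expectations should
pin $N$ explicitly rather than rely on the default.

The tail of the permutation test follows the observed deviation by
default (`alternative = "auto"`: upper for $D > 1$, lower for $D < 1$),
which mirrors how single per-gene p-values are usually reported. Note
that this adaptive choice doubles the null rejection rate relative to a
fixed tail; calibration experiments in the test suite therefore use
`alternative = "greater"`, for which the null distribution of the
empirical p-value is known exactly.

## Centrality report

Key SNPs in the LCC are ranked by degree, betweenness and closeness.
Paths are unweighted (hop counts): the interaction strengths are
evidence for edges, not distances. Betweenness is normalized by
$(n-1)(n-2)/2$ and closeness by $(n-1)/\sum_u d(v,u)$; raw values are
emitted alongside, since reported magnitudes in the literature (closeness
near 0.3 for networks of several hundred nodes) match the normalized
form. Ties are broken by node identifier so reports are deterministic. A
node appearing in all three top-5 lists is flagged as a candidate key
node.

# The data-preparation stages

* **BMI** = weight (kg) / height (m)²; *obese* is strictly BMI > 30, and
  a BMI of exactly 30 goes to the control side (the strict definition
  leaves the boundary unassigned; we close the gap conservatively).
* **Covariate adjustment**: a binomial GLM of obesity on age, age² and
  sex; individuals with positive deviance residual are cases. Since the
  sign of a binomial deviance residual equals the sign of
  $y - \hat p$, the classification is 100% concordant with the obese
  indicator whenever fitted probabilities stay inside (0, 1) — the
  concordance is recorded and checked rather than assumed.
* **MAF filter**: exclusion is strict (MAF < 0.05 removed), so a SNP at
  exactly 0.05 survives. Frequencies use non-missing calls only.
* **LD pruning**: greedy in genomic order — each surviving SNP removes
  every later same-chromosome SNP with dosage $r^2 > 0.8$. The victim
  choice ("the later SNP") is the deterministic, PLINK-like reading of
  "remove one of each pair". $r^2$ is composite (dosage correlation), as
  no phase information exists. Zero-variance SNPs get $r^2 = 0$ against
  all partners.
* **Mode imputation** replaces missing calls with the SNP's modal
  genotype; ties break toward the lowest dosage for determinism.
* **Order**: MAF filter, then LD pruning, then imputation — frequencies
  and $r^2$ are computed on observed calls, not imputed ones. Filters run
  after restriction to the candidate windows.
* **Coordinates** are 1-based fully closed throughout; BED input/output
  converts at the boundary. Gene windows are `[start − pad, end + pad]`
  with both edges included.

# The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate data with the statistical
structure the analysis assumes, so the whole pipeline is testable without
any external data. Study-scale defaults emulate the target design: 1141
individuals × 1191 SNPs across twelve gene windows (two of which overlap
after padding, so multi-label SNPs occur), MAF uniform on [0.05, 0.5],
ages uniform on 29–61 years.

* **LD** comes from a Gaussian copula: a latent AR(1) process within
  blocks (default correlation 0.95, block size 3, never spanning gene
  boundaries) thresholded at the Hardy–Weinberg quantiles of each SNP's
  MAF. This reproduces the $r^2$ structure the pruner must handle without
  haplotype machinery; it does not reproduce realistic human LD decay,
  allele-frequency spectra or imputation-panel artifacts.
* **Main effects** (default: five SNPs at 0.4 log-odds per minor allele,
  MAF 0.3 — the common-variant regime of reported BMI hits) enter an
  additive logistic model together with centered age, age² and sex terms
  (defaults 0.02, −5×10⁻⁴ and 0.3 on the log-odds scale, intercept 0 for
  a near-50/50 split).
* **Pure epistasis** uses XOR-style 3×3 penetrance tables
  (`xor_penetrance(0.6, 0.4)`) on SNP pairs fixed at MAF 0.5, where the
  genotype-weighted margins of the checkerboard are exactly uniform — so
  each SNP alone carries no information about the phenotype while the
  pair does. At other MAFs the same table leaks marginal effects, which
  is why the generator pins the pair SNPs' MAF rather than drawing it.
* **BMI** is drawn from overlapping normals (case ≈ N(33.5, 2), control
  ≈ N(26.5, 2)), and weight is derived from BMI and sex-specific height.
  About 4% of individuals fall on the "wrong" side of the 30 kg/m² cut,
  so dichotomization and covariate adjustment are exercised with
  realistic misclassification noise; embedded effect sizes downstream of
  the cut are attenuated accordingly, which the power settings below
  already absorb.
* The latent case status and case probabilities are attached as
  `attr(pheno, "sim_truth")` for validation, never used by the pipeline.

Passing tests on these cohorts demonstrates that the estimators,
thresholding, permutation and reporting machinery behave correctly under
the generator's assumptions (HWE, block LD, logistic covariates, XOR
epistasis); they do not certify performance on real genotype data with
its LD complexity, stratification or genotyping error.

# Problem sizes and numerical choices

The validation suite runs at deliberately reduced scales chosen so each
experiment isolates one property:

* estimator identities: 1000 random 3×3×2 tables against literal
  brute-force sums, agreement to 10⁻¹²;
* label-permutation mean identity: one 100-node / 300-edge graph,
  $n_1 = 30$, $R = 10{,}000$ assignments, within 3 Monte-Carlo SEs;
* null calibration: 50 random graphs (dyadicity) and pooled null cohorts
  of 500 individuals × 30 SNPs (IG), $R = 200$, rejection rate compared
  with the exact null rejection probability of the discrete empirical
  p-value, $(\lfloor \alpha R\rfloor + 1)/(R+1)$, within its 95% binomial
  interval;
* recovery: 20 cohorts of 2000 individuals × 60 SNPs with two embedded
  XOR pairs and three main-effect SNPs; the embedded pairs must top the
  scan in at least 16 of 20 seeds.

Other numerical conventions: probabilities entering `entropy()` must sum
to 1 within 10⁻⁹; mutual information is clipped at zero only within
10⁻¹² (larger negatives indicate a bug and are surfaced); empty networks,
degenerate labelings ($n_1 \in \{0, N\}$), constant phenotypes and
all-missing SNPs are explicit errors rather than silent NAs; component
ties resolve toward the lexicographically smallest member.

# Known limitations

* Plug-in estimators are biased upward at small $n$; all inference is
  permutation-based for exactly this reason, and reported MI/IG
  magnitudes should not be compared across very different sample sizes.
* Only pairwise interactions are scanned; three-way and higher
  decompositions are out of scope.
* The label-permutation null fixes the graph and randomizes labels
  uniformly; degree-preserving (configuration-model) nulls are not
  implemented.
* No multiple-testing correction is applied to per-SNP or per-pair
  permutation p-values — they are screening statistics, reported as-is.
* Betweenness/closeness are hop-count based; weighted variants are
  deliberately not offered.
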