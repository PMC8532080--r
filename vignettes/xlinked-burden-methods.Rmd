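---
title: "Methods: X-linked rare-variant burden testing with Firth regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-linked rare-variant burden testing with Firth regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlburden)
```

## The problem

X-linked recessive disease genes can be found in male case/control cohorts by
asking, gene by gene, whether cases are enriched for carriers of very rare,
functionally plausible variants. Men are hemizygous on the X chromosome, so a
single variant allele is a complete genotype and carriers can be counted
directly. Two statistical obstacles dominate the design:

* the carrier counts are tiny — often zero in one of the two groups — so
  ordinary logistic regression diverges under complete separation; and
* case/control cohorts assembled internationally differ systematically in
  age and ancestry, both of which must be adjusted for.

`xlburden` addresses both with a gene-level *collapsing* (burden) test: a
sample's rare qualifying variants in a gene are reduced to a binary carrier
indicator, and the indicator is tested against case status by a Firth
bias-corrected logistic likelihood-ratio test with ancestry principal
components and age as covariates.

## Model

For sample $i$ with covariate row $x_i$ (intercept, gene carrier indicator,
PC1–PC5, age in years) and case status $y_i \in \{0,1\}$, the logistic model
is $\pi_i = \operatorname{logit}^{-1}(x_i^\top \beta)$. Firth's correction
maximizes the penalized log-likelihood

$$
\ell^*(\beta) \;=\; \ell(\beta) + \tfrac{1}{2}\log\det I(\beta),
\qquad I(\beta) = X^\top W X,\; W = \mathrm{diag}\{\pi_i(1-\pi_i)\},
$$

the Jeffreys-prior penalty that keeps estimates finite even when carriers
occur only among cases (or only among controls). `fit_firth()` solves the
modified score equations

$$
U^*_j(\beta) \;=\; \sum_i \bigl(y_i - \pi_i + h_i(\tfrac12 - \pi_i)\bigr) x_{ij} = 0,
$$

with $h_i$ the hat-matrix diagonals of $W^{1/2}X(X^\top WX)^{-1}X^\top W^{1/2}$,
by Newton iteration from $\beta = 0$ with strict monotone step-halving
(up to 25 halvings per step). Convergence requires either the modified score
or the accepted Newton update to fall below `tol` (default $10^{-8}$) in
every coordinate, within `max_iter` (default 100) iterations; the tolerances
are package defaults, stated here because no canonical values exist. For an
intercept-plus-carrier design, the fit reproduces in closed form the log odds
ratio of the 2×2 carrier-by-status table with 0.5 added to every cell — a
useful exactness check that the test suite exercises, including on the
separated table (21, 1181, 0, 331).

### The likelihood-ratio test and its penalty

The per-gene test is a penalized likelihood-ratio test referred to
$\chi^2_1$. A genuinely open design question is what "the null model" means
under a penalized likelihood, and the two candidate constructions differ in a
way that matters:

* **Reduced-model penalty** — refit the design without the carrier column,
  each model keeping its own $\tfrac12\log\det I$. The penalty then differs
  *in dimension* between the two models, and the difference
  $\log\det I_{p+1} - \log\det I_p \approx \log(\text{information in the
  carrier column})$ inflates every statistic. In our null simulations
  (2,000 genes, carrier frequencies 0.5–3%) this construction rejected at
  0.12–0.13 under a nominal 0.05.
* **Profile (shared) penalty** — fit the null as the *same* design with the
  carrier coefficient constrained to zero, so both likelihoods carry the full
  design's penalty. This is the construction used by the established
  `logistf` implementation, and it measured 0.046 on the same simulations.

`xlburden` uses the profile construction (`firth_lrt(..., null_penalty =
"full")`, via `fit_firth(constrain=)`); the reduced-model variant remains
available as `null_penalty = "reduced"` for comparison. The test is two-sided
in the carrier coefficient.

### Multiple testing

A gene enters the family-wise correction only if at least
`min_case_carriers` (default 5) cases carry a qualifying variant; genes below
the bar are still fitted and reported but marked untested. The significance
threshold is $\alpha / n_\text{eligible}$ and corrected p-values are
$\min(1, p \cdot n_\text{eligible})$. With 226 eligible genes and
$\alpha = 0.05$ this is $2.2\times 10^{-4}$ to two significant figures.

## Qualifying variants and collapsing

A site qualifies when its population minor allele frequency is *strictly*
below `max_pop_maf` (default $10^{-4}$; variants absent from the reference
population qualify) and its consequence class is non-synonymous
(predicted loss-of-function, missense, or in-frame indel). Collapsing is
binary — carrying two qualifying variants of a gene counts once — with
CMC-style allele counting available as `mode = "count"`. A sample whose calls
are missing at every qualifying site of a gene is treated as a non-carrier
(conservative: it can only dilute a real signal) and the number of such
samples is reported per gene. The synonymous selection
(`selection_rule(control_mode = TRUE)`) is the negative control: rare
synonymous variants should show no enrichment, and their qualifying set is
disjoint from the primary one by construction.

## Quality control

Genotype-level filters run first, with strict inequalities on the published
boundaries: depth `< 8`×, genotype quality `< 20`, minor read ratio
`< 20%` where MRR is the less-covered allele's share of informative reads
(`min(ref, alt) / (ref + alt)`; boundary values 8, 20, 0.20 all pass).
Failing calls are **masked to missing**, GATK-style, rather than dropped, so
they count toward site-level missingness, which is recomputed before the site
filters run (the reverse order is available via
`site_filter_order = "site_first"` since the original order is not
documented anywhere authoritative).

Two deliberate interpretations:

* **MRR denominator** — informative reads (`ref + alt`), not DP; "total reads
  covering the position" is ambiguous when soft-clipped reads inflate DP.
* **MRR scope** — by default the MRR filter applies only to calls that carry
  the variant allele. A hemizygous (or homozygous-reference) call
  legitimately has all its reads on one allele; applying the ratio filter
  unconditionally would mask essentially every clean call on the male X.
  The filter's purpose is to flag unconvincing *variant* calls, whose read
  support is heterozygous-like under the diploid-style calling that upstream
  pipelines apply to chromosome X. `mrr_scope = "all_calls"` restores the
  literal reading.

Site-level filters, attributed in a fixed order (reference-population call
rate < 50%, non-PASS, decoy/low-complexity overlap, > 4 alleles, cohort
missingness > 20%, span > 20 nt), with boundary values passing. Decoy
regions come from a user-supplied BED (0-based half-open, read through
`rtracklayer`); no region list ships with the package. Every record is either
retained or attributed to exactly one removal reason, and `apply_qc()`
asserts the accounting internally.

## Ancestry covariates

The pipeline computes in-cohort genotype principal components rather than
projecting onto an external reference panel: the covariate's job is to absorb
case/control ancestry imbalance, which in-cohort structure captures, and a
reference panel is external data. (Externally computed scores can be supplied
as a TSV and used verbatim.) Variants enter the PCA when their in-cohort MAF
is strictly above 0.01 and call rate strictly above 0.99 after QC masking;
residual missing entries are mean-imputed. Columns are centered and scaled by
$\sqrt{\hat p(1-\hat p)}$ (the binomial standardization; unscaled PCA via
`scale = "none"`), scores are the top-$k$ left singular vectors scaled by the
singular values, and each component's sign is fixed so its largest-magnitude
loading is positive, making output deterministic. Five components are used by
default, matching common practice for ancestry adjustment.

## The synthetic cohort

The study's sequencing data are protected, so the package ships a generator
whose defaults are the study's published design: 1,202 male cases (age
truncated-normal, mean 52.9 y, SD 16.4) and 331 male controls (mean 38.7 y,
SD 17.2), a planted gene with exactly 21 case carriers and 0 control
carriers, and per-variant population MAFs log-uniform on
$[10^{-6}, 10^{-2}]$. Ages are truncated at 0.5 years (the youngest
published patient). Where the design is not published the defaults are the
package's own choices, stated here:

* 60 genes with Poisson(10) rare variants each, plus 150 common
  ancestry-informative variants — the per-gene rare-variant architecture of
  the real cohort is unpublished, and these sizes keep a full end-to-end run
  around a second while leaving every stage non-trivial;
* three ancestry strata (equal weights) with common-variant frequencies
  drawn Balding–Nichols with $F_{st} = 0.15$, enough differentiation that
  the first two PCs separate the strata;
* genotype noise: depth negative-binomial (mean 40, size 20), GQ normal
  (85, 10), carrier allelic balance Beta(25, 25) — heterozygous-like read
  support, as produced by diploid-style calling of hemizygous variants —
  plus small contamination rates (0.2% each) of low-depth, low-GQ,
  allele-imbalanced, and missing calls, and 2% of sites with elevated (40%)
  missingness, so every QC filter has work to do at the defaults;
* planted case carriers have their ages redrawn from the published index
  patients' own age distribution (truncated normal, mean 34.4 y, SD 17.5):
  a highly penetrant X-linked deficiency presents at markedly younger ages
  than the critical-disease cohort at large, and this age structure is what
  gives the age-adjusted test most of its signal. Setting
  `planted_age_mean = NULL` leaves carriers age-typical.

Planted carrier counts are exact, not expected: carriers are chosen by a
seeded shuffle of sample order, each receives one qualifying variant of the
planted gene (site chosen uniformly among its clean qualifying sites), other
carriers of those sites are cleared, and the planted calls' read metadata is
drawn conditional on passing genotype QC. Everything is a deterministic
function of the spec's seed, including the emitted files byte-for-byte.

What the generator does **not** emulate: linkage disequilibrium, relatedness,
sequencing-batch effects, genuinely continuous (admixed) ancestry, and any
correlation between QC failures and genotype. A passing test suite therefore
shows the machinery is correct under the stated sampling model, not that the
pipeline is robust to every artifact of real exomes.

### Calibration and power checks

Two simulation-based checks run in the test suite (seeds fixed; problem
sizes chosen to finish in about a minute each):

* **Power** — on 20 full-scale replicates of the planted design, the planted
  gene must rank first genome-wide and fall below the Bonferroni threshold
  in at least 95% of replicates. Its p-values land around $10^{-5}$–$10^{-3}$.
* **Type-I error** — 2,000 null genes with carrier probabilities drawn
  uniformly from 0.5–3%, the regime of genes that actually reach
  eligibility (at the generator's rare-MAF defaults the typical gene has
  0–2 carriers, where a $\chi^2$ calibration statement would be vacuous
  because nearly every p-value is 1). The rejection rate at $\alpha = 0.05$
  must sit inside the 95% binomial interval around 0.05.

## Reporter-activity classification

Functional allele classes come from NF-κB reporter activity expressed as a
percentage of the stimulated wild type (so classification is invariant to
the batch's raw luminescence scale): loss-of-function at or below `lof_max`,
hypomorphic strictly below `hypomorphic_max = 0.25` (the published "< 25%"
cutoff; 25.0% is neutral), neutral otherwise. No numeric LOF cutoff is
published; the default `lof_max = 0.05` operationalizes "indistinguishable
from the empty-vector control" and is exposed as a parameter. Replicates are
aggregated by mean. `cumulative_maf()` sums male allele frequencies over a
chosen class set — for an X-linked gene in males this approximates the
affected-genotype frequency — with deleterious = LOF ∪ hypomorphic, and a
strict-LOF mode that excludes hypomorphic alleles.

## Numerical and degenerate-input choices

* Genes whose carrier indicator is constant (no carriers after QC, or all
  samples carriers) get statistic 0 and p = 1 rather than a rank error.
* The LRT statistic is clipped at 0 before the $\chi^2$ tail.
* `penalized_loglik()` evaluates the binomial term in log space, so fitted
  probabilities numerically equal to 0 or 1 cannot overflow; the
  log-determinant uses a Cholesky factorization.
* PCA on a matrix with identical rows returns all-zero scores and zero
  explained variance instead of failing; `k` above the matrix rank is an
  error.
* Ties in QC attribution go to the first reason in the documented order, so
  removal counts always sum to the input count.
* Carrier ties in collapsing cannot occur (the indicator is binary), and
  duplicated qualifying-site records are de-duplicated before counting.

## Limitations

The test models a single binary collapse per gene; it has no variance-
component (SKAT-style) alternative, no diploid/female mode, and no
meta-analytic machinery. Eligibility counts case carriers only by default
(`count_in = "pooled"` is available). The Bonferroni family is defined by
the realized carrier matrix, so the threshold is data-dependent in the same
way as in the original design. p-values for genes with very few carriers are
conservative and discrete; they are reported but are not meaningful below
the resolution the carrier count allows.
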