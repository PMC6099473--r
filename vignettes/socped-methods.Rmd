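---
title: "Pedigree inbreeding, infidelity, and the faithful-pedigree counterfactual: methods"
author: "socped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree inbreeding, infidelity, and the faithful-pedigree counterfactual: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cooperatively breeding birds with helper sons and high female infidelity pose
a classic question: is extra-pair reproduction a mechanism of inbreeding
avoidance? Answering it needs four linked analyses on a multigenerational
genetic pedigree: (1) how common inbreeding is and by which kin routes it
arises; (2) whether inbreeding depresses offspring traits; (3) whether females
socially paired to relatives are more unfaithful; and (4) whether infidelity
actually lowers offspring inbreeding, quantified against a counterfactual
pedigree in which every female was faithful. `socped` implements all four
stages plus an agent-based generator of synthetic study populations with
recorded truth, so every estimator can be exercised against data whose
generating parameters are known.

# Pedigree machinery

The kinship coefficient $k(i,j)$ is the probability that one allele drawn
from $i$ and one from $j$ are identical by descent, and the inbreeding
coefficient of an individual is the kinship of its parents,
$f_X = k(\mathrm{sire}_X, \mathrm{dam}_X)$. We compute $k$ by the Malecot
recursion: the individual of greater generation depth is decomposed onto its
parents,
$k(i,j) = \tfrac12\,[k(i,\mathrm{sire}_j) + k(i,\mathrm{dam}_j)]$, with
$k(i,i) = \tfrac12 (1 + f_i)$. Generation depth is the topological rank from
founders (ties broken by record order), which guarantees the decomposed
individual is never an ancestor of the other. Conventions:

* Founders (records with no listed parents) are mutually unrelated and
  non-inbred. When only one parent is known, the unknown side contributes
  zero kinship, so $f = 0$ whenever either parent is missing. Such ids are
  identifiable through `known_grandparent_count()`.
* All values are finite sums of powers of $1/2$ and are computed exactly in
  double precision; classification as "inbred" uses $f > 10^{-12}$ purely to
  absorb float noise, which is conservative for dyadic rationals.
* Kinship category bounds are half-open on the upper side: high $\ge 0.25$,
  moderate $[0.125, 0.25)$, low $(0, 0.125)$.

Two independent routes verify the recursion. `relationship_matrix()` builds
the additive relationship matrix $A$ ($A_{ij} = 2k_{ij}$, diagonal $1+f$) by
the tabular method in topological order; the test suite asserts elementwise
agreement with the recursion to $10^{-9}$. `gene_drop_kinship()` transmits
founder-unique alleles down the pedigree by Monte Carlo Mendelian sampling
and estimates $k$ as the identity-by-descent fraction across replicates, with
a binomial standard error; it is assumption-free and used as a stochastic
oracle (agreement within 4 SE at $10^5$ replicates).

`restrict_pedigree(ped, m)` returns the ids with both parents known and at
least $m$ of the four grandparent slots resolvable, the completeness
restriction under which all individual-level summaries are reported. The set
is monotone decreasing in $m$, and because the individuals it removes are
mostly ones whose distant inbreeding is invisible (scored $f = 0$), the
apparent inbred fraction weakly rises with $m$.

# The synthetic-data generator

`simulate_population()` is an agent-based model of a fairy-wren-like social
system on a one-dimensional ring of territories (default 75 territories, 26
cohorts starting 1988). Each territory holds a dominant pair and a queue of
helper sons; yearly events are adult mortality, recruitment of last season's
independent fledglings (sons stay as helpers with probability 0.70 or float;
females always disperse), male vacancy filling (queue inheritance first, then
floaters or immigrants), female vacancy filling, and breeding.

Choices that define the study conditions:

* **Generative coefficients** are the field estimates for the emulated
  system: extra-pair log-odds intercept 0.47 with helper effects +0.53 (one
  helper) and +1.17 (two or more); nestling mass with inbreeding slope
  -3.64 g per unit $f$, male +0.15 g, brood-size -0.05 g per nestling,
  helper effects +0.09/+0.20 g, pre-1992 weighing-protocol offset +0.62 g,
  age slope 2.16 g/day at the raw scale with curvature -0.09; variance
  components nest 0.23, cohort 0.01, hatch interval 0.01, additive genetic
  0.10, residual 0.19 g^2; fledgling survival log-odds slope 0.33 per gram
  of day-7 mass. The survival intercept (-2.07) is set so survival at 7 g is
  about 56%, matching the observed mid-50s fledgling survival of the system.
* **Latent infidelity heterogeneity**: the extra-pair probability carries
  logit-scale random deviates for mother (variance 0.73), social father
  (0.71), cohort (0.02) and brood (1.85), the analogue of the random effects
  of a brood-level logit model. Without them the marginal extra-pair
  fraction overshoots the observed ~61%; with them it lands at 62-65%.
* **Mother-son social pairs** arise only by a helper inheriting dominance
  while his mother holds the female position; a widowed female departs
  instead with probability 0.75 (incest-avoidance dispersal), leaving
  roughly 3-4% of broods with mother-son social parents. Such pairs are
  completely unfaithful: the extra-pair probability is forced to 1, so they
  produce zero within-pair offspring at any seed.
* **Close-kin avoidance**: females never breed with their sons, their sire,
  or a full brother — the familiar nuclear-family kin a female can
  recognize. The maximum possible offspring $f$ is therefore 0.125 from
  named routes (up to 0.1875 when the parents are themselves inbred), and no
  $f = 0.25$ offspring can occur, matching the emulated system.
* **Open population**: 60% of female vacancies are settled by unrelated
  immigrants, and 30% of male vacancies without an heir go to immigrant
  males; locally hatched females settle with a geometric distance kernel
  (decay 0.4 per territory) away from their natal territory. Together these
  keep the inbred fraction in the observed few-percent range while
  maintaining local patrilines through male philopatry.
* **Extra-pair sires** are drawn uniformly from dominant males 2-10
  territories away (never a son of the mother, her sire, or a full brother),
  making all extra-pair paternity extra-group. With the settlement kernel
  this leaves extra-pair sires slightly less related to the mother than
  social partners are, so the faithful-pedigree contrast runs in the
  direction observed in such systems. The true distance kernel of extra-pair
  sires is unknown for the emulated system; the ring-uniform band is a
  stand-in, and `min_ep_distance`/`max_ep_distance` expose it.
* **Breeding**: 1-3 successful broods per female-year (probabilities
  0.5/0.4/0.1), clutches of 3-5 eggs (0.45/0.45/0.10), whole-clutch failure
  (predation) with probability 0.45, and a 5% per-nestling pre-measurement
  loss whose dependence on social-pair kinship (`early_loss_k_soc`, default
  0) exists to exercise the selective-disappearance checks. Hatch dates fall
  uniformly over 12 two-week intervals; measurement age is uniform on days
  5-8; cohorts before 1992 receive the protocol offset.
* **Additive genetics**: founder breeding values are drawn
  $N(0, V_A)$; offspring receive the midparent value plus a Mendelian
  sampling deviate with variance $(1 - (f_s + f_d)/2)\,V_A/2$.

A default run yields roughly 1700 observed broods and 6000 measured
nestlings, of which ~4600 pass the one-grandparent restriction — the scale
of a 26-year field study. Everything is reproducible from `params$seed`.

What the generator does **not** emulate: two-dimensional territory geometry
and true foray behavior, partial parentage assignment error, observation
gaps (all local parents are known), within-season renesting dynamics beyond
the brood-count distribution, and adult-trait inbreeding depression. Tests
passing on this generator therefore validate the estimators and the
pipeline, not the biology of any real population.

# Models

The brood-level infidelity model (`fit_epp_model()`) is a binomial GLMM with
response `(n_epo, n_wpo)` and fixed effects social-pair kinship, helper
class, mother age and social-father age, with random intercepts for mother,
social father, cohort, and brood. The brood term is an observation-level
random effect absorbing extra-binomial variation — the likelihood analogue
of the latent residual of a Bayesian logit model, and the reason the fitted
coefficients sit on the same latent scale as the generator's. Fits use
Laplace approximation (`lme4::glmer`); intervals are Wald. Non-convergence
and complete separation (unbounded Wald SEs) produce flagged fits rather
than errors. The companion `selective_disappearance_checks()` regress clutch
size and the clutch-to-brood survival proportion on social-pair kinship to
rule out inbreeding-driven early mortality masquerading as infidelity.

The nestling-mass animal model (`fit_mass_model()`) adds to the fixed
effects ($f$, helpers, brood size, sex, age, age$^2$, era) random intercepts
for nest, cohort and hatch interval, plus an additive genetic effect with
covariance $\sigma^2_A A$. Because the relationship matrix among ~4600
contemporaneous nestlings is dense (about a quarter of entries non-zero),
sparse mixed-model machinery is a poor fit; the package instead implements
average-information REML directly: scores
$-\tfrac12[\mathrm{tr}(PV_i) - y^\top P V_i P y]$ and the AI matrix
$\tfrac12\, y^\top P V_i P V_j P y$ drive Newton updates with step-halving,
a small positive floor on variances, and an active-set rule that pins
boundary components with negative gradients. All heavy operations are dense
BLAS calls, so one fit at $n \approx 4600$ takes about two minutes. Wald SEs
for fixed effects come from $(X^\top V^{-1} X)^{-1}$ and variance-component
SEs from the inverse AI matrix. Heritability is reported as
$V_A / \sum_i V_i$ (all components including residual). A variance component
estimated at the floor is flagged in `notes` but is not a convergence
failure. The same fixed-effect model without the animal term is available
through `lme4::lmer` and gives an unbiased (if differently weighted)
inbreeding coefficient in the generator's balanced designs; the animal term
matters for unbiasedness when additive variance is confounded with the
fixed effects and for estimating $h^2$ itself.

Fledgling survival (`fit_survival_model()`) is a binomial GLMM of survival
to independence on $f$, helpers, brood size and sex, optionally adding mass
adjusted to the day-7, current-era scale; comparing the $f$ coefficient with
and without the mass covariate separates direct from mass-mediated
inbreeding effects. The additive genetic term is omitted here: with a binary
response and the generator's survival model containing no direct additive
effect, it is not estimable at useful precision and is not needed for the
fixed-effect contrasts. `mass_adjustment()` residualizes mass using the age,
age$^2$ and era coefficients of the full fixed-effect mass model; a record
measured at day 7 in the current era is returned unchanged.

# Counterfactual and hurdle analyses

`build_faithful_pedigree()` replaces every assigned offspring's sire by its
social father, for all generations simultaneously, and re-validates the
result; the operation is idempotent. Kinship computed on this pedigree
answers "what would inbreeding have been had every female been faithful",
with substitution propagating through ancestors — our default, since the
comparison is about population-level relatedness. A one-generation variant
(`faithful_inbreeding(mode = "focal")`), where only the focal individual's
sire is swapped and ancestors keep their genetic links, is provided for
sensitivity analysis; it equals the kinship of social father and dam on the
observed pedigree.

`inbreeding_contrast()` cross-tabulates inbred/outbred status under the
observed and faithful pedigrees and by within-pair/extra-pair status;
`fisher_exact()` tests the 2x2 tables (two-sided, conditional-MLE odds
ratio; a zero margin returns p = 1 with the odds ratio flagged undefined).
Because pedigree $f$ is zero for ~94% of individuals, its dependence on
within-pair status is modelled as a hurdle (`fit_hurdle_inbreeding()`):
stage 1 is a binomial GLMM of inbred status on WP/EP status with nest and
cohort intercepts; stage 2 a linear mixed model of $\log f$ (natural log) on
the inbred subset. Offspring of mother-son social pairs are excluded by
default — their infidelity is forced, so they would bias both stages — and
helper number is deliberately not a covariate, because helpers affect
extra-pair rates and would confound the WP/EP contrast; `with_helpers`
re-enables it for sensitivity. Stage 2 requires at least 30 inbred
individuals and otherwise reports a diagnostic instead of a fit.

# Numerical and reporting conventions

Percentages in summary tables are rounded half-up to one decimal. The
pipeline (`run_pipeline()`) seeds all randomness once, captures stage errors
into the bundle instead of aborting, and writes machine-readable TSV/JSON
mirroring every number in the human-readable output. Model containers carry
`converged` and `notes`; singular variance components and separation are
flags, not exceptions.

# Problem sizes used in the tests

The test suite exercises the estimators at sizes chosen to keep the full
run in minutes while leaving Monte Carlo error well inside the asserted
bands: the shared default study (75 territories, 26 cohorts, one seed) for
calibration, recovery and counterfactual direction checks; a 25x10 study
for structural invariants; 100 replicates of a direct generative draw
(150 nests of 4) for Wald-CI coverage of the inbreeding coefficient, with
the acceptance band widened to the binomial error of 100 replicates
([0.88, 0.995] around the nominal 0.95); 50 replicates for the null
coverage of the infidelity model; and gene-drop checks at $10^5$ replicates
per pair.

# Known limitations

* The dense AI-REML animal model scales as $O(n^3)$ per iteration; beyond
  ~10,000 phenotyped individuals a sparse or subset strategy would be
  needed.
* Wald intervals are first-order; for variance components near zero they
  are unreliable, which is why boundary flags rather than interval
  statements are reported there.
* The faithful-pedigree contrast treats the social-father assignment as
  error-free, and the generator's spatial kin structure is a ring-world
  idealization: the direction of the observed-versus-faithful contrast is
  robust in simulation, but its magnitude should not be read as an estimate
  for any real population.
* Pedigree depth in the generator grows with breeder turnover, not with
  calendar time: in the limiting case of immortal adults no offspring ever
  recruits into a breeding position, so the pedigree stays shallow however
  long the simulation runs.
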