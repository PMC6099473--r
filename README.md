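# socped

Pedigree-based analysis of inbreeding, inbreeding depression, and infidelity
in cooperatively breeding birds.

## The problem

In socially monogamous birds with high female infidelity, extra-pair
paternity is often explained as inbreeding avoidance. Testing that idea
needs a multigenerational genetic pedigree and four linked analyses:

1. **How common is inbreeding, and by which kin routes?** The kinship
   coefficient k(i, j) — the probability that one allele drawn from each of
   two individuals is identical by descent — is computed by the Malecot
   recursion (k(i, j) = ½[k(i, sire_j) + k(i, dam_j)], founders unrelated,
   k(i, i) = ½(1 + f)), and an individual's inbreeding coefficient is the
   kinship of its parents, f = k(sire, dam).
2. **Does inbreeding depress offspring traits?** A linear mixed "animal
   model" of nestling mass with fixed effects f, helper class, brood size,
   sex, measurement age (+ age²) and a weighing-protocol era, and random
   effects for nest, cohort, hatch interval and an additive genetic term
   whose covariance is the pedigree relationship matrix A = 2K, fitted by
   average-information REML; plus binomial mixed models of fledgling
   survival with and without mass as a covariate.
3. **Are females paired to relatives more unfaithful?** Brood-level binomial
   mixed models of the (extra-pair, within-pair) offspring counts on
   social-pair kinship and helper number, run with and without the special
   class of mother–son social pairs, with selective-disappearance checks on
   clutch size and early survival.
4. **Does infidelity reduce inbreeding?** A counterfactual "faithful"
   pedigree in which every offspring's sire is replaced by its mother's
   social partner; observed-versus-faithful and within-pair-versus-extra-pair
   contingency tables with Fisher's exact tests; and a two-stage hurdle
   model of inbreeding status (binomial) and log f among the inbred.

Because the long-term datasets behind such studies are rarely public, the
package ships an agent-based simulator of the social system — helper queues
of sons, territory inheritance creating mother–son social pairs, obligate
female dispersal, an open population boundary, and ~60% extra-pair paternity
rising with helper number — with every generative parameter recorded, so all
estimators can be validated by parameter recovery. See the methods vignette
(`vignettes/socped-methods.Rmd`) for the model details and defaults.

## Worked example

```r
library(socped)

ped <- pedigree(
  id   = c("gm", "m1", "dau", "m2", "grandson"),
  sire = c(NA,   NA,   "m1", NA,   "m2"),
  dam  = c(NA,   NA,   "gm", NA,   "dau"),
  sex  = c("female", "male", "female", "male", "male"))
kinship(ped, "gm", "grandson")
#> kinship(gm, grandson) = 0.125
inbreeding(ped, "grandson")
#> f(grandson) = 0 [2 known grandparents]
```

A grandmother and grandson share an eighth of their genes by descent — were
they to pair socially and the female to stay faithful, their offspring would
have f = 0.125, the largest inbreeding coefficient such systems typically
show.

Simulating a full 26-cohort study population and summarizing it:

```r
study <- simulate_population(sim_params(seed = 42))
summarize_study(study)
#> broods: 1775  nestlings: 6168
#> unassisted broods: 57.1%
#> mother-son pairs:  3.2%
#> extra-pair offspring: 64.4%
#> broods with >=1 EPO:  87.2%
#> inbred fraction by restriction: min_gp_0=7.4%  min_gp_1=9.0%  min_gp_2=9.0%  min_gp_3=24.9%  min_gp_4=24.9%
```

About half the broods are raised by an unassisted pair, ~3% of broods have a
mother and her son as the social pair (all of their offspring are extra-pair
— the simulator enforces complete infidelity in that pairing), roughly
two-thirds of offspring are extra-pair, and under the one-known-grandparent
restriction ~9% of offspring are inbred; the inbred fraction rises under
tighter pedigree restrictions because the individuals excluded are mostly
ones whose distant inbreeding was invisible.

Does kinship to the social partner predict infidelity?

```r
fit_epp_model(study$broods, include_mother_son = TRUE)$coefficients[["k_soc"]]
#> kinship coefficient, mother-son pairs included:  15.94 CI [11.26, 20.62]
fit_epp_model(study$broods, include_mother_son = FALSE)$coefficients[["k_soc"]]
#> kinship coefficient, mother-son pairs excluded:  4.64 CI [-3.19, 12.48]
```

With mother–son pairs included, the kinship effect on the extra-pair
proportion is strongly positive; once they are excluded its confidence
interval spans zero — the kinship–infidelity relationship is driven entirely
by that special pairing class, exactly the signature this analysis is
designed to expose.

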