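#' Brood-level model of extra-pair paternity
#'
#' Fits a binomial mixed model of the proportion of extra-pair offspring in a
#' brood: response `(n_epo, n_wpo)`, fixed effects social-pair kinship,
#' helper class (reference 0), mother age and social-father age (reference
#' one-year-old), with random intercepts for mother, social father and
#' cohort. Optionally the kinship-by-helpers interaction is added, and broods
#' whose social pair is a mother and her son may be excluded (the convention
#' for testing whether a kinship effect survives outside that special class).
#'
#' @param broods data frame with columns `n_epo`, `n_wpo`, `k_soc`,
#'   `n_helpers` (`"0"`, `"1"`, `"2+"`), `mother_age`, `father_age`
#'   (`"1yo"`, `"older"`), `mother_id`, `social_father_id`, `cohort` and
#'   `is_mother_son`.
#' @param include_mother_son keep mother-son broods (default `TRUE`).
#' @param interaction add `k_soc` x helpers.
#' @return A `model_fit` (never an error for non-convergence: the fit is
#'   flagged via `converged`/`notes`).
#' @export
fit_epp_model <- function(broods, include_mother_son = TRUE,
                          interaction = FALSE) {
  if (!include_mother_son) {
    broods <- broods[!broods$is_mother_son, , drop = FALSE]
  }
  if (nrow(broods) < 30L) stop("need at least 30 broods")
  d <- epp_frame(broods)
  rhs <- "k_soc + n_helpers + mother_age + father_age"
  if (interaction) rhs <- paste(rhs, "+ k_soc:n_helpers")
  # (1 | nest_id) is a brood-level residual absorbing extra-binomial
  # variation, the likelihood analogue of the latent residual in a
  # logit-link brood model
  form <- as.formula(paste(
    "cbind(n_epo, n_wpo) ~", rhs,
    "+ (1 | mother_id) + (1 | social_father_id) + (1 | cohort) + (1 | nest_id)"))
  safe_fit(
    lme4::glmer(form, data = d, family = binomial,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    n_obs = nrow(d)
  )
}

epp_frame <- function(broods) {
  d <- broods
  d$n_helpers <- factor(d$n_helpers, levels = c("0", "1", "2+"))
  d$mother_age <- factor(d$mother_age, levels = c("1yo", "older"))
  d$father_age <- factor(d$father_age, levels = c("1yo", "older"))
  d$mother_id <- factor(d$mother_id)
  d$social_father_id <- factor(d$social_father_id)
  d$cohort <- factor(d$cohort)
  d
}

#' Selective-disappearance checks
#'
#' If inbred within-pair embryos die before sampling, broods of related social
#' pairs would look spuriously extra-pair. Two checks are fitted: (a) clutch
#' size on social-pair kinship with a cohort random intercept, and (b) the
#' binomial proportion surviving from clutch to measured brood on social-pair
#' kinship. A kinship effect near zero in both supports unbiased extra-pair
#' estimates.
#'
#' @param broods data frame with `clutch_size`, `brood_size`, `k_soc` and
#'   `cohort` columns.
#' @return List with elements `clutch_size` and `early_survival`, both
#'   `model_fit`s (degenerate inputs produce flagged fits, not errors).
#' @export
selective_disappearance_checks <- function(broods) {
  stopifnot(all(c("clutch_size", "brood_size", "k_soc") %in% names(broods)))
  d <- broods
  d$cohort <- factor(d$cohort)
  d$n_lost <- d$clutch_size - d$brood_size
  if (any(d$n_lost < 0)) stop("brood_size exceeds clutch_size")
  notes_a <- character(0)
  if (stats::var(d$clutch_size) == 0) notes_a <- "degenerate: constant clutch size"
  fit_a <- safe_fit(
    lme4::lmer(clutch_size ~ k_soc + (1 | cohort), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    n_obs = nrow(d), notes = notes_a)
  fit_b <- safe_fit(
    lme4::glmer(cbind(brood_size, n_lost) ~ k_soc + (1 | cohort),
                data = d, family = binomial,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    n_obs = nrow(d))
  list(clutch_size = fit_a, early_survival = fit_b)
}
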