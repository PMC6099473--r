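#' Animal model of inbreeding depression in nestling mass
#'
#' Linear mixed model of nestling mass with fixed effects inbreeding
#' coefficient, helper class, brood size, sex, measurement age (linear and
#' quadratic) and weighing-protocol era, and random intercepts for nest,
#' cohort and hatch interval. With `animal_term = TRUE` an additive genetic
#' effect is added whose covariance is the pedigree-derived relationship
#' matrix (fitted by REML through a Cholesky reparameterization), and the
#' narrow-sense heritability is reported as V_A over the sum of all variance
#' components including the residual.
#'
#' @param nestlings data frame with columns `id`, `nest_id`, `cohort`,
#'   `hatch_interval`, `sex`, `age_days`, `era`, `mass_g`, `f`, `n_helpers`,
#'   `brood_size`.
#' @param ped a [pedigree] covering all nestling ids (required when
#'   `animal_term`).
#' @param animal_term include the additive genetic effect.
#' @param interaction add the f-by-helpers interaction (retained in reporting
#'   only when significant).
#' @return A `model_fit`; when `animal_term` is on it carries a
#'   `heritability` element (estimate and all variance components).
#' @export
fit_mass_model <- function(nestlings, ped = NULL, animal_term = TRUE,
                           interaction = FALSE) {
  if (nrow(nestlings) < 200L) stop("need at least 200 nestlings")
  d <- nestling_frame(nestlings)
  if (stats::var(d$f) == 0) {
    return(new_model_fit(NULL, nrow(d), notes = "degenerate: f is constant"))
  }
  rhs <- "f + n_helpers + brood_size + sex + age_days + I(age_days^2) + era"
  if (interaction) rhs <- paste(rhs, "+ f:n_helpers")
  re <- "(1 | nest_id) + (1 | cohort) + (1 | hatch_interval)"
  if (animal_term) {
    if (is.null(ped)) stop("animal_term requires a pedigree")
    mm <- stats::model.matrix(as.formula(paste("~", rhs)), d)
    A <- relationship_matrix(ped, d$id)
    raw <- tryCatch(
      aireml(d$mass_g, mm,
             groups = list(nest = d$nest_id, cohort = d$cohort,
                           hatch_interval = d$hatch_interval),
             covmats = list(animal = A)),
      error = function(e) e)
    if (inherits(raw, "error")) {
      return(new_model_fit(NULL, nrow(d),
                           notes = paste0("fit_error: ",
                                          conditionMessage(raw))))
    }
    out <- aireml_model_fit(raw, n_obs = nrow(d))
    vc <- out$variance_components
    out$heritability <- c(h2 = unname(vc[["animal"]] / sum(vc)))
    out
  } else {
    form <- as.formula(paste("mass_g ~", rhs, "+", re))
    safe_fit(lme4::lmer(form, data = d), n_obs = nrow(d))
  }
}

nestling_frame <- function(nestlings) {
  d <- nestlings
  d$n_helpers <- factor(d$n_helpers, levels = c("0", "1", "2+"))
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$era <- factor(d$era, levels = c("1992+", "pre-1992"))
  d$nest_id <- factor(d$nest_id)
  d$cohort <- factor(d$cohort)
  d$hatch_interval <- factor(d$hatch_interval)
  if ("ep_status" %in% names(d)) d$ep_status <- factor(d$ep_status,
                                                       levels = c("EP", "WP"))
  d
}

#' Mixed model of fledgling survival
#'
#' Binomial mixed model of survival to independence with fixed effects
#' inbreeding coefficient, helper class, brood size and sex, optionally
#' adding nestling mass adjusted to the day-7, current-era scale (to test
#' whether any inbreeding effect on survival is mediated by mass), and random
#' intercepts for nest, cohort and hatch interval.
#'
#' @inheritParams fit_mass_model
#' @param with_mass include adjusted mass as a covariate (see
#'   [mass_adjustment()]).
#' @param interaction add the f-by-helpers interaction.
#' @return A `model_fit`; complete separation (e.g. all survivors) yields a
#'   flagged fit.
#' @export
fit_survival_model <- function(nestlings, with_mass = FALSE,
                               interaction = FALSE) {
  if (nrow(nestlings) < 200L) stop("need at least 200 fledglings")
  d <- nestling_frame(nestlings)
  notes <- character(0)
  if (length(unique(d$survived)) == 1L) {
    return(new_model_fit(NULL, nrow(d),
                         notes = "separation: survival outcome is constant"))
  }
  rhs <- "f + n_helpers + brood_size + sex"
  if (with_mass) {
    d$mass_adj <- mass_adjustment(nestlings)
    rhs <- paste(rhs, "+ mass_adj")
  }
  if (interaction) rhs <- paste(rhs, "+ f:n_helpers")
  form <- as.formula(paste(
    "survived ~", rhs,
    "+ (1 | nest_id) + (1 | cohort) + (1 | hatch_interval)"))
  safe_fit(
    lme4::glmer(form, data = d, family = binomial,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    n_obs = nrow(d), notes = notes)
}

#' Adjust nestling mass to the day-7, current-era scale
#'
#' Residualizes measured mass for measurement age (linear and quadratic
#' around day 7) and the pre-1992 weighing-protocol offset, using the age and
#' era coefficients of the full nestling-mass fixed-effect model (without the
#' additive genetic term, which does not alter fixed-effect definitions).
#' A record measured at day 7 in the 1992+ era is returned unchanged up to
#' the model's intercept convention.
#'
#' @param nestlings data frame as in [fit_mass_model()].
#' @return Numeric vector of adjusted masses, aligned with `nestlings` rows.
#' @export
mass_adjustment <- function(nestlings) {
  stopifnot(all(c("mass_g", "age_days", "era") %in% names(nestlings)))
  d <- nestling_frame(nestlings)
  fit <- lme4::lmer(
    mass_g ~ f + n_helpers + brood_size + sex + age_days + I(age_days^2) +
      era + (1 | nest_id) + (1 | cohort) + (1 | hatch_interval),
    data = d)
  b <- lme4::fixef(fit)
  age_part <- b[["age_days"]] * (d$age_days - 7) +
    b[["I(age_days^2)"]] * (d$age_days^2 - 49)
  era_part <- b[["erapre-1992"]] * (d$era == "pre-1992")
  d$mass_g - age_part - era_part
}
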