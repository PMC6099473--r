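test_that("mass model without the animal term recovers the f effect", {
  ne <- default_restricted()
  fit <- fit_mass_model(ne, animal_term = FALSE)
  expect_true(fit$converged)
  truth <- -3.64
  expect_lt(abs(fit$coefficients[["f"]] - truth), 3 * fit$se[["f"]])
  # the age slope at the raw scale implied by the generator: 2.16 g/day
  expect_lt(abs(fit$coefficients[["age_days"]] - 2.16),
            3 * fit$se[["age_days"]])
  expect_error(fit_mass_model(ne[1:50, ], animal_term = FALSE),
               "at least 200")
})

test_that("animal model estimates f, variance components and heritability", {
  st <- small_study()
  ne <- restricted_nestlings(st)
  fit <- fit_mass_model(ne, st$pedigree, animal_term = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["f"]] + 3.64), 3 * fit$se[["f"]])
  vc <- fit$variance_components
  expect_named(vc, c("nest", "cohort", "hatch_interval", "animal", "Residual"))
  expect_true(all(vc >= 0))
  expect_gt(fit$heritability[["h2"]], 0)
  expect_lt(fit$heritability[["h2"]], 0.6)
  # nest variance dominates among the grouped components, as generated
  expect_gt(vc[["nest"]], vc[["cohort"]])
  # no-animal specification estimates a compatible f (unbiasedness check)
  plain <- fit_mass_model(ne, animal_term = FALSE)
  expect_lt(abs(plain$coefficients[["f"]] - fit$coefficients[["f"]]),
            2 * max(plain$se[["f"]], fit$se[["f"]]))
})

test_that("zero additive variance is recovered as near-zero heritability", {
  p <- small_params(seed = 303L)
  p$mass_vc[["additive"]] <- 0
  st <- simulate_population(p)
  ne <- restricted_nestlings(st)
  fit <- fit_mass_model(ne, st$pedigree, animal_term = TRUE)
  expect_lt(fit$heritability[["h2"]], 0.08)
  # constant f is flagged, not fitted
  ne0 <- ne
  ne0$f <- 0
  flagged <- fit_mass_model(ne0, st$pedigree, animal_term = FALSE)
  expect_false(flagged$converged)
  expect_match(paste(flagged$notes, collapse = " "), "constant")
})

test_that("Wald CIs for the f coefficient attain near-nominal coverage", {
  set.seed(2024)
  reps <- 100
  hits <- 0L
  for (r in seq_len(reps)) {
    ne <- make_nestlings(n_nests = 150)
    fit <- fit_mass_model(ne, animal_term = FALSE)
    ci <- fit$ci["f", ]
    hits <- hits + as.integer(ci[1] < -3.64 && ci[2] > -3.64)
  }
  expect_gte(hits / reps, 0.88)
  expect_lte(hits / reps, 0.995)
})

test_that("survival depends on mass, not directly on f, as generated", {
  ne <- default_restricted()
  without_mass <- fit_survival_model(ne, with_mass = FALSE)
  with_mass <- fit_survival_model(ne, with_mass = TRUE)
  expect_true(with_mass$converged)
  # mass coefficient CI covers the generating log-odds slope 0.33
  expect_lt(with_mass$ci["mass_adj", "lower"], 0.33)
  expect_gt(with_mass$ci["mass_adj", "upper"], 0.33)
  expect_gt(with_mass$coefficients[["mass_adj"]], 0)
  # no direct f effect was generated: CI spans zero in both models
  for (fit in list(without_mass, with_mass)) {
    expect_lt(fit$ci["f", "lower"], 0)
    expect_gt(fit$ci["f", "upper"], 0)
  }
})

test_that("a mass-mediated f effect attenuates when mass is adjusted for", {
  set.seed(555)
  ne <- make_nestlings(n_nests = 500, f_coef = -8, p_inbred = 0.2,
                       sd_resid = sqrt(0.2))
  # survival purely through mass on the day-7 scale
  mass7 <- ne$mass_g - 0.9 * (ne$age_days - 7) + 0.09 * (ne$age_days - 7)^2 -
    0.62 * (ne$era == "pre-1992")
  ne$survived <- runif(nrow(ne)) < plogis(-7 + 1 * mass7)
  without_mass <- fit_survival_model(ne, with_mass = FALSE)
  with_mass <- fit_survival_model(ne, with_mass = TRUE)
  expect_lt(without_mass$coefficients[["f"]], 0)
  expect_lt(abs(with_mass$coefficients[["f"]]),
            0.5 * abs(without_mass$coefficients[["f"]]))
})

test_that("constant survival outcomes are flagged as separation", {
  ne <- make_nestlings(n_nests = 100)
  ne$survived <- TRUE
  fit <- fit_survival_model(ne)
  expect_false(fit$converged)
  expect_match(paste(fit$notes, collapse = " "), "separation")
})

test_that("mass adjustment standardizes to day 7 and the current era", {
  ne <- default_restricted()
  adj <- mass_adjustment(ne)
  # records already at day 7 in the 1992+ era are unchanged
  base <- ne$age_days == 7 & ne$era == "1992+"
  expect_true(any(base))
  expect_equal(adj[base], ne$mass_g[base])
  # era difference is removed up to estimation error of the era coefficient
  pre <- ne$era == "pre-1992"
  raw_gap <- mean(ne$mass_g[pre] - 0.9 * (ne$age_days[pre] - 7) +
                    0.09 * (ne$age_days[pre] - 7)^2) -
    mean(ne$mass_g[!pre] - 0.9 * (ne$age_days[!pre] - 7) +
           0.09 * (ne$age_days[!pre] - 7)^2)
  adj_gap <- mean(adj[pre]) - mean(adj[!pre])
  expect_lt(abs(adj_gap), abs(raw_gap))
})

test_that("adjusted means differ by the predicted inbreeding depression", {
  set.seed(777)
  ne2 <- make_nestlings(n_nests = 600, p_inbred = 0)
  ne2$f <- rep(c(0, 0.125), length.out = nrow(ne2))
  ne2$mass_g <- ne2$mass_g - 3.64 * ne2$f
  adj <- mass_adjustment(ne2)
  gap <- mean(adj[ne2$f == 0]) - mean(adj[ne2$f == 0.125])
  expect_lt(abs(gap - 0.455), 0.12)
})
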