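test_that("kinship effect on infidelity is driven by mother-son pairs", {
  br <- default_study()$broods
  with_ms <- fit_epp_model(br, include_mother_son = TRUE)
  without_ms <- fit_epp_model(br, include_mother_son = FALSE)
  expect_true(with_ms$converged)
  expect_true(without_ms$converged)
  # including the forced-infidelity stratum: positive, significant kinship
  expect_gt(with_ms$coefficients[["k_soc"]], 0)
  expect_gt(with_ms$ci["k_soc", "lower"], 0)
  # excluding it: the kinship CI spans zero (no population-wide relationship)
  expect_lt(without_ms$ci["k_soc", "lower"], 0)
  expect_gt(without_ms$ci["k_soc", "upper"], 0)
  # helper effects recover the generating log-odds 0.53 and 1.17
  # (single realization: allow 3.5 Wald SEs around the truth)
  for (fit in list(with_ms, without_ms)) {
    expect_lt(abs(fit$coefficients[["n_helpers1"]] - 0.53),
              3.5 * fit$se[["n_helpers1"]])
    expect_lt(abs(fit$coefficients[["n_helpers2+"]] - 1.17),
              3.5 * fit$se[["n_helpers2+"]])
    expect_gt(fit$coefficients[["n_helpers2+"]],
              fit$coefficients[["n_helpers1"]])
  }
  # removing the only all-EPO-forced stratum never inflates the kinship effect
  expect_lte(abs(without_ms$coefficients[["k_soc"]]),
             abs(with_ms$coefficients[["k_soc"]]))
  expect_error(fit_epp_model(br[1:10, ]), "at least 30")
})

# direct generative broods with known (zero) fixed effects
make_null_broods <- function(n = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bsz <- sample(3:5, n, replace = TRUE)
  mothers <- sprintf("F%03d", sample(60, n, replace = TRUE))
  fathers <- sprintf("M%03d", sample(60, n, replace = TRUE))
  k <- ifelse(runif(n) < 0.1, sample(c(0.03125, 0.0625, 0.125), n, TRUE), 0)
  epo <- rbinom(n, bsz, 0.5)
  data.frame(nest_id = sprintf("N%04d", seq_len(n)),
             mother_id = mothers, social_father_id = fathers,
             cohort = sample(1990:1999, n, TRUE),
             n_helpers = sample(c("0", "1", "2+"), n, TRUE),
             n_epo = epo, n_wpo = bsz - epo, brood_size = bsz,
             k_soc = k, is_mother_son = FALSE,
             mother_age = sample(c("1yo", "older"), n, TRUE),
             father_age = sample(c("1yo", "older"), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("null data yield near-nominal CI coverage for all fixed effects", {
  set.seed(1234)
  reps <- 50
  covered <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    fit <- suppressMessages(fit_epp_model(make_null_broods(130)))
    if (!length(fit$coefficients)) next
    terms <- setdiff(names(fit$coefficients), "(Intercept)")
    covered <- covered + sum(fit$ci[terms, "lower"] < 0 &
                               fit$ci[terms, "upper"] > 0)
    total <- total + length(terms)
  }
  expect_gt(total, 200)
  expect_gte(covered / total, 0.85)
})

test_that("permuting kinship centres its coefficient distribution on zero", {
  br <- small_study()$broods
  br <- br[!br$is_mother_son, ]
  set.seed(99)
  est <- replicate(15, {
    br$k_soc <- sample(br$k_soc)
    fit <- fit_epp_model(br)
    c(fit$coefficients[["k_soc"]],
      fit$ci["k_soc", "lower"] < 0 & fit$ci["k_soc", "upper"] > 0)
  })
  expect_gte(mean(est[2, ]), 0.8)           # CIs almost always cover zero
  expect_lt(abs(mean(est[1, ])), 2 * sd(est[1, ]))
})

test_that("selective disappearance checks are null without a mechanism", {
  br <- default_study()$broods
  chk <- selective_disappearance_checks(br)
  for (fit in list(chk$clutch_size, chk$early_survival)) {
    expect_lt(fit$ci["k_soc", "lower"], 0)
    expect_gt(fit$ci["k_soc", "upper"], 0)
  }
})

test_that("injected early inbreeding mortality is detected", {
  p <- sim_params(n_territories = 75L, n_years = 20L, seed = 404L,
                  early_loss_k_soc = 25)
  st <- simulate_population(p)
  expect_gt(nrow(st$broods), 900)
  chk <- selective_disappearance_checks(st$broods)
  expect_lt(chk$early_survival$coefficients[["k_soc"]], 0)
  expect_lt(chk$early_survival$ci["k_soc", "upper"], 0)
})

test_that("degenerate clutch data are flagged, not fatal", {
  br <- make_null_broods(60, seed = 5)
  br$clutch_size <- 4L
  br$brood_size <- pmin(br$brood_size, 4L)
  br$n_epo <- pmin(br$n_epo, br$brood_size)
  br$n_wpo <- br$brood_size - br$n_epo
  chk <- selective_disappearance_checks(br)
  expect_match(paste(chk$clutch_size$notes, collapse = " "), "degenerate")
  br$brood_size <- br$clutch_size + 1L
  expect_error(selective_disappearance_checks(br), "exceeds")
})
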