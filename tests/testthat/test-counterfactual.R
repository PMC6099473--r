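test_that("faithful pedigree substitutes sires with social fathers", {
  ms <- mother_son_ped()
  # O is an extra-pair offspring whose social father is the son S
  asg <- data.frame(offspring_id = "O", social_father_id = "S",
                    genetic_father_id = "X", ep_status = "EP")
  faithful <- build_faithful_pedigree(ms, asg)
  expect_identical(unname(inbreeding(faithful, "O")$f), 0.25)
  expect_identical(unname(inbreeding(ms, "O")$f), 0)
  # identity when the social father already is the genetic father
  asg2 <- data.frame(offspring_id = "S", social_father_id = "F0")
  same <- build_faithful_pedigree(ms, asg2)
  expect_identical(same$records, ms$records)
  expect_error(build_faithful_pedigree(ms, data.frame(
    offspring_id = "ZZZ", social_father_id = "S")), "absent")
})

test_that("focal-mode faithful inbreeding equals observed-pedigree kinship", {
  ms <- mother_son_ped()
  asg <- data.frame(offspring_id = "O", social_father_id = "S")
  f_focal <- faithful_inbreeding(ms, asg, "O", mode = "focal")
  expect_identical(unname(f_focal), unname(kinship(ms, "S", "M")$kinship))
})

test_that("faithful-pedigree construction is idempotent", {
  st <- small_study()
  ne <- st$nestlings
  asg <- data.frame(offspring_id = ne$id,
                    social_father_id = ne$social_father_id)
  f1 <- build_faithful_pedigree(st$pedigree, asg)
  f2 <- build_faithful_pedigree(f1, asg)
  expect_identical(f1$records, f2$records)
})

test_that("infidelity reduces inbreeding in the simulated population", {
  st <- default_study()
  ne <- restricted_nestlings(st)
  asg <- data.frame(offspring_id = st$nestlings$id,
                    social_father_id = st$nestlings$social_father_id)
  faithful <- build_faithful_pedigree(st$pedigree, asg)
  ct <- inbreeding_contrast(st$pedigree, faithful, ne$id,
                            ep_status = ne$ep_status)
  cells <- ct$observed_vs_faithful$cells
  expect_gte(cells["faithful", "inbred"], cells["observed", "inbred"])
  expect_true(all(ct$f_faithful >= 0))
  # margin identities
  expect_equal(unname(rowSums(cells)), rep(length(ne$id), 2))
  expect_equal(sum(ct$wp_ep$cells), length(ne$id))
})

test_that("zero extra-pair paternity makes faithful equal observed", {
  p <- small_params(seed = 305L,
                    epp_logit = c(intercept = -30, helper1 = 0,
                                  helper2plus = 0),
                    epp_vc = c(mother = 0, father = 0, cohort = 0, brood = 0),
                    widow_departure_prob = 1)
  st <- simulate_population(p)
  expect_identical(sum(st$broods$n_epo[!st$broods$is_mother_son]), 0L)
  if (sum(st$broods$is_mother_son) == 0) {
    asg <- data.frame(offspring_id = st$nestlings$id,
                      social_father_id = st$nestlings$social_father_id)
    faithful <- build_faithful_pedigree(st$pedigree, asg)
    expect_identical(faithful$records, st$pedigree$records)
  }
})

test_that("contingency tables validate and format row percentages", {
  tab <- contingency_2x2(c(130, 1597, 115, 2589),
                         row_labels = c("within-pair", "extra-pair"),
                         col_labels = c("inbred", "outbred"))
  expect_equal(unname(tab$row_totals), c(1727, 2704))
  rp <- row_percentages(tab)
  expect_equal(unname(rp[, "inbred"]), c(7.5, 4.3))
  expect_error(contingency_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fisher_exact matches full hypergeometric enumeration", {
  # every 2x2 table with all margins positive and total at most 12
  for (n in 2:12) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        lo <- max(0, c1 - (n - r1)); hi <- min(c1, r1)
        for (a in lo:hi) {
          m <- matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), 2, 2)
          if (any(m < 0)) next
          got <- fisher_exact(m)
          expect_equal(got$p_value, fisher_enum_p(m), tolerance = 1e-10)
          expect_gt(got$p_value, 0)
          expect_lte(got$p_value, 1 + 1e-12)
        }
      }
    }
  }
})

test_that("degenerate and symmetric tables are handled", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  res <- fisher_exact(matrix(c(0, 0, 3, 4), 2, 2))
  expect_identical(res$p_value, 1)
  expect_true(is.na(res$odds_ratio))
})

# direct generative hurdle data: WP offspring inbred more often and more
# deeply than EP offspring, with nest and cohort heterogeneity
make_hurdle_nestlings <- function(n_nests = 400, brood = 4, b_wp = 1.3,
                                  mag_wp = 0.5, base = -2.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_nests * brood
  nest <- rep(sprintf("N%04d", seq_len(n_nests)), each = brood)
  cohort <- rep(sample(1988:2013, n_nests, replace = TRUE), each = brood)
  nest_dev <- rep(rnorm(n_nests, 0, 0.8), each = brood)
  ep <- sample(c("WP", "EP"), n, replace = TRUE, prob = c(0.4, 0.6))
  p_inb <- plogis(base + b_wp * (ep == "WP") + nest_dev)
  inbred <- runif(n) < p_inb
  log_f <- log(0.0625) + mag_wp * (ep == "WP") + rnorm(n, 0, 0.4)
  f <- ifelse(inbred, pmin(exp(log_f), 0.5), 0)
  data.frame(id = sprintf("I%05d", seq_len(n)), nest_id = nest,
             cohort = cohort, hatch_interval = 1L, sex = "female",
             age_days = 7L, era = "1992+", mass_g = 7, survived = TRUE,
             f = f, ep_status = ep, n_helpers = "0", brood_size = brood,
             is_mother_son = FALSE, stringsAsFactors = FALSE)
}

test_that("hurdle model recovers a generated WP excess in both stages", {
  ne <- make_hurdle_nestlings(seed = 11)
  hd <- fit_hurdle_inbreeding(ne)
  expect_gt(hd$status$coefficients[["ep_statusWP"]], 0)
  expect_gt(hd$status$ci["ep_statusWP", "lower"], 0)
  expect_gt(hd$magnitude$coefficients[["ep_statusWP"]], 0)
  expect_gt(hd$magnitude$ci["ep_statusWP", "lower"], 0)
  # natural-log response: monotone in f, ordering preserved
  expect_gt(log(0.125), log(0.0625))
})

test_that("hurdle model is null when WP and EP share the relatedness pool", {
  ne <- make_hurdle_nestlings(b_wp = 0, mag_wp = 0, seed = 12)
  hd <- fit_hurdle_inbreeding(ne)
  expect_lt(hd$status$ci["ep_statusWP", "lower"], 0)
  expect_gt(hd$status$ci["ep_statusWP", "upper"], 0)
  expect_lt(hd$magnitude$ci["ep_statusWP", "lower"], 0)
  expect_gt(hd$magnitude$ci["ep_statusWP", "upper"], 0)
})

test_that("hurdle stage 2 is skipped with too few inbred offspring", {
  ne <- make_hurdle_nestlings(n_nests = 30, base = -5, seed = 13)
  hd <- fit_hurdle_inbreeding(ne)
  expect_null(hd$magnitude)
  expect_match(hd$magnitude_note, "skipped")
  # mother-son exclusion requires the flag column
  ne$is_mother_son <- NULL
  expect_error(fit_hurdle_inbreeding(ne), "is_mother_son")
})
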