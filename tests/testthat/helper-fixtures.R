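# Toy pedigrees with known analytic kinship/inbreeding values, generative
# fixtures for model-recovery tests, and memoized simulated studies shared
# across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# founder pair -> daughter; sire also mates with the daughter -> X (f = 0.25)
parent_offspring_ped <- function() {
  pedigree(id   = c("A", "B", "D", "X"),
           sire = c(NA, NA, "A", "A"),
           dam  = c(NA, NA, "B", "D"))
}

# one sire, two unrelated dams, the two half-sibs mate -> X (f = 0.125)
halfsib_ped <- function() {
  pedigree(id   = c("S", "D1", "D2", "H1", "H2", "X"),
           sire = c(NA, NA, NA, "S", "S", "H1"),
           dam  = c(NA, NA, NA, "D1", "D2", "H2"))
}

# grandmother -> daughter (founder sire) -> grandson (founder sire); kinship
# between GM and G is 0.125
grandmother_ped <- function() {
  pedigree(id   = c("GM", "S1", "D", "S2", "G"),
           sire = c(NA, NA, "S1", NA, "S2"),
           dam  = c(NA, NA, "GM", NA, "D"),
           sex  = c("female", "male", "female", "male", "male"))
}

# mother M, her son S (by founder F0), and an extra-pair offspring O of M
# whose social father is S
mother_son_ped <- function() {
  pedigree(id   = c("F0", "M", "S", "X", "O"),
           sire = c(NA, NA, "F0", NA, "X"),
           dam  = c(NA, NA, "M", NA, "M"),
           sex  = c("male", "female", "male", "male", "unknown"))
}

# random mating pedigree over discrete generations, for property tests
random_pedigree <- function(n_founders = 20, n_gen = 4, per_gen = 30,
                            seed = 1) {
  set.seed(seed)
  id <- sprintf("F%03d", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  sex <- rep(c("male", "female"), length.out = n_founders)
  for (g in seq_len(n_gen)) {
    males <- id[sex == "male"]
    females <- id[sex == "female"]
    for (k in seq_len(per_gen)) {
      nid <- sprintf("G%d_%03d", g, k)
      id <- c(id, nid)
      sire <- c(sire, sample(males, 1))
      dam <- c(dam, sample(females, 1))
      sex <- c(sex, sample(c("male", "female"), 1))
    }
  }
  pedigree(id, sire, dam, sex = sex)
}

small_params <- function(seed = 301L, ...) {
  sim_params(n_territories = 25L, n_years = 10L, seed = seed, ...)
}

small_study <- function() memo("small_study", simulate_population(small_params()))

default_study <- function() {
  memo("default_study", simulate_population(sim_params(seed = 101L)))
}

# nestling table of a study with is_mother_son joined in and the
# completeness restriction applied
restricted_nestlings <- function(study, min_gp = 1L) {
  ne <- study$nestlings
  ne$is_mother_son <-
    study$broods$is_mother_son[match(ne$nest_id, study$broods$nest_id)]
  ids <- intersect(restrict_pedigree(study$pedigree, min_gp), ne$id)
  ne[ne$id %in% ids, , drop = FALSE]
}

default_restricted <- function() {
  memo("default_restricted", restricted_nestlings(default_study()))
}

# direct generative nestling table (no agent-based layer): known fixed
# effects, nest random intercepts, iid residuals; used for estimator
# recovery and coverage checks
make_nestlings <- function(n_nests = 150, brood = 4, f_coef = -3.64,
                           p_inbred = 0.12, sd_nest = sqrt(0.23),
                           sd_resid = sqrt(0.30), era_effect = 0.62,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bsz <- if (length(brood) == 1L && brood == 4) {
    sample(3:5, n_nests, replace = TRUE)  # varied so the design is full rank
  } else {
    rep_len(brood, n_nests)
  }
  n <- sum(bsz)
  nest <- rep(sprintf("N%04d", seq_len(n_nests)), bsz)
  brood <- rep(bsz, bsz)
  cohort <- rep(sample(1988:2013, n_nests, replace = TRUE), bsz)
  hatch <- rep(sample(1:12, n_nests, replace = TRUE), bsz)
  helpers <- rep(sample(c("0", "1", "2+"), n_nests, replace = TRUE,
                        prob = c(0.55, 0.28, 0.17)), bsz)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- sample(5:8, n, replace = TRUE)
  f <- ifelse(runif(n) < p_inbred,
              sample(c(0.125, 0.0625, 0.03125), n, replace = TRUE), 0)
  era <- ifelse(cohort < 1992, "pre-1992", "1992+")
  nest_dev <- rep(rnorm(n_nests, 0, sd_nest), bsz)
  mass <- 7 + 0.15 * (sex == "male") + 0.09 * (helpers == "1") +
    0.20 * (helpers == "2+") + f_coef * f +
    era_effect * (era == "pre-1992") +
    0.9 * (age - 7) - 0.09 * (age - 7)^2 +
    nest_dev + rnorm(n, 0, sd_resid)
  data.frame(id = sprintf("I%05d", seq_len(n)), nest_id = nest,
             cohort = cohort, hatch_interval = hatch, sex = sex,
             age_days = age, era = era, mass_g = mass,
             survived = NA, f = f,
             ep_status = sample(c("WP", "EP"), n, replace = TRUE),
             n_helpers = helpers, brood_size = brood,
             is_mother_son = FALSE,
             stringsAsFactors = FALSE)
}

# independent two-sided Fisher oracle: full enumeration of the
# hypergeometric distribution of the top-left cell
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
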