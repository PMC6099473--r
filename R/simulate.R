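#' Parameters for the social-system simulator
#'
#' Builds the parameter list consumed by [simulate_population()]. The defaults
#' describe a 26-cohort study of ~75 territories of a cooperatively breeding
#' passerine with obligate female dispersal, helper queues of sons with
#' territory inheritance (so mother-son social pairs can arise), high
#' extra-pair paternity that rises with helper number, and inbreeding
#' depression acting on nestling mass. Generative coefficients default to the
#' field estimates for the system being emulated: extra-pair log-odds
#' (intercept 0.47, +0.53 with one helper, +1.17 with two or more), a mass
#' model with -3.64 g per unit f, +0.15 g for males, -0.05 g per extra
#' nestling, helper effects +0.09/+0.20 g, a +0.62 g pre-1992 protocol offset
#' and variance components (nest 0.23, cohort 0.01, hatch interval 0.01,
#' additive genetic 0.10, residual 0.19 g^2), and fledgling survival with
#' log-odds slope 0.33 per gram of day-7 mass.
#'
#' @param n_territories number of territories on a 1-D ring.
#' @param n_years number of breeding cohorts.
#' @param start_year first cohort year (the era factor splits at 1992).
#' @param broods_per_female named probabilities over 1-3 successful brood
#'   attempts per female-year.
#' @param clutch_size named probabilities over clutch sizes 3-5.
#' @param nest_failure_prob probability an attempted clutch fails wholesale
#'   (predation) and is never observed.
#' @param premeasure_loss_prob per-nestling probability of death between
#'   hatching and measurement.
#' @param early_loss_k_soc additional log-odds of pre-measurement loss per
#'   unit of social-pair kinship; 0 disables the selective-disappearance
#'   mechanism.
#' @param adult_survival annual survival probability of dominants and helpers.
#' @param juvenile_recruitment probability an independent fledgling recruits
#'   into the population the following year.
#' @param helper_retention probability a recruited male stays on his natal
#'   territory as a helper (otherwise he floats and may fill a distant
#'   vacancy).
#' @param epp_logit named coefficients (`intercept`, `helper1`,
#'   `helper2plus`) for the per-offspring extra-pair log-odds.
#' @param epp_k_soc slope of extra-pair log-odds on social-pair kinship
#'   outside mother-son pairs (0: no kinship-infidelity relationship).
#' @param epp_vc named latent (logit-scale) variances of the extra-pair
#'   probability: `mother` and `father` deviates persist across a bird's
#'   broods, `cohort` is a year effect, and `brood` is a brood-level residual
#'   (the analogue of the latent residual of a logit-link brood model).
#' @param min_ep_distance,max_ep_distance extra-pair sires are drawn
#'   uniformly from dominant males `min_ep_distance`..`max_ep_distance`
#'   territories away on the ring (the default minimum of 1 makes all
#'   extra-pair paternity extra-group; raising the minimum models females
#'   foraying farther, to males beyond their kin neighborhood).
#' @param mass_coef named generative coefficients of the nestling-mass model:
#'   `intercept_day7` (grams, for a female nestling in a brood of 4 with no
#'   helpers, era 1992+), `male`, `brood_size` (per nestling above 4),
#'   `helper1`, `helper2plus`, `inbreeding` (per unit f), `era_pre1992`,
#'   `age` (per day at day 7) and `age_sq`.
#' @param mass_vc named variance components (g^2): `nest`, `cohort`,
#'   `hatch_interval`, `additive`, `residual`.
#' @param survival_coef named coefficients (`intercept`, `mass`) of the
#'   logistic model of survival to independence on day-7-adjusted mass.
#' @param survival_f direct log-odds effect of f on survival (default 0: any
#'   inbreeding effect on survival is mediated by mass).
#' @param female_immigrant_share probability that a female vacancy is
#'   settled by an unrelated immigrant rather than a locally hatched disperser
#'   (the study area is an open sample of a much larger population, so many
#'   settling females carry no local ancestry).
#' @param male_immigrant_prob probability that a dominant-male vacancy with
#'   no helper to inherit it is taken by an unrelated immigrant rather than a
#'   local floater.
#' @param widow_departure_prob probability that a widowed dominant female
#'   departs (re-enters the dispersal pool) when the territory would
#'   otherwise be inherited by her own son, modeling incest-avoidance
#'   dispersal; the complement of this probability is what lets mother-son
#'   social pairs form at all.
#' @param female_dispersal_decay per-territory geometric decay of a
#'   locally hatched female's settlement probability with ring distance from
#'   her natal territory. Values below 1 give short-dispersing females, which
#'   (with male philopatry) builds spatial kin structure, so social partners
#'   (distance 0) are on average more related to the female than the
#'   extra-pair sires drawn from 1-5 territories away; 1 means settlement is
#'   uniform and extra-pair sires come from the same relatedness pool as
#'   social partners.
#' @param seed integer seed making the whole simulation reproducible.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_territories = 75L,
                       n_years = 26L,
                       start_year = 1988L,
                       broods_per_female = c(`1` = 0.50, `2` = 0.40, `3` = 0.10),
                       clutch_size = c(`3` = 0.45, `4` = 0.45, `5` = 0.10),
                       nest_failure_prob = 0.45,
                       premeasure_loss_prob = 0.05,
                       early_loss_k_soc = 0,
                       adult_survival = 0.72,
                       juvenile_recruitment = 0.60,
                       helper_retention = 0.70,
                       epp_logit = c(intercept = 0.47, helper1 = 0.53,
                                     helper2plus = 1.17),
                       epp_k_soc = 0,
                       epp_vc = c(mother = 0.73, father = 0.71,
                                  cohort = 0.02, brood = 1.85),
                       min_ep_distance = 2L,
                       max_ep_distance = 10L,
                       mass_coef = c(intercept_day7 = 7.0, male = 0.15,
                                     brood_size = -0.05, helper1 = 0.09,
                                     helper2plus = 0.20, inbreeding = -3.64,
                                     era_pre1992 = 0.62, age = 0.90,
                                     age_sq = -0.09),
                       mass_vc = c(nest = 0.23, cohort = 0.01,
                                   hatch_interval = 0.01, additive = 0.10,
                                   residual = 0.19),
                       survival_coef = c(intercept = -2.07, mass = 0.33),
                       survival_f = 0,
                       female_immigrant_share = 0.60,
                       male_immigrant_prob = 0.30,
                       widow_departure_prob = 0.75,
                       female_dispersal_decay = 0.40,
                       seed = 1L) {
  p <- list(n_territories = as.integer(n_territories),
            n_years = as.integer(n_years),
            start_year = as.integer(start_year),
            broods_per_female = broods_per_female,
            clutch_size = clutch_size,
            nest_failure_prob = nest_failure_prob,
            premeasure_loss_prob = premeasure_loss_prob,
            early_loss_k_soc = early_loss_k_soc,
            adult_survival = adult_survival,
            juvenile_recruitment = juvenile_recruitment,
            helper_retention = helper_retention,
            epp_logit = epp_logit,
            epp_k_soc = epp_k_soc,
            epp_vc = epp_vc,
            min_ep_distance = as.integer(min_ep_distance),
            max_ep_distance = as.integer(max_ep_distance),
            mass_coef = mass_coef,
            mass_vc = mass_vc,
            survival_coef = survival_coef,
            survival_f = survival_f,
            female_immigrant_share = female_immigrant_share,
            male_immigrant_prob = male_immigrant_prob,
            widow_departure_prob = widow_departure_prob,
            female_dispersal_decay = female_dispersal_decay,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  probs <- c(p$nest_failure_prob, p$premeasure_loss_prob, p$adult_survival,
             p$juvenile_recruitment, p$helper_retention,
             p$male_immigrant_prob, p$widow_departure_prob,
             p$female_immigrant_share)
  if (p$female_dispersal_decay <= 0 || p$female_dispersal_decay > 1) {
    stop("female_dispersal_decay must lie in (0, 1]")
  }
  if (p$min_ep_distance < 1L || p$max_ep_distance < p$min_ep_distance) {
    stop("need 1 <= min_ep_distance <= max_ep_distance")
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$n_territories < 3L) stop("need at least 3 territories")
  if (p$n_years < 1L) stop("need at least 1 year")
  for (nm in c("broods_per_female", "clutch_size")) {
    d <- p[[nm]]
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop(nm, " must be a probability distribution summing to 1")
    }
  }
  need <- c("intercept", "helper1", "helper2plus")
  if (!all(need %in% names(p$epp_logit))) {
    stop("epp_logit needs coefficients: ", paste(need, collapse = ", "))
  }
  need <- c("mother", "father", "cohort", "brood")
  if (!all(need %in% names(p$epp_vc))) {
    stop("epp_vc needs components: ", paste(need, collapse = ", "))
  }
  if (any(p$epp_vc < 0)) stop("variance components must be non-negative")
  need <- c("intercept_day7", "male", "brood_size", "helper1", "helper2plus",
            "inbreeding", "era_pre1992", "age", "age_sq")
  if (!all(need %in% names(p$mass_coef))) {
    stop("mass_coef needs coefficients: ", paste(need, collapse = ", "))
  }
  need <- c("nest", "cohort", "hatch_interval", "additive", "residual")
  if (!all(need %in% names(p$mass_vc))) {
    stop("mass_vc needs components: ", paste(need, collapse = ", "))
  }
  if (any(p$mass_vc < 0)) stop("variance components must be non-negative")
  if (!all(c("intercept", "mass") %in% names(p$survival_coef))) {
    stop("survival_coef needs coefficients: intercept, mass")
  }
  invisible(p)
}

#' Simulate a synthetic study population
#'
#' Agent-based forward simulation of the social system: each territory holds a
#' dominant pair and a queue of helper sons; on the dominant male's death the
#' oldest helper inherits (possibly socially pairing with his mother); females
#' always disperse from their natal territory before breeding, so
#' father-daughter social pairs cannot form. Each offspring is extra-pair with
#' probability given by the helper-class logit model, forced to 1 in
#' mother-son pairs; extra-pair sires are drawn from dominant males 1-5
#' territories away, never a son of the mother. Nestling mass is the linear
#' predictor plus nest, cohort, hatch-interval, additive-genetic and residual
#' deviates, with breeding values transmitted as midparent plus a Mendelian
#' sampling deviate of variance (1 - (f_s + f_d)/2) V_A / 2. Survival to
#' independence is Bernoulli on the logistic mass model. The run is fully
#' reproducible from `params$seed`.
#'
#' @param params a [sim_params()] list.
#' @return An object of class `synthetic_study`: a list with elements
#'   `pedigree` (a [pedigree]), `broods` (one row per observed brood),
#'   `nestlings` (one row per measured nestling) and `truth` (the generating
#'   parameters plus realized breeding values).
#' @export
simulate_population <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed)
  T <- params$n_territories
  years <- seq(params$start_year, length.out = params$n_years)
  vc <- params$mass_vc
  mc <- params$mass_coef

  # population accumulator -----------------------------------------------
  pop <- new.env(parent = emptyenv())
  pop$sex <- integer(0)      # 1 male, 2 female
  pop$cohort <- integer(0)
  pop$sire <- integer(0)     # NA for founders
  pop$dam <- integer(0)
  pop$f <- numeric(0)
  pop$bv <- numeric(0)
  pop$rank <- integer(0)
  new_indiv <- function(sex, cohort, sire = NA_integer_, dam = NA_integer_,
                        f = 0, bv = NULL) {
    n <- length(pop$sex) + length(sex)
    cohort <- rep_len(as.integer(cohort), length(sex))
    sire <- rep_len(as.integer(sire), length(sex))
    dam <- rep_len(as.integer(dam), length(sex))
    f <- rep_len(f, length(sex))
    if (is.null(bv)) bv <- rnorm(length(sex), 0, sqrt(vc[["additive"]]))
    pop$sex <- c(pop$sex, sex)
    pop$cohort <- c(pop$cohort, cohort)
    pop$sire <- c(pop$sire, sire)
    pop$dam <- c(pop$dam, dam)
    pop$f <- c(pop$f, f)
    pop$bv <- c(pop$bv, bv)
    rk <- ifelse(is.na(sire) & is.na(dam), 0L,
                 pmax(ifelse(is.na(sire), 0L, pop$rank[sire]),
                      ifelse(is.na(dam), 0L, pop$rank[dam])) + 1L)
    pop$rank <- c(pop$rank, as.integer(rk))
    seq.int(n - length(sex) + 1L, n)
  }
  # close-kin matings never occur: females do not mate with their sons,
  # their sire, or full brothers (familiar nuclear-family kin), so the
  # maximum possible offspring f is 0.125
  full_sib <- function(ix, jx) {
    !is.na(pop$sire[ix]) && !is.na(pop$dam[ix]) &&
      !is.na(pop$sire[jx]) && !is.na(pop$dam[jx]) &&
      pop$sire[ix] == pop$sire[jx] && pop$dam[ix] == pop$dam[jx]
  }
  ep_eligible <- function(cand, mo) {
    keep <- vapply(cand, function(cx) {
      is_son <- !is.na(pop$dam[cx]) && pop$dam[cx] == mo
      is_sire <- !is.na(pop$sire[mo]) && cx == pop$sire[mo]
      !is_son && !is_sire && !full_sib(cx, mo)
    }, logical(1))
    cand[keep]
  }
  batch_kinship <- function(ii, jj) {
    if (!length(ii)) return(numeric(0))
    s0 <- ifelse(is.na(pop$sire), -1L, pop$sire - 1L)
    d0 <- ifelse(is.na(pop$dam), -1L, pop$dam - 1L)
    .kinship_pairs_cpp(as.integer(s0), as.integer(d0), pop$rank,
                       as.integer(ii - 1L), as.integer(jj - 1L))
  }

  # founders occupy every territory --------------------------------------
  founder_cohort <- function(k) params$start_year - sample(1:3, k, replace = TRUE)
  dom_m <- new_indiv(rep(1L, T), founder_cohort(T))
  dom_f <- new_indiv(rep(2L, T), founder_cohort(T))
  helpers <- rep(list(integer(0)), T)

  hatch_dev <- rnorm(12, 0, sqrt(vc[["hatch_interval"]]))
  cohort_dev <- setNames(rnorm(length(years), 0, sqrt(vc[["cohort"]])),
                         years)
  epp_cohort_dev <- setNames(rnorm(length(years), 0,
                                   sqrt(params$epp_vc[["cohort"]])), years)
  ep_dev <- numeric(0)  # persistent per-individual latent infidelity deviate
  get_ep_dev <- function(ix, sd) {
    if (ix > length(ep_dev) || is.na(ep_dev[ix])) ep_dev[ix] <<- rnorm(1, 0, sd)
    ep_dev[ix]
  }

  fledge_m <- integer(0)   # last year's surviving male fledglings
  fledge_f <- integer(0)
  natal_terr <- integer(0) # aligned with fledge_* below via names
  natal <- integer(0)      # natal territory per individual (0 = immigrant)

  broods_acc <- list()
  nest_acc <- list()
  brood_counter <- 0L

  for (y in years) {
    first_year <- y == years[1]
    # --- adult mortality -------------------------------------------------
    if (!first_year) {
      surv <- function(ix) ix[runif(length(ix)) < params$adult_survival]
      for (t in seq_len(T)) helpers[[t]] <- surv(helpers[[t]])
      dead_m <- runif(T) >= params$adult_survival
      dead_f <- runif(T) >= params$adult_survival
      dom_m[dead_m] <- NA_integer_
      dom_f[dead_f] <- NA_integer_
    }

    # --- recruitment of last year's fledglings ---------------------------
    pool_f <- integer(0)
    floaters <- integer(0)
    if (length(fledge_m)) {
      rec <- fledge_m[runif(length(fledge_m)) < params$juvenile_recruitment]
      stay <- runif(length(rec)) < params$helper_retention
      for (ix in rec[stay]) {
        t <- natal[[ix]]
        helpers[[t]] <- c(helpers[[t]], ix)
      }
      floaters <- rec[!stay]
    }
    if (length(fledge_f)) {
      pool_f <- fledge_f[runif(length(fledge_f)) < params$juvenile_recruitment]
    }

    # --- fill male vacancies (inheritance first) -------------------------
    for (t in seq_len(T)) {
      if (is.na(dom_m[t])) {
        if (length(helpers[[t]])) {
          heir <- helpers[[t]][1L]
          # a widowed female usually departs rather than pair with her son
          if (!is.na(dom_f[t]) && !is.na(pop$dam[heir]) &&
              pop$dam[heir] == dom_f[t] &&
              runif(1) < params$widow_departure_prob) {
            natal[dom_f[t]] <- t  # will not resettle here
            pool_f <- c(pool_f, dom_f[t])
            dom_f[t] <- NA_integer_
          }
          dom_m[t] <- heir
          helpers[[t]] <- helpers[[t]][-1L]
        } else if (length(elig <- floaters[is.na(pop$dam[floaters]) |
                                             is.na(dom_f[t]) |
                                             pop$dam[floaters] != dom_f[t]]) &&
                   runif(1) >= params$male_immigrant_prob) {
          pick <- elig[sample.int(length(elig), 1L)]
          dom_m[t] <- pick
          floaters <- setdiff(floaters, pick)
        } else {
          imm <- new_indiv(1L, y - sample(1:2, 1L))
          natal[imm] <- 0L
          dom_m[t] <- imm
        }
      }
    }

    # --- fill female vacancies (obligate dispersal) ----------------------
    for (t in seq_len(T)) {
      if (is.na(dom_f[t])) {
        ok <- pool_f[vapply(pool_f, function(ix) {
          nt <- natal[[ix]]
          from_here <- !is.na(nt) && nt == t
          dad_here <- !is.na(pop$sire[ix]) && !is.na(dom_m[t]) &&
            pop$sire[ix] == dom_m[t]
          son_here <- !is.na(dom_m[t]) && !is.na(pop$dam[dom_m[t]]) &&
            pop$dam[dom_m[t]] == ix
          sib_here <- !is.na(dom_m[t]) && full_sib(dom_m[t], ix)
          !from_here && !dad_here && !son_here && !sib_here
        }, logical(1))]
        use_local <- length(ok) > 0 &&
          runif(1) >= params$female_immigrant_share
        if (use_local) {
          w <- vapply(ok, function(ix) {
            nt <- natal[[ix]]
            if (is.na(nt) || nt == 0L) return(1)
            dd <- abs(nt - t)
            params$female_dispersal_decay^min(dd, T - dd)
          }, numeric(1))
          if (sum(w) <= 0) w <- rep(1, length(ok))
          pick <- ok[sample.int(length(ok), 1L, prob = w)]
          dom_f[t] <- pick
          pool_f <- setdiff(pool_f, pick)
        } else {
          imm <- new_indiv(2L, y - sample(1:2, 1L))
          natal[imm] <- 0L
          dom_f[t] <- imm
        }
      }
    }

    # --- social-pair kinship for the year --------------------------------
    k_soc <- batch_kinship(dom_m, dom_f)
    is_ms <- !is.na(pop$dam[dom_m]) & pop$dam[dom_m] == dom_f
    h_cnt <- vapply(helpers, length, integer(1))
    h_cls <- ifelse(h_cnt == 0L, "0", ifelse(h_cnt == 1L, "1", "2+"))
    ydev <- cohort_dev[[as.character(y)]]
    pre1992 <- y < 1992L

    # --- breeding --------------------------------------------------------
    year_off <- list()  # collect offspring rows before f can be computed
    for (t in seq_len(T)) {
      mo <- dom_f[t]; sf <- dom_m[t]
      nb <- sample(as.integer(names(params$broods_per_female)), 1L,
                   prob = params$broods_per_female)
      intervals <- sort(sample(1:12, nb))
      for (b in seq_len(nb)) {
        if (runif(1) < params$nest_failure_prob) next
        clutch <- sample(as.integer(names(params$clutch_size)), 1L,
                         prob = params$clutch_size)
        p_loss <- plogis(qlogis(params$premeasure_loss_prob) +
                           params$early_loss_k_soc * k_soc[t])
        bsz <- clutch - rbinom(1L, clutch, p_loss)
        if (bsz == 0L) next
        p_ep <- if (is_ms[t]) 1 else
          plogis(params$epp_logit[["intercept"]] +
                   params$epp_logit[["helper1"]] * (h_cls[t] == "1") +
                   params$epp_logit[["helper2plus"]] * (h_cls[t] == "2+") +
                   params$epp_k_soc * k_soc[t] +
                   get_ep_dev(mo, sqrt(params$epp_vc[["mother"]])) +
                   get_ep_dev(sf, sqrt(params$epp_vc[["father"]])) +
                   epp_cohort_dev[[as.character(y)]] +
                   rnorm(1, 0, sqrt(params$epp_vc[["brood"]])))
        ep <- runif(bsz) < p_ep
        sires <- rep(sf, bsz)
        if (any(ep)) {
          dists <- seq.int(params$min_ep_distance, params$max_ep_distance)
          cand_t <- setdiff(unique(c((t - 1 + dists) %% T + 1,
                                     (t - 1 - dists) %% T + 1)), t)
          cand <- dom_m[cand_t]
          cand <- ep_eligible(cand[!is.na(cand)], mo)
          if (!length(cand)) {  # fall back to the whole ring
            cand <- ep_eligible(dom_m[-t][!is.na(dom_m[-t])], mo)
          }
          sires[ep] <- cand[sample.int(length(cand), sum(ep), replace = TRUE)]
        }
        brood_counter <- brood_counter + 1L
        year_off[[length(year_off) + 1L]] <- list(
          t = t, nest = brood_counter, interval = intervals[b],
          clutch = clutch, bsz = bsz, mo = mo, sf = sf, sires = sires,
          ep = ep, k_soc = k_soc[t], is_ms = is_ms[t], h_cls = h_cls[t])
      }
    }

    # --- phenotypes and records ------------------------------------------
    new_m <- integer(0); new_f <- integer(0)
    for (o in year_off) {
      sexes <- sample(1:2, o$bsz, replace = TRUE)
      kids <- new_indiv(sexes, rep(y, o$bsz),
                        sire = o$sires, dam = rep(o$mo, o$bsz),
                        f = rep(0, o$bsz), bv = rep(0, o$bsz))
      natal[kids] <- o$t
      f_kids <- batch_kinship(o$sires, rep(o$mo, o$bsz))
      pop$f[kids] <- f_kids
      msv <- (1 - (pop$f[o$sires] + pop$f[o$mo]) / 2) * vc[["additive"]] / 2
      pop$bv[kids] <- 0.5 * (pop$bv[o$sires] + pop$bv[o$mo]) +
        rnorm(o$bsz, 0, sqrt(pmax(msv, 0)))
      nest_dev <- rnorm(1, 0, sqrt(vc[["nest"]]))
      age <- sample(5:8, o$bsz, replace = TRUE)
      lin <- mc[["intercept_day7"]] +
        mc[["male"]] * (sexes == 1L) +
        mc[["brood_size"]] * (o$bsz - 4) +
        mc[["helper1"]] * (o$h_cls == "1") +
        mc[["helper2plus"]] * (o$h_cls == "2+") +
        mc[["inbreeding"]] * f_kids +
        mc[["era_pre1992"]] * pre1992 +
        mc[["age"]] * (age - 7) + mc[["age_sq"]] * (age - 7)^2
      mass <- lin + nest_dev + ydev + hatch_dev[o$interval] +
        pop$bv[kids] + rnorm(o$bsz, 0, sqrt(vc[["residual"]]))
      mass_day7 <- mass - mc[["age"]] * (age - 7) - mc[["age_sq"]] * (age - 7)^2 -
        mc[["era_pre1992"]] * pre1992
      p_surv <- plogis(params$survival_coef[["intercept"]] +
                         params$survival_coef[["mass"]] * mass_day7 +
                         params$survival_f * f_kids)
      survived <- runif(o$bsz) < p_surv
      new_m <- c(new_m, kids[sexes == 1L & survived])
      new_f <- c(new_f, kids[sexes == 2L & survived])
      ma <- if (y - pop$cohort[o$mo] <= 1L) "1yo" else "older"
      fa <- if (y - pop$cohort[o$sf] <= 1L) "1yo" else "older"
      broods_acc[[length(broods_acc) + 1L]] <- data.frame(
        nest_id = sprintf("N%05d", o$nest),
        mother_id = sprintf("I%05d", o$mo),
        social_father_id = sprintf("I%05d", o$sf),
        cohort = y, hatch_interval = o$interval,
        n_helpers = o$h_cls, clutch_size = o$clutch, brood_size = o$bsz,
        n_epo = sum(o$ep), n_wpo = sum(!o$ep),
        k_soc = o$k_soc, is_mother_son = o$is_ms,
        mother_age = ma, father_age = fa,
        stringsAsFactors = FALSE)
      nest_acc[[length(nest_acc) + 1L]] <- data.frame(
        id = sprintf("I%05d", kids),
        nest_id = sprintf("N%05d", o$nest),
        cohort = y, hatch_interval = o$interval,
        sex = c("male", "female")[sexes],
        age_days = age,
        era = if (pre1992) "pre-1992" else "1992+",
        mass_g = mass, survived = survived,
        f = f_kids,
        ep_status = ifelse(o$ep, "EP", "WP"),
        n_helpers = o$h_cls, brood_size = o$bsz,
        mother_id = sprintf("I%05d", o$mo),
        social_father_id = sprintf("I%05d", o$sf),
        genetic_father_id = sprintf("I%05d", o$sires),
        stringsAsFactors = FALSE)
    }
    fledge_m <- new_m
    fledge_f <- new_f
  }

  n <- length(pop$sex)
  ids <- sprintf("I%05d", seq_len(n))
  ped <- pedigree(
    id = ids,
    sire = ifelse(is.na(pop$sire), NA_character_, sprintf("I%05d", pop$sire)),
    dam = ifelse(is.na(pop$dam), NA_character_, sprintf("I%05d", pop$dam)),
    cohort = pop$cohort,
    sex = c("male", "female")[pop$sex]
  )
  structure(
    list(
      pedigree = ped,
      broods = do.call(rbind, broods_acc),
      nestlings = do.call(rbind, nest_acc),
      truth = list(params = params,
                   breeding_values = setNames(pop$bv, ids),
                   f = setNames(pop$f, ids))
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$broods), " broods, ",
      nrow(x$nestlings), " nestlings, pedigree of ",
      n_individuals(x$pedigree), "\n", sep = "")
  invisible(x)
}

#' Summarize a synthetic study
#'
#' Reports the calibration quantities of the simulated population: the helper
#' distribution, the fraction of unassisted broods, the percentage of
#' mother-son social pairs, the percentage of extra-pair offspring, and the
#' percentage of inbred offspring at each pedigree-completeness restriction.
#'
#' @param study a [simulate_population()] result.
#' @param cohorts optional vector of cohort years to keep; `NULL` keeps all.
#' @param inbred_threshold f above this value counts as inbred (a small
#'   positive tolerance absorbs floating-point noise; pedigree f values are
#'   exact dyadic rationals, so this is conservative).
#' @return A list of class `study_summary`.
#' @export
summarize_study <- function(study, cohorts = NULL, inbred_threshold = 1e-12) {
  br <- study$broods
  ne <- study$nestlings
  if (!is.null(cohorts)) {
    br <- br[br$cohort %in% cohorts, , drop = FALSE]
    ne <- ne[ne$cohort %in% cohorts, , drop = FALSE]
  }
  nb <- nrow(br)
  nn <- nrow(ne)
  helper_dist <- if (nb) prop.table(table(factor(br$n_helpers,
                                                 c("0", "1", "2+")))) else
    table(factor(character(0), c("0", "1", "2+")))
  inbred_by_restriction <- sapply(0:4, function(m) {
    ids <- intersect(restrict_pedigree(study$pedigree, m), ne$id)
    if (!length(ids)) return(NA_real_)
    f <- inbreeding(study$pedigree, ids)
    if (length(ids) == 1L) f <- f$f
    mean(f > inbred_threshold)
  })
  names(inbred_by_restriction) <- paste0("min_gp_", 0:4)
  structure(
    list(n_broods = nb,
         n_nestlings = nn,
         prop_unassisted = if (nb) mean(br$n_helpers == "0") else 0,
         helper_dist = helper_dist,
         prop_mother_son_broods = if (nb) mean(br$is_mother_son) else 0,
         prop_epo = if (nn) mean(ne$ep_status == "EP") else 0,
         prop_broods_with_epo = if (nb) mean(br$n_epo > 0) else 0,
         prop_inbred_by_restriction = inbred_by_restriction),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("broods: ", x$n_broods, "  nestlings: ", x$n_nestlings, "\n",
      "unassisted broods: ", sprintf("%.1f%%", 100 * x$prop_unassisted), "\n",
      "mother-son pairs:  ", sprintf("%.1f%%", 100 * x$prop_mother_son_broods), "\n",
      "extra-pair offspring: ", sprintf("%.1f%%", 100 * x$prop_epo), "\n",
      "broods with >=1 EPO:  ", sprintf("%.1f%%", 100 * x$prop_broods_with_epo), "\n",
      sep = "")
  cat("inbred fraction by restriction: ",
      paste(sprintf("%s=%.1f%%", names(x$prop_inbred_by_restriction),
                    100 * x$prop_inbred_by_restriction), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
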