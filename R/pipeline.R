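#' Kinship and inbreeding category summary
#'
#' Builds the headline distribution tables: (A) at brood level, the share of
#' broods whose social pair is related (k_soc > 0), split into high
#' (k >= 0.25), moderate (0.125 <= k < 0.25) and low (0 < k < 0.125)
#' kinship, with relationship-route labels for the moderate-and-above pairs;
#' and (B) the same categories for individual inbreeding coefficients over a
#' restricted id set, with routes labelled from the parents' relationship.
#' Percentages are rounded half-up to one decimal.
#'
#' @param ped a [pedigree].
#' @param broods brood table with `k_soc`, `mother_id`, `social_father_id`.
#' @param ids restricted individual ids for part B.
#' @param threshold positive-kinship tolerance.
#' @return List of class `table1_summary` with data frames `pairings`,
#'   `pairing_routes`, `individuals`, `individual_routes`.
#' @export
table1_summary <- function(ped, broods, ids, threshold = 1e-12) {
  cat_table <- function(x, n) {
    data.frame(
      category = c("all_positive", "high", "moderate", "low"),
      count = c(sum(x > threshold), sum(x >= 0.25),
                sum(x >= 0.125 & x < 0.25), sum(x > threshold & x < 0.125)),
      total = n,
      stringsAsFactors = FALSE
    )
  }
  fmt <- function(df) {
    df$percent <- round_half_up(100 * df$count / pmax(df$total, 1), 1)
    df
  }
  k <- broods$k_soc
  pairings <- fmt(cat_table(k, nrow(broods)))
  hi <- which(k >= 0.125)
  pairing_routes <- if (length(hi)) {
    lab <- classify_relationship(ped, broods$social_father_id[hi],
                                 broods$mother_id[hi])
    tb <- table(lab)
    fmt(data.frame(route = names(tb), count = as.integer(tb),
                   total = nrow(broods), stringsAsFactors = FALSE))
  } else {
    data.frame(route = character(0), count = integer(0), total = integer(0),
               percent = numeric(0))
  }
  ids <- as.character(ids)
  fv <- inbreeding(ped, ids)
  if (length(ids) == 1L) fv <- fv$f
  individuals <- fmt(cat_table(fv, length(ids)))
  hi <- which(fv >= 0.125)
  individual_routes <- if (length(hi)) {
    ii <- ped_index(ped, ids[hi])
    lab <- classify_relationship(ped, ped$records$sire[ii],
                                 ped$records$dam[ii])
    tb <- table(lab)
    fmt(data.frame(route = names(tb), count = as.integer(tb),
                   total = length(ids), stringsAsFactors = FALSE))
  } else {
    data.frame(route = character(0), count = integer(0), total = integer(0),
               percent = numeric(0))
  }
  structure(list(pairings = pairings, pairing_routes = pairing_routes,
                 individuals = individuals,
                 individual_routes = individual_routes),
            class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  cat("social pairings (brood level):\n"); print(x$pairings)
  if (nrow(x$pairing_routes)) print(x$pairing_routes)
  cat("individual inbreeding:\n"); print(x$individuals)
  if (nrow(x$individual_routes)) print(x$individual_routes)
  invisible(x)
}

# flatten a model_fit for TSV/JSON output
fit_to_df <- function(fit) {
  if (!length(fit$coefficients)) {
    return(data.frame(term = character(0), estimate = numeric(0),
                      se = numeric(0), lower = numeric(0), upper = numeric(0),
                      p = numeric(0)))
  }
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se),
             lower = unname(fit$ci[, 1]),
             upper = unname(fit$ci[, 2]),
             p = unname(fit$p_value),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Drives the end-to-end analysis: simulate (or accept) a study, restrict the
#' pedigree by completeness, summarize kinship and inbreeding categories, fit
#' the brood-level infidelity models (with and without mother-son pairs) and
#' the selective-disappearance checks, fit the nestling-mass and survival
#' inbreeding-depression models, and run the faithful-pedigree
#' counterfactual with Fisher's exact tests and the two-stage hurdle model.
#' Each stage failure is captured in `$errors` rather than aborting the
#' bundle. With a fixed seed the bundle is identical across runs.
#'
#' @param config list with elements `params` (a [sim_params()]; ignored when
#'   `study` is given), `study` (optional [simulate_population()] output),
#'   `min_grandparents` (default 1), `inbred_threshold` (default 1e-12),
#'   `animal` (fit the additive genetic term, default `TRUE`),
#'   `with_interactions` (also fit f-by-helpers / kinship-by-helpers
#'   interaction models, default `FALSE`), `out_dir` (optional output
#'   directory for TSV/JSON reports) and `seed`.
#' @return A report bundle (list) with sections `pedigree_summary`, `table1`,
#'   `epp_models`, `selective_disappearance`, `depression_models`,
#'   `counterfactual`, plus `exclusions` and `errors`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(params = sim_params(), study = NULL, min_grandparents = 1L,
         inbred_threshold = 1e-12, animal = TRUE, with_interactions = FALSE,
         out_dir = NULL, seed = 1L),
    config)
  set.seed(cfg$seed)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  study <- cfg$study
  if (is.null(study)) {
    study <- stage("simulate", {
      p <- cfg$params
      p$seed <- cfg$seed
      simulate_population(p)
    })
    if (is.null(study)) stop("simulation failed: ", errors$simulate)
  }
  ped <- study$pedigree
  broods <- study$broods
  nest <- study$nestlings
  nest$is_mother_son <- broods$is_mother_son[match(nest$nest_id,
                                                   broods$nest_id)]

  ids <- intersect(restrict_pedigree(ped, cfg$min_grandparents), nest$id)
  kept <- nest[nest$id %in% ids, , drop = FALSE]
  exclusions <- list(
    nestlings_total = nrow(nest),
    nestlings_after_restriction = nrow(kept),
    restriction = cfg$min_grandparents,
    broods_total = nrow(broods),
    mother_son_broods = sum(broods$is_mother_son)
  )

  pedigree_summary <- stage("pedigree_summary",
                            summarize_study(study,
                                            inbred_threshold = cfg$inbred_threshold))
  table1 <- stage("table1", table1_summary(ped, broods, ids,
                                           threshold = cfg$inbred_threshold))
  epp_models <- stage("epp_models", {
    out <- list(with_mother_son = fit_epp_model(broods, TRUE),
                without_mother_son = fit_epp_model(broods, FALSE))
    if (isTRUE(cfg$with_interactions)) {
      out$with_mother_son_interaction <- fit_epp_model(broods, TRUE, TRUE)
      out$without_mother_son_interaction <- fit_epp_model(broods, FALSE, TRUE)
    }
    out
  })
  selective <- stage("selective_disappearance",
                     selective_disappearance_checks(broods))
  depression <- stage("depression_models", {
    out <- list(
      mass = fit_mass_model(kept, ped, animal_term = isTRUE(cfg$animal)),
      survival_without_mass = fit_survival_model(kept, with_mass = FALSE),
      survival_with_mass = fit_survival_model(kept, with_mass = TRUE))
    if (isTRUE(cfg$with_interactions)) {
      out$mass_interaction <- fit_mass_model(kept, ped,
                                             animal_term = isTRUE(cfg$animal),
                                             interaction = TRUE)
    }
    out
  })
  counterfactual <- stage("counterfactual", {
    assignments <- data.frame(offspring_id = nest$id,
                              social_father_id = nest$social_father_id,
                              genetic_father_id = nest$genetic_father_id,
                              ep_status = nest$ep_status,
                              stringsAsFactors = FALSE)
    faithful <- build_faithful_pedigree(ped, assignments)
    contrast <- inbreeding_contrast(ped, faithful, kept$id,
                                    ep_status = kept$ep_status,
                                    threshold = cfg$inbred_threshold)
    hurdle <- fit_hurdle_inbreeding(kept, exclude_mother_son = TRUE,
                                    threshold = cfg$inbred_threshold)
    list(contrast = contrast,
         fisher_wp_ep = fisher_exact(contrast$wp_ep),
         fisher_observed_faithful = fisher_exact(contrast$observed_vs_faithful),
         hurdle = hurdle)
  })

  bundle <- list(pedigree_summary = pedigree_summary,
                 table1 = table1,
                 epp_models = epp_models,
                 selective_disappearance = selective,
                 depression_models = depression,
                 counterfactual = counterfactual,
                 exclusions = exclusions,
                 errors = errors,
                 config = cfg[c("min_grandparents", "inbred_threshold",
                                "animal", "seed")])
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

# machine-readable bundle: one JSON of headline numbers plus TSVs per fit
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$table1)) {
    tsv(bundle$table1$pairings, "table1_pairings")
    tsv(bundle$table1$individuals, "table1_individuals")
  }
  fits <- c(
    if (!is.null(bundle$epp_models))
      setNames(bundle$epp_models, paste0("epp_", names(bundle$epp_models))),
    if (!is.null(bundle$selective_disappearance))
      setNames(bundle$selective_disappearance,
               paste0("selective_", names(bundle$selective_disappearance))),
    if (!is.null(bundle$depression_models))
      setNames(bundle$depression_models,
               paste0("depression_", names(bundle$depression_models))),
    if (!is.null(bundle$counterfactual)) list(
      hurdle_status = bundle$counterfactual$hurdle$status,
      hurdle_magnitude = bundle$counterfactual$hurdle$magnitude)
  )
  for (nm in names(fits)) {
    if (inherits(fits[[nm]], "model_fit")) tsv(fit_to_df(fits[[nm]]), nm)
  }
  head_nums <- list(
    prop_epo = bundle$pedigree_summary$prop_epo,
    prop_mother_son_broods = bundle$pedigree_summary$prop_mother_son_broods,
    prop_broods_with_epo = bundle$pedigree_summary$prop_broods_with_epo,
    prop_inbred = unname(
      bundle$pedigree_summary$prop_inbred_by_restriction[["min_gp_1"]]),
    fisher_wp_ep_p = bundle$counterfactual$fisher_wp_ep$p_value,
    fisher_observed_faithful_p =
      bundle$counterfactual$fisher_observed_faithful$p_value,
    exclusions = bundle$exclusions,
    config = bundle$config
  )
  jsonlite::write_json(head_nums, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
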