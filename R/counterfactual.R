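#' Build the counterfactual "faithful" pedigree
#'
#' Constructs the pedigree that would have obtained had every female been
#' entirely faithful: each assigned offspring's sire is replaced by its
#' social father, dams are unchanged. In the default `"recursive"` mode the
#' substitution applies to every assigned individual simultaneously, so
#' descendants' kinship is evaluated on the fully substituted pedigree; the
#' `"focal"` mode is available for sensitivity analysis via
#' [faithful_inbreeding()]. The result is re-validated (acyclicity included),
#' and the operation is idempotent.
#'
#' @param ped the observed [pedigree].
#' @param assignments data frame with columns `offspring_id`,
#'   `social_father_id` (and optionally `genetic_father_id`, `ep_status`).
#' @return A [pedigree] with substituted sires.
#' @export
build_faithful_pedigree <- function(ped, assignments) {
  stopifnot(all(c("offspring_id", "social_father_id") %in% names(assignments)))
  r <- ped$records
  at <- match(assignments$offspring_id, r$id)
  if (anyNA(at)) {
    stop("assignments name offspring absent from the pedigree: ",
         paste(assignments$offspring_id[is.na(at)], collapse = ", "))
  }
  r$sire[at] <- as.character(assignments$social_father_id)
  pedigree(r$id, r$sire, r$dam, cohort = r$cohort, sex = r$sex)
}

#' Inbreeding coefficients under the faithful counterfactual
#'
#' Convenience front-end returning f for `ids` under the fully substituted
#' (`mode = "recursive"`) pedigree, or under a one-generation substitution
#' (`mode = "focal"`) where each offspring's f is the kinship of its social
#' father and dam evaluated on the *observed* pedigree (ancestral sires
#' unchanged).
#'
#' @inheritParams build_faithful_pedigree
#' @param ids identifiers to evaluate.
#' @param mode `"recursive"` (default) or `"focal"`.
#' @return Numeric vector of f values named by `ids`.
#' @export
faithful_inbreeding <- function(ped, assignments, ids,
                                mode = c("recursive", "focal")) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  if (mode == "recursive") {
    fped <- build_faithful_pedigree(ped, assignments)
    f <- inbreeding(fped, ids)
    if (length(ids) == 1L) f <- f$f
  } else {
    at <- match(ids, assignments$offspring_id)
    if (anyNA(at)) stop("focal mode requires an assignment for every id")
    sf <- as.character(assignments$social_father_id[at])
    dams <- ped$records$dam[ped_index(ped, ids)]
    if (anyNA(dams)) stop("focal mode requires a recorded dam for every id")
    f <- kinship(ped, sf, dams)
    if (length(ids) == 1L) f <- f$kinship
  }
  setNames(f, ids)
}

#' Two-by-two contingency table
#'
#' @param cells numeric matrix 2x2 (or vector of four counts, row-major) of
#'   non-negative counts.
#' @param row_labels,col_labels dimension labels.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(cells,
                            row_labels = c("row1", "row2"),
                            col_labels = c("col1", "col2")) {
  m <- matrix(as.numeric(cells), nrow = 2, byrow = !is.matrix(cells))
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative")
  dimnames(m) <- list(row_labels, col_labels)
  structure(list(cells = m,
                 row_totals = rowSums(m),
                 col_totals = colSums(m),
                 total = sum(m)),
            class = "contingency_2x2")
}

#' Row percentages of a 2x2 table
#'
#' Percentages per row, rounded half-up to one decimal (the convention of the
#' field's summary tables).
#'
#' @param tab a [contingency_2x2].
#' @return Matrix of row percentages.
#' @export
row_percentages <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  p <- 100 * tab$cells / tab$row_totals
  round_half_up(p, 1)
}

round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- cbind(x$cells, total = x$row_totals)
  print(m)
  invisible(x)
}

#' Observed-versus-faithful and WP-versus-EP inbreeding tables
#'
#' Cross-tabulates inbred (f above `threshold`) against outbred status for a
#' restricted id set under the observed and the faithful pedigree, and, when
#' `ep_status` is supplied, also the within-pair/extra-pair by inbred/outbred
#' table under the observed pedigree.
#'
#' @param ped observed [pedigree].
#' @param faithful faithful [pedigree] (from [build_faithful_pedigree()]).
#' @param ids identifiers present in both pedigrees.
#' @param ep_status optional factor/character aligned with `ids` with values
#'   `"WP"`/`"EP"`.
#' @param threshold f strictly above this counts as inbred.
#' @return List with `observed_vs_faithful` (a [contingency_2x2]), `wp_ep`
#'   (a [contingency_2x2] or `NULL`), and the underlying f vectors.
#' @export
inbreeding_contrast <- function(ped, faithful, ids, ep_status = NULL,
                                threshold = 1e-12) {
  ids <- as.character(ids)
  f_obs <- inbreeding(ped, ids)
  f_fai <- inbreeding(faithful, ids)
  if (length(ids) == 1L) { f_obs <- f_obs$f; f_fai <- f_fai$f }
  ovf <- contingency_2x2(
    c(sum(f_obs > threshold), sum(f_obs <= threshold),
      sum(f_fai > threshold), sum(f_fai <= threshold)),
    row_labels = c("observed", "faithful"),
    col_labels = c("inbred", "outbred"))
  wp_ep <- NULL
  if (!is.null(ep_status)) {
    stopifnot(length(ep_status) == length(ids))
    wp <- ep_status == "WP"
    wp_ep <- contingency_2x2(
      c(sum(wp & f_obs > threshold), sum(wp & f_obs <= threshold),
        sum(!wp & f_obs > threshold), sum(!wp & f_obs <= threshold)),
      row_labels = c("within-pair", "extra-pair"),
      col_labels = c("inbred", "outbred"))
  }
  list(observed_vs_faithful = ovf, wp_ep = wp_ep,
       f_observed = setNames(f_obs, ids), f_faithful = setNames(f_fai, ids))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (summing hypergeometric probabilities no larger
#' than that of the observed table) and the conditional-MLE odds ratio. A
#' zero margin leaves the odds ratio undefined and returns p = 1, flagged.
#'
#' @param tab a [contingency_2x2] or a 2x2 matrix of counts.
#' @return List with `p_value`, `odds_ratio` and `note`.
#' @export
fisher_exact <- function(tab) {
  m <- if (inherits(tab, "contingency_2x2")) tab$cells else
    matrix(as.numeric(tab), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_,
                note = "zero margin: odds ratio undefined"))
  }
  ft <- fisher.test(m)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       note = "conditional MLE odds ratio")
}

#' Two-stage hurdle model of offspring inbreeding
#'
#' Inbreeding coefficients are zero-heavy, so their dependence on within-pair
#' status is modelled in two stages: (1) a binomial mixed model of inbred
#' status (f above `threshold`) on WP/EP status with nest and cohort random
#' intercepts; (2) a linear mixed model of log(f) on WP/EP status over the
#' inbred subset only, with the same random intercepts. Mother-son broods are
#' excluded by default (their forced infidelity would bias both stages), and
#' helper number is deliberately not a covariate here; `with_helpers`
#' re-enables it for sensitivity analysis.
#'
#' @param nestlings data frame with columns `f`, `ep_status`, `nest_id`,
#'   `cohort`, `is_mother_son` (or a `mother_son_ids` lookup via broods) and
#'   optionally `n_helpers`.
#' @param exclude_mother_son drop offspring of mother-son social pairs
#'   (default `TRUE`; requires an `is_mother_son` column).
#' @param with_helpers add helper class to both stages.
#' @param threshold f strictly above this counts as inbred.
#' @param min_inbred minimum inbred individuals required to attempt stage 2.
#' @return List with `status` (stage-1 `model_fit`) and `magnitude` (stage-2
#'   `model_fit`, or `NULL` with a `magnitude_note` when the inbred subset is
#'   too small).
#' @export
fit_hurdle_inbreeding <- function(nestlings, exclude_mother_son = TRUE,
                                  with_helpers = FALSE, threshold = 1e-12,
                                  min_inbred = 30L) {
  d <- nestlings
  if (exclude_mother_son) {
    if (!"is_mother_son" %in% names(d)) {
      stop("exclude_mother_son requires an is_mother_son column")
    }
    d <- d[!d$is_mother_son, , drop = FALSE]
  }
  d <- nestling_frame(d)
  d$inbred <- d$f > threshold
  rhs <- "ep_status"
  if (with_helpers) rhs <- paste(rhs, "+ n_helpers")
  form1 <- as.formula(paste("inbred ~", rhs,
                            "+ (1 | nest_id) + (1 | cohort)"))
  stage1 <- safe_fit(
    lme4::glmer(form1, data = d, family = binomial,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    n_obs = nrow(d))
  di <- d[d$inbred, , drop = FALSE]
  if (nrow(di) < min_inbred) {
    return(list(status = stage1, magnitude = NULL,
                magnitude_note = sprintf(
                  "stage 2 skipped: only %d inbred individuals (< %d)",
                  nrow(di), min_inbred)))
  }
  di$log_f <- log(di$f)
  form2 <- as.formula(paste("log_f ~", rhs,
                            "+ (1 | nest_id) + (1 | cohort)"))
  stage2 <- safe_fit(
    lme4::lmer(form2, data = di,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    n_obs = nrow(di))
  list(status = stage1, magnitude = stage2, magnitude_note = NULL)
}
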