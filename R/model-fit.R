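#' @importFrom lme4 lmer glmer fixef VarCorr lmerControl glmerControl
NULL

# Uniform container for mixed-model results: coefficients with Wald SEs and
# 95% CIs on the link scale, variance components, convergence diagnostics.
new_model_fit <- function(fit, n_obs, notes = character(0)) {
  if (is.null(fit)) {
    return(structure(list(coefficients = numeric(0), se = numeric(0),
                          ci = matrix(numeric(0), 0, 2),
                          p_value = numeric(0),
                          variance_components = numeric(0),
                          n_obs = n_obs, converged = FALSE,
                          notes = notes, model = NULL),
                     class = "model_fit"))
  }
  beta <- lme4::fixef(fit)
  se <- tryCatch(sqrt(diag(as.matrix(vcov(fit)))), error = function(e) NULL)
  if (is.null(se)) {
    # degenerate fit (e.g. zero-variance response): report a flagged shell
    return(structure(list(coefficients = beta,
                          se = rep(NA_real_, length(beta)),
                          ci = cbind(lower = rep(NA_real_, length(beta)),
                                     upper = rep(NA_real_, length(beta))),
                          p_value = rep(NA_real_, length(beta)),
                          variance_components = numeric(0), n_obs = n_obs,
                          converged = FALSE,
                          notes = c(notes, "degenerate: vcov unavailable"),
                          model = fit),
                     class = "model_fit"))
  }
  z <- qnorm(0.975)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- setNames(vc$vcov, ifelse(is.na(vc$grp), "Residual", vc$grp))
  msgs <- fit@optinfo$conv$lme4$messages
  # a variance component on the zero boundary is a legitimate estimate,
  # not a convergence failure
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  conv <- length(msgs) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L)
  if (!conv) notes <- c(notes, "nonconvergence")
  # complete separation inflates Wald SEs without bound on the logit scale
  if (isGLMM(fit) && any(se > 10)) {
    notes <- c(notes, "possible_separation")
    conv <- FALSE
  }
  structure(list(coefficients = beta, se = se, ci = ci, p_value = p,
                 variance_components = vcomp, n_obs = n_obs,
                 converged = conv, notes = notes, model = fit),
            class = "model_fit")
}

isGLMM <- function(fit) methods::is(fit, "glmerMod")

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> n =", x$n_obs,
      if (x$converged) "(converged)" else
        paste0("(flagged: ", paste(x$notes, collapse = ", "), ")"), "\n")
  if (length(x$coefficients)) {
    tab <- data.frame(estimate = round(x$coefficients, 4),
                      se = round(x$se, 4),
                      lower = round(x$ci[, 1], 4),
                      upper = round(x$ci[, 2], 4),
                      p = signif(x$p_value, 3))
    print(tab)
  }
  if (length(x$variance_components)) {
    cat("variance components:\n")
    print(round(x$variance_components, 4))
  }
  invisible(x)
}

# Fit wrapper that converts hard failures into flagged fits instead of errors
# and records warnings (e.g. convergence grumbles) without losing the fit.
safe_fit <- function(expr, n_obs, notes = character(0)) {
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0("fit_error: ", conditionMessage(e)))
      NULL
    }),
    warning = function(w) {
      notes <<- c(notes, paste0("fit_warning: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  new_model_fit(fit, n_obs, notes)
}

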