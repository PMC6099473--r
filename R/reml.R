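# Average-information REML for linear mixed models with an arbitrary known
# covariance structure (the pedigree numerator relationship matrix) among one
# random term's levels. Written for the animal-model case where sparse
# mixed-model machinery degrades: the relationship matrix among ~4-5k
# phenotyped nestlings is dense, so all heavy operations here are dense BLAS
# calls (chol, crossprod, rowsum) on n x n matrices.
#
# Model: y = X beta + sum_i u_i + a + e,  u_i ~ N(0, s2_i ZZ') over factors,
# a ~ N(0, s2_A A), e ~ N(0, s2_e I). Scores and the average-information
# matrix use the standard identities
#   dL/ds2_i = -1/2 [ tr(P V_i) - y'P V_i P y ]
#   AI_ij    =  1/2  y'P V_i P V_j P y
# with P the REML projection matrix. Variance updates are Newton steps on the
# AI matrix with step-halving and clamping at a small positive floor.

aireml <- function(y, X, groups = list(), covmats = list(),
                   max_iter = 50L, tol = 1e-7) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  for (A in covmats) stopifnot(nrow(A) == n, ncol(A) == n)
  gidx <- lapply(groups, function(g) as.integer(factor(g)))
  terms <- c(names(groups), names(covmats), "Residual")
  k <- length(terms)
  kg <- length(groups)
  kc <- length(covmats)

  ols <- stats::lm.fit(X, y)
  v0 <- stats::var(ols$residuals)
  theta <- setNames(rep(v0 / k, k), terms)
  floor_v <- 1e-8 * v0

  build_V <- function(theta) {
    V <- diag(theta[["Residual"]], n)
    for (j in seq_len(kc)) {
      V <- V + theta[[kg + j]] * covmats[[j]]
    }
    for (j in seq_len(kg)) {
      g <- gidx[[j]]
      th <- theta[[j]]
      for (lev in split(seq_len(n), g)) {
        V[lev, lev] <- V[lev, lev] + th
      }
    }
    V
  }

  # returns NULL on a failed factorization
  reml_pieces <- function(theta) {
    V <- build_V(theta)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtVXinv <- chol2inv(chx)
    P <- Vinv - VX %*% XtVXinv %*% t(VX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, XtVXinv = XtVXinv, Vinv = Vinv)
  }

  pc <- reml_pieces(theta)
  if (is.null(pc)) stop("initial REML factorization failed")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- pc$P
    Py <- pc$Py
    # tr(P V_i) and quadratic forms y'P V_i P y per component
    trPV <- numeric(k)
    quad <- numeric(k)
    U <- matrix(0, n, k)  # columns V_i P y
    for (j in seq_len(kg)) {
      g <- gidx[[j]]
      B <- rowsum(P, g)                       # q x n group sums of rows
      trPV[j] <- sum(B[cbind(g, seq_len(n))])
      s <- rowsum(Py, g)
      U[, j] <- s[g]
      quad[j] <- sum(s^2)
    }
    for (j in seq_len(kc)) {
      A <- covmats[[j]]
      trPV[kg + j] <- sum(P * A)
      U[, kg + j] <- A %*% Py
      quad[kg + j] <- sum(Py * U[, kg + j])
    }
    trPV[k] <- sum(diag(P))
    U[, k] <- Py
    quad[k] <- sum(Py^2)

    score <- -0.5 * (trPV - quad)
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    # active set: components pinned at the zero floor with a negative
    # gradient stay put; Newton step over the free components only
    active <- !(theta <= floor_v * 1.01 & score < 0)
    if (!any(active)) { converged <- TRUE; break }
    delta <- numeric(k)
    sol <- tryCatch(solve(AI[active, active, drop = FALSE], score[active]),
                    error = function(e) NULL)
    if (is.null(sol)) {  # fall back to a diagonally scaled gradient step
      sol <- score[active] / pmax(diag(AI)[active], 1e-12)
    }
    delta[active] <- sol
    # step-halving onto an improved, admissible point
    step <- 1
    repeat {
      cand <- pmax(theta + step * delta, floor_v)
      pc2 <- reml_pieces(cand)
      if (!is.null(pc2) && pc2$ll >= pc$ll - 1e-10) break
      step <- step / 2
      if (step < 1e-4) { pc2 <- NULL; break }
    }
    if (is.null(pc2)) {
      # no improving admissible step exists: numerically at the
      # (possibly boundary-constrained) REML optimum
      converged <- TRUE
      break
    }
    moved <- max(abs(cand - theta) / (abs(theta) + v0 * 1e-4))
    ll_gain <- pc2$ll - pc$ll
    theta <- cand
    pc <- pc2
    if (moved < tol || ll_gain < 1e-8) { converged <- TRUE; break }
  }

  beta_cov <- pc$XtVXinv
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  beta <- drop(beta_cov %*% crossprod(X, pc$Vinv %*% y))
  names(beta) <- colnames(X)
  se <- setNames(sqrt(diag(beta_cov)), colnames(X))
  # asymptotic variance-component SEs from the AI matrix at the optimum
  vc_se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, k))
  list(coefficients = beta, se = se, beta_cov = beta_cov,
       variance_components = theta, vc_se = setNames(vc_se, terms),
       logLik = pc$ll, converged = converged, iterations = iter,
       at_boundary = terms[theta <= floor_v * 1.01])
}

# wrap an aireml result in the common model_fit container
aireml_model_fit <- function(fit, n_obs, notes = character(0)) {
  z <- qnorm(0.975)
  ci <- cbind(lower = fit$coefficients - z * fit$se,
              upper = fit$coefficients + z * fit$se)
  p <- 2 * stats::pnorm(-abs(fit$coefficients / fit$se))
  if (!fit$converged) notes <- c(notes, "nonconvergence")
  if (length(fit$at_boundary)) {
    notes <- c(notes, paste0("variance at boundary: ",
                             paste(fit$at_boundary, collapse = ", ")))
  }
  structure(list(coefficients = fit$coefficients, se = fit$se, ci = ci,
                 p_value = p, variance_components = fit$variance_components,
                 vc_se = fit$vc_se, n_obs = n_obs,
                 converged = fit$converged, notes = notes, model = fit),
            class = "model_fit")
}
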