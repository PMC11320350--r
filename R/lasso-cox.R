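# L1-penalized Cox regression for protein selection. The heavy lifting is
# done by glmnet; the design is centered and scaled here (population sd) and
# glmnet is called with standardize = FALSE, so the fitted problem is exactly
#   min_b  -(1/n) * logPL_Breslow(b_std) + lambda * ||b_std||_1
# (unpenalized columns via penalty.factor), which makes the KKT conditions
# checkable against an analytic Breslow score. Coefficients are returned on
# the original scale.

#' Fit an L1-penalized Cox model over a lambda path
#'
#' @param X numeric design matrix (participants x covariates), no missing
#'   values. Include chronological age as a column named `"age"` when
#'   training a clock.
#' @param time,event survival outcome; at least one event.
#' @param lambda optional user path (decreasing); default lets the engine
#'   choose `nlambda` values down to `lambdaMinRatio * lambda_max`.
#' @param nlambda,lambdaMinRatio path controls.
#' @param unpenalizedAge if `TRUE`, the `"age"` column is not penalized
#'   (by default age competes with the proteins for selection).
#' @param thresh coordinate-descent convergence threshold.
#' @return a [PenalizedCoxFit-class].
#' @seealso [selectLambda()], [coxKKTResidual()]
#' @export
fitLassoCox <- function(X, time, event, lambda = NULL, nlambda = 100L,
                        lambdaMinRatio = NULL, unpenalizedAge = FALSE,
                        thresh = 1e-10) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(time) || anyNA(event)) stop("missing or non-finite values")
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (sum(event) < 1) stop("no events")
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  if (any(scl == 0)) stop("constant covariate column(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pf <- rep(1, ncol(X))
  if (unpenalizedAge) {
    if (!"age" %in% colnames(X)) stop("no 'age' column to leave unpenalized")
    pf[colnames(X) == "age"] <- 0
  }
  y <- survival::Surv(time, event)
  args <- list(x = Xs, y = y, family = "cox", standardize = FALSE,
               penalty.factor = pf, thresh = thresh, maxit = 1e6)
  if (!is.null(lambda)) args$lambda <- sort(lambda, decreasing = TRUE)
  else { args$nlambda <- nlambda
         if (!is.null(lambdaMinRatio)) args$lambda.min.ratio <- lambdaMinRatio }
  fit <- do.call(glmnet::glmnet, args)
  bstd <- as.matrix(fit$beta)
  beta <- bstd / scl
  dimnames(beta) <- list(colnames(X), NULL)
  methods::new("PenalizedCoxFit", lambda = fit$lambda, beta = beta,
               penaltyFactor = pf, center = ctr, scale = scl,
               nobs = length(time), nevents = as.integer(sum(event)),
               fit = fit)
}

#' Selected proteins at a lambda value
#'
#' @param fit a [PenalizedCoxFit-class].
#' @param lambda a value on (or near) the fitted path; the closest path
#'   point is used.
#' @return character vector of covariates with nonzero coefficients.
#' @export
selectedCovariates <- function(fit, lambda) {
  i <- which.min(abs(fit@lambda - lambda))
  rownames(fit@beta)[fit@beta[, i] != 0]
}

#' Coefficients at a lambda value (original scale)
#'
#' @inheritParams selectedCovariates
#' @return named coefficient vector.
#' @export
pathCoef <- function(fit, lambda) {
  i <- which.min(abs(fit@lambda - lambda))
  stats::setNames(fit@beta[, i], rownames(fit@beta))
}

# Breslow partial-likelihood score at beta, computed with risk-set cumsums.
breslowScore <- function(X, time, event, beta) {
  eta <- drop(X %*% beta)
  w <- exp(eta - max(eta))
  ord <- order(time, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]; wo <- w[ord]
  cw <- cumsum(wo)                             # sum of w over {time >= t}
  cX <- apply(Xo * wo, 2, cumsum)              # weighted covariate sums
  # map back: for each i, risk set sums at its time (ties share the set)
  to <- time[ord]
  last <- cumsum(!duplicated(to))              # unused; handle ties below
  # position of the last index in ord with the same time (largest risk set)
  idx <- seq_along(to)
  # For tied times, the Breslow risk set is {time >= t}; take the maximal
  # cumulative position among ties.
  pos <- stats::ave(idx, to, FUN = max)
  num <- cX[pos, , drop = FALSE]
  den <- cw[pos]
  sc <- colSums((Xo - num / den)[event[ord] == 1, , drop = FALSE])
  sc
}

#' KKT residual of a penalized Cox solution
#'
#' For the objective \eqn{-(1/n)\ell(\beta) + \lambda \sum_j p_j |\beta_j|}
#' on the standardized design, stationarity requires
#' \eqn{|s_j|/n \le \lambda p_j} for zero coefficients and
#' \eqn{s_j/n = \lambda p_j \,\mathrm{sign}(\beta_j)} for active ones,
#' where s is the Breslow partial-likelihood score. Returns the maximum
#' violation over covariates at the requested path point (0 for a solution
#' converged to tolerance).
#'
#' @param fit a [PenalizedCoxFit-class].
#' @param X,time,event the training data passed to [fitLassoCox()].
#' @param lambda path point to check.
#' @return maximum KKT violation (scalar).
#' @export
coxKKTResidual <- function(fit, X, time, event, lambda) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
  i <- which.min(abs(fit@lambda - lambda))
  lam <- fit@lambda[i]
  bstd <- fit@beta[, i] * fit@scale
  s <- breslowScore(Xs, time, event, bstd) / length(time)
  pf <- fit@penaltyFactor
  act <- bstd != 0
  viol <- numeric(length(bstd))
  viol[!act] <- pmax(abs(s[!act]) - lam * pf[!act], 0)
  viol[act] <- abs(s[act] - lam * pf[act] * sign(bstd[act]))
  max(viol)
}

#' Choose the penalty by cross-validated partial likelihood (or fix it)
#'
#' `method = "cv"` runs k-fold cross-validation of the partial-likelihood
#' deviance with seed-derived fold assignment and returns the deviance
#' minimizer (`lambda.min`). `method = "fixed"` returns `value` unchanged,
#' for reproducing a published penalty.
#'
#' @param X,time,event training data (ignored for `"fixed"`).
#' @param method `"cv"` or `"fixed"`.
#' @param value the fixed penalty when `method = "fixed"`.
#' @param nfolds folds for cross-validation.
#' @param seed fold-assignment seed.
#' @param unpenalizedAge passed through to the penalized fit.
#' @return list with `lambda` and, for CV, the `cvfit` object.
#' @export
selectLambda <- function(X = NULL, time = NULL, event = NULL,
                         method = c("cv", "fixed"), value = NULL,
                         nfolds = 10L, seed = 1L, unpenalizedAge = FALSE) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("fixed method needs a value")
    return(list(lambda = value, method = "fixed"))
  }
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pf <- rep(1, ncol(X))
  if (unpenalizedAge) pf[colnames(X) == "age"] <- 0
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  cvfit <- glmnet::cv.glmnet(Xs, survival::Surv(time, event), family = "cox",
                             standardize = FALSE, penalty.factor = pf,
                             foldid = foldid, thresh = 1e-9, maxit = 1e6)
  list(lambda = cvfit$lambda.min, method = "cv", cvfit = cvfit,
       foldid = foldid)
}
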