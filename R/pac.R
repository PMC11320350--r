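#' Split participant ids into training and test sets
#'
#' Seed-deterministic random partition with `|train| = round(fraction * n)`;
#' the two sets are disjoint and exhaustive.
#'
#' @param ids participant identifiers (n >= 2).
#' @param fraction training fraction in (0, 1); the conventional split for
#'   clock training is 70/30.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @examples
#' splitCohort(paste0("S", 1:10), 0.5, seed = 1)
#' @export
splitCohort <- function(ids, fraction = 0.7, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 ids")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ntrain <- round(fraction * n)
  set.seed(seed)
  tr <- sample.int(n, ntrain)
  list(train = ids[sort(tr)], test = ids[sort(setdiff(seq_len(n), tr))])
}

#' Build a proteomic aging clock from selected proteins
#'
#' Fits two Gompertz proportional-hazards models on the same training rows:
#' the full model on chronological age plus the selected proteins, and the
#' age-only reference model on chronological age alone. Together with the
#' risk horizon they define the clock: a participant's proteomic age is the
#' chronological age at which the reference model's cumulative mortality
#' risk over the horizon equals the full model's risk for that participant.
#'
#' @param X participants-by-proteins matrix (training rows, imputed).
#' @param age chronological age at baseline (years).
#' @param time,event all-cause mortality outcome.
#' @param selected protein ids to include (typically from [fitLassoCox()]
#'   at the chosen penalty; may be empty).
#' @param horizon risk horizon k in years. The default of 10 years follows
#'   the established mortality-clock construction this transform builds on.
#' @param meta optional metadata list stored in the model.
#' @return a [PACModel-class].
#' @export
buildPAC <- function(X, age, time, event, selected, horizon = 10,
                     meta = list()) {
  X <- as.matrix(X)
  selected <- setdiff(selected, "age")
  miss <- setdiff(selected, colnames(X))
  if (length(miss)) stop("selected proteins absent from matrix: ",
                         paste(miss, collapse = ", "))
  full <- fitGompertz(cbind(age = age, X[, selected, drop = FALSE]),
                      time, event)
  ageOnly <- fitGompertz(cbind(age = age), time, event)
  if (ageOnly@coef[["age"]] <= 0)
    stop("age-only Gompertz model has non-positive age coefficient; ",
         "the proteomic-age inversion is undefined")
  meta$nTrain <- length(time)
  meta$nEvents <- sum(event)
  methods::new("PACModel", full = full, ageOnly = ageOnly,
               horizon = horizon, selected = as.character(selected),
               meta = meta)
}

#' Proteomic age of a single participant
#'
#' Computes the full-model cumulative mortality risk
#' \eqn{M = 1 - \exp\{-e^{\beta_0 + x'\beta}(e^{a k} - 1)/a\}} over the
#' clock horizon and inverts the age-only reference model at that risk:
#' \deqn{A = \frac{\log\{-\log(1 - M)\, a_0 / (e^{a_0 k} - 1)\} - \beta_{00}}
#'   {\beta_{age,0}}.}
#' The deviation A minus chronological age is the age acceleration.
#'
#' @param pac a [PACModel-class].
#' @param x named covariate vector or one-row data.frame covering `age` and
#'   every selected protein.
#' @return data.frame with `proteomic_age`, `deviation`, `risk`.
#' @export
proteomicAge <- function(pac, x) {
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  M <- gompertzCumInc(pac@full, x, pac@horizon)
  A <- invertAgeOnly(pac, M)
  data.frame(proteomic_age = A, deviation = A - unname(x[["age"]]),
             risk = M)
}

# Closed-form inversion of the age-only model at cumulative risk M.
invertAgeOnly <- function(pac, M) {
  if (any(M <= 0) || any(M >= 1))
    stop("cumulative risk must lie strictly in (0, 1)")
  m <- pac@ageOnly
  a0 <- m@shape
  denom <- if (abs(a0) < 1e-10) pac@horizon else expm1(a0 * pac@horizon) / a0
  (log(-log1p(-M) / denom) - m@lograte) / m@coef[["age"]]
}

#' Score a cohort with a proteomic aging clock
#'
#' Batch application of [proteomicAge()]: one row per participant with
#' proteomic age, deviation from chronological age, and the full-model risk
#' over the clock horizon. Results are invariant to protein column order.
#'
#' @param model a [PACModel-class].
#' @param x a [ProteomicCohort-class] (imputed) or a participants-by-
#'   covariates matrix containing an `age` column and the selected proteins.
#' @param age chronological ages, required for the matrix method when the
#'   matrix has no `age` column.
#' @param ... unused.
#' @return data.frame: `participant_id`, `age`, `proteomic_age`,
#'   `deviation`, `risk`.
#' @name scoreCohort
NULL

#' @rdname scoreCohort
#' @export
setMethod("scoreCohort", c("PACModel", "matrix"), function(model, x, age = NULL, ...) {
  if (is.null(age)) {
    if (!"age" %in% colnames(x)) stop("matrix lacks an 'age' column")
    age <- x[, "age"]
  } else x <- cbind(x, age = age)
  if (anyNA(x[, c("age", model@selected), drop = FALSE]))
    stop("missing covariate values; impute before scoring")
  M <- gompertzCumInc2(model@full, x, model@horizon)
  A <- invertAgeOnly(model, M)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  data.frame(participant_id = ids, age = unname(age),
             proteomic_age = unname(A), deviation = unname(A - age),
             risk = unname(M), row.names = NULL)
})

#' @rdname scoreCohort
#' @export
setMethod("scoreCohort", c("PACModel", "ProteomicCohort"), function(model, x, ...) {
  cd <- cohortData(x)
  scoreCohort(model, cbind(proteinMatrix(x), age = cd$age))
})

# Vectorized cumulative incidence for a covariate matrix.
gompertzCumInc2 <- function(model, x, k) {
  eta <- model@lograte + gompertzLP(model, x)
  gompertzCDF(eta, model@shape, k)
}

#' Train a proteomic aging clock end to end
#'
#' Convenience wrapper: penalized Cox selection on the training rows at a
#' chosen or cross-validated penalty, then [buildPAC()] on the selected
#' proteins.
#'
#' @param x a [ProteomicCohort-class] with no missing protein values.
#' @param trainIds participant ids to train on (default: all).
#' @param lambda `"cv"` for cross-validated selection or a numeric penalty.
#' @param horizon risk horizon in years.
#' @param unpenalizedAge leave age unpenalized in the selection step.
#' @param seed seed for cross-validation folds.
#' @return a [PACModel-class].
#' @export
trainPAC <- function(x, trainIds = NULL, lambda = "cv", horizon = 10,
                     unpenalizedAge = FALSE, seed = 1L) {
  stopifnot(methods::is(x, "ProteomicCohort"))
  cd <- cohortData(x)
  if (!all(c("time_death", "died") %in% colnames(cd)))
    stop("cohort lacks mortality outcome")
  if (is.null(trainIds)) trainIds <- colnames(x)
  keep <- colnames(x) %in% trainIds
  M <- proteinMatrix(x)[keep, , drop = FALSE]
  if (anyNA(M)) stop("protein matrix has missing values; impute first")
  cd <- cd[keep, ]
  D <- cbind(M, age = cd$age)
  if (identical(lambda, "cv")) {
    lam <- selectLambda(D, cd$time_death, cd$died, method = "cv",
                        seed = seed, unpenalizedAge = unpenalizedAge)$lambda
  } else lam <- as.numeric(lambda)
  fit <- fitLassoCox(D, cd$time_death, cd$died, unpenalizedAge = unpenalizedAge)
  if (lam < min(fit@lambda) || lam > max(fit@lambda))
    fit <- fitLassoCox(D, cd$time_death, cd$died, lambda = sort(
      unique(c(fit@lambda, lam)), decreasing = TRUE),
      unpenalizedAge = unpenalizedAge)
  sel <- setdiff(selectedCovariates(fit, lam), "age")
  buildPAC(M, cd$age, cd$time_death, cd$died, sel, horizon = horizon,
           meta = list(lambda = lam, seed = seed,
                       nSelected = length(sel)))
}

#' Serialize / restore a clock as structured text
#'
#' The model file is YAML with both Gompertz models (shape, lograte, named
#' coefficients), the horizon, and training metadata. Numeric values are
#' stored as full-precision decimal strings so a round trip reproduces
#' scores exactly.
#'
#' @param model a [PACModel-class].
#' @param path file path.
#' @return `readPACModel()` returns the restored [PACModel-class];
#'   `writePACModel()` returns `path` invisibly.
#' @export
writePACModel <- function(model, path) {
  num <- function(v) stats::setNames(sprintf("%.17g", v), names(v))
  gm <- function(m) list(shape = sprintf("%.17g", m@shape),
                         lograte = sprintf("%.17g", m@lograte),
                         coef = as.list(num(m@coef)))
  obj <- list(class = "PACModel",
              horizon = sprintf("%.17g", model@horizon),
              selected = as.list(model@selected),
              full = gm(model@full), age_only = gm(model@ageOnly),
              meta = lapply(model@meta, function(v)
                if (is.numeric(v)) sprintf("%.17g", v) else v))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePACModel
#' @export
readPACModel <- function(path) {
  obj <- yaml::read_yaml(path)
  gm <- function(l) methods::new("GompertzModel",
    shape = as.numeric(l$shape), lograte = as.numeric(l$lograte),
    coef = stats::setNames(as.numeric(unlist(l$coef)), names(l$coef)),
    vcov = matrix(NA_real_, 0, 0), loglik = NA_real_, convergence = list())
  methods::new("PACModel", full = gm(obj$full), ageOnly = gm(obj$age_only),
               horizon = as.numeric(obj$horizon),
               selected = as.character(unlist(obj$selected)),
               meta = obj$meta)
}
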