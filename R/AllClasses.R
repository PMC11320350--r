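#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#'   SummarizedExperiment
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx coef cor dnorm lm.fit na.omit optim p.adjust
#'   pchisq phyper pnorm qnorm quantile rbinom rexp rnorm runif sd setNames
#'   uniroot var
#' @importFrom utils head modifyList
NULL

#' Simulation parameters for a synthetic proteomic cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort size, the
#' protein panel and its age trends, the sparse causal protein subset driving
#' mortality, the Gompertz baseline hazard, follow-up horizon, missingness,
#' and per-disease cause-specific hazards (with death as the competing event).
#'
#' Defaults emulate the structure of a middle-aged/older adult biobank cohort:
#' baseline ages Uniform(39, 70), administrative censoring at 13.3 years of
#' follow-up, and a baseline log-rate calibrated (when `lograte = NA`) so that
#' marginal cumulative mortality over follow-up is 10.9%.
#'
#' @slot nParticipants number of participants.
#' @slot nProteins number of proteins on the panel.
#' @slot nCausal number of proteins with a true effect on mortality.
#' @slot ageRange baseline age range (years), sampled uniformly.
#' @slot ageSlopes per-protein linear age trend (expression units / year);
#'   length-0 means "draw from Normal(0, slopeSD) under the seed".
#' @slot slopeSD sd of drawn age slopes when `ageSlopes` is empty.
#' @slot noiseSD residual sd of protein expression around its age trend.
#' @slot causalBetas log hazard ratio per expression unit for each causal
#'   protein; recycled to `nCausal`.
#' @slot gompertzShape Gompertz shape (1/years), > 0.
#' @slot gompertzLograte log baseline hazard at t = 0 for zero covariates;
#'   `NA` requests calibration to `targetMortality`.
#' @slot targetMortality marginal cumulative mortality over follow-up used to
#'   calibrate `gompertzLograte` when it is `NA`.
#' @slot ageBeta log hazard ratio per year of baseline age.
#' @slot followupYears administrative censoring horizon (years).
#' @slot missingRate MCAR cell-missingness fraction in [0, 1).
#' @slot diseaseSpecs named list of cause-specific disease hazards; each
#'   element is a list with `lograte`, `ageBeta` and optionally
#'   `proteinBetas` (named by protein id).
#' @slot seed integer seed governing the whole cohort; component sub-streams
#'   are derived deterministically from it.
#' @export
setClass("SimParams", representation(
  nParticipants = "integer",
  nProteins = "integer",
  nCausal = "integer",
  ageRange = "numeric",
  ageSlopes = "numeric",
  slopeSD = "numeric",
  noiseSD = "numeric",
  causalBetas = "numeric",
  gompertzShape = "numeric",
  gompertzLograte = "numeric",
  targetMortality = "numeric",
  ageBeta = "numeric",
  followupYears = "numeric",
  missingRate = "numeric",
  diseaseSpecs = "list",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be positive")
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be positive")
  if (object@nCausal > object@nProteins)
    msg <- c(msg, "nCausal must not exceed nProteins")
  if (object@gompertzShape <= 0) msg <- c(msg, "gompertzShape must be > 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (object@followupYears <= 0) msg <- c(msg, "followupYears must be > 0")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
    msg <- c(msg, "ageRange must be (lo, hi) with lo <= hi")
  if (length(msg)) msg else TRUE
})

#' Cohort container: protein expression plus participant survival metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay, `"npx"`,
#' holding continuous protein expression values (proteins in rows,
#' participants in columns; `NA` = missing). `rowData` carries the
#' protein-to-gene-symbol map in a `gene` column; `colData` carries the
#' participant table: baseline age, sex, covariates, the all-cause mortality
#' outcome (`time_death`, `died`) and per-disease competing-risks triples
#' (`time_<name>`, `status_<name>` with 0 = censored, 1 = event,
#' 2 = death first).
#'
#' @export
setClass("ProteomicCohort", contains = "SummarizedExperiment")

setValidity("ProteomicCohort", function(object) {
  msg <- character()
  if (!"npx" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'npx' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"age" %in% colnames(cd)) msg <- c(msg, "colData must contain 'age'")
  if ("time_death" %in% colnames(cd)) {
    if (!"died" %in% colnames(cd))
      msg <- c(msg, "'time_death' requires a 'died' indicator")
    else {
      if (any(cd$time_death <= 0, na.rm = TRUE))
        msg <- c(msg, "time_death must be positive")
      if (!all(stats::na.omit(cd$died) %in% c(0, 1)))
        msg <- c(msg, "died must be 0/1")
    }
  }
  st <- grep("^status_", colnames(cd), value = TRUE)
  for (s in st) {
    if (!all(stats::na.omit(cd[[s]]) %in% 0:2))
      msg <- c(msg, sprintf("%s must be coded 0/1/2", s))
    tcol <- sub("^status", "time", s)
    if (!tcol %in% colnames(cd))
      msg <- c(msg, sprintf("%s requires matching %s", s, tcol))
  }
  if (length(msg)) msg else TRUE
})

#' Gompertz proportional-hazards model
#'
#' Hazard \eqn{h(t \mid x) = \exp(\beta_0 + a t + x'\beta)} with time `t` in
#' years since baseline: `shape` is \eqn{a} (1/years), `lograte` is
#' \eqn{\beta_0} (log hazard at t = 0 for zero covariates), and `coef` holds
#' the named covariate log hazard ratios \eqn{\beta}.
#'
#' @slot shape Gompertz shape a (1/years).
#' @slot lograte log baseline hazard at t = 0.
#' @slot coef named numeric vector of covariate log hazard ratios.
#' @slot vcov observed-information covariance of (shape, lograte, coef).
#' @slot loglik maximized log-likelihood.
#' @slot convergence list with iteration count, final gradient norm, status.
#' @export
setClass("GompertzModel", representation(
  shape = "numeric",
  lograte = "numeric",
  coef = "numeric",
  vcov = "matrix",
  loglik = "numeric",
  convergence = "list"
))

setValidity("GompertzModel", function(object) {
  msg <- character()
  if (!is.finite(object@shape) || object@shape == 0)
    msg <- c(msg, "shape must be finite and nonzero")
  if (!is.finite(object@lograte)) msg <- c(msg, "lograte must be finite")
  if (length(object@coef) && is.null(names(object@coef)))
    msg <- c(msg, "coef must be named")
  if (length(msg)) msg else TRUE
})

#' Proteomic aging clock (paired Gompertz models plus a risk horizon)
#'
#' The clock maps a participant's covariates to a proteomic age: the `full`
#' model (chronological age + selected proteins) gives the cumulative
#' mortality risk over `horizon` years, and the proteomic age is the
#' chronological age at which the `ageOnly` reference model reaches the same
#' risk.
#'
#' @slot full GompertzModel on age plus the selected proteins.
#' @slot ageOnly GompertzModel on chronological age alone.
#' @slot horizon risk horizon k in years.
#' @slot selected ids of the proteins in the full model.
#' @slot meta training metadata (lambda, sample sizes, seeds).
#' @export
setClass("PACModel", representation(
  full = "GompertzModel",
  ageOnly = "GompertzModel",
  horizon = "numeric",
  selected = "character",
  meta = "list"
))

setValidity("PACModel", function(object) {
  msg <- character()
  if (object@horizon <= 0) msg <- c(msg, "horizon must be > 0")
  if (!"age" %in% names(object@ageOnly@coef) ||
      object@ageOnly@coef[["age"]] <= 0)
    msg <- c(msg, "age-only model must have a positive age coefficient")
  if (!"age" %in% names(object@full@coef))
    msg <- c(msg, "full model must include an age coefficient")
  if (length(msg)) msg else TRUE
})

#' Penalized Cox fit along a lambda path
#'
#' L1-penalized Cox regression (Breslow ties) fitted over a decreasing
#' penalty path. Coefficients are reported on the original covariate scale;
#' the penalty applies to internally standardized covariates, so the
#' objective is \eqn{-(1/n)\,\ell(\beta) + \lambda \sum_j s_j |\beta_j|}
#' with \eqn{s_j} the (population) sd of covariate j.
#'
#' @slot lambda decreasing penalty path.
#' @slot beta p x length(lambda) coefficient matrix, original scale.
#' @slot penaltyFactor per-covariate penalty multiplier (0 = unpenalized).
#' @slot center,scale standardization constants used internally.
#' @slot nobs,nevents sample size and event count.
#' @slot fit underlying engine fit object.
#' @export
setClass("PenalizedCoxFit", representation(
  lambda = "numeric",
  beta = "matrix",
  penaltyFactor = "numeric",
  center = "numeric",
  scale = "numeric",
  nobs = "integer",
  nevents = "integer",
  fit = "ANY"
))

#' Gene-set collection with a background universe
#'
#' Named gene sets (uppercased symbols, deduplicated) plus the background
#' universe they are tested against: either an explicit symbol vector, or a
#' bare count when only the size of the universe is known (the default,
#' 20260, is the number of protein-coding genes used as enrichment
#' background).
#'
#' @slot sets named list of character vectors.
#' @slot universe background gene symbols (may be empty when only a count
#'   is known).
#' @slot universeSize background universe size.
#' @export
setClass("GeneSetLibrary", representation(
  sets = "list",
  universe = "character",
  universeSize = "integer"
))

setValidity("GeneSetLibrary", function(object) {
  msg <- character()
  if (length(object@sets) && is.null(names(object@sets)))
    msg <- c(msg, "sets must be named")
  if (any(lengths(object@sets) == 0L)) msg <- c(msg, "empty gene set")
  if (length(object@sets) &&
      object@universeSize < max(lengths(object@sets)))
    msg <- c(msg, "universe smaller than largest set")
  if (length(object@universe) &&
      object@universeSize != length(object@universe))
    msg <- c(msg, "universeSize disagrees with universe length")
  if (length(msg)) msg else TRUE
})
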