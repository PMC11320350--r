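#' Construct simulation parameters
#'
#' Builds a validated [SimParams-class] object. Defaults emulate a
#' middle-aged/older biobank proteomics cohort: baseline ages Uniform(39, 70),
#' administrative censoring at 13.3 years, Gompertz mortality with shape
#' 0.09/yr and an age effect of 0.08 log-hazard per year, a sparse causal
#' protein subset with log hazard ratios of 0.3 per expression unit, protein
#' age-trends drawn from Normal(0, 0.02) expression units per year around a
#' unit-sd noise floor, and 2% MCAR cell missingness. When `lograte = NA`
#' the baseline log-rate is calibrated so the marginal cumulative mortality
#' over follow-up equals `targetMortality` (default 10.9%).
#'
#' @param n number of participants.
#' @param nProteins panel size.
#' @param nCausal number of proteins with true mortality effects.
#' @param ageRange baseline age range in years.
#' @param ageSlopes optional fixed per-protein age slopes; default draws
#'   them from Normal(0, `slopeSD`) under the seed.
#' @param slopeSD sd of drawn age slopes (expression units / year).
#' @param noiseSD residual protein noise sd.
#' @param causalBetas log hazard ratios of the causal proteins (recycled).
#' @param shape Gompertz shape (1/years).
#' @param lograte Gompertz log baseline rate; `NA` = calibrate.
#' @param targetMortality calibration target for the marginal death
#'   fraction over follow-up.
#' @param ageBeta log hazard ratio per year of age.
#' @param followupYears administrative censoring horizon.
#' @param missingRate MCAR missingness fraction in [0, 1).
#' @param diseaseSpecs named list of cause-specific disease hazards, each a
#'   list with `lograte`, `ageBeta`, and optional named `proteinBetas`.
#' @param seed integer seed.
#' @return a [SimParams-class] object.
#' @examples
#' p <- simParams(n = 200, nProteins = 20, seed = 1)
#' @export
simParams <- function(n = 1000L, nProteins = 100L,
                      nCausal = min(10L, nProteins),
                      ageRange = c(39, 70), ageSlopes = numeric(),
                      slopeSD = 0.02, noiseSD = 1, causalBetas = 0.3,
                      shape = 0.09, lograte = NA_real_,
                      targetMortality = 0.109, ageBeta = 0.08,
                      followupYears = 13.3, missingRate = 0.02,
                      diseaseSpecs = defaultDiseaseSpecs(), seed = 1L) {
  if (n < 1) stop("n must be positive")
  if (shape <= 0) stop("shape must be > 0")
  methods::new("SimParams",
    nParticipants = as.integer(n), nProteins = as.integer(nProteins),
    nCausal = as.integer(nCausal), ageRange = as.numeric(ageRange),
    ageSlopes = as.numeric(ageSlopes), slopeSD = slopeSD, noiseSD = noiseSD,
    causalBetas = rep_len(as.numeric(causalBetas), as.integer(nCausal)),
    gompertzShape = shape, gompertzLograte = lograte,
    targetMortality = targetMortality, ageBeta = ageBeta,
    followupYears = followupYears, missingRate = missingRate,
    diseaseSpecs = diseaseSpecs, seed = as.integer(seed))
}

#' Default cause-specific disease specifications
#'
#' Two incident diseases competing with death: one driven by age and the
#' first two causal proteins, one driven by age alone (a null disease for
#' the protein signal).
#'
#' @return named list of disease specifications.
#' @export
defaultDiseaseSpecs <- function() {
  list(
    diseaseA = list(lograte = -9.5, ageBeta = 0.07,
                    proteinBetas = c(P0001 = 0.2, P0002 = 0.2)),
    diseaseB = list(lograte = -9.0, ageBeta = 0.07)
  )
}

# Deterministic sub-stream seed: one cohort seed, fixed per-component offsets.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483629)
}

#' Calibrate the Gompertz log baseline rate to a target mortality
#'
#' Solves for the log-rate \eqn{\beta_0} such that the marginal cumulative
#' mortality at the follow-up horizon, averaged over the baseline age
#' distribution, equals `target`. Uses the closed-form Gompertz CDF
#' \eqn{1 - \exp\{-e^{\beta_0 + \beta_a \cdot age}(e^{a k} - 1)/a\}}
#' integrated over Uniform(ageRange) on a fine grid.
#'
#' @param target cumulative mortality in (0, 1).
#' @param shape,ageBeta,ageRange,followupYears Gompertz/backbone settings.
#' @return calibrated log-rate.
#' @export
calibrateLograte <- function(target, shape, ageBeta, ageRange,
                             followupYears) {
  stopifnot(target > 0, target < 1)
  ages <- seq(ageRange[1], ageRange[2], length.out = 512)
  marg <- function(b0) {
    m <- 1 - exp(-exp(b0 + ageBeta * ages) *
                   expm1(shape * followupYears) / shape)
    mean(m) - target
  }
  stats::uniroot(marg, c(-60, 20), tol = 1e-12)$root
}

#' Generate a synthetic proteomic cohort with known ground truth
#'
#' Draws baseline ages uniformly, builds protein expression as a linear age
#' trend (centered at the mean of the age range so the Gompertz log-rate
#' stays interpretable) plus Gaussian noise, samples death times from a
#' Gompertz proportional-hazards model by inverse-CDF sampling with
#' administrative censoring at the follow-up horizon, simulates incident
#' diseases as cause-specific exponential hazards competing with death,
#' applies MCAR missingness, and records the generating parameters as
#' ground truth. Identical seeds reproduce identical cohorts.
#'
#' @param params a [SimParams-class] object.
#' @return a [ProteomicCohort-class]; `groundTruth()` recovers the causal
#'   indices, betas, slopes and hazard parameters.
#' @examples
#' pc <- simulateCohort(simParams(n = 300, nProteins = 20, seed = 7))
#' pc
#' @export
simulateCohort <- function(params) {
  methods::validObject(params)
  n <- params@nParticipants
  p <- params@nProteins
  ids <- sprintf("S%05d", seq_len(n))
  prot <- sprintf("P%04d", seq_len(p))
  genes <- stats::setNames(sprintf("GENE%04d", seq_len(p)), prot)

  set.seed(deriveSeed(params@seed, 1L))
  age <- stats::runif(n, params@ageRange[1], params@ageRange[2])

  set.seed(deriveSeed(params@seed, 2L))
  slopes <- if (length(params@ageSlopes))
    rep_len(params@ageSlopes, p) else stats::rnorm(p, 0, params@slopeSD)
  names(slopes) <- prot

  set.seed(deriveSeed(params@seed, 3L))
  ageC <- age - mean(params@ageRange)
  X <- outer(ageC, slopes) +
    matrix(stats::rnorm(n * p, 0, params@noiseSD), n, p)
  dimnames(X) <- list(ids, prot)

  lograte <- params@gompertzLograte
  if (is.na(lograte))
    lograte <- calibrateLograte(params@targetMortality, params@gompertzShape,
                                params@ageBeta, params@ageRange,
                                params@followupYears)

  causal <- seq_len(params@nCausal)
  betas <- stats::setNames(params@causalBetas, prot[causal])
  lp <- lograte + params@ageBeta * age +
    if (length(causal)) drop(X[, causal, drop = FALSE] %*% betas) else 0

  set.seed(deriveSeed(params@seed, 4L))
  a <- params@gompertzShape
  ev <- stats::rexp(n)                      # unit-exponential cumulative hazards
  tDeath <- log1p(a * ev / exp(lp)) / a
  died <- as.integer(tDeath <= params@followupYears)
  timeDeath <- pmin(tDeath, params@followupYears)

  set.seed(deriveSeed(params@seed, 5L))
  covs <- data.frame(
    sex = stats::rbinom(n, 1L, 0.5),
    education = sample(0:4, n, replace = TRUE),
    deprivation = stats::rnorm(n, 0, 3),
    smoking = sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10)),
    bmi = stats::rnorm(n, 27, 4.5)
  )

  cd <- data.frame(participant_id = ids, age = age, covs,
                   time_death = timeDeath, died = died,
                   row.names = ids, stringsAsFactors = FALSE)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(X)),
    rowData = S4Vectors::DataFrame(gene = unname(genes), row.names = prot),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(groundTruth = list(
      causal = prot[causal], betas = betas, slopes = slopes,
      gompertz = c(shape = a, lograte = lograte, ageBeta = params@ageBeta),
      followupYears = params@followupYears,
      trueDeathTime = stats::setNames(tDeath, ids),
      diseases = params@diseaseSpecs, seed = params@seed))
  )
  pc <- methods::new("ProteomicCohort", se)

  if (length(params@diseaseSpecs))
    pc <- simulateIncidentDisease(pc, params@diseaseSpecs,
                                  seed = deriveSeed(params@seed, 6L))
  if (params@missingRate > 0)
    pc <- injectMissingness(pc, params@missingRate, "MCAR",
                            seed = deriveSeed(params@seed, 7L))
  pc
}

#' Inject missing values into a protein matrix
#'
#' `MCAR` masks each cell independently with probability `rate`.
#' `high_miss_proteins` sets at least the stated missing fraction in the
#' designated columns (rounded up), emulating assay dropout concentrated in
#' a few proteins; use it to exercise the high-missingness filter.
#'
#' @param x a participants-by-proteins matrix or a [ProteomicCohort-class].
#' @param rate missingness fraction in [0, 1).
#' @param mechanism `"MCAR"` or `"high_miss_proteins"`.
#' @param proteins columns targeted by `high_miss_proteins`.
#' @param seed integer seed.
#' @return object of the same class with `NA`s inserted.
#' @export
injectMissingness <- function(x, rate, mechanism = c("MCAR",
                              "high_miss_proteins"), proteins = NULL,
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate >= 1 || rate < 0) stop("rate must be in [0, 1)")
  if (methods::is(x, "ProteomicCohort")) {
    m <- proteinMatrix(x)
    m <- injectMissingness(m, rate, mechanism, proteins, seed)
    SummarizedExperiment::assay(x, "npx") <- t(m)
    return(x)
  }
  if (rate == 0 && mechanism == "MCAR") return(x)
  set.seed(seed)
  if (mechanism == "MCAR") {
    mask <- stats::runif(length(x)) < rate
    x[mask] <- NA_real_
  } else {
    if (is.null(proteins)) stop("high_miss_proteins needs target columns")
    for (pr in proteins) {
      nmiss <- ceiling(rate * nrow(x))
      idx <- sample.int(nrow(x), nmiss)
      x[idx, pr] <- NA_real_
    }
  }
  x
}

#' Simulate incident diseases competing with death
#'
#' For each disease a cause-specific event time is drawn from an exponential
#' hazard \eqn{\exp(lograte + ageBeta \cdot age + x'\beta_{prot})}. Status is
#' 1 if the event precedes both death and administrative censoring, 2 if
#' death comes first, 0 otherwise; the recorded time is the first of the
#' three. Death times are the latent (uncensored) times from the mortality
#' generator so that "death first" is judged against the true death time
#' within follow-up.
#'
#' @param x a [ProteomicCohort-class] with death times.
#' @param specs named list of disease specifications (see [simParams()]).
#' @param seed integer seed.
#' @return the cohort with `time_<name>` / `status_<name>` columns added.
#' @export
simulateIncidentDisease <- function(x, specs, seed = 1L) {
  stopifnot(methods::is(x, "ProteomicCohort"))
  cd <- SummarizedExperiment::colData(x)
  if (!"time_death" %in% colnames(cd)) stop("cohort lacks death times")
  gt <- groundTruth(x)
  horizon <- gt$followupYears
  tDeath <- if (!is.null(gt$trueDeathTime)) unname(gt$trueDeathTime) else
    ifelse(cd$died == 1, cd$time_death, Inf)
  X <- proteinMatrix(x)
  set.seed(seed)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (is.nan(sp$lograte) || sp$lograte == Inf)
      stop("invalid disease lograte")  # -Inf (hazard zero) is allowed
    lp <- sp$lograte + sp$ageBeta * cd$age
    if (!is.null(sp$proteinBetas) && length(sp$proteinBetas)) {
      pb <- sp$proteinBetas
      missing <- setdiff(names(pb), colnames(X))
      if (length(missing)) stop("unknown proteins in disease spec: ",
                                paste(missing, collapse = ", "))
      lp <- lp + drop(X[, names(pb), drop = FALSE] %*% pb)
    }
    haz <- exp(lp)
    if (any(!is.finite(haz)) || any(haz < 0)) stop("negative or non-finite hazard")
    tEvent <- ifelse(haz > 0, stats::rexp(length(haz)) / haz, Inf)
    tObs <- pmin(tEvent, tDeath, horizon)
    status <- integer(length(tObs))
    status[tEvent <= pmin(tDeath, horizon)] <- 1L
    status[tDeath < tEvent & tDeath <= horizon] <- 2L
    cd[[paste0("time_", nm)]] <- tObs
    cd[[paste0("status_", nm)]] <- status
  }
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
}

#' Gompertz cumulative mortality (closed form)
#'
#' \eqn{M(k) = 1 - \exp\{-e^{\eta}(e^{a k} - 1)/a\}} for log hazard level
#' \eqn{\eta} at t = 0 and shape a; the a -> 0 limit uses \eqn{e^{\eta} k}.
#' This is the marginal CDF used both by the simulator and the clock.
#'
#' @param eta log hazard at t = 0 (lograte + covariate contribution).
#' @param shape Gompertz shape.
#' @param k horizon in years.
#' @return cumulative event probability.
#' @export
gompertzCDF <- function(eta, shape, k) {
  H <- if (abs(shape) < 1e-10) exp(eta) * k else
    exp(eta) * expm1(shape * k) / shape
  -expm1(-H)
}
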