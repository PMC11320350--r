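#' Cox proportional-hazards associations
#'
#' Fits a Cox model (Efron tie handling) by maximum partial likelihood and
#' returns per-covariate hazard ratios with Wald 95% confidence intervals
#' and p-values.
#'
#' @param X design matrix or data.frame (participants in rows).
#' @param time,event survival outcome; at least one event.
#' @return data.frame with columns `term`, `hr`, `ci_lo`, `ci_hi`, `beta`,
#'   `se`, `p`, `n`, `n_events`, `model`.
#' @export
fitCox <- function(X, time, event) {
  X <- as.data.frame(X)
  if (sum(event) < 1) stop("no events")
  df <- data.frame(.time = time, .event = event, X, check.names = FALSE)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = df, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("Cox fit produced NA coefficients (rank-deficient design?)")
  summarizeCoxFit(fit, n = nrow(df), nEvents = sum(event), model = "cox")
}

summarizeCoxFit <- function(fit, n, nEvents, model) {
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- b / se
  data.frame(term = names(b), hr = exp(b),
             ci_lo = exp(b - 1.959963984540054 * se),
             ci_hi = exp(b + 1.959963984540054 * se),
             beta = unname(b), se = unname(se),
             p = 2 * stats::pnorm(-abs(z)), n = n, n_events = nEvents,
             model = model, row.names = NULL)
}

#' Fine-Gray subdistribution-hazard associations under competing risks
#'
#' Estimates subdistribution hazard ratios for the event of interest with
#' death as the competing event, via the Geskus inverse-probability-of-
#' censoring-weighted risk-set expansion ([survival::finegray()]) followed
#' by a weighted Cox fit. Participants with competing events remain in the
#' risk set after their death time with Kaplan-Meier censoring weights.
#' With zero competing events the estimates reduce exactly to [fitCox()].
#'
#' @param X design matrix or data.frame.
#' @param time follow-up time.
#' @param status 0 = censored, 1 = event of interest, 2 = competing event
#'   (death before the event).
#' @return data.frame in the same shape as [fitCox()], `model =
#'   "fine_gray"`; `n_events` counts primary events.
#' @export
fitFineGray <- function(X, time, status) {
  X <- as.data.frame(X)
  if (!all(status %in% 0:2)) stop("status must be coded 0/1/2")
  if (sum(status == 1) < 1) stop("no primary events")
  df <- data.frame(.time = time,
                   .status = factor(status, levels = 0:2,
                                    labels = c("censor", "event", "death")),
                   X, check.names = FALSE)
  fg <- survival::finegray(survival::Surv(.time, .status) ~ ., data = df,
                           etype = "event")
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ . - fgwt,
    data = fg[, c("fgstart", "fgstop", "fgstatus", "fgwt", colnames(X))],
    weights = fg$fgwt, ties = "efron")
  out <- summarizeCoxFit(fit, n = nrow(df), nEvents = sum(status == 1),
                         model = "fine_gray")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values \eqn{q_i = \min_{j \ge i} p_{(j)} m / j}
#' (capped at 1), returned in the input order.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values.
#' @examples
#' bhFdr(c(0.005, 0.011, 0.02, 0.04, 0.13))
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values out of [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tiered covariate-adjustment definitions
#'
#' The three nested adjustment tiers used for association analyses:
#' age-adjusted (chronological age only), partially adjusted (age plus
#' sociodemographic and lifestyle covariates), and fully adjusted (the
#' partial set plus pre-existing disease indicators). Validates nesting.
#'
#' @param partial covariates added on top of age for the partial tier.
#' @param preexisting pre-existing disease indicator columns added for the
#'   full tier; when an outcome matches one of these, that indicator is
#'   dropped from its own model.
#' @return named list of covariate vectors with class "adjustmentTiers".
#' @export
adjustmentTiers <- function(partial = c("sex", "education", "deprivation",
                                        "smoking", "bmi"),
                            preexisting = character()) {
  tiers <- list(age_adjusted = "age",
                partial = c("age", partial),
                full = c("age", partial, preexisting))
  stopifnot(all(tiers$age_adjusted %in% tiers$partial),
            all(tiers$partial %in% tiers$full))
  structure(tiers, class = "adjustmentTiers", preexisting = preexisting)
}

#' Run the tiered association suite
#'
#' For each outcome and adjustment tier, fits the appropriate survival
#' model for the exposure (a biological-age deviation score): Cox for
#' all-cause mortality, Fine-Gray with death competing for incident
#' diseases. Participants with the disease prevalent at baseline (a
#' `prevalent_<outcome>` column equal to 1) are excluded from that
#' outcome's models, and in the full tier the modelled outcome's own
#' pre-existing indicator is dropped from the covariates. P-values are
#' BH-FDR adjusted across every test in the suite run (all outcomes and
#' tiers pooled).
#'
#' @param scores named numeric exposure (names = participant ids), e.g. the
#'   `deviation` column of [scoreCohort()] output.
#' @param cohort participant data.frame with ids as row names, survival
#'   columns and covariates.
#' @param outcomes outcome names: `"mortality"` and/or disease names with
#'   `time_<name>` / `status_<name>` columns.
#' @param tiers an [adjustmentTiers()] list (or any named list of covariate
#'   vectors).
#' @param exposureName label for the exposure row of interest.
#' @return data.frame of exposure associations: one row per outcome x tier
#'   with `hr`, `ci_lo`, `ci_hi`, `p`, `p_adj`, `n`, `n_events`, `model`,
#'   plus exclusion counts.
#' @export
runAssociationSuite <- function(scores, cohort, outcomes,
                                tiers = adjustmentTiers(),
                                exposureName = "deviation") {
  stopifnot(!is.null(names(scores)) || length(scores) == nrow(cohort))
  if (is.null(names(scores))) names(scores) <- rownames(cohort)
  rows <- list()
  for (oc in outcomes) {
    if (oc == "mortality") { tcol <- "time_death"; scol <- "died" }
    else { tcol <- paste0("time_", oc); scol <- paste0("status_", oc) }
    if (!all(c(tcol, scol) %in% colnames(cohort)))
      stop("cohort lacks columns for outcome ", oc)
    keep <- rownames(cohort) %in% names(scores)
    prevcol <- paste0("prevalent_", oc)
    if (prevcol %in% colnames(cohort)) keep <- keep & cohort[[prevcol]] != 1
    for (tn in names(tiers)) {
      covs <- setdiff(tiers[[tn]], paste0("prevalent_", oc))
      miss <- setdiff(covs, colnames(cohort))
      if (length(miss)) stop("tier '", tn, "' covariates missing: ",
                             paste(miss, collapse = ", "))
      dat <- cohort[keep, , drop = FALSE]
      Xd <- data.frame(exposure = scores[rownames(dat)],
                       dat[, covs, drop = FALSE], check.names = FALSE)
      cc <- stats::complete.cases(Xd) & !is.na(dat[[tcol]]) &
        !is.na(dat[[scol]])
      nExcl <- sum(!cc)
      Xc <- Xd[cc, , drop = FALSE]
      res <- if (oc == "mortality")
        fitCox(Xc, dat[[tcol]][cc], dat[[scol]][cc])
      else
        fitFineGray(Xc, dat[[tcol]][cc], dat[[scol]][cc])
      r <- res[res$term == "exposure", , drop = FALSE]
      r$term <- exposureName
      r$outcome <- oc
      r$tier <- tn
      r$n_excluded <- nExcl
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bhFdr(out$p)
  rownames(out) <- NULL
  out[, c("outcome", "tier", "term", "hr", "ci_lo", "ci_hi", "beta", "se",
          "p", "p_adj", "n", "n_events", "n_excluded", "model")]
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the member with the shorter observed time had the
#' event; pairs tied on time are comparable only when exactly one is an
#' event), counts a pair concordant when the shorter-time member carries
#' the higher risk score, 1/2 when the scores are tied. C is the concordant
#' fraction, between 0 and 1 (0.5 = no discrimination).
#'
#' @param time,event survival outcome.
#' @param risk risk score (higher = riskier).
#' @return list with `C`, `comparable` (pair count), `concordant`
#'   (weighted count).
#' @examples
#' harrellC(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))$C   # perfect concordance
#' @export
harrellC <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  comparable <- 0; concordant <- 0
  for (i in which(event == 1)) {
    cmp <- (time > time[i]) | (time == time[i] & event == 0)
    cmp[i] <- FALSE
    comparable <- comparable + sum(cmp)
    concordant <- concordant + sum(risk[cmp] < risk[i]) +
      0.5 * sum(risk[cmp] == risk[i])
  }
  # pairs of two events at the identical time are incomparable (handled by
  # the cmp definition); pairs where both die at distinct times are counted
  # once, from the earlier member.
  if (comparable == 0) stop("no comparable pairs")
  list(C = concordant / comparable, comparable = comparable,
       concordant = concordant)
}

#' Compare single-measure Cox models by concordance
#'
#' For each outcome and each candidate score column, fits a Cox model with
#' that score as the only covariate on the shared complete-case rows
#' (complete across all score columns, so every model sees the same sample)
#' and reports Harrell's C of the fitted risk. For disease outcomes,
#' competing deaths (status 2) are treated as censored at their time, the
#' standard concordance-screen simplification.
#'
#' @param cohort participant data.frame (ids as row names).
#' @param scoreColumns named list or data.frame of candidate scores
#'   (e.g. chronological age, proteomic age, other biological ages).
#' @param outcomes outcome names as in [runAssociationSuite()].
#' @return data.frame: `outcome`, `score`, `C`, `n`, `n_events`.
#' @export
compareModelsC <- function(cohort, scoreColumns, outcomes) {
  sc <- as.data.frame(scoreColumns)
  cc <- stats::complete.cases(sc)
  rows <- list()
  for (oc in outcomes) {
    if (oc == "mortality") { tcol <- "time_death"; scol <- "died" }
    else { tcol <- paste0("time_", oc); scol <- paste0("status_", oc) }
    keep <- cc & !is.na(cohort[[tcol]]) & !is.na(cohort[[scol]])
    prevcol <- paste0("prevalent_", oc)
    if (prevcol %in% colnames(cohort)) keep <- keep & cohort[[prevcol]] != 1
    if (!any(keep)) stop("empty complete-case set for outcome ", oc)
    tt <- cohort[[tcol]][keep]
    ev <- as.integer(cohort[[scol]][keep] == 1)
    for (nm in colnames(sc)) {
      fit <- survival::coxph(survival::Surv(tt, ev) ~ s,
                             data = data.frame(s = sc[[nm]][keep]))
      lp <- drop(stats::predict(fit, type = "lp"))
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, score = nm, C = harrellC(tt, ev, lp)$C,
        n = sum(keep), n_events = sum(ev))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise correlation panel, optionally age-adjusted
#'
#' Pairwise Spearman or Pearson correlations between measure columns, on
#' pairwise-complete observations. With `ageAdjust = TRUE` each measure is
#' first replaced by its residual after regression on chronological age
#' (so the panel reports correlations between age-adjusted deviations).
#'
#' @param data data.frame of measures (and an `age` column when adjusting).
#' @param columns measure columns to correlate.
#' @param method `"spearman"` or `"pearson"`.
#' @param ageAdjust residualize on `age` first.
#' @param ageColumn name of the age column.
#' @return correlation matrix.
#' @export
correlationPanel <- function(data, columns = colnames(data),
                             method = c("spearman", "pearson"),
                             ageAdjust = FALSE, ageColumn = "age") {
  method <- match.arg(method)
  m <- data[, columns, drop = FALSE]
  if (any(vapply(m, function(v) stats::var(v, na.rm = TRUE) == 0,
                 logical(1))))
    stop("constant column in correlation panel")
  if (ageAdjust) {
    age <- data[[ageColumn]]
    if (is.null(age)) stop("ageAdjust needs an age column")
    # residualize every measure on age; the age column itself stays raw
    # (its correlation with any residual is then zero by orthogonality)
    adj <- setdiff(colnames(m), ageColumn)
    m[adj] <- lapply(m[adj], ageAdjustedResiduals, age = age)
  }
  stats::cor(m, method = method, use = "pairwise.complete.obs")
}
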