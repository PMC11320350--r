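#' Accessors for ProteomicCohort objects
#'
#' `npx()` returns the stored assay (proteins in rows, participants in
#' columns). `proteinMatrix()` returns the transposed participants-by-
#' proteins matrix used as a design matrix by the modelling functions.
#' `cohortData()` returns the participant table as a plain `data.frame`;
#' `geneMap()` the protein-to-gene-symbol map; `groundTruth()` the simulation
#' ground truth (or `NULL` for real data).
#'
#' @param x a [ProteomicCohort-class].
#' @return See description; `geneMap()` gives a named character vector
#'   (protein id -> gene symbol).
#' @name npx
#' @aliases npx,ProteomicCohort-method
NULL

#' @rdname npx
#' @export
setMethod("npx", "ProteomicCohort", function(x)
  SummarizedExperiment::assay(x, "npx"))

#' @rdname npx
#' @export
setMethod("proteinMatrix", "ProteomicCohort", function(x)
  t(SummarizedExperiment::assay(x, "npx")))

#' @rdname npx
#' @export
setMethod("cohortData", "ProteomicCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname npx
#' @export
setMethod("geneMap", "ProteomicCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  stats::setNames(as.character(rd$gene), rownames(x))
})

#' @rdname npx
#' @export
setMethod("groundTruth", "ProteomicCohort", function(x)
  S4Vectors::metadata(x)$groundTruth)

#' Accessors for gene-set collections
#'
#' @param x a [GeneSetLibrary-class].
#' @return `geneSets()` the named list of sets; `universeSize()` the
#'   background count.
#' @name geneSets
NULL

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetLibrary", function(x) x@sets)

#' @rdname geneSets
#' @export
setMethod("universeSize", "GeneSetLibrary", function(x) x@universeSize)

setMethod("show", "ProteomicCohort", function(object) {
  cat(sprintf("ProteomicCohort: %d proteins x %d participants\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  if ("died" %in% colnames(cd))
    cat(sprintf("  deaths: %d (%.1f%%)\n", sum(cd$died),
                100 * mean(cd$died)))
  dis <- sub("^status_", "", grep("^status_", colnames(cd), value = TRUE))
  if (length(dis)) cat("  diseases:", paste(dis, collapse = ", "), "\n")
  miss <- mean(is.na(SummarizedExperiment::assay(object, "npx")))
  cat(sprintf("  missing cells: %.2f%%\n", 100 * miss))
  invisible(NULL)
})

setMethod("show", "GompertzModel", function(object) {
  cat("GompertzModel: h(t|x) = exp(lograte + shape*t + x'beta)\n")
  cat(sprintf("  shape = %.6g /yr, lograte = %.6g\n",
              object@shape, object@lograte))
  cat(sprintf("  %d covariate(s); loglik = %.4f\n",
              length(object@coef), object@loglik))
  if (length(object@coef) <= 6L) {
    for (nm in names(object@coef))
      cat(sprintf("    %s: %.6g\n", nm, object@coef[[nm]]))
  }
  invisible(NULL)
})

setMethod("show", "PACModel", function(object) {
  cat("PACModel (proteomic aging clock)\n")
  cat(sprintf("  horizon: %g years; %d selected protein(s)\n",
              object@horizon, length(object@selected)))
  cat(sprintf("  age-only model: shape %.5g, age coef %.5g\n",
              object@ageOnly@shape, object@ageOnly@coef[["age"]]))
  invisible(NULL)
})

setMethod("show", "PenalizedCoxFit", function(object) {
  nz <- colSums(object@beta != 0)
  cat(sprintf("PenalizedCoxFit: %d lambda value(s), %d covariates, n = %d (%d events)\n",
              length(object@lambda), nrow(object@beta), object@nobs,
              object@nevents))
  cat(sprintf("  nonzero coefficients: %d-%d along the path\n",
              min(nz), max(nz)))
  invisible(NULL)
})

setMethod("show", "GeneSetLibrary", function(object) {
  cat(sprintf("GeneSetLibrary: %d set(s), background universe %d genes\n",
              length(object@sets), object@universeSize))
  invisible(NULL)
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: n = %d, %d proteins (%d causal), ages U(%g, %g)\n",
              object@nParticipants, object@nProteins, object@nCausal,
              object@ageRange[1], object@ageRange[2]))
  cat(sprintf("  Gompertz shape %.3g, age beta %.3g, follow-up %.1f yr, seed %d\n",
              object@gompertzShape, object@ageBeta, object@followupYears,
              object@seed))
  invisible(NULL)
})
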