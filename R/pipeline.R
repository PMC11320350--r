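#' Run the full clock pipeline
#'
#' Orchestrates the end-to-end analysis: simulate or load a cohort,
#' filter high-missingness proteins, impute, split into training and test
#' sets, train the clock (penalized Cox selection + paired Gompertz
#' models), score the whole cohort, run the tiered association suite and
#' concordance comparison on the test set, and (when gene sets are
#' supplied) the protein-association + gene-set enrichment step. Writes a
#' machine-readable results bundle to `outDir`: tab-delimited tables, the
#' model as YAML, a YAML summary, and a structured log with seeds and
#' exclusion counts. Identical config + seed reproduce a byte-identical
#' bundle.
#'
#' @param config list (see [readRunConfig()]). Recognized fields:
#'   `simulate` (list of [simParams()] arguments) or `matrix`/`cohort`
#'   paths; `gmt` path (optional); `missingThreshold` (default 0.5);
#'   `imputeK` (default 10); `trainFraction` (default 0.7); `lambda`
#'   (`"cv"` or numeric, default `"cv"`); `horizon` (default 10);
#'   `outcomes` (default mortality plus simulated diseases); `seed`.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  logLines <- character()
  logf <- function(stage, ...) {
    line <- paste0("stage=", stage, " ", paste(..., collapse = " "))
    logLines <<- c(logLines, line)
  }

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sp <- do.call(simParams, modifyList(config$simulate,
                                          list(seed = deriveSeed(seed, 11L))))
      pc <- simulateCohort(sp)
      logf("simulate", sprintf("n=%d proteins=%d seed=%d",
                               ncol(pc), nrow(pc), sp@seed))
    } else {
      if (is.null(config$matrix) || is.null(config$cohort))
        stop("config field 'matrix'/'cohort': path missing and no ",
             "'simulate' block given")
      for (f in c("matrix", "cohort"))
        if (!file.exists(config[[f]]))
          stop("config field '", f, "': file not found: ", config[[f]])
      m <- readProteinMatrix(config$matrix)
      cd <- readCohortTable(config$cohort)
      pc <- makeProteomicCohort(m, cd)
      logf("input", sprintf("n=%d proteins=%d", ncol(pc), nrow(pc)))
    }

    stage <- "preprocess"
    thr <- if (is.null(config$missingThreshold)) 0.5 else
      config$missingThreshold
    pc <- filterHighMissingness(pc, thr)
    removed <- S4Vectors::metadata(pc)$removedProteins
    logf("filter", sprintf("threshold=%g removed=%d [%s]", thr,
                           length(removed), paste(removed, collapse = ",")))
    k <- if (is.null(config$imputeK)) 10L else config$imputeK
    nmiss <- sum(is.na(npx(pc)))
    if (nmiss > 0) pc <- knnImpute(pc, k)
    logf("impute", sprintf("k=%d cells=%d", k, nmiss))

    stage <- "split"
    frac <- if (is.null(config$trainFraction)) 0.7 else config$trainFraction
    sp2 <- splitCohort(colnames(pc), frac, seed = deriveSeed(seed, 12L))
    logf("split", sprintf("fraction=%g train=%d test=%d", frac,
                          length(sp2$train), length(sp2$test)))

    stage <- "train"
    lambda <- if (is.null(config$lambda)) "cv" else config$lambda
    horizon <- if (is.null(config$horizon)) 10 else config$horizon
    pac <- trainPAC(pc, sp2$train, lambda = lambda, horizon = horizon,
                    seed = deriveSeed(seed, 13L))
    logf("train", sprintf("lambda=%.6g selected=%d horizon=%g",
                          pac@meta$lambda, length(pac@selected), horizon))
    writePACModel(pac, file.path(outDir, "model.yaml"))

    stage <- "score"
    scores <- scoreCohort(pac, pc)
    scores$set <- ifelse(scores$participant_id %in% sp2$train,
                         "train", "test")
    writeCohortTable(scores, file.path(outDir, "scores.tsv"))
    logf("score", sprintf("n=%d mean_pa=%.3f", nrow(scores),
                          mean(scores$proteomic_age)))

    stage <- "validate"
    cd <- cohortData(pc)
    test <- scores$set == "test"
    cdT <- cd[scores$participant_id[test], , drop = FALSE]
    dev <- stats::setNames(scores$deviation[test],
                           scores$participant_id[test])
    outcomes <- config$outcomes
    if (is.null(outcomes))
      outcomes <- c("mortality",
                    sub("^status_", "",
                        grep("^status_", colnames(cd), value = TRUE)))
    assoc <- runAssociationSuite(dev, cdT, outcomes)
    writeCohortTable(assoc, file.path(outDir, "associations.tsv"))
    logf("associations", sprintf("tests=%d", nrow(assoc)))

    cmp <- compareModelsC(cdT,
                          list(age = cdT$age,
                               proteomic_age = scores$proteomic_age[test]),
                          outcomes)
    writeCohortTable(cmp, file.path(outDir, "concordance.tsv"))
    corr <- correlationPanel(data.frame(age = cdT$age,
                                        proteomic_age =
                                          scores$proteomic_age[test]),
                             method = "spearman")
    writeCohortTable(data.frame(measure = rownames(corr), corr),
                     file.path(outDir, "correlations.tsv"))
    logf("validate", sprintf("spearman_age=%.4f",
                             corr["age", "proteomic_age"]))

    stage <- "enrich"
    enr <- NULL
    if (!is.null(config$gmt)) {
      if (!file.exists(config$gmt))
        stop("config field 'gmt': file not found: ", config$gmt)
      gsl <- readGmt(config$gmt,
                     universeSize = config$universeSize)
      pa <- associateProteins(dev,
                              proteinMatrix(pc)[names(dev), , drop = FALSE],
                              covariates = cdT[, intersect(
                                c("sex", "education", "deprivation",
                                  "smoking", "bmi"), colnames(cdT)),
                                drop = FALSE],
                              geneMap = geneMap(pc))
      writeCohortTable(pa, file.path(outDir, "protein_associations.tsv"))
      sig <- pa$protein[pa$bonferroni_p < 0.05]
      logf("proteins", sprintf("significant=%d of %d", length(sig),
                               nrow(pa)))
      if (length(sig)) {
        genes <- mapProteinsToGenes(sig, geneMap(pc))
        enr <- runGeneSetAnalysis(genes, gsl)
        writeCohortTable(enr, file.path(outDir, "enrichment.tsv"))
        logf("enrich", sprintf("sets_tested=%d significant=%d",
                               nrow(enr), sum(enr$bonferroni_p < 0.05)))
      }
    }

    stage <- "summary"
    summary <- list(
      n = ncol(pc), n_proteins = nrow(pc), seed = seed,
      removed_proteins = as.list(removed),
      train = length(sp2$train), test = length(sp2$test),
      lambda = sprintf("%.10g", pac@meta$lambda),
      n_selected = length(pac@selected), horizon = horizon,
      mean_proteomic_age = sprintf("%.6f", mean(scores$proteomic_age)),
      sd_proteomic_age = sprintf("%.6f", stats::sd(scores$proteomic_age)),
      spearman_age = sprintf("%.6f", corr["age", "proteomic_age"]))
    yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
    writeLines(logLines, file.path(outDir, "run.log"))
    list(cohort = pc, split = sp2, model = pac, scores = scores,
         associations = assoc, concordance = cmp, correlations = corr,
         enrichment = enr)
  }, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
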