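# Tab-delimited readers/writers. All tables are TSV, UTF-8, with a header
# row; missing values are empty strings. Floating point values are written
# as full-precision decimals (%.17g) so a write -> read round trip
# reproduces the numbers exactly.

fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Read / write a protein expression matrix
#'
#' Format: tab-delimited, header row of protein ids, first column
#' `participant_id`; empty cells are missing values.
#'
#' @param path file path.
#' @return `readProteinMatrix()` returns a participants-by-proteins numeric
#'   matrix with participant ids as row names.
#' @export
readProteinMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "", colClasses = list(
                            character = 1L))
  ids <- dt[[1]]
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  if (anyDuplicated(colnames(dt))) stop("duplicate protein columns")
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) stop("non-numeric protein values")
  rownames(m) <- ids
  m
}

#' @rdname readProteinMatrix
#' @param x participants-by-proteins matrix.
#' @export
writeProteinMatrix <- function(x, path) {
  df <- data.frame(participant_id = rownames(x),
                   apply(x, 2, fmtNum), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a participant cohort table
#'
#' Tab-delimited with a `participant_id` column; numeric columns are
#' written at full precision, missing values as empty cells.
#'
#' @param path file path.
#' @return `readCohortTable()` returns a data.frame with participant ids as
#'   row names.
#' @export
readCohortTable <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = list(character = "participant_id"))
  df <- as.data.frame(dt)
  if (anyDuplicated(df$participant_id)) stop("duplicate participant ids")
  rownames(df) <- df$participant_id
  df
}

#' @rdname readCohortTable
#' @param x cohort data.frame.
#' @export
writeCohortTable <- function(x, path) {
  out <- x
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Assemble a ProteomicCohort from matrix and cohort table
#'
#' @param matrix participants-by-proteins matrix.
#' @param cohort participant data.frame (row names or `participant_id`
#'   matching matrix row names).
#' @param geneMap named protein -> gene map; defaults to identity.
#' @param groundTruth optional simulation ground truth list.
#' @return a [ProteomicCohort-class].
#' @export
makeProteomicCohort <- function(matrix, cohort, geneMap = NULL,
                                groundTruth = NULL) {
  ids <- rownames(matrix)
  stopifnot(!is.null(ids), all(ids %in% rownames(cohort)))
  cohort <- cohort[ids, , drop = FALSE]
  prot <- colnames(matrix)
  if (is.null(geneMap)) geneMap <- stats::setNames(prot, prot)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(matrix)),
    rowData = S4Vectors::DataFrame(gene = unname(geneMap[prot]),
                                   row.names = prot),
    colData = S4Vectors::DataFrame(cohort),
    metadata = list(groundTruth = groundTruth))
  methods::new("ProteomicCohort", se)
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line is `name <tab> description <tab> symbol...`. Symbols are
#' uppercased and deduplicated within a set; set order is preserved. Lines
#' with fewer than three fields are an error.
#'
#' @param path file path.
#' @param universe,universeSize background specification passed to
#'   [geneSetLibrary()].
#' @return `readGmt()` returns a [GeneSetLibrary-class].
#' @export
readGmt <- function(path, universe = character(), universeSize = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  geneSetLibrary(sets, universe = universe, universeSize = universeSize)
}

#' @rdname readGmt
#' @param x a [GeneSetLibrary-class].
#' @param descriptions optional per-set description strings.
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
  nms <- names(x@sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nms))
  lines <- vapply(seq_along(nms), function(i)
    paste(c(nms[i], descriptions[i], x@sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML with either a `simulate:` block (arguments to [simParams()]) or
#' `matrix:` / `cohort:` input paths, plus preprocessing, training and
#' validation settings. Missing fields fall back to the defaults
#' documented in [runPipeline()].
#'
#' @param path YAML file path.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate)) {
    # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back to the
    # cohort-size argument so `simulate: {n: 500}` works unquoted
    nm <- names(cfg$simulate)
    nm[nm == "FALSE"] <- "n"
    names(cfg$simulate) <- nm
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
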