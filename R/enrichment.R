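#' Per-protein association with a biological-age deviation
#'
#' Ordinary least squares of the deviation on each protein plus covariates
#' (one model per protein), with the protein values inverse-normal
#' transformed first by default. Inference for the protein coefficient uses
#' the exact OLS t-test via the Frisch-Waugh projection (identical to the
#' full regression); Bonferroni correction is over the protein count.
#'
#' @param deviation numeric response (e.g. proteomic age deviation).
#' @param X participants-by-proteins matrix (no missing values).
#' @param covariates optional data.frame of adjustment covariates.
#' @param geneMap optional named protein -> gene symbol map.
#' @param transform apply [inverseNormal()] to each protein first.
#' @return data.frame: `protein`, `gene`, `beta`, `se`, `t`, `p`,
#'   `bonferroni_p`, sorted by p.
#' @export
associateProteins <- function(deviation, X, covariates = NULL,
                              geneMap = NULL, transform = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(deviation) == n)
  if (anyNA(X) || anyNA(deviation)) stop("missing values")
  if (transform) X <- apply(X, 2, inverseNormal)
  Z <- if (is.null(covariates)) matrix(1, n, 1) else {
    cv <- as.matrix(as.data.frame(covariates))
    if (anyNA(cv)) stop("missing covariate values")
    cbind(1, cv)
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate design")
  ry <- qr.resid(qz, deviation)
  RX <- qr.resid(qz, X)
  sxx <- colSums(RX^2)
  if (any(sxx < 1e-12)) stop("protein collinear with covariates")
  beta <- colSums(RX * ry) / sxx
  df <- n - ncol(Z) - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  prot <- colnames(X)
  out <- data.frame(protein = prot,
                    gene = if (is.null(geneMap)) prot else
                      unname(geneMap[prot]),
                    beta = unname(beta), se = unname(se), t = unname(tstat),
                    p = unname(p),
                    bonferroni_p = pmin(1, unname(p) * ncol(X)),
                    row.names = NULL)
  out[order(out$p), ]
}

#' Upper-tail hypergeometric test
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' probability of drawing at least `k` annotated genes when `n` genes are
#' drawn from a universe of `N` genes of which `K` are in the set.
#'
#' @param k observed overlap.
#' @param n number of input (drawn) genes.
#' @param K set size within the universe.
#' @param N universe size.
#' @return the upper-tail p-value.
#' @examples
#' hypergeomTest(5, 5, 5, 20)   # 1 / choose(20, 5)
#' @export
hypergeomTest <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || k < 0)
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overrepresentation analysis
#'
#' Tests each gene set for overrepresentation of the input genes against
#' the background universe with an upper-tail hypergeometric test. Sets
#' overlapping the input in fewer than `minOverlap` genes are excluded
#' regardless of p-value. Bonferroni correction multiplies by the total
#' number of sets in the collection (the convention for the 50-set hallmark
#' collection), not only those passing the overlap filter.
#'
#' @param genes input gene symbols (significant genes); symbols outside an
#'   explicit universe are dropped with a warning.
#' @param collection a [GeneSetLibrary-class].
#' @param minOverlap minimum overlap for a set to be reported (default 5).
#' @return data.frame: `set`, `set_size`, `input_size`, `overlap`, `p`,
#'   `bonferroni_p`, sorted by p.
#' @export
runGeneSetAnalysis <- function(genes, collection, minOverlap = 5L) {
  stopifnot(methods::is(collection, "GeneSetLibrary"))
  genes <- unique(toupper(genes))
  if (!length(genes)) stop("empty input gene list")
  if (length(collection@universe)) {
    out <- setdiff(genes, collection@universe)
    if (length(out)) {
      warning(length(out), " input gene(s) outside the background universe dropped")
      genes <- intersect(genes, collection@universe)
    }
    if (!length(genes)) stop("no input genes inside the universe")
  }
  N <- collection@universeSize
  m <- length(collection@sets)
  rows <- lapply(names(collection@sets), function(nm) {
    set <- collection@sets[[nm]]
    if (length(collection@universe)) set <- intersect(set, collection@universe)
    k <- length(intersect(genes, set))
    data.frame(set = nm, set_size = length(set), input_size = length(genes),
               overlap = k,
               p = if (k > 0) hypergeomTest(k, length(genes), length(set), N)
                   else 1)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$p * m)
  out <- out[out$overlap >= minOverlap, , drop = FALSE]
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Map significant proteins to their gene symbols
#'
#' Collapses a (possibly many-to-many) protein -> gene mapping over a
#' protein list: the union of gene symbols of the given proteins, with
#' duplicates removed. A protein may contribute several genes and several
#' proteins may share a gene.
#'
#' @param proteins protein ids (e.g. Bonferroni-significant ones from
#'   [associateProteins()]).
#' @param mapping data.frame with `protein` and `gene` columns, or a named
#'   character vector (1:1).
#' @return character vector of unique gene symbols.
#' @export
mapProteinsToGenes <- function(proteins, mapping) {
  if (is.data.frame(mapping)) {
    miss <- setdiff(proteins, mapping$protein)
    if (length(miss)) stop("mapping lacks protein(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    unique(toupper(mapping$gene[mapping$protein %in% proteins]))
  } else {
    miss <- setdiff(proteins, names(mapping))
    if (length(miss)) stop("mapping lacks protein(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    unique(toupper(unname(mapping[proteins])))
  }
}

#' Construct a gene-set collection
#'
#' @param sets named list of gene symbol vectors (uppercased, deduplicated).
#' @param universe optional explicit background symbols.
#' @param universeSize background size when no explicit universe is given;
#'   defaults to 20260 protein-coding genes.
#' @return a [GeneSetLibrary-class].
#' @export
geneSetLibrary <- function(sets, universe = character(),
                           universeSize = NULL) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  universe <- unique(toupper(universe))
  if (is.null(universeSize))
    universeSize <- if (length(universe)) length(universe) else 20260L
  methods::new("GeneSetLibrary", sets = sets, universe = universe,
               universeSize = as.integer(universeSize))
}
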