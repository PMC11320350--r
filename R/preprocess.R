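#' Remove proteins with high missingness
#'
#' Drops every protein whose missing fraction exceeds `threshold` and
#' reports the removed ids. Assay panels typically carry a handful of
#' proteins with extreme dropout (missingness well above 50%) that are
#' excluded before imputation; the default threshold of 0.5 reproduces that
#' behaviour while leaving ordinarily-missing proteins for the imputer.
#'
#' @param x participants-by-proteins matrix (or [ProteomicCohort-class]).
#' @param threshold missing-fraction cutoff in (0, 1]; proteins with
#'   missingness strictly above it are removed.
#' @param ... unused.
#' @return for matrices, a list with `matrix` and `removed`; for cohorts,
#'   the filtered cohort with removed ids in `metadata(x)$removedProteins`.
#' @examples
#' m <- matrix(c(1, NA, NA, 2, 3, 4), 3, 2,
#'             dimnames = list(NULL, c("A", "B")))
#' filterHighMissingness(m, 0.5)$removed
#' @name filterHighMissingness
NULL

#' @rdname filterHighMissingness
#' @export
setMethod("filterHighMissingness", "matrix", function(x, threshold = 0.5, ...) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty matrix")
  frac <- colMeans(is.na(x))
  drop <- frac > threshold
  list(matrix = x[, !drop, drop = FALSE],
       removed = colnames(x)[drop],
       missingFraction = frac)
})

#' @rdname filterHighMissingness
#' @export
setMethod("filterHighMissingness", "ProteomicCohort",
  function(x, threshold = 0.5, ...) {
    res <- filterHighMissingness(proteinMatrix(x), threshold)
    out <- x[!rownames(x) %in% res$removed, ]
    S4Vectors::metadata(out)$removedProteins <- res$removed
    out
  })

#' k-nearest-neighbour imputation of protein expression
#'
#' Replaces each missing cell with the inverse-distance-weighted mean of the
#' k nearest participants that observe that protein. Distance between two
#' participants is the Euclidean distance over their jointly observed
#' proteins, scaled by the number of shared dimensions (root mean squared
#' difference), so participants with different missingness patterns remain
#' comparable. Observed cells are never altered. Neighbours at distance zero
#' take over with equal weights. If fewer than k usable neighbours exist,
#' all available ones are used with a warning; a participant with no usable
#' neighbour for a protein falls back to the protein mean.
#'
#' @param x participants-by-proteins matrix (or [ProteomicCohort-class]).
#' @param k neighbour count (>= 1); panels of ~3000 proteins are typically
#'   imputed with k = 10.
#' @param ... unused.
#' @return completed object of the same class.
#' @name knnImpute
NULL

#' @rdname knnImpute
#' @export
setMethod("knnImpute", "matrix", function(x, k = 10L, ...) {
  if (k < 1) stop("k must be >= 1")
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L))
    stop("every participant must observe at least one protein")
  x0 <- x; x0[!obs] <- 0
  n <- nrow(x)
  # Pairwise scaled squared distances over co-observed proteins:
  # d2[i,j] = sum_shared (xi - xj)^2 / n_shared
  sq <- x0^2
  cross <- tcrossprod(x0)                     # sum over shared of xi*xj
  oi <- obs * 1
  si <- sq %*% t(oi)                          # sum xi^2 over j-observed dims
  shared <- oi %*% t(oi)                      # co-observed counts
  d2 <- (si + t(si) - 2 * cross) / pmax(shared, 1)
  d2[shared == 0] <- Inf
  diag(d2) <- Inf
  warned <- FALSE
  for (i in unname(which(rowSums(!obs) > 0L))) {
    for (j in unname(which(!obs[i, ]))) {
      cand <- which(obs[, j] & is.finite(d2[i, ]))
      if (!length(cand)) { x[i, j] <- mean(x[obs[, j], j]); next }
      if (length(cand) < k && !warned) {
        warning(sprintf(
          "fewer than k = %d usable neighbours for some cells; using all available", k))
        warned <- TRUE
      }
      kk <- min(k, length(cand))
      nb <- cand[order(d2[i, cand])[seq_len(kk)]]
      d <- sqrt(d2[i, nb])
      w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
      x[i, j] <- sum(w * x[nb, j]) / sum(w)
    }
  }
  x
})

#' @rdname knnImpute
#' @export
setMethod("knnImpute", "ProteomicCohort", function(x, k = 10L, ...) {
  SummarizedExperiment::assay(x, "npx") <- t(knnImpute(proteinMatrix(x), k))
  x
})

#' Rank-based inverse normal transformation
#'
#' Maps values to z-scores via the Blom formula
#' \eqn{z_i = \Phi^{-1}\{(r_i - 3/8)/(n + 1/4)\}} with average ranks for
#' ties. Strictly monotone in the input ranks; symmetric inputs map to
#' sign-symmetric outputs. Missing values are ignored (n counts non-missing)
#' and returned as `NA`.
#'
#' @param x numeric vector, n >= 2 non-missing, not all identical.
#' @return z-score vector aligned with `x`.
#' @examples
#' inverseNormal(c(10, 20, 30))   # middle value maps to 0
#' @export
inverseNormal <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(v)) == 1L) stop("all values identical")
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}

#' Residuals of a measure after regressing out chronological age
#'
#' Least-squares residuals of `measure ~ age` (with intercept): mean zero
#' and orthogonal to age. Used for age-adjusted correlations between
#' biological-age measures.
#'
#' @param measure numeric vector.
#' @param age numeric vector of the same length, not constant.
#' @return residual vector (`NA` where either input is missing).
#' @export
ageAdjustedResiduals <- function(measure, age) {
  if (length(measure) != length(age)) stop("length mismatch")
  ok <- !is.na(measure) & !is.na(age)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(age[ok]) == 0) stop("age is constant")
  fit <- stats::lm.fit(cbind(1, age[ok]), measure[ok])
  out <- rep(NA_real_, length(measure))
  out[ok] <- fit$residuals
  out
}

#' Reverse the sign of a measure
#'
#' Elementwise negation, used to orient measures whose raw direction is
#' "higher is healthier" (e.g. telomere length: short telomere length is the
#' aging-directed version) so association directions are comparable across
#' biological-age measures.
#'
#' @param x numeric vector.
#' @return `-x`.
#' @export
reverseSign <- function(x) -x
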