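test_that("cohort split has the documented sizes and is deterministic", {
  ids <- sprintf("S%05d", 1:53021)
  sp <- splitCohort(ids, 0.70, seed = 1)
  expect_length(sp$train, 37115)
  expect_length(sp$test, 15906)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- splitCohort(ids, 0.70, seed = 1)
  expect_identical(sp, sp2)
  expect_length(splitCohort(letters[1:10], 0.5, seed = 2)$train, 5)
  expect_error(splitCohort("a", 0.5), "at least 2")
})

gmFixture <- function(shape, lograte, ageCoef, extra = numeric()) {
  new("GompertzModel", shape = shape, lograte = lograte,
      coef = c(age = ageCoef, extra), vcov = matrix(NA_real_, 0, 0),
      loglik = NA_real_, convergence = list())
}

test_that("identical full and reference models return chronological age exactly", {
  m <- gmFixture(0.09, -10, 0.085)
  pac <- new("PACModel", full = m, ageOnly = m, horizon = 10,
             selected = character(), meta = list())
  for (a in c(40, 55.5, 69.9)) {
    r <- proteomicAge(pac, c(age = a))
    expect_equal(r$proteomic_age, a, tolerance = 1e-10)
    expect_equal(r$deviation, 0, tolerance = 1e-10)
  }
})

test_that("closed-form inversion agrees with a bisection oracle", {
  pac <- new("PACModel", full = gmFixture(0.12, -11, 0.09),
             ageOnly = gmFixture(0.1, -10, 0.1), horizon = 10,
             selected = character(), meta = list())
  for (M in c(0.001, 0.05, 0.3, 0.9)) {
    A <- protclock:::invertAgeOnly(pac, M)
    # oracle: bisect gompertzCumInc of the reference model
    f <- function(a) gompertzCumInc(pac@ageOnly, c(age = a), 10) - M
    Ab <- uniroot(f, c(-500, 500), tol = 1e-12)$root
    expect_equal(unname(A), Ab, tolerance = 1e-8)
  }
  expect_error(protclock:::invertAgeOnly(pac, 0), "strictly")
  expect_error(protclock:::invertAgeOnly(pac, 1), "strictly")
})

test_that("hand-parameter case matches the oracle to 1e-8 years", {
  pac <- new("PACModel", full = gmFixture(0.1, -10, 0.1),
             ageOnly = gmFixture(0.1, -10, 0.1), horizon = 10,
             selected = character(), meta = list())
  A <- protclock:::invertAgeOnly(pac, 0.05)
  f <- function(a) gompertzCumInc(pac@ageOnly, c(age = a), 10) - 0.05
  expect_equal(unname(A), uniroot(f, c(-200, 400), tol = 1e-13)$root,
               tolerance = 1e-8)
})

test_that("proteomic age is strictly increasing in a positive-coefficient protein", {
  full <- gmFixture(0.09, -10.5, 0.08, c(P1 = 0.4))
  pac <- new("PACModel", full = full, ageOnly = gmFixture(0.09, -10, 0.08),
             horizon = 10, selected = "P1", meta = list())
  vals <- seq(-2, 2, by = 0.25)
  ages <- vapply(vals, function(v)
    proteomicAge(pac, c(age = 55, P1 = v))$proteomic_age, 0)
  expect_true(all(diff(ages) > 0))
})

test_that("batch scoring equals row-by-row application and ignores column order", {
  p <- simParams(n = 400, nProteins = 8, nCausal = 2, missingRate = 0,
                 diseaseSpecs = list(), seed = 51)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  M <- proteinMatrix(pc)
  pac <- buildPAC(M, cd$age, cd$time_death, cd$died, colnames(M)[1:3])
  sc <- scoreCohort(pac, pc)
  i <- c(1, 57, 400)
  for (ii in i) {
    r <- proteomicAge(pac, c(age = cd$age[ii], M[ii, ]))
    expect_equal(sc$proteomic_age[ii], r$proteomic_age, tolerance = 1e-12)
  }
  # permute protein columns
  perm <- cbind(M[, sample(ncol(M))], age = cd$age)
  sc2 <- scoreCohort(pac, perm)
  expect_equal(sc$proteomic_age, sc2$proteomic_age, tolerance = 1e-12)
  # identical covariate rows give identical ages
  same <- matrix(rep(c(M[1, ], 50), 3), 3, byrow = TRUE,
                 dimnames = list(NULL, c(colnames(M), "age")))
  expect_length(unique(scoreCohort(pac, same)$proteomic_age), 1)
  # deviation bookkeeping
  expect_equal(sc$deviation, sc$proteomic_age - sc$age)
  expect_true(all(sc$risk > 0 & sc$risk < 1))
})

test_that("model serialization round-trips scores exactly", {
  p <- simParams(n = 300, nProteins = 6, nCausal = 2, missingRate = 0,
                 diseaseSpecs = list(), seed = 52)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  M <- proteinMatrix(pc)
  pac <- buildPAC(M, cd$age, cd$time_death, cd$died, colnames(M)[1:2])
  f <- tempfile(fileext = ".yaml")
  writePACModel(pac, f)
  pac2 <- readPACModel(f)
  expect_identical(scoreCohort(pac, pc)$proteomic_age,
                   scoreCohort(pac2, pc)$proteomic_age)
  unlink(f)
})

test_that("nested models: full-model fit dominates the age-only fit on strong signal", {
  p <- simParams(n = 2000, nProteins = 5, nCausal = 3, causalBetas = 0.5,
                 missingRate = 0, diseaseSpecs = list(), seed = 53)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  M <- proteinMatrix(pc)
  pac <- buildPAC(M, cd$age, cd$time_death, cd$died, colnames(M)[1:3])
  expect_gt(pac@full@loglik, pac@ageOnly@loglik)
})

test_that("a clock trained end to end reproduces itself under the same seed", {
  p <- simParams(n = 500, nProteins = 20, nCausal = 3, missingRate = 0,
                 diseaseSpecs = list(), seed = 54)
  pc <- simulateCohort(p)
  sp <- splitCohort(colnames(pc), 0.7, seed = 2)
  a <- trainPAC(pc, sp$train, lambda = "cv", seed = 3)
  b <- trainPAC(pc, sp$train, lambda = "cv", seed = 3)
  expect_identical(a@selected, b@selected)
  expect_identical(a@full@coef, b@full@coef)
})
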