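test_that("identical seeds reproduce identical cohorts", {
  p <- simParams(n = 300, nProteins = 15, seed = 7)
  a <- simulateCohort(p)
  b <- simulateCohort(p)
  expect_identical(npx(a), npx(b))
  expect_identical(cohortData(a), cohortData(b))
  c <- simulateCohort(simParams(n = 300, nProteins = 15, seed = 8))
  expect_false(identical(npx(a), npx(c)))
})

test_that("marginal mortality matches the closed-form Gompertz CDF", {
  # no covariate effects: lograte solved from 1 - exp(-(b/a)(e^{13a}-1)) = 0.109
  a <- 0.09; target <- 0.109; k <- 13
  b <- -log(1 - target) * a / expm1(a * k)
  p <- simParams(n = 20000, nProteins = 1, nCausal = 0, ageBeta = 0,
                 lograte = log(b), followupYears = k, missingRate = 0,
                 diseaseSpecs = list(), seed = 41)
  cd <- cohortData(simulateCohort(p))
  se <- sqrt(target * (1 - target) / 20000)
  expect_lt(abs(mean(cd$died) - target), 3 * se)
})

test_that("protein-age correlation matches the linear-plus-noise formula", {
  slope <- 0.05; noise <- 1
  p <- simParams(n = 20000, nProteins = 4, nCausal = 0,
                 ageSlopes = slope, noiseSD = noise, missingRate = 0,
                 diseaseSpecs = list(), seed = 42)
  pc <- simulateCohort(p)
  age <- cohortData(pc)$age
  rTheory <- slope * sd(age) / sqrt(slope^2 * var(age) + noise^2)
  rEmp <- cor(proteinMatrix(pc)[, 1], age)
  expect_lt(abs(rEmp - rTheory), 0.05)
})

test_that("MCAR missingness hits the requested rate and rate 0 is identity", {
  m <- matrix(rnorm(10000), 100, 100,
              dimnames = list(NULL, sprintf("P%03d", 1:100)))
  expect_identical(injectMissingness(m, 0, "MCAR", seed = 1), m)
  mm <- injectMissingness(m, 0.1, "MCAR", seed = 1)
  expect_gte(mean(is.na(mm)), 0.08)
  expect_lte(mean(is.na(mm)), 0.12)
})

test_that("high_miss_proteins drives designated columns to the target rate", {
  m <- matrix(rnorm(5000), 500, 10,
              dimnames = list(NULL, sprintf("P%02d", 1:10)))
  mm <- injectMissingness(m, 0.74, "high_miss_proteins",
                          proteins = "P03", seed = 2)
  expect_gte(mean(is.na(mm[, "P03"])), 0.74)
  expect_equal(sum(is.na(mm[, -3])), 0)
})

test_that("zero disease hazard yields no primary events", {
  p <- simParams(n = 400, nProteins = 5, missingRate = 0, seed = 3,
                 diseaseSpecs = list(null = list(lograte = -Inf, ageBeta = 0)))
  expect_error(simulateCohort(p), NA)
  # -Inf lograte -> hazard 0 -> never an event
  cd <- cohortData(simulateCohort(p))
  expect_true(all(cd$status_null %in% c(0L, 2L)))
})

test_that("with death hazard ~0, disease event fraction follows 1 - exp(-lambda t)", {
  lam <- 0.02
  p <- simParams(n = 8000, nProteins = 1, nCausal = 0, ageBeta = 0,
                 lograte = -30, missingRate = 0, followupYears = 10,
                 diseaseSpecs = list(d = list(lograte = log(lam), ageBeta = 0)),
                 seed = 5)
  cd <- cohortData(simulateCohort(p))
  target <- 1 - exp(-lam * 10)
  se <- sqrt(target * (1 - target) / 8000)
  expect_lt(abs(mean(cd$status_d == 1) - target), 3 * se)
})

test_that("competing-risks bookkeeping is internally consistent", {
  pc <- simulateCohort(simParams(n = 1000, nProteins = 10, seed = 9,
                                 missingRate = 0))
  cd <- cohortData(pc)
  for (d in c("diseaseA", "diseaseB")) {
    tt <- cd[[paste0("time_", d)]]
    st <- cd[[paste0("status_", d)]]
    expect_true(all(st %in% 0:2))
    # death-first records carry the death time
    expect_true(all(tt[st == 2] <= cd$time_death[st == 2] + 1e-12))
    # censored records sit at the administrative horizon or death horizon
    expect_true(all(tt[st == 0] <= 13.3 + 1e-12))
    expect_true(all(tt > 0))
  }
})

test_that("status-1 fraction matches a Monte-Carlo oracle at scale", {
  spec <- list(d = list(lograte = -6.5, ageBeta = 0.05))
  p <- simParams(n = 20000, nProteins = 1, nCausal = 0, missingRate = 0,
                 diseaseSpecs = spec, seed = 13)
  cd <- cohortData(simulateCohort(p))
  frac <- mean(cd$status_d == 1)
  # oracle: 10x replication with independent seeds
  oracle <- vapply(1:10, function(s) {
    mean(cohortData(simulateCohort(
      simParams(n = 4000, nProteins = 1, nCausal = 0, missingRate = 0,
                diseaseSpecs = spec, seed = 1000 + s)))$status_d == 1)
  }, 0)
  mo <- mean(oracle)
  se <- sqrt(mo * (1 - mo) * (1 / 20000 + 1 / 40000))
  expect_lt(abs(frac - mo), 3 * se)
})

test_that("invalid parameters are rejected", {
  expect_error(simParams(n = 0), "positive")
  expect_error(simParams(shape = 0), "shape")
  expect_error(simParams(missingRate = 1), "missingRate")
  expect_error(injectMissingness(matrix(1, 2, 2), 1, "MCAR"), "rate")
})
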