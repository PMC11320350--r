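test_that("Cox association recovers a two-group hazard ratio of 2", {
  set.seed(61)
  n <- 10000
  g <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.05 * 2^g)
  cen <- runif(n, 0, 20)
  res <- fitCox(data.frame(group = g), pmin(t0, cen),
                as.integer(t0 <= cen))
  expect_lt(abs(res$beta - log(2)), 3 * res$se)
  expect_true(res$ci_lo < res$hr & res$hr < res$ci_hi)
})

test_that("tiny tie-free dataset matches a hand-maximized Efron oracle", {
  X <- matrix(c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1), 6, 1,
              dimnames = list(NULL, "x"))
  tt <- c(1.1, 2.3, 3.7, 4.1, 5.9, 7.2)
  ev <- c(1, 0, 1, 1, 0, 1)
  res <- fitCox(X, tt, ev)
  oracle <- oracleCoxEfron(X, tt, ev)
  expect_equal(res$beta, oracle, tolerance = 1e-6)
})

test_that("null covariate p-values are uniform over replicates", {
  set.seed(62)
  ps <- replicate(200, {
    n <- 80
    x <- rnorm(n)
    t0 <- rexp(n, 0.1)
    cen <- runif(n, 0, 15)
    fitCox(data.frame(x = x), pmin(t0, cen), as.integer(t0 <= cen))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Fine-Gray reduces exactly to Cox with no competing events", {
  d <- makeSurvData(400, c(0.5, -0.3), seed = 63)
  cox <- fitCox(d$X, d$time, d$event)
  fg <- fitFineGray(d$X, d$time, d$event)   # status 0/1 only
  expect_lt(max(abs(fg$beta - cox$beta)), 1e-6)
  expect_lt(max(abs(fg$se - cox$se)), 1e-6)
})

test_that("Fine-Gray recovers a subdistribution hazard ratio", {
  d <- simulateFineGray(10000, beta = 0.5, seed = 64)
  res <- fitFineGray(data.frame(x = d$x), d$time, d$status)
  expect_lt(abs(res$beta - 0.5), 3 * res$se)
})

test_that("Fine-Gray agrees with an independent competing-risks implementation", {
  d <- simulateFineGray(2000, beta = 0.4, seed = 65)
  res <- fitFineGray(data.frame(x = d$x), d$time, d$status)
  crr <- cmprsk::crr(d$time, d$status, cbind(x = d$x))
  expect_equal(res$beta, unname(crr$coef), tolerance = 1e-3)
})

test_that("BH adjustment matches the worked example and the step-up oracle", {
  expect_equal(bhFdr(c(0.005, 0.011, 0.02, 0.04, 0.13)),
               c(0.025, 0.0275, 0.02 * 5 / 3, 0.05, 0.13),
               tolerance = 1e-12)
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(rep(0.07, 6)), rep(0.07, 6))
  set.seed(66)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bhFdr(p), bruteForceBH(p), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "out of")
})

test_that("BH equals the brute-force step-up on many random draws", {
  set.seed(67)
  for (i in 1:1000) {
    p <- runif(sample(2:25, 1))
    if (max(abs(bhFdr(p) - bruteForceBH(p))) > 1e-12)
      fail(sprintf("BH mismatch at draw %d", i))
  }
  succeed()
})

test_that("Harrell's C handles the canonical cases", {
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))$C, 1)
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3))$C, 0)
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(5, 5, 5))$C, 0.5)
  r <- harrellC(c(2, 4, 5, 7), c(1, 0, 1, 1), c(9, 8, 3, 4))
  expect_equal(r$C, bruteForceC(c(2, 4, 5, 7), c(1, 0, 1, 1), c(9, 8, 3, 4)))
  expect_error(harrellC(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("Harrell's C equals brute-force enumeration on random fixtures", {
  set.seed(68)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    tt <- sample(1:20, n, replace = TRUE) + ifelse(runif(n) < 0.7, runif(n), 0)
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1L
    rk <- sample(1:8, n, replace = TRUE)
    expect_equal(harrellC(tt, ev, rk)$C, bruteForceC(tt, ev, rk),
                 info = sprintf("fixture %d", i))
  }
})

test_that("Harrell's C agrees with the survival package on tie-free data", {
  set.seed(69)
  d <- makeSurvData(300, c(0.8), seed = 69)
  risk <- drop(d$X)
  cc <- survival::concordance(survival::Surv(d$time, d$event) ~ risk,
                              reverse = TRUE)
  expect_equal(harrellC(d$time, d$event, risk)$C, unname(cc$concordance),
               tolerance = 1e-12)
})

test_that("correlation panel matches rank-formula cases and orthogonality", {
  x <- c(1, 2, 3)
  m <- data.frame(x = x, y = c(3, 1, 2), z = 2 * x + 1)
  cp <- correlationPanel(m, method = "spearman")
  expect_equal(cp["x", "y"], -0.5)      # 1 - 6*6 / (3*8)
  expect_equal(cp["x", "z"], 1)
  set.seed(70)
  df <- data.frame(age = runif(100, 40, 70))
  df$m1 <- 0.6 * df$age + rnorm(100)
  adj <- correlationPanel(df, c("age", "m1"), method = "pearson",
                          ageAdjust = TRUE)
  expect_lt(abs(adj["age", "m1"]), 1e-6)
  expect_error(correlationPanel(data.frame(a = rep(1, 5), b = 1:5)),
               "constant")
})

test_that("concordance comparison ranks the true risk highest", {
  p <- simParams(n = 3000, nProteins = 4, nCausal = 2, causalBetas = 0.6,
                 missingRate = 0, diseaseSpecs = list(), seed = 71)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  gt <- groundTruth(pc)
  M <- proteinMatrix(pc)
  trueRisk <- gt$gompertz[["ageBeta"]] * cd$age +
    drop(M[, gt$causal] %*% gt$betas)
  set.seed(72)
  res <- compareModelsC(cd, list(true_risk = trueRisk, age = cd$age,
                                 noise = rnorm(3000)), "mortality")
  expect_equal(res$score[which.max(res$C)], "true_risk")
  # independent score sits near 0.5
  cN <- res$C[res$score == "noise"]
  seC <- 1 / sqrt(res$n_events[1])   # conservative scale for a null C
  expect_lt(abs(cN - 0.5), 3 * seC)
  # duplicated column gives identical C
  res2 <- compareModelsC(cd, list(a = cd$age, b = cd$age), "mortality")
  expect_equal(res2$C[1], res2$C[2])
})

test_that("the tiered suite matches direct model calls and pools FDR", {
  p <- simParams(n = 1500, nProteins = 5, nCausal = 2, seed = 73,
                 missingRate = 0)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  score <- setNames(rnorm(1500), rownames(cd))
  out <- runAssociationSuite(score, cd, c("mortality", "diseaseA"),
                             tiers = list(age_adjusted = "age"))
  expect_equal(nrow(out), 2)
  direct <- fitCox(data.frame(exposure = score[rownames(cd)],
                              age = cd$age), cd$time_death, cd$died)
  expect_equal(out$beta[out$outcome == "mortality"],
               direct$beta[direct$term == "exposure"], tolerance = 1e-12)
  directFG <- fitFineGray(data.frame(exposure = score[rownames(cd)],
                                     age = cd$age),
                          cd$time_diseaseA, cd$status_diseaseA)
  expect_equal(out$beta[out$outcome == "diseaseA"],
               directFG$beta[directFG$term == "exposure"], tolerance = 1e-12)
  expect_equal(out$p_adj, bhFdr(out$p))
  expect_true(all(out$p_adj >= out$p))
})

test_that("prevalent cases are excluded from their own outcome", {
  p <- simParams(n = 500, nProteins = 3, seed = 74, missingRate = 0)
  pc <- simulateCohort(p)
  cd <- cohortData(pc)
  cd$prevalent_diseaseA <- rep(c(1, 0), length.out = 500)
  score <- setNames(rnorm(500), rownames(cd))
  out <- runAssociationSuite(score, cd, "diseaseA",
                             tiers = list(age_adjusted = "age"))
  expect_equal(out$n, 250)
})
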