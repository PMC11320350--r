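test_that("high-missingness filter drops exactly the proteins above threshold", {
  set.seed(1)
  n <- 10
  m <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("P", 1:5)))
  fracs <- c(0, .2, .4, .6, .8)
  for (j in 1:5) m[seq_len(fracs[j] * n), j] <- NA
  res <- filterHighMissingness(m, 0.5)
  expect_setequal(res$removed, c("P4", "P5"))
  expect_equal(ncol(res$matrix), 3)
  expect_length(filterHighMissingness(m, 1.0)$removed, 0)
})

test_that("filter reproduces a panel-scale removal set from missing fractions", {
  # 2923 proteins of which three have missingness 0.997 / 0.740 / 0.636:
  # a 0.5 threshold retains 2920. Build a thin stand-in matrix (3 rows
  # carry the pattern via per-column missing counts scaled down 10x).
  nprot <- 2923
  n <- 1000
  m <- matrix(0, n, nprot, dimnames = list(NULL, sprintf("P%04d", 1:nprot)))
  miss <- rep(0.01, nprot)
  miss[1:3] <- c(0.997, 0.740, 0.636)
  for (j in 1:3) m[seq_len(round(miss[j] * n)), j] <- NA
  for (j in 4:nprot) m[1:10, j] <- NA
  res <- filterHighMissingness(m, 0.5)
  expect_equal(ncol(res$matrix), 2920)
  expect_setequal(res$removed, sprintf("P%04d", 1:3))
})

test_that("knn imputation reproduces a brute-force weighted-mean oracle", {
  set.seed(2)
  m <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), paste0("p", 1:3)))
  m[1, 2] <- NA
  out <- knnImpute(m, k = 2)
  # oracle: all pairwise RMS distances over co-observed dims, by hand
  d <- sapply(2:6, function(j) {
    sh <- c(1, 3)                       # dims observed by both rows
    sqrt(mean((m[1, sh] - m[j, sh])^2))
  })
  nb <- order(d)[1:2] + 1
  w <- 1 / d[order(d)[1:2]]
  expect_equal(out[1, 2], sum(w * m[nb, 2]) / sum(w), tolerance = 1e-12)
  # observed cells untouched; no missing output
  expect_identical(out[-1, ], m[-1, ])
  expect_false(anyNA(out))
})

test_that("knn imputation invariants hold on random masked matrices", {
  set.seed(3)
  m <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("p", 1:8)))
  mm <- injectMissingness(m, 0.1, "MCAR", seed = 4)
  out <- knnImpute(mm, k = 5)
  obs <- !is.na(mm)
  expect_identical(out[obs], mm[obs])
  expect_false(anyNA(out))
  # convex weights keep imputed values inside each protein's observed range
  for (j in 1:8) {
    rng <- range(mm[obs[, j], j])
    expect_true(all(out[!obs[, j], j] >= rng[1] - 1e-12 &
                    out[!obs[, j], j] <= rng[2] + 1e-12))
  }
  # complete input returned unchanged
  expect_identical(knnImpute(m, 5), m)
})

test_that("knn imputation with k identical complete neighbours returns their value", {
  m <- rbind(c(1, NA, 3), matrix(rep(c(1, 7, 3), 4), 4, 3, byrow = TRUE))
  colnames(m) <- paste0("p", 1:3)
  expect_equal(unname(knnImpute(m, 4)[1, 2]), 7)
  # fewer usable neighbours than k warns and still completes
  expect_warning(out <- knnImpute(m, 10), "fewer than k")
  expect_false(anyNA(out))
})

test_that("inverse normal transform matches the Blom closed form", {
  z <- inverseNormal(c(10, 25, 17))
  expect_equal(sort(z)[2], 0)
  expect_equal(max(z), qnorm((3 - 3 / 8) / (3 + 1 / 4)))
  expect_equal(max(z), 0.8694239, tolerance = 1e-5)
  expect_equal(min(z), -max(z))
  # rank preservation on arbitrary input
  set.seed(5)
  x <- rexp(200)^2
  expect_equal(cor(x, inverseNormal(x), method = "spearman"), 1)
  # near-standardized for tie-free input
  expect_lt(abs(mean(inverseNormal(x))), 1e-6)
  expect_lt(abs(var(inverseNormal(x)) - 1), 0.05)
  # ties get average ranks -> equal z
  zt <- inverseNormal(c(1, 1, 2, 3))
  expect_equal(zt[1], zt[2])
  expect_error(inverseNormal(c(2, 2, 2)), "identical")
})

test_that("age-adjusted residuals equal the normal-equations solution", {
  set.seed(6)
  age <- runif(50, 39, 70)
  e <- rnorm(50)
  y <- 3 + 0.5 * age + e
  r <- ageAdjustedResiduals(y, age)
  # orthogonality and zero mean
  expect_lt(abs(sum(r * age)), 1e-8 * 50 * sd(y))
  expect_lt(abs(mean(r)), 1e-10)
  # oracle via explicit normal equations
  Z <- cbind(1, age)
  bhat <- solve(t(Z) %*% Z, t(Z) %*% y)
  expect_equal(r, drop(y - Z %*% bhat), tolerance = 1e-10)
  # residuals of pure age signal vanish
  expect_lt(max(abs(ageAdjustedResiduals(2 * age, age))), 1e-10)
  expect_error(ageAdjustedResiduals(y, rep(50, 50)), "constant")
})

test_that("residual correlation equals the partial-correlation formula", {
  set.seed(7)
  age <- runif(300, 39, 70)
  m1 <- 0.8 * age + rnorm(300)
  m2 <- 0.5 * age + 0.3 * m1 + rnorm(300)
  rres <- cor(ageAdjustedResiduals(m1, age), ageAdjustedResiduals(m2, age))
  r12 <- cor(m1, m2); r1a <- cor(m1, age); r2a <- cor(m2, age)
  partial <- (r12 - r1a * r2a) / sqrt((1 - r1a^2) * (1 - r2a^2))
  expect_equal(rres, partial, tolerance = 1e-10)
})

test_that("sign reversal is an involution that flips correlations", {
  x <- c(1, -2, 0.5)
  expect_equal(reverseSign(x), c(-1, 2, -0.5))
  expect_equal(reverseSign(reverseSign(x)), x)
  set.seed(8)
  y <- rnorm(3)
  expect_equal(cor(reverseSign(x), y), -cor(x, y))
})

test_that("filter then impute is idempotent on complete matrices", {
  set.seed(9)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("p", 1:10)))
  res <- filterHighMissingness(m, 0.5)
  expect_identical(res$matrix, m)
  expect_identical(knnImpute(res$matrix, 10), m)
})
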