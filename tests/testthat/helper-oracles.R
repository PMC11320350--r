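# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Harrell's C by full pair enumeration.
bruteForceC <- function(time, event, risk) {
  n <- length(time)
  comp <- 0; conc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # order the pair so a is the shorter observed time
    a <- if (time[i] <= time[j]) i else j
    b <- if (time[i] <= time[j]) j else i
    if (time[a] == time[b]) {
      if (event[a] + event[b] != 1L) next     # tied times: need exactly one event
      if (event[a] == 0L) { tmp <- a; a <- b; b <- tmp }
    } else if (event[a] == 0L) next
    comp <- comp + 1
    if (risk[a] > risk[b]) conc <- conc + 1
    else if (risk[a] == risk[b]) conc <- conc + 0.5
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# BH step-up from the definition.
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail by enumerating all draws (small N only).
bruteForceHyper <- function(k, n, K, N) {
  total <- choose(N, n)
  sum(vapply(k:min(n, K), function(i)
    choose(K, i) * choose(N - K, n - i), 0)) / total
}

# Unpenalized Cox (Breslow) by direct optimization of the partial
# likelihood, independent of survival::coxph and glmnet.
oracleCoxBreslow <- function(X, time, event) {
  nll <- function(b) {
    eta <- drop(X %*% b); s <- 0
    for (i in which(event == 1))
      s <- s + eta[i] - log(sum(exp(eta[time >= time[i]])))
    -s
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
}

# Efron-tie Cox negative log partial likelihood (for tiny-data oracle).
oracleCoxEfron <- function(X, time, event) {
  nll <- function(b) {
    eta <- drop(X %*% b); w <- exp(eta); s <- 0
    for (tt in unique(time[event == 1])) {
      D <- which(time == tt & event == 1)
      R <- which(time >= tt)
      d <- length(D)
      s <- s + sum(eta[D])
      for (l in seq_len(d) - 1)
        s <- s - log(sum(w[R]) - l / d * sum(w[D]))
    }
    -s
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
}

# Direct simulation from a proportional subdistribution-hazards model
# (inverse-CDF on F1(t; x) = 1 - {1 - p(1 - e^-t)}^{exp(b x)}) with an
# exponential competing event and uniform censoring.
simulateFineGray <- function(n, beta, pmix = 0.4, competingRate = 0.3,
                             censorMax = 8, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  ebx <- exp(beta * x)
  F1inf <- 1 - (1 - pmix)^ebx
  isev <- stats::runif(n) < F1inf
  time <- numeric(n); status <- integer(n)
  v <- stats::runif(sum(isev), 0, F1inf[isev])
  time[isev] <- -log(1 - (1 - (1 - v)^(1 / ebx[isev])) / pmix)
  status[isev] <- 1L
  time[!isev] <- stats::rexp(sum(!isev), competingRate)
  status[!isev] <- 2L
  cen <- stats::runif(n, 0, censorMax)
  status[cen < time] <- 0L
  data.frame(x = x, time = pmin(time, cen), status = status)
}

# Small complete survival dataset for reuse.
makeSurvData <- function(n, beta, seed = 1, censorMax = 3) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  t0 <- stats::rexp(n, exp(drop(X %*% beta)))
  cen <- stats::runif(n, 0, censorMax)
  list(X = X, time = pmin(t0, cen), event = as.integer(t0 <= cen))
}
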