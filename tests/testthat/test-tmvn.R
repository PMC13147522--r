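# Truncated multivariate normal numerics.

test_that("rectangle probabilities match closed forms", {
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mvn_probability(c(-Inf, -Inf), c(Inf, Inf), sigma = S2), 1)
  expect_equal(mvn_probability(0, Inf, 0, matrix(1)), 0.5)
  # positive orthant with correlation rho: 1/4 + asin(rho)/(2*pi)
  expect_equal(mvn_probability(c(0, 0), c(Inf, Inf), sigma = S2),
               1 / 4 + asin(0.5) / (2 * pi), tolerance = 1e-10)
  # dimension 3, orthant closed form for equicorrelated rho = 0.5
  S3 <- matrix(0.5, 3, 3); diag(S3) <- 1
  expect_equal(mvn_probability(rep(0, 3), rep(Inf, 3), sigma = S3),
               1 / 8 + 3 * asin(0.5) / (4 * pi), tolerance = 1e-7)
})

test_that("rectangle probabilities over a partition sum to one", {
  set.seed(4)
  for (d in 2:4) {
    S <- random_spd(d)
    cuts <- list(c(-Inf, -0.3, 0.6, Inf))[rep(1, d)]
    grid <- expand.grid(rep(list(1:3), d))
    total <- sum(apply(grid, 1, function(g) {
      lo <- vapply(seq_len(d), function(j) cuts[[j]][g[j]], numeric(1))
      hi <- vapply(seq_len(d), function(j) cuts[[j]][g[j] + 1], numeric(1))
      mvn_probability(lo, hi, mean = rep(0.1, d), sigma = S, tol = 1e-7)
    }))
    expect_equal(total, 1, tolerance = d * 1e-5)
  }
})

test_that("probability errors are raised for bad inputs", {
  expect_error(mvn_probability(c(0, 0), c(1, 1), sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(mvn_probability(c(0, 0), c(1, -1), sigma = diag(2)), "empty")
})

test_that("vectorized bivariate CDF matches Genz integration", {
  hs <- c(-1.5, -0.2, 0.4, 2.0, Inf, -Inf)
  ks <- c(0.3, -0.8, 1.1, -2.5, 0.7, 0.2)
  for (rho in c(-0.85, -0.4, 0, 0.3, 0.9)) {
    ref <- vapply(seq_along(hs), function(i) {
      if (is.infinite(hs[i]) && hs[i] < 0) return(0)
      if (is.infinite(hs[i])) return(pnorm(ks[i]))
      as.numeric(mvtnorm::pmvnorm(upper = c(hs[i], ks[i]),
                                  corr = matrix(c(1, rho, rho, 1), 2),
                                  algorithm = mvtnorm::Miwa(steps = 256)))
    }, numeric(1))
    expect_equal(thrlmm:::pbvnorm(hs, ks, rho), ref, tolerance = 1e-9)
  }
})

test_that("univariate cell moments match the classical closed forms", {
  um <- univariate_moments(2, thresholds = 0, mean = 0, var = 1)
  lambda <- dnorm(0) / 0.5
  expect_equal(um$delta, lambda, tolerance = 1e-7)
  expect_equal(um$gamma, lambda^2, tolerance = 1e-7)  # boundary terms vanish
  expect_equal(um$ltilde, 0.7978846, tolerance = 1e-7)
  expect_equal(um$var, 1 - lambda * (lambda - 0), tolerance = 1e-7)
  expect_equal(um$prob, 0.5)
  # interior category of a 3-category trait stays inside its cell
  um2 <- univariate_moments(2, thresholds = c(0, 1), mean = 0.4, var = 1.3)
  expect_gt(um2$ltilde, 0)
  expect_lt(um2$ltilde, 1)
  expect_gt(um2$gamma, 0)
  expect_error(univariate_moments(4, thresholds = c(0, 1), mean = 0, var = 1),
               "category")
})

test_that("untruncated regions return the input moments exactly", {
  S <- random_spd(3, seed = 8)
  mu <- c(0.5, -1, 2)
  expect_equal(tmvn_mean(rep(-Inf, 3), rep(Inf, 3), mu, S), mu)
  expect_equal(tmvn_cov(rep(-Inf, 3), rep(Inf, 3), mu, S), S)
})

test_that("one-sided univariate truncation matches phi/Phi forms", {
  expect_equal(tmvn_mean(0, Inf, 0, matrix(1)), 0.7978846, tolerance = 1e-7)
  expect_equal(tmvn_cov(0, Inf, 0, matrix(1))[1, 1], 0.3633802,
               tolerance = 1e-7)
})

test_that("c=1 numeric path agrees with the closed forms", {
  set.seed(21)
  for (rep in 1:10) {
    mu <- rnorm(1); v <- runif(1, 0.3, 2)
    tv <- sort(rnorm(2))
    k <- sample(3, 1)
    um <- univariate_moments(k, tv, mu, v)
    tt <- c(-Inf, tv, Inf)
    tm <- truncated_moments(tt[k], tt[k + 1], mu, matrix(v))
    expect_equal(tm$mean[1], um$ltilde, tolerance = 1e-8)
    expect_equal(tm$delta[1], um$delta, tolerance = 1e-8)
    expect_equal(tm$gamma[1, 1], um$gamma, tolerance = 1e-6)
  }
})

test_that("analytic moments agree with the rejection-sampling oracle", {
  set.seed(31)
  cases <- list(
    list(d = 2, lo = c(0, -Inf), hi = c(Inf, 0)),
    list(d = 2, lo = c(-0.8, -0.5), hi = c(1, 1.4)),
    list(d = 3, lo = c(-1, -Inf, 0), hi = c(1, 0.5, Inf)),
    list(d = 4, lo = c(-1.5, -1, -Inf, -0.5), hi = c(1, 1.5, 0.8, Inf)))
  for (cs in cases) {
    S <- random_spd(cs$d)
    mu <- rnorm(cs$d, sd = 0.3)
    an <- tmvn_moments(cs$lo, cs$hi, mu, S)
    mc <- tmvn_mc_oracle(cs$lo, cs$hi, mu, S, n_draws = 4e5,
                         seed = 1000 + cs$d)
    expect_lt(abs(an$prob - mc$prob), 3 * mc$se_prob + 1e-4)
    expect_true(all(abs(an$mean - mc$mean) < 3 * mc$se_mean + 1e-3))
    expect_true(all(abs(an$cov - mc$cov) < 3 * mc$se_cov + 2e-3))
  }
})

test_that("delta and gamma are derivatives of the log cell probability", {
  # delta = d log P / d mu and gamma = -d delta / d mu: checks mean and
  # covariance through an independent route (probabilities only)
  S <- random_spd(3, seed = 55)
  lo <- c(-1, -Inf, 0); hi <- c(1, 0.5, Inf); mu <- c(0, 0.2, -0.1)
  tm <- truncated_moments(lo, hi, mu, S, tol = 1e-12)
  num <- fd_gradient(function(m) log(mvn_probability(lo, hi, m, S, 1e-12)), mu)
  expect_equal(tm$delta, num, tolerance = 1e-5)
  expect_equal(tm$gamma, t(tm$gamma))
  ev <- eigen(tm$gamma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("bivariate fast path equals the general moment recursion", {
  set.seed(77)
  for (rep in 1:8) {
    S <- random_spd(2)
    mu <- matrix(rnorm(2, sd = 0.5), 1)
    lo <- matrix(sort(rnorm(2, sd = 1.2))[1], 1, 2)
    lo[1, 2] <- -Inf
    hi <- matrix(c(lo[1, 1] + runif(1, 0.5, 2), rnorm(1)), 1)
    fast <- thrlmm:::biv_trunc_moments(lo, hi, mu, S)
    gen <- tmvn_moments(c(lo), c(hi), c(mu), S)
    expect_equal(c(fast$mean), gen$mean, tolerance = 1e-7)
    expect_equal(fast$v11[1], gen$cov[1, 1], tolerance = 1e-6)
    expect_equal(fast$v22[1], gen$cov[2, 2], tolerance = 1e-6)
    expect_equal(fast$v12[1], gen$cov[1, 2], tolerance = 1e-6)
    expect_equal(fast$prob[1], gen$prob, tolerance = 1e-8)
  }
})

test_that("the MC oracle reproduces known quantities and guards rates", {
  mc <- tmvn_mc_oracle(0, Inf, 0, matrix(1), n_draws = 2e5, seed = 3)
  expect_lt(abs(mc$mean - 0.79788), 3 * mc$se_mean)
  expect_lt(abs(mc$prob - 0.5), 3 * mc$se_prob)
  expect_error(tmvn_mc_oracle(c(6, 6), c(7, 7), c(0, 0), diag(2),
                              n_draws = 1e4, seed = 1), "acceptance rate")
})
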