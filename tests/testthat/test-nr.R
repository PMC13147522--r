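# Newton-Raphson solver.

test_that("one round solves the linear model exactly", {
  p <- make_params(c("a", "b"), va = c(0.3, 0.5), ve = c(0.9, 1.1))
  b <- toy_bundle(40, n_generations = 2, seed = 71, params = p)
  fit <- nr_solve(b$ws, b$S, tol = 1e-12)
  expect_equal(fit$rounds, 1L)
  expect_equal(fit$theta, dense_blup(b$ws, b$S), tolerance = 1e-8)
})

test_that("assembled gradient and Hessian match finite differences of the log posterior", {
  p <- make_params(c("y1", "y2"), va = c(0.3, 0.4), ve = c(1, 0.8))
  b <- toy_bundle(3, n_generations = 1, seed = 73, params = p)
  set.seed(2)
  theta <- rnorm(b$ws$n_eq, sd = 0.2)
  sys <- assemble_mme(b$ws, theta, b$S, tol = 1e-12)
  f <- function(th) lp_direct(b$ws, th, b$S)
  expect_equal(sys$gradient, fd_gradient(f, theta), tolerance = 1e-5)
  # Hessian = -C: second central differences of the direct log posterior
  n <- b$ws$n_eq
  h <- 1e-4
  H_num <- matrix(0, n, n)
  f0 <- f(theta)
  for (j in seq_len(n)) {
    ej <- numeric(n); ej[j] <- h
    for (k in j:n) {
      ek <- numeric(n); ek[k] <- h
      H_num[j, k] <- H_num[k, j] <-
        (f(theta + ej + ek) - f(theta + ej - ek) -
           f(theta - ej + ek) + f(theta - ej - ek)) / (4 * h^2)
    }
  }
  expect_equal(as.matrix(-sys$C), H_num, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("a converged solution is a fixed point", {
  b <- toy_bundle(25, seed = 79)
  fit <- nr_solve(b$ws, b$S, tol = 1e-12)
  refit <- nr_solve(b$ws, b$S, tol = 1e-10, theta0 = fit$theta)
  expect_equal(refit$rounds, 0L)
  expect_equal(refit$theta, fit$theta, tolerance = 1e-10)
})

test_that("the gradient vanishes at the returned solution", {
  b <- toy_bundle(30, seed = 83)
  fit <- nr_solve(b$ws, b$S, tol = 1e-12)
  sys <- assemble_mme(b$ws, fit$theta, b$S)
  expect_lt(max(abs(sys$gradient)), 1e-6)
})

test_that("the log posterior is non-decreasing across accepted rounds", {
  b <- toy_bundle(40, seed = 89)
  fit <- nr_solve(b$ws, b$S, tol = 1e-12)
  lps <- vapply(fit$theta_trace, function(th) log_posterior(b$ws, th, b$S),
                numeric(1))
  expect_true(all(diff(lps) > -1e-8))
})

test_that("closed-form and numeric moment paths give the same round quantities", {
  # along an actual solver trajectory, the univariate fast path and the
  # general recursion produce matching Delta/Gamma per record
  b <- toy_bundle(10, seed = 97)
  fit <- nr_solve(b$ws, b$S, tol = 1e-10)
  p <- b$ws$patterns[[1]]
  bb <- thrlmm:::cell_bounds(b$ws, p)
  for (th in fit$theta_trace[1:min(3, length(fit$theta_trace))]) {
    eta <- thrlmm:::eta_matrix(b$ws, th)
    y2 <- b$ws$Y[p$records, p$cont, drop = FALSE]
    mu <- eta[p$records, p$cat, drop = FALSE] +
      (y2 - eta[p$records, p$cont, drop = FALSE]) %*% t(p$A12)
    fast <- thrlmm:::pattern_moments(bb$lower, bb$upper, mu, p$Sigma,
                                     p$Sigma_inv)
    for (i in seq_along(p$records)) {
      tm <- truncated_moments(bb$lower[i, ], bb$upper[i, ], mu[i, ],
                              p$Sigma)
      expect_equal(fast$Delta[i, ], tm$delta, tolerance = 1e-8)
      expect_equal(fast$G[i, , ], tm$gamma[1, 1], tolerance = 1e-8)
    }
  }
})

test_that("non-convergence raises an informative condition with the trace", {
  b <- toy_bundle(25, seed = 101)
  err <- tryCatch(nr_solve(b$ws, b$S, tol = 1e-12, max_rounds = 1L),
                  thrlmm_no_convergence = function(e) e)
  expect_s3_class(err, "thrlmm_no_convergence")
  expect_true(length(err$metric_trace) >= 1)
})

test_that("prediction error variances match the dense inverse and ordering", {
  b <- toy_bundle(12, seed = 103)
  fit <- fit_threshold_model(b$data, b$ped, b$model, tol = 1e-10)
  pv <- pev(fit)
  Cd <- solve(as.matrix(fit$C))
  ws <- fit$ws
  for (k in sample(nrow(pv), 5)) {
    apos <- match(as.character(pv$animal[k]), ws$ped$id)
    tpos <- match(pv$trait[k], ws$model$traits)
    eq <- (ws$q + apos - 1) * ws$TT + tpos
    expect_equal(pv$pev[k], Cd[eq, eq], tolerance = 1e-8)
  }
  # information ordering: a parentless animal without records has higher
  # PEV than a well-recorded parent with many progeny
  ped <- tibble::tibble(animal = 1:12, sire = c(0, 0, rep(1, 9), 0),
                        dam = c(0, 0, rep(2, 9), 0))
  p <- make_params("y", va = 0.5, ve = 1, thresholds = list())
  set.seed(1)
  dat <- tibble::tibble(animal = 1:11, sex = rep(c("F", "M"), length.out = 11),
                        generation = rep(1, 11), y = rnorm(11))
  model <- threshold_model(continuous = "y", fixed = "sex",
                           R = p$R, G0 = p$G0)
  fit2 <- fit_threshold_model(dat, ped, model, tol = 1e-10)
  pv2 <- pev(fit2, animals = c(1, 12), traits = "y")
  expect_lt(pv2$pev[pv2$animal == 1], pv2$pev[pv2$animal == 12])
})
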