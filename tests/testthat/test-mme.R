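# Working mixed model equations: block inverses, pseudo-data, assembly,
# solvers.

test_that("rtilde_inverse is the closed-form inverse of the working R", {
  set.seed(41)
  for (cc in 1:2) for (mm in 0:2) {
    R <- random_spd(cc + mm)
    gamma <- random_spd(cc) * 0.5
    if (mm) {
      R22 <- R[cc + seq_len(mm), cc + seq_len(mm), drop = FALSE]
      R22i <- solve(R22)
      R12 <- R[seq_len(cc), cc + seq_len(mm), drop = FALSE]
      A12 <- R12 %*% R22i
      Rt <- rbind(cbind(solve(gamma) + A12 %*% t(R12), R12),
                  cbind(t(R12), R22))
      Rti <- rtilde_inverse(gamma, A12, R22i)
    } else {
      Rt <- solve(gamma)
      Rti <- rtilde_inverse(gamma, matrix(0, cc, 0), matrix(0, 0, 0))
    }
    expect_lt(max(abs(Rti %*% Rt - diag(cc + mm))), 1e-10)
  }
  # R12 = 0 gives a block diagonal
  g <- matrix(0.7)
  out <- rtilde_inverse(g, matrix(0, 1, 1), matrix(2))
  expect_equal(out, rbind(c(0.7, 0), c(0, 2)))
})

test_that("the univariate working precision reduces to the scalar form", {
  # with one categorical trait, the block matrix must equal the classical
  # [[g, -g a], [-a g, a g a + R22inv]] with scalar gamma
  set.seed(43)
  R <- random_spd(3)
  R22i <- solve(R[2:3, 2:3])
  a <- R[1, 2:3, drop = FALSE] %*% R22i
  g <- 0.55
  out <- rtilde_inverse(matrix(g), a, R22i)
  expect_equal(out[1, 1], g)
  expect_equal(out[1, 2:3], -g * c(a), ignore_attr = TRUE)
  expect_equal(out[2:3, 2:3], t(a) %*% (g * a) + R22i, ignore_attr = TRUE)
})

test_that("pseudo-records satisfy the defining identity W theta + Rtilde z = ytilde", {
  set.seed(47)
  for (rep in 1:6) {
    cc <- sample(1:2, 1); mm <- sample(1:2, 1)
    R <- random_spd(cc + mm)
    R22 <- R[cc + seq_len(mm), cc + seq_len(mm), drop = FALSE]
    R22i <- solve(R22)
    R12 <- R[seq_len(cc), cc + seq_len(mm), drop = FALSE]
    A12 <- R12 %*% R22i
    Sigma <- R[seq_len(cc), seq_len(cc), drop = FALSE] - A12 %*% t(R12)
    eta1 <- rnorm(cc); eta2 <- rnorm(mm); y2 <- rnorm(mm)
    mu <- eta1 + as.vector(A12 %*% (y2 - eta2))
    tm <- truncated_moments(rep(-0.8, cc), rep(Inf, cc), mu, Sigma)
    pr <- pseudo_record(tm$delta, tm$gamma, mu, y2, eta2, A12, R22i)
    Rt <- rbind(cbind(solve(tm$gamma) + A12 %*% t(R12), R12),
                cbind(t(R12), R22))
    lhs <- c(eta1, eta2) + as.vector(Rt %*% pr$z)
    expect_equal(lhs, pr$ytilde, tolerance = 1e-9)
  }
})

test_that("all-continuous records pass through as their own pseudo-data", {
  p <- make_params(c("y1", "y2"), va = c(0.3, 0.4), ve = c(1, 0.8))
  b <- toy_bundle(15, seed = 51, params = p)
  rq <- thrlmm:::round_quantities(b$ws, rnorm(b$ws$n_eq, sd = 0.1))
  expect_equal(rq$ytilde, as.vector(t(b$ws$Y)), tolerance = 1e-12)
})

test_that("assembly is additive over records", {
  b <- toy_bundle(12, seed = 53)
  S0 <- b$S * 0
  theta <- numeric(b$ws$n_eq)
  one <- assemble_mme(b$ws, theta, S0)
  dat2 <- dplyr::bind_rows(b$data, b$data)
  ws2 <- validate_model_data(dat2, b$ped, b$model)
  two <- assemble_mme(ws2, theta, S0)
  expect_lt(max(abs(two$C - 2 * one$C)), 1e-10)
  expect_equal(two$rhs, 2 * one$rhs, tolerance = 1e-10)
})

test_that("all-continuous assembly reproduces the dense multi-trait MME", {
  p <- make_params(c("a", "b"), va = c(0.3, 0.5), ve = c(0.9, 1.1))
  b <- toy_bundle(5, n_generations = 1, seed = 57, params = p)
  sys <- assemble_mme(b$ws, numeric(b$ws$n_eq), b$S)
  theta_pkg <- solve_mme(sys$C, sys$rhs)
  expect_equal(theta_pkg, dense_blup(b$ws, b$S), tolerance = 1e-8)
})

test_that("the assembled gradient equals rhs - C theta", {
  b <- toy_bundle(20, seed = 61)
  theta <- rnorm(b$ws$n_eq, sd = 0.2)
  sys <- assemble_mme(b$ws, theta, b$S)
  expect_equal(sys$gradient, sys$rhs - as.vector(sys$C %*% theta),
               tolerance = 1e-9)
})

test_that("direct and PCG solvers agree, and PCG handles singular systems", {
  b <- toy_bundle(250, n_generations = 3, seed = 63)
  sys <- assemble_mme(b$ws, numeric(b$ws$n_eq), b$S)
  expect_gt(nrow(sys$C), 450)
  xd <- solve_mme(sys$C, sys$rhs, "direct")
  xp <- solve_mme(sys$C, sys$rhs, "pcg", tol = 1e-12)
  expect_lt(max(abs(xd - as.vector(xp))), 1e-8)
  # identity system
  expect_equal(solve_mme(Matrix::Diagonal(5), 1:5), as.numeric(1:5))
  # matrix-free operator path
  xf <- solve_mme(function(v) as.vector(sys$C %*% v), sys$rhs, "pcg",
                  tol = 1e-10, diag_C = Matrix::diag(sys$C))
  expect_lt(max(abs(xd - as.vector(xf))), 1e-6)
  # singular but consistent: rank-deficient PSD matrix
  set.seed(1)
  U <- matrix(rnorm(40 * 30), 40, 30)
  Cs <- Matrix::Matrix(tcrossprod(U), sparse = TRUE)
  x0 <- rnorm(40)
  rhs <- as.vector(Cs %*% x0)
  xs <- solve_mme(Cs, rhs, "pcg", tol = 1e-9, maxit = 20000)
  expect_lt(sqrt(sum((as.vector(Cs %*% xs) - rhs)^2)) / sqrt(sum(rhs^2)),
            1e-8)
})
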