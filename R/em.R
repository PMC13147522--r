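# Expectation-Maximization MAP solver with SQUAREM acceleration.
#
# E-step: replace each unobserved liability by its truncated-normal
# conditional expectation ltilde given the observed category, the
# continuous records and the current solutions. M-step: solve the
# ordinary multi-trait mixed model equations (W' R^-1 W + S) theta =
# W' R^-1 ydot with ydot = (ltilde, y2) as phenotypes; the coefficient
# matrix does not depend on theta, so its sparse Cholesky factorization
# is computed once and reused across all rounds. SQUAREM extrapolation is
# applied after every pair of plain EM updates, with fallback to the
# plain iterate if the accelerated point worsens the convergence metric.
# Both solvers share the Newton-Raphson residual metric as stopping rule,
# so their convergence declarations are comparable.

#' EM E-step: working liabilities
#'
#' Computes the conditional expectations of the liabilities for all
#' records and returns the working response vector `ydot` (liability
#' expectations for categorical traits, observed values for continuous
#' ones) over the workspace's observed rows.
#'
#' @inheritParams nr_solve
#' @param theta Current solutions.
#' @return Numeric vector of length `ws$n_rows`.
#' @export
em_estep <- function(ws, theta, integration_tol = 1e-8) {
  eta <- eta_matrix(ws, theta)
  ydot <- numeric(ws$n_rows)
  for (p in ws$patterns) {
    rows <- p$row_mat
    cc <- length(p$cat); mm <- length(p$cont)
    if (cc == 0L) {
      ydot[as.vector(rows)] <- as.vector(ws$Y[p$records, p$obs, drop = FALSE])
      next
    }
    eta_cat <- eta[p$records, p$cat, drop = FALSE]
    if (mm) {
      y2 <- ws$Y[p$records, p$cont, drop = FALSE]
      mu <- eta_cat + (y2 - eta[p$records, p$cont, drop = FALSE]) %*% t(p$A12)
    } else {
      y2 <- matrix(0, length(p$records), 0)
      mu <- eta_cat
    }
    bb <- cell_bounds(ws, p)
    mom <- pattern_moments(bb$lower, bb$upper, mu, p$Sigma, p$Sigma_inv,
                           integration_tol)
    ydot[as.vector(rows)] <- as.vector(cbind(mom$ltilde, y2))
  }
  ydot
}

# Constant M-step system: full-R working precision, assembled and
# factorized once. `n_factorizations` counts Cholesky calls so tests can
# assert the reuse property.
em_system <- function(ws, S) {
  Bi <- integer(0); Bj <- integer(0); Bx <- numeric(0)
  for (p in ws$patterns) {
    tmpl <- block_template(p$row_mat, p$n_obs)
    Bi <- c(Bi, tmpl$i); Bj <- c(Bj, tmpl$j)
    Bx <- c(Bx, rep(as.vector(p$R_obs_inv), each = length(p$records)))
  }
  B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx,
                            dims = c(ws$n_rows, ws$n_rows))
  WtB <- Matrix::crossprod(ws$W, B)
  C <- Matrix::forceSymmetric(WtB %*% ws$W + S)
  counter <- new.env(parent = emptyenv())
  counter$n_factorizations <- 1L
  list(C = C, WtB = WtB,
       chol = Matrix::Cholesky(C, LDL = FALSE), counter = counter)
}

#' EM M-step: linear mixed-model solve with working phenotypes
#'
#' @param sys Constant system produced internally (coefficient matrix and
#'   cached factorization); see [em_solve()].
#' @param ydot Working response from [em_estep()].
#' @return Updated solution vector.
#' @export
em_mstep <- function(sys, ydot) {
  rhs <- as.vector(sys$WtB %*% ydot)
  as.vector(Matrix::solve(sys$chol, rhs))
}

#' SQUAREM extrapolation step
#'
#' Squared-iterate extrapolation from three consecutive plain-EM iterates
#' with steplength `alpha = -||r|| / ||v||` (clamped to at most -1),
#' where `r = theta_em1 - theta_prev` and `v = theta_em2 - theta_em1 - r`.
#'
#' @param theta_prev,theta_em1,theta_em2 Consecutive EM iterates.
#' @return Extrapolated solution vector with attribute `"alpha"`.
#' @export
squarem_accelerate <- function(theta_prev, theta_em1, theta_em2) {
  r <- theta_em1 - theta_prev
  v <- theta_em2 - theta_em1 - r
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    out <- theta_em2
    attr(out, "alpha") <- -1
    return(out)
  }
  alpha <- min(-sqrt(sum(r^2)) / nv, -1)
  out <- theta_prev - 2 * alpha * r + alpha^2 * v
  attr(out, "alpha") <- alpha
  out
}

#' EM MAP estimation with SQUAREM acceleration
#'
#' @inheritParams nr_solve
#' @param accelerate Apply SQUAREM after every pair of plain EM rounds.
#' @return List with `theta`, `rounds` (M-step solves), `metric_trace`,
#'   `converged`, `n_accepted_accelerations`, `n_factorizations`.
#' @export
em_solve <- function(ws, S, tol = 1e-12, max_rounds = 1000L,
                     integration_tol = 1e-8, theta0 = NULL,
                     accelerate = TRUE) {
  theta <- theta0 %||% numeric(ws$n_eq)
  sys <- em_system(ws, S)
  metric_at <- function(th) {
    rq <- round_quantities(ws, th, integration_tol)
    mme_from_round(ws, rq, S, th)$metric
  }
  metric <- metric_at(theta)
  trace <- metric
  theta_trace <- list(theta)
  rounds <- 0L
  n_acc <- 0L
  while (metric >= tol) {
    if (rounds >= max_rounds) {
      err <- rlang::error_cnd(message = paste0(
        "EM did not converge in ", max_rounds, " rounds (metric ",
        format(metric), ")"), class = "thrlmm_no_convergence")
      err$metric_trace <- trace
      rlang::cnd_signal(err)
    }
    th1 <- em_mstep(sys, em_estep(ws, theta, integration_tol))
    rounds <- rounds + 1L
    m1 <- metric_at(th1)
    trace <- c(trace, m1)
    theta_trace <- c(theta_trace, list(th1))
    if (!accelerate || m1 < tol) {
      theta <- th1; metric <- m1
      next
    }
    th2 <- em_mstep(sys, em_estep(ws, th1, integration_tol))
    rounds <- rounds + 1L
    m2 <- metric_at(th2)
    trace <- c(trace, m2)
    th_acc <- squarem_accelerate(theta, th1, th2)
    m_acc <- metric_at(th_acc)
    if (is.finite(m_acc) && m_acc < m2) {
      theta <- as.vector(th_acc); metric <- m_acc
      n_acc <- n_acc + 1L
      trace[length(trace)] <- m_acc
    } else {
      theta <- th2; metric <- m2
    }
    theta_trace <- c(theta_trace, list(theta))
  }
  list(theta = theta, rounds = rounds, metric_trace = trace,
       theta_trace = theta_trace, converged = TRUE,
       n_accepted_accelerations = n_acc,
       n_factorizations = sys$counter$n_factorizations, method = "em")
}
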