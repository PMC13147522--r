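# Newton-Raphson MAP solver.
#
# Each outer round evaluates, per record, the conditional liability
# moments and the truncated-cell quantities at the current solutions,
# rebuilds the working system (W' Rtilde^-1 W + S) theta = W' Rtilde^-1
# ytilde, and solves it; because the objective is the joint log posterior
# and the working system encodes its exact gradient and Hessian, the
# update is a full Newton step. Convergence is declared when
# ||rhs - C theta|| / ||rhs|| drops below `tol` (default 1e-12). If a
# round increases that metric the step is halved, up to five times
# (plain Newton can overshoot on non-quadratic objectives).

#' Newton-Raphson MAP estimation
#'
#' @param ws Workspace from [validate_model_data()] (or build one by
#'   passing `data`, `pedigree`, `model` to [fit_threshold_model()]).
#' @param S Random-effect precision from [build_S()].
#' @param tol Convergence tolerance on the relative working-system
#'   residual.
#' @param max_rounds Maximum outer rounds (solves).
#' @param integration_tol Absolute tolerance of the truncated-moment
#'   integration.
#' @param inner `"direct"` sparse factorization or `"pcg"`.
#' @param theta0 Starting solutions (default all zero).
#' @param keep_system Keep the converged coefficient matrix (needed for
#'   [pev()]).
#' @return List with `theta`, `rounds`, `metric_trace`, `converged`,
#'   `halvings`, `n_floored`, and (optionally) `C`, `rhs`.
#' @export
nr_solve <- function(ws, S, tol = 1e-12, max_rounds = 100L,
                     integration_tol = 1e-8, inner = c("direct", "pcg"),
                     theta0 = NULL, keep_system = TRUE) {
  inner <- match.arg(inner)
  theta <- theta0 %||% numeric(ws$n_eq)
  rq <- round_quantities(ws, theta, integration_tol)
  sys <- mme_from_round(ws, rq, S, theta)
  metric <- sys$metric
  trace <- metric
  theta_trace <- list(theta)
  rounds <- 0L
  halvings <- 0L
  floored <- rq$n_floored
  # PCG tolerance tightens geometrically so early rounds are cheap
  pcg_tol <- 1e-6
  while (metric >= tol) {
    if (rounds >= max_rounds) {
      err <- rlang::error_cnd(message = paste0(
        "Newton-Raphson did not converge in ", max_rounds, " rounds (metric ",
        format(metric), ")"), class = "thrlmm_no_convergence")
      err$metric_trace <- trace
      rlang::cnd_signal(err)
    }
    theta_new <- if (inner == "direct") {
      solve_mme(sys$C, sys$rhs, "direct")
    } else {
      as.vector(solve_mme(sys$C, sys$rhs, "pcg", tol = pcg_tol, x0 = theta))
    }
    pcg_tol <- max(pcg_tol * 1e-2, 1e-10)
    rq_new <- round_quantities(ws, theta_new, integration_tol)
    sys_new <- mme_from_round(ws, rq_new, S, theta_new)
    h <- 0L
    while (sys_new$metric > metric && h < 5L) {
      theta_new <- theta + 0.5 * (theta_new - theta)
      rq_new <- round_quantities(ws, theta_new, integration_tol)
      sys_new <- mme_from_round(ws, rq_new, S, theta_new)
      h <- h + 1L
    }
    halvings <- halvings + h
    theta <- theta_new
    sys <- sys_new
    metric <- sys$metric
    floored <- floored + rq_new$n_floored
    trace <- c(trace, metric)
    theta_trace <- c(theta_trace, list(theta))
    rounds <- rounds + 1L
  }
  out <- list(theta = theta, rounds = rounds, metric_trace = trace,
              theta_trace = theta_trace, converged = TRUE,
              halvings = halvings, n_floored = floored, method = "nr")
  if (keep_system) { out$C <- sys$C; out$rhs <- sys$rhs }
  out
}

#' Prediction error variances
#'
#' Diagonal entries of the inverse coefficient matrix at convergence for
#' the requested equations.
#'
#' @param C Converged sparse coefficient matrix (`W' Rtilde^-1 W + S`).
#' @param equations Integer equation indices.
#' @export
pev_equations <- function(C, equations) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE)
  vapply(equations, function(e) {
    b <- numeric(nrow(C)); b[e] <- 1
    as.vector(Matrix::solve(ch, b))[e]
  }, numeric(1))
}
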