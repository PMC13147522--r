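# Working mixed model equations.
#
# One Newton-Raphson round rewrites the gradient/Hessian of the joint log
# posterior as a linear mixed model with pseudo-observations: per record,
# the truncated-moment quantities Delta and Gamma define a working
# residual precision Rtilde^-1 (closed-form block inverse, never formed by
# inverting Rtilde) and a working response ytilde. The system
# (W' Rtilde^-1 W + S) theta = W' Rtilde^-1 ytilde is assembled sparse and
# solved directly (default) or by preconditioned conjugate gradients.

#' Closed-form working residual precision block
#'
#' `Rtilde^-1` for one record:
#' rows/cols ordered categorical then continuous,
#' `[[Gamma, -Gamma A], [-A' Gamma, A' Gamma A + R22^-1]]` with
#' `A = R12 R22^-1`. Reduces to the classical univariate form when there
#' is a single categorical trait.
#'
#' @param gamma Working curvature matrix `Gamma` (c x c, symmetric PSD).
#' @param A12 The weight matrix `R12 R22^-1` (c x m).
#' @param R22_inv Inverse of the continuous residual block (m x m).
#' @return Symmetric `(c + m) x (c + m)` matrix.
#' @export
rtilde_inverse <- function(gamma, A12, R22_inv) {
  gamma <- as.matrix(gamma)
  ev <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    warn("gamma has a negative eigenvalue; flooring to PSD")
    gamma <- psd_guard(gamma, floor = 0)
  }
  if (length(R22_inv) == 0L) return((gamma + t(gamma)) / 2)
  A12 <- as.matrix(A12)
  TR <- -gamma %*% A12
  BR <- t(A12) %*% gamma %*% A12 + R22_inv
  out <- rbind(cbind(gamma, TR), cbind(t(TR), BR))
  (out + t(out)) / 2
}

#' Pseudo-record for the working mixed model equations
#'
#' Builds, for one record, the working response
#' `ytilde = (Gamma^-1 Delta + mu, y2)`, the gradient contribution `z`,
#' and the working precision block, from the record's truncated-cell
#' quantities. Satisfies the identity `W theta + Rtilde z = ytilde`, i.e.
#' `ytilde - (eta_cat, y2) = Rtilde z + (mu - eta_cat, 0)` in the
#' conditional parametrization.
#'
#' @param delta,gamma Working residual vector/matrix of the record's cell.
#' @param mu Conditional liability mean of the record.
#' @param y2,eta_cont Observed continuous values and their linear
#'   predictors.
#' @param A12,R22_inv As in [rtilde_inverse()].
#' @return List with `ytilde`, `z`, `rtilde_inv`.
#' @export
pseudo_record <- function(delta, gamma, mu, y2, eta_cont, A12, R22_inv) {
  gamma <- as.matrix(gamma)
  yhat1 <- as.vector(solve(gamma, delta)) + mu
  if (length(y2)) {
    z2 <- as.vector(-crossprod(as.matrix(A12), delta) +
                      R22_inv %*% (y2 - eta_cont))
  } else {
    z2 <- numeric(0)
  }
  list(ytilde = c(yhat1, y2), z = c(delta, z2),
       rtilde_inv = rtilde_inverse(gamma, A12, R22_inv))
}

# ---- per-round record quantities (vectorized over patterns) -----------
# Returns the block-diagonal working precision B (over observed rows), the
# working response and gradient-contribution vectors, and bookkeeping.
round_quantities <- function(ws, theta, tol = 1e-8, prob_floor = 1e-12) {
  eta <- eta_matrix(ws, theta)
  ytilde <- numeric(ws$n_rows)
  zvec <- numeric(ws$n_rows)
  Bi <- integer(0); Bj <- integer(0); Bx <- numeric(0)
  n_floored <- 0L
  sum_log_prob <- 0
  for (p in ws$patterns) {
    n_i <- length(p$records)
    Tp <- p$n_obs
    rows <- p$row_mat
    template <- block_template(rows, Tp)
    cc <- length(p$cat)
    if (cc == 0L) {
      y2 <- ws$Y[p$records, p$obs, drop = FALSE]
      resid <- y2 - eta[p$records, p$obs, drop = FALSE]
      blk <- array(rep(as.vector(p$R_obs_inv), each = n_i), c(n_i, Tp, Tp))
      z2 <- resid %*% p$R_obs_inv
      ytilde[as.vector(rows)] <- as.vector(y2)
      zvec[as.vector(rows)] <- as.vector(z2)
    } else {
      mm <- length(p$cont)
      eta_cat <- eta[p$records, p$cat, drop = FALSE]
      if (mm) {
        y2 <- ws$Y[p$records, p$cont, drop = FALSE]
        eta_cont <- eta[p$records, p$cont, drop = FALSE]
        mu <- eta_cat + (y2 - eta_cont) %*% t(p$A12)
      } else {
        y2 <- matrix(0, n_i, 0); eta_cont <- y2
        mu <- eta_cat
      }
      bb <- cell_bounds(ws, p)
      mom <- pattern_moments(bb$lower, bb$upper, mu, p$Sigma, p$Sigma_inv,
                             tol, prob_floor)
      n_floored <- n_floored + mom$floored
      sum_log_prob <- sum_log_prob + sum(log(mom$prob))
      G <- mom$G                      # n_i x cc x cc
      Dl <- mom$Delta                 # n_i x cc
      yhat1 <- mom$yhat1_part + mu    # Gamma^-1 Delta + mu
      # working precision blocks
      blk <- array(0, c(n_i, Tp, Tp))
      blk[, seq_len(cc), seq_len(cc)] <- G
      if (mm) {
        A <- p$A12
        for (q in seq_len(cc)) for (r in seq_len(mm)) {
          v <- 0
          for (k in seq_len(cc)) v <- v - G[, q, k] * A[k, r]
          blk[, q, cc + r] <- v
          blk[, cc + r, q] <- v
        }
        for (q in seq_len(mm)) for (r in seq_len(mm)) {
          v <- p$R22_inv[q, r]
          for (k in seq_len(cc)) for (l in seq_len(cc)) {
            v <- v + A[k, q] * G[, k, l] * A[l, r]
          }
          blk[, cc + q, cc + r] <- v
        }
        z2 <- -Dl %*% A + (y2 - eta_cont) %*% p$R22_inv
      } else {
        z2 <- matrix(0, n_i, 0)
      }
      ytilde[as.vector(rows)] <- as.vector(cbind(yhat1, y2))
      zvec[as.vector(rows)] <- as.vector(cbind(Dl, z2))
    }
    Bi <- c(Bi, template$i); Bj <- c(Bj, template$j)
    Bx <- c(Bx, as.vector(blk))
  }
  B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx,
                            dims = c(ws$n_rows, ws$n_rows))
  list(B = B, ytilde = ytilde, z = zvec, n_floored = n_floored,
       sum_log_prob = sum_log_prob)
}

block_template <- function(row_mat, Tp) {
  list(i = as.vector(row_mat[, rep(seq_len(Tp), times = Tp), drop = FALSE]),
       j = as.vector(row_mat[, rep(seq_len(Tp), each = Tp), drop = FALSE]))
}

# Truncated-cell quantities for all records of one pattern.
# Returns G (n x c x c working curvature), Delta (n x c), yhat1_part
# (Gamma^-1 Delta), prob, floored count. Fast closed-form paths for c = 1
# and c = 2; the general path loops records through truncated_moments().
pattern_moments <- function(lower, upper, mu, Sigma, Sigma_inv,
                            tol = 1e-8, prob_floor = 1e-12) {
  n <- nrow(mu)
  cc <- ncol(mu)
  G <- array(0, c(n, cc, cc))
  Dl <- matrix(0, n, cc)
  yp <- matrix(0, n, cc)
  ltilde <- matrix(0, n, cc)
  if (cc == 1L) {
    um <- uni_trunc_moments(lower[, 1], upper[, 1], mu[, 1],
                            sqrt(Sigma[1, 1]), prob_floor)
    G[, 1, 1] <- um$gamma
    Dl[, 1] <- um$delta
    yp[, 1] <- um$delta / um$gamma
    ltilde[, 1] <- um$mean
    prob <- um$prob
    floored <- um$floored
  } else if (cc == 2L) {
    bm <- biv_trunc_moments(lower, upper, mu, Sigma, prob_floor)
    p11 <- Sigma_inv[1, 1]; p12 <- Sigma_inv[1, 2]; p22 <- Sigma_inv[2, 2]
    d1 <- bm$mean[, 1] - mu[, 1]; d2 <- bm$mean[, 2] - mu[, 2]
    Dl[, 1] <- p11 * d1 + p12 * d2
    Dl[, 2] <- p12 * d1 + p22 * d2
    # Gamma = Sinv - Sinv V Sinv, elementwise over records
    sv11 <- p11 * bm$v11 + p12 * bm$v12
    sv12 <- p11 * bm$v12 + p12 * bm$v22
    sv21 <- p12 * bm$v11 + p22 * bm$v12
    sv22 <- p12 * bm$v12 + p22 * bm$v22
    g11 <- p11 - (sv11 * p11 + sv12 * p12)
    g12 <- p12 - (sv11 * p12 + sv12 * p22)
    g22 <- p22 - (sv21 * p12 + sv22 * p22)
    G[, 1, 1] <- g11; G[, 1, 2] <- g12; G[, 2, 1] <- g12; G[, 2, 2] <- g22
    det <- pmax(g11 * g22 - g12^2, 1e-14)
    yp[, 1] <- (g22 * Dl[, 1] - g12 * Dl[, 2]) / det
    yp[, 2] <- (-g12 * Dl[, 1] + g11 * Dl[, 2]) / det
    ltilde <- bm$mean
    prob <- bm$prob
    floored <- bm$floored
  } else {
    prob <- numeric(n)
    floored <- 0L
    for (i in seq_len(n)) {
      tm <- truncated_moments(lower[i, ], upper[i, ], mu[i, ], Sigma,
                              tol, prob_floor)
      G[i, , ] <- tm$gamma
      Dl[i, ] <- tm$delta
      yp[i, ] <- solve(tm$gamma, tm$delta)
      ltilde[i, ] <- tm$mean
      prob[i] <- tm$prob
      floored <- floored + isTRUE(tm$floored)
    }
  }
  list(G = G, Delta = Dl, yhat1_part = yp, ltilde = ltilde,
       prob = prob, floored = floored)
}

#' Assemble the working mixed model equations
#'
#' Computes the sparse coefficient matrix `C = W' Rtilde^-1 W + S`, the
#' right-hand side `W' Rtilde^-1 ytilde`, and the gradient
#' `W' z - S theta` (which equals `rhs - C theta`) at the supplied
#' solutions.
#'
#' @param ws Workspace from [validate_model_data()].
#' @param theta Current solution vector (length `ws$n_eq`).
#' @param S Precision structure from [build_S()].
#' @param tol Integration tolerance passed to the truncated moments.
#' @return List with `C`, `rhs`, `gradient`, `metric`
#'   (`||rhs - C theta|| / ||rhs||`, the convergence measure), plus
#'   safeguard bookkeeping.
#' @export
assemble_mme <- function(ws, theta, S, tol = 1e-8) {
  rq <- round_quantities(ws, theta, tol)
  sys <- mme_from_round(ws, rq, S, theta)
  sys$gradient <- as.vector(Matrix::crossprod(ws$W, rq$z)) -
    as.vector(S %*% theta)
  sys$n_floored <- rq$n_floored
  sys
}

mme_from_round <- function(ws, rq, S, theta) {
  BW <- rq$B %*% ws$W
  C <- Matrix::forceSymmetric(Matrix::crossprod(ws$W, BW) + S)
  rhs <- as.vector(Matrix::crossprod(ws$W, rq$B %*% rq$ytilde))
  r <- rhs - as.vector(C %*% theta)
  list(C = C, rhs = rhs,
       metric = sqrt(sum(r^2)) / sqrt(sum(rhs^2)))
}

#' Solve a sparse symmetric mixed-model system
#'
#' @param C Sparse symmetric positive (semi)definite coefficient matrix,
#'   or a function of one vector argument for the matrix-free PCG path.
#' @param rhs Right-hand side vector.
#' @param method `"direct"` (sparse Cholesky, default) or `"pcg"`
#'   (Jacobi-preconditioned conjugate gradients).
#' @param tol Relative-residual tolerance for PCG.
#' @param maxit Maximum PCG iterations.
#' @param diag_C Diagonal of `C` (required for the matrix-free PCG path).
#' @param x0 PCG starting vector.
#' @return Solution vector; PCG attaches the residual history as
#'   attribute `"residuals"`.
#' @export
solve_mme <- function(C, rhs, method = c("direct", "pcg"), tol = 1e-10,
                      maxit = 5000L, diag_C = NULL, x0 = NULL) {
  method <- match.arg(method)
  if (method == "direct") {
    if (is.function(C)) abort("direct solve needs an explicit matrix")
    return(as.vector(Matrix::solve(C, rhs)))
  }
  mult <- if (is.function(C)) C else function(v) as.vector(C %*% v)
  d <- if (!is.null(diag_C)) diag_C else Matrix::diag(C)
  d[d <= 0] <- 1
  x <- if (is.null(x0)) numeric(length(rhs)) else x0
  r <- rhs - mult(x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nrhs <- sqrt(sum(rhs^2))
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- mult(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nrhs
    hist <- c(hist, res)
    if (res < tol) {
      attr(x, "residuals") <- hist
      return(x)
    }
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  abort(paste0("PCG did not reach tol ", format(tol), " in ", maxit,
               " iterations (last residual ", format(hist[length(hist)]), ")"))
}

#' Joint log posterior of the threshold-linear model
#'
#' Direct evaluation (up to an additive constant): the sum of log cell
#' probabilities via [mvn_probability()], the Gaussian log likelihood of
#' the continuous records, and the random-effect penalty
#' `-theta' S theta / 2`. Used as an independent check of the gradient and
#' Hessian assembly and of solver monotonicity; not on the solver hot
#' path.
#'
#' @inheritParams assemble_mme
#' @export
log_posterior <- function(ws, theta, S, tol = 1e-8) {
  eta <- eta_matrix(ws, theta)
  lp <- -0.5 * sum(theta * as.vector(S %*% theta))
  for (p in ws$patterns) {
    n_i <- length(p$records)
    cc <- length(p$cat); mm <- length(p$cont)
    if (mm) {
      y2 <- ws$Y[p$records, p$cont, drop = FALSE]
      resid <- y2 - eta[p$records, p$cont, drop = FALSE]
      R22 <- if (cc) solve(p$R22_inv) else p$R_obs
      lp <- lp - 0.5 * sum(resid * (resid %*% solve(R22))) -
        n_i / 2 * determinant(as.matrix(R22))$modulus[1] -
        n_i * mm / 2 * log(2 * pi)
    }
    if (cc) {
      eta_cat <- eta[p$records, p$cat, drop = FALSE]
      if (mm) {
        mu <- eta_cat + (y2 - eta[p$records, p$cont, drop = FALSE]) %*% t(p$A12)
      } else mu <- eta_cat
      bb <- cell_bounds(ws, p)
      for (i in seq_len(n_i)) {
        pr <- mvn_probability(bb$lower[i, ], bb$upper[i, ], mu[i, ],
                              p$Sigma, tol)
        lp <- lp + log(max(pr, 1e-300))
      }
    }
  }
  lp
}
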