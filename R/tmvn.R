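# Truncated multivariate normal numerics.
#
# The liability of each ordinal trait is a latent Gaussian; an observed
# category pins the liability vector inside a hyper-rectangle. Both solvers
# need moments of that truncated distribution: the mean feeds the EM E-step
# and the Newton-Raphson pseudo-data, the covariance feeds the working
# residual precision. Means and covariances follow the classical moment
# recursions (Tallis; Manjunath & Wilhelm), which reduce every moment to
# rectangle probabilities of the normal distribution of dimension c, c-1
# and c-2. Rectangle probabilities use Genz's recursive quasi-Monte-Carlo
# integration (mvtnorm) under a fixed internal seed so solver runs are
# reproducible.

#' Multivariate normal rectangle probability
#'
#' Computes `P(lower < X <= upper)` for `X ~ N(mean, sigma)`. Dimension 1
#' uses the closed form, dimension 2 a deterministic Gauss-Legendre
#' quadrature of Drezner-Wesolowsky type, higher dimensions Genz's
#' recursive integration (via \pkg{mvtnorm}) with a fixed internal seed so
#' repeated calls are identical.
#'
#' @param lower,upper Numeric vectors of equal length; `-Inf`/`Inf` encode
#'   half-infinite sides and are propagated exactly.
#' @param mean Mean vector (recycled scalar allowed).
#' @param sigma Symmetric positive definite covariance matrix.
#' @param tol Absolute error target for the numerical integration.
#' @return A single probability in `[0, 1]`.
#' @examples
#' mvn_probability(c(0, 0), c(Inf, Inf), sigma = matrix(c(1, .5, .5, 1), 2))
#' @export
mvn_probability <- function(lower, upper, mean = 0, sigma, tol = 1e-8) {
  d <- length(lower)
  stopifnot(length(upper) == d, tol > 0)
  mean <- rep_len(mean, d)
  sigma <- as.matrix(sigma)
  check_spd(sigma, "sigma")
  if (any(lower >= upper)) {
    abort("empty truncation region: `lower` must be elementwise below `upper`")
  }
  sdv <- sqrt(diag(sigma))
  lo <- (lower - mean) / sdv
  hi <- (upper - mean) / sdv
  if (d == 1L) {
    return(max(0, pnorm(hi) - pnorm(lo)))
  }
  cr <- stats::cov2cor(sigma)
  if (d == 2L) {
    rho <- cr[1, 2]
    p <- pbvnorm(hi[1], hi[2], rho) - pbvnorm(lo[1], hi[2], rho) -
      pbvnorm(hi[1], lo[2], rho) + pbvnorm(lo[1], lo[2], rho)
    return(min(1, max(0, p)))
  }
  maxpts <- 25000L
  repeat {
    p <- with_fixed_seed(
      mvtnorm::pmvnorm(lower = lo, upper = hi, corr = cr,
                       algorithm = mvtnorm::GenzBretz(abseps = tol,
                                                      maxpts = maxpts))
    )
    err <- attr(p, "error") %||% 0
    if (err <= max(tol, 1e-10) || maxpts >= 2e6) break
    maxpts <- maxpts * 8L
  }
  min(1, max(0, as.numeric(p)))
}

# Vectorized standard bivariate normal CDF P(X <= h, Y <= k), correlation
# rho (scalar). Drezner-Wesolowsky integral over the correlation with
# 48-node Gauss-Legendre; |rho| is capped below 1 by the caller's model
# (residual correlations), and accuracy ~1e-14 for |rho| <= 0.95.
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- numeric(n)
  # infinite arguments collapse to univariate forms
  hi_inf <- is.infinite(h); ki_inf <- is.infinite(k)
  both <- !hi_inf & !ki_inf
  out[hi_inf & h > 0] <- pnorm(k[hi_inf & h > 0])
  out[ki_inf & k > 0 & !hi_inf] <- pnorm(h[ki_inf & k > 0 & !hi_inf])
  # (-Inf in either slot leaves 0)
  if (any(both)) {
    hb <- h[both]; kb <- k[both]
    if (abs(rho) < 1e-14) {
      out[both] <- pnorm(hb) * pnorm(kb)
    } else if (abs(rho) <= 0.95) {
      gl <- gauss_legendre_48()
      r <- rho * (gl$x + 1) / 2          # nodes on (0, rho)
      wr <- rho / 2 * gl$w
      acc <- numeric(length(hb))
      for (j in seq_along(r)) {
        rj <- r[j]
        acc <- acc + wr[j] / sqrt(1 - rj^2) *
          exp(-(hb^2 - 2 * rj * hb * kb + kb^2) / (2 * (1 - rj^2)))
      }
      out[both] <- pnorm(hb) * pnorm(kb) + acc / (2 * pi)
    } else {
      # rare extreme-correlation fallback: Genz integration per pair
      cr <- matrix(c(1, rho, rho, 1), 2)
      out[both] <- vapply(seq_along(hb), function(j) {
        with_fixed_seed(as.numeric(
          mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(hb[j], kb[j]),
                           corr = cr,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-12))
        ))
      }, numeric(1))
    }
  }
  pmin(1, pmax(0, out))
}

gauss_legendre_48 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # Golub-Welsch from the Jacobi matrix of Legendre polynomials
      n <- 48L
      i <- seq_len(n - 1)
      b <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- b
      J[cbind(i + 1, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      cache <<- list(x = e$values, w = 2 * e$vectors[1, ]^2)
    }
    cache
  }
})

check_spd <- function(m, label = "matrix", tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort(paste0("`", label, "` must be symmetric"))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    abort(paste0("`", label, "` must be positive definite (min eigenvalue ",
                 format(min(ev)), ")"))
  }
  invisible(TRUE)
}

# Unnormalized one-dimensional marginal F_k(x) of the truncation integrand:
# density of coordinate k at x times the probability that the remaining
# coordinates fall in their (conditional) box. Centered parametrization.
marginal_F <- function(x, k, lower, upper, sigma, tol = 1e-8) {
  if (!is.finite(x)) return(0)
  d <- nrow(sigma)
  dk <- dnorm(x, 0, sqrt(sigma[k, k]))
  if (d == 1L) return(dk)
  cm <- sigma[-k, k, drop = FALSE] / sigma[k, k]
  cmean <- as.vector(cm * x)
  ccov <- sigma[-k, -k, drop = FALSE] -
    tcrossprod(sigma[-k, k, drop = FALSE]) / sigma[k, k]
  dk * mvn_prob_centered(lower[-k] - cmean, upper[-k] - cmean, ccov, tol)
}

# Unnormalized two-dimensional marginal F_{kq}(x, y).
marginal_F2 <- function(x, y, k, q, lower, upper, sigma, tol = 1e-8) {
  if (!is.finite(x) || !is.finite(y)) return(0)
  d <- nrow(sigma)
  S2 <- sigma[c(k, q), c(k, q)]
  dens <- mvtnorm::dmvnorm(c(x, y), sigma = S2)
  if (d == 2L) return(dens)
  rest <- setdiff(seq_len(d), c(k, q))
  B <- sigma[rest, c(k, q), drop = FALSE] %*% solve(S2)
  cmean <- as.vector(B %*% c(x, y))
  ccov <- sigma[rest, rest, drop = FALSE] -
    B %*% sigma[c(k, q), rest, drop = FALSE]
  dens * mvn_prob_centered(lower[rest] - cmean, upper[rest] - cmean, ccov, tol)
}

# rectangle probability for a centered normal; tolerates dimension 0
mvn_prob_centered <- function(lower, upper, sigma, tol = 1e-8) {
  if (length(lower) == 0L) return(1)
  mvn_probability(lower, upper, mean = 0, sigma = sigma, tol = tol)
}

#' Moments of a truncated multivariate normal distribution
#'
#' Mean and covariance of `X ~ N(mean, sigma)` restricted to the rectangle
#' `lower < X <= upper`, together with the rectangle probability, by the
#' Tallis / Manjunath-Wilhelm moment recursions. These are the quantities
#' the threshold-model solvers consume per record.
#'
#' @inheritParams mvn_probability
#' @param prob_floor Rectangle probabilities below this floor are clamped
#'   before division (boundary cells); a `floored` attribute reports it.
#' @return List with `prob`, `mean` (length c), `cov` (c x c).
#' @export
tmvn_moments <- function(lower, upper, mean = 0, sigma, tol = 1e-8,
                         prob_floor = 1e-12) {
  d <- length(lower)
  mean <- rep_len(mean, d)
  sigma <- as.matrix(sigma)
  a <- lower - mean
  b <- upper - mean
  if (d == 1L) {
    um <- uni_trunc_moments(a, b, 0, sqrt(sigma[1, 1]), prob_floor)
    return(list(prob = um$prob, mean = mean + um$mean,
                cov = matrix(um$var, 1, 1), floored = um$floored > 0))
  }
  if (d == 2L) {
    bm <- biv_trunc_moments(matrix(a, 1), matrix(b, 1), matrix(0, 1, 2),
                            sigma, prob_floor)
    return(list(prob = bm$prob, mean = mean + c(bm$mean),
                cov = matrix(c(bm$v11, bm$v12, bm$v12, bm$v22), 2, 2),
                floored = bm$floored > 0))
  }
  alpha <- mvn_prob_centered(a, b, sigma, tol)
  floored <- alpha < prob_floor
  alpha <- max(alpha, prob_floor)
  Fa <- vapply(seq_len(d), function(k) marginal_F(a[k], k, a, b, sigma, tol),
               numeric(1))
  Fb <- vapply(seq_len(d), function(k) marginal_F(b[k], k, a, b, sigma, tol),
               numeric(1))
  m1 <- as.vector(sigma %*% (Fa - Fb)) / alpha
  # second raw moments E[X_q X_r] (centered at 0)
  aF <- ifelse(is.finite(a), a, 0) * Fa
  bF <- ifelse(is.finite(b), b, 0) * Fb
  # bivariate marginal difference terms, one matrix per ordered pair (k, l)
  D <- matrix(0, d, d)
  for (k in seq_len(d)) {
    for (l in seq_len(d)) {
      if (l == k) next
      D[k, l] <- marginal_F2(a[k], a[l], k, l, a, b, sigma, tol) -
        marginal_F2(a[k], b[l], k, l, a, b, sigma, tol) -
        marginal_F2(b[k], a[l], k, l, a, b, sigma, tol) +
        marginal_F2(b[k], b[l], k, l, a, b, sigma, tol)
    }
  }
  E2 <- matrix(0, d, d)
  for (q in seq_len(d)) {
    for (r in seq_len(d)) {
      val <- sigma[q, r]
      for (k in seq_len(d)) {
        val <- val + sigma[q, k] * sigma[r, k] / sigma[k, k] *
          (aF[k] - bF[k]) / alpha
        for (l in seq_len(d)) {
          if (l == k) next
          val <- val + sigma[q, k] *
            (sigma[r, l] - sigma[k, l] * sigma[r, k] / sigma[k, k]) *
            D[k, l] / alpha
        }
      }
      E2[q, r] <- val
    }
  }
  V <- (E2 + t(E2)) / 2 - tcrossprod(m1)
  V <- psd_guard(V)
  list(prob = alpha, mean = mean + m1, cov = V, floored = floored)
}

# symmetrize + eigenvalue floor; truncated covariances computed from
# near-degenerate cells can come out numerically indefinite
psd_guard <- function(V, floor = 1e-12) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < floor) {
    V <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    V <- (V + t(V)) / 2
  }
  V
}

#' @rdname tmvn_moments
#' @param region Optional list with elements `lower` and `upper`, an
#'   alternative to passing the bounds separately.
#' @export
tmvn_mean <- function(lower, upper, mean = 0, sigma, tol = 1e-8,
                      region = NULL) {
  if (!is.null(region)) { lower <- region$lower; upper <- region$upper }
  tmvn_moments(lower, upper, mean, sigma, tol)$mean
}

#' @rdname tmvn_moments
#' @export
tmvn_cov <- function(lower, upper, mean = 0, sigma, tol = 1e-8,
                     region = NULL) {
  if (!is.null(region)) { lower <- region$lower; upper <- region$upper }
  tmvn_moments(lower, upper, mean, sigma, tol)$cov
}

#' Working residual quantities of a truncated cell
#'
#' Bundles the truncated moments with the working-residual vectors the
#' Newton-Raphson solver needs: `delta = sigma^{-1} (E_T[l] - mean)` and
#' `gamma = sigma^{-1} - sigma^{-1} Var_T(l) sigma^{-1}`, the multivariate
#' analogues of the classical univariate quantities.
#'
#' @inheritParams tmvn_moments
#' @return List with `prob`, `mean`, `cov`, `delta`, `gamma`.
#' @export
truncated_moments <- function(lower, upper, mean = 0, sigma, tol = 1e-8,
                              prob_floor = 1e-12) {
  tm <- tmvn_moments(lower, upper, mean, sigma, tol, prob_floor)
  sigma <- as.matrix(sigma)
  Sinv <- solve(sigma)
  mean <- rep_len(mean, length(lower))
  tm$delta <- as.vector(Sinv %*% (tm$mean - mean))
  G <- Sinv - Sinv %*% tm$cov %*% Sinv
  tm$gamma <- (G + t(G)) / 2
  tm
}

# ---- vectorized univariate cell moments (closed forms) ----------------
# lower/upper/mu/sd vectors; returns prob, mean, var, delta, gamma, ltilde.
uni_trunc_moments <- function(lower, upper, mu, sd, prob_floor = 1e-12) {
  eta_hi <- (upper - mu) / sd
  eta_lo <- (lower - mu) / sd
  P <- pnorm(eta_hi) - pnorm(eta_lo)
  floored <- sum(P < prob_floor)
  P <- pmax(P, prob_floor)
  phi_hi <- ifelse(is.finite(eta_hi), dnorm(eta_hi), 0)
  phi_lo <- ifelse(is.finite(eta_lo), dnorm(eta_lo), 0)
  ephi_hi <- ifelse(is.finite(eta_hi), eta_hi * phi_hi, 0)
  ephi_lo <- ifelse(is.finite(eta_lo), eta_lo * phi_lo, 0)
  lam <- (phi_hi - phi_lo) / P              # E[Z] = -lam for standardized Z
  mean <- mu - sd * lam
  vz <- 1 - (ephi_hi - ephi_lo) / P - lam^2 # Var of standardized truncation
  v <- pmax(vz, 1e-12) * sd^2
  delta <- (mean - mu) / sd^2
  gamma <- (1 - vz) / sd^2
  list(prob = P, mean = mean, var = v, delta = delta, gamma = gamma,
       ltilde = mean, floored = floored)
}

#' Univariate threshold-cell moments
#'
#' Closed-form cell probability, working residual scalars and conditional
#' liability expectation for a single ordinal trait: the classical
#' standardized thresholds `eta_k = (t_k - mu)/sigma`, cell probability
#' `P_k`, gradient weight `delta`, curvature weight `gamma`, and the
#' truncated expectation `ltilde` used as the EM pseudo-phenotype. Serves
#' as the c = 1 fast path and as an oracle for the numeric multivariate
#' path.
#'
#' @param y_category Observed category (integer in `1..K`).
#' @param thresholds Increasing vector of the `K - 1` finite thresholds.
#' @param mean,var Conditional mean and variance of the liability.
#' @param prob_floor Probability floor applied before division.
#' @return List with `eta_lower`, `eta_upper`, `prob`, `delta`, `gamma`,
#'   `ltilde`, `mean`, `var`.
#' @export
univariate_moments <- function(y_category, thresholds, mean, var,
                               prob_floor = 1e-12) {
  stopifnot(var > 0)
  K <- length(thresholds) + 1L
  if (y_category < 1L || y_category > K) {
    abort(sprintf("category %d outside 1..%d", y_category, K))
  }
  tt <- c(-Inf, thresholds, Inf)
  lo <- tt[y_category]
  hi <- tt[y_category + 1L]
  sd <- sqrt(var)
  um <- uni_trunc_moments(lo, hi, mean, sd, prob_floor)
  list(eta_lower = (lo - mean) / sd, eta_upper = (hi - mean) / sd,
       prob = um$prob, delta = um$delta, gamma = um$gamma,
       ltilde = um$ltilde, mean = um$mean, var = um$var)
}

# ---- vectorized bivariate cell moments --------------------------------
# lower/upper/mu: n x 2 matrices (already centered if mu = 0); Sigma 2 x 2
# shared across rows (records in one missingness pattern share it).
# Closed forms: the one- and two-dimensional marginal integrals of the
# moment recursion collapse to phi * Phi products and bivariate densities.
biv_trunc_moments <- function(lower, upper, mu, Sigma, prob_floor = 1e-12) {
  a1 <- lower[, 1] - mu[, 1]; a2 <- lower[, 2] - mu[, 2]
  b1 <- upper[, 1] - mu[, 1]; b2 <- upper[, 2] - mu[, 2]
  s1 <- sqrt(Sigma[1, 1]); s2 <- sqrt(Sigma[2, 2])
  s12 <- Sigma[1, 2]
  rho <- s12 / (s1 * s2)
  csd2 <- s2 * sqrt(max(1 - rho^2, 1e-14))  # sd of coord 2 | coord 1
  csd1 <- s1 * sqrt(max(1 - rho^2, 1e-14))
  # rectangle probability
  P <- pbvnorm(b1 / s1, b2 / s2, rho) - pbvnorm(a1 / s1, b2 / s2, rho) -
    pbvnorm(b1 / s1, a2 / s2, rho) + pbvnorm(a1 / s1, a2 / s2, rho)
  floored <- sum(P < prob_floor)
  P <- pmax(P, prob_floor)
  # unnormalized marginals F_k(x) = phi(x) * P(other coord in box | x)
  F1 <- function(x) {
    out <- numeric(length(x)); fin <- is.finite(x)
    if (any(fin)) {
      xm <- x[fin]
      cm <- (s12 / Sigma[1, 1]) * xm
      out[fin] <- dnorm(xm, 0, s1) *
        (pnorm((b2[fin] - cm) / csd2) - pnorm((a2[fin] - cm) / csd2))
    }
    out
  }
  F2 <- function(x) {
    out <- numeric(length(x)); fin <- is.finite(x)
    if (any(fin)) {
      xm <- x[fin]
      cm <- (s12 / Sigma[2, 2]) * xm
      out[fin] <- dnorm(xm, 0, s2) *
        (pnorm((b1[fin] - cm) / csd1) - pnorm((a1[fin] - cm) / csd1))
    }
    out
  }
  Fa1 <- F1(a1); Fb1 <- F1(b1); Fa2 <- F2(a2); Fb2 <- F2(b2)
  d1 <- (Fa1 - Fb1); d2 <- (Fa2 - Fb2)
  m1 <- (Sigma[1, 1] * d1 + Sigma[1, 2] * d2) / P
  m2 <- (Sigma[2, 1] * d1 + Sigma[2, 2] * d2) / P
  # bivariate density differences (corner terms)
  dens2 <- function(x, y) {
    out <- numeric(length(x)); fin <- is.finite(x) & is.finite(y)
    if (any(fin)) {
      xf <- x[fin] / s1; yf <- y[fin] / s2
      q <- (xf^2 - 2 * rho * xf * yf + yf^2) / (1 - rho^2)
      out[fin] <- exp(-q / 2) / (2 * pi * s1 * s2 * sqrt(1 - rho^2))
    }
    out
  }
  D <- dens2(a1, a2) - dens2(a1, b2) - dens2(b1, a2) + dens2(b1, b2)
  aF1 <- ifelse(is.finite(a1), a1, 0) * Fa1
  bF1 <- ifelse(is.finite(b1), b1, 0) * Fb1
  aF2 <- ifelse(is.finite(a2), a2, 0) * Fa2
  bF2 <- ifelse(is.finite(b2), b2, 0) * Fb2
  t1 <- (aF1 - bF1) / P                      # coordinate-1 edge terms
  t2 <- (aF2 - bF2) / P
  e2 <- function(q, r) {
    Sigma[q, r] +
      Sigma[q, 1] * Sigma[r, 1] / Sigma[1, 1] * t1 +
      Sigma[q, 2] * Sigma[r, 2] / Sigma[2, 2] * t2 +
      (Sigma[q, 1] * (Sigma[r, 2] - Sigma[1, 2] * Sigma[r, 1] / Sigma[1, 1]) +
       Sigma[q, 2] * (Sigma[r, 1] - Sigma[2, 1] * Sigma[r, 2] / Sigma[2, 2])) *
        D / P
  }
  v11 <- pmax(e2(1, 1) - m1^2, 1e-12)
  v22 <- pmax(e2(2, 2) - m2^2, 1e-12)
  v12 <- (e2(1, 2) + e2(2, 1)) / 2 - m1 * m2
  # keep each 2x2 block positive definite
  lim <- sqrt(v11 * v22) * (1 - 1e-10)
  v12 <- pmin(pmax(v12, -lim), lim)
  list(prob = P, mean = cbind(mu[, 1] + m1, mu[, 2] + m2),
       v11 = v11, v22 = v22, v12 = v12, floored = floored)
}

#' Monte-Carlo oracle for truncated normal moments
#'
#' Rejection-sampling estimates of the rectangle probability, mean and
#' covariance of a truncated multivariate normal, with Monte-Carlo
#' standard errors. Intended as an independent check of the analytic
#' moment recursions, not for production use.
#'
#' @inheritParams mvn_probability
#' @param n_draws Number of proposal draws (at least 1e4).
#' @param seed RNG seed for reproducibility.
#' @return List with `prob`, `mean`, `cov`, `se_prob`, `se_mean`, `se_cov`
#'   and the number of accepted draws `n_accept`.
#' @export
tmvn_mc_oracle <- function(lower, upper, mean = 0, sigma, n_draws = 1e6,
                           seed = 1L) {
  d <- length(lower)
  stopifnot(n_draws >= 1e4)
  mean <- rep_len(mean, d)
  sigma <- as.matrix(sigma)
  L <- chol(sigma)
  acc_n <- 0; acc_sum <- numeric(d); acc_ss <- matrix(0, d, d)
  acc_sum4 <- NULL
  kept <- NULL
  set.seed(seed)
  chunk <- 2e5
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    X <- matrix(rnorm(m * d), m, d) %*% L
    X <- sweep(X, 2, mean, "+")
    ok <- rep(TRUE, m)
    for (j in seq_len(d)) ok <- ok & X[, j] > lower[j] & X[, j] <= upper[j]
    if (any(ok)) kept <- rbind(kept, X[ok, , drop = FALSE])
    done <- done + m
  }
  n_acc <- NROW(kept)
  p <- n_acc / n_draws
  if (p < 1e-4) {
    abort("acceptance rate below 1e-4; increase n_draws or shrink the region")
  }
  mu_hat <- colMeans(kept)
  V_hat <- stats::cov(kept)
  se_mean <- sqrt(diag(V_hat) / n_acc)
  # SE of covariance entries from the empirical 4th moments
  Z <- sweep(kept, 2, mu_hat)
  se_cov <- matrix(0, d, d)
  for (q in seq_len(d)) for (r in q:d) {
    w <- Z[, q] * Z[, r]
    se_cov[q, r] <- se_cov[r, q] <- sd(w) / sqrt(n_acc)
  }
  list(prob = p, mean = mu_hat, cov = V_hat,
       se_prob = sqrt(p * (1 - p) / n_draws),
       se_mean = se_mean, se_cov = se_cov, n_accept = n_acc)
}
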