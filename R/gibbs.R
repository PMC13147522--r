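# Single-site Gibbs sampler benchmark.
#
# With variance components and thresholds known, the full conditionals
# are standard: each liability given everything else is a univariate
# truncated normal inside its category's threshold interval, and each
# location equation given the liabilities is a scalar normal from the
# ordinary (full-R) mixed model equations. Posterior means of the kept
# samples are the benchmark EBVs. The sampler is deliberately single-site
# (the scheme MCMC samplers for these models classically use); it is
# defined by its stationary distribution, and its slow mixing relative to
# the MAP solvers is part of what the package demonstrates.

# Per-pattern full-conditional ingredients for the liability updates:
# each liability given the other observed traits of its record is normal
# with regression weights R[j,-j] R[-j,-j]^-1 and the matching Schur
# variance; cell bounds come from the observed categories.
gibbs_liability_conditionals <- function(ws) {
  lapply(ws$patterns, function(p) {
    cc <- length(p$cat)
    if (cc) {
      bb <- cell_bounds(ws, p)
      p$lower <- bb$lower; p$upper <- bb$upper
      p$cond <- lapply(seq_len(cc), function(j) {
        others <- setdiff(seq_len(p$n_obs), j)
        if (length(others)) {
          Rjo <- p$R_obs[j, others, drop = FALSE]
          w <- Rjo %*% solve(p$R_obs[others, others, drop = FALSE])
          cvar <- p$R_obs[j, j] - sum(w * Rjo)
        } else {
          w <- matrix(0, 1, 0); cvar <- p$R_obs[j, j]
        }
        list(others = others, w = as.vector(w), csd = sqrt(cvar))
      })
    }
    p
  })
}

# One sweep over all liabilities (trait within record), drawing each from
# its truncated-normal full conditional by inverse-CDF sampling.
sample_liabilities <- function(pats, V, eta) {
  for (p in pats) {
    cc <- length(p$cat)
    if (cc == 0L) next
    recs <- p$records
    for (j in seq_len(cc)) {
      cnd <- p$cond[[j]]
      tj <- p$cat[j]
      m <- eta[recs, tj]
      if (length(cnd$others)) {
        ot <- p$obs[cnd$others]
        dev <- V[recs, ot, drop = FALSE] - eta[recs, ot, drop = FALSE]
        m <- m + as.vector(dev %*% cnd$w)
      }
      V[recs, tj] <- truncnorm::rtruncnorm(
        length(recs), a = p$lower[, j], b = p$upper[, j],
        mean = m, sd = cnd$csd)
    }
  }
  V
}

#' Gibbs sampler posterior means for the threshold-linear model
#'
#' @inheritParams nr_solve
#' @param n_samples Total sweeps (kept samples = `n_samples - burn_in`).
#' @param burn_in Sweeps discarded before accumulating.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed RNG seed; chains with the same seed are identical.
#' @param n_batches Number of batches for Monte-Carlo standard errors.
#' @return List with `theta` (posterior means), `theta_se` (batch-mean
#'   MC standard errors), `n_kept`, `method = "gibbs"`.
#' @export
gibbs_solve <- function(ws, S, n_samples = 10000L, burn_in = 1000L,
                        thin = 1L, seed = 1L, n_batches = 20L) {
  stopifnot(n_samples > burn_in)
  set.seed(seed)
  sys <- em_system(ws, S)
  Cg <- methods::as(methods::as(sys$C, "generalMatrix"), "CsparseMatrix")
  Cp <- Cg@p; Cix <- Cg@i; Cx <- Cg@x
  pats <- gibbs_liability_conditionals(ws)
  # working values per record x observed trait; liabilities start from a
  # draw of the prior cell-truncated marginal
  V <- ws$Y
  for (p in pats) {
    for (j in seq_along(p$cat)) {
      tj <- p$cat[j]
      V[p$records, tj] <- truncnorm::rtruncnorm(
        length(p$records), a = p$lower[, j], b = p$upper[, j],
        mean = 0, sd = sqrt(ws$model$R[tj, tj]))
    }
  }
  theta <- numeric(ws$n_eq)
  ydot <- numeric(ws$n_rows)
  keep <- 0L
  acc <- numeric(ws$n_eq)
  n_keep_total <- (n_samples - burn_in) %/% thin
  batch_of <- pmin(ceiling(seq_len(n_keep_total) / (n_keep_total / n_batches)),
                   n_batches)
  batch_acc <- matrix(0, ws$n_eq, n_batches)
  for (s in seq_len(n_samples)) {
    eta <- eta_matrix(ws, theta)
    V <- sample_liabilities(pats, V, eta)
    for (p in pats) {
      ydot[as.vector(p$row_mat)] <-
        as.vector(V[p$records, p$obs, drop = FALSE])
    }
    rhs <- as.vector(sys$WtB %*% ydot)
    theta <- gibbs_location_sweep(Cp, Cix, Cx, rhs, theta)
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      keep <- keep + 1L
      acc <- acc + theta
      batch_acc[, batch_of[keep]] <- batch_acc[, batch_of[keep]] + theta
    }
  }
  post_mean <- acc / keep
  per_batch <- table(factor(batch_of, levels = seq_len(n_batches)))
  bm <- sweep(batch_acc, 2, as.numeric(per_batch), "/")
  se <- sqrt(apply(bm, 1, var) / n_batches)
  list(theta = post_mean, theta_se = se, n_kept = keep, method = "gibbs",
       n_samples = n_samples, burn_in = burn_in, thin = thin, seed = seed)
}
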