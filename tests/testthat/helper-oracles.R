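# Shared fixtures and independent oracles. Everything here is built from
# first principles (dense base-R algebra, direct integration, tabular
# recursions) so the package's sparse/recursive paths are checked against
# genuinely different computations.

# flexible scenario parameters for small test models
make_params <- function(traits, va, ve, thresholds = list(),
                        corg = 0.3, core = 0.2) {
  TT <- length(traits)
  Cg <- matrix(corg, TT, TT); diag(Cg) <- 1
  Ce <- matrix(core, TT, TT); diag(Ce) <- 1
  G0 <- diag(sqrt(va), TT) %*% Cg %*% diag(sqrt(va), TT)
  R <- diag(sqrt(ve), TT) %*% Ce %*% diag(sqrt(ve), TT)
  dimnames(G0) <- dimnames(R) <- list(traits, traits)
  sex_effects <- rbind(F = seq(0, 0.3, length.out = TT),
                       M = seq(0.2, 0.5, length.out = TT))
  colnames(sex_effects) <- traits
  list(traits = traits, G0 = G0, R = R, thresholds = thresholds,
       sex_effects = sex_effects,
       generation_trend = rep(0.05, TT))
}

# small simulated bundle: pedigree + phenotypes + model + workspace + S
toy_bundle <- function(n_animals = 30, n_generations = 2, seed = 99,
                       params = make_params(c("y1", "y2"), va = c(0.3, 0.4),
                                            ve = c(1, 0.8),
                                            thresholds = list(y1 = 0))) {
  set.seed(seed)
  ped <- sim_pedigree(n_animals, n_generations)
  u <- sim_breeding_values(ped, params$G0)
  dat <- sim_phenotypes(ped, u, params)
  cont <- setdiff(params$traits, names(params$thresholds))
  model <- threshold_model(categorical = params$thresholds,
                           continuous = cont,
                           fixed = c("sex", "generation"),
                           R = params$R, G0 = params$G0)
  ws <- validate_model_data(dat, ped, model)
  S <- build_S(model$G0, a_inverse(ped), ws$n_fixed_eq)
  list(ped = ped, data = dat, model = model, ws = ws, S = S, u = u,
       params = params)
}

# Dense multi-trait mixed model equations for complete records via the
# Kronecker identity C = (M'M) x Rinv, rhs = vec(Rinv Y' M); equations
# unit-major with traits contiguous, matching the package's layout.
dense_blup <- function(ws, S) {
  M <- as.matrix(ws$M)
  Y <- ws$Y
  stopifnot(!anyNA(Y))
  Rinv <- solve(ws$model$R)
  C <- kronecker(crossprod(M), Rinv) + as.matrix(S)
  rhs <- as.vector(Rinv %*% t(Y) %*% M)
  solve(C, rhs)
}

# Direct log posterior: per record, the log cell probability of the
# observed categories (conditional on the continuous traits) plus the
# Gaussian log density of the continuous traits, plus the quadratic
# random-effect penalty. Uses base/mvtnorm numerics only.
lp_direct <- function(ws, theta, S) {
  eta <- thrlmm:::eta_matrix(ws, theta)
  model <- ws$model
  lp <- -0.5 * sum(theta * as.vector(S %*% theta))
  for (i in seq_len(ws$n_rec)) {
    ot <- which(ws$obs[i, ])
    cat_t <- ot[ot <= model$n_cat]
    cont_t <- ot[ot > model$n_cat]
    Ro <- model$R[ot, ot, drop = FALSE]
    ci <- seq_along(cat_t)
    mi <- length(cat_t) + seq_along(cont_t)
    if (length(cont_t)) {
      y2 <- ws$Y[i, cont_t]
      R22 <- Ro[mi, mi, drop = FALSE]
      lp <- lp + mvtnorm::dmvnorm(y2, mean = eta[i, cont_t],
                                  sigma = R22, log = TRUE)
    }
    if (length(cat_t)) {
      if (length(cont_t)) {
        A <- Ro[ci, mi, drop = FALSE] %*% solve(R22)
        mu <- eta[i, cat_t] + as.vector(A %*% (y2 - eta[i, cont_t]))
        Sg <- Ro[ci, ci, drop = FALSE] - A %*% Ro[mi, ci, drop = FALSE]
      } else {
        mu <- eta[i, cat_t]
        Sg <- Ro[ci, ci, drop = FALSE]
      }
      lo <- hi <- numeric(length(cat_t))
      for (j in seq_along(cat_t)) {
        tv <- c(-Inf, model$thresholds[[cat_t[j]]], Inf)
        k <- ws$Y[i, cat_t[j]]
        lo[j] <- tv[k]; hi[j] <- tv[k + 1]
      }
      pr <- if (length(cat_t) == 1L) {
        pnorm(hi, mu, sqrt(Sg[1, 1])) - pnorm(lo, mu, sqrt(Sg[1, 1]))
      } else {
        as.numeric(mvtnorm::pmvnorm(lower = lo, upper = hi, mean = mu,
                                    sigma = Sg,
                                    algorithm = mvtnorm::Miwa(steps = 512)))
      }
      lp <- lp + log(max(pr, 1e-300))
    }
  }
  lp
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# random SPD matrix with unit-scale variances
random_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) / d + diag(d) * 0.5
  S
}
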