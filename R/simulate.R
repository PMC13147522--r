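# Synthetic data generator.
#
# Emulates the validation design the solvers are benchmarked on: an
# overlapping-generation pedigree without directional selection, additive
# breeding values drawn trait-jointly from N(0, A %x% G0), phenotypes
# built from sex and generation fixed effects plus correlated residuals,
# and categorical traits produced by cutting the liabilities at the
# model thresholds. Defaults define the standard 4-trait scenario (one
# binary, one three-category, two continuous traits) at desk scale;
# everything is overridable.

#' Default 4-trait simulation scenario parameters
#'
#' Moderate heritabilities (0.2-0.35), all-pairs genetic correlation 0.3,
#' all-pairs residual correlation 0.2, categorical residual variances 1
#' (probit identification), thresholds 0 for the binary trait and (0, 1)
#' for the three-category trait.
#'
#' @return Named list with `G0`, `R`, `thresholds`, `sex_effects`,
#'   `generation_trend`, trait names.
#' @export
default_scenario_parameters <- function() {
  traits <- c("cat1", "cat2", "cont1", "cont2")
  va <- c(0.30, 0.40, 0.40, 0.50)
  ve <- c(1.00, 1.00, 0.80, 1.00)
  corg <- matrix(0.3, 4, 4); diag(corg) <- 1
  core <- matrix(0.2, 4, 4); diag(core) <- 1
  G0 <- diag(sqrt(va)) %*% corg %*% diag(sqrt(va))
  R <- diag(sqrt(ve)) %*% core %*% diag(sqrt(ve))
  dimnames(G0) <- dimnames(R) <- list(traits, traits)
  sex_effects <- rbind(F = c(0.00, 0.20, 1.00, 0.50),
                       M = c(0.20, 0.00, 1.30, 0.75))
  colnames(sex_effects) <- traits
  list(traits = traits, G0 = G0, R = R,
       thresholds = list(cat1 = 0, cat2 = c(0, 1)),
       sex_effects = sex_effects,
       generation_trend = c(0.05, 0.05, 0.08, 0.08))
}

#' Simulate an overlapping-generation pedigree
#'
#' Founders make up generation 1; each later animal draws its sire and
#' dam at random (no selection) from the previous generation, or from two
#' generations back with probability `overlap`. Sexes are assigned at
#' random, so selfing is impossible, and parents always precede offspring.
#'
#' @param n_animals Total pedigree size.
#' @param n_generations Number of (overlapping) generations.
#' @param overlap Probability that a parent is drawn from generation
#'   `g - 2` rather than `g - 1`.
#' @param seed RNG seed.
#' @return Tibble with `animal`, `sire`, `dam`, `sex`, `generation`
#'   (0 = unknown parent; founders have sire = dam = 0).
#' @export
sim_pedigree <- function(n_animals, n_generations, overlap = 0.2,
                         seed = NULL) {
  stopifnot(n_generations >= 1, n_animals >= n_generations)
  if (!is.null(seed)) set.seed(seed)
  per_gen <- diff(round(seq(0, n_animals, length.out = n_generations + 1)))
  gen <- rep(seq_len(n_generations), times = per_gen)
  sex <- sample(c("F", "M"), n_animals, replace = TRUE)
  # guarantee both sexes in every generation that must produce parents
  for (g in seq_len(n_generations)) {
    idx <- which(gen == g)
    if (length(idx) >= 2) {
      sex[idx[1]] <- "F"; sex[idx[2]] <- "M"
    }
  }
  sire <- integer(n_animals); dam <- integer(n_animals)
  for (g in seq(2, length.out = max(0, n_generations - 1))) {
    idx <- which(gen == g)
    for (i in idx) {
      pick <- function(want_sex) {
        from <- if (g > 2 && runif(1) < overlap) g - 2 else g - 1
        pool <- which(gen == from & sex == want_sex)
        if (!length(pool)) pool <- which(gen == g - 1 & sex == want_sex)
        if (!length(pool)) abort(
          paste0("no available ", want_sex, " parent for generation ", g))
        if (length(pool) == 1) pool else sample(pool, 1)
      }
      sire[i] <- pick("M")
      dam[i] <- pick("F")
    }
  }
  tibble::tibble(animal = seq_len(n_animals), sire = sire, dam = dam,
                 sex = sex, generation = gen)
}

#' Simulate multi-trait breeding values over a pedigree
#'
#' Founders draw `u ~ N(0, G0)`; descendants are the parent average plus
#' Mendelian sampling `N(0, G0 / 2)` (both parents known; 3/4 with one
#' parent, non-inbred recursion), so jointly `u ~ N(0, A %x% G0)`.
#'
#' @param pedigree Pedigree tibble (parents must precede offspring, as
#'   produced by [sim_pedigree()] or [validate_pedigree()]).
#' @param G0 Genetic covariance among traits.
#' @param seed RNG seed.
#' @return Matrix `n_animals x n_traits` of true breeding values.
#' @export
sim_breeding_values <- function(pedigree, G0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G0 <- as.matrix(G0)
  TT <- nrow(G0)
  n <- nrow(pedigree)
  L_f <- chol(G0)             # founders
  L_h <- chol(0.75 * G0)      # one parent known
  L_m <- chol(0.5 * G0)       # both parents known
  u <- matrix(0, n, TT)
  zz <- matrix(rnorm(n * TT), n, TT)
  s <- pedigree$sire; d <- pedigree$dam
  for (i in seq_len(n)) {
    if (s[i] > 0 && d[i] > 0) {
      u[i, ] <- 0.5 * (u[s[i], ] + u[d[i], ]) + zz[i, ] %*% L_m
    } else if (s[i] > 0 || d[i] > 0) {
      p <- max(s[i], d[i])
      u[i, ] <- 0.5 * u[p, ] + zz[i, ] %*% L_h
    } else {
      u[i, ] <- zz[i, ] %*% L_f
    }
  }
  colnames(u) <- colnames(G0)
  u
}

#' Simulate phenotypes from breeding values
#'
#' Liabilities / phenotypes are `fixed effects + u + e` with `e ~ N(0, R)`
#' per animal; ordinal traits are discretized by their thresholds
#' (category k iff `t_{k-1} < l <= t_k`).
#'
#' @param pedigree Pedigree tibble with `sex` and `generation` columns.
#' @param u Breeding-value matrix from [sim_breeding_values()].
#' @param params Parameter list as from [default_scenario_parameters()].
#' @param seed RNG seed.
#' @return Tibble of records (`animal`, `sex`, `generation`, one column
#'   per trait) with the true liabilities kept in attribute `"liability"`.
#' @export
sim_phenotypes <- function(pedigree, u, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pedigree)
  R <- as.matrix(params$R)
  TT <- nrow(R)
  e <- matrix(rnorm(n * TT), n, TT) %*% chol(R)
  fx <- params$sex_effects[pedigree$sex, , drop = FALSE] +
    outer(pedigree$generation - 1, params$generation_trend)
  liab <- fx + u + e
  out <- tibble::tibble(animal = pedigree$animal, sex = pedigree$sex,
                        generation = pedigree$generation)
  for (j in seq_len(TT)) {
    tn <- params$traits[j]
    if (tn %in% names(params$thresholds)) {
      tv <- c(-Inf, params$thresholds[[tn]], Inf)
      out[[tn]] <- as.integer(cut(liab[, j], breaks = tv, labels = FALSE))
    } else {
      out[[tn]] <- liab[, j]
    }
  }
  attr(out, "liability") <- liab
  out
}

#' Build the full 4-trait validation scenario
#'
#' Simulates the standard scenario (binary + three-category + two
#' continuous traits, sex and generation fixed effects, overlapping
#' generations without selection) at the requested size, and attaches the
#' three biased-variance sensitivity settings: the additive variances of
#' the categorical traits scaled by (a) 0.8 / 1.1, (b) 1.2 / 0.9,
#' (c) 0.8 / 0.8, genetic correlations preserved.
#'
#' @param n_animals Pedigree size (>= 100).
#' @param n_generations Overlapping generations.
#' @param seed RNG seed driving pedigree, breeding values, phenotypes.
#' @param params Scenario parameters (defaults:
#'   [default_scenario_parameters()]).
#' @param overlap Passed to [sim_pedigree()].
#' @return List with `pedigree`, `data`, `model`, `true_u`, `true_b`,
#'   `params`, and `biased_G0` (list `a`, `b`, `c`).
#' @export
sim_scenario <- function(n_animals = 3000, n_generations = 6, seed = 1,
                         params = default_scenario_parameters(),
                         overlap = 0.2) {
  stopifnot(n_animals >= 100)
  set.seed(seed)
  ped <- sim_pedigree(n_animals, n_generations, overlap)
  u <- sim_breeding_values(ped, params$G0)
  dat <- sim_phenotypes(ped, u, params)
  cont <- setdiff(params$traits, names(params$thresholds))
  model <- threshold_model(categorical = params$thresholds,
                           continuous = cont,
                           fixed = c("sex", "generation"),
                           R = params$R, G0 = params$G0)
  scale_cat_variance <- function(f1, f2) {
    sc <- rep(1, length(params$traits))
    sc[match(names(params$thresholds), params$traits)] <- sqrt(c(f1, f2))
    D <- diag(sc)
    out <- D %*% params$G0 %*% D
    dimnames(out) <- dimnames(params$G0)
    out
  }
  list(pedigree = ped, data = dat, model = model, true_u = u,
       true_b = list(sex = params$sex_effects,
                     generation_trend = params$generation_trend),
       params = params,
       biased_G0 = list(a = scale_cat_variance(0.8, 1.1),
                        b = scale_cat_variance(1.2, 0.9),
                        c = scale_cat_variance(0.8, 0.8)))
}
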