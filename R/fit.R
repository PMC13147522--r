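# Tidy user-facing fitting surface.

#' Fit a multi-trait threshold-linear model
#'
#' Estimates fixed effects and breeding values for a model with any mix
#' of ordinal and continuous traits, by joint posterior mode
#' (Newton-Raphson or EM) or by Gibbs-sampler posterior means. Variance
#' components and thresholds are taken as known from the model object.
#'
#' @param data Phenotype tibble: `animal` column plus the model's trait
#'   and fixed-effect columns (`NA` = missing record).
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`; 0 or
#'   `NA` = unknown parent).
#' @param model A [threshold_model()].
#' @param method `"nr"` (Newton-Raphson, default), `"em"`
#'   (SQUAREM-accelerated EM) or `"gibbs"` (single-site sampler).
#' @param tol Convergence tolerance on the relative working-system
#'   residual (MAP methods).
#' @param max_rounds Outer-round cap for the MAP methods.
#' @param relationship_inverse Optional precomputed inverse relationship
#'   matrix (pedigree, genomic or single-step); default is Henderson's
#'   `A`-inverse of `pedigree`.
#' @param inbreeding Passed to [a_inverse()] when the default
#'   relationship is used.
#' @param inner Inner linear solver for Newton-Raphson.
#' @param gibbs_control List with `n_samples`, `burn_in`, `thin`, `seed`
#'   for `method = "gibbs"`.
#' @param workspace Optional prebuilt [validate_model_data()] result (to
#'   refit the same data with several methods without recompiling);
#'   `data` and `pedigree` may then be omitted.
#' @return A `thrlmm_fit` object; see [tidy.thrlmm_fit()], [glance.thrlmm_fit()],
#'   [ebv()].
#' @examples
#' sc <- sim_scenario(n_animals = 300, n_generations = 3, seed = 42)
#' fit <- fit_threshold_model(sc$data, sc$pedigree, sc$model, tol = 1e-10)
#' glance(fit)
#' @export
fit_threshold_model <- function(data = NULL, pedigree = NULL, model,
                                method = c("nr", "em", "gibbs"),
                                tol = 1e-12, max_rounds = NULL,
                                relationship_inverse = NULL,
                                inbreeding = FALSE,
                                inner = c("direct", "pcg"),
                                gibbs_control = list(),
                                workspace = NULL) {
  method <- match.arg(method)
  inner <- match.arg(inner)
  ws <- workspace %||% build_workspace(data, pedigree, model)
  Kinv <- relationship_inverse %||% a_inverse(ws$ped, inbreeding = inbreeding)
  S <- build_S(model$G0, Kinv, ws$n_fixed_eq)
  res <- switch(method,
    nr = nr_solve(ws, S, tol = tol, max_rounds = max_rounds %||% 100L,
                  inner = inner),
    em = em_solve(ws, S, tol = tol, max_rounds = max_rounds %||% 1000L),
    gibbs = {
      gc <- utils::modifyList(list(n_samples = 10000L, burn_in = 1000L,
                                   thin = 1L, seed = 1L), gibbs_control)
      gibbs_solve(ws, S, n_samples = gc$n_samples, burn_in = gc$burn_in,
                  thin = gc$thin, seed = gc$seed)
    })
  structure(c(res, list(ws = ws, model = model, S = S)),
            class = "thrlmm_fit")
}

# equation index for (unit, trait); units are fixed design columns then
# animals, traits contiguous within unit
eq_index <- function(ws, unit, trait) (unit - 1L) * ws$TT + trait

#' Extract estimated breeding values
#'
#' @param fit A `thrlmm_fit`.
#' @return Tibble with `animal` (original ids), `trait`, `ebv` (and the
#'   Monte-Carlo standard error for Gibbs fits).
#' @export
ebv <- function(fit) {
  ws <- fit$ws
  units <- ws$q + seq_len(ws$n_anim)
  idx <- as.vector(vapply(seq_len(ws$TT),
                          function(t) eq_index(ws, units, t),
                          numeric(ws$n_anim)))
  out <- tibble::tibble(
    animal = rep(ws$ped$id, times = ws$TT),
    trait = rep(ws$model$traits, each = ws$n_anim),
    ebv = fit$theta[idx])
  if (!is.null(fit$theta_se)) out$mc_se <- fit$theta_se[idx]
  out
}

#' Tidy solutions of a threshold-linear model fit
#'
#' @param x A `thrlmm_fit`.
#' @param ... Unused.
#' @return Tibble with `effect` (`"fixed"` / `"genetic"`), `term` (design
#'   column or animal id), `trait`, `estimate`.
#' @method tidy thrlmm_fit
#' @export
tidy.thrlmm_fit <- function(x, ...) {
  ws <- x$ws
  fixed_idx <- as.vector(vapply(seq_len(ws$TT),
                                function(t) eq_index(ws, seq_len(ws$q), t),
                                numeric(ws$q)))
  fixed <- tibble::tibble(
    effect = "fixed",
    term = rep(ws$fixed_names, times = ws$TT),
    trait = rep(ws$model$traits, each = ws$q),
    estimate = x$theta[fixed_idx])
  gen <- ebv(x)
  genetic <- tibble::tibble(effect = "genetic", term = as.character(gen$animal),
                            trait = gen$trait, estimate = gen$ebv)
  dplyr::bind_rows(fixed, genetic)
}

#' One-row fit summary
#'
#' @param x A `thrlmm_fit`.
#' @param ... Unused.
#' @method glance thrlmm_fit
#' @export
glance.thrlmm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_records = x$ws$n_rec,
    n_animals = x$ws$n_anim,
    n_traits = x$ws$TT,
    n_equations = x$ws$n_eq,
    rounds = x$rounds %||% NA_integer_,
    samples_kept = x$n_kept %||% NA_integer_,
    converged = x$converged %||% TRUE,
    final_metric = if (!is.null(x$metric_trace))
      x$metric_trace[length(x$metric_trace)] else NA_real_)
}

#' @export
print.thrlmm_fit <- function(x, ...) {
  g <- glance(x)
  cat("<thrlmm_fit> method = ", x$method, ", ", g$n_equations,
      " equations\n", sep = "")
  if (!is.na(g$rounds)) {
    cat("  rounds: ", g$rounds, ", final metric: ",
        format(g$final_metric, digits = 3), "\n", sep = "")
  }
  if (!is.na(g$samples_kept)) {
    cat("  kept samples: ", g$samples_kept, "\n", sep = "")
  }
  invisible(x)
}

#' Prediction error variances of breeding values
#'
#' Diagonal of the inverse converged coefficient matrix for the requested
#' animal-trait combinations. Requires a Newton-Raphson fit with
#' `keep_system` (the default).
#'
#' @param fit A `thrlmm_fit` from `method = "nr"`.
#' @param animals Animal ids (default all).
#' @param traits Trait names (default all).
#' @return Tibble with `animal`, `trait`, `pev`.
#' @export
pev <- function(fit, animals = NULL, traits = NULL) {
  if (is.null(fit$C)) abort("fit carries no converged system; refit with method = 'nr'")
  ws <- fit$ws
  animals <- animals %||% ws$ped$id
  traits <- traits %||% ws$model$traits
  apos <- match(as.character(animals), ws$ped$id)
  if (anyNA(apos)) abort("unknown animal id in `animals`")
  tpos <- match(traits, ws$model$traits)
  if (anyNA(tpos)) abort("unknown trait in `traits`")
  grid <- expand.grid(a = apos, t = tpos)
  eqs <- eq_index(ws, ws$q + grid$a, grid$t)
  tibble::tibble(animal = rep(animals, times = length(tpos)),
                 trait = rep(traits, each = length(apos)),
                 pev = pev_equations(fit$C, eqs))
}
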