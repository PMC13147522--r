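# Agreement analytics between solvers: per-trait regression of the
# benchmark EBVs on the candidate EBVs plus Pearson correlation, the
# validation summary the sampler-vs-MAP comparison is judged on.

#' Regress benchmark EBVs on candidate EBVs
#'
#' Per trait, ordinary least squares of the benchmark solutions on the
#' candidate solutions over the animals present in both sets, plus the
#' Pearson correlation. Near-perfect agreement shows as slope ~ 1,
#' intercept ~ 0, correlation ~ 1.
#'
#' @param benchmark,candidate `thrlmm_fit` objects or tibbles with
#'   columns `animal`, `trait`, `ebv`.
#' @return A `thrlmm_agreement` tibble with `trait`, `n`, `correlation`,
#'   `slope`, `intercept`; the joined per-animal values are kept for
#'   [autoplot.thrlmm_agreement()].
#' @export
compare_ebv <- function(benchmark, candidate) {
  as_ebv <- function(x) {
    if (inherits(x, "thrlmm_fit")) x <- ebv(x)
    tibble::as_tibble(x)[c("animal", "trait", "ebv")]
  }
  b <- as_ebv(benchmark); cnd <- as_ebv(candidate)
  joined <- dplyr::inner_join(b, cnd, by = c("animal", "trait"),
                              suffix = c("_benchmark", "_candidate"))
  if (!nrow(joined)) abort("no overlapping animal/trait combinations")
  report <- joined |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      if (sd(d$ebv_candidate) == 0) {
        abort(paste0("candidate EBVs have zero variance for trait ",
                     key$trait[[1]]))
      }
      fit <- lm(ebv_benchmark ~ ebv_candidate, data = d)
      tibble::tibble(n = nrow(d),
                     correlation = cor(d$ebv_benchmark, d$ebv_candidate),
                     slope = coef(fit)[[2]],
                     intercept = coef(fit)[[1]])
    }) |>
    dplyr::ungroup()
  structure(report, class = c("thrlmm_agreement", class(report)),
            values = joined)
}

#' Scatter plot of benchmark versus candidate EBVs
#'
#' @param object A [compare_ebv()] report.
#' @param ... Unused.
#' @return A ggplot faceted by trait with the identity line dashed.
#' @method autoplot thrlmm_agreement
#' @export
autoplot.thrlmm_agreement <- function(object, ...) {
  vals <- attr(object, "values")
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$ebv_candidate,
                                     y = .data$ebv_benchmark)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "candidate EBV", y = "benchmark EBV")
}

#' End-to-end validation run
#'
#' Simulates the 4-trait scenario, fits it by Newton-Raphson, EM and the
#' Gibbs benchmark with the true parameters, and reports per-trait
#' agreement of the benchmark with each MAP solver; optionally repeats
#' Newton-Raphson under the three biased-variance settings against the
#' true-parameter benchmark.
#'
#' @param n_animals,n_generations,seed Scenario size and seed.
#' @param gibbs_control Sampler settings (see [fit_threshold_model()]).
#' @param tol MAP convergence tolerance.
#' @param sensitivity Also run the biased-variance scenarios.
#' @return List with `agreement` (`nr`, `em` reports), `sensitivity`
#'   (reports per biased scenario, categorical traits), `fits`, and the
#'   scenario bundle.
#' @export
run_validation <- function(n_animals = 3000, n_generations = 6, seed = 1,
                           gibbs_control = list(n_samples = 10000L,
                                                burn_in = 1000L, seed = 1L),
                           tol = 1e-12, sensitivity = TRUE) {
  sc <- sim_scenario(n_animals, n_generations, seed)
  ws <- build_workspace(sc$data, sc$pedigree, sc$model)
  fit_nr <- fit_threshold_model(model = sc$model, method = "nr", tol = tol,
                                workspace = ws)
  fit_em <- fit_threshold_model(model = sc$model, method = "em", tol = tol,
                                workspace = ws)
  fit_gibbs <- fit_threshold_model(model = sc$model, method = "gibbs",
                                   gibbs_control = gibbs_control,
                                   workspace = ws)
  out <- list(scenario = sc,
              fits = list(nr = fit_nr, em = fit_em, gibbs = fit_gibbs),
              agreement = list(nr = compare_ebv(fit_gibbs, fit_nr),
                               em = compare_ebv(fit_gibbs, fit_em)))
  if (sensitivity) {
    cat_traits <- names(sc$model$thresholds)
    out$sensitivity <- lapply(sc$biased_G0, function(G0b) {
      mb <- sc$model
      mb$G0 <- G0b
      fit_b <- fit_threshold_model(model = mb, method = "nr", tol = tol,
                                   workspace = ws)
      rep <- compare_ebv(fit_gibbs, fit_b)
      rep[rep$trait %in% cat_traits, ]
    })
  }
  out
}
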