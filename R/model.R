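# Model specification and data compilation.
#
# A threshold-linear model couples c ordinal traits (observed categories,
# latent Gaussian liabilities cut by thresholds) with m continuous traits
# through a joint residual covariance R and a joint genetic covariance G0.
# Thresholds and both covariance matrices are treated as known; the
# categorical residual variances fix the liability scale (probit
# identification), and choosing them is the user's responsibility.

#' Specify a multi-trait threshold-linear model
#'
#' @param categorical Named list: one element per ordinal trait, the
#'   vector of its finite thresholds (increasing; a binary trait has one).
#'   Names are the phenotype columns holding integer category codes 1..K.
#' @param continuous Character vector of continuous trait columns.
#' @param fixed Character vector of fixed-effect factor columns shared by
#'   all traits (the first factor keeps all its levels; later factors drop
#'   their first level for full rank).
#' @param R Residual covariance among all traits, ordered categorical
#'   first then continuous.
#' @param G0 Additive-genetic covariance among all traits, same order.
#' @return A `thrlmm_model` object.
#' @export
threshold_model <- function(categorical = list(), continuous = character(),
                            fixed, R, G0) {
  c_n <- length(categorical)
  m_n <- length(continuous)
  if (c_n + m_n == 0L) abort("at least one trait is required")
  if (c_n > 0 && is.null(names(categorical))) {
    abort("`categorical` must be a named list of threshold vectors")
  }
  traits <- c(names(categorical), continuous)
  if (anyDuplicated(traits)) abort("duplicated trait names")
  R <- as.matrix(R); G0 <- as.matrix(G0)
  TT <- c_n + m_n
  if (!all(dim(R) == TT) || !all(dim(G0) == TT)) {
    abort("`R` and `G0` must be square with one row per trait")
  }
  check_spd(R, "R"); check_spd(G0, "G0")
  thresholds <- lapply(categorical, function(tv) {
    tv <- as.numeric(tv)
    if (length(tv) < 1L) abort("each categorical trait needs >= 1 threshold")
    if (any(diff(tv) <= 0)) abort("thresholds not strictly increasing")
    tv
  })
  dimnames(R) <- dimnames(G0) <- list(traits, traits)
  structure(list(traits = traits, n_cat = c_n, n_cont = m_n,
                 is_cat = c(rep(TRUE, c_n), rep(FALSE, m_n)),
                 thresholds = thresholds, fixed = fixed, R = R, G0 = G0),
            class = "thrlmm_model")
}

#' @export
print.thrlmm_model <- function(x, ...) {
  cat("<thrlmm_model> ", x$n_cat, " categorical + ", x$n_cont,
      " continuous trait(s)\n", sep = "")
  for (j in seq_len(x$n_cat)) {
    cat("  ", x$traits[j], ": thresholds ",
        paste(x$thresholds[[j]], collapse = ", "), "\n", sep = "")
  }
  if (x$n_cont) cat("  continuous: ",
                    paste(x$traits[!x$is_cat], collapse = ", "), "\n", sep = "")
  cat("  fixed effects: ", paste(x$fixed, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Validate a model / phenotype / pedigree bundle
#'
#' Checks category codes against each trait's threshold count, trait and
#' factor columns, animal resolvability against the pedigree, and the
#' covariance matrices; returns a compiled workspace ready for the
#' solvers.
#'
#' @param data Phenotype data frame: one row per animal with records;
#'   column `animal` plus the model's trait and fixed-effect columns.
#'   `NA` marks a missing trait record.
#' @param pedigree Pedigree accepted by [validate_pedigree()].
#' @param model A [threshold_model()].
#' @return A `thrlmm_workspace` (internal structure; also accepted by the
#'   fitting functions to avoid recompilation).
#' @export
validate_model_data <- function(data, pedigree, model) {
  build_workspace(data, pedigree, model)
}

# ---- workspace --------------------------------------------------------
# Equation ordering: fixed-effect design columns first, then animals;
# within every unit the traits are contiguous (trait within animal).
build_workspace <- function(data, pedigree, model) {
  stopifnot(inherits(model, "thrlmm_model"))
  data <- tibble::as_tibble(data)
  ped <- validate_pedigree(pedigree)
  n_anim <- nrow(ped)
  TT <- length(model$traits)
  if (!"animal" %in% names(data)) abort("`data` needs an `animal` column")
  miss <- setdiff(c(model$traits, model$fixed), names(data))
  if (length(miss)) abort(paste0("missing data column(s): ",
                                 paste(miss, collapse = ", ")))
  arow <- match(as.character(data$animal), ped$id)
  if (anyNA(arow)) {
    abort(paste0("record animal not in pedigree: ",
                 as.character(data$animal)[is.na(arow)][1]))
  }
  # category codes
  Y <- as.matrix(data[model$traits])
  for (j in seq_len(model$n_cat)) {
    K <- length(model$thresholds[[j]]) + 1L
    yj <- Y[, j]
    bad <- which(!is.na(yj) & (yj < 1 | yj > K | yj != round(yj)))
    if (length(bad)) {
      abort(sprintf("invalid category %s for trait %s (animal %s): must be 1..%d",
                    format(yj[bad[1]]), model$traits[j],
                    as.character(data$animal)[bad[1]], K))
    }
  }
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L)) abort("record with no observed trait")
  # fixed-effect design: all levels of the first factor, drop-first for
  # later factors (full-rank cross-classified parametrization); a later
  # factor with a single level contributes nothing
  X <- NULL
  for (f in seq_along(model$fixed)) {
    fac <- factor(data[[model$fixed[f]]])
    keep <- if (f == 1L) levels(fac) else levels(fac)[-1]
    for (lv in keep) {
      col <- as.numeric(fac == lv)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(model$fixed[f], lv)
    }
  }
  q <- ncol(X)
  n_rec <- nrow(data)
  n_fixed_eq <- q * TT
  n_eq <- n_fixed_eq + n_anim * TT
  # unit incidence M: records x (q + n_anim)
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  Zs <- Matrix::sparseMatrix(i = seq_len(n_rec), j = arow, x = 1,
                             dims = c(n_rec, n_anim))
  M <- cbind(Xs, Zs)
  # expanded incidence over observed (record, trait) rows
  obs_t <- t(obs)
  row_trait <- rep(seq_len(TT), n_rec)[as.vector(obs_t)]
  row_rec <- rep(seq_len(n_rec), times = colSums(obs_t))
  n_rows <- length(row_rec)
  Mt <- methods::as(M, "TsparseMatrix")
  mi <- Mt@i + 1L; mj <- Mt@j + 1L; mx <- Mt@x
  # map (record, trait) -> expanded row
  row_of <- matrix(0L, TT, n_rec)
  row_of[cbind(row_trait, row_rec)] <- seq_len(n_rows)
  wi <- integer(0); wj <- integer(0); wx <- numeric(0)
  for (t in seq_len(TT)) {
    rk <- row_of[t, mi]
    keep <- rk > 0L
    wi <- c(wi, rk[keep])
    wj <- c(wj, (mj[keep] - 1L) * TT + t)
    wx <- c(wx, mx[keep])
  }
  W <- Matrix::sparseMatrix(i = wi, j = wj, x = wx, dims = c(n_rows, n_eq))
  # missingness patterns
  pat_key <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  pats <- list()
  for (key in unique(pat_key)) {
    recs <- which(pat_key == key)
    ot <- as.integer(strsplit(key, ",")[[1]])
    cat_t <- ot[ot <= model$n_cat]
    cont_t <- ot[ot > model$n_cat]
    Ro <- model$R[ot, ot, drop = FALSE]
    p <- list(records = recs, obs = ot, cat = cat_t, cont = cont_t,
              n_obs = length(ot))
    p$R_obs <- Ro
    p$R_obs_inv <- solve(Ro)
    if (length(cat_t)) {
      ci <- seq_along(cat_t)
      mi2 <- length(cat_t) + seq_along(cont_t)
      if (length(cont_t)) {
        R22 <- Ro[mi2, mi2, drop = FALSE]
        p$R22_inv <- solve(R22)
        p$A12 <- Ro[ci, mi2, drop = FALSE] %*% p$R22_inv  # R12 R22^-1
        p$Sigma <- Ro[ci, ci, drop = FALSE] -
          p$A12 %*% Ro[mi2, ci, drop = FALSE]
      } else {
        p$R22_inv <- matrix(0, 0, 0)
        p$A12 <- matrix(0, length(cat_t), 0)
        p$Sigma <- Ro[ci, ci, drop = FALSE]
      }
      p$Sigma <- (p$Sigma + t(p$Sigma)) / 2
      p$Sigma_inv <- solve(p$Sigma)
      # category cell bounds are record-specific; thresholds cached here
      p$thr <- model$thresholds[cat_t]
    } else {
      p$R22_inv <- p$R_obs_inv
    }
    # expanded row indices of this pattern's records (block-contiguous)
    p$rows <- lapply(recs, function(r) row_of[ot, r])
    p$row_mat <- do.call(rbind, p$rows)   # n_i x n_obs
    pats[[key]] <- p
  }
  structure(list(model = model, ped = ped, data = data, Y = Y, obs = obs,
                 arow = arow, X = X, M = M, W = W, n_rows = n_rows,
                 q = q, TT = TT, n_anim = n_anim, n_rec = n_rec,
                 n_fixed_eq = n_fixed_eq, n_eq = n_eq,
                 fixed_names = colnames(X), patterns = pats,
                 row_of = row_of),
            class = "thrlmm_workspace")
}

#' @export
print.thrlmm_workspace <- function(x, ...) {
  cat("<thrlmm_workspace> ", x$n_rec, " records, ", x$n_anim, " animals, ",
      x$TT, " traits, ", x$n_eq, " equations (", x$n_fixed_eq, " fixed)\n",
      sep = "")
  invisible(x)
}

# linear predictors per record x trait from a solution vector
eta_matrix <- function(ws, theta) {
  Theta <- matrix(theta, nrow = ws$TT)      # traits x units
  as.matrix(ws$M %*% t(Theta))
}

#' Conditional liability moments given continuous records
#'
#' For one record, the mean and covariance of the categorical liabilities
#' conditional on the record's observed continuous traits and the current
#' solutions: `mu = W1 theta1 + R12 R22^-1 (y2 - W2 theta2)` and the Schur
#' complement `Sigma = R11 - R12 R22^-1 R21`, both restricted to the
#' observed traits.
#'
#' @param eta_cat,eta_cont Linear predictors for the record's observed
#'   categorical and continuous traits.
#' @param y2 Observed continuous values (same order as `eta_cont`).
#' @param R Residual covariance restricted to the record's observed
#'   traits, categorical block first.
#' @param n_cat Number of observed categorical traits in `R`.
#' @return List with `mu`, `sigma`, and the weight matrix `A12`
#'   (`R12 R22^-1`).
#' @export
conditional_moments <- function(eta_cat, eta_cont, y2, R, n_cat) {
  R <- as.matrix(R)
  ci <- seq_len(n_cat)
  mi <- setdiff(seq_len(nrow(R)), ci)
  if (length(mi)) {
    R22 <- R[mi, mi, drop = FALSE]
    R22i <- tryCatch(solve(R22), error = function(e) {
      abort("singular continuous residual block")
    })
    A12 <- R[ci, mi, drop = FALSE] %*% R22i
    mu <- as.vector(eta_cat + A12 %*% (y2 - eta_cont))
    Sigma <- R[ci, ci, drop = FALSE] - A12 %*% R[mi, ci, drop = FALSE]
  } else {
    A12 <- matrix(0, n_cat, 0)
    mu <- as.vector(eta_cat)
    Sigma <- R[ci, ci, drop = FALSE]
  }
  list(mu = mu, sigma = (Sigma + t(Sigma)) / 2, A12 = A12)
}

# cell bounds for a pattern's records: list(lower, upper) n_i x c matrices
cell_bounds <- function(ws, p) {
  n_i <- length(p$records)
  cc <- length(p$cat)
  lower <- matrix(-Inf, n_i, cc)
  upper <- matrix(Inf, n_i, cc)
  for (j in seq_len(cc)) {
    tv <- c(-Inf, p$thr[[j]], Inf)
    k <- ws$Y[p$records, p$cat[j]]
    lower[, j] <- tv[k]
    upper[, j] <- tv[k + 1L]
  }
  list(lower = lower, upper = upper)
}
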