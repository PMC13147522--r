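# Pedigree relationship machinery: validation/reordering, Henderson's
# sparse A-inverse, the dense tabular A (used as an oracle and for the
# genotyped submatrix in single-step), and assembly of the random-effect
# precision S = blockdiag(0, Kinv %x% G0inv).

#' Validate and topologically sort a pedigree
#'
#' @param pedigree Data frame with columns `animal`, `sire`, `dam`
#'   (anything coercible; 0 or `NA` marks an unknown parent). Extra
#'   columns are carried through.
#' @return A tibble sorted so parents precede offspring, with integer
#'   columns `animal`, `sire`, `dam` recoded to row indices (0 = unknown)
#'   and the original identifiers kept in `id`.
#' @export
validate_pedigree <- function(pedigree) {
  pedigree <- tibble::as_tibble(pedigree)
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(pedigree))) {
    abort("pedigree needs columns `animal`, `sire`, `dam`")
  }
  ids <- as.character(pedigree$animal)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated animal id: ", ids[duplicated(ids)][1]))
  }
  n <- length(ids)
  code <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "")] <- NA
    m <- match(x, ids)
    if (any(!is.na(x) & is.na(m))) {
      abort(paste0("parent id not in pedigree: ", x[!is.na(x) & is.na(m)][1]))
    }
    ifelse(is.na(m), 0L, m)
  }
  sire <- code(pedigree$sire)
  dam <- code(pedigree$dam)
  if (any(sire == seq_len(n)) || any(dam == seq_len(n))) {
    bad <- which(sire == seq_len(n) | dam == seq_len(n))[1]
    abort(paste0("animal is its own parent: ", ids[bad]))
  }
  # fast path: input already has parents before offspring
  if (all(sire < seq_len(n)) && all(dam < seq_len(n))) {
    out <- pedigree
    out$id <- ids
    out$animal <- seq_len(n)
    out$sire <- sire
    out$dam <- dam
    return(out)
  }
  # Kahn topological sort; detects cycles
  parents <- cbind(sire, dam)
  order <- integer(0)
  indeg <- (sire > 0) + (dam > 0)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[i, ]) {
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)[1]
    abort(paste0("pedigree cycle involving animal ", ids[bad]))
  }
  newpos <- integer(n); newpos[order] <- seq_len(n)
  remap <- function(x) ifelse(x > 0, newpos[pmax(x, 1L)], 0L)
  out <- pedigree[order, , drop = FALSE]
  out$id <- ids[order]
  out$animal <- seq_len(n)
  out$sire <- remap(sire[order])
  out$dam <- remap(dam[order])
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules: each animal contributes `w`, `-w/2`, `w/4` entries
#' to the (animal, animal), (animal, parent) and (parent, parent) cells,
#' with `w` the inverse Mendelian-sampling variance. By default animals
#' are treated as non-inbred; `inbreeding = TRUE` computes inbreeding
#' coefficients by the tabular recursion first (dense, desk scale).
#'
#' @param pedigree A pedigree accepted by [validate_pedigree()].
#' @param inbreeding Account for inbreeding in the Mendelian-sampling
#'   variances?
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) in the sorted
#'   pedigree's animal order.
#' @export
a_inverse <- function(pedigree, inbreeding = FALSE) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$sire; d <- ped$dam
  if (inbreeding) {
    f <- inbreeding_coefficients(ped)
  } else {
    f <- rep(0, n)
  }
  fs <- ifelse(s > 0, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0, f[pmax(d, 1L)], 0)
  nk <- (s > 0) + (d > 0)
  msv <- ifelse(nk == 2, 0.5 - 0.25 * (fs + fd),
         ifelse(nk == 1, 0.75 - 0.25 * ifelse(s > 0, fs, fd), 1))
  w <- 1 / msv
  ii <- c(); jj <- c(); xx <- c()
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  par1 <- ifelse(s > 0, s, NA); par2 <- ifelse(d > 0, d, NA)
  add(seq_len(n), seq_len(n), w)
  for (p in list(par1, par2)) {
    k <- which(!is.na(p))
    if (length(k)) {
      add(k, p[k], -w[k] / 2); add(p[k], k, -w[k] / 2)
      add(p[k], p[k], w[k] / 4)
    }
  }
  both <- which(!is.na(par1) & !is.na(par2))
  if (length(both)) {
    add(par1[both], par2[both], w[both] / 4)
    add(par2[both], par1[both], w[both] / 4)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = FALSE)
  methods::as(Matrix::forceSymmetric(A), "symmetricMatrix")
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Independent recursion used as an oracle for [a_inverse()] and as the
#' genotyped-block source in [h_inverse()]. O(n^2) memory: desk scale.
#'
#' @inheritParams a_inverse
#' @export
a_matrix <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        a <- 0
        if (s > 0) a <- a + 0.5 * A[j, s]
        if (d > 0) a <- a + 0.5 * A[j, d]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

inbreeding_coefficients <- function(ped) {
  A <- a_matrix(ped)
  diag(A) - 1
}

#' Random-effect precision structure for the mixed model equations
#'
#' Places the Kronecker precision `Kinv %x% G0inv` (animal-major, trait
#' within animal) on the random-effect equations and zeros on the fixed
#' ones, matching the equation ordering used throughout the package.
#'
#' @param g0 Genetic covariance matrix among traits (SPD).
#' @param relationship_inverse Sparse symmetric PSD inverse relationship
#'   matrix (pedigree `A`-inverse, genomic, single-step `H`-inverse, or
#'   identity — the solvers are agnostic).
#' @param n_fixed_equations Number of leading fixed-effect equations.
#' @return Sparse symmetric matrix of size
#'   `n_fixed_equations + ntraits * nanimals`.
#' @export
build_S <- function(g0, relationship_inverse, n_fixed_equations) {
  g0 <- as.matrix(g0)
  check_spd(g0, "g0")
  g0inv <- solve(g0)
  g0inv <- (g0inv + t(g0inv)) / 2
  Kinv <- methods::as(relationship_inverse, "CsparseMatrix")
  Su <- Matrix::kronecker(Kinv, g0inv)
  S <- Matrix::bdiag(Matrix::Matrix(0, n_fixed_equations, n_fixed_equations,
                                    sparse = TRUE), Su)
  methods::as(Matrix::forceSymmetric(S), "symmetricMatrix")
}

#' Single-step inverse relationship matrix
#'
#' Combines the pedigree `A`-inverse with a genomic relationship matrix
#' for the genotyped subset: `Hinv = Ainv + blockdiag(0, Gb_inv - A22_inv)`
#' where `Gb = (1 - blend) * grm + blend * A22`.
#'
#' @param a_inv Sparse pedigree `A`-inverse (from [a_inverse()]).
#' @param pedigree The matching pedigree (for the `A22` block).
#' @param grm Genomic relationship matrix for the genotyped animals.
#' @param genotyped Integer positions (sorted-pedigree order) of the
#'   genotyped animals, in the row order of `grm`.
#' @param blend Weight on `A22` when blending the genomic matrix.
#' @return Sparse symmetric matrix accepted by [build_S()].
#' @export
h_inverse <- function(a_inv, pedigree, grm, genotyped, blend = 0.05) {
  if (length(genotyped) == 0L) return(a_inv)
  A <- a_matrix(pedigree)
  A22 <- A[genotyped, genotyped, drop = FALSE]
  Gb <- (1 - blend) * as.matrix(grm) + blend * A22
  check_spd(Gb, "blended grm")
  A22inv <- tryCatch(solve(A22), error = function(e) {
    abort("A22 block is singular; check genotyped ids")
  })
  H <- as(a_inv, "CsparseMatrix")
  delta <- solve(Gb) - A22inv
  H[genotyped, genotyped] <- H[genotyped, genotyped] + delta
  methods::as(Matrix::forceSymmetric(H), "symmetricMatrix")
}
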