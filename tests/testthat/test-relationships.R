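# Pedigree relationship machinery.

test_that("pedigree validation sorts, recodes and reports violations", {
  ped <- tibble::tibble(animal = c("c", "a", "b"),
                        sire = c("a", "0", "a"),
                        dam = c("b", "0", "0"))
  v <- validate_pedigree(ped)
  expect_true(all(v$sire < v$animal | v$sire == 0))
  expect_true(all(v$dam < v$animal | v$dam == 0))
  expect_error(validate_pedigree(
    tibble::tibble(animal = 1, sire = 1, dam = 0)), "own parent")
  expect_error(validate_pedigree(
    tibble::tibble(animal = c(1, 2), sire = c(2, 1), dam = c(0, 0))),
    "cycle")
  expect_error(validate_pedigree(
    tibble::tibble(animal = c(1, 1), sire = 0, dam = 0)), "duplicated")
  expect_error(validate_pedigree(
    tibble::tibble(animal = 1, sire = 9, dam = 0)), "not in pedigree")
})

test_that("A-inverse matches known small cases", {
  expect_equal(as.matrix(a_inverse(tibble::tibble(animal = 1, sire = 0,
                                                  dam = 0))),
               matrix(1), ignore_attr = TRUE)
  trio <- tibble::tibble(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  expect_equal(as.matrix(a_inverse(trio)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE)
})

test_that("A-inverse inverts the tabular A on random pedigrees", {
  ped <- sim_pedigree(150, 4, seed = 5)
  A <- a_matrix(ped)
  # random overlapping-generation matings create inbreeding
  expect_gt(max(diag(A)), 1)
  Ainv <- a_inverse(ped, inbreeding = TRUE)
  expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(nrow(A)))), 1e-10)
  # without inbreeding, the rules invert the non-inbred recursion: check
  # on a pedigree of unrelated matings
  ped0 <- tibble::tibble(animal = 1:6, sire = c(0, 0, 0, 0, 1, 3),
                         dam = c(0, 0, 0, 0, 2, 4))
  expect_lt(max(abs(as.matrix(a_inverse(ped0) %*% a_matrix(ped0)) -
                      diag(6))), 1e-12)
})

test_that("S places the Kronecker precision on random-effect equations", {
  ped <- sim_pedigree(10, 2, seed = 11)
  Ainv <- a_inverse(ped, inbreeding = TRUE)
  G0 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  S <- build_S(G0, Ainv, n_fixed_equations = 4)
  expect_equal(dim(S), c(24L, 24L))
  expect_true(all(as.matrix(S[1:4, ]) == 0))
  # identity case: unit diagonal on random equations only
  S_id <- build_S(diag(2), Matrix::Diagonal(10), 4)
  expect_equal(Matrix::diag(S_id), c(rep(0, 4), rep(1, 20)))
  # quadratic form against a dense Kronecker construction
  set.seed(2)
  u <- rnorm(20)
  dense <- kronecker(solve(a_matrix(ped)), solve(G0))
  expect_equal(sum(u * as.vector(S[5:24, 5:24] %*% u)),
               sum(u * (dense %*% u)), tolerance = 1e-8)
  expect_error(build_S(matrix(c(1, 2, 2, 1), 2), Ainv, 4),
               "positive definite")
})

test_that("relabeling animals permutes S consistently", {
  ped <- sim_pedigree(12, 2, seed = 13)
  G0 <- matrix(c(0.4, 0.1, 0.1, 0.6), 2)
  S1 <- build_S(G0, a_inverse(ped, inbreeding = TRUE), 0)
  # relabel ids and shuffle rows; validation re-sorts, so rows permute
  set.seed(1)
  shuffle <- sample(12)
  lab <- function(x) ifelse(x > 0, paste0("id", x), "0")
  ped2 <- tibble::tibble(animal = lab(ped$animal), sire = lab(ped$sire),
                         dam = lab(ped$dam))[shuffle, ]
  v2 <- validate_pedigree(ped2)
  S2 <- build_S(G0, a_inverse(v2, inbreeding = TRUE), 0)
  # equations of S2, mapped back to the original animal order
  pos <- match(paste0("id", seq_len(12)), v2$id)
  eq <- as.vector(t(cbind((pos - 1) * 2 + 1, (pos - 1) * 2 + 2)))
  expect_lt(max(abs(as.matrix(S2[eq, eq]) - as.matrix(S1))), 1e-10)
})

test_that("single-step H-inverse reduces correctly", {
  ped <- sim_pedigree(40, 3, seed = 17)
  Ainv <- a_inverse(ped, inbreeding = TRUE)
  expect_identical(h_inverse(Ainv, ped, matrix(0, 0, 0), integer(0)), Ainv)
  A <- a_matrix(ped)
  gen <- 25:40
  # grm equal to A22 (blend 0): corrections cancel
  H <- h_inverse(Ainv, ped, A[gen, gen], gen, blend = 0)
  expect_lt(max(abs(as.matrix(H - Ainv))), 1e-8)
  # all animals genotyped: H-inverse collapses to the blended G inverse
  grm <- 0.95 * A + 0.05 * diag(40)
  H_all <- h_inverse(Ainv, ped, grm, 1:40, blend = 0.1)
  Gb <- 0.9 * grm + 0.1 * A
  expect_lt(max(abs(as.matrix(H_all) - solve(Gb))), 1e-8)
})
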