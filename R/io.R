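# Delimited-text readers and writers for pedigrees, phenotypes and
# solutions. Pedigree files are 3+ column whitespace- or comma-delimited
# (animal sire dam), 0 = unknown parent; phenotype files are delimited
# with a header, with a configurable missing-value sentinel.

#' Read a pedigree file
#'
#' @param path Text file with columns animal, sire, dam (header optional;
#'   detected from the first line). Whitespace- or comma-delimited.
#' @return Tibble with `animal`, `sire`, `dam`.
#' @export
read_pedigree_file <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("animal", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (!header) names(df)[1:3] <- c("animal", "sire", "dam")
  tibble::as_tibble(df[, 1:3])
}

#' Write a (renumbered) pedigree file
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @export
write_pedigree_file <- function(pedigree, path) {
  utils::write.table(pedigree[c("animal", "sire", "dam")], path,
                     quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a phenotype file
#'
#' @param path Delimited text file with a header naming the animal,
#'   fixed-effect and trait columns.
#' @param sep Field separator (`""` = any whitespace).
#' @param na Missing-value sentinels.
#' @export
read_phenotype_file <- function(path, sep = "", na = c("NA", "-999")) {
  first <- readLines(path, n = 1)
  if (sep == "" && grepl(",", first)) sep <- ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      na.strings = na,
                                      stringsAsFactors = FALSE))
}

#' @rdname read_phenotype_file
#' @param data Phenotype tibble.
#' @export
write_phenotype_file <- function(data, path) {
  utils::write.table(data, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Write and read solution files
#'
#' Solutions are written as delimited text with columns `effect`, `term`,
#' `trait`, `estimate` (the [tidy.thrlmm_fit()] layout).
#'
#' @param fit A `thrlmm_fit` (or a tidy solutions tibble).
#' @param path Output path.
#' @export
write_solution_file <- function(fit, path) {
  sol <- if (inherits(fit, "thrlmm_fit")) tidy(fit) else fit
  utils::write.table(sol, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_solution_file
#' @export
read_solution_file <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE,
                                      stringsAsFactors = FALSE))
}
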