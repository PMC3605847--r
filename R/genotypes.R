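#' Diploid multilocus genotype dataset
#'
#' Container for diploid microsatellite calls of individuals grouped into
#' subpopulations. Allele calls are positive integer codes (fragment or repeat
#' sizes); a missing genotype is `NA` in both allele matrices. A genotype with
#' one missing allele cannot be represented in Genepop and is treated as fully
#' missing.
#'
#' @param pop character or factor, subpopulation of each individual. Level
#'   order (order of first appearance for character input) fixes the
#'   subpopulation order.
#' @param id character, unique individual identifiers.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes, `NA`
#'   for missing. The pair is unordered; constructors normalise so that
#'   `a1 <= a2`.
#' @param loci character, locus names (defaults to `colnames(a1)`).
#' @param repeat_unit integer repeat-unit length per locus (recycled), used by
#'   the M-ratio; microsatellite data are commonly dinucleotide (default 2).
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `pop` (factor), `id`, `loci`, `a1`, `a2`, `repeat_unit`.
#' @export
genotype_dataset <- function(pop, id, a1, a2, loci = colnames(a1),
                             repeat_unit = 2L) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(id)
  if (length(pop) != n || nrow(a1) != n || nrow(a2) != n)
    stop("pop, id and allele matrices must agree in length")
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (is.null(loci)) loci <- paste0("Locus", seq_len(ncol(a1)))
  if (length(loci) != ncol(a1)) stop("locus names must match allele columns")
  if (anyDuplicated(id)) stop("individual ids must be unique")
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(as.character(pop)))
  pop <- droplevels(pop)
  # half-called genotypes collapse to missing; unordered pair stored sorted
  miss <- is.na(a1) | is.na(a2) | a1 <= 0L | a2 <= 0L
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(
    list(pop = pop, id = as.character(id), loci = as.character(loci),
         a1 = a1, a2 = a2,
         repeat_unit = as.integer(rep_len(repeat_unit, length(loci)))),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", length(x$id), "individuals,",
      nlevels(x$pop), "subpopulations,", length(x$loci), "loci\n")
  tab <- table(x$pop)
  cat("  subpopulations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  per_pop <- table(object$pop)
  k <- vapply(seq_along(object$loci), function(l) {
    length(unique(stats::na.omit(c(object$a1[, l], object$a2[, l]))))
  }, integer(1))
  out <- list(n = length(object$id), subpops = per_pop,
              loci = setNames(k, object$loci),
              mean_alleles = mean(k), missing = mean(is.na(object$a1)))
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", x$n, "individuals\n")
  print(x$subpops)
  cat(sprintf("Alleles per locus: mean %.1f (range %d-%d)\n",
              x$mean_alleles, min(x$loci), max(x$loci)))
  cat(sprintf("Missing genotypes: %.1f%%\n", 100 * x$missing))
  invisible(x)
}

#' Extract one subpopulation
#'
#' @param ds a [genotype_dataset()].
#' @param pop subpopulation label (or integer position).
#' @return A `genotype_dataset` holding only that subpopulation.
#' @export
pop_subset <- function(ds, pop) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.numeric(pop)) pop <- levels(ds$pop)[pop]
  if (!pop %in% levels(ds$pop)) stop("unknown subpopulation: ", pop)
  keep_individuals(ds, ds$pop == pop)
}

# subset by logical/integer index over individuals, preserving structure
keep_individuals <- function(ds, keep) {
  out <- ds
  out$pop <- droplevels(ds$pop[keep])
  out$id <- ds$id[keep]
  out$a1 <- ds$a1[keep, , drop = FALSE]
  out$a2 <- ds$a2[keep, , drop = FALSE]
  out
}

#' Number of individuals per subpopulation
#' @param ds a [genotype_dataset()].
#' @return Named integer vector in subpopulation order.
#' @export
pop_sizes <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  tab <- table(ds$pop)
  setNames(as.integer(tab), names(tab))
}
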