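#' Apply per-individual and per-subpopulation sample filters
#'
#' Individuals with more than `max_missing_loci` missing genotypes are removed
#' first; subpopulations left with fewer than `min_pop_size` individuals are
#' then removed entirely. These are the standard screening rules for
#' single-sample Ne estimation from microsatellite surveys (a minimum of 20
#' individuals per sample, at most three loci missing per individual).
#'
#' @param ds a [genotype_dataset()].
#' @param min_pop_size minimum retained individuals per subpopulation.
#' @param max_missing_loci maximum missing loci tolerated per individual.
#' @return The filtered `genotype_dataset`, with attribute `"removal_log"`:
#'   a data frame (`stage`, `subpop`, `id`, `reason`) of removals. The filter
#'   is idempotent.
#' @export
filter_dataset <- function(ds, min_pop_size = 20L, max_missing_loci = 3L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!length(ds$id)) stop("empty dataset")
  n_miss <- rowSums(is.na(ds$a1))
  drop_ind <- n_miss > max_missing_loci
  log1 <- data.frame(stage = rep("individual", sum(drop_ind)),
                     subpop = as.character(ds$pop[drop_ind]),
                     id = ds$id[drop_ind],
                     reason = sprintf("%d missing loci > %d",
                                      n_miss[drop_ind], max_missing_loci),
                     stringsAsFactors = FALSE)
  out <- keep_individuals(ds, !drop_ind)

  sizes <- table(out$pop)
  small <- names(sizes)[sizes < min_pop_size]
  drop_pop <- as.character(out$pop) %in% small
  log2 <- data.frame(stage = rep("subpopulation", sum(drop_pop)),
                     subpop = as.character(out$pop[drop_pop]),
                     id = out$id[drop_pop],
                     reason = rep(sprintf("subpopulation below %d individuals",
                                          min_pop_size), sum(drop_pop)),
                     stringsAsFactors = FALSE)
  out <- keep_individuals(out, !drop_pop)
  if (!length(out$id)) stop("no analyzable subpopulations")
  attr(out, "removal_log") <- rbind(log1, log2)
  out
}

#' Write a removal log as delimited text
#'
#' @param ds a dataset returned by [filter_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(ds, path) {
  log <- attr(ds, "removal_log")
  if (is.null(log))
    log <- data.frame(stage = character(), subpop = character(),
                      id = character(), reason = character())
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-subpopulation and pooled allele frequencies
#'
#' Frequencies are computed over non-missing gene copies. Cells (subpop x
#' locus) with zero non-missing copies are flagged and left `NULL`.
#'
#' @param ds a [genotype_dataset()].
#' @return An object of class `allele_freq_table`: list with
#'   * `freq`: `freq[[pop]][[locus]]`, named numeric vector of relative
#'     frequencies;
#'   * `copies`: matrix (pop x locus) of non-missing gene-copy counts;
#'   * `pooled`: `pooled[[locus]]`, metapopulation frequencies;
#'   * `empty`: data frame of flagged (subpop, locus) cells with no data.
#' @export
allele_freqs <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!length(ds$id)) stop("empty dataset")
  pops <- levels(ds$pop)
  loci <- ds$loci
  copies <- matrix(0L, length(pops), length(loci),
                   dimnames = list(pops, loci))
  freq <- setNames(vector("list", length(pops)), pops)
  empty <- list()
  for (p in pops) {
    idx <- ds$pop == p
    freq[[p]] <- setNames(vector("list", length(loci)), loci)
    for (l in seq_along(loci)) {
      al <- c(ds$a1[idx, l], ds$a2[idx, l])
      al <- al[!is.na(al)]
      copies[p, l] <- length(al)
      if (!length(al)) {
        empty[[length(empty) + 1L]] <- data.frame(subpop = p, locus = loci[l])
        next
      }
      tab <- table(al)
      freq[[p]][[l]] <- setNames(as.numeric(tab) / length(al), names(tab))
    }
  }
  pooled <- setNames(vector("list", length(loci)), loci)
  for (l in seq_along(loci)) {
    al <- c(ds$a1[, l], ds$a2[, l])
    al <- al[!is.na(al)]
    if (length(al)) {
      tab <- table(al)
      pooled[[l]] <- setNames(as.numeric(tab) / length(al), names(tab))
    }
  }
  structure(list(freq = freq, copies = copies, pooled = pooled,
                 empty = if (length(empty)) do.call(rbind, empty)
                         else data.frame(subpop = character(),
                                         locus = character())),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("Allele frequency table:", nrow(x$copies), "subpopulations x",
      ncol(x$copies), "loci\n")
  if (nrow(x$empty))
    cat("  cells with no data:", nrow(x$empty), "\n")
  invisible(x)
}
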