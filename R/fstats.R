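#' Weir-Cockerham F-statistics
#'
#' Multi-locus variance-components estimators of FST (theta), FIS (f) and
#' FIT (F) following Weir and Cockerham (1984), summing components over
#' alleles and loci. Also returns Nei-type plug-in within-subpopulation
#' (`hs`, copy-weighted across demes so that `hs <= ht` always holds) and
#' total (`ht`) gene diversities and heterozygosity-standardized
#' analogues `fst_std`/`fit_std` (Hedrick's k-deme maximum; see
#' [standardize_fstat()]).
#'
#' Negative multi-locus estimates are reported as computed; standardization
#' clips to \[0, 1\].
#'
#' @param ds a [genotype_dataset()] with at least 2 subpopulations and one
#'   polymorphic locus.
#' @return An object of class `fstats_result`: list with `fst`, `fis`, `fit`,
#'   `fst_std`, `fit_std`, `hs`, `ht`, `k` (number of subpopulations) and
#'   `per_locus`, a data frame of per-locus components and estimates.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Evolution 38:1358-1370.
#' @export
weir_cockerham <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  r_pops <- nlevels(ds$pop)
  if (r_pops < 2L) stop("need at least 2 subpopulations")
  pops <- levels(ds$pop)
  L <- length(ds$loci)

  per <- data.frame(locus = ds$loci, a = NA_real_, b = NA_real_, c = NA_real_,
                    fst = NA_real_, fis = NA_real_, fit = NA_real_,
                    hs = NA_real_, ht = NA_real_, stringsAsFactors = FALSE)
  any_poly <- FALSE
  for (l in seq_len(L)) {
    comp <- wc_locus(ds, l, pops)
    if (is.null(comp)) next
    any_poly <- TRUE
    per$a[l] <- comp$a; per$b[l] <- comp$b; per$c[l] <- comp$c
    tot <- comp$a + comp$b + comp$c
    if (tot > 0) {
      per$fst[l] <- comp$a / tot
      per$fit[l] <- 1 - comp$c / tot
      if (comp$b + comp$c > 0) per$fis[l] <- 1 - comp$c / (comp$b + comp$c)
    }
    per$hs[l] <- comp$hs; per$ht[l] <- comp$ht
  }
  if (!any_poly) stop("FST undefined: all loci monomorphic")

  A <- sum(per$a, na.rm = TRUE); B <- sum(per$b, na.rm = TRUE)
  C <- sum(per$c, na.rm = TRUE)
  tot <- A + B + C
  fst <- A / tot
  fit <- 1 - C / tot
  fis <- 1 - C / (B + C)
  hs <- mean(per$hs, na.rm = TRUE)
  ht <- mean(per$ht, na.rm = TRUE)
  fst_std <- standardize_fstat(max(fst, 0), hs, r_pops)
  fit_std <- standardize_fstat(max(fit, 0), hs, r_pops)
  structure(list(fst = fst, fis = fis, fit = fit,
                 fst_std = fst_std, fit_std = fit_std,
                 hs = hs, ht = ht, k = r_pops, per_locus = per),
            class = "fstats_result")
}

# Weir-Cockerham variance components for one locus; NULL if monomorphic or
# fewer than 2 subpopulations have data.
wc_locus <- function(ds, l, pops) {
  a1 <- ds$a1[, l]; a2 <- ds$a2[, l]
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  pop <- ds$pop[ok]; a1 <- a1[ok]; a2 <- a2[ok]
  n_i <- as.numeric(table(pop)[pops]); names(n_i) <- pops
  use <- !is.na(n_i) & n_i > 0
  if (sum(use) < 2L) return(NULL)
  pops <- pops[use]; n_i <- n_i[use]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  r <- length(pops)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)

  a_sum <- b_sum <- c_sum <- 0
  hs_vals <- numeric(r); names(hs_vals) <- pops
  p_pool <- numeric(length(alleles))
  for (ai in seq_along(alleles)) {
    u <- alleles[ai]
    # per-pop allele frequency and observed heterozygote frequency for u
    p_iu <- h_iu <- numeric(r)
    for (pi in seq_len(r)) {
      idx <- pop == pops[pi]
      dos <- (a1[idx] == u) + (a2[idx] == u)
      p_iu[pi] <- sum(dos) / (2 * n_i[pi])
      h_iu[pi] <- mean(dos == 1L)
    }
    pbar <- sum(n_i * p_iu) / (r * nbar)
    p_pool[ai] <- pbar
    s2 <- sum(n_i * (p_iu - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_iu) / (r * nbar)
    a_u <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_u <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_u <- hbar / 2
    a_sum <- a_sum + a_u; b_sum <- b_sum + b_u; c_sum <- c_sum + c_u
  }
  for (pi in seq_len(r)) {
    idx <- pop == pops[pi]
    al <- c(a1[idx], a2[idx])
    p <- as.numeric(table(factor(al, levels = alleles))) / length(al)
    hs_vals[pi] <- 1 - sum(p^2)
  }
  # copy-weighted within-deme gene diversity; with the copy-weighted pooled
  # diversity this guarantees hs <= ht (Wahlund/Jensen), keeping the two on
  # the same (plug-in) scale
  list(a = a_sum, b = b_sum, c = c_sum,
       hs = sum(2 * n_i * hs_vals) / sum(2 * n_i), ht = 1 - sum(p_pool^2))
}

#' @export
print.fstats_result <- function(x, ...) {
  cat("Weir-Cockerham F-statistics over", nrow(x$per_locus), "loci,",
      x$k, "subpopulations\n")
  cat(sprintf("  FST = %.4f   FIS = %.4f   FIT = %.4f\n", x$fst, x$fis, x$fit))
  cat(sprintf("  F'ST = %.4f  F'IT = %.4f  (Hs = %.4f, Ht = %.4f)\n",
              x$fst_std, x$fit_std, x$hs, x$ht))
  invisible(x)
}

#' Standardize an F-statistic by its heterozygosity maximum
#'
#' Divides `f` by its maximum attainable value given mean within-subpopulation
#' heterozygosity `hs` and `k` demes (Hedrick's G'ST-type standardization):
#' `f' = f * (k - 1 + hs) / ((k - 1) * (1 - hs))`, clipped to \[0, 1\].
#'
#' @param f unitless F-statistic in \[0, 1).
#' @param hs mean within-subpopulation expected heterozygosity, `0 <= hs < 1`.
#' @param k number of demes, `>= 2`.
#' @return The standardized statistic, in \[0, 1\].
#' @references Hedrick, P.W. (2005) Evolution 59:1633-1638.
#' @export
standardize_fstat <- function(f, hs, k) {
  if (hs >= 1) stop("hs = 1: maximum F is 0, standardization undefined")
  if (hs < 0 || k < 2) stop("need 0 <= hs < 1 and k >= 2")
  fmax <- (k - 1) * (1 - hs) / (k - 1 + hs)
  min(max(f / fmax, 0), 1)
}

#' Garza-Williamson M-ratio
#'
#' `M = k / (r + 1)` with `k` the number of distinct alleles and r the
#' allelic range `(max - min) / repeat_unit` in repeat units. Values
#' well below 1 indicate missing allelic states, the signature of a
#' bottleneck under stepwise mutation.
#'
#' @param alleles_present integer allele sizes observed at a locus.
#' @param repeat_unit repeat-unit length (default 2); sizes not conforming to
#'   the repeat ladder are rounded to the nearest rung with a warning.
#' @return M in (0, 1\].
#' @references Garza, J.C. & Williamson, E.G. (2001) Mol Ecol 10:305-318.
#' @export
m_ratio <- function(alleles_present, repeat_unit = 2L) {
  al <- unique(as.numeric(alleles_present))
  al <- al[!is.na(al)]
  if (!length(al)) stop("empty allele set")
  if (length(al) == 1L) return(1)
  rel <- (al - min(al)) / repeat_unit
  if (any(abs(rel - round(rel)) > 1e-8)) {
    warning("allele sizes not multiples of repeat unit apart; rounding")
    rel <- round(rel)
  }
  k <- length(unique(rel))
  r <- max(rel)
  k / (r + 1)
}

#' Pairwise Weir-Cockerham FST between subpopulations
#'
#' @param ds a [genotype_dataset()] with >= 2 subpopulations.
#' @return Data frame with columns `pop1`, `pop2`, `fst`.
#' @export
pairwise_fst <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- levels(ds$pop)
  if (length(pops) < 2L) stop("need at least 2 subpopulations")
  cmb <- utils::combn(pops, 2L)
  out <- data.frame(pop1 = cmb[1, ], pop2 = cmb[2, ], fst = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    sub <- keep_individuals(ds, ds$pop %in% cmb[, i])
    sub$pop <- factor(as.character(sub$pop), levels = cmb[, i])
    out$fst[i] <- tryCatch(weir_cockerham(sub)$fst, error = function(e) NA_real_)
  }
  out
}

#' Write per-locus and global F-statistics as delimited text
#'
#' @param fs an `fstats_result` from [weir_cockerham()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fstats <- function(fs, path) {
  stopifnot(inherits(fs, "fstats_result"))
  glob <- data.frame(locus = "GLOBAL", a = NA, b = NA, c = NA,
                     fst = fs$fst, fis = fs$fis, fit = fs$fit,
                     hs = fs$hs, ht = fs$ht)
  write.table(rbind(fs$per_locus, glob), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
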