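#' Single-sample Ne estimate container
#'
#' @param method `"LD"` or `"ABC"`.
#' @param point point estimate in individuals (may be `Inf`).
#' @param ci_low,ci_high 95% interval bounds (`ci_high` may be `Inf`).
#' @param s_sample individuals used (harmonic mean over comparisons for LD).
#' @param n_comparisons allele-pair comparison count (LD) or accepted draws
#'   (ABC).
#' @param replicate replicate index or `NA`.
#' @param ... further fields stored alongside (e.g. `mean_r2`).
#' @return An object of class `ne_estimate`.
#' @export
ne_estimate <- function(method, point, ci_low, ci_high, s_sample,
                        n_comparisons, replicate = NA_integer_, ...) {
  stopifnot(method %in% c("LD", "ABC"))
  if (is.finite(point) && point <= 0) stop("Ne point estimate must be > 0")
  if (all(is.finite(c(ci_low, point, ci_high))) &&
      !(ci_low <= point + 1e-9 && point <= ci_high + 1e-9))
    stop("confidence bounds must bracket the point estimate")
  structure(list(method = method, point = point, ci_low = ci_low,
                 ci_high = ci_high, s_sample = s_sample,
                 n_comparisons = n_comparisons, replicate = replicate, ...),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) sprintf("%.1f", v) else "Inf"
  cat(sprintf("Ne (%s): %s  [95%%: %s - %s]  S = %.1f, comparisons = %d\n",
              x$method, fmt(x$point), fmt(x$ci_low), fmt(x$ci_high),
              x$s_sample, as.integer(x$n_comparisons)))
  invisible(x)
}

#' Mean squared Burrows composite-disequilibrium correlation
#'
#' For every pair of loci and every retained pair of alleles, computes the
#' squared correlation of allele dosages across individuals (the phase-free
#' Burrows composite measure of disequilibrium for unphased diploid data).
#' Alleles with frequency below `pcrit` (or above `1 - pcrit`) are screened
#' out to control the bias from rare alleles; `pcrit = "auto"` sets the
#' standard `1/(2S)` threshold. For a biallelic locus only one allele is used
#' (the second is its complement). Comparisons are weighted by the number of
#' individuals complete at both loci.
#'
#' @param ds_pop a single-subpopulation [genotype_dataset()].
#' @param pcrit minor-allele frequency cut-off, or `"auto"` for `1/(2S)`.
#' @return List with `mean_r2` (weighted mean squared correlation),
#'   `n_comparisons`, `s_harmonic` (harmonic-mean pairwise sample size), and
#'   `pcrit` as used.
#' @export
burrows_r2 <- function(ds_pop, pcrit = "auto") {
  stopifnot(inherits(ds_pop, "genotype_dataset"))
  if (nlevels(ds_pop$pop) != 1L)
    stop("burrows_r2 expects a single subpopulation; see pop_subset()")
  S <- length(ds_pop$id)
  if (identical(pcrit, "auto")) pcrit <- 1 / (2 * S)
  stopifnot(is.numeric(pcrit), pcrit >= 0, pcrit < 0.5)

  dose <- list(); locus_of <- integer(0)
  for (l in seq_along(ds_pop$loci)) {
    a1 <- ds_pop$a1[, l]; a2 <- ds_pop$a2[, l]
    al <- c(a1, a2); al <- al[!is.na(al)]
    if (!length(al)) next
    tab <- table(al)
    p <- as.numeric(tab) / length(al)
    keep <- p >= pcrit & p <= 1 - pcrit
    alleles <- as.integer(names(tab))[keep]
    if (length(alleles) < 1L) next
    if (length(tab) == 2L && length(alleles) == 2L) alleles <- alleles[1L]
    if (length(tab) < 2L) next  # monomorphic locus carries no signal
    for (u in alleles) {
      d <- (a1 == u) + (a2 == u)
      dose[[length(dose) + 1L]] <- d
      locus_of[length(locus_of) + 1L] <- l
    }
  }
  if (length(unique(locus_of)) < 2L)
    stop("insufficient comparisons: fewer than 2 polymorphic loci after screening")
  D <- do.call(cbind, dose)
  cc <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))
  obs <- !is.na(D)
  npair <- crossprod(obs)  # individuals complete at both columns

  cross <- outer(locus_of, locus_of, "!=") & upper.tri(cc)
  w <- npair[cross]
  # Burrows composite with the standard n/(n-1) small-sample correction on
  # Delta; as a correlation this is (n/(n-1)) * cor, hence the squared factor
  r2 <- cc[cross]^2 * (w / (w - 1))^2
  ok <- !is.na(r2) & w >= 2
  if (!any(ok)) stop("insufficient comparisons: no defined locus-pair correlations")
  r2 <- r2[ok]; w <- w[ok]
  list(mean_r2 = sum(w * r2) / sum(w),
       n_comparisons = length(r2),
       s_harmonic = length(r2) / sum(1 / w),
       pcrit = pcrit)
}

#' LD-based effective population size
#'
#' Converts a mean squared Burrows correlation into an estimate of the
#' effective number of parents. The sampling expectation under random mating,
#' `E = 1/S + 3.19/S^2` for `S >= 30` (`E = 0.0018 + 0.907/S + 4.44/S^2`
#' below, with a warning), is subtracted to give the drift signal
#' `r2' = mean_r2 - E`, and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`.
#' A non-positive `r2'` (or a negative discriminant) means no detectable
#' drift signal and yields an infinite estimate. Parametric confidence
#' bounds treat `n_comparisons` as chi-square degrees of freedom for
#' `mean_r2` (`r2_bound = mean_r2 * n / qchisq(q, n)`) and transform each
#' bound through the same formula; the known non-independence of comparisons
#' is accepted.
#'
#' @param mean_r2 weighted mean squared correlation from [burrows_r2()].
#' @param s_harmonic harmonic-mean sample size over comparisons.
#' @param n_comparisons number of allele-pair comparisons.
#' @param alpha two-sided error rate for the confidence interval.
#' @return An [ne_estimate()] with fields `mean_r2` and `r2_prime` attached.
#' @references Waples, R.S. (2006) Conserv Genet 7:167-184; Waples, R.S. &
#'   Do, C. (2008) Mol Ecol Resour 8:753-756.
#' @export
ld_ne <- function(mean_r2, s_harmonic, n_comparisons, alpha = 0.05) {
  if (n_comparisons < 1) stop("n_comparisons must be at least 1")
  small <- s_harmonic < 30
  if (small)
    warning("harmonic-mean sample size below 30; small-sample coefficients used")
  expected <- if (small) 0.0018 + 0.907 / s_harmonic + 4.44 / s_harmonic^2
              else 1 / s_harmonic + 3.19 / s_harmonic^2
  kq <- if (small) c(int = 0.308, disc = 0.308^2, quad = 2.08)
        else c(int = 1 / 3, disc = 1 / 9, quad = 2.76)
  ne_of <- function(r2) {
    r2p <- r2 - expected
    if (r2p <= 0) return(Inf)
    disc <- kq[["disc"]] - kq[["quad"]] * r2p
    if (disc < 0) return(Inf)
    (kq[["int"]] + sqrt(disc)) / (2 * r2p)
  }
  point <- ne_of(mean_r2)
  n <- n_comparisons
  r2_low <- mean_r2 * n / qchisq(1 - alpha / 2, df = n)
  r2_high <- mean_r2 * n / qchisq(alpha / 2, df = n)
  ne_estimate(method = "LD", point = point,
              ci_low = ne_of(r2_high), ci_high = ne_of(r2_low),
              s_sample = s_harmonic, n_comparisons = n_comparisons,
              mean_r2 = mean_r2, r2_prime = mean_r2 - expected,
              pcrit = NA_real_)
}

#' LD-Ne for every subpopulation of a dataset
#'
#' Convenience wrapper running [burrows_r2()] (with `pcrit = "auto"` by
#' default) and [ld_ne()] per subpopulation.
#'
#' @param ds a [genotype_dataset()].
#' @param pcrit minor-allele screening threshold or `"auto"`.
#' @param alpha CI error rate.
#' @return Named list of [ne_estimate()]s, one per subpopulation; failures
#'   (e.g. too few polymorphic loci) are stored as `NULL` with a warning.
#' @export
ld_ne_all <- function(ds, pcrit = "auto", alpha = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  out <- setNames(vector("list", nlevels(ds$pop)), levels(ds$pop))
  for (p in levels(ds$pop)) {
    est <- tryCatch({
      b <- burrows_r2(pop_subset(ds, p), pcrit = pcrit)
      e <- ld_ne(b$mean_r2, b$s_harmonic, b$n_comparisons, alpha = alpha)
      e$pcrit <- b$pcrit
      e
    }, error = function(e) {
      warning("LD-Ne failed for ", p, ": ", conditionMessage(e))
      NULL
    })
    out[[p]] <- est
  }
  out
}

#' Tabulate a list of Ne estimates
#'
#' @param estimates named list of [ne_estimate()]s (NULL entries allowed).
#' @return Data frame with one row per subpopulation.
#' @export
ne_table <- function(estimates) {
  rows <- lapply(names(estimates), function(p) {
    e <- estimates[[p]]
    if (is.null(e))
      return(data.frame(subpop = p, method = NA, S = NA, n_comparisons = NA,
                        mean_r2 = NA, r2_prime = NA, ne = NA,
                        ci_low = NA, ci_high = NA))
    data.frame(subpop = p, method = e$method, S = e$s_sample,
               n_comparisons = e$n_comparisons,
               mean_r2 = if (is.null(e$mean_r2)) NA else e$mean_r2,
               r2_prime = if (is.null(e$r2_prime)) NA else e$r2_prime,
               ne = e$point, ci_low = e$ci_low, ci_high = e$ci_high)
  })
  do.call(rbind, rows)
}
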