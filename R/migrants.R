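# per-locus global allele lists, per-pop count matrices and copy totals
pop_locus_counts <- function(ds) {
  pops <- levels(ds$pop)
  L <- length(ds$loci)
  alleles <- counts <- vector("list", L)
  copies <- matrix(0L, length(pops), L, dimnames = list(pops, ds$loci))
  for (l in seq_len(L)) {
    al_all <- c(ds$a1[, l], ds$a2[, l])
    glob <- sort(unique(al_all[!is.na(al_all)]))
    alleles[[l]] <- glob
    cm <- matrix(0L, length(glob), length(pops),
                 dimnames = list(glob, pops))
    for (p in pops) {
      idx <- ds$pop == p
      al <- c(ds$a1[idx, l], ds$a2[idx, l])
      al <- al[!is.na(al)]
      if (length(al)) {
        tab <- table(factor(al, levels = glob))
        cm[, p] <- as.integer(tab)
      }
      copies[p, l] <- length(al)
    }
    counts[[l]] <- cm
  }
  list(alleles = alleles, counts = counts, copies = copies,
       k = lengths(alleles), pops = pops)
}

#' Rannala-Mountain genotype log-likelihood
#'
#' Log-likelihood that a diploid multilocus genotype was drawn from a
#' reference subpopulation, with the equal-prior Dirichlet
#' posterior-predictive allele probability `(count + 1/k) / (copies + 1)`,
#' where `k` is the number of alleles observed at the locus across all
#' candidate populations (so unobserved alleles never get zero probability).
#' Genotype probabilities assume Hardy-Weinberg within the reference
#' (`p^2` / `2 p q`). With `leave_one_out` the focal individual's own two
#' allele copies are removed from the reference counts before scoring, as
#' required when the reference is the individual's sampling population.
#' Missing loci are skipped.
#'
#' @param a1,a2 integer allele vectors of the genotype (one entry per locus,
#'   `NA` = missing).
#' @param ref_counts list, per locus, of named integer allele counts in the
#'   reference subpopulation (names are allele codes).
#' @param k_alleles integer vector: alleles observed per locus across all
#'   populations.
#' @param leave_one_out remove the focal genotype's own alleles from the
#'   counts first.
#' @return The log-likelihood (natural log).
#' @references Rannala, B. & Mountain, J.L. (1997) PNAS 94:9197-9201.
#' @export
rm_loglik <- function(a1, a2, ref_counts, k_alleles, leave_one_out = FALSE) {
  L <- length(a1)
  stopifnot(length(a2) == L, length(ref_counts) == L, length(k_alleles) == L)
  ll <- 0
  for (l in seq_len(L)) {
    if (is.na(a1[l])) next
    cnt <- ref_counts[[l]]
    cp <- sum(cnt)
    k <- k_alleles[l]
    get <- function(a) {
      v <- cnt[as.character(a)]
      if (is.na(v)) 0 else as.numeric(v)
    }
    c1 <- get(a1[l]); c2 <- get(a2[l])
    if (leave_one_out) {
      if (a1[l] == a2[l]) c1 <- c2 <- c1 - 2 else { c1 <- c1 - 1; c2 <- c2 - 1 }
      cp <- cp - 2
      if (min(c1, c2) < 0)
        stop("leave-one-out requires the focal alleles to be in the counts")
    }
    denom <- cp + 1
    if (a1[l] == a2[l]) {
      ll <- ll + 2 * log((c1 + 1 / k) / denom)
    } else {
      ll <- ll + log(2) + log((c1 + 1 / k) / denom) +
        log((c2 + 1 / k) / denom)
    }
  }
  ll
}

# Vectorised log-likelihood of individuals (allele matrices) against every
# pop. ix1/ix2: n x L matrices of indices into tabs$alleles[[l]] (NA =
# missing). home: integer vector (pop index) or NULL; when given, the home
# column is replaced by the leave-one-out likelihood (own copies deducted,
# which requires the individuals' copies to be included in the counts --
# for simulated genotypes drawn without replacement from the gene pool the
# deduction is equally valid and keeps the null calibrated).
loglik_all_pops <- function(ix1, ix2, tabs, home = NULL) {
  n <- nrow(ix1); L <- ncol(ix1); s <- length(tabs$pops)
  LL <- matrix(0, n, s, dimnames = list(NULL, tabs$pops))
  for (l in seq_len(L)) {
    cm <- tabs$counts[[l]]
    k <- tabs$k[l]
    ok <- !is.na(ix1[, l])
    if (!any(ok)) next
    het <- ok & ix1[, l] != ix2[, l]
    for (p in seq_len(s)) {
      logp <- log((cm[, p] + 1 / k) / (tabs$copies[p, l] + 1))
      contrib <- rep(0, n)
      contrib[ok] <- logp[ix1[ok, l]] + logp[ix2[ok, l]] +
        log(2) * het[ok]
      LL[, p] <- LL[, p] + contrib
    }
    if (!is.null(home)) {
      c1 <- cm[cbind(ix1[, l], home)]
      c2 <- cm[cbind(ix2[, l], home)]
      cp <- tabs$copies[cbind(home, l)]
      d1 <- ifelse(het, c1 - 1, c1 - 2)
      d2 <- ifelse(het, c2 - 1, c2 - 2)
      loo <- ifelse(het,
                    log(2) + log((d1 + 1 / k) / (cp - 1)) +
                      log((d2 + 1 / k) / (cp - 1)),
                    2 * log((d1 + 1 / k) / (cp - 1)))
      hidx <- cbind(seq_len(n), home)
      LL[hidx] <- ifelse(ok, LL[hidx] -
        (log((c1 + 1 / k) / (cp + 1)) + log((c2 + 1 / k) / (cp + 1)) +
           log(2) * het) + loo, LL[hidx])
    }
  }
  LL
}

#' Detect first-generation immigrants
#'
#' For each individual the ratio of its genotype likelihood in its sampling
#' (home) population, `Lh`, to the maximum likelihood over all candidate
#' populations, `Lmax`, is computed with [rm_loglik()] scoring; the home
#' likelihood is leave-one-out. Significance of
#' `delta = log(Lh) - log(Lmax) <= 0` is assessed against a Monte Carlo null
#' of `n_mc` genotypes per population, resampled (two gene copies drawn
#' without replacement) from the home population's gene pool and scored
#' identically; `p = Pr(null delta <= observed delta)`. Individuals with
#' `p < alpha` are flagged as putative immigrants. The returned table doubles
#' as the likelihood scatter-plot data (`log_lh` vs `log_lmax`) used for
#' graphical screening.
#'
#' @param ds a [genotype_dataset()] with at least 2 subpopulations.
#' @param alpha type-I error rate (default 0.01).
#' @param n_mc Monte Carlo null size per population (values below 100 give
#'   an unstable tail and trigger a warning).
#' @param seed optional integer seed.
#' @return A data frame of class `migrant_flags`: `id`, `home_pop`,
#'   `best_pop`, `log_lh`, `log_lmax`, `delta`, `p_value`, `flagged`.
#' @export
detect_migrants <- function(ds, alpha = 0.01, n_mc = 1000L, seed = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (nlevels(ds$pop) < 2L) stop("need at least 2 subpopulations")
  if (n_mc < 100L) warning("n_mc below 100: unstable null tail")
  if (!is.null(seed)) set.seed(seed)
  tabs <- pop_locus_counts(ds)
  n <- length(ds$id); L <- length(ds$loci)

  to_index <- function(am) {
    ix <- matrix(NA_integer_, nrow(am), L)
    for (l in seq_len(L))
      ix[, l] <- match(am[, l], tabs$alleles[[l]])
    ix
  }
  ix1 <- to_index(ds$a1); ix2 <- to_index(ds$a2)
  home <- as.integer(ds$pop)
  LL <- loglik_all_pops(ix1, ix2, tabs, home = home)
  log_lh <- LL[cbind(seq_len(n), home)]
  log_lmax <- apply(LL, 1, max)
  best <- tabs$pops[max.col(LL, ties.method = "first")]
  delta <- log_lh - log_lmax

  # null distribution of delta per home population
  null_delta <- vector("list", length(tabs$pops))
  for (p in seq_along(tabs$pops)) {
    na1 <- matrix(NA_integer_, n_mc, L); na2 <- matrix(NA_integer_, n_mc, L)
    for (l in seq_len(L)) {
      cm <- tabs$counts[[l]][, p]
      pool <- rep(seq_along(cm), cm)  # gene pool as allele indices
      m2 <- length(pool)
      if (m2 < 2L) next
      pos1 <- sample.int(m2, n_mc, replace = TRUE)
      pos2 <- sample.int(m2 - 1L, n_mc, replace = TRUE)
      pos2 <- pos2 + (pos2 >= pos1)
      na1[, l] <- pool[pos1]; na2[, l] <- pool[pos2]
    }
    swap <- !is.na(na1) & na1 > na2
    tmp <- na1[swap]; na1[swap] <- na2[swap]; na2[swap] <- tmp
    LLn <- loglik_all_pops(na1, na2, tabs, home = rep(p, n_mc))
    null_delta[[p]] <- LLn[, p] - apply(LLn, 1, max)
  }
  p_value <- vapply(seq_len(n), function(i) {
    nd <- null_delta[[home[i]]]
    mean(nd <= delta[i])
  }, numeric(1))
  p_value[p_value == 0] <- 1 / (n_mc + 1)  # never exactly zero

  out <- data.frame(id = ds$id, home_pop = as.character(ds$pop),
                    best_pop = best, log_lh = log_lh, log_lmax = log_lmax,
                    delta = delta, p_value = p_value,
                    flagged = p_value < alpha, stringsAsFactors = FALSE)
  class(out) <- c("migrant_flags", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_mc") <- n_mc
  names(null_delta) <- tabs$pops
  attr(out, "null_delta") <- null_delta  # per-pop null deltas (diagnostics)
  out
}

#' @export
print.migrant_flags <- function(x, ...) {
  cat("Migrant screen:", nrow(x), "individuals,", sum(x$flagged),
      "flagged at alpha =", attr(x, "alpha"), "\n")
  if (any(x$flagged)) print.data.frame(x[x$flagged, ], row.names = FALSE)
  invisible(x)
}

#' Re-estimate Ne after excluding putative immigrants
#'
#' Removes flagged individuals from their home subpopulations and re-runs
#' the chosen estimator, returning paired "closed" (all individuals) and
#' "open" (migrants excluded) estimates per subpopulation. Subpopulations
#' falling below `min_pop_size` after exclusion are marked
#' `"insufficient after exclusion"`.
#'
#' @param ds a [genotype_dataset()].
#' @param flags a `migrant_flags` table from [detect_migrants()] computed on
#'   `ds`.
#' @param estimator `"LD"` or `"ABC"`.
#' @param min_pop_size minimum sample size for estimation.
#' @param cfg an [abc_config()] (ABC estimator only).
#' @param replicates ABC replicates (ABC estimator only).
#' @return Data frame with one row per subpopulation: sample sizes, removal
#'   count, closed and open point estimates and 95% bounds, and a status
#'   column. Attribute `"estimates"` holds the paired [ne_estimate()]s.
#' @export
exclude_and_reestimate <- function(ds, flags, estimator = c("LD", "ABC"),
                                   min_pop_size = 20L, cfg = abc_config(),
                                   replicates = 4L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(flags, "migrant_flags"))
  if (!all(flags$id %in% ds$id)) stop("flags were not computed on this dataset")
  drop_ids <- flags$id[flags$flagged]
  open_ds <- keep_individuals(ds, !(ds$id %in% drop_ids))

  one <- function(dsp) {
    if (estimator == "LD") {
      b <- burrows_r2(dsp, pcrit = "auto")
      ld_ne(b$mean_r2, b$s_harmonic, b$n_comparisons)
    } else abc_ne(dsp, cfg, replicates = replicates)
  }
  pops <- levels(ds$pop)
  ests <- list()
  rows <- lapply(pops, function(p) {
    closed_pop <- pop_subset(ds, p)
    n_rm <- sum(flags$flagged & flags$home_pop == p)
    open_pop <- if (p %in% levels(open_ds$pop)) pop_subset(open_ds, p) else NULL
    e_closed <- tryCatch(one(closed_pop), error = function(e) NULL)
    s_open <- if (is.null(open_pop)) 0L else length(open_pop$id)
    status <- "ok"
    e_open <- NULL
    if (s_open < min_pop_size) {
      status <- "insufficient after exclusion"
    } else if (n_rm == 0L) {
      e_open <- e_closed  # nothing removed: open estimate identical
    } else {
      e_open <- tryCatch(one(open_pop), error = function(e) NULL)
    }
    ests[[p]] <<- list(closed = e_closed, open = e_open)
    gv <- function(e, f) if (is.null(e)) NA_real_ else e[[f]]
    data.frame(subpop = p, S_closed = length(closed_pop$id),
               n_removed = n_rm, S_open = s_open,
               ne_closed = gv(e_closed, "point"),
               ci_low_closed = gv(e_closed, "ci_low"),
               ci_high_closed = gv(e_closed, "ci_high"),
               ne_open = gv(e_open, "point"),
               ci_low_open = gv(e_open, "ci_low"),
               ci_high_open = gv(e_open, "ci_high"),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- ests
  out
}
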