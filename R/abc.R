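#' ABC configuration
#'
#' Settings for the rejection-ABC single-sample Ne estimator: a uniform prior
#' on Ne between `ne_min` and `ne_max` (the standard 10-2000 microsatellite
#' survey prior), `n_sims` prior draws, the accepted quantile `tolerance`,
#' and the length of the ideal Wright-Fisher drift phase each simulated
#' population undergoes before being re-sampled.
#'
#' @param ne_min,ne_max uniform prior bounds on Ne (individuals).
#' @param n_sims number of prior draws.
#' @param tolerance accepted fraction of draws, in (0, 0.2].
#' @param drift_generations generations of drift at the candidate Ne before
#'   re-sampling; 6 lets unlinked-locus disequilibrium reach ~98% of its
#'   drift equilibrium (it halves each generation).
#' @param distance_stats which summary statistics enter the acceptance
#'   distance. All four are always computed and reported, but because the
#'   candidate populations are reconstituted from the sample's own allele
#'   frequencies, the sample is its own reference for the diversity
#'   statistics (`mean_alleles`, `he`, `m_ratio`): their observed-vs-
#'   simulated gap is a parametric-bootstrap conditioning artifact carrying
#'   no information about Ne, and including them biases acceptance towards
#'   the upper prior bound. The disequilibrium statistic `mean_r2` has a
#'   parameter-free sampling baseline and carries the drift signal, so it
#'   alone drives the distance by default.
#' @param seed integer seed or `NULL`.
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(ne_min = 10, ne_max = 2000, n_sims = 5000,
                       tolerance = 0.05, drift_generations = 6L,
                       distance_stats = "mean_r2", seed = NULL) {
  if (!(ne_min > 0 && ne_min < ne_max)) stop("need 0 < ne_min < ne_max")
  if (!(tolerance > 0 && tolerance <= 0.2))
    stop("tolerance must be in (0, 0.2]")
  all_stats <- c("mean_alleles", "he", "m_ratio", "mean_r2")
  if (!length(distance_stats) || !all(distance_stats %in% all_stats))
    stop("distance_stats must be a subset of: ",
         paste(all_stats, collapse = ", "))
  structure(list(ne_min = ne_min, ne_max = ne_max, n_sims = as.integer(n_sims),
                 tolerance = tolerance,
                 drift_generations = as.integer(drift_generations),
                 distance_stats = distance_stats, seed = seed),
            class = "abc_config")
}

# unbiased expected heterozygosity (gene diversity), mean over loci
expected_het <- function(a1, a2) {
  L <- ncol(a1)
  h <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    al <- c(a1[, l], a2[, l]); al <- al[!is.na(al)]
    if (length(al) < 2L) next
    p <- as.numeric(table(al)) / length(al)
    h[l] <- (1 - sum(p^2)) * length(al) / (length(al) - 1)
  }
  mean(h, na.rm = TRUE)
}

#' Summary statistics for ABC Ne estimation
#'
#' Four statistics that respond to effective size: mean number of alleles per
#' locus, unbiased expected heterozygosity, mean Garza-Williamson M-ratio,
#' and the mean squared Burrows disequilibrium correlation
#' ([burrows_r2()] with `pcrit = "auto"`).
#'
#' @param ds_pop a single-subpopulation [genotype_dataset()] with at least 2
#'   polymorphic loci.
#' @return Named numeric vector `mean_alleles`, `he`, `m_ratio`, `mean_r2`.
#' @export
summarize_sample <- function(ds_pop) {
  stopifnot(inherits(ds_pop, "genotype_dataset"))
  L <- length(ds_pop$loci)
  k <- m <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    al <- unique(c(ds_pop$a1[, l], ds_pop$a2[, l]))
    al <- al[!is.na(al)]
    if (!length(al)) next
    k[l] <- length(al)
    m[l] <- m_ratio(al, ds_pop$repeat_unit[l])
  }
  if (sum(k > 1, na.rm = TRUE) < 2L)
    stop("need at least 2 polymorphic loci for summary statistics")
  r2 <- burrows_r2(ds_pop, pcrit = "auto")$mean_r2
  c(mean_alleles = mean(k, na.rm = TRUE),
    he = expected_het(ds_pop$a1, ds_pop$a2),
    m_ratio = mean(m, na.rm = TRUE),
    mean_r2 = r2)
}

#' Rejection-ABC estimate of effective population size
#'
#' Simplified single-sample ABC in the spirit of coalescent-free Ne samplers:
#' candidate sizes are drawn uniformly from the prior; for each, an ideal
#' Wright-Fisher population of that size is initialized from the sample's
#' allele frequencies (Hardy-Weinberg genotypes), drifts
#' `drift_generations` generations (individual-based, so unlinked-locus
#' disequilibrium accumulates at its drift expectation), is re-sampled at the
#' observed sample size, and summarized with [summarize_sample()]'s four
#' statistics. Statistics are standardized by their median absolute deviation
#' across draws; the `tolerance` quantile of draws nearest the observed
#' vector (Euclidean distance over `cfg$distance_stats`; see [abc_config()]
#' for why the drift-informative disequilibrium statistic drives acceptance
#' by default) is accepted. The posterior point estimate is
#' the accepted median, with 2.5%/97.5% accepted quantiles as credible
#' limits.
#'
#' @param ds_pop a single-subpopulation [genotype_dataset()].
#' @param cfg an [abc_config()].
#' @return An [ne_estimate()] (method `"ABC"`) with fields `accepted`
#'   (accepted draws) and `observed` (observed summary statistics).
#' @export
abc_estimate <- function(ds_pop, cfg = abc_config()) {
  stopifnot(inherits(ds_pop, "genotype_dataset"), inherits(cfg, "abc_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- length(ds_pop$id)
  L <- length(ds_pop$loci)
  obs <- summarize_sample(ds_pop)

  # per-locus sample allele frequencies for initialization
  fr <- lapply(seq_len(L), function(l) {
    al <- c(ds_pop$a1[, l], ds_pop$a2[, l]); al <- al[!is.na(al)]
    tab <- table(al)
    list(codes = as.integer(names(tab)), p = as.numeric(tab) / length(al))
  })

  ne_draws <- runif(cfg$n_sims, cfg$ne_min, cfg$ne_max)
  stat_mat <- abc_sim_stats_cpp(lapply(fr, `[[`, "codes"),
                                lapply(fr, `[[`, "p"),
                                ne_draws, S, cfg$drift_generations,
                                ds_pop$repeat_unit)
  colnames(stat_mat) <- names(obs)
  ok <- complete.cases(stat_mat)
  if (!any(ok)) stop("all simulated draws produced undefined statistics")
  use <- cfg$distance_stats
  scale <- apply(stat_mat[ok, use, drop = FALSE], 2, stats::mad)
  sdv <- apply(stat_mat[ok, use, drop = FALSE], 2, sd)
  scale[!is.finite(scale) | scale == 0] <- sdv[!is.finite(scale) | scale == 0]
  scale[!is.finite(scale) | scale == 0] <- 1
  d <- sqrt(colSums((t(stat_mat[, use, drop = FALSE]) - obs[use])^2 /
                      scale^2))
  d[!ok] <- Inf
  n_accept <- max(1L, floor(cfg$tolerance * cfg$n_sims))
  acc <- order(d)[seq_len(n_accept)]
  accepted <- ne_draws[acc]
  if (!length(accepted)) stop("zero accepted draws: tolerance too small")
  q <- quantile(accepted, c(0.025, 0.5, 0.975), names = FALSE)
  ne_estimate(method = "ABC", point = q[2], ci_low = q[1], ci_high = q[3],
              s_sample = S, n_comparisons = n_accept,
              accepted = accepted, observed = obs)
}

#' Replicated ABC Ne with harmonic-mean aggregation
#'
#' Runs [abc_estimate()] `replicates` times with distinct seeds and
#' aggregates the posterior medians by harmonic mean, which damps the
#' influence of occasional very large replicates.
#'
#' @param ds_pop a single-subpopulation [genotype_dataset()].
#' @param cfg an [abc_config()]; its seed anchors the replicate seeds.
#' @param replicates number of replicate runs (default 4).
#' @return An [ne_estimate()] whose point is the harmonic mean of replicate
#'   medians, with `ci_low`/`ci_high` the extreme replicate credible limits
#'   and field `replicates` holding the per-replicate estimates.
#' @export
abc_ne <- function(ds_pop, cfg = abc_config(), replicates = 4L) {
  base_seed <- if (is.null(cfg$seed)) sample.int(2^30, 1) else cfg$seed
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- base_seed + r
    reps[[r]] <- abc_estimate(ds_pop, cfg_r)
    reps[[r]]$replicate <- r
  }
  pts <- vapply(reps, `[[`, numeric(1), "point")
  ne_estimate(method = "ABC", point = harmonic_mean(pts),
              ci_low = min(vapply(reps, `[[`, numeric(1), "ci_low")),
              ci_high = max(vapply(reps, `[[`, numeric(1), "ci_high")),
              s_sample = length(ds_pop$id),
              n_comparisons = reps[[1]]$n_comparisons,
              replicates = reps)
}

#' Harmonic mean of Ne values
#'
#' `n / sum(1/x)`; infinite values contribute zero to the reciprocal sum,
#' matching the convention that an infinite replicate carries no drift
#' signal.
#'
#' @param points positive Ne values, possibly including `Inf`.
#' @return The harmonic mean (individuals).
#' @export
harmonic_mean <- function(points) {
  if (!length(points)) stop("empty list of estimates")
  if (any(is.na(points)) || any(points <= 0))
    stop("all values must be positive (Inf allowed)")
  recip <- ifelse(is.infinite(points), 0, 1 / points)
  if (sum(recip) == 0) return(Inf)
  length(points) / sum(recip)
}
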