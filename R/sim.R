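#' Define a Wright-Fisher riverscape scenario
#'
#' Scenarios describe ideal monoecious Wright-Fisher demes (census = local
#' Ne) connected by a backward migration matrix: each offspring in deme i
#' draws its parental deme from row i, then two parents uniformly with
#' replacement from that deme. Microsatellite loci start with `init_alleles`
#' equifrequent allelic states and mutate stepwise (+/- one repeat unit) at
#' rate `mutation_rate` per allele copy per generation.
#'
#' @param census integer vector of deme sizes.
#' @param mig backward migration matrix (rows sum to 1), `s x s`.
#' @param n_loci number of unlinked loci.
#' @param mutation_rate stepwise mutation probability per copy per generation.
#' @param init_alleles number of equifrequent starting alleles per locus
#'   (10 gives initial expected heterozygosity 0.9).
#' @param sample_sizes individuals sampled per deme at the final generation;
#'   0 means the deme is not sampled. Must not exceed `census`.
#' @param generations number of non-overlapping generations to run.
#' @param labels deme labels.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(census, mig, n_loci = 12L, mutation_rate = 5e-4,
                         init_alleles = 10L, sample_sizes = census,
                         generations = 100L,
                         labels = paste0("P", seq_along(census))) {
  census <- as.integer(census)
  s <- length(census)
  mig <- as.matrix(mig)
  if (any(census < 2L)) stop("each deme needs census >= 2")
  if (!all(dim(mig) == s)) stop("migration matrix must be ", s, " x ", s)
  if (any(mig < 0) || any(abs(rowSums(mig) - 1) > 1e-8))
    stop("migration matrix rows must be non-negative and sum to 1")
  sample_sizes <- as.integer(rep_len(sample_sizes, s))
  if (any(sample_sizes > census)) stop("sample_sizes must not exceed census")
  if (length(labels) != s) stop("labels must match deme count")
  dimnames(mig) <- list(labels, labels)
  structure(list(census = setNames(census, labels), mig = mig,
                 n_loci = as.integer(n_loci), mutation_rate = mutation_rate,
                 init_alleles = as.integer(init_alleles),
                 sample_sizes = setNames(sample_sizes, labels),
                 generations = as.integer(generations), labels = labels),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Riverscape scenario:", length(x$census), "demes,",
      x$n_loci, "loci,", x$generations, "generations\n")
  cat("  census:", paste(sprintf("%s=%d", x$labels, x$census),
                         collapse = " "), "\n")
  cat(sprintf("  mean immigration rate: %.3f  mutation: %.1e  init alleles: %d\n",
              mean(1 - diag(x$mig)), x$mutation_rate, x$init_alleles))
  invisible(x)
}

#' Seven-pond riverscape scenarios
#'
#' Builds a scenario emulating a chain of seven linearly connected ponds in
#' which water flows P1 -> P2 -> P3 -> P4 -> P5 and P7 -> P6 -> P5. Ponds P1
#' and P7 sit above waterfalls impassable from below: they receive no
#' immigrants (emigration only). The remaining ponds receive downstream-biased
#' gene flow (80% of immigration from the upstream neighbour, 20% from the
#' downstream one; the confluence P5 draws equally on P4 and P6). The mean
#' immigration rate across the seven ponds is set to the species profile's
#' value.
#'
#' Profiles differ in mean immigration rate, locus number, deme size and
#' sampling, mirroring three salmonid community members with contrasting
#' structure: `"salar"`-like (strong structure, mean immigration 0.053, 12
#' loci, six ponds sampled), `"fontinalis"`-like (0.061, 13 loci, all seven
#' sampled) and `"alpinus"`-like (weak structure, 0.153, 11 loci, large demes,
#' only P2-P4 sampled).
#'
#' @param species_profile one of `"salar"`, `"fontinalis"`, `"alpinus"`.
#' @param ... overrides passed to [sim_scenario()] (e.g. `generations`,
#'   `census`, `mutation_rate`). Overriding `mig` is checked for
#'   row-stochasticity by the constructor.
#' @return A `sim_scenario`.
#' @export
make_humber_scenario <- function(species_profile = c("salar", "fontinalis",
                                                     "alpinus"), ...) {
  species_profile <- match.arg(species_profile)
  prof <- switch(species_profile,
    salar      = list(m_bar = 0.053, n_loci = 12L, census = 150L,
                      sampled = 1:6, n_sample = 76L),
    fontinalis = list(m_bar = 0.061, n_loci = 13L, census = 300L,
                      sampled = 1:7, n_sample = 100L),
    alpinus    = list(m_bar = 0.153, n_loci = 11L, census = 2000L,
                      sampled = 2:4, n_sample = 100L))
  s <- 7L
  upstream <- list(P2 = "P1", P3 = "P2", P4 = "P3", P5 = c("P4", "P6"),
                   P6 = "P7")
  downstream <- list(P2 = "P3", P3 = "P4", P4 = "P5", P5 = character(0),
                     P6 = "P5")
  labels <- paste0("P", 1:7)
  mig <- diag(1, s); dimnames(mig) <- list(labels, labels)
  m_in <- prof$m_bar * s / length(upstream)  # immigration per receiving pond
  for (p in names(upstream)) {
    up <- upstream[[p]]; dn <- downstream[[p]]
    up_share <- if (length(dn)) 0.8 else 1.0
    for (u in up) mig[p, u] <- up_share * m_in / length(up)
    for (d in dn) mig[p, d] <- (1 - up_share) * m_in
    mig[p, p] <- 1 - m_in
  }
  sample_sizes <- integer(s)
  sample_sizes[prof$sampled] <- prof$n_sample
  defaults <- list(census = rep(prof$census, s), mig = mig,
                   n_loci = prof$n_loci, sample_sizes = sample_sizes,
                   generations = 100L, labels = labels)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_scenario, args)
}

#' Run a riverscape scenario
#'
#' Simulates the scenario forward in time and samples the final generation
#' into a [genotype_dataset()] (sampled ponds only, without replacement).
#' Alleles are integer repeat scores starting at `100 .. 100+init_alleles-1`
#' (`repeat_unit = 1`), so datasets round-trip through Genepop's 3-digit
#' encoding.
#'
#' @param sc a [sim_scenario()].
#' @param track record heterozygosity trajectories (needed by
#'   [realized_meta_ne()]).
#' @return List with `dataset` (a `genotype_dataset`) and `truth` (class
#'   `sim_truth`): scenario snapshot, pooled and per-deme expected
#'   heterozygosity trajectories (generation 0 first).
#' @export
simulate_riverscape <- function(sc, track = TRUE) {
  stopifnot(inherits(sc, "sim_scenario"))
  n <- sum(sc$census)
  codes <- 100L + seq_len(sc$init_alleles) - 1L
  a1 <- matrix(sample(codes, n * sc$n_loci, replace = TRUE), n, sc$n_loci)
  a2 <- matrix(sample(codes, n * sc$n_loci, replace = TRUE), n, sc$n_loci)
  res <- wf_metapop_cpp(a1, a2, unname(sc$census), unname(sc$mig),
                        sc$generations, sc$mutation_rate, track)
  offsets <- c(0L, cumsum(sc$census))
  keep <- integer(0); pop <- character(0)
  for (d in seq_along(sc$census)) {
    ns <- sc$sample_sizes[d]
    if (ns == 0L) next
    pick <- offsets[d] + sample.int(sc$census[d], ns)
    keep <- c(keep, pick)
    pop <- c(pop, rep(sc$labels[d], ns))
  }
  if (!length(keep)) stop("scenario samples no ponds")
  id <- paste0(pop, "_", unlist(lapply(table(factor(pop, levels = unique(pop))),
                                       seq_len)))
  ds <- genotype_dataset(pop = factor(pop, levels = unique(pop)), id = id,
                         a1 = res$a1[keep, , drop = FALSE],
                         a2 = res$a2[keep, , drop = FALSE],
                         loci = paste0("L", seq_len(sc$n_loci)),
                         repeat_unit = 1L)
  truth <- structure(
    list(scenario = sc,
         het_trajectory = if (track) as.numeric(res$het_pooled) else NULL,
         subpop_het = if (track) {
           m <- res$het_sub; colnames(m) <- sc$labels; m
         } else NULL),
    class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$scenario$census), "demes,",
      x$scenario$generations, "generations\n")
  if (!is.null(x$het_trajectory))
    cat(sprintf("  pooled heterozygosity: %.3f -> %.3f\n",
                x$het_trajectory[1], tail(x$het_trajectory, 1)))
  invisible(x)
}

#' Realized metapopulation effective size from a heterozygosity trajectory
#'
#' The asymptotic rate of loss of pooled expected heterozygosity defines
#' meta-Ne: `H_t ~ lambda^t` with `lambda = 1 - 1/(2 Ne)`. With
#' `method = "slope"` the log-linear least-squares slope of `ln(H_t)` after
#' `burn_in` generations is used: `Ne = 1 / (2 (1 - exp(slope)))`. With
#' `method = "offset"` the trajectory is fitted as `H_t = C + A exp(r t)`,
#' which accommodates reducible riverscapes (two or more headwater sources)
#' whose pooled heterozygosity decays to a positive plateau rather than zero;
#' the decaying component's rate is then used. Requires a mutation-free run.
#'
#' @param truth a `sim_truth` from [simulate_riverscape()] run with
#'   `mutation_rate = 0` and `track = TRUE`.
#' @param burn_in generations discarded before fitting (default `4 s`, past
#'   the eigen-structure transient).
#' @param method `"slope"` (pure log-linear) or `"offset"` (plateau-corrected).
#' @return Realized meta-Ne in individuals.
#' @export
realized_meta_ne <- function(truth, burn_in = NULL,
                             method = c("slope", "offset")) {
  stopifnot(inherits(truth, "sim_truth"))
  method <- match.arg(method)
  if (truth$scenario$mutation_rate != 0)
    stop("realized meta-Ne requires a mutation-free run")
  H <- truth$het_trajectory
  if (is.null(H)) stop("scenario was run without trajectory tracking")
  s <- length(truth$scenario$census)
  if (is.null(burn_in)) burn_in <- 4L * s
  gen <- seq_along(H) - 1L
  use <- gen > burn_in
  if (sum(use) < 10L) stop("trajectory too short after burn-in")
  H <- H[use]; gen <- gen[use]
  if (any(H <= 0)) stop("heterozygosity hit 0 before fit window; ",
                        "increase loci or census")
  sl <- unname(coef(lm(log(H) ~ gen))[2])
  if (method == "offset") {
    C0 <- max(min(H) * 0.5, 1e-6)
    fit <- tryCatch(
      nls(H ~ C + A * exp(r * gen),
          start = list(C = C0, A = max(H[1] - C0, 1e-3),
                       r = min(sl * 2, -1e-7)),
          control = list(maxiter = 500, warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      r <- coef(fit)[["r"]]
      if (is.finite(r) && r < 0) sl <- r
    }
  }
  if (sl >= 0) return(Inf)
  1 / (2 * (1 - exp(sl)))
}
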