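#' Compare Ne estimates among species
#'
#' Kruskal-Wallis test of the (harmonic-mean) per-subpopulation Ne values
#' grouped by species, one-tailed Mann-Whitney tests for every ordered pair
#' in the hypothesized direction, and an exact two-tailed Kendall rank
#' correlation of Ne against sample size within each species. Infinite
#' estimates carry no rank information about magnitude and are excluded
#' (the exclusion count is reported). Mann-Whitney p-values are exact
#' (full-enumeration) up to a combined group size of 30 and normal-
#' approximated above; Kendall correlations are skipped for species with
#' fewer than 4 finite estimates.
#'
#' @param ne_by_subpop data frame with columns `species`, `subpop`, `ne` and
#'   optionally `sample_size`.
#' @param order character vector of species labels in hypothesized increasing
#'   Ne order (default: the factor/appearance order of `species`).
#' @return An object of class `species_comparison`: list with `kw_chi2`,
#'   `kw_df`, `kw_p`, `pairwise` (data frame of one-tailed tests), `kendall`
#'   (per-species tau and exact p, or `NA` when skipped), `n_excluded`.
#' @export
compare_species <- function(ne_by_subpop, order = NULL) {
  df <- as.data.frame(ne_by_subpop)
  stopifnot(all(c("species", "ne") %in% names(df)))
  if (is.null(order)) order <- unique(as.character(df$species))
  df$species <- factor(as.character(df$species), levels = order)
  if (anyNA(df$species)) stop("species present that are not in 'order'")
  fin <- is.finite(df$ne)
  n_excluded <- sum(!fin)
  df <- df[fin, , drop = FALSE]
  counts <- table(df$species)
  if (sum(counts >= 2) < 2L)
    stop("need at least 2 species with at least 2 finite estimates")

  kw <- kruskal.test(df$ne, df$species)

  pairs <- utils::combn(order, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    lo <- pairs[1, i]; hi <- pairs[2, i]
    x <- df$ne[df$species == lo]; y <- df$ne[df$species == hi]
    if (length(x) < 1L || length(y) < 1L)
      return(data.frame(lower = lo, higher = hi, n_lower = length(x),
                        n_higher = length(y), U = NA_real_, p = NA_real_))
    exact <- (length(x) + length(y)) <= 30 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "less", exact = exact))
    data.frame(lower = lo, higher = hi, n_lower = length(x),
               n_higher = length(y), U = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pw)

  kendall <- lapply(order, function(sp) {
    sub <- df[df$species == sp, , drop = FALSE]
    if (!"sample_size" %in% names(sub) || nrow(sub) < 4L)
      return(data.frame(species = sp, n = nrow(sub), tau = NA_real_,
                        p = NA_real_))
    exact <- !any(duplicated(sub$ne)) && !any(duplicated(sub$sample_size))
    ct <- suppressWarnings(cor.test(sub$ne, sub$sample_size,
                                    method = "kendall", exact = exact))
    data.frame(species = sp, n = nrow(sub), tau = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  structure(list(kw_chi2 = unname(kw$statistic), kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, pairwise = pairwise,
                 kendall = do.call(rbind, kendall),
                 n_excluded = n_excluded, order = order),
            class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi2 = %.3g, df = %d, p = %.3g\n",
              x$kw_chi2, x$kw_df, x$kw_p))
  cat("One-tailed Mann-Whitney (hypothesized direction lower < higher):\n")
  print.data.frame(x$pairwise, row.names = FALSE, digits = 3)
  cat("Kendall tau (Ne vs sample size, exact two-tailed):\n")
  print.data.frame(x$kendall, row.names = FALSE, digits = 3)
  if (x$n_excluded)
    cat("Excluded infinite estimates:", x$n_excluded, "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: load (Genepop) or simulate (scenario) genotypes; filter;
#' F-statistics; closed-population LD and ABC Ne per subpopulation; migrant
#' detection and migrant-excluded ("open") re-estimation; the meta-Ne model
#' suite. Each stage writes a delimited table under `out_dir` plus a
#' machine-readable `summary.json`; a failed stage is recorded and later
#' independent stages still run. All stochastic stages derive their seeds
#' from `config$seed`, so identical configurations reproduce identical
#' output.
#'
#' @param config list (or path to a YAML file) with entries:
#' \describe{
#'   \item{input}{either `list(genepop = "path")` or
#'     `list(scenario = <sim_scenario or list(profile=, ...)>)`; exactly one.}
#'   \item{seed}{integer master seed.}
#'   \item{out_dir}{output directory (created if absent); `NULL` for none.}
#'   \item{filter}{optional `list(min_pop_size=, max_missing_loci=)`.}
#'   \item{abc}{optional [abc_config()] arguments as a list, plus
#'     `replicates`.}
#'   \item{migrants}{optional `list(alpha=, n_mc=)`.}
#'   \item{meta}{optional `list(migration_matrix = path or matrix,
#'     habitat = list(L=, sigma2=, b=), use_standardized=)`. For scenario
#'     input the scenario's own migration matrix is the default.}
#' }
#' @return A list of class `pipeline_report` with per-stage results and a
#'   `stages` status table, invisibly written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$input))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  status <- list()
  report <- list(config = config, seed = seed)
  note <- function(stage, ok, msg = "") {
    status[[stage]] <<- data.frame(stage = stage,
                                   status = if (ok) "ok" else "failed",
                                   message = msg, stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch({ v <- force(expr); note(name, TRUE); v },
             error = function(e) { note(name, FALSE, conditionMessage(e)); NULL })
  }
  emit <- function(obj, file) {
    if (!is.null(out_dir) && !is.null(obj))
      write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }

  # --- input ------------------------------------------------------------
  scenario_truth <- NULL
  ds <- stage("input", {
    inp <- config$input
    if (!is.null(inp$genepop) && !is.null(inp$scenario))
      stop("config must give exactly one input source")
    if (!is.null(inp$genepop)) {
      read_genepop(inp$genepop)
    } else if (!is.null(inp$scenario)) {
      sc <- inp$scenario
      if (!inherits(sc, "sim_scenario")) {
        prof <- if (is.null(sc$profile)) "salar" else sc$profile
        sc <- do.call(make_humber_scenario,
                      c(list(species_profile = prof),
                        sc[setdiff(names(sc), "profile")]))
      }
      set.seed(seed)
      sim <- simulate_riverscape(sc, track = FALSE)
      scenario_truth <<- sim$truth
      sim$dataset
    } else stop("config$input needs 'genepop' or 'scenario'")
  })
  if (is.null(ds)) {
    report$stages <- do.call(rbind, status)
    return(invisible(structure(report, class = "pipeline_report")))
  }

  # --- filter -----------------------------------------------------------
  f <- config$filter
  ds <- stage("filter", do.call(filter_dataset, c(list(ds), f))) %||% ds
  if (!is.null(out_dir)) write_removal_log(ds, file.path(out_dir, "removals.tsv"))

  # --- F-statistics -----------------------------------------------------
  fs <- stage("fstats", weir_cockerham(ds))
  if (!is.null(fs) && !is.null(out_dir))
    write_fstats(fs, file.path(out_dir, "fstats.tsv"))

  # --- closed-population Ne --------------------------------------------
  set.seed(seed + 1L)
  ld <- stage("ld_ne", ld_ne_all(ds))
  abc_args <- config$abc %||% list()
  reps <- abc_args$replicates %||% 4L
  abc_args$replicates <- NULL
  cfg <- do.call(abc_config, c(abc_args[setdiff(names(abc_args), "seed")],
                               list(seed = seed + 2L)))
  abc <- stage("abc_ne", {
    out <- setNames(vector("list", nlevels(ds$pop)), levels(ds$pop))
    for (p in levels(ds$pop)) {
      cfg_p <- cfg; cfg_p$seed <- cfg$seed + 10L * match(p, levels(ds$pop))
      out[[p]] <- tryCatch(abc_ne(pop_subset(ds, p), cfg_p, replicates = reps),
                           error = function(e) NULL)
    }
    out
  })
  emit(if (!is.null(ld)) ne_table(ld), "ne_ld.tsv")
  emit(if (!is.null(abc)) ne_table(abc), "ne_abc.tsv")

  # --- migrants and open re-estimation ---------------------------------
  mg <- config$migrants %||% list()
  flags <- stage("migrants",
                 detect_migrants(ds, alpha = mg$alpha %||% 0.01,
                                 n_mc = mg$n_mc %||% 1000L,
                                 seed = seed + 3L))
  emit(flags, "migrant_flags.tsv")
  open_tab <- NULL
  if (!is.null(flags)) {
    set.seed(seed + 4L)
    open_tab <- stage("open_ne",
                      exclude_and_reestimate(ds, flags, estimator = "LD"))
    emit(open_tab, "ne_open_ld.tsv")
  }

  # --- meta-Ne suite ----------------------------------------------------
  meta_cfg <- config$meta %||% list()
  mig <- meta_cfg$migration_matrix
  if (is.character(mig)) mig <- read_migration_matrix(mig)
  if (is.null(mig) && !is.null(scenario_truth)) {
    sc <- scenario_truth$scenario
    sampled <- names(sc$sample_sizes)[sc$sample_sizes > 0]
    if (setequal(sampled, sc$labels)) mig <- migration_matrix(sc$mig)
  }
  if (!is.null(mig)) mig <- migration_matrix(as.matrix(mig))
  habitat <- meta_cfg$habitat
  if (is.list(habitat) && !inherits(habitat, "habitat_params"))
    habitat <- do.call(habitat_params, habitat)
  meta <- stage("meta_ne", {
    ests <- abc %||% ld
    if (is.null(ests)) stop("no local Ne estimates available")
    meta_ne_suite(ests, fstats = fs, mig = mig, habitat = habitat,
                  use_standardized = meta_cfg$use_standardized %||% TRUE)
  })
  emit(meta, "meta_ne.tsv")

  report$dataset <- ds
  report$truth <- scenario_truth
  report$fstats <- fs
  report$ld <- ld
  report$abc <- abc
  report$migrants <- flags
  report$open <- open_tab
  report$meta <- meta
  report$stages <- do.call(rbind, status)

  if (!is.null(out_dir)) {
    summary_json <- list(
      seed = seed,
      n_individuals = length(ds$id),
      subpops = as.list(pop_sizes(ds)),
      fst = if (!is.null(fs)) fs$fst else NULL,
      fst_std = if (!is.null(fs)) fs$fst_std else NULL,
      ne_ld = if (!is.null(ld)) lapply(ld, function(e)
        if (is.null(e)) NULL else unclass(e)[c("point", "ci_low", "ci_high")])
        else NULL,
      ne_abc = if (!is.null(abc)) lapply(abc, function(e)
        if (is.null(e)) NULL else unclass(e)[c("point", "ci_low", "ci_high")])
        else NULL,
      n_flagged = if (!is.null(flags)) sum(flags$flagged) else NULL,
      meta_ne = if (!is.null(meta))
        setNames(as.list(meta$estimate), meta$model) else NULL,
      stages = lapply(status, function(x) x$status))
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(structure(report, class = "pipeline_report"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  print.data.frame(x$stages, row.names = FALSE)
  if (!is.null(x$meta)) print(x$meta)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
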