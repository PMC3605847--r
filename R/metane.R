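#' Backward migration matrix
#'
#' `m[i, j]` is the probability that a gene sampled in subpopulation i
#' descends from subpopulation j one generation back; rows must sum to 1.
#' The mean immigration rate is `mean(1 - diag(m))`.
#'
#' @param m square numeric matrix.
#' @param labels subpopulation labels (defaults to existing dimnames or
#'   `P1..Ps`).
#' @return A validated matrix of class `migration_matrix`.
#' @export
migration_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  s <- nrow(m)
  if (ncol(m) != s) stop("migration matrix must be square")
  if (any(m < 0) || any(m > 1)) stop("migration rates must be in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-12))
    stop("migration matrix rows must sum to 1 (tolerance 1e-12)")
  if (is.null(labels))
    labels <- if (!is.null(rownames(m))) rownames(m) else paste0("P", seq_len(s))
  dimnames(m) <- list(labels, labels)
  class(m) <- c("migration_matrix", "matrix")
  m
}

#' Mean immigration rate of a migration matrix
#' @param m a [migration_matrix()] (or plain row-stochastic matrix).
#' @return `mean(1 - diag(m))`.
#' @export
mean_immigration <- function(m) mean(1 - diag(as.matrix(m)))

#' Read/write a migration matrix as a delimited table
#'
#' The format is an `s x s` table with header labels and the row label in
#' the first column.
#'
#' @param path file path.
#' @return [read_migration_matrix()]: a `migration_matrix`;
#'   the writer returns `path` invisibly.
#' @export
read_migration_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  migration_matrix(as.matrix(df), labels = rownames(df))
}

#' @rdname read_migration_matrix
#' @param m a migration matrix.
#' @export
write_migration_matrix <- function(m, path) {
  df <- data.frame(subpop = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Habitat parameters for spatial meta-Ne models
#'
#' @param L linear habitat length (km), `> 0`.
#' @param D effective linear density (individuals/km); computed as
#'   `sum(Ne)/L` where needed if omitted.
#' @param sigma2 variance of dispersal distance (km^2); derived from `b`
#'   via [sigma2_from_ibd()] if omitted.
#' @param b isolation-by-distance slope (per km; see [ibd_slope()]).
#' @return An object of class `habitat_params`.
#' @export
habitat_params <- function(L, D = NULL, sigma2 = NULL, b = NULL) {
  if (L <= 0) stop("habitat length L must be positive")
  if (!is.null(D) && D < 0) stop("density D must be >= 0")
  if (!is.null(sigma2) && !is.na(sigma2) && sigma2 < 0)
    stop("sigma2 must be >= 0")
  structure(list(L = L, D = D, sigma2 = sigma2, b = b),
            class = "habitat_params")
}

meta_ne_result <- function(model, estimate, ci_low = NA_real_,
                           ci_high = NA_real_, inputs = list()) {
  if (is.finite(estimate) && estimate <= 0)
    stop("meta-Ne estimate must be positive")
  structure(list(model = model, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, inputs = inputs),
            class = "meta_ne")
}

#' @export
print.meta_ne <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else if (is.finite(v))
    sprintf("%.1f", v) else "Inf"
  cat(sprintf("meta-Ne [%s]: %s", x$model, fmt(x$estimate)))
  if (!is.na(x$ci_low) || !is.na(x$ci_high))
    cat(sprintf("  [95%%: %s - %s]", fmt(x$ci_low), fmt(x$ci_high)))
  cat("\n")
  invisible(x)
}

#' Null-model meta-Ne: sum of local estimates
#'
#' The null model simply sums the local Ne estimates. Its 95% bounds are
#' propagated per side: each component's bound is converted to a pseudo
#' standard error (`(point - ci_low)/1.96`, `(ci_high - point)/1.96`; the
#' two sides may differ) and the per-side SEs combine as
#' `sqrt(sum(SE^2))`. Infinite components propagate to infinity.
#'
#' @param estimates list of [ne_estimate()]s (at least one finite).
#' @return A `meta_ne` (model `"null"`).
#' @export
null_meta_ne <- function(estimates) {
  estimates <- estimates[!vapply(estimates, is.null, logical(1))]
  if (!length(estimates)) stop("empty list of estimates")
  pts <- vapply(estimates, `[[`, numeric(1), "point")
  los <- vapply(estimates, `[[`, numeric(1), "ci_low")
  his <- vapply(estimates, `[[`, numeric(1), "ci_high")
  if (!any(is.finite(pts))) stop("need at least one finite estimate")
  point <- sum(pts)
  se_low <- sqrt(sum(((pts - los) / 1.96)^2))
  se_high <- sqrt(sum(((his - pts) / 1.96)^2))
  meta_ne_result("null", point,
                 ci_low = max(point - 1.96 * se_low, 0),
                 ci_high = point + 1.96 * se_high,
                 inputs = list(s = length(pts), points = pts))
}

#' Island-model meta-Ne
#'
#' `meta-Ne = sum(Ne) / (1 - FST)`: under island-model structure the
#' metapopulation retains diversity longer than the pooled demes, the excess
#' growing with divergence.
#'
#' @param sum_ne sum of local Ne estimates.
#' @param fst global divergence, `0 <= fst < 1` (values `>= 1` give `Inf`
#'   with a warning).
#' @return A `meta_ne` (model `"island"`).
#' @export
island_meta_ne <- function(sum_ne, fst) {
  if (fst < 0) stop("fst must be >= 0")
  if (fst >= 1) {
    warning("fst >= 1: island meta-Ne is infinite")
    return(meta_ne_result("island", Inf, inputs = list(sum_ne = sum_ne,
                                                       fst = fst)))
  }
  meta_ne_result("island", sum_ne / (1 - fst),
                 inputs = list(sum_ne = sum_ne, fst = fst))
}

#' Circular stepping-stone meta-Ne
#'
#' Maruyama's circular stepping-stone habitat: s demes of mean size `ne_bar`
#' exchanging a total fraction `m_bar` with their two neighbours. Via the
#' mean pairwise coalescence time of the model
#' (`meta-Ne = s*ne_bar + (s^2 - 1)/(24 m_bar)`), the estimate exceeds
#' `s*ne_bar`, grows as immigration declines, and tends to `s*ne_bar` under
#' strong migration.
#'
#' @param s number of demes, `>= 2`.
#' @param ne_bar mean local Ne.
#' @param m_bar mean immigration rate, `0 < m_bar <= 1` (0 gives `Inf`).
#' @return A `meta_ne` (model `"stepping_stone"`).
#' @export
stepping_stone_meta_ne <- function(s, ne_bar, m_bar) {
  if (s < 2) stop("need s >= 2 demes")
  if (m_bar < 0 || m_bar > 1) stop("m_bar must be in [0, 1]")
  est <- if (m_bar == 0) Inf else s * ne_bar + (s^2 - 1) / (24 * m_bar)
  meta_ne_result("stepping_stone", est,
                 inputs = list(s = s, ne_bar = ne_bar, m_bar = m_bar))
}

#' Linear-habitat (neighborhood) meta-Ne
#'
#' Wright-Maruyama continuous linear habitat of length `L` with density `D`
#' and dispersal variance `sigma2` per generation. Via mean pairwise
#' coalescence time, `meta-Ne = sum(Ne) * (1 + L / (8 D sigma2))`, which at
#' `D = sum(Ne)/L` equals `D L + L^2/(8 sigma2)`: the estimate exceeds the
#' null sum, grows with habitat length and shrinks with density. Without
#' isolation by distance (undefined `sigma2`) the model is not applicable.
#'
#' @param h a [habitat_params()]; `sigma2` (directly or via `b`) is required.
#' @param sum_ne sum of local Ne estimates.
#' @return A `meta_ne` (model `"neighborhood"`).
#' @export
neighborhood_meta_ne <- function(h, sum_ne) {
  stopifnot(inherits(h, "habitat_params"))
  D <- if (is.null(h$D)) sum_ne / h$L else h$D
  sigma2 <- h$sigma2
  if (is.null(sigma2) && !is.null(h$b) && !is.na(h$b) && h$b > 0)
    sigma2 <- sigma2_from_ibd(h$b, D)
  if (is.null(sigma2) || is.na(sigma2) || sigma2 <= 0)
    stop("not applicable: no isolation by distance (sigma2 undefined)")
  meta_ne_result("neighborhood", sum_ne * (1 + h$L / (8 * D * sigma2)),
                 inputs = list(L = h$L, D = D, sigma2 = sigma2,
                               sum_ne = sum_ne))
}

#' Dispersal variance from the isolation-by-distance slope
#'
#' Inverts Rousset's relation `4 D sigma2 = 1/b` for a linear habitat:
#' `sigma2 = 1 / (4 D b)`.
#'
#' @param b isolation-by-distance slope (per km), `> 0`.
#' @param d effective linear density (individuals/km), `> 0`.
#' @return `sigma2` in km^2.
#' @references Rousset, F. (1997) Genetics 145:1219-1228.
#' @export
sigma2_from_ibd <- function(b, d) {
  if (is.na(b) || b <= 0) stop("no isolation by distance (slope <= 0)")
  if (d <= 0) stop("density must be positive")
  1 / (4 * d * b)
}

#' Isolation-by-distance slope
#'
#' Least-squares slope of Rousset's linearization `fst/(1 - fst)` against
#' waterway distance.
#'
#' @param pairwise_fst pairwise FST values (at least 3 pairs).
#' @param distances matching distances (km).
#' @return The slope `b` (per km).
#' @export
ibd_slope <- function(pairwise_fst, distances) {
  stopifnot(length(pairwise_fst) == length(distances))
  ok <- is.finite(pairwise_fst) & is.finite(distances)
  if (sum(ok) < 3L) stop("need at least 3 pairs")
  if (var(distances[ok]) == 0) stop("zero distance variance")
  y <- pairwise_fst[ok] / (1 - pairwise_fst[ok])
  unname(coef(lm(y ~ distances[ok]))[2])
}

#' Interdemic meta-Ne
#'
#' `meta-Ne = sum(Ne) / (1 + FIT)`: variable reproductive success among
#' demes (metapopulation inbreeding) shrinks the effective size below the
#' null sum.
#'
#' @param sum_ne sum of local Ne estimates.
#' @param fit global inbreeding coefficient, `> -1`.
#' @return A `meta_ne` (model `"interdemic"`).
#' @export
interdemic_meta_ne <- function(sum_ne, fit) {
  if (fit <= -1) stop("fit must be > -1")
  meta_ne_result("interdemic", sum_ne / (1 + fit),
                 inputs = list(sum_ne = sum_ne, fit = fit))
}

#' Spatiotemporal meta-Ne
#'
#' Kobayashi-Yamamura-type estimate centred on the average number of
#' contemporary immigrants per deme per generation,
#' `M = ne_bar * m_bar`: `meta-Ne = s * ne_bar * (1 + 1/(4 M))`. The excess
#' over the null sum grows as migrants become scarce and vanishes under
#' abundant migration, paralleling the island model expressed through `M`
#' instead of `FST`.
#'
#' @param s number of demes.
#' @param ne_bar mean local Ne.
#' @param m_big migrants per generation `M`; computed as `ne_bar * m_bar`
#'   when omitted.
#' @param m_bar mean immigration rate (used only to derive `m_big`).
#' @return A `meta_ne` (model `"spatiotemporal"`).
#' @export
spatiotemporal_meta_ne <- function(s, ne_bar, m_big = NULL, m_bar = NULL) {
  if (is.null(m_big)) {
    if (is.null(m_bar)) stop("supply m_big or m_bar")
    m_big <- ne_bar * m_bar
  }
  if (m_big < 0) stop("m_big must be >= 0")
  est <- if (m_big == 0) Inf else s * ne_bar * (1 + 1 / (4 * m_big))
  meta_ne_result("spatiotemporal", est,
                 inputs = list(s = s, ne_bar = ne_bar, m_big = m_big))
}

#' Tufto-Hindar eigenvalue meta-Ne
#'
#' The bottom-up model for arbitrary deme sizes and asymmetric migration.
#' Probabilities of non-identity `g[i,j]` of random gene pairs from
#' subpopulations i and j obey the linear recursion
#' `g'[i,j] = sum_{k,l} m[i,k] m[j,l] (1 - d(k,l)/(2 Ne_k)) g[k,l]`
#' (with `d(k,l)` the Kronecker delta), i.e. a `s^2 x s^2` matrix A built
#' from the backward migration matrix and local sizes. The dominant
#' eigenvalue lambda of A is the asymptotic per-generation retention rate of
#' diversity, and `meta-Ne = 1 / (2 (1 - lambda))`.
#'
#' Gene pairs that can never coalesce (e.g. pairs spanning two fully
#' isolated demes or two headwater sources) create structural eigenvalue-1
#' modes; these non-decaying modes are excluded (tolerance 1e-12) so the
#' estimate reflects the dominant decaying mode. With identity migration
#' this yields `max(Ne_i)`; with a single deme it is exact.
#'
#' @param ne vector of local effective sizes (all `> 0`).
#' @param mig a [migration_matrix()] of matching dimension.
#' @return A `meta_ne` (model `"tufto_hindar"`) whose `inputs` carry
#'   `lambda` and the leading right eigenvector (s x s, scaled to max 1),
#'   the asymptotic structure of diversity.
#' @references Tufto, J. & Hindar, K. (2003) Theor Popul Biol 64:273-280.
#' @export
tufto_hindar_meta_ne <- function(ne, mig) {
  mig <- migration_matrix(unclass(as.matrix(mig)))
  s <- nrow(mig)
  if (length(ne) != s) stop("length(ne) must equal migration matrix dimension")
  if (any(!is.finite(ne)) || any(ne <= 0)) stop("all ne must be finite and > 0")
  # column (k,l) index: (k-1)*s + l; kronecker(M, M) has exactly that layout
  dvec <- rep(1, s * s)
  diag_cols <- ((seq_len(s) - 1) * s) + seq_len(s)
  dvec[diag_cols] <- 1 - 1 / (2 * ne)
  A <- kronecker(unclass(mig), unclass(mig)) *
    matrix(dvec, s * s, s * s, byrow = TRUE)
  eig <- eigen(A)
  mods <- Mod(eig$values)
  decaying <- mods < 1 - 1e-12
  if (!any(decaying))
    stop("no decaying mode: matrix check failed (all eigenvalues at 1)")
  idx <- which(decaying)[which.max(mods[decaying])]
  lambda <- eig$values[idx]
  if (abs(Im(lambda)) > 1e-8 * max(1, abs(Re(lambda))))
    stop("dominant decaying eigenvalue is complex: matrix check failed")
  lambda <- Re(lambda)
  if (lambda >= 1) stop("lambda >= 1: matrix check failed")
  vec <- Re(eig$vectors[, idx])
  vec <- vec / vec[which.max(abs(vec))]
  gmat <- matrix(vec, s, s, byrow = TRUE,
                 dimnames = list(rownames(mig), colnames(mig)))
  meta_ne_result("tufto_hindar", 1 / (2 * (1 - lambda)),
                 inputs = list(lambda = lambda, structure = gmat,
                               ne = ne, m_bar = mean_immigration(mig)))
}

#' Run the full suite of meta-Ne models
#'
#' Computes the null model and, where their inputs permit, the island,
#' stepping-stone, neighborhood, interdemic, spatiotemporal and
#' Tufto-Hindar models. Models whose assumptions fail (no isolation by
#' distance, no migration matrix, ...) are marked skipped with the reason
#' rather than erroring.
#'
#' @param estimates named list of local [ne_estimate()]s (one per
#'   subpopulation, `NULL`s allowed and skipped).
#' @param fstats an `fstats_result` from [weir_cockerham()], or `NULL`.
#' @param mig a [migration_matrix()] aligned with `estimates`, or `NULL`.
#' @param habitat a [habitat_params()], or `NULL`.
#' @param use_standardized use heterozygosity-standardized F'ST/F'IT (the
#'   default) rather than raw Weir-Cockerham values.
#' @return A data frame of class `meta_ne_suite` (`model`, `estimate`,
#'   `ci_low`, `ci_high`, `status`, `reason`), with attribute `"results"`
#'   holding the `meta_ne` objects.
#' @export
meta_ne_suite <- function(estimates, fstats = NULL, mig = NULL,
                          habitat = NULL, use_standardized = TRUE) {
  estimates <- estimates[!vapply(estimates, is.null, logical(1))]
  if (!length(estimates)) stop("no local estimates supplied")
  pts <- vapply(estimates, `[[`, numeric(1), "point")
  fin <- is.finite(pts)
  sum_ne <- sum(pts[fin])
  s <- sum(fin)
  ne_bar <- mean(pts[fin])
  fst <- if (is.null(fstats)) NULL else
    if (use_standardized) fstats$fst_std else fstats$fst
  fit <- if (is.null(fstats)) NULL else
    if (use_standardized) fstats$fit_std else fstats$fit
  m_bar <- if (is.null(mig)) NULL else mean_immigration(mig)

  run <- function(model, fun) {
    tryCatch(list(res = fun(), status = "ok", reason = ""),
             error = function(e) list(res = NULL, status = "skipped",
                                      reason = conditionMessage(e)))
  }
  specs <- list(
    null = function() null_meta_ne(estimates[fin]),
    island = function() {
      if (is.null(fst)) stop("no F-statistics supplied")
      island_meta_ne(sum_ne, fst)
    },
    stepping_stone = function() {
      if (is.null(m_bar)) stop("no migration matrix supplied")
      stepping_stone_meta_ne(s, ne_bar, m_bar)
    },
    neighborhood = function() {
      if (is.null(habitat)) stop("no habitat parameters supplied")
      neighborhood_meta_ne(habitat, sum_ne)
    },
    interdemic = function() {
      if (is.null(fit)) stop("no F-statistics supplied")
      interdemic_meta_ne(sum_ne, fit)
    },
    spatiotemporal = function() {
      if (is.null(m_bar)) stop("no migration matrix supplied")
      spatiotemporal_meta_ne(s, ne_bar, m_bar = m_bar)
    },
    tufto_hindar = function() {
      if (is.null(mig)) stop("no migration matrix supplied")
      if (!all(fin)) stop("infinite local estimates; T&H needs all finite")
      labs <- rownames(mig)
      ne_v <- if (!is.null(labs) && !is.null(names(pts)) &&
                  setequal(labs, names(pts))) pts[labs]
              else if (nrow(mig) == length(pts)) unname(pts)
              else stop("migration matrix does not match local estimates")
      tufto_hindar_meta_ne(ne_v, mig)
    })
  results <- lapply(names(specs), function(nm) run(nm, specs[[nm]]))
  names(results) <- names(specs)
  rows <- lapply(names(specs), function(nm) {
    r <- results[[nm]]
    if (is.null(r$res))
      data.frame(model = nm, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, status = r$status, reason = r$reason,
                 stringsAsFactors = FALSE)
    else
      data.frame(model = nm, estimate = r$res$estimate,
                 ci_low = r$res$ci_low, ci_high = r$res$ci_high,
                 status = "ok", reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "results") <- lapply(results, `[[`, "res")
  class(out) <- c("meta_ne_suite", "data.frame")
  out
}

#' @export
print.meta_ne_suite <- function(x, ...) {
  cat("Metapopulation effective size under seven models:\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
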