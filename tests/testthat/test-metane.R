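mk_est <- function(point, lo = point * 0.6, hi = point * 1.8) {
  ne_estimate("ABC", point, lo, hi, s_sample = 50, n_comparisons = 100)
}

test_that("null model sums points and propagates per-side pseudo-SEs", {
  ests <- lapply(c(10, 20, 30), mk_est)
  expect_equal(null_meta_ne(ests)$estimate, 60)
  # upper-side SEs 3 and 4 combine to 5
  e1 <- ne_estimate("ABC", 100, 100 - 1.96 * 2, 100 + 1.96 * 3, 50, 10)
  e2 <- ne_estimate("ABC", 200, 200 - 1.96 * 5, 200 + 1.96 * 4, 50, 10)
  nm <- null_meta_ne(list(e1, e2))
  expect_equal(nm$ci_high, 300 + 1.96 * 5)
  expect_equal(nm$ci_low, 300 - 1.96 * sqrt(4 + 25))
  # single component: identity
  single <- null_meta_ne(list(e1))
  expect_equal(single$estimate, 100)
  expect_equal(single$ci_low, e1$ci_low, tolerance = 1e-9)
  expect_equal(single$ci_high, e1$ci_high, tolerance = 1e-9)
  # infinite components propagate
  expect_identical(null_meta_ne(list(e1, mk_est(Inf, 50, Inf)))$estimate, Inf)
  expect_error(null_meta_ne(list()), "empty")
})

test_that("island model: sum/(1-FST) with its boundary behaviour", {
  expect_equal(island_meta_ne(100, 0)$estimate, 100)
  expect_equal(island_meta_ne(100, 0.202)$estimate, 125.31, tolerance = 1e-3)
  expect_equal(island_meta_ne(500, 0.5)$estimate, 1000)
  expect_warning(res <- island_meta_ne(100, 1), "infinite")
  expect_identical(res$estimate, Inf)
  expect_error(island_meta_ne(100, -0.1), ">= 0")
})

test_that("circular stepping-stone: bounds, monotonicity, panmixia limit", {
  expect_gt(stepping_stone_meta_ne(7, 100, 0.05)$estimate,
            stepping_stone_meta_ne(7, 100, 0.15)$estimate)
  expect_gte(stepping_stone_meta_ne(7, 100, 0.15)$estimate, 700)
  expect_lt(stepping_stone_meta_ne(7, 100, 0.5)$estimate, 700 * 1.1)
  expect_identical(stepping_stone_meta_ne(5, 100, 0)$estimate, Inf)
})

test_that("neighborhood model responds to habitat length and density", {
  h <- function(L, D = NULL, s2 = 0.026) habitat_params(L, D = D, sigma2 = s2)
  base <- neighborhood_meta_ne(h(11, D = 50), 550)$estimate
  expect_gte(base, 550)
  expect_gte(neighborhood_meta_ne(h(22, D = 50), 550)$estimate, base)
  expect_lte(neighborhood_meta_ne(h(11, D = 100), 550)$estimate, base)
  expect_error(neighborhood_meta_ne(habitat_params(11), 550), "not applicable")
  # sigma2 derivable from the IBD slope
  via_b <- neighborhood_meta_ne(habitat_params(11, D = 50, b = 0.2), 550)
  expect_equal(via_b$inputs$sigma2, 1 / (4 * 50 * 0.2))
})

test_that("dispersal variance from IBD slope inverts Rousset's relation", {
  expect_equal(sigma2_from_ibd(0.25, 1), 1)
  b <- 1 / (4 * 2.5 * 0.026)  # sigma2 = 0.026 at density 2.5
  expect_equal(sigma2_from_ibd(b, 2.5), 0.026, tolerance = 1e-12)
  expect_error(sigma2_from_ibd(-0.1, 1), "no isolation by distance")
})

test_that("IBD slope is the least-squares slope of fst/(1-fst) on distance", {
  d <- c(1, 3, 5, 8)
  fst <- (0.02 * d) / (1 + 0.02 * d)  # exactly linear after linearization
  expect_equal(ibd_slope(fst, d), 0.02, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(ibd_slope(fst[perm], d[perm]), 0.02, tolerance = 1e-12)
  expect_error(ibd_slope(fst, rep(2, 4)), "zero distance variance")
  expect_error(ibd_slope(fst[1:2], d[1:2]), "3 pairs")
})

test_that("interdemic model shrinks with metapopulation inbreeding", {
  expect_equal(interdemic_meta_ne(100, 0)$estimate, 100)
  expect_equal(interdemic_meta_ne(100, 0.202)$estimate, 83.19,
               tolerance = 1e-3)
  fits <- seq(0, 0.5, by = 0.1)
  est <- vapply(fits, function(f) interdemic_meta_ne(100, f)$estimate,
                numeric(1))
  expect_true(all(diff(est) < 0))
  expect_true(all(est[-1] < 100))
})

test_that("spatiotemporal model exceeds the null sum and matches island", {
  for (s in c(3, 5, 7)) for (nb in c(50, 200)) for (M in c(1, 5, 20)) {
    expect_gte(spatiotemporal_meta_ne(s, nb, m_big = M)$estimate, s * nb)
  }
  expect_equal(spatiotemporal_meta_ne(5, 100, m_big = 10)$estimate,
               spatiotemporal_meta_ne(5, 100, m_bar = 0.1)$estimate)
  # island-equilibrium FST for the same mean migrant number agrees within 15%
  s <- 6; N <- 100; m <- 0.1
  fst_eq <- 1 / (1 + 4 * N * m * (s / (s - 1))^2)
  isl <- island_meta_ne(s * N, fst_eq)$estimate
  st <- spatiotemporal_meta_ne(s, N, m_bar = m)$estimate
  expect_lt(abs(st - isl) / isl, 0.15)
  expect_identical(spatiotemporal_meta_ne(4, 100, m_big = 0)$estimate, Inf)
})

test_that("Tufto-Hindar limits: single deme exact, isolation gives max", {
  expect_equal(tufto_hindar_meta_ne(100, migration_matrix(matrix(1, 1, 1)))
               $estimate, 100, tolerance = 1e-9)
  th <- tufto_hindar_meta_ne(c(50, 200), migration_matrix(diag(2)))
  expect_equal(th$estimate, 200, tolerance = 1e-9)
  th3 <- tufto_hindar_meta_ne(c(30, 80, 200), migration_matrix(diag(3)))
  expect_equal(th3$estimate, 200, tolerance = 1e-9)
})

test_that("Tufto-Hindar is label-invariant and penalizes asymmetry", {
  set.seed(81)
  m <- matrix(c(0.8, 0.15, 0.05,
                0.05, 0.9, 0.05,
                0.1, 0.2, 0.7), 3, 3, byrow = TRUE)
  ne <- c(120, 60, 200)
  est <- tufto_hindar_meta_ne(ne, migration_matrix(m))$estimate
  perm <- c(3, 1, 2)
  est_p <- tufto_hindar_meta_ne(ne[perm],
                                migration_matrix(m[perm, perm]))$estimate
  expect_equal(est_p, est, tolerance = 1e-9)
  expect_true(est > 0 && is.finite(est))

  # increasing asymmetry at fixed mean immigration never raises meta-Ne
  s <- 4; ne4 <- rep(100, s); m_bar <- 0.12
  skew <- function(w) {
    # off-diagonal mass m_bar per row, tilted towards deme 1 by weight w
    M <- matrix(0, s, s)
    for (i in 1:s) {
      others <- setdiff(1:s, i)
      wts <- ifelse(others == 1, w, 1)
      M[i, others] <- m_bar * wts / sum(wts)
      M[i, i] <- 1 - m_bar
    }
    M
  }
  ests <- vapply(c(1, 3, 10, 30, 100),
                 function(w) tufto_hindar_meta_ne(ne4, migration_matrix(
                   skew(w)))$estimate, numeric(1))
  expect_true(all(diff(ests) <= 1e-9))
  expect_lt(ests[length(ests)], sum(ne4))
})

test_that("model suite ordering, skip semantics and Table-2 inequalities", {
  ests <- list(P1 = mk_est(120), P2 = mk_est(80), P3 = mk_est(100))
  fs <- structure(list(fst = 0.08, fis = 0.01, fit = 0.09, fst_std = 0.2,
                       fit_std = 0.21, hs = 0.8, ht = 0.85, k = 3),
                  class = "fstats_result")
  m <- matrix(c(0.9, 0.05, 0.05, 0.05, 0.9, 0.05, 0.05, 0.05, 0.9), 3, 3)
  dimnames(m) <- list(names(ests), names(ests))
  suite <- meta_ne_suite(ests, fstats = fs, mig = migration_matrix(m),
                         habitat = habitat_params(11, sigma2 = 0.03))
  expect_equal(suite$model, c("null", "island", "stepping_stone",
                              "neighborhood", "interdemic", "spatiotemporal",
                              "tufto_hindar"))
  expect_true(all(suite$status == "ok"))
  null_est <- suite$estimate[suite$model == "null"]
  expect_gte(suite$estimate[suite$model == "island"], null_est)
  expect_gte(suite$estimate[suite$model == "stepping_stone"], null_est)
  expect_gte(suite$estimate[suite$model == "spatiotemporal"], null_est)
  expect_lte(suite$estimate[suite$model == "interdemic"], null_est)

  # no isolation by distance: stepping stone still runs, neighborhood skips;
  # no migration matrix: stepping stone, spatiotemporal and T&H skip
  suite2 <- meta_ne_suite(ests, fstats = fs, mig = migration_matrix(m),
                          habitat = NULL)
  expect_equal(suite2$status[suite2$model == "neighborhood"], "skipped")
  suite3 <- meta_ne_suite(ests, fstats = fs, mig = NULL, habitat = NULL)
  expect_equal(suite3$status[suite3$model %in%
                 c("stepping_stone", "spatiotemporal", "tufto_hindar")],
               rep("skipped", 3))
  expect_match(suite3$reason[suite3$model == "tufto_hindar"], "migration")

  # deterministic given fixed inputs
  suite_b <- meta_ne_suite(ests, fstats = fs, mig = migration_matrix(m),
                           habitat = habitat_params(11, sigma2 = 0.03))
  expect_identical(suite$estimate, suite_b$estimate)
})

test_that("migration matrices validate and round-trip as delimited text", {
  m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  mm <- migration_matrix(m, labels = c("up", "down"))
  expect_equal(mean_immigration(mm), 0.15)
  f <- tempfile(fileext = ".tsv")
  write_migration_matrix(mm, f)
  mm2 <- read_migration_matrix(f)
  expect_equal(unclass(mm2), unclass(mm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(migration_matrix(matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)),
               "sum to 1")
})
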