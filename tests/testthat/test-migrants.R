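test_that("posterior-predictive genotype likelihood follows the stated prior", {
  # k = 2 alleles overall; home counts {a: 9, b: 1} (10 copies); genotype
  # (a, a): p_a = (9 + 1/2) / (10 + 1), contribution log(p_a^2)
  ref <- list(c(a = 9L, b = 1L))
  ll <- rm_loglik(a1 = "a", a2 = "a", ref_counts = ref, k_alleles = 2)
  expect_equal(ll, 2 * log(9.5 / 11))
  expect_equal(exp(ll), 0.7459, tolerance = 1e-4)

  # heterozygote factorization 2 * p_a * p_b
  ll_het <- rm_loglik(a1 = "a", a2 = "b", ref_counts = ref, k_alleles = 2)
  expect_equal(ll_het, log(2) + log(9.5 / 11) + log(1.5 / 11))

  # leave-one-out removes the focal copies first
  ll_loo <- rm_loglik(a1 = "a", a2 = "a", ref_counts = ref, k_alleles = 2,
                      leave_one_out = TRUE)
  expect_equal(ll_loo, 2 * log((9 - 2 + 0.5) / 9))

  # an allele absent from the reference still has positive probability
  ll_abs <- rm_loglik(a1 = "c", a2 = "c", ref_counts = list(c(a = 9L, b = 1L)),
                      k_alleles = 3)
  expect_true(is.finite(ll_abs))
  # missing locus is skipped
  expect_equal(rm_loglik(NA, NA, ref, 2), 0)
})

test_that("genotypes are assigned to the population where they are common", {
  set.seed(71)
  # pop A rich in alleles 1-3, pop B rich in 6-8
  mk <- function(codes, n) {
    list(a1 = matrix(sample(codes, n * 6, TRUE), n, 6),
         a2 = matrix(sample(codes, n * 6, TRUE), n, 6))
  }
  ga <- mk(1:3, 30); gb <- mk(6:8, 30)
  ds <- genotype_dataset(rep(c("A", "B"), each = 30), paste0("i", 1:60),
                         rbind(ga$a1, gb$a1), rbind(ga$a2, gb$a2),
                         loci = paste0("L", 1:6), repeat_unit = 1)
  fl <- detect_migrants(ds, alpha = 0.01, n_mc = 200, seed = 1)
  expect_true(all(fl$best_pop == fl$home_pop))
  expect_true(all(fl$delta <= 1e-12))
  # home-is-best individuals have delta 0 and are never flagged
  expect_true(all(fl$p_value[fl$delta == 0] > 0.5))
  expect_false(any(fl$flagged[fl$delta == 0]))
})

test_that("delta is invariant to locus order and allele relabeling", {
  set.seed(72)
  ds <- random_dataset(c(A = 25, B = 25), n_loci = 5, n_alleles = 4)
  fl <- detect_migrants(ds, n_mc = 100, seed = 3)
  perm <- c(3, 1, 5, 2, 4)
  remap <- function(m) matrix(c(300L, 100L, 400L, 200L)[m - 99L],
                              nrow(m), ncol(m))
  ds2 <- genotype_dataset(ds$pop, ds$id, remap(ds$a1)[, perm],
                          remap(ds$a2)[, perm], loci = ds$loci[perm],
                          repeat_unit = 1)
  fl2 <- detect_migrants(ds2, n_mc = 100, seed = 3)
  expect_equal(fl2$delta, fl$delta, tolerance = 1e-10)
  expect_equal(fl2$log_lh, fl$log_lh, tolerance = 1e-10)
})

test_that("null flag rate is calibrated and null p-values are uniform", {
  set.seed(73)
  S <- 100; L <- 10; s <- 3
  freqs <- lapply(1:L, function(l) { p <- rexp(6); p / sum(p) })
  a1 <- sapply(1:L, function(l) sample(1:6, S * s, TRUE, freqs[[l]]))
  a2 <- sapply(1:L, function(l) sample(1:6, S * s, TRUE, freqs[[l]]))
  ds <- genotype_dataset(rep(paste0("P", 1:s), each = S),
                         paste0("i", 1:(S * s)), a1, a2,
                         loci = paste0("L", 1:L), repeat_unit = 1)
  fl <- detect_migrants(ds, alpha = 0.01, n_mc = 1000, seed = 9)
  n <- nrow(fl)
  expect_lt(mean(fl$flagged), 0.01 + 3 * sqrt(0.01 * 0.99 / n))
  # randomized PIT against the stored null deltas is uniform
  nd <- attr(fl, "null_delta")
  pit <- vapply(seq_len(n), function(i) {
    d0 <- nd[[fl$home_pop[i]]]
    (sum(d0 < fl$delta[i]) +
       runif(1) * (sum(d0 == fl$delta[i]) + 1)) / (length(d0) + 1)
  }, numeric(1))
  expect_gt(ks.test(pit, "punif")$p.value, 0.01)
})

test_that("planted migrants are detected under strong structure", {
  set.seed(74)
  sc <- sim_scenario(census = c(50, 50), mig = diag(2), n_loci = 12,
                     mutation_rate = 0, init_alleles = 10,
                     generations = 25, sample_sizes = c(50, 50))
  hits <- 0; n_pl <- 25
  for (r in 1:n_pl) {
    sim <- simulate_riverscape(sc, track = FALSE)
    ds <- sim$dataset
    i <- sample(which(ds$pop == "P1"), 1)
    ds$pop[i] <- "P2"   # relabel: a true P1 genotype sampled in P2
    fl <- detect_migrants(ds, alpha = 0.01, n_mc = 400, seed = r)
    hits <- hits + fl$flagged[i]
  }
  expect_gte(hits / n_pl, 0.7)
})

test_that("exclusion bookkeeping and open re-estimation", {
  set.seed(75)
  ds <- random_dataset(c(A = 40, B = 40), n_loci = 8, n_alleles = 6)
  fl <- detect_migrants(ds, alpha = 0.01, n_mc = 200, seed = 2)
  # zero flagged: open identical to closed
  fl$flagged[] <- FALSE
  tab0 <- exclude_and_reestimate(ds, fl, estimator = "LD")
  expect_equal(tab0$ne_open, tab0$ne_closed)
  expect_equal(tab0$n_removed, c(0L, 0L))
  # plant 3 flags in pond A of 40 -> S_open 37
  fl$flagged[which(fl$home_pop == "A")[1:3]] <- TRUE
  tab3 <- exclude_and_reestimate(ds, fl, estimator = "LD")
  expect_equal(tab3$S_open[tab3$subpop == "A"], 37L)
  expect_equal(tab3$n_removed[tab3$subpop == "A"], 3L)
  # dropping below the minimum size marks the pond, not an error
  fl$flagged[which(fl$home_pop == "B")[1:25]] <- TRUE
  tab_low <- exclude_and_reestimate(ds, fl, estimator = "LD",
                                    min_pop_size = 20)
  expect_equal(tab_low$status[tab_low$subpop == "B"],
               "insufficient after exclusion")
})
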