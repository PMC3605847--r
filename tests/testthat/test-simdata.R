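test_that("scenarios validate their inputs", {
  expect_error(sim_scenario(census = c(10, 10),
                            mig = matrix(c(0.9, 0.2, 0.2, 0.8), 2, 2)),
               "sum to 1")
  expect_error(sim_scenario(census = 50, mig = matrix(1, 1, 1),
                            sample_sizes = 60), "exceed census")
  expect_error(make_humber_scenario("salar",
                                    mig = matrix(1 / 7, 7, 7) * 1.1),
               "sum to 1")
})

test_that("riverscape scenarios encode the pond network and profiles", {
  sal <- make_humber_scenario("salar")
  expect_lt(abs(mean_immigration(sal$mig) - 0.053), 0.005)
  expect_equal(unname(sal$mig["P1", "P1"]), 1)     # waterfall barrier
  expect_equal(unname(sal$mig["P7", "P7"]), 1)
  expect_equal(sum(sal$sample_sizes > 0), 6)       # P7 unsampled
  expect_equal(sal$n_loci, 12L)
  # downstream bias: P3 receives more from P2 (upstream) than from P4
  expect_gt(sal$mig["P3", "P2"], sal$mig["P3", "P4"])
  # confluence P5 fed by both branches
  expect_gt(sal$mig["P5", "P4"], 0); expect_gt(sal$mig["P5", "P6"], 0)

  fon <- make_humber_scenario("fontinalis")
  expect_lt(abs(mean_immigration(fon$mig) - 0.061), 0.005)
  expect_equal(sum(fon$sample_sizes > 0), 7)

  alp <- make_humber_scenario("alpinus")
  expect_lt(abs(mean_immigration(alp$mig) - 0.153), 0.005)
  expect_equal(names(alp$sample_sizes)[alp$sample_sizes > 0],
               c("P2", "P3", "P4"))
  expect_gt(min(alp$census), 1000)                 # large demes
})

test_that("simulation is reproducible under a fixed seed", {
  sc <- make_humber_scenario("salar", n_loci = 4, census = rep(30L, 7),
                             sample_sizes = c(rep(10L, 6), 0L),
                             generations = 5L)
  set.seed(123); r1 <- simulate_riverscape(sc)
  set.seed(123); r2 <- simulate_riverscape(sc)
  expect_identical(r1$dataset$a1, r2$dataset$a1)
  expect_identical(r1$truth$het_trajectory, r2$truth$het_trajectory)
})

test_that("single-deme heterozygosity decays at the Wright-Fisher rate", {
  set.seed(91)
  N <- 50
  sc <- sim_scenario(census = N, mig = matrix(1, 1, 1), n_loci = 500,
                     mutation_rate = 0, generations = 80, sample_sizes = N)
  sim <- simulate_riverscape(sc)
  H <- sim$truth$het_trajectory
  # non-increasing in expectation: allow tiny upticks, require overall decay
  expect_lt(tail(H, 1), H[1])
  expect_lt(mean(diff(H) > 0.002), 0.05)
  ne_hat <- realized_meta_ne(sim$truth, burn_in = 4)
  expect_lt(abs(ne_hat - N) / N, 0.15)
})

test_that("two isolated demes decay at the larger deme's rate", {
  set.seed(92)
  sc <- sim_scenario(census = c(50, 200), mig = diag(2), n_loci = 400,
                     mutation_rate = 0, generations = 350,
                     sample_sizes = c(50, 200))
  sim <- simulate_riverscape(sc)
  # pooled heterozygosity plateaus at the never-coalescing between-deme
  # component; the offset fit isolates the decaying mode
  ne_hat <- realized_meta_ne(sim$truth, burn_in = 50, method = "offset")
  expect_lt(abs(ne_hat - 200) / 200, 0.25)
})

test_that("samples round-trip through Genepop", {
  set.seed(93)
  sc <- make_humber_scenario("salar", n_loci = 3, census = rep(25L, 7),
                             sample_sizes = c(rep(20L, 6), 0L),
                             generations = 10L)
  sim <- simulate_riverscape(sc, track = FALSE)
  f <- tempfile(fileext = ".gen")
  write_genepop(sim$dataset, f)
  ds2 <- read_genepop(f, repeat_unit = 1)
  expect_identical(unname(ds2$a1), unname(sim$dataset$a1))
  expect_identical(levels(ds2$pop), levels(sim$dataset$pop))
})

test_that("realized_meta_ne guards its preconditions", {
  sc <- sim_scenario(census = 30, mig = matrix(1, 1, 1), n_loci = 10,
                     mutation_rate = 1e-3, generations = 20,
                     sample_sizes = 30)
  set.seed(94)
  sim <- simulate_riverscape(sc)
  expect_error(realized_meta_ne(sim$truth), "mutation-free")
  sc0 <- sim_scenario(census = 30, mig = matrix(1, 1, 1), n_loci = 10,
                      mutation_rate = 0, generations = 12, sample_sizes = 30)
  sim0 <- simulate_riverscape(sc0, track = FALSE)
  expect_error(realized_meta_ne(sim0$truth), "without trajectory")
})
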