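test_that("genepop write/read round-trips generated datasets losslessly", {
  set.seed(101)
  for (digits in c(2L, 3L)) {
    base <- if (digits == 2L) 10L else 100L
    ds <- random_dataset(c(P1 = 8, P2 = 12), n_loci = 4, n_alleles = 5,
                         missing_rate = 0.1, base_code = base)
    f <- tempfile(fileext = ".gen")
    write_genepop(ds, f, digits = digits)
    ds2 <- read_genepop(f, repeat_unit = 1L)
    expect_identical(levels(ds2$pop), levels(ds$pop))
    expect_identical(ds2$loci, ds$loci)
    expect_identical(unname(ds2$a1), unname(ds$a1))
    expect_identical(unname(ds2$a2), unname(ds$a2))
    expect_identical(ds2$id, ds$id)
  }
})

test_that("missing-code conventions: 0000 and half-calls collapse to missing", {
  f <- write_lines_tmp(c("toy", "loc1", "loc2", "POP",
                         "A_1 , 0101 0000",
                         "A_2 , 0102 0100"))
  ds <- read_genepop(f)
  expect_equal(unname(ds$a1[1, ]), c(1L, NA))
  expect_equal(unname(ds$a2[1, ]), c(1L, NA))
  # half-called genotype (01 00) is treated as fully missing
  expect_true(is.na(ds$a1[2, 2]) && is.na(ds$a2[2, 2]))
  expect_equal(unname(ds$a1[2, 1]), 1L)
})

test_that("POP block sizes and order of appearance are preserved", {
  sizes <- c(30L, 40L, 25L, 35L, 20L, 22L, 28L)
  set.seed(7)
  lines <- c("seven ponds", "locA", "POP")
  for (b in seq_along(sizes)) {
    if (b > 1) lines <- c(lines, "POP")
    lines <- c(lines, sprintf("B%d_%02d ,  %03d%03d", b, seq_len(sizes[b]),
                              sample(100:105, sizes[b], TRUE),
                              sample(100:105, sizes[b], TRUE)))
  }
  ds <- read_genepop(write_lines_tmp(lines))
  expect_equal(unname(pop_sizes(ds)), sizes)
  expect_equal(levels(ds$pop), paste0("B", 1:7))
})

test_that("malformed genepop input errors name the offending line", {
  f <- write_lines_tmp(c("bad", "loc1", "POP", "A_1 , 0101", "A_2 , 01x1"))
  expect_error(read_genepop(f), "line 5")
  f2 <- write_lines_tmp(c("bad", "loc1", "loc2", "POP", "A_1 , 0101"))
  expect_error(read_genepop(f2), "line 5")
})

test_that("delimited genotype table round-trips through the secondary reader", {
  set.seed(11)
  ds <- random_dataset(c(X = 6, Y = 7), n_loci = 3, missing_rate = 0.15)
  f <- tempfile(fileext = ".tsv")
  write_genotype_table(ds, f)
  ds2 <- read_genotype_table(f, repeat_unit = 1L)
  expect_identical(unname(ds2$a1), unname(ds$a1))
  expect_identical(unname(ds2$a2), unname(ds$a2))
  expect_identical(levels(ds2$pop), levels(ds$pop))
})

test_that("filter removes high-missing individuals first, then small subpops", {
  set.seed(21)
  # pop A: 19 complete individuals -> removed by the size rule;
  # pop B: 25 individuals, one missing 4/12 loci (removed), one missing 3/12
  # (retained)
  ds <- random_dataset(c(A = 19, B = 25), n_loci = 12)
  ds$a1[20, 1:4] <- NA; ds$a2[20, 1:4] <- NA   # first B individual: 4 missing
  ds$a1[21, 1:3] <- NA; ds$a2[21, 1:3] <- NA   # second B individual: 3 missing
  out <- filter_dataset(ds, min_pop_size = 20, max_missing_loci = 3)
  expect_equal(levels(out$pop), "B")
  expect_equal(unname(pop_sizes(out)), 24L)
  expect_false(ds$id[20] %in% out$id)
  expect_true(ds$id[21] %in% out$id)
  log <- attr(out, "removal_log")
  expect_setequal(log$stage, c("individual", "subpopulation"))
  expect_equal(sum(log$stage == "subpopulation"), 19L)
})

test_that("filter is a no-op on clean data and is idempotent", {
  set.seed(31)
  ds <- random_dataset(c(A = 22, B = 30), n_loci = 6)
  out <- filter_dataset(ds)
  expect_identical(unname(out$a1), unname(ds$a1))
  expect_equal(nrow(attr(out, "removal_log")), 0L)
  out2 <- filter_dataset(out)
  expect_identical(out2$id, out$id)
  expect_error(filter_dataset(random_dataset(c(A = 5), n_loci = 3)),
               "no analyzable subpopulations")
})

test_that("allele frequencies match direct gene-copy counts", {
  ds <- one_locus_dataset(list(A = list(c(1, 1), c(1, 2))))
  af <- allele_freqs(ds)
  expect_equal(af$freq$A$L1, c(`1` = 0.75, `2` = 0.25))
  expect_equal(unname(af$copies["A", "L1"]), 4L)

  mono <- one_locus_dataset(list(A = list(c(3, 3), c(3, 3))))
  expect_equal(allele_freqs(mono)$freq$A$L1, c(`3` = 1))

  # planted counts across two pops, with pooled = weighted mean (no missing)
  ds2 <- one_locus_dataset(list(
    A = list(c(1, 1), c(1, 2), c(2, 2)),
    B = list(c(1, 2), c(2, 2))))
  af2 <- allele_freqs(ds2)
  expect_equal(af2$freq$A$L1, c(`1` = 3 / 6, `2` = 3 / 6))
  expect_equal(af2$freq$B$L1, c(`1` = 1 / 4, `2` = 3 / 4))
  w <- c(6, 4) / 10
  expect_equal(unname(af2$pooled$L1["1"]),
               sum(w * c(af2$freq$A$L1["1"], af2$freq$B$L1["1"])))
  # frequencies sum to one per cell
  sums <- unlist(lapply(af2$freq, vapply, sum, numeric(1)))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("empty frequency cells are flagged, not fabricated", {
  ds <- random_dataset(c(A = 5, B = 5), n_loci = 2)
  ds$a1[ds$pop == "A", 2] <- NA; ds$a2[ds$pop == "A", 2] <- NA
  af <- allele_freqs(ds)
  expect_equal(nrow(af$empty), 1L)
  expect_equal(af$empty$subpop, "A")
  expect_null(af$freq$A$L2)
})
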