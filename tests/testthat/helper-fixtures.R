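# Fixtures and independent oracles used across the suite.

# random genotype dataset builder
random_dataset <- function(n_per_pop = c(A = 20, B = 20), n_loci = 5,
                           n_alleles = 6, missing_rate = 0, base_code = 100) {
  n <- sum(n_per_pop)
  codes <- base_code + seq_len(n_alleles) - 1L
  a1 <- matrix(sample(codes, n * n_loci, TRUE), n, n_loci)
  a2 <- matrix(sample(codes, n * n_loci, TRUE), n, n_loci)
  if (missing_rate > 0) {
    miss <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  genotype_dataset(pop = rep(names(n_per_pop), n_per_pop),
                   id = sprintf("i%03d", seq_len(n)),
                   a1 = a1, a2 = a2,
                   loci = paste0("L", seq_len(n_loci)), repeat_unit = 1L)
}

# dataset from an explicit list of per-pop genotype lists:
# geno_list[[pop]] = list of c(a1, a2) pairs, one locus
one_locus_dataset <- function(geno_list, locus = "L1") {
  pops <- rep(names(geno_list), lengths(geno_list))
  g <- do.call(rbind, unlist(geno_list, recursive = FALSE))
  genotype_dataset(pop = pops, id = sprintf("i%03d", seq_along(pops)),
                   a1 = g[, 1, drop = FALSE], a2 = g[, 2, drop = FALSE],
                   loci = locus, repeat_unit = 1L)
}

# Independent Weir-Cockerham (1984) oracle for a single locus, coded from
# the ANOVA sums-of-squares formulation (distinct algebra from the package's
# per-allele moment implementation).
wc_oracle_locus <- function(pop, a1, a2) {
  pops <- unique(pop)
  r <- length(pops)
  alleles <- sort(unique(c(a1, a2)))
  n_i <- sapply(pops, function(p) sum(pop == p))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (u in alleles) {
    # per-individual dosages, grouped
    x <- (a1 == u) + (a2 == u)
    p_i <- sapply(pops, function(p) sum(x[pop == p]) / (2 * n_i[p == pops]))
    pbar <- sum(n_i * p_i) / sum(n_i)
    h_i <- sapply(pops, function(p) mean(x[pop == p] == 1))
    hbar <- sum(n_i * h_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a_u <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b_u <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    c_u <- hbar / 2
    a_tot <- a_tot + a_u; b_tot <- b_tot + b_u; c_tot <- c_tot + c_u
  }
  list(fst = a_tot / (a_tot + b_tot + c_tot),
       fis = 1 - c_tot / (b_tot + c_tot),
       fit = 1 - c_tot / (a_tot + b_tot + c_tot))
}

# exact one-tailed Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  cmb <- utils::combn(n + m, n)
  u_obs <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  u_all <- apply(cmb, 2, function(idx) {
    xx <- vals[idx]; yy <- vals[-idx]
    sum(outer(xx, yy, "<")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  # alternative "less": low ranks of x, i.e. many x<y pairs -> large u.
  mean(u_all >= u_obs)
}

# write a genepop text file from raw lines
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".gen")
  writeLines(lines, f)
  f
}
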