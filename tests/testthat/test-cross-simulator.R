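test_that("EMS mutation simulation respects density, spectrum and seed", {
  g <- genome_model(c(s1 = 1e7))

  expect_equal(nrow(simulate_ems_mutations(g, density = 0, seed = 1)), 0L)
  expect_error(genome_model(data.frame(name = character(0), length = numeric(0))),
               "at least one scaffold")

  mu <- simulate_ems_mutations(g, density = 10, spectrum = 1, seed = 42)
  expect_true(all((mu$ref == "C" & mu$alt == "T") |
                  (mu$ref == "G" & mu$alt == "A")))
  expect_true(all(mu$pos >= 1 & mu$pos <= 1e7))
  expect_false(anyDuplicated(mu$pos) > 0)
  expect_identical(mu, simulate_ems_mutations(g, density = 10, spectrum = 1, seed = 42))

  # mixed spectrum: realised G:C->A:T fraction near the requested one
  mu2 <- simulate_ems_mutations(g, density = 100, spectrum = 0.7, seed = 7)
  ems <- (mu2$ref == "C" & mu2$alt == "T") | (mu2$ref == "G" & mu2$alt == "A")
  se <- sqrt(0.7 * 0.3 / nrow(mu2))
  expect_lt(abs(mean(ems) - 0.7), 3 * se)
})

test_that("mutation counts are Poisson with mean density x genome length", {
  g <- genome_model(c(s1 = 1e7))
  counts <- vapply(1:1000, function(s)
    nrow(simulate_ems_mutations(g, density = 100, seed = s)), numeric(1))
  # mean of 1000 replicates within 3 standard errors of 1000
  se <- sqrt(1000) / sqrt(1000)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("F2 population follows Mendelian expectations", {
  g <- genome_model(c(s1 = 1e6))
  mu <- make_mutations(3)
  d0 <- cross_design(mu$id[1], n_progeny = 0)
  pop0 <- simulate_f2_population(d0, mu, g, seed = 1)
  expect_length(pop0$id, 0)

  expect_error(
    simulate_f2_population(cross_design("nope", n_progeny = 5), mu, g, seed = 1),
    "missing from the mutation set")

  d <- cross_design(mu$id[1], n_progeny = 10000)
  pop <- simulate_f2_population(d, mu, g, seed = 3)
  frac <- mean(pop$phenotype == "mutant")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_true(all(pop$genotypes %in% 0:2))
  # dominant inheritance flips the expectation to 3/4
  dd <- cross_design(mu$id[1], inheritance = "dominant", n_progeny = 10000)
  popd <- simulate_f2_population(dd, mu, g, seed = 3)
  expect_lt(abs(mean(popd$phenotype == "mutant") - 0.75), 3 * se)
})

test_that("zero recombination makes all loci on a scaffold co-segregate", {
  g <- genome_model(c(s1 = 1e6), recomb_rate = 0)
  mu <- make_mutations(5)
  pop <- simulate_f2_population(cross_design(mu$id[1], n_progeny = 50), mu, g, seed = 9)
  expect_true(all(apply(pop$genotypes, 1, function(x) length(unique(x)) == 1L)))
})

test_that("pooling partitions by phenotype and flags degenerate pools", {
  mu <- make_mutations(1)
  pop <- make_population(matrix(c(rep(2, 70), rep(c(0, 1), 105)), ncol = 1), mu)
  pools <- pool_individuals(pop)
  expect_length(pools$mt$id, 70)
  expect_length(pools$wt$id, 210)
  expect_equal(length(pools$mt$id) + length(pools$wt$id), length(pop$id))

  all_wt <- make_population(matrix(0, 4, 1), mu)
  expect_warning(pool_individuals(all_wt), "MT pool is empty")
})

test_that("pooled read counts follow the binomial sampling model", {
  mu <- make_mutations(1000)
  # two individuals, one aa one AA, at every SNP: pool alt frequency 0.5
  pop <- make_population(rbind(rep(2, 1000), rep(0, 1000)), mu)
  rc <- simulate_pooled_reads(pop, mu, depth = 100, error_rate = 0, seed = 11)
  tot <- rowSums(rc[, c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")])
  alt <- rc$alt_fwd + rc$alt_rev
  frac <- sum(alt) / sum(tot)
  se <- sqrt(0.5 * 0.5 / sum(tot))
  expect_lt(abs(frac - 0.5), 3 * se)
  # realized depth is Poisson(100): check the mean
  expect_lt(abs(mean(tot) - 100), 3 * sqrt(100 / 1000))

  # depth 0 -> all-zero DP4
  rc0 <- simulate_pooled_reads(pop, mu, depth = 0, seed = 1)
  expect_true(all(rc0[, -1] == 0))

  # fixed aa pool, no error -> zero ref reads, SNP-index 1 wherever covered
  popaa <- make_population(matrix(2, 3, 1000), mu)
  rca <- simulate_pooled_reads(popaa, mu, depth = 50, error_rate = 0, seed = 2)
  expect_true(all(rca$ref_fwd + rca$ref_rev == 0))
  covered <- rca$alt_fwd + rca$alt_rev > 0
  idx <- snp_index(rca[, c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")])
  expect_true(all(idx[covered] == 1))

  empty <- make_population(matrix(0, 0, 1000), mu)
  expect_error(simulate_pooled_reads(empty, mu, depth = 10), "empty pool")
})

test_that("pool allele frequency at linked markers decays as 1 - r", {
  # markers at r = 0, 0.1, 0.25 on the causal scaffold and an unlinked one
  fx <- genome_for_r(c(0, 0.1, 0.25, 0.5))
  d <- cross_design(fx$causal, n_progeny = 20000)
  pop <- simulate_f2_population(d, fx$mutations, fx$genome, seed = 17)
  mt <- pool_individuals(pop)$mt
  r_truth <- recomb_fraction_to(fx$mutations, fx$genome, fx$causal)
  q <- colSums(mt$genotypes) / (2 * length(mt$id))
  for (j in seq_along(r_truth)) {
    expected <- 1 - r_truth[j]
    se <- sqrt(expected * (1 - expected) / (2 * length(mt$id)))
    expect_lt(abs(q[j] - expected), max(3 * se, 1e-12))
  }
  # unlinked marker sits at 0.5 in the WT pool too (1:2:1 genotype ratio)
  wt <- pool_individuals(pop)$wt
  q_un <- colSums(wt$genotypes)[fx$mutations$scaffold == "scfB"] / (2 * length(wt$id))
  expect_lt(abs(q_un - 0.5), 3 * sqrt(0.25 / (2 * length(wt$id))))
})

test_that("simulation is bit-identical under a fixed seed", {
  g <- genome_model(c(s1 = 1e6, s2 = 5e5))
  mu1 <- simulate_ems_mutations(g, 30, seed = 5)
  mu2 <- simulate_ems_mutations(g, 30, seed = 5)
  expect_identical(mu1, mu2)
  d <- cross_design(mu1$id[1], n_progeny = 40)
  p1 <- simulate_f2_population(d, mu1, g, seed = 6)
  p2 <- simulate_f2_population(d, mu2, g, seed = 6)
  expect_identical(p1$genotypes, p2$genotypes)
  r1 <- simulate_pooled_reads(p1, mu1, depth = 30, seed = 7)
  r2 <- simulate_pooled_reads(p2, mu2, depth = 30, seed = 7)
  expect_identical(r1, r2)
})
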