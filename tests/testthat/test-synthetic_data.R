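test_that("truth records validate their invariants", {
  expect_error(sim_truth(c(0.5, 0.6)), "sum to 1")
  expect_error(sim_truth(c(1.2, -0.2)), "\\[0, 1\\]")
  bad_cnv <- tibble::tibble(contig = "c1", start = 10L, end = 10L,
                            copy_number = 2, carrier_frequency = 0.5)
  expect_error(sim_truth(1, cnv = bad_cnv), "start < end")
  bad_hgt <- tibble::tibble(donor = "S2", contig = "c1", start = 0L,
                            end = 10L, frequency = 1.5)
  expect_error(sim_truth(1, hgt = bad_hgt), "\\[0, 1\\]")
})

test_that("strain panels are deterministic and divergence-0 is monomorphic", {
  a <- simulate_strain_panel(genome_length = 3000, divergence = 0.01, seed = 11)
  b <- simulate_strain_panel(genome_length = 3000, divergence = 0.01, seed = 11)
  expect_identical(a$panel$sequences, b$panel$sequences)
  expect_identical(a$truth$private_sites, b$truth$private_sites)
  c2 <- simulate_strain_panel(genome_length = 3000, divergence = 0.01, seed = 12)
  expect_false(identical(a$panel$sequences, c2$panel$sequences))

  z <- simulate_strain_panel(genome_length = 2000, divergence = 0, seed = 5)
  expect_equal(nrow(z$truth$private_sites), 0L)
  expect_equal(nrow(find_diagnostic_sites(z$panel)), 0L)
})

test_that("private-site counts match the binomial expectation", {
  # a site is private to one strain iff it mutates there and nowhere else
  d <- 0.01; L <- 50000; k <- 5
  p_priv <- d * (1 - d)^(k - 1)
  expectation <- L * p_priv
  sd <- sqrt(L * p_priv * (1 - p_priv))
  sim <- simulate_strain_panel(n_strains = k, genome_length = L,
                               divergence = d, seed = 101)
  counts <- table(sim$truth$private_sites$strain)
  expect_length(counts, k)
  for (cnt in counts) {
    expect_lt(abs(cnt - expectation), 4 * sd)
  }
  # and the generator's truth agrees with independent re-derivation from
  # the sequences themselves
  sites <- find_diagnostic_sites(sim$panel)
  truth_keys <- with(sim$truth$private_sites, paste(contig, pos, strain))
  site_keys <- with(sites, paste(contig, pos, strain))
  expect_setequal(site_keys, truth_keys)
})

test_that("a pure single-strain pool has frequency 1 at its own diagnostic sites", {
  sim <- simulate_strain_panel(genome_length = 10000, seed = 21)
  truth <- sim_truth(c(S1 = 1, S2 = 0, S3 = 0, S4 = 0, S5 = 0),
                     error_rate = 0, seed = 21)
  smp <- simulate_pooled_sample(sim$panel, truth, mean_coverage = 60)
  sites <- find_diagnostic_sites(sim$panel)
  fr <- diagnostic_allele_frequencies(smp$pileup, sites, min_depth = 1)
  expect_true(all(fr$freq[fr$strain == "S1"] == 1))
  expect_true(all(fr$freq[fr$strain != "S1"] == 0))
})

test_that("diagnostic-frequency medians recover a skewed mixture", {
  mixture <- c(S1 = 0.60, S2 = 0.25, S3 = 0.10, S4 = 0.04, S5 = 0.01)
  sim <- simulate_strain_panel(genome_length = 50000, seed = 31)
  truth <- sim_truth(mixture, error_rate = 0.001, seed = 31)
  smp <- simulate_pooled_sample(sim$panel, truth, mean_coverage = 100)
  sites <- find_diagnostic_sites(sim$panel)
  fr <- diagnostic_allele_frequencies(smp$pileup, sites, min_depth = 10)
  med <- tapply(fr$freq, fr$strain, median)
  for (s in names(mixture)) {
    expect_lt(abs(med[[s]] - mixture[[s]]), 0.05)
  }
  # independent estimates: medians may overshoot 1 only by sampling noise
  expect_lte(sum(med), 1 + 3 * sqrt(0.25 / 100))
})

test_that("planted CNVs scale expected depth by 1 + cf * (cn - 1)", {
  sim <- simulate_strain_panel(genome_length = 30000, n_contigs = 1, seed = 41)
  cnv <- tibble::tibble(contig = "ctg1", start = 5000L, end = 7000L,
                        copy_number = 3, carrier_frequency = 0.5)
  truth <- sim_truth(default_mix5(), cnv = cnv, seed = 41)
  smp <- simulate_pooled_sample(sim$panel, truth, mean_coverage = 100)
  inside <- smp$coverage$depth[smp$coverage$pos >= 5000 &
                                 smp$coverage$pos < 7000]
  outside <- smp$coverage$depth[smp$coverage$pos < 5000]
  # factor 1 + 0.5 * 2 = 2; Poisson means separate cleanly at these sizes
  expect_lt(abs(mean(inside) / mean(outside) - 2), 0.1)
})

test_that("a copy-number-1 'event' is the identity", {
  sim <- simulate_strain_panel(genome_length = 20000, n_contigs = 1, seed = 43)
  cnv <- tibble::tibble(contig = "ctg1", start = 2000L, end = 4000L,
                        copy_number = 1, carrier_frequency = 1)
  t0 <- sim_truth(default_mix5(), seed = 43)
  t1 <- sim_truth(default_mix5(), cnv = cnv, seed = 43)
  s0 <- simulate_pooled_sample(sim$panel, t0, mean_coverage = 80)
  s1 <- simulate_pooled_sample(sim$panel, t1, mean_coverage = 80)
  expect_identical(s0$coverage, s1$coverage)
})

test_that("inconsistent truth is rejected", {
  sim <- simulate_strain_panel(genome_length = 5000, seed = 45)
  bad <- sim_truth(default_mix5(),
                   cnv = tibble::tibble(contig = "nope", start = 0L,
                                        end = 10L, copy_number = 2,
                                        carrier_frequency = 1),
                   seed = 45)
  expect_error(simulate_pooled_sample(sim$panel, bad), "inconsistent truth")
})

test_that("haplotype windows honour theta and reproduce under a seed", {
  w0 <- simulate_haplotype_window(n_haplotypes = 8, length = 2000,
                                  theta_per_site = 0, seed = 1)
  expect_equal(ncol(w0$haplotypes), 0L)
  w1 <- simulate_haplotype_window(n_haplotypes = 8, length = 2000,
                                  theta_per_site = 0.01, seed = 2)
  w2 <- simulate_haplotype_window(n_haplotypes = 8, length = 2000,
                                  theta_per_site = 0.01, seed = 2)
  expect_identical(w1$positions, w2$positions)
  expect_identical(w1$haplotypes, w2$haplotypes)
  # noise-free pooled counts mirror the haplotype matrix exactly
  expect_equal(w1$sites$freq, colSums(w1$haplotypes) / 8)
})

test_that("pooled pi from a haplotype window equals the pairwise-difference loop", {
  w <- simulate_haplotype_window(n_haplotypes = 6, length = 1000,
                                 theta_per_site = 0.008, seed = 9)
  pi_pkg <- window_theta_pi(w$sites, window_length = 1, maf = 0)
  expect_equal(pi_pkg, oracle_pairwise_pi(w$haplotypes), tolerance = 1e-12)
})
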