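test_that("polarization uses the outgroup consensus and drops ambiguity", {
  # 4 focal haplotypes (s1, s2), 2 outgroup haplotypes (s3)
  haps <- rbind(c(1L, 0L, 1L, 1L),
                c(0L, 0L, 1L, 0L),
                c(1L, 0L, 0L, 0L),
                c(0L, 0L, 1L, 0L),
                c(0L, 0L, 1L, 1L),   # outgroup hap 1
                c(0L, 0L, 1L, 0L))   # outgroup hap 2
  pan <- toy_panel(haps, c(10L, 20L, 30L, 40L), pops = c("f", "f", "o"))
  s <- polarize(pan, focal = c("s1", "s2"), outgroup = "s3",
                accessible_length = 1000)
  # site 1: outgroup fixed 0 -> derived count 2; site 2: monomorphic (skip);
  # site 3: outgroup fixed 1 -> derived = 4 - 3 = 1;
  # site 4: outgroup 50/50 -> dropped
  expect_identical(s$counts, c(1L, 1L, 0L))
  expect_identical(s$dropped, 1L)
  expect_identical(s$n, 4L)

  # outgroup fixed ancestral everywhere: identical to the direct histogram
  pan2 <- single_pop_panel()
  og <- paste0("pop_", 19:20)
  fc <- paste0("pop_", 1:18)
  forced <- pan2
  for (ch in names(forced$chromosomes)) {
    ogr <- hap_rows(forced, samples = og)
    forced$chromosomes[[ch]]$haplotypes[ogr, ] <- 0L
  }
  s2 <- polarize(forced, fc, og)
  direct <- panel_sfs(forced, fc)
  expect_identical(s2$counts, direct$counts)
  expect_identical(s2$dropped, 0L)
})

test_that("expected SFS reduces to theta*L/i at zero intensity", {
  Ne <- 10000; mu <- 3.75e-9; L <- 1e6; n <- 12
  ev <- expected_sfs(bottleneck_model(Ne, 1, 0), n, L, mu,
                     reps = 2000, seed = 42)
  se <- attr(ev, "se")
  theta <- 4 * Ne * mu
  for (i in seq_len(n - 1))
    expect_lt(abs(ev[i] - theta * L / i), 3 * se[i] + 1e-9)
})

test_that("a crushing early bottleneck leaves essentially only singletons", {
  ev <- expected_sfs(bottleneck_model(10000, 10, 50), n = 10, L = 1e6,
                     mu = 3.75e-9, reps = 500, seed = 7)
  expect_gt(ev[1] / sum(ev), 0.95)
})

test_that("expected SFS matches an independent coalescent simulator", {
  # msprime (through simulate_panel) is the independent oracle: mean SFS of
  # replicate simulations at (Ne = 10,000, T_b = 500, I = 0.4)
  m <- demography_model(c(pop = 10000),
                        bottlenecks = data.frame(population = "pop",
                                                 time = 500, intensity = 0.4))
  reps <- 8; L <- 5e5; n <- 20
  obs <- matrix(0, reps, n - 1)
  for (r in 1:reps) {
    pan <- simulate_panel(m, sim_params(chrom_lengths = c(chr1 = L),
                                        seed = 1300 + r), c(pop = n / 2))
    obs[r, ] <- panel_sfs(pan, pan$samples)$counts
  }
  ev <- expected_sfs(bottleneck_model(10000, 500, 0.4), n, L, 3.75e-9,
                     reps = 4000, seed = 11)
  se_obs <- apply(obs, 2, stats::sd) / sqrt(reps)
  se_tot <- sqrt(se_obs^2 + attr(ev, "se")^2)
  for (i in seq_len(n - 1))
    expect_lt(abs(mean(obs[, i]) - ev[i]), 3.5 * se_tot[i] + 1e-9)
})

test_that("coalesced fraction behaves at the limits and matches the oracle", {
  expect_equal(coalesced_fraction(bottleneck_model(1e4, 500, 0), 20), 0)
  # extreme intensity: everything alive at T_b coalesces, approaching
  # (k - 1)/k where k is the lineage count at the bottleneck
  cf <- coalesced_fraction(bottleneck_model(1e4, 100, 100), 20,
                           reps = 2000, seed = 3)
  # with T_b tiny relative to 2Ne, nearly all 20 lineages reach the burst
  expect_gt(cf, 0.9)
  # intermediate intensity against the scalar reference implementation
  cf_mid <- coalesced_fraction(bottleneck_model(1e4, 2000, 0.5), 15,
                               reps = 4000, seed = 5)
  set.seed(99)
  oracle <- burst_chain_slow(15, 2000 / (2e4), 0.5, 4000)
  expect_lt(abs(cf_mid - oracle), 0.02)
})

test_that("Ne from diversity reproduces the reported rounded sizes", {
  expect_equal(ne_from_pi(0.00137, 3.75e-9, "hundred"), 91300)
  expect_equal(ne_from_pi(0.00137, 9.05e-10, "thousand"), 378000)
  expect_equal(ne_from_pi(4 * 2e-9, 2e-9), 1)
  expect_error(ne_from_pi(0.001, 0), "positive")
})

test_that("intensity conversion inverts duration/(2 Ne_b)", {
  expect_equal(intensity_convert(20, 0.4), 25)
  expect_equal(intensity_convert(10, 0.5), 10)
  expect_error(intensity_convert(10, 0), "positive")
})

test_that("nucleotide diversity matches direct pair counting", {
  # two haplotypes differing at 1 of 1000 accessible sites
  h <- matrix(0L, 2, 1); h[1, 1] <- 1L
  pan <- toy_panel(h, 500L, len = 1000)
  expect_equal(nucleotide_diversity(pan, 1:2)$pi, 0.001)

  # identical haplotypes: pi = 0
  h0 <- matrix(0L, 4, 3)
  expect_equal(nucleotide_diversity(toy_panel(h0, c(1L, 2L, 3L),
                                              len = 100), 1:4)$pi, 0)

  # three listed haplotypes: hand enumeration over pairs
  h3 <- rbind(c(1L, 0L, 1L, 0L),
              c(0L, 0L, 1L, 1L),
              c(1L, 1L, 0L, 0L),
              c(0L, 0L, 0L, 0L))
  pan3 <- toy_panel(h3, c(10L, 20L, 30L, 40L), len = 200)
  got <- nucleotide_diversity(pan3, 1:3)$pi
  p <- colMeans(h3[1:3, ])
  expected <- sum(2 * p * (1 - p) * 3 / 2) / 200
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(expected, pi_oracle(h3[1:3, ]) / 200, tolerance = 1e-12)
})

test_that("bottleneck fit satisfies its internal consistency invariants", {
  m <- demography_model(c(pop = 10000),
                        bottlenecks = data.frame(population = "pop",
                                                 time = 500, intensity = 0.6))
  pan <- simulate_panel(m, sim_params(chrom_lengths = c(chr1 = 1e6,
                                                        chr2 = 1e6),
                                      seed = 77), c(pop = 10))
  s <- panel_sfs(pan, pan$samples)
  fit <- fit_bottleneck(s, 3.75e-9, restarts = 3, reps = 200, seed = 3,
                        maxit = 200)
  expect_gte(fit$loglik, max(fit$replicates$loglik) - 1e-9)
  expect_gte(fit$loglik, fit$null$loglik)
  expect_gte(fit$lr, 0)
  expect_error(fit_bottleneck(sfs(integer(9), 10, 1e6), 3.75e-9), "empty")
})

test_that("constant-size data prefers the null model", {
  pan <- simulate_panel(demography_model(c(pop = 10000)),
                        sim_params(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                                   seed = 88), c(pop = 10))
  s <- panel_sfs(pan, pan$samples)
  fit <- fit_bottleneck(s, 3.75e-9, restarts = 3, reps = 200, seed = 4,
                        maxit = 200)
  # likelihood-ratio statistic small relative to a real bottleneck signal
  expect_lt(fit$lr, 30)
})
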