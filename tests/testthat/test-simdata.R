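test_that("simulated diversity matches the coalescent expectation 4*Ne*mu", {
  # 20 replicate 300-kb chromosomes, Ne = 10,000: E[pi] = 1.5e-4 per bp
  m <- demography_model(c(pop = 10000))
  pis <- vapply(1:20, function(r) {
    pan <- simulate_panel(m, sim_params(chrom_lengths = c(chr1 = 3e5),
                                        seed = 5000 + r), c(pop = 20))
    nucleotide_diversity(pan, pan$samples)$pi
  }, 0)
  expected <- 4 * 10000 * 3.75e-9
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se + 1e-12)
})

test_that("Watterson's theta from simulated S matches 4*Ne*mu", {
  pan <- single_pop_panel()
  n <- 2 * length(pan$samples)
  S <- sum(vapply(pan$chromosomes, function(c) length(c$positions), 0L))
  L <- sum(pan$chrom_lengths)
  theta_w <- S / (sum(1 / seq_len(n - 1)) * L)
  # coalescent SD of S is approximately sqrt(theta*L*a1 + (theta*L)^2*a2)
  theta <- 4 * 10000 * 3.75e-9
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  sd_S <- sqrt(theta * L * a1 + (theta * L)^2 * a2)
  expect_lt(abs(S - theta * L * a1), 3 * sd_S)
  expect_gt(theta_w, 0)
})

test_that("zero mutation rate yields zero variant sites", {
  pan <- simulate_panel(demography_model(c(pop = 1000)),
                        sim_params(mutation_rate = 0,
                                   chrom_lengths = c(chr1 = 1e5), seed = 3),
                        c(pop = 5))
  expect_identical(sum(vapply(pan$chromosomes,
                              function(c) length(c$positions), 0L)), 0L)
})

test_that("identical seeds reproduce the panel bit for bit", {
  m <- demography_model(c(pop = 5000))
  p <- sim_params(chrom_lengths = c(chr1 = 2e5), seed = 99)
  a <- simulate_panel(m, p, c(pop = 6))
  b <- simulate_panel(m, p, c(pop = 6))
  expect_identical(a$chromosomes, b$chromosomes)
})

test_that("inconsistent split topologies are rejected", {
  expect_error(demography_model(
    c(a = 100, b = 100),
    splits = data.frame(time = c(10, 20), derived = c("a", "a"),
                        ancestral = c("b", "b"))), "topology")
  expect_error(demography_model(
    c(a = 100, b = 100),
    splits = data.frame(time = c(10, 20), derived = c("a", "b"),
                        ancestral = c("b", "a"))), "cycle")
})

test_that("plant_tracts is a bookkept copy that touches nothing else", {
  pan <- single_pop_panel()
  # empty tract list: bit-identical no-op
  res0 <- plant_tracts(pan, NULL)
  expect_identical(res0$panel$chromosomes, pan$chromosomes)
  expect_identical(nrow(res0$truth$tracts), 0L)

  pan2 <- pan
  pan2$populations[1:2] <- "donor"  # repurpose two samples as a donor pop
  tr <- data.frame(sample = "pop_5", haplotype = 1, chrom = "chr1",
                   start = 2e5, end = 7e5 - 1, donor = "donor")
  res <- plant_tracts(pan2, tr, seed = 4)
  expect_identical(nrow(res$truth$tracts), 1L)
  expect_equal(res$truth$tracts$start, 2e5)
  expect_equal(res$truth$tracts$end, 7e5 - 1)
  # recipient haplotype equals the recorded donor haplotype inside the tract
  ch <- res$panel$chromosomes$chr1
  cols <- which(ch$positions >= 2e5 & ch$positions < 7e5)
  rrow <- match("pop_5_1", rownames(ch$haplotypes))
  drow <- match(res$truth$tracts$donor_haplotype, rownames(ch$haplotypes))
  expect_identical(ch$haplotypes[rrow, cols], ch$haplotypes[drow, cols])
  # nothing outside the interval changed, on any haplotype or chromosome
  out_cols <- setdiff(seq_along(ch$positions), cols)
  expect_identical(ch$haplotypes[, out_cols],
                   pan$chromosomes$chr1$haplotypes[, out_cols])
  other <- ch$haplotypes[-rrow, cols, drop = FALSE]
  expect_identical(other, pan$chromosomes$chr1$haplotypes[-rrow, cols])
  expect_identical(res$panel$chromosomes$chr2, pan$chromosomes$chr2)
})

test_that("overlapping requested tracts on one haplotype are an error", {
  pan <- single_pop_panel()
  pan$populations[1] <- "donor"
  tr <- data.frame(sample = c("pop_5", "pop_5"), haplotype = 1,
                   chrom = "chr1", start = c(1e5, 2e5), end = c(3e5, 4e5),
                   donor = "donor")
  expect_error(plant_tracts(pan, tr), "overlapping")
})

test_that("plant_sweep fixes the core haplotype at f = 1 and respects f", {
  pan <- single_pop_panel()
  grp <- paste0("pop_", 1:10)
  res <- plant_sweep(pan, grp, "chr1", 3e5, 5e5, carrier_fraction = 1,
                     seed = 5)
  ch <- res$panel$chromosomes$chr1
  cols <- which(ch$positions >= 3e5 & ch$positions <= 5e5)
  rows <- hap_rows(pan, samples = grp)
  H <- ch$haplotypes[rows, cols]
  expect_true(all(apply(H, 2, function(x) length(unique(x)) == 1)))
  # G12 = 1 in windows fully inside the swept interval
  g <- g_stats(res$panel, grp, window = 50)
  interior <- g$chrom == "chr1" & g$start_bp >= 3e5 & g$end_bp <= 5e5
  expect_true(all(g$G12[interior] == 1))
  # f = 0.6: top haplotype frequency >= 0.6 inside
  res6 <- plant_sweep(pan, grp, "chr1", 3e5, 5e5, carrier_fraction = 0.6,
                      seed = 5)
  H6 <- res6$panel$chromosomes$chr1$haplotypes[rows, cols]
  top <- max(table(apply(H6, 1, paste, collapse = "")))
  expect_gte(top / nrow(H6), 0.6)
  # nothing changes outside the interval
  out_cols <- setdiff(seq_along(ch$positions), cols)
  expect_identical(res$panel$chromosomes$chr1$haplotypes[, out_cols],
                   pan$chromosomes$chr1$haplotypes[, out_cols])
  expect_identical(res$panel$chromosomes$chr2, pan$chromosomes$chr2)
  expect_error(plant_sweep(pan, character(0), "chr1", 1, 2, 0.5), "empty")
})

test_that("assign_sex follows the stated penetrance probabilities", {
  status <- rep(c("XX", "XY"), each = 50)
  full <- assign_sex(status = stats::setNames(status, paste0("s", 1:100)),
                     penetrance = c(1, 1), seed = 2)
  expect_identical(full$sex, ifelse(status == "XX", "F", "M"))

  big <- assign_sex(status = rep("XX", 10000), penetrance = c(0.87, 0.93),
                    seed = 3)
  fr <- mean(big$sex == "F")
  se <- sqrt(0.87 * 0.13 / 10000)
  expect_lt(abs(fr - 0.87), 3 * se)

  none <- assign_sex(status = rep(c("XX", "XY"), each = 2000),
                     penetrance = c(0.5, 0.5), seed = 4)
  tab <- table(none$genotype, none$sex)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("observe_trio obeys its read-count model", {
  tg <- simulate_trio(800, seed = 9)
  # noise-free, deep coverage: calls equal truth, no Mendelian errors
  obs0 <- observe_trio(tg, coverage = 100, error_rate = 0, seed = 9)
  expect_identical(unname(obs0$GT), unname(tg))
  expect_identical(mendelian_errors(obs0)$n_errors, 0L)
  # mean DP within 3 SE of coverage
  obs <- observe_trio(tg, coverage = 15, error_rate = 0.02, seed = 10)
  ndp <- length(obs$DP)
  expect_lt(abs(mean(obs$DP) - 15), 3 * sqrt(15 / ndp))
  # doubling the error rate approximately doubles Mendelian errors
  err_at <- function(e) {
    mean(vapply(1:8, function(r) {
      o <- observe_trio(tg, coverage = 12, error_rate = e, seed = 100 + r)
      mendelian_errors(o)$n_errors
    }, 0))
  }
  e1 <- err_at(0.05); e2 <- err_at(0.10)
  expect_gt(e2 / e1, 1.4)
  expect_lt(e2 / e1, 3.0)
})
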