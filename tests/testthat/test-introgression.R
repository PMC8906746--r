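freq_panel <- function(p1, p2, p3, pO, n_per = 10L, pos = NULL) {
  # build a panel whose group derived-allele frequencies are exactly the
  # given vectors (one haplotype group per population)
  S <- length(p1)
  mk <- function(p) {
    vapply(p, function(x) {
      k <- round(x * n_per)
      sample(c(rep(1L, k), rep(0L, n_per - k)))
    }, integer(n_per))
  }
  set.seed(1)
  haps <- rbind(mk(p1), mk(p2), mk(p3), mk(pO))
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = S)
  toy_panel(haps, pos, pops = rep(c("p1", "p2", "p3", "o"), each = n_per / 2))
}

test_that("D and f4 follow the site-pattern definitions", {
  # p1 = p2 everywhere: perfect symmetry, D = 0, f4 = 0
  p <- rep(0.6, 50)
  pan <- freq_panel(p, p, rep(0.4, 50), rep(0, 50))
  q <- quartet_spec(pan, p1 = 1:10, p2 = 11:20, p3 = 21:30, outgroup = 31:40)
  st <- pattern_stats(pan, q)
  expect_equal(st$D, 0)
  expect_equal(st$f4, 0)

  # single pure ABBA site: D = 1
  pan2 <- freq_panel(0, 1, 1, 0)
  q2 <- quartet_spec(pan2, 1:10, 11:20, 21:30, 31:40)
  st2 <- pattern_stats(pan2, q2)
  expect_equal(st2$abba, 1)
  expect_equal(st2$baba, 0)
  expect_equal(st2$D, 1)

  # hand-enumerated two-site case: D = (1.125 - 0.125)/(1.125 + 0.125) = 0.8
  pan3 <- freq_panel(c(0.5, 0), c(0.5, 1), c(0.5, 1), c(0, 0))
  q3 <- quartet_spec(pan3, 1:10, 11:20, 21:30, 31:40)
  st3 <- pattern_stats(pan3, q3)
  expect_equal(st3$D, 0.8)
  expect_true(st3$defined)

  # no informative sites: undefined, flagged
  pan4 <- freq_panel(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  st4 <- pattern_stats(pan4, quartet_spec(pan4, 1:10, 11:20, 21:30, 31:40))
  expect_false(st4$defined)
  expect_true(is.na(st4$D))
})

test_that("quartet groups must be disjoint and non-empty", {
  pan <- single_pop_panel()
  expect_error(quartet_spec(pan, "pop_1", "pop_1", "pop_2", "pop_3"),
               "disjoint")
  expect_error(quartet_spec(pan, character(0), "pop_1", "pop_2", "pop_3"))
})

test_that("fdm windows advance by 25 SNPs and respect symmetry and bounds", {
  set.seed(2)
  S <- 250
  p2v <- runif(S); p3v <- runif(S)
  pan <- freq_panel(p2v, p2v, p3v, rep(0, S))
  q <- quartet_spec(pan, 1:10, 11:20, 21:30, 31:40)
  tr <- fdm_scan(pan, q)
  expect_identical(nrow(tr), 7L)                      # starts 1, 26, ..., 151
  expect_identical(tr$first_snp, seq(1L, 151L, 25L))
  expect_true(all(tr$fdm[!is.na(tr$fdm)] == 0))       # p1 = p2 everywhere

  pan2 <- species_panel()
  q2 <- quartet_spec(pan2, paste0("ornamental_", 2:10), "ornamental_1",
                     paste0("imbellis_", 1:4), paste0("outgroup_", 1:2))
  tr2 <- fdm_scan(pan2, q2)
  ok <- !is.na(tr2$fdm)
  expect_true(all(tr2$fdm[ok] >= -1 - 1e-9 & tr2$fdm[ok] <= 1 + 1e-9))
  st <- pattern_stats(pan2, q2)
  expect_true(abs(st$D) <= 1)

  expect_warning(
    fdm_scan(freq_panel(runif(50), runif(50), runif(50), rep(0, 50)), q),
    "fewer than")
})

test_that("MAD winsorization clips single-window spikes before segmentation", {
  tr <- data.frame(chrom = "chr1", first_snp = 1, last_snp = 100,
                   start_bp = seq(1e3, by = 5e3, length.out = 60),
                   end_bp = seq(6e3, by = 5e3, length.out = 60),
                   mid_bp = seq(3.5e3, by = 5e3, length.out = 60),
                   n_snps = 100, fdm = rep(0.01, 60))
  class(tr) <- c("fdm_track", "data.frame")
  # constant track: a single segment with that mean
  seg0 <- robust_segment(tr)
  expect_identical(nrow(seg0), 1L)
  expect_equal(seg0$mean_fdm, 0.01)
  # single 10.0 spike: clipped, still one segment with mean near 0.01
  tr$fdm[30] <- 10
  seg1 <- robust_segment(tr)
  expect_identical(nrow(seg1), 1L)
  expect_lt(seg1$mean_fdm, 0.05)
})

test_that("changepoint segmentation recovers a clean step within one window", {
  tr <- data.frame(chrom = "chr1", first_snp = 1, last_snp = 100,
                   start_bp = seq(1e3, by = 5e3, length.out = 80),
                   end_bp = seq(6e3, by = 5e3, length.out = 80),
                   mid_bp = seq(3.5e3, by = 5e3, length.out = 80),
                   n_snps = 100,
                   fdm = c(rep(0.01, 40), rep(0.4, 40)))
  class(tr) <- c("fdm_track", "data.frame")
  seg <- robust_segment(tr)
  expect_identical(nrow(seg), 2L)
  expect_lte(abs(seg$last_window[1] - 40L), 1L)
  expect_lt(seg$mean_fdm[1], 0.1)
  expect_gt(seg$mean_fdm[2], 0.3)
})

test_that("tract calling thresholds at 0.2 and merges across gaps <= 5 kb", {
  seg <- data.frame(chrom = "chr1",
                    first_window = c(1L, 10L, 20L),
                    last_window = c(9L, 19L, 30L),
                    start_bp = c(10e3, 54e3, 120e3),
                    end_bp = c(50e3, 100e3, 160e3),
                    n_windows = c(9L, 10L, 11L),
                    mean_fdm = c(0.25, 0.30, 0.15))
  class(seg) <- c("fdm_segments", "data.frame")
  tr <- call_tracts(seg)           # gap 4 kb between the first two: merged
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$start, 10e3)
  expect_equal(tr$end, 100e3)
  expect_equal(tr$mean_fdm, (0.25 * 9 + 0.30 * 10) / 19)

  seg$start_bp[2] <- 56001          # gap > 5 kb: two tracts
  expect_identical(nrow(call_tracts(seg)), 2L)

  seg$mean_fdm <- c(0.15, 0.1, 0.05)  # all below threshold: none
  expect_identical(nrow(call_tracts(seg)), 0L)
})

test_that("introgressed fraction is tract length over accessible length", {
  tr <- data.frame(chrom = "chr1", start = 1e6, end = 7e6, mean_fdm = 0.4,
                   n_windows = 10L)
  class(tr) <- c("tract_set", "data.frame")
  expect_equal(introgressed_fraction(tr, 1e8), 0.06)
  expect_equal(introgressed_fraction(tr[0, ], 1e8), 0)
  expect_error(introgressed_fraction(tr, 0), "positive")
})

test_that("planted tracts are recovered with the correct f_dM sign", {
  pan <- species_panel()
  tr <- data.frame(sample = "ornamental_1", haplotype = 1, chrom = "chr2",
                   start = 8e5, end = 9.6e5, donor = "imbellis")
  planted <- plant_tracts(pan, tr, seed = 11)$panel
  q <- quartet_spec(planted, paste0("ornamental_", 2:10), "ornamental_1",
                    paste0("imbellis_", 1:4), paste0("outgroup_", 1:2))
  tracts <- call_tracts(robust_segment(fdm_scan(planted, q)))
  hit <- tracts[tracts$chrom == "chr2" & tracts$start < 9.6e5 &
                  tracts$end > 8e5, ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(hit$mean_fdm > 0.2))

  # same tract planted into a p1 sample drives f_dM negative
  trn <- transform(tr, sample = "ornamental_2")
  planted2 <- plant_tracts(pan, trn, seed = 11)$panel
  q2 <- quartet_spec(planted2, "ornamental_2", "ornamental_1",
                     paste0("imbellis_", 1:4), paste0("outgroup_", 1:2))
  sc <- fdm_scan(planted2, q2)
  inside <- sc$chrom == "chr2" & sc$start_bp >= 8e5 & sc$end_bp <= 9.6e5
  expect_lt(mean(sc$fdm[inside], na.rm = TRUE), 0)
})
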