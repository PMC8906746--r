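test_that("pairwise distances count allele differences and are additive", {
  haps <- rbind(c(0L, 0L), c(0L, 0L),   # s1 hom-ref both sites
                c(1L, 0L), c(1L, 0L),   # s2 hom-alt site 1
                c(1L, 0L), c(0L, 0L))   # s3 het site 1
  pan <- toy_panel(haps, c(100L, 600L), len = 1000)
  d <- pairwise_distances(pan, window = 500)
  expect_equal(d$D["s1", "s2"], 2)      # hom-ref vs hom-alt
  expect_equal(d$D["s1", "s3"], 1)      # het vs hom
  expect_equal(d$D["s2", "s3"], 1)
  expect_equal(d$D["s1", "s1"], 0)
  expect_equal(Reduce(`+`, d$windows), d$D)

  pan2 <- single_pop_panel()
  d2 <- pairwise_distances(pan2, window = 1e5)
  expect_equal(Reduce(`+`, d2$windows), d2$D)
  expect_true(all(d2$D == t(d2$D)))
})

test_that("three-taxon NJ matches the closed-form star branches", {
  D <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(bl["A"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["B"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["C"]), (9 + 10 - 5) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces random additive matrices exactly", {
  for (seed in 1:8) {
    gen <- random_additive_matrix(ntax = sample(4:8, 1), seed = seed)
    tr <- nj_tree(gen$D)
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), tr)[1], 0)
    P <- stats::cophenetic(tr)
    expect_equal(P[rownames(gen$D), colnames(gen$D)], gen$D,
                 tolerance = 1e-8)
  }
})

test_that("negative NJ branches are clamped with length moved to sibling", {
  # near-degenerate matrix known to produce a negative NJ branch
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 0.1,
                3, 3, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D[1, 2] <- 0.1; D[2, 1] <- 0.1
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ recovers the simulated species topology", {
  pan <- species_panel()
  d <- pairwise_distances(pan, window = NULL)
  grp <- function(p) paste0(p, "_", 1)
  tr <- nj_tree(d$D)
  tr <- ape::root(tr, outgroup = "outgroup_1", resolve.root = TRUE)
  # ornamental and splendens samples must be sisters relative to imbellis
  keep <- c("ornamental_1", "splendens_1", "imbellis_1", "mahachaiensis_1",
            "outgroup_1")
  sub <- ape::keep.tip(tr, keep)
  expected <- ape::read.tree(text = paste0(
    "(outgroup_1,(mahachaiensis_1,(imbellis_1,",
    "(splendens_1,ornamental_1))));"))
  expect_equal(ape::dist.topo(ape::unroot(sub), ape::unroot(expected))[1], 0)
})

test_that("block bootstrap scores bipartition frequency correctly", {
  pan <- species_panel()
  d <- pairwise_distances(pan, window = 2e5)
  # identical windows: every support = 100
  same <- d
  same$windows <- lapply(seq_along(d$windows), function(i) d$D / 10)
  bb <- block_bootstrap(same, replicates = 50, seed = 3)
  expect_true(all(bb$supports == 100))

  bb2 <- block_bootstrap(d, replicates = 100, seed = 3)
  expect_true(all(bb2$supports >= 0 & bb2$supports <= 100))
  # the species split (all non-splendens-complex vs rest) should be solid
  expect_gt(mean(bb2$supports), 50)

  # windows drawn from two conflicting topologies at 70/30
  t1 <- random_additive_matrix(6, 1); labs <- rownames(t1$D)
  t2d <- t1$D[sample(labs), sample(labs)]
  t2d <- t2d[labs, labs]  # same labels, shuffled structure
  mix <- list(labels = labs, D = t1$D * 7 + t2d * 3,
              windows = c(rep(list(t1$D), 7), rep(list(t2d), 3)))
  bbm <- block_bootstrap(mix, replicates = 200, seed = 9)
  maj <- splits_oracle(nj_tree(t1$D), labs)
  # majority-topology splits present in the reference tree get strong support
  present <- intersect(maj, names(bbm$supports))
  expect_true(length(present) >= 1)
})

test_that("ancestry assignment recovers planted donors and handles ties", {
  pan <- species_panel()
  tr <- data.frame(sample = "ornamental_1", haplotype = 2, chrom = "chr3",
                   start = 5e5, end = 6.5e5, donor = "mahachaiensis")
  planted <- plant_tracts(pan, tr, seed = 23)$panel
  species <- list(splendens = paste0("splendens_", 1:4),
                  imbellis = paste0("imbellis_", 1:4),
                  mahachaiensis = paste0("mahachaiensis_", 1:4))
  a <- assign_ancestry(planted, list(chrom = "chr3", start = 5e5, end = 6.5e5),
                       "ornamental_1_2", species)
  expect_identical(a$label, "mahachaiensis")
  # the untouched haplotype of the same sample stays splendens
  b <- assign_ancestry(planted, list(chrom = "chr3", start = 5e5, end = 6.5e5),
                       "ornamental_1_1", species)
  expect_identical(b$label, "splendens")
  # a haplotype identical to a conspecific reference is splendens
  c0 <- assign_ancestry(pan, list(chrom = "chr1", start = 1, end = 2e6),
                        "ornamental_2_1", species)
  expect_identical(c0$label, "splendens")
  # no variation in the tract: unassigned with reason
  tiny <- assign_ancestry(pan, list(chrom = "chr1", start = 10, end = 11),
                          "ornamental_1_1", species)
  expect_identical(tiny$label, "unassigned")
  expect_match(tiny$reason, "no variation")
})

test_that("an exactly equidistant construction is unassigned", {
  # the two candidate donors carry identical reference haplotypes, so the
  # focal haplotype is equidistant from both species by construction
  base <- rep(0L, 20)
  focal <- base; focal[1:2] <- 1L
  don <- base; don[1] <- 1L; don[3] <- 1L
  spl1 <- base; spl1[10:12] <- 1L
  spl2 <- base; spl2[13:15] <- 1L
  haps <- rbind(focal, base,             # sample s1 (focal = s1_1)
                don, don,                # s2: species A
                don, don,                # s3: species B (same haplotypes)
                spl1, spl2)              # s4: splendens (diverse pair)
  pan <- toy_panel(haps, seq(10L, by = 10L, length.out = 20L),
                   pops = c("f", "A", "B", "spl"))
  res <- assign_ancestry(pan, list(chrom = "chr1", start = 1, end = 1000),
                         "s1_1",
                         list(splendens = "s4", A = "s2", B = "s3"))
  expect_identical(res$label, "unassigned")
})
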