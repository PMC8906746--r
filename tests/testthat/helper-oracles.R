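# Independent brute-force oracles used to validate the package's statistics.

# Two-tailed Fisher exact P by full hypergeometric enumeration.
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)), 0)
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact binomial P by point-probability enumeration.
binom_enum <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Tajima's D from first principles: pi as the mean over haplotype pairs of
# their per-window difference count, S directly, constants written out.
tajima_oracle <- function(hapmat) {
  nh <- nrow(hapmat)
  pairs <- utils::combn(nh, 2)
  diffs <- vapply(seq_len(ncol(pairs)), function(j)
    sum(hapmat[pairs[1, j], ] != hapmat[pairs[2, j], ]), 0)
  pi <- mean(diffs)
  p <- colMeans(hapmat)
  S <- sum(p > 0 & p < 1)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(nh - 1)); a2 <- sum(1 / seq_len(nh - 1)^2)
  b1 <- (nh + 1) / (3 * (nh - 1)); b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Mean pairwise per-site diversity by direct pair enumeration.
pi_oracle <- function(hapmat) {
  nh <- nrow(hapmat)
  pairs <- utils::combn(nh, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j)
    sum(hapmat[pairs[1, j], ] != hapmat[pairs[2, j], ]), 0))
}

# Scalar reference implementation of the burst-coalescent lineage chain;
# independent of the vectorized path used by expected_sfs.
burst_chain_slow <- function(n, tau_b, I, reps) {
  enter <- leave <- integer(reps)
  for (r in seq_len(reps)) {
    k <- n; t <- 0; enter[r] <- 1L; leave[r] <- 1L
    tb <- tau_b
    while (k > 1) {
      dt <- stats::rexp(1, k * (k - 1) / 2)
      if (is.finite(tb) && t + dt >= tb) {
        enter[r] <- k
        el <- 0
        while (k > 1) {
          el <- el + stats::rexp(1, k * (k - 1) / 2)
          if (el >= I) break
          k <- k - 1
        }
        leave[r] <- k
        tb <- Inf
        t <- 0
      } else {
        t <- t + dt
        k <- k - 1
      }
    }
  }
  mean((enter - leave) / pmax(enter, 1))
}

# Random additive (tree-metric) distance matrix plus its generating tree.
random_additive_matrix <- function(ntax, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntax, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  list(tree = tr, D = stats::cophenetic(tr))
}

# Unrooted bipartition keys of a tree (leaf side not containing ref label).
splits_oracle <- function(tree, labels) {
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- attr(parts, "labels")[p]
    if (labels[1] %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2 && length(side) <= length(labels) - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}
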