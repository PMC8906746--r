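#' Unfolded site frequency spectrum with outgroup polarization
#'
#' Assigns the ancestral allele at each site as the allele carried by at
#' least \code{threshold} of the outgroup haplotypes; sites without such a
#' consensus are dropped (and counted). Derived-allele counts among the
#' focal haplotypes are tallied into the unfolded spectrum xi_1..xi_{n-1}
#' (fixed classes 0 and n are excluded).
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param focal sample ids (or haplotype rows) whose spectrum is wanted.
#' @param outgroup sample ids (or haplotype rows) used for polarization.
#' @param threshold outgroup consensus frequency (default 0.9).
#' @param accessible_length accessible genome length L in bp (default: sum
#'   of chromosome lengths).
#' @return object of class \code{sfs}: list(counts, n, L, dropped).
#' @export
polarize <- function(panel, focal, outgroup, threshold = 0.9,
                     accessible_length = sum(panel$chrom_lengths)) {
  frow <- if (is.character(focal)) hap_rows(panel, samples = focal) else
    as.integer(focal)
  orow <- if (is.character(outgroup)) hap_rows(panel, samples = outgroup) else
    as.integer(outgroup)
  if (!length(orow)) stop("outgroup needs >= 1 haplotype")
  n <- length(frow)
  counts <- integer(n - 1)
  dropped <- 0L
  for (chrom in names(panel$chromosomes)) {
    hap <- panel$chromosomes[[chrom]]$haplotypes
    if (!ncol(hap)) next
    f1 <- colMeans(hap[orow, , drop = FALSE])
    anc <- ifelse(f1 >= threshold, 1L, ifelse(1 - f1 >= threshold, 0L, NA))
    dropped <- dropped + sum(is.na(anc))
    dc <- colSums(hap[frow, , drop = FALSE])
    dc <- ifelse(anc == 1L, n - dc, dc)
    dc <- dc[!is.na(anc) & dc > 0 & dc < n]
    if (length(dc)) {
      tab <- tabulate(dc, nbins = n - 1)
      counts <- counts + tab
    }
  }
  structure(list(counts = counts, n = n, L = accessible_length,
                 dropped = dropped), class = "sfs")
}

#' Unfolded SFS from known ancestral states
#'
#' For panels whose ancestral allele is known (allele 0 in simulated
#' panels), tallies derived-allele counts among the chosen haplotypes
#' directly, without outgroup polarization.
#'
#' @inheritParams polarize
#' @return object of class \code{sfs}.
#' @export
panel_sfs <- function(panel, focal,
                      accessible_length = sum(panel$chrom_lengths)) {
  if (!panel$ancestral_known)
    stop("ancestral state unknown; use polarize() with an outgroup")
  frow <- if (is.character(focal)) hap_rows(panel, samples = focal) else
    as.integer(focal)
  n <- length(frow)
  counts <- integer(n - 1)
  for (chrom in names(panel$chromosomes)) {
    hap <- panel$chromosomes[[chrom]]$haplotypes
    if (!ncol(hap)) next
    dc <- colSums(hap[frow, , drop = FALSE])
    dc <- dc[dc > 0 & dc < n]
    if (length(dc)) counts <- counts + tabulate(dc, nbins = n - 1)
  }
  structure(list(counts = counts, n = n, L = accessible_length,
                 dropped = 0L), class = "sfs")
}

#' Build an SFS object directly
#' @param counts xi_1..xi_{n-1}.
#' @param n haplotype sample size.
#' @param L accessible length in bp.
#' @param dropped sites dropped by polarization.
#' @return object of class \code{sfs}.
#' @export
sfs <- function(counts, n, L, dropped = 0L) {
  stopifnot(length(counts) == n - 1, all(counts >= 0))
  structure(list(counts = counts, n = n, L = L, dropped = dropped),
            class = "sfs")
}

#' Single-bottleneck demographic model
#'
#' An otherwise constant diploid population of size Ne with one
#' instantaneous bottleneck at time T_b generations ago of intensity I in
#' coalescent units (I = duration / (2 * Ne during the bottleneck)): at T_b
#' the coalescent experiences I extra units of coalescent opportunity
#' without the passage of real time.
#'
#' @param Ne baseline diploid effective size.
#' @param T_b bottleneck time in generations (0 < T_b <= 3000 in the default
#'   search bounds).
#' @param I bottleneck intensity (>= 0; 0 = no bottleneck).
#' @return object of class \code{bottleneck_model}.
#' @export
bottleneck_model <- function(Ne, T_b, I) {
  stopifnot(Ne > 0, T_b > 0, I >= 0)
  structure(list(Ne = Ne, T_b = T_b, I = I), class = "bottleneck_model")
}

# Simulate the coalescent block-counting (lineage-count) chain under the
# burst model, in coalescent time units of 2Ne generations. Returns, per
# replicate, the vector of k * (scaled time with k lineages) accumulated
# OUTSIDE the burst (the burst is instantaneous in real time), plus the
# lineage counts entering/leaving the burst.
burst_chain <- function(n, tau_b, I, reps) {
  kt <- matrix(0, nrow = reps, ncol = n)   # column k = k * scaled T_k
  enter <- leave <- rep(1L, reps)
  ks <- n:2                                 # lineage counts of each epoch
  inv_rate <- 2 / (ks * (ks - 1))
  # all randomness drawn up front (three standard-exponential streams per
  # replicate: pre-burst epochs, burst epochs, post-burst epochs)
  E1 <- matrix(stats::rexp(reps * (n - 1)), reps)
  E2 <- matrix(stats::rexp(reps * (n - 1)), reps)
  E3 <- matrix(stats::rexp(reps * (n - 1)), reps)
  for (r in seq_len(reps)) {
    w <- E1[r, ] * inv_rate                 # scaled epoch durations
    ct <- cumsum(w)
    if (!is.finite(tau_b) || ct[n - 1] <= tau_b) {
      # MRCA reached before the burst (or no burst): plain Kingman path
      kt[r, ks] <- ks * w
      next
    }
    hit <- which.max(ct > tau_b)            # epoch interrupted by the burst
    kb <- n - hit + 1L                      # lineages entering the burst
    if (hit > 1) {
      pre <- seq_len(hit - 1)
      kt[r, ks[pre]] <- ks[pre] * w[pre]
    }
    kt[r, kb] <- kt[r, kb] + kb * (tau_b - (if (hit > 1) ct[hit - 1] else 0))
    enter[r] <- kb
    kp <- kb
    if (kb > 1) {
      bi <- hit:(n - 1)                     # epochs kb, kb-1, ..., 2
      eb <- cumsum(E2[r, seq_along(bi)] * inv_rate[bi])
      kp <- kb - sum(eb <= I)
    }
    leave[r] <- kp
    if (kp > 1) {
      pi <- (n - kp + 1L):(n - 1L)          # epochs kp..2
      kt[r, kp:2] <- kt[r, kp:2] + (kp:2) * (E3[r, seq_along(pi)] * inv_rate[pi])
    }
  }
  list(kt = kt, enter = enter, leave = leave)
}

.weights_cache <- new.env(parent = emptyenv())

# P[a lineage among k ancestors subtends i of n leaves] for the
# exchangeable coalescent: C(n-i-1, k-2) / C(n-1, k-1).
subtend_weights <- function(n) {
  key <- as.character(n)
  if (!is.null(W <- .weights_cache[[key]])) return(W)
  W <- matrix(0, nrow = n - 1, ncol = n)   # rows i = 1..n-1, cols k = 1..n
  for (k in 2:n)
    for (i in seq_len(n - 1))
      if (n - i - 1 >= k - 2)
        W[i, k] <- exp(lchoose(n - i - 1, k - 2) - lchoose(n - 1, k - 1))
  .weights_cache[[key]] <- W
  W
}

#' Expected unfolded SFS under the instantaneous-bottleneck coalescent
#'
#' E[xi_i] = mu * L * E[branch length subtending i of n leaves], where the
#' genealogy follows a coalescent whose scaled time advances at rate
#' 1/(2 Ne) per generation and receives an instantaneous extra I units of
#' coalescent opportunity at T_b generations ago. The expectation is Monte
#' Carlo over genealogical lineage-count trajectories combined with the
#' exact leaf-subtending probabilities of the exchangeable coalescent;
#' I = 0 reduces to the constant-size coalescent with E[xi_i] = theta L / i.
#'
#' @param model a \code{\link{bottleneck_model}}.
#' @param n haplotype sample size (>= 2).
#' @param L accessible length in bp.
#' @param mu mutation rate per bp per generation.
#' @param reps Monte Carlo genealogy replicates (default 200).
#' @param seed integer seed (recorded in the result).
#' @return numeric vector E[xi_1..xi_{n-1}] with attributes \code{se}
#'   (per-class Monte Carlo standard error) and \code{seed}.
#' @export
expected_sfs <- function(model, n, L, mu, reps = 200, seed = 1L) {
  stopifnot(n >= 2, reps >= 1)
  tau_b <- model$T_b / (2 * model$Ne)
  sim <- with_seed(seed, burst_chain(n, if (model$I > 0) tau_b else Inf,
                                     model$I, reps))
  W <- subtend_weights(n)
  B <- sim$kt %*% t(W) * (2 * model$Ne)    # reps x (n-1), generations
  cm <- colMeans(B)
  ev <- mu * L * cm
  csd <- if (reps > 1)
    sqrt(pmax(colSums(B^2) - reps * cm^2, 0) / (reps - 1)) else rep(0, n - 1)
  se <- mu * L * csd / sqrt(reps)
  attr(ev, "se") <- se
  attr(ev, "seed") <- seed
  ev
}

#' Expected fraction of lineages coalescing during the bottleneck
#'
#' Monte Carlo mean of (lineages entering - lineages leaving) / (lineages
#' entering) at the instantaneous bottleneck event.
#'
#' @inheritParams expected_sfs
#' @return a fraction in [0, 1); 0 when I = 0.
#' @export
coalesced_fraction <- function(model, n, reps = 2000, seed = 1L) {
  stopifnot(n >= 2)
  if (model$I == 0) return(0)
  tau_b <- model$T_b / (2 * model$Ne)
  sim <- with_seed(seed, burst_chain(n, tau_b, model$I, reps))
  mean((sim$enter - sim$leave) / sim$enter)
}

# Composite log-likelihood of observed SFS counts against expectations.
sfs_loglik <- function(obs, expected, likelihood = c("poisson", "multinomial")) {
  likelihood <- match.arg(likelihood)
  e <- pmax(expected, 1e-9)
  if (likelihood == "poisson")
    sum(obs * log(e) - e)
  else {
    p <- e / sum(e)
    sum(obs * log(p))
  }
}

#' Fit the instantaneous-bottleneck model to an observed SFS
#'
#' Maximizes the composite log-likelihood of the observed unfolded spectrum
#' against \code{\link{expected_sfs}} over (Ne, T_b, I) by derivative-free
#' simplex search on transformed parameters (log Ne, logit-bounded T_b,
#' sqrt I so the I = 0 boundary is reachable), from \code{restarts} seeded
#' random starts plus a start at the null optimum. A null model with I = 0
#' is fitted alongside with the same Monte Carlo randomness, so the
#' alternative's maximized likelihood is never below the null's. The
#' default Poisson likelihood factorizes as the multinomial spectrum-shape
#' term times a Poisson term for the total segregating-site count; the
#' total-count term is what makes Ne and T_b separately identifiable.
#'
#' @param sfs_obs an \code{\link{sfs}}.
#' @param mu mutation rate per bp per generation.
#' @param bounds list with elements Ne (length-2), T_b (length-2, default
#'   c(1, 3000)), I (upper bound, default 5).
#' @param restarts random restarts (default 5).
#' @param reps Monte Carlo replicates per likelihood evaluation.
#' @param likelihood "poisson" (default) or "multinomial".
#' @param seed integer seed (starts and common random numbers).
#' @param maxit simplex iterations per restart.
#' @return object of class \code{bottleneck_fit}: list(best = c(Ne, T_b, I),
#'   loglik, null = list(Ne, loglik), lr (likelihood ratio statistic),
#'   replicates (per-restart optima), seed).
#' @export
fit_bottleneck <- function(sfs_obs, mu, bounds = list(Ne = c(100, 5e6),
                                                      T_b = c(1, 3000),
                                                      I = 5),
                           restarts = 5, reps = 400,
                           likelihood = c("poisson", "multinomial"),
                           seed = 1L, maxit = 500) {
  likelihood <- match.arg(likelihood)
  if (!sum(sfs_obs$counts)) stop("empty SFS")
  obs <- sfs_obs$counts
  n <- sfs_obs$n
  L <- sfs_obs$L
  eval_seed <- seed + 777L
  tb_lo <- bounds$T_b[1]; tb_hi <- bounds$T_b[2]

  decode <- function(x) {
    Ne <- exp(x[1])
    T_b <- tb_lo + (tb_hi - tb_lo) / (1 + exp(-x[2]))
    I <- x[3]^2
    c(Ne = Ne, T_b = T_b, I = I)
  }
  objective <- function(x) {
    p <- decode(x)
    if (p["Ne"] < bounds$Ne[1] || p["Ne"] > bounds$Ne[2] || p["I"] > bounds$I)
      return(1e12)
    ev <- expected_sfs(bottleneck_model(p["Ne"], p["T_b"], p["I"]),
                       n, L, mu, reps = reps, seed = eval_seed)
    -sfs_loglik(obs, ev, likelihood)
  }
  # null model: I = 0; same Monte Carlo machinery, 1-D in log Ne
  null_obj <- function(lne) {
    ev <- expected_sfs(bottleneck_model(exp(lne), 1, 0), n, L, mu,
                       reps = reps, seed = eval_seed)
    -sfs_loglik(obs, ev, likelihood)
  }
  # Watterson-style moment start for Ne
  a1 <- sum(1 / seq_len(n - 1))
  ne_w <- max(bounds$Ne[1], min(bounds$Ne[2], sum(obs) / (4 * mu * L * a1)))
  null_fit <- stats::optimize(null_obj, log(bounds$Ne))
  null_ne <- exp(null_fit$minimum)
  null_ll <- -null_fit$objective

  starts <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      ne0 <- ne_w * exp(stats::runif(1, -1, 1))
      tb0 <- stats::runif(1, tb_lo + 1, tb_hi - 1)
      i0 <- stats::runif(1, 0.1, 1)
      c(log(ne0), stats::qlogis((tb0 - tb_lo) / (tb_hi - tb_lo)), sqrt(i0))
    })
  })
  starts <- c(starts, list(c(log(null_ne), 0, 0)))
  fits <- lapply(starts, function(x0) {
    f <- stats::optim(x0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
    # fresh simplex from the optimum to escape premature contraction
    stats::optim(f$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9))
  })
  opt_tab <- do.call(rbind, lapply(fits, function(f)
    c(decode(f$par), loglik = -f$value)))
  opt_tab <- as.data.frame(opt_tab)
  best_i <- which.max(opt_tab$loglik)
  best <- fits[[best_i]]
  best_par <- decode(best$par)
  structure(list(
    best = best_par, loglik = -best$value,
    null = list(Ne = null_ne, loglik = null_ll),
    lr = 2 * ((-best$value) - null_ll),
    replicates = opt_tab, likelihood = likelihood, seed = seed,
    reps = reps), class = "bottleneck_fit")
}

#' @export
print.bottleneck_fit <- function(x, ...) {
  cat(sprintf("<bottleneck_fit> Ne = %.0f, T_b = %.0f gen, I = %.3f\n",
              x$best["Ne"], x$best["T_b"], x$best["I"]))
  cat(sprintf("  loglik = %.2f (null, I = 0: %.2f); LR = %.2f\n",
              x$loglik, x$null$loglik, x$lr))
  invisible(x)
}

#' Effective population size from nucleotide diversity
#'
#' Ne = pi / (4 mu) for a neutral equilibrium diploid population, with an
#' optional rounding mode for reporting.
#'
#' @param pi nucleotide diversity per bp (> 0).
#' @param mu mutation rate per bp per generation (> 0).
#' @param round_to "none", "hundred" or "thousand".
#' @return diploid Ne.
#' @export
ne_from_pi <- function(pi, mu, round_to = c("none", "hundred", "thousand")) {
  round_to <- match.arg(round_to)
  if (mu <= 0) stop("mu must be positive")
  if (pi <= 0) stop("pi must be positive")
  ne <- pi / (4 * mu)
  switch(round_to,
         none = ne,
         hundred = round(ne / 100) * 100,
         thousand = round(ne / 1000) * 1000)
}

#' Bottleneck census size implied by an intensity
#'
#' Inverts intensity = duration / (2 * Ne_bottleneck): for an assumed
#' bottleneck duration in generations, returns the implied diploid size
#' during the bottleneck.
#'
#' @param duration bottleneck duration in generations.
#' @param I bottleneck intensity (> 0).
#' @return Ne during the bottleneck.
#' @export
intensity_convert <- function(duration, I) {
  if (I <= 0) stop("intensity must be positive")
  duration / (2 * I)
}

#' Nucleotide diversity with accessible-site denominator
#'
#' Per-site unbiased pairwise diversity 2 p (1 - p) n/(n - 1), summed over
#' variant sites and divided by the accessible (variant plus invariant)
#' length; also returns a windowed track (10 kb windows, 100 bp slide,
#' windows with 3 kb or less accessible dropped) and a leave-one-
#' chromosome-out jackknife confidence interval.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids or haplotype row indices.
#' @param accessible optional per-chromosome list of accessible-interval
#'   matrices (columns start, end, 0-based half-open); NULL = everything.
#' @param window,slide windowed-track parameters in bp.
#' @param min_accessible minimum accessible bp per emitted window
#'   (exclusive, default 3000).
#' @return list with pi, ci (95\% jackknife), se, per_chromosome, windows.
#' @export
nucleotide_diversity <- function(panel, group, accessible = NULL,
                                 window = 1e4, slide = 100,
                                 min_accessible = 3000) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  n <- length(rows)
  if (n < 2) stop("need >= 2 haplotypes")
  chroms <- names(panel$chromosomes)
  sums <- lens <- stats::setNames(numeric(length(chroms)), chroms)
  wins <- list()
  for (chrom in chroms) {
    ch <- panel$chromosomes[[chrom]]
    accm <- if (is.null(accessible)) NULL else accessible[[chrom]]
    len <- panel$chrom_lengths[[chrom]]
    acc_len <- interval_overlap(0, len, accm)
    p <- colMeans(ch$haplotypes[rows, , drop = FALSE])
    pos0 <- ch$positions - 1
    use <- p > 0 & p < 1
    if (!is.null(accm))
      use <- use & interval_overlap(pos0, pos0 + 1, accm) > 0
    d <- (n / (n - 1)) * 2 * p[use] * (1 - p[use])
    sums[chrom] <- sum(d)
    lens[chrom] <- acc_len
    starts <- seq(0, max(0, len - window), by = slide)
    ends <- pmin(starts + window, len)
    pv <- pos0[use]
    cs <- c(0, cumsum(d))
    lo <- findInterval(starts - 0.5, pv) + 1L
    hi <- findInterval(ends - 0.5, pv)
    acc_bp <- interval_overlap(starts, ends, accm)
    piw <- ifelse(acc_bp > min_accessible,
                  (cs[hi + 1L] - cs[lo]) / acc_bp, NA_real_)
    wins[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                accessible_bp = acc_bp, pi = piw,
                                stringsAsFactors = FALSE)
  }
  if (sum(lens) == 0) stop("zero accessible sites")
  pi_hat <- sum(sums) / sum(lens)
  m <- length(chroms)
  ci <- c(NA_real_, NA_real_); se <- NA_real_
  if (m > 1) {
    loo <- vapply(seq_len(m), function(j)
      sum(sums[-j]) / sum(lens[-j]), 0)
    se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
    ci <- pi_hat + c(-1.96, 1.96) * se
  }
  list(pi = pi_hat, ci = ci, se = se,
       per_chromosome = sums / pmax(lens, 1),
       windows = do.call(rbind, c(wins, make.row.names = FALSE)))
}
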