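#' Simulate a phased haplotype panel under a demographic model
#'
#' Draws a neutral coalescent sample (with recombination and binary
#' mutations) under the given demography, using the msprime engine through
#' the bundled Python backend. The ancestral allele is 0 at every emitted
#' site and only segregating sites are returned. The result is
#' bit-reproducible given the seed in \code{params}.
#'
#' @param model a \code{\link{demography_model}}.
#' @param params a \code{\link{sim_params}} (rates, chromosome layout, seed).
#' @param samples_per_population named integer vector: diploids sampled per
#'   population (populations absent from the vector are not sampled).
#'
#' @return a \code{\link{haplotype_panel}}.
#' @export
simulate_panel <- function(model, params, samples_per_population) {
  stopifnot(inherits(model, "demography_model"), inherits(params, "sim_params"))
  if (is.null(names(samples_per_population)) ||
      !all(names(samples_per_population) %in% names(model$populations)))
    stop("samples_per_population must name populations of the model")
  if (any(samples_per_population < 1))
    stop("counts must be >= 1 per sampled population")

  out_dir <- tempfile("bettapop_sim_")
  cfg <- list(
    populations = lapply(names(model$populations), function(p)
      list(name = p, size = unname(model$populations[p]))),
    splits = df_records(model$splits),
    pulses = df_records(model$pulses),
    bottlenecks = df_records(model$bottlenecks),
    samples = as.list(stats::setNames(as.integer(samples_per_population),
                                      names(samples_per_population))),
    chromosomes = as.list(params$chrom_lengths),
    mutation_rate = params$mutation_rate,
    recombination_rate = params$recombination_rate,
    seed = params$seed,
    out_dir = out_dir
  )
  cfg_file <- tempfile("bettapop_cfg_", fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  on.exit(unlink(c(cfg_file, out_dir), recursive = TRUE), add = TRUE)

  script <- system.file("python", "msprime_panel.py", package = "bettapop")
  if (!nzchar(script)) stop("bundled msprime backend not found")
  res <- suppressWarnings(
    system2("python", c(shQuote(script), shQuote(cfg_file)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if ((!is.null(status) && status != 0) || !file.exists(file.path(out_dir, "DONE")))
    stop("coalescent backend failed:\n", paste(res, collapse = "\n"))

  meta <- utils::read.table(file.path(out_dir, "samples.txt"), sep = "\t",
                            col.names = c("sample", "population"),
                            colClasses = "character")
  chroms <- lapply(names(params$chrom_lengths), function(chrom) {
    f <- file.path(out_dir, paste0(chrom, ".tsv"))
    if (file.size(f) == 0)
      return(list(positions = integer(0),
                  haplotypes = matrix(integer(0), nrow = 2L * nrow(meta))))
    dt <- data.table::fread(f, header = FALSE, data.table = FALSE)
    pos <- as.integer(dt[[1]])
    hap <- t(as.matrix(dt[, -1, drop = FALSE]))
    storage.mode(hap) <- "integer"
    dimnames(hap) <- NULL
    # msprime can place two sites at the same discrete coordinate on rare
    # occasions after filtering; keep the first.
    keep <- !duplicated(pos)
    list(positions = pos[keep], haplotypes = hap[, keep, drop = FALSE])
  })
  names(chroms) <- names(params$chrom_lengths)
  haplotype_panel(meta$sample, meta$population, chroms, params$chrom_lengths,
                  ancestral_known = TRUE, seed = params$seed)
}

df_records <- function(df) {
  if (is.null(df) || !nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' An empty ground-truth table
#'
#' Records the signals planted into a panel: introgression tracts, sweep
#' haplotypes, and the sex-determining locus. Used to score recovery by the
#' downstream callers.
#' @return an object of class \code{truth_table}.
#' @export
truth_table <- function() {
  structure(list(
    tracts = data.frame(sample = character(), haplotype = integer(),
                        chrom = character(), start = numeric(),
                        end = numeric(), donor = character(),
                        donor_haplotype = character(),
                        stringsAsFactors = FALSE),
    sweeps = data.frame(group = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        carrier_fraction = numeric(), stringsAsFactors = FALSE),
    sex_locus = NULL
  ), class = "truth_table")
}

#' Plant introgressed tracts into a panel
#'
#' Copies, for each requested interval, the alleles of a randomly chosen
#' donor-population haplotype onto one haplotype of the recipient sample.
#' Nothing outside the requested intervals is touched.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param tracts data.frame with columns \code{sample}, \code{haplotype}
#'   (1 or 2), \code{chrom}, \code{start}, \code{end} (bp, inclusive),
#'   \code{donor} (population label).
#' @param seed integer seed controlling donor haplotype choice.
#' @return list with elements \code{panel} (modified copy) and \code{truth}
#'   (a \code{truth_table} with one record per planted tract).
#' @export
plant_tracts <- function(panel, tracts, seed = 1L) {
  truth <- truth_table()
  if (is.null(tracts) || !nrow(tracts)) return(list(panel = panel, truth = truth))
  stopifnot(all(c("sample", "haplotype", "chrom", "start", "end", "donor")
                %in% names(tracts)))
  key <- paste(tracts$sample, tracts$haplotype, tracts$chrom)
  for (k in unique(key)) {
    sub <- tracts[key == k, , drop = FALSE]
    if (nrow(sub) > 1) {
      o <- order(sub$start)
      if (any(sub$start[o][-1] <= sub$end[o][-nrow(sub)]))
        stop("overlapping requested tracts on the same haplotype")
    }
  }
  for (i in seq_len(nrow(tracts))) {
    lim <- panel$chrom_lengths[[tracts$chrom[i]]]
    if (is.null(lim) || tracts$start[i] < 1 || tracts$end[i] > lim ||
        tracts$start[i] > tracts$end[i])
      stop("tract interval out of chromosome bounds")
  }
  donor_hap <- character(nrow(tracts))
  with_seed(seed, {
    for (i in seq_len(nrow(tracts))) {
      donors <- hap_rows(panel, populations = tracts$donor[i])
      if (!length(donors)) stop("donor population has no haplotypes")
      src <- if (length(donors) == 1) donors else sample(donors, 1)
      ch <- panel$chromosomes[[tracts$chrom[i]]]
      cols <- which(ch$positions >= tracts$start[i] &
                    ch$positions <= tracts$end[i])
      row <- 2L * match(tracts$sample[i], panel$samples) -
        2L + as.integer(tracts$haplotype[i])
      if (length(cols))
        panel$chromosomes[[tracts$chrom[i]]]$haplotypes[row, cols] <-
          ch$haplotypes[src, cols]
      donor_hap[i] <- rownames(ch$haplotypes)[src]
    }
  })
  truth$tracts <- data.frame(sample = tracts$sample,
                             haplotype = as.integer(tracts$haplotype),
                             chrom = tracts$chrom, start = tracts$start,
                             end = tracts$end, donor = tracts$donor,
                             donor_haplotype = donor_hap,
                             stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

#' Plant a selective-sweep haplotype into a group
#'
#' Chooses one core haplotype within the group and copies its alleles over
#' the interval onto a fraction \code{carrier_fraction} of the group's
#' haplotypes, emulating the extended-homozygosity footprint of a recent
#' sweep. Alleles outside the interval are untouched.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group character vector of sample ids forming the swept group.
#' @param chrom,start,end the swept interval (bp, inclusive).
#' @param carrier_fraction fraction f in (0, 1] of group haplotypes carrying
#'   the core haplotype after planting.
#' @param seed integer seed (core and carrier choice).
#' @return list with \code{panel} and \code{truth} (sweep record).
#' @export
plant_sweep <- function(panel, group, chrom, start, end, carrier_fraction,
                        seed = 1L) {
  if (!length(group)) stop("group empty")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  rows <- hap_rows(panel, samples = group)
  ch <- panel$chromosomes[[chrom]]
  if (is.null(ch)) stop("unknown chromosome ", chrom)
  cols <- which(ch$positions >= start & ch$positions <= end)
  with_seed(seed, {
    core <- if (length(rows) == 1) rows else sample(rows, 1)
    k <- max(1L, round(carrier_fraction * length(rows)))
    carriers <- unique(c(core, sample(setdiff(rows, core),
                                      max(0L, k - 1L))))
    if (length(cols))
      for (r in carriers)
        panel$chromosomes[[chrom]]$haplotypes[r, cols] <-
          ch$haplotypes[core, cols]
  })
  truth <- truth_table()
  truth$sweeps <- data.frame(group = paste(group, collapse = ","),
                             chrom = chrom, start = start, end = end,
                             carrier_fraction = carrier_fraction,
                             stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

#' Assign gonadal sex from an XY locus with incomplete penetrance
#'
#' Each sample's XX/XY status is read from the panel (the Y allele is the
#' derived allele at the locus site) or supplied directly, and sex is drawn
#' per sample as a Bernoulli variable: females arise with probability
#' \code{penetrance[1]} among XX and males with probability
#' \code{penetrance[2]} among XY (and YY, if present).
#'
#' @param panel a \code{\link{haplotype_panel}}, or NULL when \code{status}
#'   is supplied.
#' @param locus list(chrom=, pos=) identifying the sex-determining site, or
#'   NULL with \code{status} given.
#' @param penetrance numeric length 2: (P(female | XX), P(male | XY)).
#' @param status optional character vector of per-sample "XX"/"XY" calls,
#'   bypassing the locus lookup.
#' @param seed integer seed.
#' @return data.frame with columns sample, genotype, sex.
#' @export
assign_sex <- function(panel = NULL, locus = NULL, penetrance = c(0.87, 0.93),
                       status = NULL, seed = 1L) {
  stopifnot(length(penetrance) == 2, all(penetrance >= 0 & penetrance <= 1))
  if (is.null(status)) {
    ch <- panel$chromosomes[[locus$chrom]]
    j <- match(locus$pos, ch$positions)
    if (is.na(j)) stop("no site at the sex locus position")
    g <- genotype_matrix(panel, locus$chrom)[, j]
    status <- ifelse(g == 0, "XX", ifelse(g == 1, "XY", "YY"))
    samples <- panel$samples
  } else {
    samples <- names(status)
    if (is.null(samples)) samples <- paste0("s", seq_along(status))
  }
  sex <- with_seed(seed, {
    u <- stats::runif(length(status))
    ifelse(status == "XX",
           ifelse(u < penetrance[1], "F", "M"),
           ifelse(u < penetrance[2], "M", "F"))
  })
  data.frame(sample = samples, genotype = status, sex = sex,
             stringsAsFactors = FALSE)
}

#' Observe a sequenced trio with a simple read-count error model
#'
#' Takes true biallelic genotypes for a father/mother/offspring trio and
#' produces quality-annotated called genotypes: per genotype, depth DP is
#' Poisson(coverage); the alt-supporting read count AD is Binomial(DP, 1/2)
#' for true heterozygotes, Binomial(DP, error_rate) for true hom-ref, and
#' DP - Binomial(DP, error_rate) for true hom-alt. Genotypes are re-called
#' from the reads (het iff the minor-read fraction is >= 0.2, else the
#' majority homozygote; missing when DP = 0); GQ is the phred-scaled
#' binomial log-likelihood gap between the best and second-best genotype,
#' capped at 99; site MQ is 60 except for a small contaminant fraction of
#' sites drawn uniformly in [20, 45].
#'
#' @param genotypes integer matrix 3 x n_sites (values 0/1/2 counting alt
#'   alleles), rows named father/mother/offspring (order is kept as given).
#' @param coverage mean sequencing depth (> 0).
#' @param error_rate per-read base error rate in [0, 1).
#' @param positions optional site positions (default 1, 101, 201, ...).
#' @param chrom chromosome label for the sites.
#' @param low_mq_fraction fraction of sites given a low MQ draw.
#' @param seed integer seed.
#' @return an \code{\link{annotated_genotypes}} table.
#' @export
observe_trio <- function(genotypes, coverage, error_rate,
                         positions = NULL, chrom = "chr1",
                         low_mq_fraction = 0.02, seed = 1L) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == 3, coverage > 0,
            error_rate >= 0, error_rate < 1)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- c("father", "mother", "offspring")
  ns <- ncol(genotypes)
  if (is.null(positions)) positions <- seq(1L, by = 100L, length.out = ns)
  with_seed(seed, {
    dp <- matrix(stats::rpois(3 * ns, coverage), nrow = 3)
    ad <- matrix(0L, nrow = 3, ncol = ns)
    het <- genotypes == 1L
    ad[het] <- stats::rbinom(sum(het), dp[het], 0.5)
    hr <- genotypes == 0L
    ad[hr] <- stats::rbinom(sum(hr), dp[hr], error_rate)
    ha <- genotypes == 2L
    ad[ha] <- dp[ha] - stats::rbinom(sum(ha), dp[ha], error_rate)
    mq <- rep(60, ns)
    low <- stats::runif(ns) < low_mq_fraction
    mq[low] <- stats::runif(sum(low), 20, 45)
  })
  vaf <- ifelse(dp > 0, ad / dp, NA_real_)
  minor <- pmin(vaf, 1 - vaf)
  gt <- ifelse(dp == 0, NA_integer_,
               ifelse(minor >= 0.2, 1L, ifelse(vaf >= 0.5, 2L, 0L)))
  # phred-scaled likelihood gap; error floor keeps the gap finite
  e <- max(error_rate, 1e-3)
  ll <- function(p) stats::dbinom(ad, dp, p, log = TRUE)
  lmat <- array(c(ll(e), ll(0.5), ll(1 - e)), dim = c(3, ns, 3))
  best2 <- apply(lmat, c(1, 2), function(v) {
    s <- sort(v, decreasing = TRUE)
    s[1] - s[2]
  })
  gq <- pmin(round(10 / log(10) * best2), 99)
  gq[is.na(gt)] <- 0
  storage.mode(gq) <- "integer"
  annotated_genotypes(
    sites = data.frame(chrom = chrom, pos = positions, ref = "A", alt = "T",
                       MQ = mq, stringsAsFactors = FALSE),
    GT = gt, GQ = gq, DP = dp, AD = ad,
    samples = rownames(genotypes),
    params = list(coverage = coverage, error_rate = error_rate,
                  low_mq_fraction = low_mq_fraction, seed = seed,
                  het_call_minor_fraction = 0.2))
}

#' Simulate true trio genotypes
#'
#' Draws parental genotypes from Hardy-Weinberg proportions at the given
#' allele frequencies and the offspring by Mendelian transmission; a
#' convenience generator for exercising the trio observation model and the
#' Mendelian-error machinery.
#'
#' @param n_sites number of sites.
#' @param maf allele frequency (scalar or per site).
#' @param seed integer seed.
#' @return integer matrix 3 x n_sites with rows father/mother/offspring.
#' @export
simulate_trio <- function(n_sites, maf = 0.3, seed = 1L) {
  with_seed(seed, {
    p <- rep_len(maf, n_sites)
    fa <- stats::rbinom(n_sites, 2, p)
    mo <- stats::rbinom(n_sites, 2, p)
    transmit <- function(g) ifelse(g == 0, 0L, ifelse(g == 2, 1L,
                                   stats::rbinom(n_sites, 1, 0.5)))
    off <- transmit(fa) + transmit(mo)
    out <- rbind(father = fa, mother = mo, offspring = off)
    storage.mode(out) <- "integer"
    out
  })
}
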