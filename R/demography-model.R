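#' Demographic model for panel simulation
#'
#' A rooted multi-population history given as present-day populations, a set
#' of (backwards-in-time) population splits, optional admixture pulses, and
#' optional single instantaneous bottlenecks. Bottleneck intensity is
#' expressed in coalescent units: intensity = duration / (2 * Ne during the
#' bottleneck), so the event adds that much coalescent opportunity at a single
#' generation.
#'
#' @param populations named numeric vector of diploid effective sizes; names
#'   are population labels (ancestral populations included).
#' @param splits data.frame with columns \code{time} (generations, > 0),
#'   \code{derived}, \code{ancestral}: at \code{time}, lineages of
#'   \code{derived} merge into \code{ancestral}.
#' @param pulses data.frame with columns \code{time}, \code{source},
#'   \code{recipient}, \code{fraction}: forward in time, \code{recipient}
#'   receives \code{fraction} of its ancestry from \code{source}.
#' @param bottlenecks data.frame with columns \code{population}, \code{time},
#'   \code{intensity} (coalescent units, >= 0); at most one per population.
#'
#' @return An object of class \code{demography_model}.
#' @export
demography_model <- function(populations, splits = NULL, pulses = NULL,
                             bottlenecks = NULL) {
  if (is.null(names(populations)) || any(populations <= 0))
    stop("populations must be a named vector of positive diploid sizes")
  pops <- names(populations)
  if (!is.null(splits) && nrow(splits)) {
    stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
    if (any(splits$time <= 0)) stop("split times must be strictly positive")
    if (!all(c(splits$derived, splits$ancestral) %in% pops))
      stop("split references unknown population")
    if (anyDuplicated(splits$derived))
      stop("inconsistent split topology: a population splits twice")
    # A single rooted tree: following derived -> ancestral links must never
    # cycle, and exactly one population is never derived (the root).
    anc <- stats::setNames(splits$ancestral, splits$derived)
    for (p in splits$derived) {
      seen <- character()
      q <- p
      while (q %in% names(anc)) {
        if (q %in% seen) stop("inconsistent split topology: cycle at ", q)
        seen <- c(seen, q)
        if (anc[[q]] == p) stop("inconsistent split topology: cycle at ", p)
        q <- anc[[q]]
      }
    }
  }
  if (!is.null(pulses) && nrow(pulses)) {
    stopifnot(all(c("time", "source", "recipient", "fraction") %in% names(pulses)))
    if (any(pulses$time <= 0)) stop("pulse times must be strictly positive")
    if (any(pulses$fraction < 0 | pulses$fraction > 1))
      stop("pulse fractions must be in [0, 1]")
    if (!all(c(pulses$source, pulses$recipient) %in% pops))
      stop("pulse references unknown population")
  }
  if (!is.null(bottlenecks) && nrow(bottlenecks)) {
    stopifnot(all(c("population", "time", "intensity") %in% names(bottlenecks)))
    if (any(bottlenecks$time <= 0)) stop("bottleneck times must be positive")
    if (any(bottlenecks$intensity < 0)) stop("bottleneck intensity must be >= 0")
    if (anyDuplicated(bottlenecks$population))
      stop("at most one bottleneck per population")
    if (!all(bottlenecks$population %in% pops))
      stop("bottleneck references unknown population")
  }
  structure(list(populations = populations, splits = splits, pulses = pulses,
                 bottlenecks = bottlenecks),
            class = "demography_model")
}

#' Simulation parameters
#'
#' Genome layout and per-generation rates used by \code{\link{simulate_panel}}.
#' Defaults are the betta study conditions: mutation rate 3.75e-9 per bp per
#' generation, recombination 6.6 cM/Mb, and 21 chromosomes of 14 Mb each
#' (scalable down for desk-scale work).
#'
#' @param mutation_rate per bp per generation.
#' @param recomb_cm_mb recombination rate in centimorgan per megabase
#'   (1 cM/Mb = 1e-8 crossovers per bp per generation).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param seed integer random seed recorded in all outputs.
#'
#' @return An object of class \code{sim_params}.
#' @export
sim_params <- function(mutation_rate = 3.75e-9, recomb_cm_mb = 6.6,
                       chrom_lengths = stats::setNames(rep(14e6, 21),
                                                       paste0("chr", 1:21)),
                       seed = 1L) {
  stopifnot(mutation_rate >= 0, recomb_cm_mb >= 0, length(chrom_lengths) >= 1,
            all(chrom_lengths > 0))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(list(mutation_rate = mutation_rate,
                 recomb_cm_mb = recomb_cm_mb,
                 recombination_rate = recomb_cm_mb * 1e-8,
                 chrom_lengths = chrom_lengths,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' The default five-species study scenario
#'
#' A single-rooted five-population history shaped like the betta species
#' complex: an outgroup, two candidate donor species (mahachaiensis-like and
#' imbellis-like), a wild splendens population, and an ornamental focal
#' population that split from wild splendens most recently. Split times are
#' free configuration of the generator (they are not study estimates); they
#' are chosen deep enough between species that donor tracts are clearly
#' differentiated, and shallow between ornamental and wild splendens.
#'
#' @param Ne diploid size used for every population.
#' @param bottleneck optional data.frame passed through to
#'   \code{\link{demography_model}}.
#' @return a \code{demography_model}.
#' @export
default_scenario <- function(Ne = 10000, bottleneck = NULL) {
  pops <- stats::setNames(rep(Ne, 8),
                          c("ornamental", "splendens", "imbellis",
                            "mahachaiensis", "outgroup",
                            "anc1", "anc2", "root"))
  # Topology (outgroup, (mahachaiensis, (imbellis, (splendens, ornamental))))
  splits <- data.frame(
    time      = c(4000,        120000,      120000, 250000, 250000,
                  500000, 500000),
    derived   = c("ornamental", "splendens", "imbellis", "anc1",
                  "mahachaiensis", "anc2", "outgroup"),
    ancestral = c("splendens",  "anc1",      "anc1",  "anc2",
                  "anc2",          "root", "root"),
    stringsAsFactors = FALSE)
  demography_model(pops, splits = splits, bottlenecks = bottleneck)
}
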