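#' Pairwise allele-difference distances between diploid samples
#'
#' Counts, for every sample pair, the number of allele differences between
#' diploid genotypes summed over sites (hom-ref vs hom-alt contributes 2, a
#' het vs either hom contributes 1), both genome-wide and on a fixed
#' 100-kb window grid; windowed matrices sum to the whole-genome matrix.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param window window size in bp (default 1e5); NULL disables windowing.
#' @return list with \code{labels}, \code{D} (whole-genome matrix) and
#'   \code{windows} (named list of per-window matrices, names
#'   "chrom:start-end" with 0-based half-open bounds).
#' @export
pairwise_distances <- function(panel, window = 1e5) {
  labels <- panel$samples
  n <- length(labels)
  total <- matrix(0, n, n, dimnames = list(labels, labels))
  wins <- list()
  for (chrom in names(panel$chromosomes)) {
    G <- genotype_matrix(panel, chrom)
    pos <- panel$chromosomes[[chrom]]$positions
    if (is.null(window)) {
      if (ncol(G)) total <- total + manhattan(G)
      next
    }
    len <- panel$chrom_lengths[[chrom]]
    starts <- seq(0, max(0, len - 1), by = window)
    wi <- findInterval(pos - 1, starts)
    for (b in seq_along(starts)) {
      cols <- which(wi == b)
      dm <- if (length(cols)) manhattan(G[, cols, drop = FALSE]) else
        matrix(0, n, n, dimnames = list(labels, labels))
      nm <- sprintf("%s:%d-%d", chrom, as.integer(starts[b]),
                    as.integer(min(starts[b] + window, len)))
      wins[[nm]] <- dm
      total <- total + dm
    }
  }
  list(labels = labels, D = total, windows = wins)
}

manhattan <- function(G) {
  d <- as.matrix(stats::dist(G, method = "manhattan"))
  dimnames(d) <- list(rownames(G), rownames(G))
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor joining on a distance matrix; any negative branch
#' length is clamped to zero and its magnitude transferred to the sibling
#' branch at the same node, preserving path lengths through the parent.
#'
#' @param D symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 labels")
  tr <- ape::nj(D)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amount <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sib)) {
      s <- sib[1]
      tr$edge.length[s] <- tr$edge.length[s] + amount
    }
  }
  tr
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Each internal edge splits the leaves; the side NOT containing the
# reference label (first in `labels`) identifies the split.
tree_splits <- function(tree, labels) {
  nt <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], desc))
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nt) next  # trivial split
    side <- desc(child)
    if (labels[1] %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > length(labels) - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Block-bootstrap node supports for the whole-genome NJ tree
#'
#' Resamples the 100-kb windowed distance matrices with replacement, sums
#' each resample into a genome-scale matrix, rebuilds the NJ tree, and
#' scores how often each bipartition of the whole-genome tree appears.
#'
#' @param dists output of \code{\link{pairwise_distances}} (with windows).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{tree} (whole-genome NJ tree whose
#'   \code{node.label} holds supports in [0, 100]) and \code{supports}
#'   (named vector per bipartition).
#' @export
block_bootstrap <- function(dists, replicates = 1000, seed = 1L) {
  wins <- dists$windows
  if (length(wins) < 2) stop("need at least 2 windows")
  labels <- dists$labels
  ref <- nj_tree(dists$D)
  ref_keys <- tree_splits(ref, labels)
  counts <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      idx <- sample(length(wins), length(wins), replace = TRUE)
      Dm <- Reduce(`+`, wins[idx])
      keys <- tree_splits(nj_tree(Dm), labels)
      hit <- ref_keys %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / replicates
  # attach supports to internal nodes of the reference tree
  nt <- length(ref$tip.label)
  nn <- ref$Nnode
  node_lab <- rep("", nn)
  children <- split(ref$edge[, 2], ref$edge[, 1])
  desc <- function(node) {
    if (node <= nt) return(ref$tip.label[node])
    unlist(lapply(children[[as.character(node)]], desc))
  }
  for (node in seq_len(nn) + nt) {
    side <- desc(node)
    if (labels[1] %in% side) side <- setdiff(labels, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports))
      node_lab[node - nt] <- format(supports[[key]], digits = 4)
  }
  ref$node.label <- node_lab
  list(tree = ref, supports = supports)
}

#' Assign donor ancestry to a tract haplotype
#'
#' Builds a local NJ tree over the haplotypes spanning a called tract and
#' computes the focal haplotype's mean patristic (branch-length) distance
#' to the haplotypes of each candidate species. The focal haplotype is
#' assigned to a donor species when (a) its mean distance to that species
#' is smaller than its mean distance to the splendens reference haplotypes
#' and (b) smaller than the mean plus 2 SD of the pairwise patristic
#' distances among the splendens haplotypes; otherwise it is labelled
#' "splendens". Exact ties between qualifying donors give "unassigned", as
#' does a tract with no variation.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param tract list or one-row data.frame with chrom, start, end.
#' @param focal_hap haplotype id (e.g. "orn_1_2") or row index.
#' @param species named list mapping species label to sample ids serving as
#'   references (each candidate needs >= 2 haplotypes).
#' @param splendens name of the conspecific reference group in
#'   \code{species} (default "splendens").
#' @return list with \code{label}, \code{mean_distances}, \code{threshold},
#'   and \code{reason} for unassigned calls.
#' @export
assign_ancestry <- function(panel, tract, focal_hap, species,
                            splendens = "splendens") {
  stopifnot(splendens %in% names(species))
  ch <- panel$chromosomes[[tract$chrom]]
  cols <- which(ch$positions >= tract$start & ch$positions <= tract$end)
  rows_by_sp <- lapply(species, function(s) hap_rows(panel, samples = s))
  focal <- if (is.character(focal_hap))
    match(focal_hap, rownames(ch$haplotypes)) else as.integer(focal_hap)
  if (is.na(focal)) stop("unknown focal haplotype")
  rows_by_sp <- lapply(rows_by_sp, setdiff, y = focal)
  if (any(lengths(rows_by_sp) < 2))
    stop("each reference species needs >= 2 haplotypes")
  use <- c(focal, unlist(rows_by_sp))
  H <- ch$haplotypes[use, cols, drop = FALSE]
  rownames(H) <- c("FOCAL", rownames(ch$haplotypes)[unlist(rows_by_sp)])
  if (!length(cols) || all(apply(H, 2, function(x) length(unique(x)) == 1)))
    return(list(label = "unassigned", mean_distances = NULL, threshold = NA,
                reason = "no variation in tract"))
  D <- manhattan(H)
  tr <- nj_tree(D)
  P <- stats::cophenetic(tr)
  sp_names <- rownames(ch$haplotypes)
  idx_of <- function(rows) match(sp_names[rows], rownames(P))
  mean_d <- vapply(rows_by_sp, function(rows)
    mean(P["FOCAL", idx_of(rows)]), 0)
  spl_idx <- idx_of(rows_by_sp[[splendens]])
  within <- P[spl_idx, spl_idx][upper.tri(P[spl_idx, spl_idx])]
  sd_w <- if (length(within) > 1) stats::sd(within) else 0
  thr <- mean(within) + 2 * sd_w
  cand <- setdiff(names(species), splendens)
  ok <- cand[mean_d[cand] < mean_d[[splendens]] & mean_d[cand] < thr]
  label <- if (!length(ok)) splendens else {
    best <- ok[mean_d[ok] == min(mean_d[ok])]
    if (length(best) > 1) "unassigned" else best
  }
  list(label = label, mean_distances = mean_d, threshold = thr,
       reason = if (identical(label, "unassigned")) "tie" else NA_character_)
}
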