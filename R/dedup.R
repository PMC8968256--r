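#' Pairwise identity-by-state over homozygous, non-missing sites
#'
#' For every accession pair, identity is the fraction of sites where both
#' carry the same homozygous code, among sites where both are homozygous
#' and non-missing; heterozygous or missing calls are excluded from both
#' numerator and denominator. For duplicate detection the matrix should
#' first be filtered to informative sites (conventionally MAF > 0.05,
#' missing < 50%, het < 10%).
#'
#' @param G a `geno_matrix` with at least two accessions.
#' @param min_compared minimum number of jointly homozygous loci for a
#'   pair to be evaluable; pairs below the floor get `NA` identity (never
#'   "identical by too little data").
#' @return An `ibs_result`: list with `ids`, `identity` (N x N, unit
#'   diagonal) and `compared` (N x N locus counts).
#' @export
ibs_matrix <- function(G, min_compared = 500) {
  stopifnot(inherits(G, "geno_matrix"))
  if (n_accessions(G) < 2L) stop("at least two accessions required")
  a0 <- !is.na(G$calls) & G$calls == 0L
  a2 <- !is.na(G$calls) & G$calls == 2L
  storage.mode(a0) <- "numeric"
  storage.mode(a2) <- "numeric"
  match_mat <- tcrossprod(a0) + tcrossprod(a2)
  hom <- a0 + a2
  compared <- tcrossprod(hom)
  identity <- match_mat / compared
  identity[compared < min_compared] <- NA_real_
  diag(identity) <- 1
  ids <- accession_ids(G)
  dimnames(identity) <- dimnames(compared) <- list(ids, ids)
  structure(list(ids = ids, identity = identity, compared = compared,
                 min_compared = min_compared),
            class = "ibs_result")
}

#' @export
print.ibs_result <- function(x, ...) {
  off <- x$identity[upper.tri(x$identity)]
  cat(sprintf("ibs_result: %d accessions, %d pairs (%d undefined)\n",
              length(x$ids), length(off), sum(is.na(off))))
  if (any(!is.na(off))) {
    cat(sprintf("  identity range %.4f - %.4f\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Automatic identity threshold discovery
#'
#' Histograms the off-diagonal identity fractions and looks for the
#' near-perfect-identity mode produced by duplicated accessions (a local
#' maximum in the region above `high_region`, populated by at least
#' `min_mode_count` pairs), separated from the bulk of unrelated pairs.
#' The threshold returned is the midpoint of a minimum-density bin
#' between the global bulk mode and the duplicate mode nearest 1.0; when
#' the valley is a flat run of equally sparse bins, the cut is placed at
#' the run's upper quarter, leaning toward the duplicate mode, because a
#' threshold set too low (merging genuinely distinct accessions) is the
#' costlier curation error.
#' Without a separated high-identity mode the `default` is returned and
#' the `note` attribute explains why.
#'
#' @param values numeric vector of pairwise identity fractions (at least
#'   100).
#' @param bin_width histogram bin width (0.25 percentage points by
#'   default, fine enough to resolve a 99% valley at typical GBS marker
#'   densities).
#' @param default threshold used when no duplicate mode is found.
#' @param high_region duplicate modes are searched above this identity;
#'   clones differ only by genotyping error, so their mode sits near 1.
#' @param min_mode_count minimum pairs in a bin for it to count as a
#'   mode (guards against sparse bulk-tail bins).
#' @return threshold fraction, with attribute `note`.
#' @export
detect_identity_threshold <- function(values, bin_width = 0.0025, default = 0.99,
                                      high_region = 0.95, min_mode_count = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 100L) stop("at least 100 pairwise identity values required")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  nb <- length(cnt)
  low <- which(h$mids < high_region)
  if (!length(low) || all(cnt[low] == 0L)) {
    return(structure(default, note = "no duplicate mode"))
  }
  bulk <- low[which.max(cnt[low])]
  left <- c(0L, cnt[-nb])
  right <- c(cnt[-1L], 0L)
  candidates <- which(cnt >= min_mode_count & cnt >= left & cnt >= right &
                        h$mids >= high_region & seq_len(nb) > bulk)
  if (!length(candidates)) {
    return(structure(default, note = "no duplicate mode"))
  }
  high <- max(candidates)
  if (high - bulk < 2L) {
    return(structure(default, note = "no separated duplicate mode"))
  }
  between <- seq(bulk + 1L, high - 1L)
  valley <- min(cnt[between])
  if (valley >= min(cnt[bulk], cnt[high])) {
    return(structure(default, note = "no separated duplicate mode"))
  }
  at_min <- between[cnt[between] == valley]
  # the bulk can itself be multimodal (within- vs between-group pairs), so
  # use the minimal-density run directly below the duplicate mode; within
  # that run, cut at its upper quarter: merging distinct accessions
  # (threshold too low) is the costlier curation error, so the separation
  # point leans toward the duplicate mode
  runs <- split(at_min, cumsum(c(1L, diff(at_min) != 1L)))
  last_run <- runs[[length(runs)]]
  pick <- last_run[ceiling(3 * length(last_run) / 4)]
  structure(h$mids[pick], note = "duplicate mode found")
}

#' Group genetically identical accessions
#'
#' Builds a graph with an edge for every defined pair at or above the
#' identity threshold; connected components of size >= 2 are the sets of
#' genetically identical accessions (identity is treated as transitive
#' within a set, matching how curators handle "identical groups").
#'
#' @param ibs an [ibs_matrix()] result.
#' @param threshold identity fraction declaring a pair identical.
#' @return A `duplicate_groups` object: list with `threshold`, `groups`
#'   (list of id vectors, largest first), `unique_count`
#'   (`N - sum(size - 1)`) and `n`.
#' @export
duplicate_groups <- function(ibs, threshold = 0.99) {
  stopifnot(inherits(ibs, "ibs_result"))
  adj <- !is.na(ibs$identity) & ibs$identity >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(ibs$ids, comp$membership)
  groups <- members[lengths(members) >= 2L]
  groups <- groups[order(-lengths(groups))]
  names(groups) <- NULL
  n <- length(ibs$ids)
  structure(
    list(threshold = threshold, groups = groups,
         unique_count = n - sum(lengths(groups) - 1L), n = n),
    class = "duplicate_groups"
  )
}

#' @export
print.duplicate_groups <- function(x, ...) {
  redundant <- x$n - x$unique_count
  cat(sprintf(
    "duplicate_groups: %d group(s) at identity >= %.4f\n  %d of %d accessions redundant; %d unique (%.1f%%)\n",
    length(x$groups), x$threshold, redundant, x$n, x$unique_count,
    100 * x$unique_count / x$n))
  if (length(x$groups)) {
    cat(sprintf("  largest set: %d accessions\n", length(x$groups[[1L]])))
  }
  invisible(x)
}

#' Cross-validate duplicate groups against glume colour
#'
#' Genetically identical accessions should share morphology; for each
#' group the distinct non-missing glume colour scores (0 white - 9 black)
#' are listed and groups with more than one distinct score are flagged for
#' curator review.
#'
#' @param groups a [duplicate_groups()] object (or list of id vectors).
#' @param passports passport data frame with `accession_id` and
#'   `glume_score`.
#' @return data frame with one row per group: `group`, `n_members`,
#'   `scores` (collapsed distinct scores), `status` (`consistent`,
#'   `mismatch`, `no phenotype`).
#' @export
phenotype_consistency <- function(groups, passports) {
  if (inherits(groups, "duplicate_groups")) groups <- groups$groups
  rows <- lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    sc <- passports$glume_score[match(ids, passports$accession_id)]
    sc <- sort(unique(sc[!is.na(sc)]))
    data.frame(
      group = i, n_members = length(ids),
      scores = paste(sc, collapse = ","),
      status = if (!length(sc)) "no phenotype"
               else if (length(sc) == 1L) "consistent" else "mismatch",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows) %||% data.frame(group = integer(), n_members = integer(),
                                       scores = character(), status = character())
}
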