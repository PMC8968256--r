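#' Pairwise genetic distance matrix
#'
#' Two metrics are offered. `one_minus_ibs` (default) is
#' `1 - identity-by-state` over jointly homozygous non-missing sites — the
#' missing-data-robust choice for sparse GBS calls. `euclidean` is the
#' root-sum-square of dosage differences over shared non-missing sites,
#' rescaled by `sqrt(L_total / L_shared)` so pairs with different overlap
#' are comparable.
#'
#' @param G a `geno_matrix`.
#' @param metric `"one_minus_ibs"` or `"euclidean"`.
#' @param min_compared for `one_minus_ibs`, minimum jointly homozygous
#'   loci per pair; an undefined pair is an error (the matrix must be
#'   filtered or the floor lowered).
#' @return A `geno_dist`: list with `ids`, `d` (symmetric matrix, zero
#'   diagonal) and `metric`. Use [stats::as.dist()] on `$d` for clustering
#'   functions.
#' @export
distance_matrix <- function(G, metric = c("one_minus_ibs", "euclidean"),
                            min_compared = 500) {
  metric <- match.arg(metric)
  stopifnot(inherits(G, "geno_matrix"))
  ids <- accession_ids(G)
  if (metric == "one_minus_ibs") {
    ibs <- ibs_matrix(G, min_compared = min_compared)
    d <- 1 - ibs$identity
    if (anyNA(d)) {
      bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
      stop("pair with too few compared loci: ",
           ids[bad[1L]], " / ", ids[bad[2L]])
    }
  } else {
    w <- !is.na(G$calls)
    a <- G$calls
    a[!w] <- 0L
    storage.mode(a) <- "numeric"
    storage.mode(w) <- "numeric"
    a2 <- a^2
    ss <- a2 %*% t(w) + w %*% t(a2) - 2 * tcrossprod(a)
    l_shared <- tcrossprod(w)
    if (any(l_shared[upper.tri(l_shared)] == 0)) {
      bad <- which(l_shared == 0 & upper.tri(l_shared), arr.ind = TRUE)[1L, ]
      stop("pair with no shared genotyped loci: ",
           ids[bad[1L]], " / ", ids[bad[2L]])
    }
    d <- sqrt(pmax(ss, 0) * n_sites(G) / l_shared)
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, metric = metric), class = "geno_dist")
}

#' @export
print.geno_dist <- function(x, ...) {
  cat(sprintf("geno_dist (%s): %d accessions\n", x$metric, length(x$ids)))
  invisible(x)
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a genetic distance matrix, as used for
#' distance-based clustering of gene bank collections. Negative branch
#' length estimates (a finite-sample artefact of NJ) are clamped to zero;
#' the number clamped is stored in the `clamped` attribute.
#'
#' @param D a [distance_matrix()] result (or a plain symmetric matrix with
#'   dimnames).
#' @return An unrooted `phylo` tree (see \pkg{ape}).
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "geno_dist")) D$d else as.matrix(D)
  if (nrow(d) < 3L) stop("at least 3 accessions required for a tree")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths; the unrooted tree is written with
#' its basal multifurcation as-is. Labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
to_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  needs_quote <- grepl("[][ ():;,]", tree$tip.label)
  orig <- tree$tip.label
  # write.tree sanitises labels, so awkward ones go through placeholders
  # and come back single-quoted
  tree$tip.label[needs_quote] <-
    sprintf("GCQUOTE%04dX", which(needs_quote))
  s <- ape::write.tree(tree)
  for (i in which(needs_quote)) {
    s <- sub(sprintf("GCQUOTE%04dX", i),
             paste0("'", orig[i], "'"), s, fixed = TRUE)
  }
  writeLines(s, path)
  invisible(path)
}

#' PCA on the genomic relationship matrix
#'
#' Centres each site by twice its alternate-allele frequency (missing
#' calls contribute the site mean, i.e. zero after centring), forms the
#' additive relationship matrix `Z Z' / (2 * sum p (1 - p))` and
#' eigendecomposes it. Coordinates are eigenvectors scaled by the square
#' root of their eigenvalues, and variance explained is eigenvalue over
#' trace.
#'
#' @param G a `geno_matrix` with at least two accessions.
#' @param k number of components to return.
#' @return A `grm_pca` object: `coordinates` (N x k, rownames = ids),
#'   `variance_explained` (length k) and `values` (all eigenvalues).
#' @export
grm_pca <- function(G, k = 10) {
  stopifnot(inherits(G, "geno_matrix"), n_accessions(G) >= 2L)
  p <- colMeans(G$calls, na.rm = TRUE) / 2
  use <- !is.na(p)
  denom <- 2 * sum(p[use] * (1 - p[use]))
  if (denom == 0) stop("no polymorphism: relationship matrix has zero variance")
  z <- sweep(G$calls[, use, drop = FALSE], 2L, 2 * p[use])
  z[is.na(z)] <- 0
  kin <- tcrossprod(z) / denom
  e <- eigen(kin, symmetric = TRUE)
  k <- min(k, nrow(kin))
  vals <- e$values
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(k)], 0)), k)
  rownames(coords) <- accession_ids(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(coordinates = coords,
         variance_explained = pmax(vals, 0)[seq_len(k)] / sum(pmax(vals, 0)),
         values = vals),
    class = "grm_pca"
  )
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("grm_pca: %d accessions, %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Flag putatively misclassified accessions
#'
#' Advisory k-nearest-neighbour vote on genetic distance: an accession is
#' flagged when the majority taxon among its k nearest non-self
#' neighbours differs from its own passport label and the majority is
#' strong (fraction >= `agreement`). Duplicate accessions should be
#' collapsed to one representative first so clone clusters cannot
#' dominate the vote. Flags are curation proposals, never auto-applied.
#'
#' @param D a [distance_matrix()] result.
#' @param labels named character vector mapping accession id to passport
#'   taxon label; must cover all ids in `D`.
#' @param k_neighbors neighbours considered.
#' @param agreement minimum majority fraction to flag.
#' @return data frame of proposals: `accession_id`, `passport_label`,
#'   `proposed_label`, `agreement`.
#' @export
flag_misclassified <- function(D, labels, k_neighbors = 10, agreement = 0.8) {
  stopifnot(inherits(D, "geno_dist"))
  n <- length(D$ids)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of accessions")
  lab <- labels[D$ids]
  if (anyNA(lab)) {
    stop("labels missing for: ",
         paste(D$ids[is.na(lab)], collapse = ", "))
  }
  rows <- lapply(seq_len(n), function(i) {
    ord <- order(D$d[i, ])
    ord <- ord[ord != i][seq_len(k_neighbors)]
    tab <- sort(table(lab[ord]), decreasing = TRUE)
    maj <- names(tab)[1L]
    frac <- tab[[1L]] / k_neighbors
    if (maj != lab[i] && frac >= agreement) {
      data.frame(accession_id = D$ids[i], passport_label = unname(lab[i]),
                 proposed_label = maj, agreement = frac,
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(accession_id = character(), passport_label = character(),
                      proposed_label = character(), agreement = numeric())
}
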