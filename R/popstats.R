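#' Nei gene diversity
#'
#' Average expected heterozygosity over sites: per site
#' `h = 1 - p^2 - q^2 = 2 p q` with `p` the alternate-allele frequency
#' over non-missing alleles; the index is the plain mean of `h` over all
#' sites with a defined frequency. No small-sample correction is applied
#' (set `correct = TRUE` for the `n/(n-1)` allele-count correction when
#' validating against estimators that use it).
#'
#' @param G a `geno_matrix` with >= 2 accessions.
#' @param correct apply the small-sample correction `2n/(2n-1)` per site.
#' @return diversity index in `[0, 0.5]` for biallelic loci.
#' @export
nei_diversity <- function(G, correct = FALSE) {
  stopifnot(inherits(G, "geno_matrix"), n_accessions(G) >= 2L)
  st <- site_stats(G)
  ok <- !is.na(st$alt_freq)
  if (!any(ok)) stop("no site with a defined allele frequency")
  h <- 2 * st$alt_freq[ok] * (1 - st$alt_freq[ok])
  if (correct) {
    nal <- 2 * (st$n_hom_ref + st$n_het + st$n_hom_alt)[ok]
    h <- h * nal / (nal - 1)
  }
  mean(h)
}

#' Count segregating loci in a group
#'
#' A site segregates when at least two distinct non-missing genotype
#' classes are observed. For large groups (more than `min_population`
#' accessions) the single-heterozygote fixed-locus rule is applied first
#' when `apply_single_het_rule` is `TRUE`, so isolated heterozygote calls
#' on a fixed background are not counted as segregation.
#'
#' @param G a `geno_matrix` restricted to one group.
#' @param apply_single_het_rule drop single-het otherwise-fixed loci
#'   first.
#' @param min_population gate for the single-het rule.
#' @return integer count of segregating sites.
#' @export
segregating_count <- function(G, apply_single_het_rule = TRUE,
                              min_population = 100) {
  st <- site_stats(G)
  seg <- (st$n_hom_ref > 0L) + (st$n_het > 0L) + (st$n_hom_alt > 0L) >= 2L
  if (apply_single_het_rule && n_accessions(G) > min_population) {
    single <- st$n_het == 1L & (st$n_hom_ref == 0L | st$n_hom_alt == 0L)
    seg <- seg & !single
  }
  sum(seg)
}

#' Indices of segregating sites (same rule as [segregating_count()])
#' @inheritParams segregating_count
#' @return integer site indices.
#' @export
segregating_sites <- function(G, apply_single_het_rule = TRUE,
                              min_population = 100) {
  st <- site_stats(G)
  seg <- (st$n_hom_ref > 0L) + (st$n_het > 0L) + (st$n_hom_alt > 0L) >= 2L
  if (apply_single_het_rule && n_accessions(G) > min_population) {
    single <- st$n_het == 1L & (st$n_hom_ref == 0L | st$n_hom_alt == 0L)
    seg <- seg & !single
  }
  which(seg)
}

.group_site_summary <- function(G, ids) {
  sub <- subset_geno(G, accessions = ids)
  calls <- sub$calls
  n_obs <- colSums(!is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  p <- (2 * colSums(calls == 2L, na.rm = TRUE) + n_het) / (2 * n_obs)
  p[n_obs == 0L] <- NA_real_
  list(n = n_obs, p = p, h = ifelse(n_obs > 0L, n_het / n_obs, NA_real_))
}

.resolve_pair <- function(groups, pair) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2L]]),
                              as.character(groups[[1L]]))
  }
  stopifnot(length(pair) == 2L)
  ids1 <- names(groups)[groups == pair[1L]]
  ids2 <- names(groups)[groups == pair[2L]]
  if (length(ids1) < 2L || length(ids2) < 2L) {
    stop("both groups need at least 2 members: ",
         pair[1L], " (", length(ids1), "), ", pair[2L], " (", length(ids2), ")")
  }
  list(ids1 = ids1, ids2 = ids2)
}

#' Pairwise group F_ST (G_ST-style ratio of sums)
#'
#' Nei-style fixation index between two groups:
#' `F = 1 - sum_j H_S,j / sum_j H_T,j`, where `H_S,j` is the
#' sample-size-weighted mean within-group expected heterozygosity at site
#' j and `H_T,j` the expected heterozygosity of the pooled allele
#' frequency. The ratio-of-sums form is used for stability at
#' low-diversity loci. Sites undefined in either group are skipped.
#'
#' @param G a `geno_matrix`.
#' @param groups named character vector (accession id -> group label) or
#'   two-column data frame.
#' @param pair character vector of the two group labels to compare.
#' @return F_ST value; `NA` with a warning when both groups are fixed
#'   identically everywhere (total heterozygosity zero).
#' @export
pairwise_fst <- function(G, groups, pair) {
  pr <- .resolve_pair(groups, pair)
  g1 <- .group_site_summary(G, pr$ids1)
  g2 <- .group_site_summary(G, pr$ids2)
  ok <- !is.na(g1$p) & !is.na(g2$p)
  if (!any(ok)) stop("no site with defined frequencies in both groups")
  n1 <- g1$n[ok]; n2 <- g2$n[ok]
  p1 <- g1$p[ok]; p2 <- g2$p[ok]
  hs <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ht <- 2 * pbar * (1 - pbar)
  if (sum(ht) == 0) {
    warning("total heterozygosity is zero; F_ST undefined")
    return(NA_real_)
  }
  1 - sum(hs) / sum(ht)
}

#' Per-site Weir-Cockerham F_ST (theta-hat) for two groups
#'
#' The 1984 variance-components estimator with components computed from
#' per-group sample sizes, allele frequencies and observed heterozygote
#' fractions at each site. Sites where either group has fewer than two
#' non-missing calls, or where `a + b + c = 0`, are undefined (`NA`).
#' Negative per-site estimates are retained: clamping would bias the
#' genome-wide mean and standard deviation used by the selection scan.
#'
#' @inheritParams pairwise_fst
#' @return A `wc_fst` data frame: `chrom`, `pos`, `id`, `n1`, `n2`, `a`,
#'   `b`, `c`, `theta`.
#' @export
wc_fst_per_site <- function(G, groups, pair) {
  pr <- .resolve_pair(groups, pair)
  g1 <- .group_site_summary(G, pr$ids1)
  g2 <- .group_site_summary(G, pr$ids2)
  r <- 2
  n1 <- g1$n; n2 <- g2$n
  defined <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * g1$p + n2 * g2$p) / (r * nbar)
  s2 <- (n1 * (g1$p - pbar)^2 + n2 * (g2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * g1$h + n2 * g2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!defined] <- NA_real_; b[!defined] <- NA_real_; cc[!defined] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  out <- data.frame(chrom = G$sites$chrom, pos = G$sites$pos,
                    id = G$sites$id, n1 = n1, n2 = n2,
                    a = a, b = b, c = cc, theta = theta,
                    stringsAsFactors = FALSE)
  class(out) <- c("wc_fst", "data.frame")
  out
}

#' Multi-locus Weir-Cockerham F_ST
#'
#' Ratio-of-sums summary `sum(a) / sum(a + b + c)` over all sites with
#' defined variance components — the standard multi-locus estimate.
#'
#' @param x a [wc_fst_per_site()] result.
#' @return single F_ST estimate.
#' @export
wc_fst_multilocus <- function(x) {
  stopifnot(inherits(x, "wc_fst"))
  ok <- !is.na(x$a)
  sum(x$a[ok]) / sum(x$a[ok] + x$b[ok] + x$c[ok])
}

#' Per-group diversity report
#'
#' Tabulates, for each group of a labelled collection, the number of
#' accessions, Nei diversity and segregating-locus count and percentage —
#' the summary curators use to compare species, races and core sets.
#'
#' @param G a `geno_matrix`.
#' @param groups named character vector (accession id -> group label).
#' @param apply_single_het_rule,min_population passed to
#'   [segregating_count()].
#' @return data frame with columns `group`, `n`, `nei`, `segregating`,
#'   `segregating_pct`.
#' @export
diversity_report <- function(G, groups, apply_single_het_rule = TRUE,
                             min_population = 100) {
  labs <- unique(groups[names(groups) %in% accession_ids(G)])
  rows <- lapply(labs, function(g) {
    ids <- names(groups)[groups == g]
    ids <- intersect(ids, accession_ids(G))
    sub <- subset_geno(G, accessions = ids)
    seg <- segregating_count(sub, apply_single_het_rule, min_population)
    data.frame(group = g, n = length(ids),
               nei = if (length(ids) >= 2L) nei_diversity(sub) else NA_real_,
               segregating = seg,
               segregating_pct = 100 * seg / n_sites(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise F_ST matrix over all group pairs
#'
#' @inheritParams diversity_report
#' @param method `"gst"` (ratio-of-sums G_ST, [pairwise_fst()]) or
#'   `"wc"` (multi-locus Weir-Cockerham).
#' @return symmetric matrix of pairwise F_ST with group labels as
#'   dimnames.
#' @export
fst_matrix <- function(G, groups, method = c("gst", "wc")) {
  method <- match.arg(method)
  labs <- unique(groups[names(groups) %in% accession_ids(G)])
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  diag(m) <- 0
  if (length(labs) >= 2L) {
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in seq((i + 1L), length(labs))) {
        val <- if (method == "gst") {
          pairwise_fst(G, groups, c(labs[i], labs[j]))
        } else {
          wc_fst_multilocus(wc_fst_per_site(G, groups, c(labs[i], labs[j])))
        }
        m[i, j] <- m[j, i] <- val
      }
    }
  }
  m
}
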