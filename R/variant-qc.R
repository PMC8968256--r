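#' Per-site genotype statistics
#'
#' Counts genotype classes per site and derives minor-allele frequency,
#' missing rate and heterozygosity rate. Frequencies are computed over
#' non-missing alleles only; a site with no non-missing call gets `NA`
#' frequency and is thereby flagged as degenerate.
#'
#' @param G a `geno_matrix`.
#' @return data frame with one row per site: `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing`, `alt_freq`, `maf`, `missing_rate`, `het_rate`.
#' @export
site_stats <- function(G) {
  stopifnot(inherits(G, "geno_matrix"), nrow(G$calls) >= 1L)
  calls <- G$calls
  n <- nrow(calls)
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(calls == 2L, na.rm = TRUE)
  n_missing <- colSums(is.na(calls))
  n_hom_ref <- n - n_het - n_hom_alt - n_missing
  n_obs <- n - n_missing
  q <- (2 * n_hom_alt + n_het) / (2 * n_obs)
  q[n_obs == 0L] <- NA_real_
  data.frame(
    n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt,
    n_missing = n_missing,
    alt_freq = q,
    maf = pmin(q, 1 - q),
    missing_rate = n_missing / n,
    het_rate = ifelse(n_obs > 0L, n_het / n_obs, NA_real_),
    row.names = G$sites$id
  )
}

#' One-sided Fisher exact P for disassociation of ref and alt alleles
#'
#' For inbred material a true biallelic SNP should appear as mutually
#' exclusive homozygotes across accessions. Per site a 2x2 per-accession
#' allele-presence table is formed (both alleles present = heterozygotes,
#' ref only = hom-ref, alt only = hom-alt, neither = missing) and the
#' one-sided Fisher exact P-value for under-representation of
#' co-occurrence (odds ratio < 1) is the lower hypergeometric tail of the
#' heterozygote count given the table margins.
#'
#' @param n_het,n_hom_ref,n_hom_alt,n_missing integer vectors of per-site
#'   genotype-class counts.
#' @return numeric vector of P-values.
#' @export
fisher_disassociation_p <- function(n_het, n_hom_ref, n_hom_alt, n_missing) {
  n <- n_het + n_hom_ref + n_hom_alt + n_missing
  ref_present <- n_het + n_hom_ref
  alt_present <- n_het + n_hom_alt
  stats::phyper(n_het, alt_present, n - alt_present, ref_present)
}

#' Fisher exact disassociation filter
#'
#' Keeps sites whose genotype-class pattern is significantly more
#' "mutually exclusive homozygote" than expected under independent allele
#' presence — the behaviour of real variants in selfing collections.
#' Artifact sites (e.g. collapsed paralogs) where both alleles co-occur
#' freely are removed.
#'
#' @param G a `geno_matrix`.
#' @param alpha significance level; sites with P < `alpha` are kept.
#' @return list with `kept` (site indices), `p` (per-site P-values) and
#'   `report` (a [filter_report()]).
#' @export
fisher_disassociation_filter <- function(G, alpha = 0.001) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  st <- site_stats(G)
  p <- fisher_disassociation_p(st$n_het, st$n_hom_ref, st$n_hom_alt, st$n_missing)
  kept <- which(p < alpha)
  list(
    kept = kept, p = p,
    report = filter_report("fisher_disassociation",
                           n_sites(G), length(kept),
                           n_accessions(G), n_accessions(G),
                           list(alpha = alpha))
  )
}

#' Site-level MAF / missingness / heterozygosity filter
#'
#' A site is kept iff `maf > maf_min` and `missing_rate < missing_max` and
#' `het_rate < het_max` — strict inequalities, so boundary values fail.
#' Sites with undefined statistics (all calls missing) are removed.
#'
#' @param G a `geno_matrix`.
#' @param maf_min,missing_max,het_max thresholds.
#' @return list with `kept` (site indices) and `report`.
#' @export
filter_sites <- function(G, maf_min = 0.01, missing_max = 0.30, het_max = 0.10) {
  st <- site_stats(G)
  ok <- !is.na(st$maf) & st$maf > maf_min &
    st$missing_rate < missing_max & st$het_rate < het_max
  kept <- which(ok)
  list(
    kept = kept,
    report = filter_report("site_filters", n_sites(G), length(kept),
                           n_accessions(G), n_accessions(G),
                           list(maf_min = maf_min, missing_max = missing_max,
                                het_max = het_max))
  )
}

#' Accession-level missingness filter
#'
#' Removes accessions whose fraction of missing calls exceeds
#' `missing_max` (strict `>`, so an accession at exactly the threshold is
#' kept).
#'
#' @param G a `geno_matrix`.
#' @param missing_max maximum tolerated missing fraction.
#' @return list with `kept` (accession ids) and `report`.
#' @export
filter_accessions <- function(G, missing_max = 0.55) {
  stopifnot(n_sites(G) >= 1L)
  frac <- rowMeans(is.na(G$calls))
  keep <- frac <= missing_max
  if (!any(keep)) stop("all accessions removed by missingness filter")
  list(
    kept = rownames(G$calls)[keep],
    report = filter_report("accession_missingness", n_sites(G), n_sites(G),
                           n_accessions(G), sum(keep),
                           list(missing_max = missing_max))
  )
}

#' Remove single-heterozygote, otherwise-fixed loci
#'
#' In a large analysis group, a locus whose only signal is a single
#' heterozygous accession on an otherwise fixed background is most likely
#' a sequencing error. When the group holds more than `min_population`
#' accessions, such loci are removed; for smaller groups this is a no-op.
#'
#' @param G a `geno_matrix` restricted to one analysis group.
#' @param min_population rule applies only when `n_accessions(G)` exceeds
#'   this.
#' @return list with `kept` (site indices) and `report`.
#' @export
drop_single_het_fixed <- function(G, min_population = 100) {
  st <- site_stats(G)
  if (n_accessions(G) > min_population) {
    drop <- st$n_het == 1L & (st$n_hom_ref == 0L | st$n_hom_alt == 0L)
  } else {
    drop <- rep(FALSE, n_sites(G))
  }
  kept <- which(!drop)
  list(
    kept = kept,
    report = filter_report("single_het_fixed", n_sites(G), length(kept),
                           n_accessions(G), n_accessions(G),
                           list(min_population = min_population))
  )
}

#' Deterministic mode imputation
#'
#' Replaces each missing call with the most frequent non-missing code at
#' that site; ties break toward the lower code. A simple, fully
#' deterministic scheme suitable for downstream statistics that only need
#' complete matrices (the smoothed F_ST scan).
#'
#' @param G a `geno_matrix`; every site must have at least one non-missing
#'   call.
#' @return A `geno_matrix` without missing calls.
#' @export
mode_impute <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- G$calls
  counts <- cbind(
    colSums(calls == 0L, na.rm = TRUE),
    colSums(calls == 1L, na.rm = TRUE),
    colSums(calls == 2L, na.rm = TRUE)
  )
  none <- rowSums(counts) == 0L
  if (any(none)) {
    stop("all calls missing at site(s): ",
         paste(G$sites$id[none], collapse = ", "))
  }
  mode_code <- max.col(counts, ties.method = "first") - 1L
  idx <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(idx)) calls[idx] <- mode_code[idx[, 2L]]
  genotype_matrix(calls, G$sites, rownames(G$calls))
}
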