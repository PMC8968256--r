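.presence_matrix <- function(G) {
  # accessions x (site, homozygous class) presence, hets masked first
  calls <- G$calls
  calls[calls == 1L] <- NA_integer_
  p <- cbind(!is.na(calls) & calls == 0L, !is.na(calls) & calls == 2L)
  colnames(p) <- c(paste0(G$sites$id, ":ref"), paste0(G$sites$id, ":alt"))
  p[, colSums(p) > 0L, drop = FALSE]
}

#' Allele coverage of a subset of accessions
#'
#' Heterozygous calls are masked to missing first. The target set T is
#' every (site, homozygous genotype class) pair observed at least once in
#' the full collection; coverage of a subset S is the fraction of T also
#' observed within S.
#'
#' @param G a `geno_matrix` (the full collection defining T).
#' @param ids accession ids of the subset (may be empty).
#' @return coverage fraction in `[0, 1]`.
#' @export
allele_coverage <- function(G, ids) {
  p <- .presence_matrix(G)
  if (ncol(p) == 0L) stop("no polymorphism: target set is empty")
  unknown <- setdiff(ids, rownames(p))
  if (length(unknown)) stop("unknown accession id(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(ids)) return(0)
  sum(colSums(p[ids, , drop = FALSE]) > 0L) / ncol(p)
}

#' Greedy core-collection selection by allele coverage
#'
#' Iteratively adds the accession with the largest incremental allele
#' coverage (ties break to the lowest accession index, making the result
#' deterministic and invariant to relabelling). Selection stops when
#' coverage reaches `cv`, when the best incremental gain falls below `d`,
#' or when accessions are exhausted.
#'
#' @param G a `geno_matrix`.
#' @param cv target coverage in (0, 1].
#' @param d minimum incremental coverage gain in (0, 1].
#' @return A `core_selection`: list with `ids` (selection order),
#'   `coverage_after_each`, `final_coverage`, `stop_reason`
#'   (`coverage_target`, `marginal_gain` or `exhausted`) and `parameters`.
#' @export
greedy_core <- function(G, cv = 0.99, d = 0.0001) {
  if (!is.numeric(cv) || cv <= 0 || cv > 1) stop("cv must be in (0, 1]")
  if (!is.numeric(d) || d <= 0 || d > 1) stop("d must be in (0, 1]")
  p <- .presence_matrix(G)
  if (ncol(p) == 0L) stop("no polymorphism: target set is empty")
  n_t <- ncol(p)
  uncovered <- rep(TRUE, n_t)
  remaining <- seq_len(nrow(p))
  selected <- integer()
  coverage <- numeric()
  stop_reason <- "exhausted"
  while (length(remaining)) {
    gains <- rowSums(p[remaining, uncovered, drop = FALSE])
    best <- which.max(gains)  # first maximum = lowest index tie-break
    if (gains[best] / n_t < d) { stop_reason <- "marginal_gain"; break }
    pick <- remaining[best]
    selected <- c(selected, pick)
    uncovered <- uncovered & !p[pick, ]
    coverage <- c(coverage, 1 - sum(uncovered) / n_t)
    remaining <- remaining[-best]
    if (coverage[length(coverage)] >= cv) { stop_reason <- "coverage_target"; break }
  }
  structure(
    list(ids = rownames(p)[selected],
         coverage_after_each = coverage,
         final_coverage = if (length(coverage)) coverage[length(coverage)] else 0,
         stop_reason = stop_reason,
         parameters = list(cv = cv, d = d)),
    class = "core_selection"
  )
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf(
    "core_selection: %d accessions, coverage %.4f (stop: %s; cv = %g, d = %g)\n",
    length(x$ids), x$final_coverage, x$stop_reason,
    x$parameters$cv, x$parameters$d))
  invisible(x)
}

#' Core collection accounting report
#'
#' For each group: core size, Nei diversity of the core members, the
#' percentage of the group's segregating loci still segregating in the
#' core, and the passport countries represented.
#'
#' @param core a [greedy_core()] result or character vector of core ids.
#' @param G the full `geno_matrix`.
#' @param groups named character vector (accession id -> group label);
#'   `NULL` treats the collection as one group called "all".
#' @param passports optional passport data frame (for country coverage).
#' @return data frame with one row per group: `group`, `group_n`,
#'   `core_n`, `core_nei`, `group_segregating`, `core_segregating`,
#'   `segregating_retained_pct`, `countries`.
#' @export
core_report <- function(core, G, groups = NULL, passports = NULL) {
  core_ids <- if (inherits(core, "core_selection")) core$ids else core
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", n_accessions(G)), accession_ids(G))
  }
  labs <- unique(groups[names(groups) %in% accession_ids(G)])
  rows <- lapply(labs, function(g) {
    ids <- intersect(names(groups)[groups == g], accession_ids(G))
    sub <- subset_geno(G, accessions = ids)
    seg_idx <- segregating_sites(sub)
    cids <- intersect(core_ids, ids)
    core_seg <- if (length(cids) && length(seg_idx)) {
      core_sub <- subset_geno(sub, accessions = cids, sites = seg_idx)
      segregating_count(core_sub, apply_single_het_rule = FALSE)
    } else 0L
    countries <- if (!is.null(passports) && "country" %in% names(passports)) {
      paste(sort(unique(stats::na.omit(
        passports$country[match(cids, passports$accession_id)]))),
        collapse = ";")
    } else NA_character_
    data.frame(
      group = g, group_n = length(ids), core_n = length(cids),
      core_nei = if (length(cids) >= 2L)
        nei_diversity(subset_geno(sub, accessions = cids)) else NA_real_,
      group_segregating = length(seg_idx),
      core_segregating = core_seg,
      segregating_retained_pct =
        if (length(seg_idx)) 100 * core_seg / length(seg_idx) else NA_real_,
      countries = countries, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
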