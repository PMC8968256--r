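#' Parameters for the end-to-end curation workflow
#'
#' One place for every stage's tunables; each has the conventional
#' default used throughout the package documentation.
#'
#' @param fisher_alpha Fisher disassociation filter significance level.
#' @param maf_min,missing_max,het_max site filter thresholds.
#' @param acc_missing_max accession missingness cap.
#' @param min_population gate for the single-het fixed-locus rule.
#' @param dedup_maf,dedup_missing,dedup_het site filters used only for
#'   the identity-by-state stage.
#' @param ibs_threshold identity threshold; `NULL` auto-discovers it from
#'   the identity histogram (falling back to 0.99).
#' @param min_compared minimum jointly homozygous loci per evaluable
#'   pair.
#' @param k_neighbors,agreement misclassification vote parameters.
#' @param scan_pair two group labels for the F_ST selection scan, or
#'   `NULL` to skip it.
#' @param lowess_f,k_sigma scan smoothing fraction and outlier
#'   multiplier.
#' @param cv,d core-selection coverage target and minimum gain.
#' @param seed master seed (group balancing).
#' @return A `curation_config` list.
#' @export
curation_config <- function(fisher_alpha = 0.001, maf_min = 0.01,
                            missing_max = 0.30, het_max = 0.10,
                            acc_missing_max = 0.55, min_population = 100,
                            dedup_maf = 0.05, dedup_missing = 0.50,
                            dedup_het = 0.10, ibs_threshold = NULL,
                            min_compared = 500, k_neighbors = 10,
                            agreement = 0.8, scan_pair = NULL,
                            lowess_f = 0.1, k_sigma = 3,
                            cv = 0.99, d = 0.0001, seed = 42) {
  structure(as.list(environment()), class = "curation_config")
}

#' Run the full genotype-based curation workflow
#'
#' Executes, in order: Fisher disassociation filter, site filters,
#' accession missingness filter, split by passport taxon, per-group
#' single-het locus drop, per-group duplicate detection, structure
#' analysis (NJ tree, relationship-matrix PCA, kNN misclassification
#' proposals on duplicate-collapsed representatives), per-group diversity
#' and pairwise F_ST tables, the optional smoothed F_ST selection scan
#' for a named group pair, and per-group plus combined greedy core
#' selection. Every stage's counts and parameters are recorded in the
#' manifest.
#'
#' @param geno a `geno_matrix` (e.g. from [read_vcf()]).
#' @param passports passport data frame with `accession_id` and `taxon`.
#' @param config a [curation_config()].
#' @return A `curation` object; see [print.curation()].
#' @export
run_curation <- function(geno, passports, config = curation_config()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "curation_config"))
  manifest <- list()
  note <- function(stage, ...) {
    manifest[[length(manifest) + 1L]] <<- c(list(stage = stage), list(...))
  }
  reports <- list()

  fis <- fisher_disassociation_filter(geno, alpha = config$fisher_alpha)
  geno <- subset_geno(geno, sites = fis$kept)
  reports$fisher <- fis$report
  note("fisher_filter", sites = n_sites(geno), alpha = config$fisher_alpha)

  sf <- filter_sites(geno, config$maf_min, config$missing_max, config$het_max)
  geno <- subset_geno(geno, sites = sf$kept)
  reports$site_filters <- sf$report
  note("site_filters", sites = n_sites(geno))

  af <- filter_accessions(geno, config$acc_missing_max)
  geno <- subset_geno(geno, accessions = af$kept)
  reports$accession_filter <- af$report
  note("accession_filter", accessions = n_accessions(geno))

  pp <- passports[passports$accession_id %in% accession_ids(geno), ]
  groups <- stats::setNames(as.character(pp$taxon), pp$accession_id)
  groups <- groups[!is.na(groups)]
  by_group <- split_geno(geno, groups)
  by_group <- lapply(by_group, function(g) {
    keep <- drop_single_het_fixed(g, config$min_population)$kept
    subset_geno(g, sites = keep)
  })
  note("group_split", groups = paste(names(by_group), collapse = ","),
       sizes = paste(vapply(by_group, n_accessions, integer(1)), collapse = ","))

  # per-group duplicate detection on dedup-specific site filters
  dedup <- lapply(by_group, function(g) {
    ds <- filter_sites(g, config$dedup_maf, config$dedup_missing,
                       config$dedup_het)
    gd <- subset_geno(g, sites = ds$kept)
    if (n_accessions(gd) < 2L || n_sites(gd) < config$min_compared) {
      return(NULL)
    }
    ibs <- ibs_matrix(gd, min_compared = config$min_compared)
    vals <- ibs$identity[upper.tri(ibs$identity)]
    thr <- config$ibs_threshold
    if (is.null(thr)) {
      thr <- if (sum(!is.na(vals)) >= 100L)
        as.numeric(detect_identity_threshold(vals)) else 0.99
    }
    list(ibs = ibs, groups = duplicate_groups(ibs, threshold = thr))
  })
  dedup <- dedup[!vapply(dedup, is.null, logical(1))]
  dup_sets <- unlist(lapply(dedup, function(d) d$groups$groups),
                     recursive = FALSE)
  redundant <- sum(vapply(dup_sets, length, integer(1)) - 1L)
  note("dedup", groups_with_duplicates = length(dup_sets),
       redundant = redundant,
       unique = n_accessions(geno) - redundant)

  pheno <- phenotype_consistency(dup_sets, pp)

  # collapse each duplicate set to its first member for structure analysis
  drop_ids <- unlist(lapply(dup_sets, function(s) s[-1L]))
  reps <- setdiff(accession_ids(geno), drop_ids)
  gstruct <- subset_geno(geno, accessions = reps)
  dstruct <- distance_matrix(gstruct, "one_minus_ibs",
                             min_compared = min(config$min_compared,
                                                n_sites(gstruct)))
  tree <- if (n_accessions(gstruct) >= 3L) nj_tree(dstruct) else NULL
  pca <- grm_pca(gstruct, k = min(10L, n_accessions(gstruct)))
  k_nn <- min(config$k_neighbors, n_accessions(gstruct) - 1L)
  proposals <- flag_misclassified(dstruct, groups[reps], k_neighbors = k_nn,
                                  agreement = config$agreement)
  note("structure", representatives = length(reps),
       misclassification_proposals = nrow(proposals))

  diversity <- diversity_report(geno, groups,
                                min_population = config$min_population)
  fst <- fst_matrix(geno, groups, method = "gst")
  note("diversity", groups = nrow(diversity))

  scan <- NULL
  if (!is.null(config$scan_pair)) {
    pair_ids <- names(groups)[groups %in% config$scan_pair]
    gscan <- mode_impute(subset_geno(
      geno, accessions = pair_ids,
      sites = which(colSums(!is.na(geno$calls[pair_ids, , drop = FALSE])) > 0L)))
    scan <- run_scan(gscan, groups, config$scan_pair,
                     scan_config(f = config$lowess_f, k_sigma = config$k_sigma,
                                 seed = config$seed))
    note("fst_scan", pair = paste(config$scan_pair, collapse = " vs "),
         regions = nrow(scan$regions))
  }

  cores <- lapply(by_group, function(g) {
    if (n_accessions(g) < 2L) return(NULL)
    greedy_core(g, cv = config$cv, d = config$d)
  })
  cores <- cores[!vapply(cores, is.null, logical(1))]
  combined_ids <- unique(unlist(lapply(cores, `[[`, "ids")))
  core_tab <- core_report(combined_ids, geno, groups, pp)
  note("core", combined_size = length(combined_ids),
       per_group = paste(vapply(cores, function(x) length(x$ids), integer(1)),
                         collapse = ","))

  structure(
    list(geno = geno, groups = groups, reports = reports,
         dedup = dedup, duplicate_sets = dup_sets,
         phenotype_check = pheno,
         tree = tree, pca = pca, misclassification = proposals,
         diversity = diversity, fst = fst, scan = scan,
         cores = cores, core_ids = combined_ids, core_table = core_tab,
         manifest = manifest, config = config),
    class = "curation"
  )
}

#' @export
print.curation <- function(x, ...) {
  cat("genotype-based curation summary\n")
  cat(sprintf("  retained: %d accessions x %d sites\n",
              n_accessions(x$geno), n_sites(x$geno)))
  redundant <- sum(vapply(x$duplicate_sets, length, integer(1)) - 1L)
  cat(sprintf("  duplicates: %d identical set(s), %d redundant accessions (unique %d)\n",
              length(x$duplicate_sets), redundant,
              n_accessions(x$geno) - redundant))
  cat(sprintf("  misclassification proposals: %d\n", nrow(x$misclassification)))
  if (!is.null(x$scan)) {
    cat(sprintf("  selection scan: %d region(s), threshold %.3f\n",
                nrow(x$scan$regions), x$scan$threshold))
  }
  cat(sprintf("  combined core: %d accessions\n", length(x$core_ids)))
  invisible(x)
}

#' @export
#' @rdname print.curation
#' @param object,x a `curation` object.
#' @param ... unused.
summary.curation <- function(object, ...) {
  cat("== stage manifest ==\n")
  for (m in object$manifest) {
    cat(sprintf("- %s: %s\n", m$stage,
                paste(names(m)[-1L], unlist(m[-1L]), sep = "=",
                      collapse = ", ")))
  }
  cat("\n== diversity ==\n")
  print(object$diversity, row.names = FALSE)
  cat("\n== pairwise F_ST ==\n")
  print(round(object$fst, 3))
  cat("\n== core report ==\n")
  print(object$core_table, row.names = FALSE)
  invisible(object)
}
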