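#' Configuration for a synthetic gene bank collection
#'
#' Defines a predominantly selfing diploid collection with K
#' Balding-Nichols differentiated subpopulations, GBS-style artifacts
#' (random missingness, spurious heterozygote calls), near-clonal
#' duplicate accessions, an optional localized high-differentiation sweep
#' window between two groups, and a fraction of wrongly labelled
#' passports. The defaults emulate a diploid wheat collection: four
#' subpopulations (a strongly diverged sister species, a domesticated
#' group and two wild races), several hundred accessions, thousands of
#' SNPs on seven chromosomes, inbreeding coefficient 0.97 and a
#' per-clone discordance of 0.002.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param L total number of SNP sites.
#' @param n_chrom number of chromosomes (named `1A`, `2A`, ...).
#' @param chrom_length chromosome length in bp.
#' @param pop_labels subpopulation (taxon) labels, length K.
#' @param n_per_pop accessions per subpopulation, length K.
#' @param F_pop per-subpopulation Balding-Nichols differentiation from
#'   the common ancestral pool, each in (0, 1). The expected pairwise
#'   F_ST between pops i and j is approximately `(F_i + F_j) / 2`.
#' @param f_is within-accession inbreeding coefficient (selfing).
#' @param missing_rate per-call missing probability.
#' @param het_error_rate probability a non-missing homozygote is
#'   miscalled heterozygous.
#' @param duplicates list with `count` (clone pairs to plant) and
#'   `epsilon` (per-site discordance of a clone from its source).
#' @param sweep `NULL`, or list with `chrom`, `n_sites`, `pair` (two pop
#'   labels), `p_high`, `p_low` describing a planted selection window.
#' @param mislabel_fraction fraction of (non-clone) accessions whose
#'   passport taxon is swapped to a wrong label.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, L = 5000, n_chrom = 7, chrom_length = 5e8,
                       pop_labels = c("urartu", "monococcum",
                                      "aegilopoides_alpha", "aegilopoides_gamma"),
                       n_per_pop = c(100, 100, 150, 50),
                       F_pop = c(0.6, 0.4, 0.3, 0.35),
                       f_is = 0.97, missing_rate = 0.1,
                       het_error_rate = 0.005,
                       duplicates = list(count = 10, epsilon = 0.002),
                       sweep = NULL, mislabel_fraction = 0.02) {
  stopifnot(length(pop_labels) == length(n_per_pop),
            length(F_pop) == length(pop_labels),
            all(F_pop > 0), all(F_pop < 1),
            f_is >= 0, f_is <= 1,
            missing_rate >= 0, missing_rate <= 1,
            het_error_rate >= 0, het_error_rate <= 1,
            mislabel_fraction >= 0, mislabel_fraction <= 1)
  if (!is.null(sweep)) {
    stopifnot(all(c("chrom", "n_sites", "pair", "p_high", "p_low") %in% names(sweep)),
              length(sweep$pair) == 2L, all(sweep$pair %in% pop_labels))
  }
  structure(
    list(seed = as.integer(seed), L = as.integer(L),
         n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
         pop_labels = pop_labels, n_per_pop = as.integer(n_per_pop),
         F_pop = stats::setNames(F_pop, pop_labels), f_is = f_is,
         missing_rate = missing_rate, het_error_rate = het_error_rate,
         duplicates = duplicates, sweep = sweep,
         mislabel_fraction = mislabel_fraction),
    class = "sim_config"
  )
}

.subseed <- function(seed, k) as.integer((as.double(seed) * 13 + k) %% 2147483587)

#' Draw Balding-Nichols subpopulation allele frequencies
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each
#' subpopulation's frequency at each locus is Beta-distributed around the
#' ancestral value with parameters `p0 (1 - F) / F` and
#' `(1 - p0)(1 - F) / F`, so `E[p_k] = p0` and
#' `Var[p_k] = F p0 (1 - p0)`.
#'
#' @param L number of loci.
#' @param K number of subpopulations.
#' @param F_pop differentiation per subpopulation, each in (0, 1);
#'   recycled to length K.
#' @param seed integer seed.
#' @return list with `p0` (length L) and `p` (L x K matrix).
#' @export
draw_subpop_freqs <- function(L, K, F_pop, seed = 1) {
  F_pop <- rep_len(F_pop, K)
  if (any(F_pop <= 0 | F_pop >= 1)) stop("F_pop values must be in (0, 1)")
  with_seed(seed, {
    p0 <- stats::runif(L, 0.05, 0.95)
    p <- vapply(seq_len(K), function(k) {
      f <- F_pop[k]
      stats::rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }, numeric(L))
    list(p0 = p0, p = p)
  })
}

.sample_pop_calls <- function(p, n, f_is) {
  # genotype: het w.p. 2pq(1-f); hom-alt w.p. p^2 + f p q; else hom-ref
  L <- length(p)
  p_hom_alt <- p^2 + f_is * p * (1 - p)
  p_het <- 2 * p * (1 - p) * (1 - f_is)
  u <- matrix(stats::runif(n * L), n, L)
  calls <- matrix(0L, n, L)
  thr1 <- rep(p_hom_alt, each = n)
  thr2 <- rep(p_hom_alt + p_het, each = n)
  calls[u < thr1] <- 2L
  calls[u >= thr1 & u < thr2] <- 1L
  calls
}

#' Sample inbred genotypes from subpopulation frequencies
#'
#' Per accession and locus the genotype is heterozygous with probability
#' `2 p q (1 - f_is)`, homozygous alternate with probability
#' `p^2 + f_is p q`, otherwise homozygous reference — the
#' inbreeding-adjusted Hardy-Weinberg proportions of a selfing species.
#'
#' @param freqs result of [draw_subpop_freqs()].
#' @param n_per_pop accessions per subpopulation.
#' @param f_is inbreeding coefficient.
#' @param seed integer seed.
#' @return list with `calls` (N x L integer matrix) and `pop`
#'   (subpopulation index per accession).
#' @export
sample_genotypes <- function(freqs, n_per_pop, f_is = 0.97, seed = 1) {
  K <- ncol(freqs$p)
  stopifnot(length(n_per_pop) == K)
  with_seed(seed, {
    calls <- do.call(rbind, lapply(seq_len(K), function(k) {
      .sample_pop_calls(freqs$p[, k], n_per_pop[k], f_is)
    }))
    list(calls = calls, pop = rep(seq_len(K), n_per_pop))
  })
}

#' Apply GBS-style artifacts to a call matrix
#'
#' Each call is independently set missing with probability
#' `missing_rate`; each remaining homozygous call is flipped to
#' heterozygous with probability `het_error_rate`.
#'
#' @param calls integer call matrix.
#' @param missing_rate per-call missing probability.
#' @param het_error_rate per-homozygote miscall probability.
#' @param seed integer seed.
#' @return modified call matrix.
#' @export
apply_artifacts <- function(calls, missing_rate = 0.1,
                            het_error_rate = 0.005, seed = 1) {
  with_seed(seed, {
    if (missing_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < missing_rate,
                   nrow(calls))] <- NA_integer_
    }
    if (het_error_rate > 0) {
      flip <- !is.na(calls) & calls != 1L &
        matrix(stats::runif(length(calls)) < het_error_rate, nrow(calls))
      calls[flip] <- 1L
    }
    calls
  })
}

.pop_meta <- function(K) {
  countries <- c("Turkey", "Iraq", "Iran", "Syria", "Lebanon", "Armenia",
                 "Georgia", "Greece")
  glume <- c(2L, 1L, 7L, 5L, 4L, 8L, 3L, 6L)
  list(country = rep_len(countries, K), glume = rep_len(glume, K))
}

#' Simulate a complete synthetic collection with known truth
#'
#' Composes the generators: chromosome positions, Balding-Nichols
#' frequencies, optional planted sweep window (the window's per-pop
#' frequencies are overwritten with `p_high` / `p_low` for the named
#' group pair before genotypes are drawn), inbred genotype sampling,
#' clone planting with per-site discordance, GBS artifacts, passports
#' and planted mislabels. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `genotypes.vcf`,
#'   `passports.csv` and `truth.json` there.
#' @return A `sim_collection`: list with `geno` (a `geno_matrix`),
#'   `passports` (data frame), `truth` (planted ground truth) and
#'   `config`.
#' @export
simulate_collection <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  K <- length(config$pop_labels)
  chrom_names <- paste0(seq_len(config$n_chrom), "A")

  # site map: L sites spread over chromosomes, positions uniform then sorted
  per_chrom <- rep(config$L %/% config$n_chrom, config$n_chrom)
  extra <- config$L %% config$n_chrom
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  sites <- with_seed(.subseed(seed, 1L), {
    bases <- c("A", "C", "G", "T")
    pos <- unlist(lapply(per_chrom, function(li) {
      sort(sample.int(config$chrom_length, li))
    }))
    ref <- sample(bases, config$L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    data.frame(chrom = rep(chrom_names, per_chrom), pos = pos,
               ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  })

  freqs <- draw_subpop_freqs(config$L, K, config$F_pop, .subseed(seed, 2L))

  truth_sweep <- NULL
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    chrom_idx <- which(chrom_names == sw$chrom)
    if (!length(chrom_idx)) stop("sweep chromosome not in the simulated genome")
    in_chrom <- which(sites$chrom == sw$chrom)
    if (sw$n_sites > length(in_chrom)) {
      stop("sweep window exceeds chromosome site count")
    }
    start <- with_seed(.subseed(seed, 3L),
                       sample.int(length(in_chrom) - sw$n_sites + 1L, 1L))
    win <- in_chrom[start:(start + sw$n_sites - 1L)]
    freqs$p[win, match(sw$pair[1L], config$pop_labels)] <- sw$p_high
    freqs$p[win, match(sw$pair[2L], config$pop_labels)] <- sw$p_low
    truth_sweep <- list(chrom = sw$chrom,
                        start_bp = sites$pos[win[1L]],
                        end_bp = sites$pos[win[length(win)]],
                        n_sites = sw$n_sites, pair = sw$pair)
  }

  drawn <- sample_genotypes(freqs, config$n_per_pop, config$f_is,
                            .subseed(seed, 4L))
  calls <- drawn$calls
  pop <- config$pop_labels[drawn$pop]
  n0 <- nrow(calls)
  ids <- sprintf("SIM%04d", seq_len(n0))

  # clone planting: copy source rows, flip homozygotes with prob epsilon
  dup_pairs <- data.frame(source = character(), clone = character(),
                          epsilon = numeric(), stringsAsFactors = FALSE)
  n_dup <- config$duplicates$count %||% 0L
  if (n_dup > 0L) {
    eps <- config$duplicates$epsilon %||% 0.002
    dup_rows <- with_seed(.subseed(seed, 5L), {
      src <- sample.int(n0, n_dup)
      clones <- calls[src, , drop = FALSE]
      hom <- !is.na(clones) & clones != 1L
      flip <- hom & matrix(stats::runif(length(clones)) < eps, n_dup)
      clones[flip] <- 2L - clones[flip]
      list(src = src, clones = clones)
    })
    clone_ids <- paste0(ids[dup_rows$src], "_d")
    calls <- rbind(calls, dup_rows$clones)
    pop <- c(pop, pop[dup_rows$src])
    ids <- c(ids, clone_ids)
    dup_pairs <- data.frame(source = ids[dup_rows$src], clone = clone_ids,
                            epsilon = eps, stringsAsFactors = FALSE)
  }

  calls <- apply_artifacts(calls, config$missing_rate,
                           config$het_error_rate, .subseed(seed, 6L))
  rownames(calls) <- ids
  geno <- genotype_matrix(calls, sites, ids)

  meta <- .pop_meta(K)
  pop_idx <- match(pop, config$pop_labels)
  passports <- with_seed(.subseed(seed, 7L), {
    data.frame(
      accession_id = ids,
      taxon = pop,
      race = NA_character_,
      country = meta$country[pop_idx],
      site_name = paste0(meta$country[pop_idx], "_site",
                         sample.int(5L, length(ids), replace = TRUE)),
      lat = round(34 + 2 * pop_idx + stats::runif(length(ids), -1, 1), 4),
      lon = round(36 + 3 * pop_idx + stats::runif(length(ids), -1, 1), 4),
      glume_score = meta$glume[pop_idx],
      stringsAsFactors = FALSE
    )
  })
  # clones inherit the passport phenotype of their source
  if (nrow(dup_pairs)) {
    src_row <- match(dup_pairs$source, passports$accession_id)
    cln_row <- match(dup_pairs$clone, passports$accession_id)
    passports$glume_score[cln_row] <- passports$glume_score[src_row]
    passports$site_name[cln_row] <- passports$site_name[src_row]
  }

  mislabels <- data.frame(accession_id = character(), true_taxon = character(),
                          assigned_taxon = character(), stringsAsFactors = FALSE)
  n_mis <- round(config$mislabel_fraction * n0)
  if (n_mis > 0L) {
    mislabels <- with_seed(.subseed(seed, 8L), {
      victims <- sample.int(n0, n_mis)  # clones are never mislabelled
      wrong <- vapply(victims, function(i) {
        sample(setdiff(config$pop_labels, pop[i]), 1L)
      }, character(1))
      data.frame(accession_id = ids[victims], true_taxon = pop[victims],
                 assigned_taxon = wrong, stringsAsFactors = FALSE)
    })
    passports$taxon[match(mislabels$accession_id, passports$accession_id)] <-
      mislabels$assigned_taxon
  }

  truth <- list(
    pops = stats::setNames(pop, ids),
    F_pop = config$F_pop,
    duplicate_pairs = dup_pairs,
    sweep = truth_sweep,
    mislabels = mislabels,
    seed = seed
  )
  out <- structure(list(geno = geno, passports = passports, truth = truth,
                        config = config),
                   class = "sim_collection")
  if (!is.null(dir)) write_collection(out, dir)
  out
}

#' @export
print.sim_collection <- function(x, ...) {
  cat(sprintf(
    "sim_collection (seed %d): %d accessions x %d sites, %d pops\n",
    x$config$seed, n_accessions(x$geno), n_sites(x$geno),
    length(x$config$pop_labels)))
  cat(sprintf("  planted: %d clone pair(s), %d mislabel(s), sweep: %s\n",
              nrow(x$truth$duplicate_pairs), nrow(x$truth$mislabels),
              if (is.null(x$truth$sweep)) "none" else
                sprintf("%s:%d-%d", x$truth$sweep$chrom,
                        x$truth$sweep$start_bp, x$truth$sweep$end_bp)))
  invisible(x)
}

#' Write a simulated collection to disk
#'
#' Emits `genotypes.vcf`, `passports.csv` and `truth.json` into `dir`.
#'
#' @param sim a `sim_collection`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_collection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
  write_passport(sim$passports, file.path(dir, "passports.csv"))
  truth <- sim$truth
  truth$pops <- as.list(truth$pops)
  truth$F_pop <- as.list(truth$F_pop)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
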