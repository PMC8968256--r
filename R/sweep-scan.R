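#' Scan configuration
#'
#' Parameters of the genome-wide F_ST selection scan: the Lowess smoother
#' fraction `f`, the number of robustifying iterations, the
#' `k_sigma` outlier multiplier and the seed used when balancing group
#' sizes.
#'
#' @param f Lowess span as a fraction of sites per chromosome.
#' @param iterations bisquare robustifying passes. The scan defaults to
#'   0: robust passes treat a localized run of high-F_ST sites — the very
#'   signal a selection scan looks for — as outliers and smooth it away,
#'   so outlier-robust smoothing is counterproductive here (it remains
#'   available for profiles contaminated by isolated artefacts).
#' @param k_sigma threshold is `mean + k_sigma * sd` of the per-site
#'   values.
#' @param seed integer seed for the balancing subsample.
#' @param threshold_on compute the outlier threshold from `"raw"`
#'   per-site values (default) or from the `"smoothed"` profile.
#' @return A `scan_config` list.
#' @export
scan_config <- function(f = 0.1, iterations = 0, k_sigma = 3, seed = 1,
                        threshold_on = c("raw", "smoothed")) {
  stopifnot(f > 0, f <= 1, k_sigma > 0, iterations >= 0)
  structure(list(f = f, iterations = as.integer(iterations),
                 k_sigma = k_sigma, seed = as.integer(seed),
                 threshold_on = match.arg(threshold_on)),
            class = "scan_config")
}

#' Balance two group sizes by seeded subsampling
#'
#' Differentiation statistics compare groups most cleanly at equal sample
#' size; the larger group is subsampled without replacement to the size of
#' the smaller one using a seeded generator, the smaller group is
#' unchanged.
#'
#' @param ids_a,ids_b character vectors of accession ids.
#' @param seed integer seed.
#' @return list with balanced `a` and `b` id vectors.
#' @export
balance_groups <- function(ids_a, ids_b, seed = 1) {
  stopifnot(length(ids_a) >= 1L, length(ids_b) >= 1L)
  na <- length(ids_a); nb <- length(ids_b)
  if (na == nb) return(list(a = ids_a, b = ids_b))
  target <- min(na, nb)
  if (na > nb) {
    ids_a <- with_seed(seed, sample(ids_a, target))
  } else {
    ids_b <- with_seed(seed, sample(ids_b, target))
  }
  list(a = ids_a, b = ids_b)
}

#' Lowess smoothing of a per-site profile along a chromosome
#'
#' Locally weighted linear regression with tricube weights over the
#' nearest `ceiling(f * n)` points and `iterations` bisquare robustifying
#' passes, evaluated at every input position (no interpolation
#' shortcut). Smoothing must never cross chromosome boundaries; this
#' function operates on a single chromosome.
#'
#' @param positions strictly increasing numeric positions (bp).
#' @param values numeric values aligned with `positions`.
#' @param f span fraction.
#' @param iterations robustifying passes.
#' @return smoothed values at the same positions.
#' @export
lowess_smooth <- function(positions, values, f = 0.1, iterations = 3) {
  if (length(positions) < 5L) stop("at least 5 points required")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing within a chromosome")
  }
  stopifnot(length(positions) == length(values), f > 0, f <= 1)
  stats::lowess(positions, values, f = f, iter = iterations, delta = 0)$y
}

#' Call selection-signature regions from a smoothed F_ST profile
#'
#' The genome-wide outlier threshold is `mean + k_sigma * sd` of the
#' defined per-site values (raw by default; configurable). A region is a
#' maximal run of consecutive sites on one chromosome whose smoothed
#' value exceeds the threshold; its peak is the site with the maximal
#' smoothed value (ties break to the lowest position).
#'
#' @param data data frame with `chrom`, `pos`, `raw`, `smoothed`.
#' @param k_sigma threshold multiplier.
#' @param threshold_on `"raw"` or `"smoothed"` basis for mean/sd.
#' @return list with `threshold`, `genome_mean`, `genome_sd` and
#'   `regions` (data frame `chrom`, `start_bp`, `end_bp`, `peak_bp`,
#'   `peak_smoothed`, `n_sites`).
#' @export
call_selection_regions <- function(data, k_sigma = 3,
                                   threshold_on = c("raw", "smoothed")) {
  threshold_on <- match.arg(threshold_on)
  base <- if (threshold_on == "raw") data$raw else data$smoothed
  base <- base[!is.na(base)]
  genome_mean <- mean(base)
  genome_sd <- stats::sd(base)
  threshold <- genome_mean + k_sigma * genome_sd
  regions <- list()
  for (ch in unique(data$chrom)) {
    d <- data[data$chrom == ch & !is.na(data$smoothed), , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    if (!nrow(d)) next
    above <- d$smoothed > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- d[starts[k]:ends[k], , drop = FALSE]
      peak <- seg[which.max(seg$smoothed), ]  # which.max: first = lowest pos
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start_bp = min(seg$pos), end_bp = max(seg$pos),
        peak_bp = peak$pos, peak_smoothed = peak$smoothed,
        n_sites = nrow(seg), stringsAsFactors = FALSE
      )
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
               peak_bp = integer(), peak_smoothed = numeric(),
               n_sites = integer(), stringsAsFactors = FALSE)
  list(threshold = threshold, genome_mean = genome_mean,
       genome_sd = genome_sd, regions = regions)
}

#' Genome-wide F_ST selection scan between two groups
#'
#' Composes the full scan: balance group sizes (seeded subsample of the
#' larger group), per-site Weir-Cockerham F_ST, per-chromosome Lowess
#' smoothing, and 3-sigma outlier region calling. The input matrix should
#' be imputed or complete for the two groups (see [mode_impute()]).
#'
#' @param G a `geno_matrix`.
#' @param groups named character vector (accession id -> group label).
#' @param pair the two group labels to compare.
#' @param config a [scan_config()].
#' @return An `fst_profile`: list with `data` (per-site `chrom`, `pos`,
#'   `raw`, `smoothed`), `genome_mean`, `genome_sd`, `threshold`,
#'   `regions`, `config` and the balanced group sizes.
#' @export
run_scan <- function(G, groups, pair, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  pr <- .resolve_pair(groups, pair)
  bal <- balance_groups(pr$ids1, pr$ids2, seed = config$seed)
  sub <- subset_geno(G, accessions = c(bal$a, bal$b))
  bal_groups <- stats::setNames(
    rep(pair, c(length(bal$a), length(bal$b))), c(bal$a, bal$b))
  wc <- wc_fst_per_site(sub, bal_groups, pair)
  data <- data.frame(chrom = wc$chrom, pos = wc$pos, raw = wc$theta,
                     smoothed = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(data$chrom)) {
    sel <- which(data$chrom == ch & !is.na(data$raw))
    if (length(sel) >= 5L) {
      sel <- sel[order(data$pos[sel])]
      data$smoothed[sel] <- lowess_smooth(data$pos[sel], data$raw[sel],
                                          f = config$f,
                                          iterations = config$iterations)
    }
  }
  called <- call_selection_regions(data, k_sigma = config$k_sigma,
                                   threshold_on = config$threshold_on)
  structure(
    list(data = data, genome_mean = called$genome_mean,
         genome_sd = called$genome_sd, threshold = called$threshold,
         regions = called$regions, config = config,
         n_per_group = stats::setNames(c(length(bal$a), length(bal$b)), pair),
         wc = wc),
    class = "fst_profile"
  )
}

#' @export
print.fst_profile <- function(x, ...) {
  cat(sprintf(
    "fst_profile: %d sites on %d chromosome(s); %d vs %d accessions\n",
    nrow(x$data), length(unique(x$data$chrom)),
    x$n_per_group[1L], x$n_per_group[2L]))
  cat(sprintf("  genome mean %.4f, sd %.4f -> threshold %.4f (%s, k = %g)\n",
              x$genome_mean, x$genome_sd, x$threshold,
              x$config$threshold_on, x$config$k_sigma))
  cat(sprintf("  %d selection region(s) called\n", nrow(x$regions)))
  if (nrow(x$regions)) {
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

#' Plot an F_ST scan profile
#'
#' Raw per-site values as points, the Lowess-smoothed profile as a line,
#' the outlier threshold as a horizontal dashed line, one panel per
#' chromosome.
#'
#' @param x an `fst_profile`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fst_profile <- function(x, ...) {
  chroms <- unique(x$data$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    d <- x$data[x$data$chrom == ch, ]
    graphics::plot(d$pos / 1e6, d$raw, pch = 16, cex = 0.3,
                   col = "grey60", ylim = c(min(0, d$raw, na.rm = TRUE), 1),
                   xlab = "", ylab = expression(F[ST]), main = ch, ...)
    ok <- !is.na(d$smoothed)
    graphics::lines(d$pos[ok] / 1e6, d$smoothed[ok], col = "firebrick", lwd = 2)
    graphics::abline(h = x$threshold, lty = 2, col = "navy")
  }
  invisible(x)
}

#' Write scan regions as a BED file
#'
#' BED uses 0-based half-open intervals; the 1-based inclusive region
#' coordinates are converted accordingly. The score column carries the
#' peak smoothed F_ST.
#'
#' @param profile an `fst_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(profile, path) {
  r <- profile$regions
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%.4f",
                   r$chrom, r$start_bp - 1L, r$end_bp, r$peak_bp,
                   r$peak_smoothed)
  writeLines(lines, path)
  invisible(path)
}
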