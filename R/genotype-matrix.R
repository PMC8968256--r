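#' Construct a genotype matrix
#'
#' The central container of the package: an accessions x sites matrix of
#' alternate-allele dosages for biallelic SNPs. Calls are coded
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' and `NA` = missing. Phase is ignored throughout (selfing species,
#' unphased GBS data).
#'
#' @param calls integer matrix (accessions in rows, sites in columns) with
#'   values in \{0, 1, 2, NA\}.
#' @param sites data frame with one row per site and columns `chrom`,
#'   `pos` (1-based bp), `ref`, `alt`, and optionally `id`. `ref` and `alt`
#'   must be single, distinct bases.
#' @param accession_ids character vector of unique accession identifiers;
#'   defaults to `rownames(calls)`.
#' @return An object of class `geno_matrix` with elements `calls`
#'   (named integer matrix) and `sites`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(c("a", "b"), NULL)),
#'   data.frame(chrom = "1A", pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' g
#' @export
genotype_matrix <- function(calls, sites, accession_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(accession_ids)) {
    stop("accession ids are required (rownames of `calls` or `accession_ids`)")
  }
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(accession_ids)) {
    stop("duplicate accession ids: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  }
  if (length(accession_ids) != nrow(calls)) {
    stop("length of accession_ids does not match nrow(calls)")
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sites) != ncol(calls)) {
    stop("nrow(sites) does not match ncol(calls)")
  }
  if (is.null(sites$id)) {
    sites$id <- paste(sites$chrom, sites$pos, sep = "_")
  }
  sites$pos <- as.integer(sites$pos)
  if (nrow(sites)) {
    if (any(sites$pos < 1L)) stop("site positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L)) {
      stop("only single-base (biallelic SNP) alleles are supported")
    }
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L)) {
    stop("calls must be 0, 1, 2 or NA")
  }
  rownames(calls) <- accession_ids
  colnames(calls) <- sites$id
  structure(list(calls = calls, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  n <- nrow(x$calls); l <- ncol(x$calls)
  miss <- if (n * l > 0) mean(is.na(x$calls)) else 0
  cat(sprintf("geno_matrix: %d accessions x %d sites (%.1f%% missing)\n",
              n, l, 100 * miss))
  if (l) {
    chroms <- unique(x$sites$chrom)
    cat(sprintf("  chromosomes: %s\n",
                paste(utils::head(chroms, 8), collapse = ", ")))
  }
  invisible(x)
}

#' Number of accessions / sites
#' @param G a `geno_matrix`.
#' @return integer count.
#' @export
n_accessions <- function(G) nrow(G$calls)

#' @rdname n_accessions
#' @export
n_sites <- function(G) ncol(G$calls)

#' Accession identifiers
#' @param G a `geno_matrix`.
#' @return character vector of ids in matrix order.
#' @export
accession_ids <- function(G) rownames(G$calls)

#' Subset a genotype matrix
#'
#' Retains the requested accessions and/or sites, preserving the original
#' order of whichever are kept and slicing the site metadata consistently.
#'
#' @param G a `geno_matrix`.
#' @param accessions character vector of accession ids to keep, or `NULL`
#'   for all. Unknown ids are an error.
#' @param sites integer vector of site indices (or logical mask) to keep,
#'   or `NULL` for all.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(G, accessions = NULL, sites = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  ri <- seq_len(nrow(G$calls))
  if (!is.null(accessions)) {
    unknown <- setdiff(accessions, rownames(G$calls))
    if (length(unknown)) {
      stop("unknown accession id(s): ", paste(unknown, collapse = ", "))
    }
    keep <- rownames(G$calls) %in% accessions
    ri <- ri[keep]
  }
  ci <- seq_len(ncol(G$calls))
  if (!is.null(sites)) {
    if (is.logical(sites)) {
      stopifnot(length(sites) == ncol(G$calls))
      ci <- ci[sites]
    } else {
      sites <- as.integer(sites)
      if (length(sites) && (any(sites < 1L) || any(sites > ncol(G$calls)))) {
        stop("site index out of range")
      }
      ci <- sites
    }
  }
  genotype_matrix(G$calls[ri, ci, drop = FALSE],
                  G$sites[ci, , drop = FALSE],
                  rownames(G$calls)[ri])
}

#' Split a genotype matrix by a group assignment
#'
#' @param G a `geno_matrix`.
#' @param groups named character vector mapping accession id to group label
#'   (e.g. passport taxon); accessions without a label are dropped.
#' @return Named list of `geno_matrix`, one per group label.
#' @export
split_geno <- function(G, groups) {
  stopifnot(inherits(G, "geno_matrix"))
  groups <- groups[names(groups) %in% accession_ids(G)]
  lab <- unique(groups)
  out <- lapply(lab, function(g) subset_geno(G, accessions = names(groups)[groups == g]))
  names(out) <- lab
  out
}
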