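#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT calls to dosage codes (0/1/2). Phase separators are
#' ignored (`0|1` is `0/1`), and any GT containing `.` — including
#' half-calls — becomes missing. Multiallelic records and non-SNP records
#' (indels, symbolic alleles) are dropped; the number dropped is reported
#' with a message and stored in the `dropped` attribute.
#'
#' @param path path to a VCF (v4.x, plain or gzipped) with a GT FORMAT field.
#' @return A [genotype_matrix()] with attribute `dropped` (records removed
#'   as non-biallelic/non-SNP).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF contains zero samples")
  fmt <- v@gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records lack a GT FORMAT field")
  }
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " multiallelic/non-SNP record(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(unname(code[gt]), nrow = nrow(gt), ncol = ncol(gt))
  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = "_"),
                fix[keep, "ID"]),
    stringsAsFactors = FALSE
  )
  G <- genotype_matrix(t(calls), sites, colnames(gt))
  attr(G, "dropped") <- dropped
  G
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits dosage codes as unphased GT strings (`0/0`, `0/1`, `1/1`; missing
#' as `./.`). The output round-trips through [read_vcf()] exactly.
#'
#' @param G a `geno_matrix`.
#' @param path output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- matrix(gt_str[G$calls + 1L], nrow = nrow(G$calls))
  body[is.na(G$calls)] <- "./."
  s <- G$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=genocurate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$calls)), collapse = "\t"),
    vapply(seq_len(nrow(s)), function(j) {
      paste(c(s$chrom[j], s$pos[j], s$id[j], s$ref[j], s$alt[j],
              ".", "PASS", ".", "GT", body[, j]), collapse = "\t")
    }, character(1))
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a TASSEL-dialect HapMap genotype file
#'
#' Expects the classic layout: 11 metadata columns (`rs#`, `alleles`,
#' `chrom`, `pos`, ...) followed by one genotype column per accession.
#' Homozygotes are mapped to 0/2 by matching the declared alleles,
#' IUPAC ambiguity codes (R, Y, S, W, K, M) and two-letter heterozygote
#' spellings map to 1, and `N` (or `NN`) to missing. Calls inconsistent
#' with the declared alleles are set missing and counted in the
#' `inconsistent` attribute (with a warning).
#'
#' @param path path to a tab-separated HapMap file with header.
#' @return A [genotype_matrix()] with attribute `inconsistent`.
#' @export
read_hapmap <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 12L) stop("HapMap file must have 11 metadata columns plus samples")
  al <- strsplit(tab[[2L]], "/", fixed = TRUE)
  ref <- vapply(al, `[`, character(1), 1L)
  alt <- vapply(al, `[`, character(1), 2L)
  samples <- colnames(tab)[-(1:11)]
  raw <- as.matrix(tab[, -(1:11), drop = FALSE])
  L <- nrow(tab)
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = L)
  inconsistent <- 0L
  decode <- function(cell, r, a) {
    # returns dosage or NA; -1L marks an inconsistent call
    if (is.na(cell) || cell == "N" || cell == "NN" || cell == "") return(NA_integer_)
    cell <- gsub("/", "", cell, fixed = TRUE)
    if (nchar(cell) == 1L) {
      if (cell == r) return(0L)
      if (cell == a) return(2L)
      pair <- .iupac_het[cell]
      if (!is.na(pair)) {
        ok <- identical(sort(c(r, a)), sort(strsplit(pair, "")[[1L]]))
        return(if (ok) 1L else -1L)
      }
      return(-1L)
    }
    if (nchar(cell) == 2L) {
      ab <- strsplit(cell, "")[[1L]]
      if (!all(ab %in% c(r, a))) return(-1L)
      return(sum(ab == a))
    }
    -1L
  }
  for (j in seq_len(L)) {
    v <- vapply(raw[j, ], decode, integer(1), r = ref[j], a = alt[j])
    bad <- !is.na(v) & v == -1L
    inconsistent <- inconsistent + sum(bad)
    v[bad] <- NA_integer_
    calls[, j] <- v
  }
  if (inconsistent) {
    warning(inconsistent, " genotype call(s) inconsistent with declared alleles set to missing")
  }
  sites <- data.frame(chrom = tab[[3L]], pos = as.integer(tab[[4L]]),
                      ref = ref, alt = alt, id = tab[[1L]],
                      stringsAsFactors = FALSE)
  G <- genotype_matrix(calls, sites, samples)
  attr(G, "inconsistent") <- inconsistent
  G
}

#' Read an accession passport table
#'
#' Delimited text (comma or tab, auto-detected) with a header containing at
#' least `accession_id`; the conventional columns are
#' `accession_id, taxon, race, country, site_name, lat, lon, glume_score`.
#' Unknown taxon labels are preserved verbatim; blank numeric fields become
#' `NA`. Glume colour scores are validated against the 0 (white) to
#' 9 (black) scale.
#'
#' @param path path to CSV/TSV file.
#' @return data frame with one row per accession.
#' @export
read_passport <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           quote = "\"", comment.char = "")
  if (!"accession_id" %in% names(tab)) {
    stop("passport table must have an `accession_id` column")
  }
  tab$accession_id <- as.character(tab$accession_id)
  dup <- unique(tab$accession_id[duplicated(tab$accession_id)])
  if (length(dup)) {
    stop("duplicate accession_id rows: ", paste(dup, collapse = ", "))
  }
  for (col in c("lat", "lon")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("glume_score" %in% names(tab)) {
    tab$glume_score <- suppressWarnings(as.integer(tab$glume_score))
    bad <- !is.na(tab$glume_score) & (tab$glume_score < 0L | tab$glume_score > 9L)
    if (any(bad)) {
      stop("glume_score out of [0, 9] for: ",
           paste(tab$accession_id[bad], collapse = ", "))
    }
  }
  tab
}

#' Write an accession passport table
#' @param passports data frame as returned by [read_passport()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_passport <- function(passports, path) {
  utils::write.csv(passports, path, row.names = FALSE, na = "")
  invisible(path)
}
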