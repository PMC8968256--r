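vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", "s1", "s2", "s3", sep = "\t")
)

test_that("VCF genotypes parse to dosage codes, with missing and phase handled", {
  path <- write_tiny_vcf(c(
    vcf_header,
    "1A\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "1A\t200\tsnp2\tA\tC\t.\tPASS\t.\tGT\t./.\t0|1\t./1"
  ))
  g <- read_vcf(path)
  expect_equal(unname(g$calls[, "snp1"]), c(0L, 2L, 1L))
  expect_equal(unname(g$calls[, "snp2"]), c(NA_integer_, 1L, NA_integer_))
  expect_equal(accession_ids(g), c("s1", "s2", "s3"))
  expect_equal(g$sites$pos, c(100L, 200L))
})

test_that("multiallelic and non-SNP records are dropped and counted", {
  path <- write_tiny_vcf(c(
    vcf_header,
    "1A\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "1A\t150\tmulti\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2",
    "1A\t180\tindel\tAT\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/0",
    "1A\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"
  ))
  expect_message(g <- read_vcf(path), "2 multiallelic/non-SNP")
  expect_equal(n_sites(g), 2L)
  expect_equal(attr(g, "dropped"), 2L)
  expect_equal(g$sites$id, c("snp1", "snp2"))
})

test_that("VCF round-trip is the identity on calls, ids and site order", {
  set.seed(42)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 12, replace = TRUE), 3, 4)
  g <- make_geno(calls, chrom = c("1A", "1A", "2A", "2A"),
                 pos = c(5L, 50L, 7L, 70L))
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_equal(g2$calls, g$calls)
  expect_equal(g2$sites$chrom, g$sites$chrom)
  expect_equal(g2$sites$pos, g$sites$pos)
})

test_that("HapMap IUPAC and two-letter genotypes decode; inconsistencies flagged", {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly",
                 "center", "protLSID", "assayLSID", "panel", "QCcode",
                 "s1", "s2", "s3", "s4", "s5"), collapse = "\t")
  row1 <- paste(c("snp1", "A/G", "1A", "100", "+", "NA", "NA", "NA", "NA",
                  "NA", "NA", "A", "G", "R", "N", "T"), collapse = "\t")
  row2 <- paste(c("snp2", "C/T", "1A", "200", "+", "NA", "NA", "NA", "NA",
                  "NA", "NA", "CC", "CT", "TT", "NN", "Y"), collapse = "\t")
  path <- tempfile(fileext = ".hmp.txt")
  writeLines(c(hdr, row1, row2), path)
  expect_warning(g <- read_hapmap(path), "1 genotype call")
  expect_equal(unname(g$calls[, 1]), c(0L, 2L, 1L, NA, NA))
  expect_equal(unname(g$calls[, 2]), c(0L, 1L, 2L, NA, 1L))
  expect_equal(attr(g, "inconsistent"), 1L)
})

test_that("the same logical dataset parses identically from VCF and HapMap", {
  set.seed(7)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 40, replace = TRUE,
                         prob = c(.4, .1, .4, .1)), 4, 10)
  g <- make_geno(calls, ids = paste0("s", 1:4))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(g, vcf)
  # write the same data in HapMap dialect (ref A, alt G, het = R)
  letter <- function(v) c("A", "R", "G")[v + 1L]
  hm <- vapply(seq_len(nrow(calls)), function(i) {
    x <- letter(calls[i, ])
    x[is.na(calls[i, ])] <- "N"
    x
  }, character(10))
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly",
                 "center", "protLSID", "assayLSID", "panel", "QCcode",
                 paste0("s", 1:4)), collapse = "\t")
  rows <- vapply(seq_len(10), function(j) {
    paste(c(g$sites$id[j], "A/G", g$sites$chrom[j], g$sites$pos[j],
            "+", "NA", "NA", "NA", "NA", "NA", "NA", hm[j, ]),
          collapse = "\t")
  }, character(1))
  hmp <- tempfile(fileext = ".hmp.txt")
  writeLines(c(hdr, rows), hmp)
  expect_equal(read_hapmap(hmp)$calls, read_vcf(vcf)$calls)
})

test_that("passport parsing validates ids and glume scores", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "accession_id,taxon,race,country,site_name,lat,lon,glume_score",
    "TA471,aegilopoides,alpha,Turkey,,37.1,38.8,7",
    "TA999,urartu,,Lebanon,Bekaa,,,"
  ), path)
  pp <- read_passport(path)
  expect_equal(pp$glume_score[pp$accession_id == "TA471"], 7L)
  expect_true(is.na(pp$lat[2]) && is.na(pp$glume_score[2]))

  writeLines(c("accession_id,glume_score", "x,12"), path)
  expect_error(read_passport(path), "glume_score")
  writeLines(c("accession_id,taxon", "x,a", "x,b"), path)
  expect_error(read_passport(path), "duplicate")
})

test_that("subsetting preserves order, slices metadata, and partitions by taxon", {
  calls <- matrix(0:2, 6, 4)
  g <- make_geno(calls, ids = paste0("t", 1:6))
  expect_equal(subset_geno(g)$calls, g$calls)
  tiny <- subset_geno(g, accessions = "t3", sites = 2L)
  expect_equal(dim(tiny$calls), c(1L, 1L))
  expect_error(subset_geno(g, accessions = "nope"), "nope")

  taxa <- stats::setNames(rep(c("u", "m"), 3), paste0("t", 1:6))
  parts <- split_geno(g, taxa)
  expect_equal(sum(vapply(parts, n_accessions, integer(1))), 6L)
  expect_equal(accession_ids(parts$u), c("t1", "t3", "t5"))
})
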