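# shared fixture builders; everything is generated in code, no stored data

make_geno <- function(calls, chrom = NULL, pos = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  l <- ncol(calls)
  if (is.null(ids)) ids <- paste0("acc", seq_len(nrow(calls)))
  rownames(calls) <- ids
  genotype_matrix(
    calls,
    data.frame(chrom = chrom %||% rep("1A", l),
               pos = pos %||% seq_len(l) * 100L,
               ref = rep("A", l), alt = rep("G", l))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a single-column geno matrix from a call vector (one site, many accessions)
one_site <- function(calls) make_geno(matrix(as.integer(calls), ncol = 1))

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# two-group inbred simulation used by several statistical tests
two_pop_geno <- function(seed, L = 2000, n = 50, F_pop = c(0.1, 0.1),
                         f_is = 0.97, labels = c("a", "b")) {
  fr <- draw_subpop_freqs(L, 2, F_pop, seed = seed)
  g <- sample_genotypes(fr, c(n, n), f_is = f_is, seed = seed + 1)
  ids <- sprintf("s%03d", seq_len(2 * n))
  calls <- g$calls
  rownames(calls) <- ids
  geno <- genotype_matrix(
    calls,
    data.frame(chrom = "1A", pos = seq_len(L) * 50L,
               ref = "A", alt = "G"))
  list(geno = geno,
       groups = stats::setNames(labels[g$pop], ids),
       freqs = fr)
}
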