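test_that("Balding-Nichols frequencies have the model's mean and variance", {
  L <- 20000
  fr <- draw_subpop_freqs(L, 2, c(0.1, 0.3), seed = 101)
  expect_true(all(fr$p0 > 0.05 & fr$p0 < 0.95))
  # E[p_k] = p0, Var[p_k] = F p0 (1 - p0); check standardised residual moments
  for (k in 1:2) {
    f <- c(0.1, 0.3)[k]
    dev <- fr$p[, k] - fr$p0
    expect_lt(abs(mean(dev)), 4 * sqrt(mean(f * fr$p0 * (1 - fr$p0))) / sqrt(L))
    ratio <- mean(dev^2) / mean(f * fr$p0 * (1 - fr$p0))
    expect_lt(abs(ratio - 1), 0.05)
  }
  # F -> 0 concentrates the frequencies at the ancestral value
  tight <- draw_subpop_freqs(5000, 1, 0.001, seed = 102)
  expect_lt(stats::var(tight$p[, 1] - tight$p0), 0.001)
  expect_identical(draw_subpop_freqs(100, 2, 0.2, seed = 7),
                   draw_subpop_freqs(100, 2, 0.2, seed = 7))
  expect_error(draw_subpop_freqs(10, 1, 1.2), "F_pop")
})

test_that("inbred genotype sampling matches the selfing model's rates", {
  # f_is = 1: no heterozygotes at all
  fr <- draw_subpop_freqs(2000, 1, 0.2, seed = 111)
  g1 <- sample_genotypes(fr, 50, f_is = 1, seed = 112)
  expect_equal(sum(g1$calls == 1L), 0L)

  # p = 0.5, f_is = 0.97: het rate 2pq(1-f) = 0.015, within 3 binomial SD
  frc <- list(p0 = rep(0.5, 10000), p = matrix(0.5, 10000, 1))
  g2 <- sample_genotypes(frc, 100, f_is = 0.97, seed = 113)
  n_calls <- length(g2$calls)
  het <- mean(g2$calls == 1L)
  expect_lt(abs(het - 0.015), 3 * sqrt(0.015 * 0.985 / n_calls))
  # emitted allele frequency is unbiased for p
  expect_lt(abs(mean(g2$calls) / 2 - 0.5), 3 * sqrt(0.5 * 0.5 / n_calls))
})

test_that("artifacts add missingness and spurious heterozygotes at the set rates", {
  set.seed(121)
  calls <- matrix(sample(c(0L, 2L), 200 * 500, replace = TRUE), 200)
  expect_identical(apply_artifacts(calls, 0, 0, seed = 1), calls)

  miss <- apply_artifacts(calls, 0.1, 0, seed = 2)
  rate <- mean(is.na(miss))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(calls)))

  hets <- apply_artifacts(calls, 0, 0.005, seed = 3)
  hrate <- mean(hets == 1L)
  expect_lt(abs(hrate - 0.005), 3 * sqrt(0.005 * 0.995 / length(calls)))
})

test_that("planted clones sit at the configured identity-by-state", {
  cfg <- sim_config(seed = 131, L = 3000, n_per_pop = c(60, 60),
                    pop_labels = c("p1", "p2"), F_pop = c(0.2, 0.2),
                    missing_rate = 0.05, het_error_rate = 0.003,
                    duplicates = list(count = 8, epsilon = 0.002),
                    mislabel_fraction = 0)
  sim <- simulate_collection(cfg)
  ibs <- ibs_matrix(sim$geno, min_compared = 500)
  eps <- 0.002
  for (i in seq_len(nrow(sim$truth$duplicate_pairs))) {
    pr <- sim$truth$duplicate_pairs[i, ]
    idty <- ibs$identity[pr$source, pr$clone]
    ncomp <- ibs$compared[pr$source, pr$clone]
    expect_lt(abs(idty - (1 - eps)), 3 * sqrt(eps * (1 - eps) / ncomp) + 1e-9)
  }
  # a zero-discordance clone is exactly identical over compared loci
  cfg0 <- sim_config(seed = 132, L = 1000, n_per_pop = c(30, 30),
                     pop_labels = c("p1", "p2"), F_pop = c(0.2, 0.2),
                     missing_rate = 0, het_error_rate = 0,
                     duplicates = list(count = 2, epsilon = 0),
                     mislabel_fraction = 0)
  sim0 <- simulate_collection(cfg0)
  ibs0 <- ibs_matrix(sim0$geno, min_compared = 100)
  pr0 <- sim0$truth$duplicate_pairs
  expect_equal(unname(diag(ibs0$identity[pr0$source, pr0$clone])), c(1, 1))
})

test_that("a simulated collection round-trips losslessly through the writers", {
  cfg <- sim_config(seed = 141, L = 400, n_per_pop = c(15, 15, 15, 15))
  dir <- tempfile("sim")
  sim <- simulate_collection(cfg, dir = dir)
  g2 <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(g2$calls, sim$geno$calls)
  expect_equal(g2$sites$pos, sim$geno$sites$pos)
  pp2 <- read_passport(file.path(dir, "passports.csv"))
  expect_equal(pp2$accession_id, sim$passports$accession_id)
  expect_equal(pp2$glume_score, sim$passports$glume_score)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 141L)

  # same seed -> byte-identical outputs
  dir2 <- tempfile("sim")
  simulate_collection(cfg, dir = dir2)
  for (f in c("genotypes.vcf", "passports.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("realized between-population F_ST matches the configured target", {
  cfg <- sim_config(seed = 151, L = 4000, n_per_pop = c(60, 60),
                    pop_labels = c("p1", "p2"), F_pop = c(0.2, 0.3),
                    missing_rate = 0, het_error_rate = 0,
                    duplicates = list(count = 0, epsilon = 0),
                    mislabel_fraction = 0)
  sim <- simulate_collection(cfg)
  wc <- wc_fst_multilocus(wc_fst_per_site(sim$geno, sim$truth$pops,
                                          c("p1", "p2")))
  expect_lt(abs(wc - 0.25), 0.02)  # target (F1 + F2) / 2
})

test_that("planted mislabels are recorded and applied to the passports", {
  cfg <- sim_config(seed = 161, L = 300, n_per_pop = c(20, 20, 20),
                    pop_labels = c("x", "y", "z"), F_pop = c(0.3, 0.3, 0.3),
                    duplicates = list(count = 0, epsilon = 0),
                    mislabel_fraction = 0.1)
  sim <- simulate_collection(cfg)
  mis <- sim$truth$mislabels
  expect_equal(nrow(mis), 6)
  idx <- match(mis$accession_id, sim$passports$accession_id)
  expect_equal(sim$passports$taxon[idx], mis$assigned_taxon)
  expect_true(all(mis$assigned_taxon != mis$true_taxon))
  expect_equal(unname(sim$truth$pops[mis$accession_id]), mis$true_taxon)
})
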