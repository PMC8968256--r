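test_that("Nei diversity: direct arithmetic and the 2m(1-m) identity", {
  expect_equal(nei_diversity(make_geno(rbind(c(0L), c(2L)))), 0.5)
  expect_equal(nei_diversity(make_geno(matrix(0L, 4, 6))), 0)

  # sites with p = 0.5 and p = 0.1 -> (0.5 + 0.18) / 2 = 0.34
  s1 <- c(rep(0L, 5), rep(2L, 5))
  s2 <- c(rep(0L, 9), 2L)
  expect_equal(nei_diversity(make_geno(cbind(s1, s2))), 0.34)

  # every site at MAF m gives exactly 2 m (1 - m)
  m <- 0.2
  site <- c(rep(2L, 4), rep(0L, 16))
  g <- make_geno(matrix(site, 20, 7))
  expect_equal(nei_diversity(g), 2 * m * (1 - m))

  expect_error(nei_diversity(make_geno(matrix(NA_integer_, 3, 2))), "defined")
})

test_that("segregating loci counting honours the single-het rule", {
  g <- make_geno(cbind(c(0L, 0L, 2L), c(0L, 0L, 0L), c(0L, 1L, 0L)))
  expect_equal(segregating_count(g), 2L)  # small group: no rule
  big <- make_geno(cbind(c(1L, rep(0L, 149)), rep(c(0L, 2L), length.out = 150)))
  expect_equal(segregating_count(big), 1L)
  expect_equal(segregating_count(big, apply_single_het_rule = FALSE), 2L)
})

test_that("pairwise G_ST-style F_ST matches hand arithmetic and its limits", {
  ids <- paste0("i", 1:4)
  groups <- stats::setNames(c("A", "A", "B", "B"), ids)

  opposite <- make_geno(rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L)),
                        ids = ids)
  expect_equal(pairwise_fst(opposite, groups, c("A", "B")), 1)

  same <- make_geno(rbind(c(0L, 2L), c(2L, 0L), c(0L, 2L), c(2L, 0L)),
                    ids = ids)
  expect_equal(pairwise_fst(same, groups, c("A", "B")), 0)

  # A: p = {1, 0.5}; B: p = {0, 0.5}; equal n -> F = 1 - 0.5 / 1 = 0.5
  toy <- make_geno(rbind(c(2L, 0L), c(2L, 2L), c(0L, 2L), c(0L, 0L)),
                   ids = ids)
  expect_equal(pairwise_fst(toy, groups, c("A", "B")), 0.5)

  fixed_same <- make_geno(matrix(0L, 4, 3), ids = ids)
  expect_warning(res <- pairwise_fst(fixed_same, groups, c("A", "B")),
                 "undefined")
  expect_true(is.na(res))

  expect_error(pairwise_fst(toy, groups, c("A", "C")), "at least 2")
})

# independent re-coding of the Weir-Cockerham (1984) two-group components,
# written from the variance-component definitions rather than the package's
# vectorised path
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("per-site Weir-Cockerham theta matches an independent implementation", {
  ids <- paste0("i", sprintf("%03d", 1:100))
  groups <- stats::setNames(rep(c("A", "B"), each = 50), ids)

  # n1 = n2 = 50, p1 = 0.9, p2 = 0.1, no heterozygotes
  gA <- c(rep(2L, 45), rep(0L, 5))
  gB <- c(rep(2L, 5), rep(0L, 45))
  g <- make_geno(matrix(c(gA, gB), ncol = 1), ids = ids)
  wc <- wc_fst_per_site(g, groups, c("A", "B"))
  expect_equal(wc$theta, wc_oracle(50, 0.9, 0, 50, 0.1, 0), tolerance = 1e-12)

  # random sites, including heterozygotes and missing calls
  set.seed(19)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 100 * 30, replace = TRUE,
                         prob = c(.4, .1, .4, .1)), 100, 30)
  g2 <- make_geno(calls, ids = ids)
  wc2 <- wc_fst_per_site(g2, groups, c("A", "B"))
  for (j in seq_len(30)) {
    a <- calls[1:50, j]; b <- calls[51:100, j]
    n1 <- sum(!is.na(a)); n2 <- sum(!is.na(b))
    ref <- wc_oracle(n1, sum(a, na.rm = TRUE) / (2 * n1),
                     mean(a[!is.na(a)] == 1),
                     n2, sum(b, na.rm = TRUE) / (2 * n2),
                     mean(b[!is.na(b)] == 1))
    expect_equal(wc2$theta[j], ref, tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham limits: fixed difference gives 1, no differentiation <= 0", {
  ids <- paste0("i", 1:20)
  groups <- stats::setNames(rep(c("A", "B"), each = 10), ids)
  fixed <- make_geno(matrix(rep(c(0L, 2L), each = 10), ncol = 1), ids = ids)
  expect_equal(wc_fst_per_site(fixed, groups, c("A", "B"))$theta, 1)

  balanced <- make_geno(matrix(rep(c(0L, 2L), 10), ncol = 1), ids = ids)
  expect_lte(wc_fst_per_site(balanced, groups, c("A", "B"))$theta, 0)
})

test_that("random label permutation drives both estimators to zero", {
  sim <- two_pop_geno(seed = 77, L = 3000, n = 100, F_pop = c(0.2, 0.2))
  set.seed(78)
  permuted <- stats::setNames(sample(sim$groups), names(sim$groups))
  gst <- pairwise_fst(sim$geno, permuted, c("a", "b"))
  wc <- wc_fst_multilocus(wc_fst_per_site(sim$geno, permuted, c("a", "b")))
  expect_lte(abs(gst), 0.01)
  expect_lte(abs(wc), 0.01)
})

test_that("diversity report and F_ST matrix cover all labelled groups", {
  sim <- two_pop_geno(seed = 55, L = 500, n = 15, F_pop = c(0.3, 0.3))
  rep <- diversity_report(sim$geno, sim$groups)
  expect_setequal(rep$group, c("a", "b"))
  expect_true(all(rep$nei >= 0 & rep$nei <= 0.5))
  expect_true(all(rep$segregating <= n_sites(sim$geno)))
  m <- fst_matrix(sim$geno, sim$groups)
  expect_equal(m["a", "b"], pairwise_fst(sim$geno, sim$groups, c("a", "b")))
  expect_equal(diag(m), c(a = 0, b = 0))
})
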