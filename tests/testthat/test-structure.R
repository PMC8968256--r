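test_that("distance matrix: IBS complement and scaled euclidean", {
  row <- rep(c(0L, 2L), 10)
  g <- make_geno(rbind(row, row))
  d <- distance_matrix(g, "one_minus_ibs", min_compared = 5)
  expect_equal(d$d[1, 2], 0)

  # identity 0.8 -> distance 0.2
  g2 <- make_geno(rbind(c(0L, 0L, 2L, 2L, 0L), c(0L, 0L, 2L, 2L, 2L)))
  expect_equal(distance_matrix(g2, min_compared = 1)$d[1, 2], 0.2)

  # euclidean with full overlap: calls (0,2) vs (2,0) -> sqrt(8)
  g3 <- make_geno(rbind(c(0L, 2L), c(2L, 0L)))
  expect_equal(distance_matrix(g3, "euclidean")$d[1, 2], sqrt(8))

  # missing-scaled euclidean: shared half the sites, rescaled by sqrt(L/Ls)
  g4 <- make_geno(rbind(c(0L, 2L, NA, NA), c(2L, 0L, 0L, 0L)))
  expect_equal(distance_matrix(g4, "euclidean")$d[1, 2], sqrt(8 * 4 / 2))
})

test_that("three-taxon neighbour joining reproduces the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pend <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(pend[["a"]], 1)
  expect_equal(pend[["b"]], 1)
  expect_equal(pend[["c"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "3 accessions")
})

test_that("NJ recovers additive distances exactly and clamps negatives", {
  set.seed(13)
  true_tree <- ape::rtree(5, br = function(n) runif(n, 0.2, 1))
  d <- ape::cophenetic.phylo(true_tree)
  rec <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(attr(rec, "clamped"), 0L)

  # duplicate accessions become zero-length sisters
  row <- rep(c(0L, 2L), 25)
  g <- make_geno(rbind(row, row, rep(0L, 50), rep(2L, 50)))
  tr <- nj_tree(distance_matrix(g, min_compared = 10))
  pend <- tr$edge.length[match(match(c("acc1", "acc2"), tr$tip.label),
                               tr$edge[, 2])]
  expect_equal(pend, c(0, 0))
})

test_that("Newick export writes the closed-form tree and quotes awkward labels", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- tempfile(fileext = ".nwk")
  to_newick(nj_tree(d), path)
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, c("a", "b", "c"))
  expect_equal(ape::cophenetic.phylo(reread)[c("a", "b", "c"), c("a", "b", "c")],
               d, tolerance = 1e-10)

  tr <- nj_tree(d)
  tr$tip.label <- c("taxon one", "b", "c")
  path2 <- tempfile(fileext = ".nwk")
  to_newick(tr, path2)
  expect_match(readLines(path2), "'taxon one'")
})

test_that("relationship-matrix PCA separates fixed blocks and respects the trace", {
  calls <- rbind(matrix(0L, 5, 40), matrix(2L, 5, 40))
  g <- make_geno(calls)
  p <- grm_pca(g, k = 4)
  expect_gt(p$variance_explained[1], 0.999)
  expect_true(all(sign(p$coordinates[1:5, 1]) == -sign(p$coordinates[6:10, 1])))

  set.seed(17)
  calls2 <- matrix(sample(c(0L, 1L, 2L), 300, replace = TRUE), 10, 30)
  g2 <- make_geno(calls2)
  pf <- grm_pca(g2, k = 10)
  expect_equal(sum(pf$values / sum(pf$values)), 1, tolerance = 1e-9)

  # duplicated accessions land on identical coordinates
  g3 <- make_geno(rbind(calls2, calls2[1, , drop = FALSE]),
                  ids = c(paste0("acc", 1:10), "dup"))
  p3 <- grm_pca(g3, k = 3)
  expect_equal(p3$coordinates["dup", ], p3$coordinates["acc1", ])

  expect_error(grm_pca(make_geno(matrix(0L, 3, 5))), "no polymorphism")
})

test_that("PCA coordinates are order-invariant up to per-axis sign", {
  set.seed(23)
  calls <- matrix(sample(c(0L, 1L, 2L), 600, replace = TRUE), 15, 40)
  g <- make_geno(calls)
  perm <- sample(15)
  g_perm <- make_geno(calls[perm, ], ids = paste0("acc", perm))
  p1 <- grm_pca(g, k = 3)
  p2 <- grm_pca(g_perm, k = 3)
  for (k in 1:3) {
    r <- stats::cor(p1$coordinates[, k],
                    p2$coordinates[accession_ids(g), k])
    expect_equal(abs(r), 1, tolerance = 1e-6)
  }
})

test_that("kNN misclassification voting flags planted labels and respects the gate", {
  sim <- two_pop_geno(seed = 41, L = 800, n = 20, F_pop = c(0.4, 0.4))
  labels <- sim$groups
  labels[c("s003", "s030")] <- rev(labels[c("s003", "s030")])  # swap two
  d <- distance_matrix(sim$geno, min_compared = 50)
  flags <- flag_misclassified(d, labels, k_neighbors = 10, agreement = 0.8)
  expect_setequal(flags$accession_id, c("s003", "s030"))
  expect_equal(flags$proposed_label,
               unname(sim$groups[flags$accession_id]))

  none <- flag_misclassified(d, stats::setNames(rep("x", 40), names(labels)),
                             k_neighbors = 10)
  expect_equal(nrow(none), 0)

  expect_error(flag_misclassified(d, labels, k_neighbors = 40), "smaller")

  # weak majority below the agreement gate is not flagged
  ids <- c("q1", "q2", "q3", "q4", "q5", "q6")
  dm <- matrix(1, 6, 6, dimnames = list(ids, ids))
  diag(dm) <- 0
  dm["q1", 2:6] <- dm[2:6, "q1"] <- c(.1, .1, .1, .2, .2)
  dd <- structure(list(ids = ids, d = dm, metric = "one_minus_ibs"),
                  class = "geno_dist")
  lab <- stats::setNames(c("A", "B", "B", "B", "A", "A"), ids)
  expect_equal(nrow(flag_misclassified(dd, lab, k_neighbors = 5,
                                       agreement = 0.8)), 0)
})
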