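test_that("nmi handles worked examples and degenerate conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  expect_equal(nmi(c(1, 1, 1), c(2, 2, 2)), 1)  # both single-cluster
  # A = {1,2},{3,4}; B = {1},{2,3,4}: direct entropy arithmetic
  a <- c(1, 1, 2, 2)
  b <- c(1, 2, 2, 2)
  expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-12)
})

test_that("nmi is symmetric, permutation-invariant and oracle-exact", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-10)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-14)
    perm <- c("w", "x", "y", "z")[a]
    expect_equal(nmi(perm, b), nmi(a, b), tolerance = 1e-14)
  }
})

test_that("nmi agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(nmi(a, b),
                 igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-10)
  }
})

test_that("nmi aligns named labellings and rejects mismatched item sets", {
  a <- c(x = 1, y = 1, z = 2)
  b <- c(z = "b", x = "a", y = "a")
  expect_equal(nmi(a, b), 1)
  expect_error(nmi(c(x = 1), c(q = 1)), "different item sets")
})

test_that("category evaluation restricts to the labelled overlap", {
  p <- partition(c(A = 0, B = 0, C = 1, D = 1))
  full <- c(A = "m", B = "m", C = "s", D = "s")
  expect_equal(evaluate_against_categories(p, full)$nmi, 1)
  half <- full[c("A", "C")]
  res <- evaluate_against_categories(p, half)
  expect_equal(res$n_scored, 2L)
  expect_equal(res$n_excluded, 2L)
  expect_equal(res$nmi, 1)
  expect_error(evaluate_against_categories(p, c(ZZ = "x")), "no pathway")
})

test_that("max overlap fraction detects containment and disjointness", {
  u <- sprintf("G%03d", 1:100)
  coll <- geneset_collection(
    list(KEGG_SMALL = u[1:10], REACTOME_BIG = u[1:40],
         KEGG_FAR = u[61:70]),
    universe = u)
  cross <- max_overlap_fraction(coll, scope = "cross")
  expect_equal(cross$fraction[cross$id == "KEGG_SMALL"], 1)  # subset
  expect_equal(cross$best_partner[cross$id == "KEGG_SMALL"],
               "REACTOME_BIG")
  within <- max_overlap_fraction(coll, scope = "within")
  expect_equal(within$fraction[within$id == "KEGG_SMALL"], 0)
  disj <- geneset_collection(list(A = u[1:5], B = u[11:15], C = u[21:25]),
                             universe = u)
  expect_true(all(max_overlap_fraction(disj, "any")$fraction == 0))
  # 7 of 10 genes shared with the best partner
  coll2 <- geneset_collection(list(A = u[1:10], B = c(u[1:7], u[90:95])),
                              universe = u)
  expect_equal(max_overlap_fraction(coll2, "any")$fraction[1], 0.7)
})

test_that("pathways with no eligible partner are flagged", {
  u <- sprintf("G%03d", 1:50)
  coll <- geneset_collection(list(KEGG_A = u[1:10], KEGG_B = u[5:14]),
                             universe = u)
  res <- max_overlap_fraction(coll, scope = "cross")
  expect_true(all(res$no_partner))
  expect_true(all(res$fraction == 0))
})

test_that("gene over-representation matches hypergeometric oracles", {
  u <- sprintf("G%03d", 1:60)
  # gene u[1] in all pathways; gene u[2] only in community 0's members
  sets <- list(A1 = c(u[1], u[2], u[3:12]), A2 = c(u[1], u[2], u[13:22]),
               A3 = c(u[1], u[2], u[23:32]),
               B1 = c(u[1], u[33:42]), B2 = c(u[1], u[43:52]),
               B3 = c(u[1], u[44:53]))
  coll <- geneset_collection(sets, universe = u)
  part <- partition(c(A1 = 0, A2 = 0, A3 = 0, B1 = 1, B2 = 1, B3 = 1))
  res <- gene_overrepresentation(coll, part)
  g1 <- res[res$gene == toupper(u[1]), ]
  expect_true(all(g1$p_raw == 1))
  g2 <- res[res$gene == toupper(u[2]) & res$community == 0, ]
  expect_equal(g2$p_raw, 1 / choose(6, 3), tolerance = 1e-12)
  # every (gene, community) p matches the explicit pmf summation
  check <- res[sample(seq_len(nrow(res)), 50), ]
  for (i in seq_len(nrow(check))) {
    r <- check[i, ]
    expect_equal(r$p_raw, hyper_tail_oracle(r$x, r$K, r$n, r$N),
                 tolerance = 1e-10)
  }
  # observed counts are conserved across communities
  sums <- tapply(res$x, res$gene, sum)
  Ks <- tapply(res$K, res$gene, unique)
  expect_equal(unname(sums), unname(Ks))
})

test_that("assignment agreement applies the argmax and tie rules", {
  qa <- c(g1 = "c1", g2 = "c2", g3 = "c1")
  founders <- list(
    g1 = c(c1 = 5, c2 = 1),              # unique argmax, agree
    g2 = c(c1 = 4, c2 = 2, c3 = 3),      # assigned has rank 3
    g3 = c(c1 = 3, c2 = 3)               # tie, assigned is an argmax
  )
  rep <- assignment_agreement(qa, founders)
  expect_equal(rep$per_group$agree, c(TRUE, FALSE, TRUE))
  expect_equal(rep$per_group$rank, c(1L, 3L, 1L))
  expect_equal(rep$summary, 2 / 3)
  # groups without founders are excluded with a warning
  expect_warning(
    rep2 <- assignment_agreement(c(qa, g4 = "c9"), founders),
    "g4")
  expect_equal(nrow(rep2$per_group), 3L)
})
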