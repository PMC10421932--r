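test_that("p-distance counts mismatches over comparable columns", {
  al <- c(a = "ACDE", b = "ACDE")
  expect_equal(unname(distance_matrix(al, "p_distance_on_alignment")["a", "b"]), 0)
  al2 <- c(a = "ACDE", b = "ACDF")
  expect_equal(unname(distance_matrix(al2)["a", "b"]), 0.25)
  # one gapped column of five: 4 comparable, 1 mismatch
  al3 <- c(a = "ACDEF", b = "AC-EY")
  expect_equal(unname(distance_matrix(al3)["a", "b"]), 0.25)
  expect_error(distance_matrix(c(a = "ACDE", b = "ACD")), "ragged")
})

test_that("feature distance modes are metric-consistent", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 0))
  De <- distance_matrix(m, "feature_euclidean")
  expect_equal(De["a", "c"], 1)
  expect_equal(De["a", "b"], sqrt(2))
  Dc <- distance_matrix(m, "feature_cosine")
  expect_equal(Dc["a", "c"], 0)          # parallel vectors
  expect_equal(Dc["a", "b"], 1)          # orthogonal vectors
})

test_that("neighbor joining solves the 3-leaf case in closed form", {
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(D)
  expect_identical(ape::Ntip(tree), 3L)
  # x = (dab + dac - dbc)/2 etc.
  br <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(unname(br["a"]), 1)
  expect_equal(unname(br["b"]), 2)
  expect_equal(unname(br["c"]), 4)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the quartet split and random additive topologies", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tree <- neighbor_joining(D)
  expect_true(is_monophyletic(tree, c("A", "B")))
  expect_true(is_monophyletic(tree, c("C", "D")))

  for (s in 1:20) {
    gen <- random_additive_matrix(8, seed = s)
    expect_identical(robinson_foulds(neighbor_joining(gen$D), gen$tree), 0L)
  }
})

test_that("Robinson-Foulds counts split differences and validates leaves", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(robinson_foulds(t1, t1), 0L)
  expect_identical(robinson_foulds(t1, t2), 2L)
  expect_identical(robinson_foulds(t1, t2), oracle_rf(t1, t2))

  cat5 <- ape::read.tree(text = "(((((a,b),c),d),e));")
  rev5 <- ape::read.tree(text = "(((((e,d),c),b),a));")
  expect_identical(robinson_foulds(cat5, rev5), oracle_rf(cat5, rev5))

  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "leaf sets differ")

  # metric sanity on sampled triples
  for (s in 1:5) {
    trees <- lapply(s * 10 + 1:3,
                    function(k) random_additive_matrix(7, k)$tree)
    d12 <- robinson_foulds(trees[[1]], trees[[2]])
    d21 <- robinson_foulds(trees[[2]], trees[[1]])
    d13 <- robinson_foulds(trees[[1]], trees[[3]])
    d23 <- robinson_foulds(trees[[2]], trees[[3]])
    expect_identical(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("monophyly testing works in the unrooted sense", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d")))
  expect_true(is_monophyletic(tr, "a"))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, c("a", "b")))
  # complement of a clade is monophyletic on an unrooted tree
  cat6 <- ape::read.tree(text = "(((a,b),c),(d,(e,f)));")
  expect_true(is_monophyletic(cat6, c("c", "d", "e", "f")))
  expect_error(is_monophyletic(tr, c("a", "z")), "unknown leaf")
})

test_that("descriptor distances make each divergent group a clade", {
  g3 <- list(
    group_spec("ly6_anchored", 8, 1:10, has_mad_tail = TRUE,
               signal_start = "MKL"),
    group_spec("ly6_secreted", 8, 1:10, signal_start = "MKL"),
    group_spec("long_chain", 8, 1:10, extra_cys_in_loop2 = 2L,
               loop2_extension = 6L))
  fam <- generate_protein_family(g3, seed = 11)
  coh <- fam[fam$group != "marker", ]
  feats <- compose_features(stats::setNames(coh$mature, coh$id),
                            "cys_descriptor")
  D <- distance_matrix(feats, "feature_euclidean")
  within <- mean(D[coh$group == "long_chain", coh$group == "long_chain"])
  between <- mean(D[coh$group == "long_chain", coh$group != "long_chain"])
  expect_gte(between, 3 * within)
  tree <- suppressWarnings(neighbor_joining(D))
  expect_true(is_monophyletic(tree, coh$id[coh$group == "long_chain"]))
  expect_true(is_monophyletic(tree, coh$id[coh$group == "ly6_anchored"]))
})
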