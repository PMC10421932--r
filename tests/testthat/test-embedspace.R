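test_that("feature construction matches its definitions", {
  f <- compose_features(c(p = "AAAA"), "composition20")
  expect_equal(unname(f[1, "A"]), 1)
  expect_equal(sum(f), 1)

  set.seed(31)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  seqs <- vapply(1:20, function(i) {
    paste(sample(aa, 40, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:20)
  comp <- compose_features(seqs, "composition20")
  expect_equal(unname(rowSums(comp)), rep(1, 20), tolerance = 1e-9)

  k <- compose_features(c(p = "CC"), "kmer", standardize = FALSE)
  expect_equal(sum(k != 0), 1L)
  expect_equal(unname(k[1, "CC"]), 1)

  expect_error(compose_features(c(p = "AA"), "pca"), "unknown feature mode")
  vecs <- matrix(1, 1, 4, dimnames = list("other", NULL))
  expect_error(compose_features(c(p = "AA"), "imported", imported = vecs),
               "missing ids: p")
})

test_that("projection is deterministic, order-preserving and guarded", {
  set.seed(32)
  blobs <- rbind(matrix(rnorm(300, 0, 0.1), ncol = 3),
                 matrix(rnorm(300, 100, 0.1), ncol = 3))
  rownames(blobs) <- paste0("p", 1:200)
  prm <- projection_params(n_neighbors = 25, seed = 42)
  a <- project(blobs, prm)
  b <- project(blobs, prm)
  expect_identical(a, b)
  expect_identical(rownames(a), rownames(blobs))

  # two far-separated blobs stay pure under nearest-neighbour labelling
  truth <- rep(1:2, each = 100)
  d <- as.matrix(dist(a))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(truth[nn] == truth), 0.99)

  few <- blobs[1:25, ]
  expect_error(project(few, prm), "n_neighbors")
})

test_that("k-means honours k extremes and recovers well-separated blobs", {
  set.seed(33)
  pts <- matrix(rnorm(40), ncol = 2)
  expect_identical(kmeans_cluster(pts, 1), rep(0L, 20))
  labs_n <- kmeans_cluster(pts, nrow(pts), seed = 4)
  expect_identical(sort(unique(labs_n)), 0:(nrow(pts) - 1L))

  centers <- matrix(rnorm(14, sd = 10), ncol = 2)
  pts7 <- do.call(rbind, lapply(1:7, function(g) {
    sweep(matrix(rnorm(40, sd = 0.1), ncol = 2), 2, centers[g, ], "+")
  }))
  truth <- rep(1:7, each = 20)
  labs <- kmeans_cluster(pts7, 7, seed = 5)
  expect_equal(concordance(labs, truth), 1)
  expect_error(kmeans_cluster(pts, 21), "fewer points")
})

test_that("DBSCAN matches its contract cases and the reachability oracle", {
  six <- rbind(matrix(rnorm(12, sd = 0.02), ncol = 2), c(100, 100))
  labs <- dbscan_cluster(six, eps = 0.55, min_pts = 5)
  expect_identical(labs, c(rep(1L, 6), 0L))

  same <- matrix(1, nrow = 8, ncol = 3)
  expect_identical(dbscan_cluster(same, 0.55, 5), rep(1L, 8))
  expect_identical(dbscan_cluster(same, 0.55, 9), rep(0L, 8))

  set.seed(34)
  for (trial in 1:40) {
    n <- sample(4:12, 1)
    pts <- matrix(runif(2 * n, 0, 2), ncol = 2)
    expect_identical(dbscan_cluster(pts, 0.55, 5),
                     oracle_dbscan(pts, 0.55, 5))
  }
})

test_that("OPTICS ordering matches the naive oracle and xi finds structure", {
  set.seed(35)
  for (trial in 1:25) {
    n <- sample(5:12, 1)
    pts <- matrix(runif(2 * n, 0, 2), ncol = 2)
    got <- optics_xi(pts, min_pts = 3, xi = 0.01)
    want <- oracle_optics_order(pts, min_pts = 3)
    expect_identical(got$order, want$order)
    expect_equal(got$reachability, want$reachability)
  }

  set.seed(36)
  blob <- function(center) cbind(center + 0:5 + rnorm(6, 0, 1e-4), 0)
  two <- rbind(blob(0), blob(100))
  res <- optics_xi(two, min_pts = 2, xi = 0.01)
  leaves <- optics_leaves(res)
  expect_identical(nrow(leaves), 2L)
  expect_identical(length(unique(res$labels)), 2L)

  set.seed(37)
  one <- cbind(1:12 + rnorm(12, 0, 1e-3), 0)
  res1 <- optics_xi(one, min_pts = 3, xi = 0.01)
  leaves1 <- optics_leaves(res1)
  expect_identical(nrow(leaves1), 1L)
  expect_identical(leaves1$start, 1L)
  expect_identical(leaves1$end, 12L)

  same <- matrix(0, nrow = 5, ncol = 2)
  res2 <- optics_xi(same, min_pts = 5, xi = 0.01)
  expect_identical(nrow(optics_leaves(res2)), 1L)
  expect_identical(length(unique(res2$labels)), 1L)
})

test_that("concordance is the adjusted Rand index with noise as a class", {
  expect_equal(concordance(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(concordance(1:4, rep(1, 4)), 0)
  expect_equal(concordance(1:4, rep(1, 4)), oracle_ari(1:4, rep(1, 4)))

  set.seed(38)
  a <- sample(0:3, 40, replace = TRUE)  # 0 plays the noise role
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(concordance(a, b), oracle_ari(a, b))
  perm <- c(3, 1, 2, 4)[a + 1]
  expect_equal(concordance(perm, b), concordance(a, b))
  expect_error(concordance(1:3, 1:4), "length")
})
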