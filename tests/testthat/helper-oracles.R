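# Independent oracles used to cross-check the package implementations.
# Each is a deliberately naive (quadratic/cubic) reimplementation that
# shares no code with the package's algorithms.

# Plain-R affine-gap local alignment (Gotoh recurrences), score only.
# Gap of length k costs open + k * extend.
oracle_sw_score <- function(query, target, sub = blosum62_matrix(),
                            gap_open = 11, gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F_ <- matrix(-Inf, m + 1, n + 1)
  gfirst <- gap_open + gap_extend
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gfirst, E[i + 1, j] - gap_extend)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - gfirst, F_[i, j + 1] - gap_extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + sub[q[i], t[j]],
                             E[i + 1, j + 1], F_[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Brute-force DBSCAN by density reachability: core points, transitive
# closure over core-core adjacency, then border assignment to the lowest
# cluster index among core neighbours.
oracle_dbscan <- function(points, eps, min_pts) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(d)
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  reach <- nb & outer(core, core, "&")  # core-core adjacency
  diag(reach) <- core
  repeat {  # transitive closure
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (core[i] && labels[i] == 0L) {
      cl <- cl + 1L
      labels[reach[i, ] & core] <- cl
    }
  }
  for (i in which(!core)) {
    cand <- labels[nb[i, ] & core]
    if (length(cand)) labels[i] <- min(cand)
  }
  labels
}

# Naive OPTICS ordering: at each step recompute every unprocessed point's
# reachability from scratch as min over processed points p of
# max(coredist(p), d(p, .)), then extract the minimum (ties: lowest index;
# fresh components start at the lowest unprocessed index).
oracle_optics_order <- function(points, min_pts) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(d)
  core <- apply(d, 1, function(r) sort(r)[min_pts])
  processed <- logical(n)
  ord <- integer(0)
  reach_out <- numeric(0)
  while (any(!processed)) {
    un <- which(!processed)
    done <- which(processed)
    r <- vapply(un, function(qq) {
      if (!length(done)) return(Inf)
      min(pmax(core[done], d[done, qq]))
    }, 0)
    pick <- un[order(r, un)][1]
    ord <- c(ord, pick)
    reach_out <- c(reach_out, min(r[un == pick], Inf))
    processed[pick] <- TRUE
  }
  list(order = ord, reachability = reach_out)
}

# Adjusted Rand index straight from the pair-counting contingency formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Non-trivial bipartitions of an unrooted tree by direct edge traversal of
# the ape edge matrix; each split canonicalised as the sorted side
# containing the alphabetically first tip.
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next  # pendant edge: trivial split
    # tips below this internal node
    below <- integer(0)
    stack <- child
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      below <- c(below, kids[kids <= n])
      stack <- c(stack, kids[kids > n])
    }
    side <- sort(tree$tip.label[below])
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (min(side) < min(other)) side else other
    splits <- c(splits, paste(key, collapse = "|"))
  }
  unique(splits)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1)
  s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Shared small fixtures ------------------------------------------------

demo_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_protein_family(default_groups(c(5, 1, 1, 1, 1, 1, 0)),
                                        seed = 42)
    }
    cache
  }
})

demo_genome_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fam <- demo_family()
      species <- mutate_proteins(fam, 0.10, seed = 43)
      genome <- generate_genome(genome_config("demo", seed = 44), species)
      hits <- find_exon_hits(genome$scaffold, exon_query_panel(fam))
      models <- chain_hits_to_genes(hits, genome$scaffold)
      cache <<- list(fam = fam, genome = genome, hits = hits, models = models)
    }
    cache
  }
})
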