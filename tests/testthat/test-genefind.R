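# A small hand-built scaffold: one exact 3-exon gene on the forward strand
# with GT..AG introns, assembled from a known peptide.
make_toy_locus <- function(pep1 = "MKTLLLIVAVLSAQA",
                           pep2 = "LECYTDCKNGFDTSVCPAGQNVCFKRWHYTSENC",
                           pep3 = "ADTIKCLGKSANVYCSGTDRPCVRCTEGKC",
                           strand = "+") {
  e <- vapply(c(pep1, pep2, pep3), back_translate, "")
  set.seed(99)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  i1 <- paste0("GT", pad(96), "AG")
  i2 <- paste0("GT", pad(120), "AG")
  gene <- paste0(e[1], i1, e[2], i2, e[3])
  dna <- paste0(pad(200), gene, pad(200))
  starts <- 200L + c(0L, nchar(e[1]) + nchar(i1),
                     nchar(e[1]) + nchar(i1) + nchar(e[2]) + nchar(i2))
  ends <- starts + nchar(e)
  if (strand == "-") {
    L <- nchar(dna)
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    tmp <- L - ends
    ends <- L - starts
    starts <- tmp
  }
  queries <- c(pep1, pep2, pep3)
  names(queries) <- paste0("toy:", c("E1", "E2", "E3"))
  list(scaffold = c(toy_scaf = dna), truth = cbind(starts, ends),
       queries = queries)
}

test_that("an implanted exact exon yields one perfect hit per query", {
  toy <- make_toy_locus()
  hits <- find_exon_hits(toy$scaffold, toy$queries)
  expect_identical(nrow(hits), 3L)
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$strand == "+"))
  ord <- order(hits$start)
  expect_equal(hits$start[ord], unname(toy$truth[, 1]))
  expect_equal(hits$end[ord], unname(toy$truth[, 2]))
  expect_error(find_exon_hits(toy$scaffold, character(0)), "empty query")
})

test_that("minus-strand exons are reported in forward-strand coordinates", {
  toy <- make_toy_locus(strand = "-")
  hits <- find_exon_hits(toy$scaffold, toy$queries)
  expect_identical(nrow(hits), 3L)
  expect_true(all(hits$strand == "-"))
  ord <- order(hits$start)
  expect_equal(hits$start[ord], sort(unname(toy$truth[, 1])))
  expect_equal(hits$end[ord], sort(unname(toy$truth[, 2])))
})

test_that("random DNA produces no hits at default thresholds", {
  set.seed(77)
  aa <- c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  q <- stats::setNames(paste(sample(aa, 25, replace = TRUE), collapse = ""),
                       "null:E2")
  n_hits <- 0L
  for (trial in 1:30) {
    dna <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    n_hits <- n_hits + nrow(find_exon_hits(c(rand = dna), q))
  }
  expect_identical(n_hits, 0L)
})

test_that("chaining assembles the toy gene and refuses cross-strand joins", {
  toy <- make_toy_locus()
  hits <- find_exon_hits(toy$scaffold, toy$queries)
  models <- chain_hits_to_genes(hits, toy$scaffold)
  expect_length(models, 1L)
  m <- models[[1]]
  expect_identical(m$status, "intact")
  expect_identical(m$exons$role, c("E1", "E2", "E3"))
  expect_equal(m$exons$start, unname(toy$truth[, 1]))
  expect_equal(m$exons$end, unname(toy$truth[, 2]))

  # flip one hit's strand: the pair must no longer chain
  flipped <- hits
  flipped$strand[2] <- "-"
  models2 <- chain_hits_to_genes(flipped, toy$scaffold)
  expect_true(all(vapply(models2, function(x) nrow(x$exons), 0L) < 3L))
})

test_that("status calls follow the spliced translation", {
  run <- demo_genome_run()
  genome <- run$genome
  models <- run$models
  truth <- genome$genes
  for (i in seq_len(nrow(truth))) {
    ovl <- vapply(models, function(m) {
      iv <- range(m$exons$start, m$exons$end)
      max(0, min(iv[2], truth$end[i]) - max(iv[1], truth$start[i]))
    }, 0)
    expect_gt(max(ovl), 0)
    m <- models[[which.max(ovl)]]
    expect_identical(m$status, truth$status[i])
    if (truth$status[i] == "intact") {
      p <- genome$proteins[paste0("demo_", genome$proteins$id) ==
                             truth$gene_id[i], ]
      expect_identical(m$protein, p$sequence)
    }
  }
  # a lone exon hit is an orphan exon set
  toy <- make_toy_locus()
  hits <- find_exon_hits(toy$scaffold, toy$queries)
  lone <- chain_hits_to_genes(hits[hits$role == "E2", , drop = FALSE],
                              toy$scaffold)
  expect_length(lone, 1L)
  expect_identical(lone[[1]]$status, "orphan_exon_set")
  # exon outside scaffold bounds
  bad <- list(id = "m", strand = "+",
              exons = data.frame(role = c("E1", "E2"),
                                 start = c(0L, 900000L),
                                 end = c(30L, 900030L)))
  expect_error(call_gene_status(bad, toy$scaffold), "bounds")
})

test_that("duplicated exon-3 copies are labelled E3dup 5' of E3", {
  run <- demo_genome_run()
  rec <- evaluate_recovery(run$models, run$genome)
  expect_identical(rec$dup3_recall, 1)
})
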