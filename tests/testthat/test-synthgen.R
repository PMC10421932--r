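test_that("group specs validate cysteine parity and length ranges", {
  expect_error(group_spec("odd", 1, cys_slots = 1:9),
               "odd total cysteine count")
  expect_silent(group_spec("ok9", 1, cys_slots = 1:9,
                           disulfide_complete = FALSE))
  expect_error(group_spec("short", 1, core_length_range = c(10, 30)),
               "core_length_range")
})

test_that("generated proteins carry the specified cysteine scaffold", {
  plesio <- group_spec("plesiotypic", 5, cys_slots = 1:10)
  fam <- generate_protein_family(list(plesio), seed = 3)
  fam <- fam[fam$group != "marker", ]
  for (m in fam$mature) {
    expect_identical(lengths(regmatches(m, gregexpr("C", m))), 10L)
  }
  none <- group_spec("bare", 3, cys_slots = integer(0))
  fam0 <- generate_protein_family(list(none), seed = 3)
  fam0 <- fam0[fam0$group != "marker", ]
  for (m in fam0$mature) expect_false(grepl("C", m))
})

test_that("signal peptides and anchoring tails meet their contracts", {
  fam <- demo_family()
  fam <- fam[fam$group != "marker", ]
  expect_true(all(fam$signal_length >= 18 & fam$signal_length <= 24))
  for (i in seq_len(nrow(fam))) {
    start3 <- substr(fam$sequence[i], 1, 3)
    expect_identical(substr(start3, 1, 2),
                     substr(c(ly6_anchored = "MK", ly6_secreted = "MK",
                              pre3ftx = "MK", plesiotypic = "MK",
                              short_chain = "MK", long_chain = "MK",
                              non_standard = "MK")[[fam$group[i]]], 1, 2))
    if (fam$mad_truth[i]) {
      tl <- fam$tail_length[i]
      tail <- substr(fam$mature[i], nchar(fam$mature[i]) - tl + 1,
                     nchar(fam$mature[i]))
      expect_gte(tl, 12)
      expect_gte(mean_hydropathy(tail), 1.0)
    }
  }
})

test_that("same seed and specs give byte-identical outputs", {
  g <- default_groups(c(2, 1, 0, 1, 0, 0, 0))
  f1 <- generate_protein_family(g, seed = 9)
  f2 <- generate_protein_family(g, seed = 9)
  expect_identical(f1, f2)
  sp <- mutate_proteins(f1, 0.1, seed = 10)
  g1 <- generate_genome(genome_config("d", seed = 11), sp)
  g2 <- generate_genome(genome_config("d", seed = 11), sp)
  expect_identical(g1$scaffold, g2$scaffold)
  expect_identical(g1$exons, g2$exons)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_genome(g1, d1)
  p2 <- write_genome(g2, d2)
  for (k in c("fasta", "gff", "proteins")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("genome composition, splicing round-trip and intron motifs hold", {
  run <- demo_genome_run()
  genome <- run$genome
  g <- genome$genes
  expect_identical(sum(g$status == "pseudogene"), 1L)
  expect_identical(sum(g$status == "orphan_exon_set"), 1L)
  expect_identical(sum(g$n_exons == 4L), 1L)
  expect_identical(sum(genome$exons$role == "E3dup"), 1L)

  # dup copy sits 5' of the functional exon 3 in gene orientation
  dup_gene <- g$gene_id[g$n_exons == 4L]
  ex <- genome$exons[genome$exons$gene_id == dup_gene, ]
  dup <- ex[ex$role == "E3dup", ]
  e3 <- ex[ex$role == "E3", ]
  if (dup$strand == "+") expect_lt(dup$start, e3$start)
  else expect_gt(dup$start, e3$start)

  # splice-and-translate round trip for every intact gene
  for (gid in g$gene_id[g$status == "intact"]) {
    p <- genome$proteins[paste0("demo_", genome$proteins$id) == gid, ]
    expect_identical(splice_translate_truth(genome, gid), p$sequence)
  }

  # every intron starts GT and ends AG in gene orientation
  scaf <- genome$scaffold[[1]]
  for (gid in unique(genome$exons$gene_id)) {
    ex <- genome$exons[genome$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    for (k in seq_len(nrow(ex) - 1)) {
      intron <- substr(scaf, ex$end[k] + 1, ex$start[k + 1])
      if (ex$strand[1] == "-") {
        intron <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(intron)))
      }
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
})

test_that("dup3 truncation mode yields a tail-less secreted truth protein", {
  fam <- generate_protein_family(default_groups(c(3, 0, 0, 0, 0, 0, 0)),
                                 seed = 5)
  cfg <- genome_config("tr", n_pseudogenes = 0, n_orphan_exon_sets = 0,
                       n_dup3_genes = 1, dup3_truncation_mode = TRUE,
                       seed = 6)
  genome <- generate_genome(cfg, fam)
  dup_gene <- genome$genes$gene_id[genome$genes$n_exons == 4L]
  pid <- sub("^tr_", "", dup_gene)
  p <- genome$proteins[genome$proteins$id == pid, ]
  expect_identical(p$tail_length, 0L)
  expect_false(p$mad_truth)
  expect_identical(p$secretion_truth, "secreted")
  # the retained exon 3 is followed by a stop before the vestigial tail DNA
  expect_identical(splice_translate_truth(genome, dup_gene), p$sequence)
})

test_that("pseudogenize introduces exactly the requested lesion", {
  fam <- generate_protein_family(default_groups(c(1, 0, 0, 0, 0, 0, 0)),
                                 seed = 8)
  prow <- fam[fam$group != "marker", ][1, ]
  gene <- ly6tools:::build_gene_dna(prow, c(80L, 120L))
  splice <- function(g) {
    paste(substring(g$dna, g$exons$start + 1, g$exons$end), collapse = "")
  }
  stopg <- pseudogenize(gene, "stop", seed = 1)
  aa <- Biostrings::translate(Biostrings::DNAString(splice(stopg)))
  expect_true(grepl("*", as.character(aa), fixed = TRUE))
  expect_identical(stopg$status, "pseudogene")

  fs <- pseudogenize(gene, "frameshift", seed = 2)
  expect_identical(nchar(splice(fs)) %% 3L, 2L)  # one deleted base

  expect_error(pseudogenize(list(dna = "", exons = NULL), "stop"), "no exons")
  expect_error(pseudogenize(gene, "swap"), "arg")
})
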