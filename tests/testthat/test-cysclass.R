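REF <- ly6tools:::LU_REFERENCE_CORE

test_that("signal cleavage follows annotations exactly and flags failures", {
  seq90 <- paste(rep("A", 90), collapse = "")
  mp <- cleave_signal_peptide(seq90, annotation = 21)
  expect_identical(nchar(mp$mature_sequence), 69L)
  expect_false(mp$flagged)
  expect_error(cleave_signal_peptide("MKT", annotation = 5), "beyond")

  short <- cleave_signal_peptide("MKTLLVIVAQ")
  expect_true(short$flagged)
  expect_identical(short$mature_sequence, "MKTLLVIVAQ")
})

test_that("the heuristic recovers generator cleavage sites exactly", {
  fam <- demo_family()
  fam <- fam[fam$group != "marker", ]
  for (i in seq_len(nrow(fam))) {
    mp <- cleave_signal_peptide(fam$sequence[i])
    expect_false(mp$flagged)
    expect_identical(mp$cleavage_site, fam$signal_length[i])
    expect_identical(mp$mature_sequence, fam$mature[i])
  }
})

test_that("framework mapping: identity, slot loss, and generator long-chain", {
  fw <- map_cysteine_framework(REF)
  expect_true(all(fw$slot_occupancy))
  expect_length(fw$extra_cys, 0L)
  expect_identical(fw$loop2_extension, 0L)
  expect_identical(fw$tail_length, 0L)

  mutated <- REF
  slots <- ly6tools:::LU_SLOT_POSITIONS
  substr(mutated, slots[2], slots[2]) <- "S"
  substr(mutated, slots[3], slots[3]) <- "S"
  fw2 <- map_cysteine_framework(mutated)
  expect_identical(sum(fw2$slot_occupancy), 8L)
  expect_false(any(fw2$slot_occupancy[2:3]))
  expect_length(fw2$extra_cys, 0L)

  lc <- group_spec("long_chain", 4, 1:10, extra_cys_in_loop2 = 2L,
                   loop2_extension = 6L)
  fam <- generate_protein_family(list(lc), seed = 13)
  fam <- fam[fam$group != "marker", ]
  for (m in fam$mature) {
    fw3 <- map_cysteine_framework(m)
    expect_length(fw3$extra_cys, 2L)
    expect_identical(fw3$loop2_extension, 6L)
    # the extras sit inside loop II (between slots 4 and 5)
    expect_true(all(fw3$extra_cys > fw3$slot_positions[4] &
                      fw3$extra_cys < fw3$slot_positions[5]))
  }
})

test_that("cysteine accounting and occupancy monotonicity hold", {
  fam <- demo_family()
  fam <- fam[fam$group != "marker", ]
  for (i in seq_len(nrow(fam))) {
    m <- fam$mature[i]
    fw <- map_cysteine_framework(m)
    core <- substr(m, 1, fw$core_end)
    n_cys_core <- lengths(regmatches(core, gregexpr("C", core)))
    expect_identical(sum(fw$slot_occupancy) + length(fw$extra_cys),
                     as.integer(n_cys_core))
    # appending residues after the tail never changes slot occupancy
    fw_ext <- map_cysteine_framework(paste0(m, "GGSSGGSS"))
    expect_identical(fw_ext$slot_occupancy, fw$slot_occupancy)
  }
})

test_that("tail detection applies both length and hydropathy rules", {
  fw0 <- map_cysteine_framework(REF)
  expect_identical(detect_mad(fw0, REF), "secreted")

  acidic <- paste0(REF, paste(rep("E", 20), collapse = ""))
  fw_a <- map_cysteine_framework(acidic)
  expect_identical(fw_a$tail_length, 20L)
  expect_identical(detect_mad(fw_a, acidic), "secreted")

  greasy <- paste0(REF, paste(rep(c("L", "V", "I"), 6), collapse = ""))
  fw_g <- map_cysteine_framework(greasy)
  expect_identical(detect_mad(fw_g, greasy), "anchored")
})

test_that("the four-category rules fire in order", {
  mk_fw <- function(occ, extras = integer(0), ext = 0L) {
    list(slot_occupancy = occ, extra_cys = extras, loop2_extension = ext,
         slot_positions = ifelse(occ, seq(3, 64, length.out = 10), NA),
         tail_length = 0L)
  }
  all10 <- rep(TRUE, 10)
  expect_identical(classify_scaffold(mk_fw(all10), "secreted")$scaffold_class,
                   "plesiotypic")
  lost <- all10; lost[2:3] <- FALSE
  expect_identical(classify_scaffold(mk_fw(lost), "secreted")$scaffold_class,
                   "short_chain")
  expect_identical(
    classify_scaffold(mk_fw(all10, extras = c(25L, 30L), ext = 6L),
                      "secreted")$scaffold_class,
    "long_chain")
  nine <- all10; nine[2] <- FALSE
  expect_identical(classify_scaffold(mk_fw(nine), "secreted")$scaffold_class,
                   "non_standard")
  # a different 8-slot loss pattern is not short-chain
  wrong8 <- all10; wrong8[c(5, 6)] <- FALSE
  expect_identical(classify_scaffold(mk_fw(wrong8), "secreted")$scaffold_class,
                   "non_standard")
})

test_that("every generator protein receives its truth class and secretion", {
  groups <- lapply(default_groups(), function(g) { g$n_genes <- 8L; g })
  fam <- generate_protein_family(groups, seed = 21)
  fam <- fam[fam$group != "marker", ]
  calls <- classify_proteins(stats::setNames(fam$sequence, fam$id))
  expect_identical(calls$class, fam$class_truth)
  expect_identical(calls$secretion, fam$secretion_truth)
  expect_true(all(nzchar(calls$evidence)))
})
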