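test_that("FASTA round-trips and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set.seed(1)
  recs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:80, 1), replace = TRUE),
          collapse = "")
  }, "")
  names(recs) <- sprintf("seq%03d", 1:100)
  write_fasta(recs, tmp)
  back <- read_fasta(tmp)
  expect_identical(names(back), names(recs))
  expect_identical(unname(unclass(back)[seq_along(recs)]), unname(recs))

  one <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), one)
  r1 <- read_fasta(one)
  expect_identical(names(r1), "a")
  expect_identical(unname(r1[1]), "ACGT")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_fasta(dup), "duplicate")
  expect_error(write_fasta(c(a = "ACGT", a = "GG"), tmp), "duplicate")
  expect_error(write_fasta(c(a = ""), tmp), "empty")
})

test_that("GFF3 converts coordinates exactly and is byte-stable", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  ann <- data.frame(scaffold_id = "s1", feature_type = "exon",
                    start = 0L, end = 30L, strand = "+",
                    ID = "x1", status = "intact", role = "E1",
                    stringsAsFactors = FALSE)
  write_gff3(ann, tmp)
  lines <- readLines(tmp)
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body[1], "\t")[[1]]
  expect_identical(cols[4], "1")   # 0-based half-open [0,30) -> file 1..30
  expect_identical(cols[5], "30")
  expect_identical(cols[7], "+")

  back <- read_gff3(tmp)
  expect_identical(back$start, 0L)
  expect_identical(back$end, 30L)

  # file coordinates 101..130 -> in-memory [100,130)
  ann2 <- ann; ann2$start <- 100L; ann2$end <- 130L
  write_gff3(ann2, tmp)
  back2 <- read_gff3(tmp)
  expect_identical(back2$start, 100L)
  expect_identical(back2$end, 130L)

  # second-pass byte stability
  tmp2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(read_gff3(tmp), tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))

  expect_error(write_gff3(transform(ann, strand = "."), tmp), "strand")
  expect_error(write_gff3(transform(ann, end = 0L - 1L), tmp), "end")
  dot <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "s1\ttool\texon\t1\t30\t.\t.\t.\tID=x"), dot)
  expect_error(read_gff3(dot), "strand")
})

test_that("Newick round-trips topology, lengths and labels", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a:1,(b:2,c:3):1);", tmp)
  tree <- read_newick(tmp)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  tmp2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tmp2)
  back <- read_newick(tmp2)
  expect_equal(robinson_foulds(tree, back), 0L)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,(b:2;", bad)
  expect_error(read_newick(bad))
})

test_that("vector files read with constant dimension and reject ragged rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  set.seed(2)
  m <- matrix(rnorm(5 * 1024), nrow = 5,
              dimnames = list(paste0("p", 1:5), NULL))
  write_vectors(m, tmp)
  back <- read_vectors(tmp)
  expect_identical(dim(back), c(5L, 1024L))
  expect_identical(rownames(back), rownames(m))
  expect_equal(unname(back), unname(m), tolerance = 1e-12)

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("a", rep("0.5", 1024)), collapse = "\t"),
               paste(c("b", rep("0.5", 1023)), collapse = "\t")), ragged)
  expect_error(read_vectors(ragged), "ragged")
})
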