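# Synthetic LY6/3FTX cluster generator.
#
# Emulates the statistical structure of the marker-anchored LY6/3FTX genomic
# cluster: 3-exon genes (exon 1 = signal peptide, exon 3 = C-terminus /
# membrane-anchoring tail), pseudogenes with in-frame stops or frameshifts,
# orphan exons, 4-exon genes carrying a duplicated pseudogenized exon-3 copy
# 5' of the functional exon 3, and protein groups differing in cysteine
# framework and tail presence.  Every implanted feature carries a ground-truth
# record, so downstream recovery is measurable.

HYDROPHOBIC_AA <- c("L", "I", "V", "F", "A")

# Mature-core geometry (template coordinates, 1-based; see LU_REFERENCE_CORE)
LOOP2_START <- 24L          # first residue of loop II (after slot 4)
LOOP2_END <- 33L            # last residue of loop II (before slot 5)
LOOP2_INSERT_AT <- 28L      # extension inserted after this template position
LOOP2_EXTRA_CYS_AT <- c(26L, 31L)  # template positions recruited as novel cys
# exon 2 / exon 3 boundary: after this slot, so exon 3 encodes the region
# from loop III onward plus the C-terminal stub and any membrane anchor
EXON23_BOUNDARY_SLOT <- 6L

#' Specify one protein group of the synthetic family
#'
#' A group models one paralogous LY6/3FTX lineage: which of the 10 canonical
#' cysteine slots are occupied, extra loop-II cysteines, loop-II extension
#' length, presence of a hydrophobic membrane-anchoring C-terminal tail
#' (MaD), the signal-peptide start tripeptide, and the pre-tail mature core
#' length range.
#'
#' @param name group label
#' @param n_genes number of member genes
#' @param cys_slots integer subset of 1:10, occupied canonical slots
#' @param extra_cys_in_loop2 0, 1 or 2 extra cysteines recruited in loop II
#' @param loop2_extension residues inserted into loop II (0 = none)
#' @param has_mad_tail whether members carry a hydrophobic C-terminal tail
#' @param signal_start first three residues of the signal peptide
#' @param core_length_range pre-tail mature length range (template is 64)
#' @param disulfide_complete whether the scaffold pairs all its cysteines;
#'   if \code{TRUE} the total cysteine count must be even
#' @return a \code{ly6_group_spec} list
#' @export
group_spec <- function(name, n_genes, cys_slots = 1:10,
                       extra_cys_in_loop2 = 0L, loop2_extension = 0L,
                       has_mad_tail = FALSE, signal_start = "MKT",
                       core_length_range = c(64L, 68L),
                       disulfide_complete = TRUE) {
  cys_slots <- sort(unique(as.integer(cys_slots)))
  stopifnot(all(cys_slots %in% 1:10), n_genes >= 0,
            extra_cys_in_loop2 %in% 0:2, loop2_extension >= 0,
            nchar(signal_start) == 3L, length(core_length_range) == 2L)
  if (core_length_range[1] < 40 || core_length_range[2] > 120 ||
      core_length_range[1] > core_length_range[2]) {
    stop("core_length_range must be an increasing pair within [40, 120]")
  }
  total_cys <- length(cys_slots) + extra_cys_in_loop2
  if (disulfide_complete && total_cys %% 2L != 0L) {
    stop("odd total cysteine count (", total_cys,
         ") in a disulfide-complete spec for group '", name, "'")
  }
  structure(list(
    name = name, n_genes = as.integer(n_genes), cys_slots = cys_slots,
    extra_cys_in_loop2 = as.integer(extra_cys_in_loop2),
    loop2_extension = as.integer(loop2_extension),
    has_mad_tail = isTRUE(has_mad_tail), signal_start = signal_start,
    core_length_range = as.integer(core_length_range),
    disulfide_complete = isTRUE(disulfide_complete)
  ), class = "ly6_group_spec")
}

#' Default seven-group family emulating the LY6/3FTX cluster
#'
#' Anchored LY6 (the majority, mirroring the observation that most LY6 carry
#' a C-terminal membrane-anchoring tail), secreted LY6 (SLURP-like), a
#' pre-3FTX-like reptilian group (MaD-bearing, signal starting MK but not
#' MKT), and the four toxin categories: plesiotypic (ancestral 10-cysteine
#' arrangement), short-chain (8 cysteines, slots 2-3 lost), long-chain (10
#' ancestral plus a novel loop-II pair and an extended loop), and
#' non-standard (here: 9 occupied slots).
#'
#' @param n_per_group optional integer (length 1 or 7) overriding member
#'   counts; the default mix is anchored-heavy (12/2/2/3/3/3/3).
#' @return list of [group_spec()] objects
#' @export
default_groups <- function(n_per_group = NULL) {
  n <- c(12L, 2L, 2L, 3L, 3L, 3L, 3L)
  if (!is.null(n_per_group)) n <- rep_len(as.integer(n_per_group), 7L)
  list(
    group_spec("ly6_anchored", n[1], 1:10, has_mad_tail = TRUE,
               signal_start = "MKL"),
    group_spec("ly6_secreted", n[2], 1:10, signal_start = "MKL"),
    group_spec("pre3ftx", n[3], 1:10, has_mad_tail = TRUE,
               signal_start = "MKS"),
    group_spec("plesiotypic", n[4], 1:10),
    group_spec("short_chain", n[5], setdiff(1:10, LOST_SLOT_PAIR)),
    group_spec("long_chain", n[6], 1:10, extra_cys_in_loop2 = 2L,
               loop2_extension = 6L),
    group_spec("non_standard", n[7], setdiff(1:10, 2L),
               disulfide_complete = FALSE)
  )
}

truth_class_of_spec <- function(spec, e_min = 4L) {
  ns <- length(spec$cys_slots)
  if (ns == 10L && spec$extra_cys_in_loop2 == 0L &&
      spec$loop2_extension < e_min) return("plesiotypic")
  if (identical(spec$cys_slots, sort(setdiff(1:10, LOST_SLOT_PAIR))) &&
      spec$extra_cys_in_loop2 == 0L) return("short_chain")
  if (ns >= 8L && spec$extra_cys_in_loop2 == 2L &&
      spec$loop2_extension >= e_min) return("long_chain")
  "non_standard"
}

random_aa <- function(n, exclude_cys = TRUE) {
  pool <- if (exclude_cys) setdiff(AA20, "C") else AA20
  sample(pool, n, replace = TRUE)
}

build_signal <- function(start3, len) {
  h <- sample(HYDROPHOBIC_AA, len - 6L, replace = TRUE)
  paste0(start3, paste(h, collapse = ""), "SNA")
}

# One group consensus mature core in template coordinates: the reference
# core point-substituted at `divergence` (paralogous lineages share the
# fold scaffold, so consensuses stay alignable to the reference), with
# unoccupied slots mutated C->S, extra loop-II cysteines recruited, and the
# loop-II extension inserted.
build_consensus_core <- function(spec, divergence = 0.30) {
  core <- strsplit(mutate_peptide(LU_REFERENCE_CORE, divergence), "",
                   fixed = TRUE)[[1]]
  slots <- LU_SLOT_POSITIONS
  core[slots] <- "S"
  core[slots[spec$cys_slots]] <- "C"
  if (spec$extra_cys_in_loop2 > 0L) {
    core[LOOP2_EXTRA_CYS_AT[seq_len(spec$extra_cys_in_loop2)]] <- "C"
  }
  if (spec$loop2_extension > 0L) {
    ins <- random_aa(spec$loop2_extension)
    core <- append(core, ins, after = LOOP2_INSERT_AT)
  }
  paste(core, collapse = "")
}

#' Generate a synthetic protein family with full ground truth
#'
#' Each group draws one consensus mature core from the canonical cysteine
#' slot template; members are point-substituted copies of it (cysteines and
#' exon-boundary-defining geometry are preserved), prefixed with a signal
#' peptide of 18-24 residues starting with the group's tripeptide, padded
#' with a short C-terminal stub and, for anchored groups, a hydrophobic
#' membrane-anchoring tail of 14-20 residues (mean Kyte-Doolittle hydropathy
#' >= 1.0 by construction).  A single-copy marker gene protein (orthogroup
#' \code{TOP1MT}) is always appended.  Deterministic for a given seed.
#'
#' @param groups list of [group_spec()] objects
#' @param seed integer seed
#' @param within_divergence per-residue substitution rate between a group's
#'   consensus and each member (models within-group paralog divergence)
#' @param consensus_divergence substitution rate between the canonical
#'   reference core and each group's consensus (models the ancient
#'   divergence between paralogous lineages while keeping them alignable)
#' @return data.frame with one row per protein: id, group, orthogroup,
#'   sequence, signal_length, mature, exon2_end (mature residues in exon 2),
#'   tail_length, mad_truth, class_truth, secretion_truth, loop2_extension,
#'   n_extra_cys, cys_slots
#' @export
generate_protein_family <- function(groups, seed, within_divergence = 0.08,
                                    consensus_divergence = 0.30) {
  if (inherits(groups, "ly6_group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "ly6_group_spec")))
  set.seed(as.integer(seed))
  rows <- list()
  for (spec in groups) {
    if (spec$n_genes == 0L) next
    consensus <- build_consensus_core(spec, consensus_divergence)
    # mature position of the exon-2/3 boundary slot (loop-II extension
    # precedes it and shifts it)
    b2 <- LU_SLOT_POSITIONS[EXON23_BOUNDARY_SLOT] + spec$loop2_extension
    for (i in seq_len(spec$n_genes)) {
      core <- mutate_peptide(consensus, within_divergence)
      stub_n <- sample(seq(spec$core_length_range[1],
                           spec$core_length_range[2]), 1L) - 64L
      stub <- if (stub_n > 0L) paste(random_aa(stub_n), collapse = "") else ""
      tail <- ""
      if (spec$has_mad_tail) {
        tail <- paste(sample(HYDROPHOBIC_AA, sample(14:20, 1L),
                             replace = TRUE), collapse = "")
      }
      sig_len <- sample(18:24, 1L)
      signal <- build_signal(spec$signal_start, sig_len)
      mature <- paste0(core, stub, tail)
      id <- sprintf("%s_g%02d", spec$name, i)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, group = spec$name, orthogroup = id,
        sequence = paste0(signal, mature),
        signal_length = sig_len, mature = mature,
        exon2_end = b2,
        tail_length = nchar(stub) + nchar(tail),
        mad_truth = spec$has_mad_tail,
        class_truth = truth_class_of_spec(spec),
        secretion_truth = if (spec$has_mad_tail) "anchored" else "secreted",
        loop2_extension = spec$loop2_extension,
        n_extra_cys = spec$extra_cys_in_loop2,
        cys_slots = paste(spec$cys_slots, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  fam <- do.call(rbind, rows)
  marker_seq <- paste(sample(AA20, 105L, replace = TRUE), collapse = "")
  marker <- data.frame(
    id = "TOP1MT", group = "marker", orthogroup = "TOP1MT",
    sequence = marker_seq, signal_length = 0L, mature = marker_seq,
    exon2_end = 70L, tail_length = 0L, mad_truth = FALSE,
    class_truth = NA_character_, secretion_truth = NA_character_,
    loop2_extension = 0L, n_extra_cys = 0L, cys_slots = "",
    stringsAsFactors = FALSE
  )
  out <- rbind(fam, marker)
  rownames(out) <- NULL
  out
}

# Point-substitute a mature core: cysteines are invariant, substitutions
# never create a cysteine (so the framework truth stays exact).
mutate_peptide <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  can <- which(aa != "C")
  hit <- can[stats::runif(length(can)) < rate]
  if (length(hit)) {
    aa[hit] <- vapply(aa[hit], function(old) {
      sample(setdiff(AA20, c("C", old)), 1L)
    }, "")
  }
  paste(aa, collapse = "")
}

#' Derive a diverged species variant of a protein family
#'
#' Fixed-rate point substitution of each protein, preserving cysteines, the
#' signal-peptide start tripeptide and cleavage region (positions mutated
#' within the signal's hydrophobic stretch stay hydrophobic), and the
#' exon-boundary geometry.  Models orthologous divergence between the query
#' panel species and a surveyed genome; no indels.
#'
#' @param family output of [generate_protein_family()]
#' @param rate per-residue substitution probability
#' @param seed integer seed
#' @return the family data.frame with substituted sequences
#' @export
mutate_proteins <- function(family, rate, seed) {
  set.seed(as.integer(seed))
  for (r in seq_len(nrow(family))) {
    sl <- family$signal_length[r]
    full <- family$sequence[r]
    if (sl > 0L) {
      sig <- strsplit(substr(full, 1L, sl), "", fixed = TRUE)[[1]]
      hpos <- seq(4L, sl - 3L)
      hit <- hpos[stats::runif(length(hpos)) < rate]
      if (length(hit)) {
        sig[hit] <- vapply(sig[hit], function(old) {
          sample(setdiff(HYDROPHOBIC_AA, old), 1L)
        }, "")
      }
      mat <- mutate_peptide(substr(full, sl + 1L, nchar(full)), rate)
      family$sequence[r] <- paste0(paste(sig, collapse = ""), mat)
      family$mature[r] <- mat
    } else {
      family$sequence[r] <- mutate_peptide(full, rate)
      family$mature[r] <- family$sequence[r]
    }
  }
  family
}

#' Back-translate a peptide with the fixed codon table
#'
#' @param peptide amino-acid string
#' @return DNA string (no terminator)
#' @export
back_translate <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(HUMAN_CODON))
  if (length(bad)) stop("cannot back-translate residue: ", bad[1])
  paste(HUMAN_CODON[aa], collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_intron <- function(range) {
  len <- sample(seq(range[1], range[2]), 1L)
  paste0("GT", random_dna(len - 4L), "AG")
}

# Build one gene's DNA and local (gene-forward, 0-based half-open) exon table
# from a protein truth row.  Exon 1 = signal peptide, exon 2 = mature core up
# to the slot-8 boundary, exon 3 = C-terminal segment (incl. stub and tail);
# a TAA terminator follows exon 3 outside the exon.  The marker gene is split
# into three equal-length exons.
build_gene_dna <- function(prow, intron_range, dup3 = FALSE,
                           truncate_tail = FALSE) {
  full <- prow$sequence
  sl <- prow$signal_length
  if (prow$group == "marker") {
    n <- nchar(full)
    cut1 <- 35L; cut2 <- 70L
    peps <- c(substr(full, 1L, cut1), substr(full, cut1 + 1L, cut2),
              substr(full, cut2 + 1L, n))
  } else {
    mat <- prow$mature
    b2 <- prow$exon2_end
    e3_pep <- substr(mat, b2 + 1L, nchar(mat))
    if (truncate_tail) {
      drop <- prow$tail_length
      if (nchar(e3_pep) - drop < 4L) stop("tail truncation leaves exon 3 too short")
      vestige <- substr(e3_pep, nchar(e3_pep) - drop + 1L, nchar(e3_pep))
      e3_pep <- substr(e3_pep, 1L, nchar(e3_pep) - drop)
    }
    peps <- c(substr(full, 1L, sl), substr(mat, 1L, b2), e3_pep)
  }
  if (any(nchar(peps) < 4L)) stop("protein too short to split into exons")
  exon_dna <- vapply(peps, back_translate, "")
  roles <- c("E1", "E2", "E3")
  if (dup3) {
    dup <- pseudogenize_exon_dna(exon_dna[3])
    exon_dna <- c(exon_dna[1:2], E3dup = unname(dup), exon_dna[3])
    roles <- c("E1", "E2", "E3dup", "E3")
  }
  introns <- replicate(length(exon_dna) - 1L, random_intron(intron_range))
  pieces <- character(0)
  starts <- integer(0); ends <- integer(0)
  pos <- 0L
  for (k in seq_along(exon_dna)) {
    starts[k] <- pos
    pieces <- c(pieces, exon_dna[k])
    pos <- pos + nchar(exon_dna[k])
    ends[k] <- pos
    if (k < length(exon_dna)) {
      pieces <- c(pieces, introns[k])
      pos <- pos + nchar(introns[k])
    }
  }
  tail_dna <- "TAA"
  if (prow$group != "marker" && truncate_tail) {
    # vestigial tail DNA downstream of the new stop (the secreted-form
    # origin mechanism: a stop inserted before the membrane anchor)
    tail_dna <- paste0("TAA", back_translate(vestige))
  }
  list(dna = paste0(paste(pieces, collapse = ""), tail_dna),
       exons = data.frame(role = roles, start = starts, end = ends,
                          stringsAsFactors = FALSE))
}

# Replace one internal codon of an exon's DNA with TAA (never the first or
# last codon, keeping boundary detection well-posed).
pseudogenize_exon_dna <- function(dna) {
  ncod <- nchar(dna) %/% 3L
  codon <- sample(seq(2L, ncod - 1L), 1L)
  paste0(substr(dna, 1L, (codon - 1L) * 3L), "TAA",
         substr(dna, codon * 3L + 1L, nchar(dna)))
}

#' Introduce a pseudogenizing lesion into a gene model
#'
#' Exactly one lesion is placed at a uniformly drawn in-exon position, never
#' in the first or last codon of an exon: either an in-frame stop codon
#' (\code{mode = "stop"}) or a 1-bp deletion (\code{mode = "frameshift"}).
#'
#' @param gene list with \code{dna} and \code{exons} as returned by the
#'   genome builder (gene-local forward coordinates)
#' @param mode \code{"stop"} or \code{"frameshift"}
#' @param seed integer seed
#' @return the mutated gene list, with \code{status = "pseudogene"}
#' @export
pseudogenize <- function(gene, mode = c("stop", "frameshift"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(gene$exons) || nrow(gene$exons) == 0L) {
    stop("cannot pseudogenize a gene with no exons")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  coding <- which(gene$exons$role != "E3dup")
  k <- if (length(coding) > 1L) sample(coding, 1L) else coding
  ex <- gene$exons[k, ]
  ncod <- (ex$end - ex$start) %/% 3L
  codon <- if (ncod > 2L) sample(seq(2L, ncod - 1L), 1L) else stop("exon too short")
  pos <- ex$start + (codon - 1L) * 3L  # 0-based start of the lesion codon
  if (mode == "stop") {
    substr(gene$dna, pos + 1L, pos + 3L) <- "TAA"
  } else {
    gene$dna <- paste0(substr(gene$dna, 1L, pos),
                       substr(gene$dna, pos + 2L, nchar(gene$dna)))
    after <- gene$exons$start >= ex$end
    gene$exons$end[k] <- gene$exons$end[k] - 1L
    gene$exons$start[after] <- gene$exons$start[after] - 1L
    gene$exons$end[after] <- gene$exons$end[after] - 1L
  }
  gene$status <- "pseudogene"
  gene
}

#' Genome configuration for the synthetic cluster
#'
#' @param species_id label for the scaffold/species
#' @param n_pseudogenes genes to pseudogenize (drawn among non-marker genes)
#' @param n_orphan_exon_sets lone exon-2 copies to implant
#' @param n_dup3_genes genes given a duplicated pseudogenized exon-3 copy
#'   5' of the functional exon 3
#' @param dup3_truncation_mode if \code{TRUE}, the retained exon 3 of dup3
#'   genes encodes a premature stop before the membrane-anchoring tail
#'   (secreted-form origin mechanism); requires tail-bearing candidates
#' @param pseudogene_modes lesion mode(s) used for pseudogenes
#' @param marker_position where the single-copy marker gene sits relative to
#'   the cluster: \code{"flank5"} (upstream, the commonest arrangement),
#'   \code{"middle"}, or \code{"flank3"}
#' @param intron_length_range bp, min >= 20
#' @param intergenic_length_range bp
#' @param seed integer seed
#' @return a \code{ly6_genome_config} list
#' @export
genome_config <- function(species_id = "synthA", n_pseudogenes = 1L,
                          n_orphan_exon_sets = 1L, n_dup3_genes = 1L,
                          dup3_truncation_mode = FALSE,
                          pseudogene_modes = "stop",
                          marker_position = "flank5",
                          intron_length_range = c(80L, 300L),
                          intergenic_length_range = c(300L, 800L),
                          seed = 1L) {
  stopifnot(n_pseudogenes >= 0, n_orphan_exon_sets >= 0, n_dup3_genes >= 0,
            intron_length_range[1] >= 20L,
            all(pseudogene_modes %in% c("stop", "frameshift")),
            marker_position %in% c("flank5", "middle", "flank3"))
  structure(list(
    species_id = species_id, n_pseudogenes = as.integer(n_pseudogenes),
    n_orphan_exon_sets = as.integer(n_orphan_exon_sets),
    n_dup3_genes = as.integer(n_dup3_genes),
    dup3_truncation_mode = isTRUE(dup3_truncation_mode),
    pseudogene_modes = pseudogene_modes,
    marker_position = marker_position,
    intron_length_range = as.integer(intron_length_range),
    intergenic_length_range = as.integer(intergenic_length_range),
    seed = as.integer(seed)
  ), class = "ly6_genome_config")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Generate a synthetic genomic scaffold with ground truth
#'
#' Every supplied protein becomes one gene (reverse-translated with the fixed
#' codon table and split into 3 exons at the signal/core and core/C-terminus
#' boundaries; introns begin GT and end AG).  The marker gene is implanted
#' exactly once at the configured position; gene order follows the protein
#' table (conserved across species) while strands, intron and intergenic
#' lengths are drawn per seed.  Configured numbers of genes are
#' pseudogenized, given duplicated exon-3 copies, or accompanied by orphan
#' exons.  Truth coordinates are 0-based half-open on the scaffold's forward
#' strand.
#'
#' @param config [genome_config()] object
#' @param proteins protein truth table ([generate_protein_family()] layout);
#'   must contain exactly one marker row
#' @return list with \code{scaffold} (named character), \code{genes} and
#'   \code{exons} truth data.frames, and the updated \code{proteins} table
#'   (dup3-truncated genes get their truncated truth protein)
#' @export
generate_genome <- function(config, proteins) {
  stopifnot(inherits(config, "ly6_genome_config"))
  if (sum(proteins$group == "marker") != 1L) {
    stop("proteins must contain exactly one marker gene row")
  }
  set.seed(config$seed)
  n <- nrow(proteins)
  marker_idx <- which(proteins$group == "marker")
  nonmarker <- setdiff(seq_len(n), marker_idx)
  if (config$n_dup3_genes > 0L) {
    cand <- if (config$dup3_truncation_mode) {
      nonmarker[proteins$mad_truth[nonmarker]]
    } else nonmarker
    if (length(cand) < config$n_dup3_genes) {
      stop("not enough candidate genes for dup3 (truncation mode needs tails)")
    }
    dup3_idx <- sample(cand, config$n_dup3_genes)
  } else dup3_idx <- integer(0)
  pg_cand <- setdiff(nonmarker, dup3_idx)
  if (length(pg_cand) < config$n_pseudogenes) stop("not enough genes to pseudogenize")
  pg_idx <- if (config$n_pseudogenes > 0L) sample(pg_cand, config$n_pseudogenes) else integer(0)
  pg_mode <- sample(rep_len(config$pseudogene_modes, max(1L, config$n_pseudogenes)),
                    config$n_pseudogenes)

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- i %in% dup3_idx && config$dup3_truncation_mode
    g <- build_gene_dna(proteins[i, ], config$intron_length_range,
                        dup3 = i %in% dup3_idx, truncate_tail = tr)
    g$status <- "intact"
    g$gene_id <- paste0(config$species_id, "_", proteins$id[i])
    g$orthogroup <- proteins$orthogroup[i]
    g$group <- proteins$group[i]
    if (tr) {  # truth protein loses its tail
      drop <- proteins$tail_length[i]
      m <- proteins$mature[i]
      proteins$mature[i] <- substr(m, 1L, nchar(m) - drop)
      proteins$sequence[i] <- paste0(
        substr(proteins$sequence[i], 1L, proteins$signal_length[i]),
        proteins$mature[i])
      proteins$tail_length[i] <- 0L
      proteins$mad_truth[i] <- FALSE
      proteins$secretion_truth[i] <- "secreted"
    }
    genes[[i]] <- g
  }
  for (k in seq_along(pg_idx)) {
    genes[[pg_idx[k]]] <- pseudogenize(genes[[pg_idx[k]]], pg_mode[k])
  }

  # orphan exon sets: lone diverged exon-2 copies of random family genes
  orphans <- list()
  for (k in seq_len(config$n_orphan_exon_sets)) {
    src <- proteins[sample(nonmarker, 1L), ]
    pep <- mutate_peptide(substr(src$mature, 1L, src$exon2_end), 0.05)
    orphans[[k]] <- list(
      dna = back_translate(pep),
      exons = data.frame(role = "E2", start = 0L, end = nchar(pep) * 3L,
                         stringsAsFactors = FALSE),
      status = "orphan_exon_set",
      gene_id = sprintf("%s_ORPH%02d", config$species_id, k),
      orthogroup = src$orthogroup, group = "orphan")
  }

  # scaffold layout: gene order follows the protein table (the cluster's
  # gene order is conserved across species), orphans appended, marker
  # implanted at the configured position
  items <- c(genes[nonmarker], orphans)
  at <- switch(config$marker_position, flank5 = 0L,
               middle = length(items) %/% 2L, flank3 = length(items))
  items <- append(items, genes[marker_idx], after = at)

  scaffold_id <- paste0(config$species_id, "_scaf1")
  seq_parts <- random_dna(sample(seq(config$intergenic_length_range[1],
                                     config$intergenic_length_range[2]), 1L))
  pos <- nchar(seq_parts)
  gene_rows <- list(); exon_rows <- list()
  for (it in items) {
    strand <- sample(c("+", "-"), 1L)
    L <- nchar(it$dna)
    dna <- it$dna
    ex <- it$exons
    if (strand == "-") {
      dna <- revcomp(dna)
      new_start <- L - ex$end
      ex$end <- L - ex$start
      ex$start <- new_start
      ex <- ex[order(ex$start), , drop = FALSE]
    }
    ex$start <- ex$start + pos
    ex$end <- ex$end + pos
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = it$gene_id, scaffold_id = scaffold_id, strand = strand,
      status = it$status, orthogroup = it$orthogroup, group = it$group,
      start = pos, end = pos + L, n_exons = nrow(ex),
      stringsAsFactors = FALSE)
    ex$gene_id <- it$gene_id
    ex$strand <- strand
    ex$status <- it$status
    exon_rows[[length(exon_rows) + 1L]] <- ex
    seq_parts <- paste0(seq_parts, dna,
                        random_dna(sample(seq(config$intergenic_length_range[1],
                                              config$intergenic_length_range[2]), 1L)))
    pos <- nchar(seq_parts)
  }
  scaffold <- c(seq_parts)
  names(scaffold) <- scaffold_id
  list(scaffold = scaffold,
       genes = do.call(rbind, gene_rows),
       exons = do.call(rbind, exon_rows)[, c("gene_id", "role", "start",
                                             "end", "strand", "status")],
       proteins = proteins,
       config = config)
}

#' Splice and translate a truth gene from the scaffold
#'
#' Concatenates the gene's exons (excluding any E3dup copy) in gene
#' orientation and translates them; for an intact gene this reproduces the
#' source protein exactly.
#'
#' @param genome output of [generate_genome()]
#' @param gene_id truth gene id
#' @return amino-acid string
#' @export
splice_translate_truth <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id &
                       genome$exons$role != "E3dup", , drop = FALSE]
  if (!nrow(ex)) stop("unknown gene id: ", gene_id)
  scaf <- genome$scaffold[[1]]
  strand <- ex$strand[1]
  ex <- ex[order(ex$start), , drop = FALSE]
  seqs <- substring(scaf, ex$start + 1L, ex$end)
  cds <- paste(seqs, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  translate_dna(cds)
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

#' Exon-peptide query panel from a protein family
#'
#' Splits each family protein at its exon boundaries and returns the exon
#' peptides, named \code{"<gene>:<role>"}, for use as translated-search
#' queries.
#'
#' @param family protein truth table
#' @return named character vector of peptides
#' @export
exon_query_panel <- function(family) {
  out <- character(0)
  for (i in seq_len(nrow(family))) {
    p <- family[i, ]
    if (p$group == "marker") {
      n <- nchar(p$sequence)
      peps <- c(substr(p$sequence, 1L, 35L), substr(p$sequence, 36L, 70L),
                substr(p$sequence, 71L, n))
    } else {
      peps <- c(substr(p$sequence, 1L, p$signal_length),
                substr(p$mature, 1L, p$exon2_end),
                substr(p$mature, p$exon2_end + 1L, nchar(p$mature)))
    }
    names(peps) <- paste0(p$id, ":", c("E1", "E2", "E3"))
    out <- c(out, peps)
  }
  out
}

#' Export a synthetic genome to disk
#'
#' Writes the scaffold FASTA, a GFF3 of truth genes/exons (1-based inclusive
#' on file; attributes \code{role}, \code{status}, \code{orthogroup}), the
#' protein truth TSV, and a key=value sidecar echoing the configuration.
#'
#' @param genome output of [generate_genome()]
#' @param dir output directory (created if needed)
#' @return named character vector of the paths written
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "scaffold.fasta"),
    gff = file.path(dir, "truth.gff3"),
    proteins = file.path(dir, "proteins.tsv"),
    config = file.path(dir, "config.txt")
  )
  write_fasta(genome$scaffold, paths["fasta"])
  write_gff3(truth_to_gff(genome), paths["gff"])
  utils::write.table(genome$proteins, paths["proteins"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- genome$config
  keys <- vapply(cfg, function(v) paste(v, collapse = ","), "")
  writeLines(paste0(names(cfg), "=", keys), paths["config"])
  paths
}

truth_to_gff <- function(genome) {
  g <- genome$genes
  e <- genome$exons
  scaffold_id <- names(genome$scaffold)[1]
  gene_df <- data.frame(
    scaffold_id = scaffold_id, feature_type = "gene",
    start = g$start, end = g$end, strand = g$strand,
    ID = g$gene_id, status = g$status, orthogroup = g$orthogroup,
    stringsAsFactors = FALSE)
  exon_df <- data.frame(
    scaffold_id = scaffold_id, feature_type = "exon",
    start = e$start, end = e$end, strand = e$strand,
    ID = paste0(e$gene_id, ".", e$role), status = e$status,
    orthogroup = NA_character_, stringsAsFactors = FALSE)
  exon_df$Parent <- e$gene_id
  gene_df$Parent <- NA_character_
  exon_df$role <- e$role
  gene_df$role <- NA_character_
  rbind(gene_df, exon_df)
}
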