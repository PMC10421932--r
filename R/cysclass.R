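# Cysteine-framework extraction and four-category classification of mature
# three-finger-fold proteins, plus detection of the C-terminal
# membrane-anchoring tail (MaD).  External signal-peptide and
# membrane-topology predictors are replaced by transparent heuristics with
# exposed thresholds; user-supplied annotations always take precedence.

#' Remove the signal peptide from a protein
#'
#' With an annotation, cleavage happens exactly there.  Without one, a
#' heuristic is used: the signal's hydrophobic core is taken as the first
#' run of at least 6 consecutive residues with Kyte-Doolittle hydropathy
#' >= 1.5 starting within the first 8 positions; cleavage is placed 3
#' residues (the short polar c-region) after that run ends.  If the
#' resulting site falls outside positions 15-30 the sequence is returned
#' uncleaved with a warning flag.
#'
#' @param sequence amino-acid string
#' @param annotation optional cleavage site: number of signal residues
#'   (the mature sequence starts at position \code{annotation + 1})
#' @return list: \code{full_sequence}, \code{cleavage_site} (or \code{NA}),
#'   \code{mature_sequence}, \code{flagged}
#' @export
cleave_signal_peptide <- function(sequence, annotation = NULL) {
  n <- nchar(sequence)
  if (!is.null(annotation)) {
    if (annotation >= n) stop("cleavage annotation beyond sequence length")
    return(list(full_sequence = sequence, cleavage_site = as.integer(annotation),
                mature_sequence = substr(sequence, annotation + 1L, n),
                flagged = FALSE))
  }
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  kd <- KD_HYDROPATHY[aa]
  kd[is.na(kd)] <- 0
  hydro <- kd >= 1.5
  site <- NA_integer_
  run_start <- NA_integer_
  i <- 1L
  while (i <= min(8L, n)) {
    if (hydro[i] && (i == 1L || !hydro[i - 1L])) {
      j <- i
      while (j < n && hydro[j + 1L]) j <- j + 1L
      if (j - i + 1L >= 6L) { run_start <- i; site <- j + 3L; break }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.na(site) || site < 15L || site > 30L || site >= n) {
    return(list(full_sequence = sequence, cleavage_site = NA_integer_,
                mature_sequence = sequence, flagged = TRUE))
  }
  list(full_sequence = sequence, cleavage_site = site,
       mature_sequence = substr(sequence, site + 1L, n), flagged = FALSE)
}

#' Map a mature protein onto the canonical 10-cysteine-slot framework
#'
#' Globally aligns the mature sequence against the canonical three-finger
#' reference core (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5).
#' Each reference slot column with an aligned cysteine marks that slot
#' occupied at the aligned mature position; unslotted cysteines within the
#' core region become \code{extra_cys}.  Loop II is the region between
#' slots 4 and 5: its aligned mature length minus the reference loop length
#' (floor 0) is the loop-II extension.  Everything after the last occupied
#' slot (or after slot 10's reference column when slot 10 is unoccupied) is
#' the C-terminal tail.
#'
#' @param mature mature amino-acid string
#' @param reference reference core (default the built-in template)
#' @return list: \code{slot_occupancy} (logical 10), \code{slot_positions}
#'   (1-based mature positions, NA where unoccupied), \code{extra_cys}
#'   (positions), \code{loop2_extension}, \code{tail_length},
#'   \code{core_end} (last core position)
#' @export
map_cysteine_framework <- function(mature, reference = LU_REFERENCE_CORE) {
  stopifnot(nzchar(mature))
  sub <- blosum62_matrix()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(mature),
    subject = Biostrings::AAString(reference),
    substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ref <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pat)
  ref_pos <- cumsum(ref != "-")
  mat_pos <- cumsum(pat != "-")
  slot_cols <- match(LU_SLOT_POSITIONS, ref_pos)  # first column per ref pos
  occupancy <- logical(10L)
  positions <- rep(NA_integer_, 10L)
  for (s in 1:10) {
    col <- slot_cols[s]
    if (!is.na(col) && pat[col] == "C") {
      occupancy[s] <- TRUE
      positions[s] <- mat_pos[col]
    }
  }
  # core ends at the last occupied slot; if slot 10 is unoccupied, at the
  # mature residue aligned at (or last before) slot 10's reference column
  if (occupancy[10]) {
    core_end <- positions[10]
  } else {
    col10 <- slot_cols[10]
    core_end <- if (is.na(col10)) max(mat_pos) else mat_pos[col10]
  }
  if (any(occupancy)) core_end <- max(core_end, max(positions, na.rm = TRUE))
  mat_chars <- strsplit(mature, "")[[1]]
  cys_all <- which(mat_chars == "C")
  extra <- setdiff(cys_all[cys_all <= core_end], positions[occupancy])
  c4 <- slot_cols[4]; c5 <- slot_cols[5]
  loop_cols <- if (!is.na(c4) && !is.na(c5) && c5 > c4 + 1L)
    seq(c4 + 1L, c5 - 1L) else integer(0)
  loop_len <- sum(pat[loop_cols] != "-")
  ref_loop_len <- LU_SLOT_POSITIONS[5] - LU_SLOT_POSITIONS[4] - 1L
  list(slot_occupancy = occupancy,
       slot_positions = positions,
       extra_cys = extra,
       loop2_extension = max(0L, loop_len - ref_loop_len),
       tail_length = nchar(mature) - core_end,
       core_end = core_end)
}

#' Detect a membrane-anchoring C-terminal tail
#'
#' A protein is called anchored when its tail (the region after the last
#' occupied cysteine slot) is at least \code{l_min} residues long and has
#' mean Kyte-Doolittle hydropathy of at least \code{h_min}; otherwise it is
#' called secreted.
#'
#' @param framework output of [map_cysteine_framework()]
#' @param mature mature amino-acid string
#' @param l_min minimum tail length (residues)
#' @param h_min minimum mean tail hydropathy
#' @return \code{"anchored"} or \code{"secreted"}
#' @export
detect_mad <- function(framework, mature, l_min = 12L, h_min = 0.5) {
  tl <- framework$tail_length
  if (tl < l_min) return("secreted")
  tail <- substr(mature, nchar(mature) - tl + 1L, nchar(mature))
  h <- mean_hydropathy(tail)
  if (!is.na(h) && h >= h_min) "anchored" else "secreted"
}

#' Four-category scaffold classification
#'
#' Applied in rule order: (1) all 10 ancestral slots occupied, no extra
#' cysteines, loop-II extension below \code{e_min}: plesiotypic; (2)
#' exactly 8 slots occupied matching the derived-loss pattern (the lost
#' pair defaults to slots 2-3), no extras: short_chain; (3) at least 8
#' slots occupied with exactly 2 extra loop-II cysteines and loop-II
#' extension >= \code{e_min}: long_chain; (4) otherwise non_standard.
#'
#' @param framework output of [map_cysteine_framework()]
#' @param secretion output of [detect_mad()]
#' @param e_min loop-II extension threshold (residues)
#' @param lost_pair the slot pair lost in derived short-chain forms
#' @return list: \code{scaffold_class}, \code{secretion}, \code{evidence}
#' @export
classify_scaffold <- function(framework, secretion, e_min = 4L,
                              lost_pair = LOST_SLOT_PAIR) {
  occ <- framework$slot_occupancy
  nex <- length(framework$extra_cys)
  ext <- framework$loop2_extension
  if (all(occ) && nex == 0L && ext < e_min) {
    cls <- "plesiotypic"
    ev <- "all 10 ancestral slots, no extras, no loop extension"
  } else if (sum(occ) == 8L && all(!occ[lost_pair]) && nex == 0L) {
    cls <- "short_chain"
    ev <- sprintf("8 slots with derived loss of pair %s, no extras",
                  paste(lost_pair, collapse = "-"))
  } else if (sum(occ) >= 8L && nex == 2L && ext >= e_min) {
    cls <- "long_chain"
    ev <- sprintf("novel loop-II pair with %d-residue loop extension", ext)
  } else {
    cls <- "non_standard"
    ev <- sprintf("%d slots, %d extras, extension %d fit no standard category",
                  sum(occ), nex, ext)
  }
  list(scaffold_class = cls, secretion = secretion, evidence = ev)
}

#' Classify a set of proteins end to end
#'
#' Convenience pipeline: signal-peptide removal (annotations take
#' precedence), framework mapping, tail detection, classification.
#'
#' @param sequences named character vector of full protein sequences
#' @param cleavage_sites optional named integer vector of annotated sites
#' @param l_min,h_min,e_min thresholds (see [detect_mad()],
#'   [classify_scaffold()])
#' @return data.frame: id, class, secretion, occupancy (10-character mask),
#'   n_extra_cys, loop2_extension, tail_length, cleavage_site, flagged,
#'   evidence
#' @export
classify_proteins <- function(sequences, cleavage_sites = NULL,
                              l_min = 12L, h_min = 0.5, e_min = 4L) {
  stopifnot(!is.null(names(sequences)))
  rows <- lapply(names(sequences), function(id) {
    ann <- if (!is.null(cleavage_sites) && id %in% names(cleavage_sites))
      cleavage_sites[[id]] else NULL
    mp <- cleave_signal_peptide(sequences[[id]], ann)
    fw <- map_cysteine_framework(mp$mature_sequence)
    sec <- detect_mad(fw, mp$mature_sequence, l_min = l_min, h_min = h_min)
    call <- classify_scaffold(fw, sec, e_min = e_min)
    data.frame(id = id, class = call$scaffold_class, secretion = sec,
               occupancy = paste(as.integer(fw$slot_occupancy), collapse = ""),
               n_extra_cys = length(fw$extra_cys),
               loop2_extension = fw$loop2_extension,
               tail_length = fw$tail_length,
               cleavage_site = mp$cleavage_site, flagged = mp$flagged,
               evidence = call$evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
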