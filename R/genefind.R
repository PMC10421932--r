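# Exon-homology gene finding: translated local alignment of exon peptide
# queries against genomic scaffolds, chaining of hits into gene models,
# status calling, and marker-anchored synteny maps.  This re-expresses the
# two-round exon BLAST + manual assembly route as one algorithm: a
# seed-and-extend Smith-Waterman over all six frames, followed by a
# dynamic-programming chain over role-ordered, splice-consistent hits.

#' Search parameters for the translated exon search
#'
#' The e-value cutoffs of a BLAST-based search do not port directly to raw
#' Smith-Waterman scores; they are replaced by a per-column score floor on
#' the BLOSUM62 scale plus a minimum identity, both exposed here.
#'
#' @param gap_open,gap_extend affine gap penalties (a gap of length k costs
#'   \code{gap_open + k * gap_extend}); protein-BLAST defaults 11/1
#' @param min_normalized_score minimum alignment score per aligned column
#' @param min_identity minimum fraction of identical aligned columns
#' @param max_intron_bp maximum intron length bridged when chaining
#' @param min_intron_bp minimum intron length (shorter gaps cannot be introns)
#' @param intron_penalty_per_bp chaining cost per bridged intron base; makes
#'   compact gene models outscore chains that jump across neighbouring
#'   genes to collect extra exons
#' @param min_query_coverage minimum fraction of the query spanned by the
#'   local alignment; rejects short spurious matches (a lone cysteine pair
#'   scores 9 per column) that the per-column floor cannot catch
#' @param min_raw_score absolute score floor, the fixed-search-space analog
#'   of an e-value cutoff: low-complexity dust (hydrophobic signal-peptide
#'   queries matching random DNA) passes the per-column and identity floors
#'   but not this one
#' @param require_splice_motifs require GT...AG at chained intron boundaries
#'   (in gene orientation); switch off for degraded pseudogene loci
#' @param seed_kmer exact peptide word size for seeding
#' @return a \code{ly6_search_params} list
#' @export
search_params <- function(gap_open = 11, gap_extend = 1,
                          min_normalized_score = 1.0, min_identity = 0.35,
                          max_intron_bp = 10000L, min_intron_bp = 20L,
                          intron_penalty_per_bp = 0.1,
                          min_query_coverage = 0.6,
                          min_raw_score = 30,
                          require_splice_motifs = TRUE, seed_kmer = 4L) {
  stopifnot(gap_open > 0, gap_extend > 0, min_identity >= 0, min_identity <= 1,
            max_intron_bp > min_intron_bp, seed_kmer >= 2L,
            intron_penalty_per_bp >= 0,
            min_query_coverage >= 0, min_query_coverage <= 1)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 min_normalized_score = min_normalized_score,
                 min_identity = min_identity,
                 max_intron_bp = as.integer(max_intron_bp),
                 min_intron_bp = as.integer(min_intron_bp),
                 intron_penalty_per_bp = intron_penalty_per_bp,
                 min_query_coverage = min_query_coverage,
                 min_raw_score = min_raw_score,
                 require_splice_motifs = isTRUE(require_splice_motifs),
                 seed_kmer = as.integer(seed_kmer)),
            class = "ly6_search_params")
}

#' Six-frame translation with exact coordinate maps
#'
#' Translates frames +0/+1/+2 of the forward strand and -0/-1/-2 of the
#' reverse complement.  \code{N} translates to \code{X}; other non-DNA
#' characters are an error.  Each frame carries the arithmetic needed to map
#' a peptide interval back onto the forward strand of the scaffold, exactly.
#'
#' @param scaffold single (optionally named) DNA string
#' @return list of six frames, each \code{list(frame, strand, offset,
#'   peptide)}; use [frame_to_scaffold()] to map peptide intervals back.
#' @export
sixframe_translate <- function(scaffold) {
  dna <- toupper(scaffold[[1]])
  if (grepl("[^ACGTN]", dna)) {
    stop("non-DNA character in scaffold: ",
         regmatches(dna, regexpr("[^ACGTN]", dna)))
  }
  L <- nchar(dna)
  rc <- revcomp(dna)
  frames <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") dna else rc
    for (f in 0:2) {
      frames[[length(frames) + 1L]] <- list(
        frame = f, strand = strand, length = L,
        peptide = translate_dna(substr(src, f + 1L, L)))
    }
  }
  names(frames) <- c("+0", "+1", "+2", "-0", "-1", "-2")
  frames
}

#' Map a peptide interval of a translation frame onto the scaffold
#'
#' @param frame one element of [sixframe_translate()] output
#' @param pep_start,pep_end 0-based half-open interval in the frame peptide
#' @return integer c(start, end), 0-based half-open on the forward strand
#' @export
frame_to_scaffold <- function(frame, pep_start, pep_end) {
  a <- frame$frame + 3L * pep_start
  b <- frame$frame + 3L * pep_end
  if (frame$strand == "+") c(a, b) else c(frame$length - b, frame$length - a)
}

# 0-based integer encoding over the substitution-matrix alphabet;
# anything unknown maps to X (scored 0 against everything)
encode_aa <- function(pep, alphabet) {
  idx <- match(strsplit(pep, "", fixed = TRUE)[[1]], alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Best local alignment of two peptides (Smith-Waterman, affine gaps)
#'
#' Full dynamic programming with the Gotoh recurrences; a gap of length k
#' costs \code{gap_open + k * gap_extend}.  Ties on the optimal score are
#' broken towards the smallest query end, then smallest target end.  The
#' ambiguity residue \code{X} scores 0 against everything.
#'
#' @param query,target peptide strings
#' @param params [search_params()]
#' @return list with \code{score}, \code{q_start}/\code{q_end} and
#'   \code{t_start}/\code{t_end} (0-based half-open), \code{identity}
#'   (matches / aligned columns) and \code{n_cols}
#' @export
local_align_protein <- function(query, target, params = search_params()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence in local alignment")
  sub <- blosum62_matrix()
  alpha <- rownames(sub)
  res <- sw_align_cpp(encode_aa(query, alpha), encode_aa(target, alpha),
                      sub, params$gap_open, params$gap_extend)
  res$identity <- if (res$n_cols > 0) res$n_match / res$n_cols else 0
  res
}

# exact k-mer seed index of a frame peptide: named list kmer -> positions
kmer_index <- function(pep, k) {
  n <- nchar(pep)
  if (n < k) return(list())
  kmers <- substring(pep, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  split(seq_len(n - k + 1L), kmers)
}

#' Find exon-peptide hits on a scaffold
#'
#' Runs the translated search for every query in all six frames.  The
#' default path is seed-and-extend: exact \code{seed_kmer}-mer matches are
#' grouped into windows and full Smith-Waterman is run inside each window;
#' \code{exhaustive = TRUE} forces full dynamic programming over whole
#' frames (iteratively masking each reported alignment), for oracle testing.
#' Hits below \code{min_normalized_score} or \code{min_identity} are
#' dropped; overlapping hits for the same query collapse to the
#' best-scoring one.  Reported intervals are extended by any unaligned
#' query overhang (3 bp per residue), so a full-length exon match maps the
#' complete exon even when its terminal residues are diverged.
#'
#' @param scaffold named single DNA string
#' @param exon_queries named character vector of exon peptides; names encode
#'   \code{"<gene>:<role>"}
#' @param params [search_params()]
#' @param exhaustive force full-frame dynamic programming
#' @return data.frame of hits (one row each): query_id, gene, role,
#'   scaffold_id, strand, frame, start, end, score, norm_score, identity
#' @export
find_exon_hits <- function(scaffold, exon_queries, params = search_params(),
                           exhaustive = FALSE) {
  if (!length(exon_queries)) stop("empty query panel")
  scaffold_id <- if (!is.null(names(scaffold))) names(scaffold)[1] else "scaffold"
  frames <- sixframe_translate(scaffold)
  sub <- blosum62_matrix()
  alpha <- rownames(sub)
  hits <- list()
  for (fr in frames) {
    plen <- nchar(fr$peptide)
    if (plen < params$seed_kmer) next
    tgt_enc <- encode_aa(fr$peptide, alpha)
    idx <- if (!exhaustive) kmer_index(fr$peptide, params$seed_kmer) else NULL
    for (qi in seq_along(exon_queries)) {
      q <- exon_queries[[qi]]
      qlen <- nchar(q)
      windows <- if (exhaustive) {
        matrix(c(0L, plen), nrow = 1)
      } else {
        seed_windows(q, idx, qlen, plen, params$seed_kmer)
      }
      if (is.null(windows) || !nrow(windows)) next
      qenc <- encode_aa(q, alpha)
      for (w in seq_len(nrow(windows))) {
        ws <- windows[w, 1]; we <- windows[w, 2]
        tseg <- tgt_enc[(ws + 1L):we]
        # a window (or whole frame) may hold several gene copies: report
        # each by masking the previous alignment and re-running
        repeat {
          res <- sw_align_cpp(qenc, tseg, sub, params$gap_open, params$gap_extend)
          if (res$n_cols == 0) break
          norm <- res$score / res$n_cols
          idy <- res$n_match / res$n_cols
          cov <- (res$q_end - res$q_start) / qlen
          if (norm < params$min_normalized_score || idy < params$min_identity ||
              cov < params$min_query_coverage ||
              res$score < params$min_raw_score) break
          # extend by unaligned query overhang, clipped to the frame
          ps <- max(0L, ws + res$t_start - res$q_start)
          pe <- min(plen, ws + res$t_end + (qlen - res$q_end))
          iv <- frame_to_scaffold(fr, ps, pe)
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = names(exon_queries)[qi],
            scaffold_id = scaffold_id, strand = fr$strand, frame = fr$frame,
            start = iv[1], end = iv[2], score = res$score,
            norm_score = norm, identity = idy, stringsAsFactors = FALSE)
          tseg[(res$t_start + 1L):res$t_end] <- match("X", alpha) - 1L
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query_id = character(0), gene = character(0),
                      role = character(0), scaffold_id = character(0),
                      strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), norm_score = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  df$gene <- sub(":[^:]*$", "", df$query_id)
  df$role <- sub("^.*:", "", df$query_id)
  df <- df[, c("query_id", "gene", "role", "scaffold_id", "strand", "frame",
               "start", "end", "score", "norm_score", "identity")]
  collapse_query_hits(df)
}

# group seed matches into target windows (one candidate locus each)
seed_windows <- function(q, idx, qlen, plen, k) {
  qk <- substring(q, seq_len(max(0L, qlen - k + 1L)),
                  seq_len(max(0L, qlen - k + 1L)) + k - 1L)
  tpos <- sort(unique(unlist(idx[unique(qk)], use.names = FALSE)))
  if (!length(tpos)) return(NULL)
  gap <- qlen + 10L
  brk <- c(0L, which(diff(tpos) > gap), length(tpos))
  out <- matrix(0L, nrow = length(brk) - 1L, ncol = 2L)
  for (i in seq_len(length(brk) - 1L)) {
    grp <- tpos[(brk[i] + 1L):brk[i + 1L]]
    out[i, ] <- c(max(0L, min(grp) - qlen - 10L),
                  min(plen, max(grp) + qlen + 10L + k))
  }
  out
}

# per-query collapse: keep the best-scoring hit among scaffold-overlapping
# hits of the same query (ties: lowest coordinate, then query id is equal)
collapse_query_hits <- function(df) {
  keep <- logical(nrow(df))
  for (q in unique(df$query_id)) {
    rows <- which(df$query_id == q)
    ord <- rows[order(-df$score[rows], df$start[rows])]
    taken <- integer(0)
    for (r in ord) {
      ov <- any(df$start[r] < df$end[taken] & df$end[r] > df$start[taken])
      if (!ov) { keep[r] <- TRUE; taken <- c(taken, r) }
    }
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$start, out$query_id), , drop = FALSE]
}

ROLE_RANK <- c(E1 = 1L, E2 = 2L, E3 = 3L)

#' Chain exon hits into gene models
#'
#' Dynamic programming over compatible hit pairs: hits chain only if they
#' share a strand, respect exon order E1 < E2 < E3 in gene orientation,
#' are separated by a plausible intron (\code{min_intron_bp} to
#' \code{max_intron_bp}), and (if required) the intervening sequence starts
#' GT and ends AG in gene orientation.  Two exon-3 hits may chain once per
#' gene; the 5' copy is labelled \code{E3dup}.  Chains are extracted
#' greedily by total raw score; hits overlapping an extracted chain are
#' discarded; remaining single hits become \code{orphan_exon_set} models.
#'
#' @param hits data.frame from [find_exon_hits()] (one scaffold)
#' @param scaffold the scaffold searched (named single DNA string)
#' @param params [search_params()]
#' @return list of gene models; each \code{list(id, scaffold_id, strand,
#'   exons, status, orthogroup, cds, protein)} where \code{exons} is a
#'   data.frame (role, start, end) in forward coordinates
#' @export
chain_hits_to_genes <- function(hits, scaffold, params = search_params()) {
  models <- list()
  if (!nrow(hits)) return(models)
  dna <- toupper(scaffold[[1]])
  scaffold_id <- hits$scaffold_id[1]
  remaining <- hits
  repeat {
    if (!nrow(remaining)) break
    chain <- best_chain(remaining, dna, params)
    rows <- remaining[chain, , drop = FALSE]
    model <- build_model(rows, dna, scaffold_id,
                         sprintf("model_%03d", length(models) + 1L))
    models[[length(models) + 1L]] <- model
    ov <- rep(FALSE, nrow(remaining))
    for (k in seq_len(nrow(rows))) {
      ov <- ov | (remaining$start < rows$end[k] & remaining$end > rows$start[k])
    }
    remaining <- remaining[!ov, , drop = FALSE]
  }
  # deterministic order: by scaffold coordinate
  starts <- vapply(models, function(m) min(m$exons$start), 0)
  models <- models[order(starts)]
  for (k in seq_along(models)) models[[k]]$id <- sprintf("model_%03d", k)
  models
}

# highest-scoring chain among the remaining hits (indices into `remaining`);
# DP over hits sorted in gene orientation, with a dup-used state so that a
# second exon-3 may follow the first exactly once
best_chain <- function(remaining, dna, params) {
  best <- NULL
  best_score <- -Inf
  for (strand in c("+", "-")) {
    rows <- which(remaining$strand == strand)
    if (!length(rows)) next
    h <- remaining[rows, , drop = FALSE]
    ord <- if (strand == "+") order(h$start, h$query_id)
           else order(-h$start, h$query_id)
    h <- h[ord, , drop = FALSE]
    n <- nrow(h)
    rank <- ROLE_RANK[h$role]
    s0 <- h$score; s1 <- rep(-Inf, n)       # chain score, dup unused/used
    p0 <- integer(n); p1 <- integer(n)      # predecessor (0 = none)
    st <- integer(n)                         # predecessor state for s1
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        gap <- intron_gap(h, j, i, strand, dna, params, remaining)
        if (is.na(gap)) next
        add <- h$score[i] - params$intron_penalty_per_bp * gap
        if (rank[i] == rank[j] + 1L) {
          if (s0[j] + add > s0[i]) { s0[i] <- s0[j] + add; p0[i] <- j }
          if (s1[j] + add > s1[i]) { s1[i] <- s1[j] + add; p1[i] <- j; st[i] <- 1L }
        } else if (rank[i] == 3L && rank[j] == 3L) {
          if (s0[j] + add > s1[i]) { s1[i] <- s0[j] + add; p1[i] <- j; st[i] <- 0L }
        }
      }
    }
    for (i in seq_len(n)) {
      for (state in 0:1) {
        sc <- if (state == 0) s0[i] else s1[i]
        better <- sc > best_score + 1e-9
        tie <- !better && abs(sc - best_score) <= 1e-9 && !is.null(best) &&
          h$start[i] < best$tiebreak
        if (better || tie) {
          idx <- integer(0); cur <- i; curst <- state
          while (cur != 0L) {
            idx <- c(cur, idx)
            if (curst == 1L) { nxt <- p1[cur]; curst <- st[cur] }
            else nxt <- p0[cur]
            cur <- nxt
          }
          best_score <- sc
          best <- list(rows = rows[ord][idx], tiebreak = h$start[i])
        }
      }
    }
  }
  best$rows
}

# intron length between chained hits j -> i (gene orientation), or NA when
# the pair is not chainable.  A candidate intron that fully contains some
# other hit is rejected: exons are merged only when nothing chainable lies
# between them, which stops a chain from bridging across a neighbouring
# gene to collect one of its exons.
intron_gap <- function(h, j, i, strand, dna, params, all_hits = h) {
  if (strand == "+") {
    lo <- h$end[j]; hi <- h$start[i]
    gap <- hi - lo
    if (gap < params$min_intron_bp || gap > params$max_intron_bp) return(NA_integer_)
    if (params$require_splice_motifs) {
      don <- substr(dna, lo + 1L, lo + 2L)
      acc <- substr(dna, hi - 1L, hi)
      if (don != "GT" || acc != "AG") return(NA_integer_)
    }
  } else {
    lo <- h$end[i]; hi <- h$start[j]
    gap <- hi - lo
    if (gap < params$min_intron_bp || gap > params$max_intron_bp) return(NA_integer_)
    if (params$require_splice_motifs) {
      # gene-strand GT...AG reads CT...AC on the forward strand
      acc <- substr(dna, lo + 1L, lo + 2L)
      don <- substr(dna, hi - 1L, hi)
      if (acc != "CT" || don != "AC") return(NA_integer_)
    }
  }
  if (any(all_hits$start >= lo & all_hits$end <= hi)) return(NA_integer_)
  gap
}

build_model <- function(rows, dna, scaffold_id, id) {
  strand <- rows$strand[1]
  # gene orientation: rows arrive chained 5'->3' on the gene strand
  roles <- rows$role
  if (sum(roles == "E3") == 2L) roles[which(roles == "E3")[1]] <- "E3dup"
  ex <- data.frame(role = roles, start = rows$start, end = rows$end,
                   stringsAsFactors = FALSE)
  ex <- ex[order(ex$start), , drop = FALSE]
  orthogroup <- rows$gene[which.max(rows$score)]
  model <- list(id = id, scaffold_id = scaffold_id, strand = strand,
                exons = ex, orthogroup = orthogroup)
  model$status <- call_gene_status(model, stats::setNames(dna, scaffold_id))
  coding <- ex[ex$role != "E3dup", , drop = FALSE]
  cds <- paste(substring(dna, coding$start + 1L, coding$end), collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  model$cds <- cds
  model$protein <- translate_dna(cds)
  model
}

#' Call the status of a gene model
#'
#' Intact iff the spliced CDS (excluding any E3dup exon) translates without
#' an internal stop and its length is a multiple of 3; otherwise pseudogene.
#' Single-exon unchained models are orphan exon sets.
#'
#' @param model gene model list with \code{exons} and \code{strand}
#' @param scaffold named single DNA string
#' @return one of \code{"intact"}, \code{"pseudogene"},
#'   \code{"orphan_exon_set"}
#' @export
call_gene_status <- function(model, scaffold) {
  dna <- toupper(scaffold[[1]])
  ex <- model$exons
  if (!nrow(ex)) stop("model has no exons")
  if (any(ex$start < 0L) || any(ex$end > nchar(dna))) {
    stop("exon outside scaffold bounds in model ", model$id)
  }
  if (nrow(ex) == 1L) return("orphan_exon_set")
  coding <- ex[ex$role != "E3dup", , drop = FALSE]
  coding <- coding[order(coding$start), , drop = FALSE]
  cds <- paste(substring(dna, coding$start + 1L, coding$end), collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L) return("pseudogene")
  aa <- translate_dna(cds)
  if (grepl("*", aa, fixed = TRUE)) return("pseudogene")
  "intact"
}

#' Marker-anchored synteny map
#'
#' @param models list of gene models (one scaffold)
#' @param marker_orthogroup orthogroup id of the single-copy marker
#' @param species_id label
#' @return list with \code{species_id}, \code{scaffold_id}, \code{anchor_id}
#'   and \code{entries}: a data.frame (gene_id, orthogroup, orientation,
#'   start) ordered by scaffold coordinate, orientation +1/-1 relative to
#'   the marker strand
#' @export
build_synteny_map <- function(models, marker_orthogroup = "TOP1MT",
                              species_id = "species") {
  og <- vapply(models, `[[`, "", "orthogroup")
  anchor <- which(og == marker_orthogroup)
  if (length(anchor) == 0L) stop("marker ", marker_orthogroup, " absent")
  if (length(anchor) > 1L) stop("marker ", marker_orthogroup, " duplicated")
  starts <- vapply(models, function(m) min(m$exons$start), 0)
  strands <- vapply(models, `[[`, "", "strand")
  ord <- order(starts)
  anchor_strand <- strands[anchor]
  entries <- data.frame(
    gene_id = vapply(models, `[[`, "", "id")[ord],
    orthogroup = og[ord],
    orientation = ifelse(strands[ord] == anchor_strand, 1L, -1L),
    start = starts[ord],
    stringsAsFactors = FALSE)
  list(species_id = species_id,
       scaffold_id = models[[1]]$scaffold_id,
       anchor_id = vapply(models, `[[`, "", "id")[anchor],
       entries = entries)
}

#' Compare two synteny maps
#'
#' @param mapA,mapB outputs of [build_synteny_map()]
#' @return list with \code{shared} (count of shared orthogroups) and
#'   \code{tau} (Kendall rank correlation of their relative orders over the
#'   shared orthogroups, first occurrence per map)
#' @export
compare_synteny <- function(mapA, mapB) {
  a <- mapA$entries[!duplicated(mapA$entries$orthogroup), ]
  b <- mapB$entries[!duplicated(mapB$entries$orthogroup), ]
  shared <- intersect(a$orthogroup, b$orthogroup)
  if (length(shared) < 2L) {
    return(list(shared = length(shared), tau = NA_real_))
  }
  ra <- match(shared, a$orthogroup)
  rb <- match(shared, b$orthogroup)
  list(shared = length(shared),
       tau = unname(stats::cor(ra, rb, method = "kendall")))
}

#' Measure recovery of generator truth by the gene finder
#'
#' @param models list of gene models from [chain_hits_to_genes()]
#' @param genome output of [generate_genome()]
#' @return list: \code{exon_recovery} (fraction of truth exons whose exact
#'   interval was recovered), \code{status_accuracy} (fraction of truth
#'   genes whose best-overlapping model carries the truth status),
#'   \code{dup3_recall} (fraction of truth 4-exon genes whose model has an
#'   E3dup 5' of E3), and the per-category count table
#' @export
evaluate_recovery <- function(models, genome) {
  truth_ex <- genome$exons
  rec_ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(start = m$exons$start, end = m$exons$end,
               role = m$exons$role, stringsAsFactors = FALSE)
  }))
  hit <- logical(nrow(truth_ex))
  for (i in seq_len(nrow(truth_ex))) {
    hit[i] <- any(rec_ex$start == truth_ex$start[i] &
                    rec_ex$end == truth_ex$end[i])
  }
  exon_recovery <- mean(hit)

  genes <- genome$genes
  status_ok <- logical(nrow(genes))
  dup3_truth <- genes$gene_id[genes$n_exons == 4L]
  dup3_ok <- logical(length(dup3_truth))
  for (i in seq_len(nrow(genes))) {
    ovl <- vapply(models, function(m) {
      iv <- range(m$exons$start, m$exons$end)
      max(0, min(iv[2], genes$end[i]) - max(iv[1], genes$start[i]))
    }, 0)
    if (max(ovl) <= 0) next
    m <- models[[which.max(ovl)]]
    status_ok[i] <- identical(m$status, genes$status[i])
    if (genes$gene_id[i] %in% dup3_truth) {
      k <- match(genes$gene_id[i], dup3_truth)
      ex <- m$exons
      if ("E3dup" %in% ex$role && "E3" %in% ex$role) {
        ddup <- ex[ex$role == "E3dup", ]
        de3 <- ex[ex$role == "E3", ]
        dup3_ok[k] <- if (m$strand == "+") ddup$start < de3$start
                      else ddup$start > de3$start
      }
    }
  }
  list(exon_recovery = exon_recovery,
       status_accuracy = mean(status_ok),
       dup3_recall = if (length(dup3_truth)) mean(dup3_ok) else NA_real_,
       status_table = table(truth = genes$status,
                            recovered = vapply(seq_len(nrow(genes)), function(i) {
                              ovl <- vapply(models, function(m) {
                                iv <- range(m$exons$start, m$exons$end)
                                max(0, min(iv[2], genes$end[i]) - max(iv[1], genes$start[i]))
                              }, 0)
                              if (max(ovl) <= 0) "missed" else models[[which.max(ovl)]]$status
                            }, "")))
}

#' Export gene models as a GFF3-ready annotation table
#'
#' @param models list of gene models
#' @return data.frame in the [write_gff3()] layout
#' @export
models_to_gff <- function(models) {
  rows <- lapply(models, function(m) {
    gene <- data.frame(scaffold_id = m$scaffold_id, feature_type = "gene",
                       start = min(m$exons$start), end = max(m$exons$end),
                       strand = m$strand, ID = m$id, status = m$status,
                       orthogroup = m$orthogroup, role = NA_character_,
                       stringsAsFactors = FALSE)
    ex <- data.frame(scaffold_id = m$scaffold_id, feature_type = "exon",
                     start = m$exons$start, end = m$exons$end,
                     strand = m$strand, ID = paste0(m$id, ".", m$exons$role),
                     status = m$status, orthogroup = NA_character_,
                     role = m$exons$role, stringsAsFactors = FALSE)
    rbind(gene, ex)
  })
  do.call(rbind, rows)
}
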