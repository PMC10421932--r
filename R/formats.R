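# Readers/writers for the standard formats the pipeline touches.  All
# in-memory coordinates are 0-based half-open; only the file boundary
# converts (GFF3 is 1-based inclusive on disk).

#' Read a FASTA file
#'
#' @param path file path
#' @return a named character vector of sequences; names are record ids,
#'   descriptions (text after the first whitespace) in the
#'   \code{"description"} attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record: ", ids[!nzchar(seqs)][1])
  }
  if (any(!nzchar(ids))) stop("malformed FASTA header: empty id")
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param records named character vector (names become ids); an optional
#'   \code{"description"} attribute is appended to headers.
#' @param path output path
#' @param width line-wrap width
#' @return \code{path}, invisibly
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.character(records), !is.null(names(records)))
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA id: ", names(records)[duplicated(names(records))][1])
  }
  if (any(!nzchar(records))) {
    stop("empty sequence for record: ", names(records)[!nzchar(records)][1])
  }
  desc <- attr(records, "description")
  headers <- names(records)
  if (!is.null(desc)) {
    has <- nzchar(desc)
    headers[has] <- paste(headers[has], desc[has])
  }
  set <- Biostrings::BStringSet(unname(records))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Coordinates are converted from the file's 1-based inclusive convention to
#' 0-based half-open.
#'
#' @param path file path
#' @return data.frame with columns \code{scaffold_id}, \code{source},
#'   \code{feature_type}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand}, and one column per attribute key.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("unknown strand symbol for feature at row ", which(strand == "*")[1])
  }
  df <- data.frame(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(S4Vectors::mcols(gr)$source),
    feature_type = as.character(S4Vectors::mcols(gr)$type),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) stop("empty interval after conversion")
  extra <- S4Vectors::mcols(gr)
  keep <- setdiff(colnames(extra), c("source", "type", "score", "phase"))
  for (k in keep) df[[k]] <- as.character(extra[[k]])
  df
}

#' Write annotations to GFF3
#'
#' @param annotations data.frame in the layout produced by [read_gff3()];
#'   any columns beyond the fixed seven become GFF3 attributes.
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_gff3 <- function(annotations, path) {
  req <- c("scaffold_id", "feature_type", "start", "end", "strand")
  if (!all(req %in% names(annotations))) {
    stop("missing columns: ", paste(setdiff(req, names(annotations)), collapse = ", "))
  }
  if (any(annotations$end <= annotations$start)) {
    stop("end <= start for feature at row ",
         which(annotations$end <= annotations$start)[1])
  }
  if (!all(annotations$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         annotations$strand[!annotations$strand %in% c("+", "-")][1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$scaffold_id,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand
  )
  S4Vectors::mcols(gr)$source <-
    if ("source" %in% names(annotations)) annotations$source else "ly6tools"
  S4Vectors::mcols(gr)$type <- annotations$feature_type
  attr_cols <- setdiff(names(annotations),
                       c(req, "source"))
  for (k in attr_cols) S4Vectors::mcols(gr)[[k]] <- annotations[[k]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} that validate leaf-label uniqueness.
#'
#' @param path file path
#' @return [read_newick()]: an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  tree
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo} object
#' @return [write_newick()]: \code{path}, invisibly
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read labeled per-protein feature vectors
#'
#' Reads a TSV/CSV of one labeled row per protein (first column = id, the
#' rest numeric of constant dimension).
#'
#' @param path file path
#' @param sep field separator; default tab
#' @return numeric matrix with protein ids as rownames; row order follows
#'   the file.
#' @export
read_vectors <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty vector file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  first <- parts[[1]]
  header <- is.na(suppressWarnings(as.numeric(first[2])))
  if (header) { parts <- parts[-1]; widths <- widths[-1] }
  if (!length(parts)) stop("vector file has no data rows: ", path)
  if (length(unique(widths)) != 1L) {
    stop("ragged vector rows: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ", widths[1])
  }
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(widths[1] - 1L)))
  if (anyNA(vals)) stop("non-numeric value in vector file: ", path)
  rownames(vals) <- ids
  vals
}

#' Write labeled feature vectors as TSV
#'
#' @param vectors numeric matrix with rownames
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (is.null(colnames(vectors))) {
    colnames(vectors) <- paste0("V", seq_len(ncol(vectors)))
  }
  df <- data.frame(id = rownames(vectors), vectors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
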