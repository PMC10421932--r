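#' @useDynLib ly6tools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Kyte-Doolittle hydropathy scale (kcal-free index, standard values)
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

AA20 <- names(KD_HYDROPATHY)

# Fixed back-translation table: the most frequent human codon per amino acid.
# Any fixed table works; fixing one makes generated genomes reproducible.
HUMAN_CODON <- c(
  A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
  Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
  L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG"
)

# Canonical mature three-finger (LU domain) core used as the cysteine-slot
# reference: 64 residues, 10 cysteines in the family-wide arrangement.
# Slot positions (1-based) are a fixed template modeled on mature LY6 cores
# of 60-74 residues; loop II is the region between slot 4 and slot 5.
LU_REFERENCE_CORE <- "LECYTDCKNGFDTSVCPAGQNVCFKRWHYTSENCADTIKCLGKSANVYCSGTDRPCVRCTEGKC"
LU_SLOT_POSITIONS <- c(3L, 7L, 16L, 23L, 34L, 40L, 49L, 56L, 59L, 64L)

# The cysteine pair lost in derived short-chain three-finger toxins.
# The reference figures show the lost bond graphically; its identity is fixed
# here as slots 2-3 of the template and exposed as a parameter downstream.
LOST_SLOT_PAIR <- c(2L, 3L)

#' BLOSUM62 substitution matrix with neutral ambiguity scoring
#'
#' Returns the standard BLOSUM62 matrix (from \pkg{Biostrings}) with the
#' ambiguity code \code{X} rescored to 0 against every residue, so unknown
#' translations neither reward nor penalise an alignment.
#'
#' @return An integer matrix over the amino-acid alphabet including
#'   \code{X} and \code{*}.
#' @export
blosum62_matrix <- function() {
  mat <- get_blosum62()
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Mean Kyte-Doolittle hydropathy of a peptide
#'
#' Non-standard residues are ignored; an empty (or all non-standard) peptide
#' yields \code{NA}.
#'
#' @param peptide single amino-acid string
#' @return numeric scalar
#' @export
mean_hydropathy <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  vals <- KD_HYDROPATHY[aa]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
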