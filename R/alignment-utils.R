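# Shared scoring machinery: BLOSUM62 with the X intron marker neutralized,
# Karlin-Altschul significance for raw local-alignment scores, and a thin
# wrapper around Biostrings' Smith-Waterman.

.pkg_cache <- new.env(parent = emptyenv())

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues; \code{X} is reserved as the intron position
#' marker and scores zero against every letter (including itself).
#'
#' @return Character vector of the 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Robinson-Robinson background residue frequencies, the set BLOSUM-style
# scoring matrices are calibrated against; used by the simulator's
# substitution draw.
aa_background <- function() {
  f <- c(A = 0.0785, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
         Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
         L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
         S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)
  f / sum(f)
}

#' BLOSUM62 substitution matrix with a neutral X marker
#'
#' Returns the standard BLOSUM62 matrix with the row and column for \code{X}
#' set to zero, so intron markers neither attract nor repel alignments:
#' coincident introns co-align because their flanking residues do.
#'
#' @return Integer matrix with residue row/column names.
#' @export
blosum62x <- function() {
  if (is.null(.pkg_cache$blosum62x)) {
    m <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .pkg_cache$blosum62x <- m
  }
  .pkg_cache$blosum62x
}

#' Karlin-Altschul significance of a raw local alignment score
#'
#' Computes \code{E = K * m * n * exp(-lambda * S)} from the raw
#' Smith-Waterman score \code{S} and the two sequence lengths.  The default
#' constants are the ungapped BLOSUM62 values; the quantity is a ranking and
#' threshold device emulating a BLASTP E-value, not a calibrated statistic.
#'
#' @param score Raw local alignment score.
#' @param m,n Lengths of the two sequences.
#' @param lambda,K Karlin-Altschul constants.
#' @return Numeric E-value-like significance (>= 0).
#' @export
alignment_significance <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  stopifnot(m > 0, n > 0)
  K * m * n * exp(-lambda * score)
}

#' Bit score of a raw local alignment score
#'
#' @inheritParams alignment_significance
#' @return Bit score \code{(lambda * S - ln K) / ln 2}.
#' @export
alignment_bits <- function(score, lambda = 0.3176, K = 0.134) {
  (lambda * score - log(K)) / log(2)
}

# Smith-Waterman local alignment of two protein strings under blosum62x with
# BLAST-style affine gaps (open 11, extend 1: a gap of length k costs 11 + k).
# Returns raw score, bits, significance and the 0-based half-open aligned
# intervals on query and subject.
local_align <- function(query, subject, gap_open = 11, gap_extend = 1,
                        lambda = 0.3176, K = 0.134) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("local_align: sequences must be nonempty")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62x(),
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(pa)
  list(
    score = s,
    bits = alignment_bits(s, lambda, K),
    significance = alignment_significance(s, nchar(query), nchar(subject),
                                          lambda, K),
    qstart = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    qend = Biostrings::end(Biostrings::pattern(pa)),
    sstart = Biostrings::start(Biostrings::subject(pa)) - 1L,
    send = Biostrings::end(Biostrings::subject(pa))
  )
}

# reverse-complement for plain character DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a DNA string (no stop handling; '*' retained); N-containing or
# otherwise fuzzy codons become X
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}
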