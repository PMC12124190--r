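# Progressive multiple alignment of X-marked proteins and derivation of the
# per-species intron presence/absence matrix from aligned X columns.
#
# The aligner is a standard guide-tree progressive scheme: pairwise
# distances are 1 - fractional identity from global pairwise alignments,
# the guide tree is average-linkage clustering on those distances, and
# profiles are merged with an affine-gap profile-profile DP (BLOSUM62,
# gap open 11 / extend 1, X scoring zero against everything).  Everything is
# deterministic for a fixed input order.  Externally produced alignments
# (e.g. MUSCLE output) can be attached with import_alignment().

.aln_codes <- function() c(aa_alphabet(), "X", "-")

# 22x22 numeric score matrix over codes (X and gap rows/cols are zero)
.aln_score_matrix <- function() {
  if (is.null(.pkg_cache$aln_score_matrix)) {
    codes <- .aln_codes()
    m <- matrix(0, 22L, 22L, dimnames = list(codes, codes))
    b <- blosum62x()
    aa <- aa_alphabet()
    m[aa, aa] <- b[aa, aa]
    .pkg_cache$aln_score_matrix <- m
  }
  .pkg_cache$aln_score_matrix
}

.encode_seq <- function(s) {
  codes <- .aln_codes()
  i <- match(strsplit(s, "", fixed = TRUE)[[1]], codes) - 1L
  if (anyNA(i)) stop("alignment: sequence contains letters outside ",
                     "the 20-residue alphabet plus X")
  i
}

.decode_row <- function(v) paste(.aln_codes()[v + 1L], collapse = "")

# merge two alignments (matrices of codes, rows = sequences) with the
# compiled profile aligner; returns the merged matrix
.merge_profiles <- function(A, B, gap_open = 11, gap_ext = 1) {
  res <- .profile_align_cpp(A, B, .aln_score_matrix(), gap_open, gap_ext)
  ac <- res$a_cols
  bc <- res$b_cols
  gap <- 21L
  newA <- matrix(gap, nrow(A), length(ac))
  newB <- matrix(gap, nrow(B), length(bc))
  newA[, ac > 0L] <- A[, ac[ac > 0L], drop = FALSE]
  newB[, bc > 0L] <- B[, bc[bc > 0L], drop = FALSE]
  rbind(newA, newB)
}

#' Progressive multiple alignment of marked proteins
#'
#' @param marked List of `marked_protein` objects (>= 1), or a named
#'   character vector of marked sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return An object of class `marked_alignment` with fields `aligned`
#'   (named character vector of equal-length rows, in input order),
#'   `accession`, `species`.
#' @export
build_msa <- function(marked, gap_open = 11, gap_extend = 1) {
  info <- .marked_input(marked)
  n <- length(info$seqs)
  if (n == 0L) stop("build_msa: empty input")
  rows <- lapply(info$seqs, .encode_seq)
  if (n == 1L) {
    return(.new_alignment(stats::setNames(info$seqs, info$accession),
                          info$accession, info$species))
  }
  # pairwise distances: 1 - fractional identity over mutually aligned columns
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- .merge_profiles(matrix(rows[[i]], 1L), matrix(rows[[j]], 1L),
                           gap_open, gap_extend)
      both <- m[1L, ] != 21L & m[2L, ] != 21L
      id <- if (any(both)) mean(m[1L, both] == m[2L, both]) else 0
      D[i, j] <- D[j, i] <- 1 - id
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- lapply(seq_len(n), function(i) matrix(rows[[i]], 1L))
  members <- lapply(seq_len(n), function(i) i)
  merged <- vector("list", n - 1L)
  merged_members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(idx) {
      if (idx < 0L) list(g = groups[[-idx]], m = members[[-idx]])
      else list(g = merged[[idx]], m = merged_members[[idx]])
    }
    a <- pick(hc$merge[k, 1L])
    b <- pick(hc$merge[k, 2L])
    merged[[k]] <- .merge_profiles(a$g, b$g, gap_open, gap_extend)
    merged_members[[k]] <- c(a$m, b$m)
  }
  final <- merged[[n - 1L]]
  ord <- order(merged_members[[n - 1L]])
  final <- final[ord, , drop = FALSE]
  aligned <- vapply(seq_len(n), function(i) .decode_row(final[i, ]), "")
  .new_alignment(stats::setNames(aligned, info$accession),
                 info$accession, info$species)
}

.marked_input <- function(marked) {
  if (is.character(marked)) {
    acc <- names(marked)
    if (is.null(acc)) acc <- paste0("seq", seq_along(marked))
    return(list(seqs = unname(marked), accession = acc,
                species = rep(NA_character_, length(marked))))
  }
  list(seqs = vapply(marked, `[[`, "", "marked"),
       accession = vapply(marked, `[[`, "", "accession"),
       species = vapply(marked, `[[`, "", "species"))
}

.new_alignment <- function(aligned, accession, species) {
  if (length(unique(nchar(aligned))) > 1L) {
    stop("alignment rows have unequal length")
  }
  structure(list(aligned = aligned, accession = accession, species = species),
            class = "marked_alignment")
}

#' @export
print.marked_alignment <- function(x, ...) {
  cat(sprintf("<marked_alignment> %d rows x %d columns\n",
              length(x$aligned), nchar(x$aligned[1L])))
  invisible(x)
}

#' Attach an externally produced alignment
#'
#' Reads an aligned FASTA (e.g. MUSCLE output over the marked sequences) and
#' validates that each row, after removing gaps, reproduces the
#' corresponding marked protein.
#'
#' @param path Path to aligned FASTA.
#' @param marked List of `marked_protein` objects the alignment must cover.
#' @return A `marked_alignment` (rows ordered as in `marked`).
#' @export
import_alignment <- function(path, marked) {
  set <- Biostrings::readAAStringSet(path)
  aligned <- stats::setNames(as.character(set), names(set))
  info <- .marked_input(marked)
  for (i in seq_along(info$accession)) {
    acc <- info$accession[i]
    if (!acc %in% names(aligned)) {
      stop("import_alignment: accession ", acc, " missing from alignment")
    }
    if (gsub("-", "", aligned[[acc]], fixed = TRUE) != info$seqs[i]) {
      stop("import_alignment: row ", acc,
           " does not ungap to its marked sequence")
    }
  }
  .new_alignment(aligned[info$accession], info$accession, info$species)
}

#' Intron presence/absence matrix from aligned X markers
#'
#' For each X column of the focal row and each other row, the status is
#' `present` if that row has an X within `tolerance` columns, `uncovered`
#' if the row has no residue on one side of the column (the ortholog does
#' not span the intron position, e.g. a truncated annotation), and `absent`
#' otherwise.
#'
#' @param alignment A `marked_alignment`.
#' @param focal_accession Accession of the focal row.
#' @param tolerance Column tolerance for "same position" (default 0, exact
#'   column).
#' @return An object of class `presence_matrix`: a character matrix (rows =
#'   non-focal accessions, columns = focal intron ordinals) with attributes
#'   `species`, `focal`, `columns` (alignment column of each focal X) and
#'   `offset` (signed column offset of the matched X, `NA` where not
#'   present).
#' @export
presence_matrix <- function(alignment, focal_accession, tolerance = 0L) {
  if (!focal_accession %in% names(alignment$aligned)) {
    stop("presence_matrix: focal accession ", focal_accession,
         " not found in alignment")
  }
  rows <- lapply(alignment$aligned,
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  fr <- rows[[focal_accession]]
  xcols <- which(fr == "X")
  others <- setdiff(names(alignment$aligned), focal_accession)
  m <- matrix(NA_character_, length(others), length(xcols),
              dimnames = list(others,
                              as.character(seq_along(xcols))))
  off <- matrix(NA_integer_, length(others), length(xcols),
                dimnames = dimnames(m))
  for (a in others) {
    r <- rows[[a]]
    nong <- which(r != "-")
    rx <- which(r == "X")
    for (k in seq_along(xcols)) {
      cc <- xcols[k]
      hit <- rx[abs(rx - cc) <= tolerance]
      if (length(hit)) {
        m[a, k] <- "present"
        off[a, k] <- hit[which.min(abs(hit - cc))][1L] - cc
      } else if (!any(nong < cc) || !any(nong > cc)) {
        m[a, k] <- "uncovered"
      } else {
        m[a, k] <- "absent"
      }
    }
  }
  sp <- alignment$species[match(others, alignment$accession)]
  structure(m, offset = off, columns = xcols,
            species = stats::setNames(sp, others),
            focal = focal_accession, class = "presence_matrix")
}
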