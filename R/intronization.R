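# Detection of intronization signatures: orthologs that retain, as coding
# sequence, the segment that became an intron in the focal species.  The
# signature is a split match of the two flanking exonic sequences with a
# gap whose length matches one third of the intron length, plus residual
# similarity between the translated intron and the ortholog's gap segment.

#' Scan orthologs for split flanking-exon matches
#'
#' For each ortholog lacking the intron, the residues flanking the intron
#' position in the focal protein (up to `flank_len` on each side, truncated
#' at the protein ends) are locally aligned against the ortholog
#' independently.  A candidate is reported when both flanks match with
#' significance at most `threshold`, in order, with a positive gap `g`
#' between the two matched regions; `length_match` records whether `g` is
#' within `max(tol_abs, tol_frac * expected)` of the expected
#' `round(intron_length/3)` residues.
#'
#' @param marked_focal A `marked_protein` of the focal gene (its `marks`
#'   must carry `intron_length`).
#' @param ordinal Intron ordinal to scan.
#' @param orthologs Named character vector of ortholog protein sequences
#'   (orthologs that lack the intron; accessions as names).
#' @param species Optional named character vector accession to species.
#' @param flank_len Flank length in residues (default 50).
#' @param threshold Flank match significance threshold (default `1e-6`).
#' @param tol_abs,tol_frac Gap-length tolerance: `max(tol_abs, tol_frac *
#'   expected)` (defaults 5 and 0.2).
#' @return data.frame of class `intronization_candidates`, one row per
#'   retained ortholog: accession, species, matched flank intervals on the
#'   ortholog (0-based half-open), observed gap `g`, `expected` residues,
#'   `length_match`.
#' @export
flanking_exon_scan <- function(marked_focal, ordinal, orthologs,
                               species = NULL, flank_len = 50L,
                               threshold = 1e-6, tol_abs = 5L,
                               tol_frac = 0.2) {
  marks <- marked_focal$marks
  if (!ordinal %in% marks$ordinal) {
    stop("flanking_exon_scan: intron ordinal ", ordinal, " not found")
  }
  mk <- marks[marks$ordinal == ordinal, ]
  raw <- marked_focal$raw
  pos <- mk$protein_index  # intron sits immediately left of this residue
  left <- substr(raw, max(1L, pos - flank_len), pos - 1L)
  right <- substr(raw, pos, min(nchar(raw), pos + flank_len - 1L))
  if (!nzchar(left) || !nzchar(right)) {
    stop("flanking_exon_scan: intron at the protein boundary leaves an ",
         "empty flank")
  }
  expected <- expected_gap_residues(mk$intron_length)
  tol <- max(tol_abs, tol_frac * expected)
  rows <- list()
  for (acc in names(orthologs)) {
    subj <- orthologs[[acc]]
    la <- local_align(left, subj)
    ra <- local_align(right, subj)
    if (la$significance > threshold || ra$significance > threshold) next
    g <- ra$sstart - la$send
    if (g <= 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = marked_focal$accession, intron_ordinal = ordinal,
      ortholog = acc,
      species = if (!is.null(species)) unname(species[[acc]]) else
        NA_character_,
      left_start = la$sstart, left_end = la$send,
      right_start = ra$sstart, right_end = ra$send,
      g = g, expected = expected,
      length_match = abs(g - expected) <= tol,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(), intron_ordinal = integer(), ortholog = character(),
    species = character(), left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(), g = integer(),
    expected = numeric(), length_match = logical(),
    stringsAsFactors = FALSE)
  class(out) <- c("intronization_candidates", class(out))
  out
}

#' Translate an intron sequence in all three reading frames
#'
#' Each frame is translated up to (and not through) the first stop codon;
#' trailing partial codons are dropped.  `N` is tolerated and translates to
#' `X`; any other non-ACGT character is an error.
#'
#' @param dna Intron DNA sequence (length >= 3).
#' @return Character vector of length 3 (frames 0, 1, 2); a frame whose
#'   first codon is a stop yields an empty peptide.
#' @export
translate_intron_frames <- function(dna) {
  if (nchar(dna) < 3L) stop("translate_intron_frames: sequence too short")
  if (grepl("[^ACGTN]", dna)) {
    stop("translate_intron_frames: invalid character in DNA sequence")
  }
  vapply(0:2, function(f) {
    p <- translate_dna(substr(dna, f + 1L, nchar(dna)))
    sub("\\*.*$", "", p)
  }, "")
}

#' Similarity between a translated intron and the ortholog gap segment
#'
#' Locally aligns each of the three frame translations against the
#' ortholog's gap segment (the residues between the two flank matches) and
#' returns the best frame; ties break toward the lowest frame index.  When
#' every frame translation is empty (immediate stops) a flagged
#' no-similarity result is returned rather than an error.
#'
#' @param peptides Character vector of 3 frame translations, from
#'   [translate_intron_frames()].
#' @param gap_segment Ortholog residues spanning the intron position
#'   (nonempty).
#' @return List with `frame` (0, 1 or 2, or `NA`), `bits`, `significance`,
#'   and `no_similarity` flag.
#' @export
intron_translation_similarity <- function(peptides, gap_segment) {
  stopifnot(length(peptides) == 3L)
  if (!nzchar(gap_segment)) {
    stop("intron_translation_similarity: empty gap segment")
  }
  ok <- which(nzchar(peptides))
  if (length(ok) == 0L) {
    return(list(frame = NA_integer_, bits = NA_real_,
                significance = NA_real_, no_similarity = TRUE))
  }
  best <- NULL
  for (f in ok) {
    al <- local_align(peptides[f], gap_segment)
    if (is.null(best) || al$score > best$score) {
      best <- list(frame = f - 1L, score = al$score, bits = al$bits,
                   significance = al$significance)
    }
  }
  list(frame = best$frame, bits = best$bits,
       significance = best$significance, no_similarity = FALSE)
}

#' Full intronization scan for one candidate gained intron
#'
#' Convenience driver: runs [flanking_exon_scan()] over the orthologs that
#' lack the intron, then, for every candidate, extracts the intron DNA,
#' translates it in three frames and scores the similarity of the best
#' frame against the ortholog's gap segment.
#'
#' @param family Family object as in [run_gain_pipeline()] (needs `genomes`
#'   to extract intron DNA).
#' @param ordinal Focal intron ordinal.
#' @param lacking_accessions Accessions of orthologs lacking the intron.
#' @param ... Passed to [flanking_exon_scan()].
#' @return The candidate data.frame with added columns `frame`, `bits`,
#'   `significance`.
#' @export
scan_intronization <- function(family, ordinal, lacking_accessions, ...) {
  focal_acc <- family$focal_accession
  model <- family$models[[focal_acc]]
  marks <- intron_marks(model)
  marked <- mark_protein(family$proteins[[focal_acc]], marks, focal_acc,
                         family$focal_species)
  cands <- flanking_exon_scan(marked, ordinal,
                              family$proteins[lacking_accessions],
                              species = family$species_map, ...)
  if (nrow(cands) == 0L) {
    cands$frame <- integer(0)
    cands$bits <- numeric(0)
    cands$significance <- numeric(0)
    return(cands)
  }
  dna <- intron_dna(family, focal_acc, ordinal)
  peptides <- translate_intron_frames(dna)
  cands$frame <- NA_integer_
  cands$bits <- NA_real_
  cands$significance <- NA_real_
  for (i in seq_len(nrow(cands))) {
    subj <- family$proteins[[cands$ortholog[i]]]
    gap <- substr(subj, cands$left_end[i] + 1L, cands$right_start[i])
    if (!nzchar(gap)) next
    sim <- intron_translation_similarity(peptides, gap)
    cands$frame[i] <- sim$frame
    cands$bits[i] <- sim$bits
    cands$significance[i] <- sim$significance
  }
  cands
}
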