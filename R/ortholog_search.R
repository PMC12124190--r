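# Best-hit-per-species ortholog identification over a protein collection.
#
# Pairwise scoring is Smith-Waterman under BLOSUM62 (gap open 11 / extend 1,
# X neutral) with a Karlin-Altschul E-value emulation used as the
# significance threshold; a tabular import hook accepts hit tables produced
# by real BLASTP runs (outfmt 6) for full-scale use.

#' Score one query/subject protein pair
#'
#' Local alignment under BLOSUM62 with the X intron marker scoring zero
#' against every letter; significance is `K * m * n * exp(-lambda * S)` on
#' the raw score with ungapped constants by default.
#'
#' @param query,subject Protein sequences (20-letter alphabet plus X).
#' @param query_id,subject_id,subject_species Identifiers carried into the
#'   record.
#' @param lambda,K Karlin-Altschul constants.
#' @return A one-row data.frame (a hit record) with columns `query`,
#'   `subject`, `species`, `bits`, `significance`, and 0-based half-open
#'   aligned intervals `qstart`, `qend`, `sstart`, `send`.
#' @export
score_pair <- function(query, subject, query_id = "query",
                       subject_id = "subject",
                       subject_species = NA_character_,
                       lambda = 0.3176, K = 0.134) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("score_pair: empty sequence")
  }
  al <- local_align(query, subject, lambda = lambda, K = K)
  data.frame(query = query_id, subject = subject_id,
             species = subject_species, score = al$score, bits = al$bits,
             significance = al$significance, qstart = al$qstart,
             qend = al$qend, sstart = al$sstart, send = al$send,
             stringsAsFactors = FALSE)
}

#' Single best ortholog hit per species
#'
#' Scores the query against every subject and keeps, for each species, the
#' hit with the smallest significance (ties broken by higher bit score, then
#' lexicographically smaller accession).  Hits with significance above
#' `threshold` are dropped.
#'
#' @param query Query protein sequence.
#' @param subjects Named character vector of subject protein sequences
#'   (names are accessions).
#' @param species_map Named character vector mapping accession to species.
#' @param threshold Maximum significance (default `1e-6`).
#' @param query_id Identifier for the query.
#' @param exclude_species Species to skip (typically the query's own).
#' @return data.frame of hit records, one row per species, sorted by
#'   species; zero rows when nothing passes.
#' @export
best_hit_per_species <- function(query, subjects, species_map,
                                 threshold = 1e-6, query_id = "query",
                                 exclude_species = character(0)) {
  stopifnot(!is.null(names(subjects)))
  keep <- names(subjects)[!(species_map[names(subjects)] %in% exclude_species)]
  if (length(keep) == 0L) return(.empty_hits())
  hits <- lapply(keep, function(acc) {
    score_pair(query, subjects[[acc]], query_id, acc,
               unname(species_map[[acc]]))
  })
  hits <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_hits())
  hits <- hits[hits$significance <= threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(.empty_hits())
  hits <- hits[order(hits$species, hits$significance, -hits$bits,
                     hits$subject), , drop = FALSE]
  hits <- hits[!duplicated(hits$species), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(query = character(), subject = character(), species = character(),
             score = numeric(), bits = numeric(), significance = numeric(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), stringsAsFactors = FALSE)
}

#' Collect paralog hits within one species
#'
#' Scores the query against every protein of one species except the already
#' selected ortholog, keeping hits passing the significance threshold,
#' sorted by increasing significance.
#'
#' @param query Query protein sequence.
#' @param species_proteins Named character vector of that species' proteins.
#' @param exclude Accession of the already selected ortholog.
#' @param threshold Maximum significance.
#' @param query_id,species Identifiers carried into the records.
#' @return data.frame of hit records (possibly empty).
#' @export
find_paralogs <- function(query, species_proteins, exclude,
                          threshold = 1e-6, query_id = "query",
                          species = NA_character_) {
  accs <- setdiff(names(species_proteins), exclude)
  if (length(accs) == 0L) return(.empty_hits())
  hits <- lapply(accs, function(acc) {
    score_pair(query, species_proteins[[acc]], query_id, acc, species)
  })
  hits <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_hits())
  hits <- hits[hits$significance <= threshold, , drop = FALSE]
  hits <- hits[order(hits$significance, -hits$bits, hits$subject), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Import a 12-column tabular hit table
#'
#' Reads a BLAST outfmt-6 style table (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) together
#' with an accession-to-species map, converting aligned intervals to 0-based
#' half-open coordinates.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param species_map Named character vector mapping subject accession to
#'   species, or path to a two-column tab-separated file.
#' @return data.frame of hit records as in [score_pair()] (raw scores `NA`).
#' @export
import_hit_table <- function(path, species_map = NULL) {
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map)) {
    sm <- utils::read.delim(species_map, header = TRUE,
                            stringsAsFactors = FALSE)
    species_map <- stats::setNames(sm[[2L]], sm[[1L]])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_hits())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != 12L) {
      stop("import_hit_table: line ", i, ": expected 12 columns, got ",
           length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(7:12)]))
    if (anyNA(num)) {
      stop("import_hit_table: line ", i, ": non-numeric field")
    }
    sp <- if (!is.null(species_map) && f[2L] %in% names(species_map)) {
      unname(species_map[[f[2L]]])
    } else NA_character_
    out[[i]] <- data.frame(
      query = f[1L], subject = f[2L], species = sp, score = NA_real_,
      bits = num[6L], significance = num[5L],
      qstart = as.integer(num[1L]) - 1L, qend = as.integer(num[2L]),
      sstart = as.integer(num[3L]) - 1L, send = as.integer(num[4L]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
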