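# Gene models and projection of intron positions into protein coordinates.
#
# Internally every interval is 0-based half-open in genomic forward
# coordinates; exon and CDS lists are kept in transcription order (descending
# genomic coordinate on the minus strand).  GFF3 files are read and written
# in the standard 1-based inclusive dialect.

#' Construct a gene model
#'
#' @param species Species label.
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome/contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column matrices of 0-based half-open intervals in
#'   transcription order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(species, gene_id, transcript_id, chrom, strand,
                       exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2)
  cds <- matrix(as.integer(cds), ncol = 2)
  if (nrow(exons) == 0L) stop("gene_model: at least one exon required")
  if (any(exons[, 2] <= exons[, 1]) || any(cds[, 2] <= cds[, 1])) {
    stop("gene_model: empty or reversed interval")
  }
  # transcription order: ascending on +, descending on -
  key <- if (strand == "+") exons[, 1] else -exons[, 1]
  if (is.unsorted(key, strictly = TRUE)) {
    stop("gene_model: exons not in transcription order for strand ", strand)
  }
  # non-overlap in genomic coordinates
  g <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(g) > 1L && any(g[-1L, 1] < g[-nrow(g), 2])) {
    stop("gene_model: overlapping exons")
  }
  total_cds <- sum(cds[, 2] - cds[, 1])
  if (total_cds %% 3L != 0L) {
    stop("malformed model ", transcript_id, ": CDS length ", total_cds,
         " not divisible by 3")
  }
  structure(list(species = species, gene_id = gene_id,
                 transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s, %d exon(s), CDS %d nt\n",
              x$transcript_id, x$species, x$chrom,
              paste0(min(x$exons[, 1]), "-", max(x$exons[, 2])), x$strand,
              nrow(x$exons), sum(x$cds[, 2] - x$cds[, 1])))
  invisible(x)
}

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon/CDS records, groups them by transcript, converts
#' coordinates to the internal 0-based half-open convention, and orders
#' minus-strand exons into transcription order.  Transcripts without CDS
#' records are skipped with a warning; a transcript whose total CDS length is
#' not a multiple of 3 raises an error naming the transcript.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label to attach to every model (default: the file
#'   name without extension).
#' @return List of [gene_model] objects, named by transcript id.
#' @export
parse_gff <- function(path, species = NULL) {
  if (is.null(species)) {
    species <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("parse_gff requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$chrom <- as.character(df$seqnames)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  df$id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$parent <- vapply(as.list(df$Parent), function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, "")

  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(tx))) {
    tid <- tx$id[k]
    ex <- df[df$type == "exon" & df$parent == tid, , drop = FALSE]
    cd <- df[df$type == "CDS" & df$parent == tid, , drop = FALSE]
    if (nrow(cd) == 0L) {
      warning("parse_gff: transcript ", tid, " has no CDS; skipped")
      next
    }
    if (nrow(ex) == 0L) ex <- cd
    strand <- tx$strand[k]
    to0 <- function(d) {
      m <- cbind(d$start - 1L, d$end)
      m[order(if (strand == "+") m[, 1] else -m[, 1]), , drop = FALSE]
    }
    out[[tid]] <- gene_model(species = species, gene_id = tx$parent[k],
                             transcript_id = tid, chrom = tx$chrom[k],
                             strand = strand, exons = to0(ex), cds = to0(cd))
  }
  out
}

#' Read gene models from a simple exon table
#'
#' Tab-separated with header columns `transcript`, `chrom`, `strand`,
#' `exon_start`, `exon_end`, `cds_start`, `cds_end` (1-based inclusive, one
#' row per exon; `NA` cds columns for non-coding exons).
#'
#' @param path Path to the table.
#' @param species Species label (default: file name).
#' @return List of [gene_model] objects named by transcript id.
#' @export
read_exon_table <- function(path, species = NULL) {
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "chrom", "strand", "exon_start", "exon_end",
            "cds_start", "cds_end")
  if (!all(need %in% names(df))) {
    stop("read_exon_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- list()
  for (tid in unique(df$transcript)) {
    d <- df[df$transcript == tid, , drop = FALSE]
    strand <- d$strand[1L]
    ex <- cbind(d$exon_start - 1L, d$exon_end)
    ex <- ex[order(if (strand == "+") ex[, 1] else -ex[, 1]), , drop = FALSE]
    cc <- d[!is.na(d$cds_start), , drop = FALSE]
    cd <- cbind(cc$cds_start - 1L, cc$cds_end)
    cd <- cd[order(if (strand == "+") cd[, 1] else -cd[, 1]), , drop = FALSE]
    out[[tid]] <- gene_model(species = species, gene_id = tid,
                             transcript_id = tid, chrom = d$chrom[1L],
                             strand = strand, exons = ex, cds = cd)
  }
  out
}

# coding nucleotides of each exon (transcription order)
.exon_cds_nt <- function(model) {
  vapply(seq_len(nrow(model$exons)), function(i) {
    e <- model$exons[i, ]
    sum(pmax(0L, pmin(model$cds[, 2], e[2]) - pmax(model$cds[, 1], e[1])))
  }, integer(1))
}

#' Intron positions of a gene model in protein coordinates
#'
#' One mark is produced per junction between consecutive CDS-bearing exons.
#' For each mark, `coding_offset` is the number of coding nucleotides
#' preceding the intron (`c`), `phase = c %% 3`, and `protein_index` is the
#' 1-based residue index that the X marker is inserted to the left of
#' (`floor(c/3) + 1`, which places a phase-0 intron between residues `c/3`
#' and `c/3 + 1` and a mid-codon intron immediately left of the interrupted
#' residue).  Junctions flanked by non-coding sequence only (UTR introns) are
#' ignored.
#'
#' @param model A [gene_model].
#' @return data.frame with columns `ordinal`, `coding_offset`,
#'   `protein_index`, `phase`, `intron_length`, `start`, `end` (genomic
#'   0-based half-open interval of the intron).
#' @export
intron_marks <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n <- nrow(model$exons)
  cds_nt <- .exon_cds_nt(model)
  total <- sum(cds_nt)
  res <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    c_off <- sum(cds_nt[seq_len(i)])
    if (c_off == 0L || c_off >= total) next  # UTR-only junction
    e1 <- model$exons[i, ]
    e2 <- model$exons[i + 1L, ]
    if (model$strand == "+") {
      iv <- c(e1[2], e2[1])
    } else {
      iv <- c(e2[2], e1[1])
    }
    res[[length(res) + 1L]] <- data.frame(
      coding_offset = c_off,
      protein_index = c_off %/% 3L + 1L,
      phase = c_off %% 3L,
      intron_length = iv[2] - iv[1],
      start = iv[1], end = iv[2])
  }
  if (length(res) == 0L) {
    return(data.frame(ordinal = integer(), coding_offset = integer(),
                      protein_index = integer(), phase = integer(),
                      intron_length = integer(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, res)
  out <- cbind(ordinal = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Insert X intron markers into a protein sequence
#'
#' @param protein Raw amino-acid sequence (no markers).
#' @param marks data.frame as returned by [intron_marks()] (only
#'   `protein_index` and `coding_offset` are used; may be empty).
#' @param accession,species Optional identifiers carried along.
#' @return An object of class `marked_protein` with fields `raw`, `marked`,
#'   `marks`, `accession`, `species`.
#' @export
mark_protein <- function(protein, marks, accession = NA_character_,
                         species = NA_character_) {
  L <- nchar(protein)
  if (nrow(marks) > 0L) {
    if (any(marks$protein_index > L)) {
      bad <- marks$protein_index[marks$protein_index > L][1L]
      stop("mark_protein: mark at residue ", bad,
           " is out of range for protein of length ", L,
           " (position falls at or beyond the stop codon)")
    }
    if (any(marks$protein_index < 1L)) stop("mark_protein: mark before start")
    marks <- marks[order(marks$protein_index, marks$coding_offset), ,
                   drop = FALSE]
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  # insert right-to-left so earlier indices stay valid
  marked <- chars
  for (i in rev(seq_len(nrow(marks)))) {
    p <- marks$protein_index[i]
    marked <- append(marked, "X", after = p - 1L)
  }
  structure(list(accession = accession, species = species,
                 raw = protein, marked = paste(marked, collapse = ""),
                 marks = marks),
            class = "marked_protein")
}

#' Remove intron markers from a marked protein
#'
#' Inverse of [mark_protein()]: deletes exactly the inserted X characters
#' (located via the stored marks), recovering the raw sequence.
#'
#' @param x A `marked_protein`, or a plain marked string (in which case all
#'   X characters are removed).
#' @return Character scalar, the unmarked sequence.
#' @export
unmark_protein <- function(x) {
  if (inherits(x, "marked_protein")) {
    chars <- strsplit(x$marked, "", fixed = TRUE)[[1]]
    if (nrow(x$marks) > 0L) {
      idx <- sort(x$marks$protein_index) + seq_len(nrow(x$marks)) - 1L
      chars <- chars[-idx]
    }
    return(paste(chars, collapse = ""))
  }
  gsub("X", "", x, fixed = TRUE)
}

#' Expected residue span of an intronized segment
#'
#' An intron created by intronization removed `length/3` residues from the
#' protein, so an ortholog retaining the ancestral exon is expected to carry
#' that many extra residues at the intron position.
#'
#' @param intron_length Intron length in nucleotides (> 0).
#' @return `round(intron_length / 3)` (exact when the length is a multiple of
#'   3; ties round to even).
#' @export
expected_gap_residues <- function(intron_length) {
  if (any(intron_length <= 0)) {
    stop("expected_gap_residues: intron_length must be positive")
  }
  round(intron_length / 3)
}

#' Spliced CDS of a gene model
#'
#' Extracts and concatenates the CDS intervals from the genomic sequence in
#' mRNA orientation (reverse-complemented on the minus strand).
#'
#' @param genome Character scalar, the contig sequence the model lives on.
#' @param model A [gene_model].
#' @return Character scalar, the spliced coding sequence.
#' @export
splice_cds <- function(genome, model) {
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    iv <- model$cds[i, ]
    s <- substr(genome, iv[1] + 1L, iv[2])
    if (model$strand == "-") revcomp(s) else s
  }, "")
  paste(pieces, collapse = "")
}

#' Translate a spliced CDS to protein, dropping the terminal stop
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @return Protein string without the trailing stop.
#' @export
translate_cds <- function(cds) {
  p <- translate_dna(cds)
  sub("\\*$", "", p)
}
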