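# Mapping intron presence/absence onto the species taxonomy, locating the
# gain clade that maximizes R - B, and the candidate filters.

#' Find the clade maximizing R - B for one intron
#'
#' Among all clades (tree nodes, including the focal leaf itself) whose leaf
#' set contains the focal species -- i.e. the nodes on the path from the
#' focal leaf to the root -- returns the one maximizing `R - B`, where `R`
#' counts in-clade species whose ortholog has the intron at the aligned
#' position (the focal species always counts in `R`) and `B` counts in-clade
#' species whose ortholog lacks it.  Species with `uncovered` status, and
#' species with no ortholog at all, count in neither.  Ties are broken
#' toward the smallest clade (the most recent gain consistent with the
#' data).
#'
#' @param tree Species tree (`phylo`; multifurcations allowed).
#' @param presence Named character vector over species with orthologs:
#'   values in `present`, `absent`, `uncovered`.  Must not include the focal
#'   species.
#' @param focal_species Focal leaf label.
#' @return An object of class `gain_event` with fields `node`,
#'   `clade_leaves`, `R`, `B`, `score`, `clade_age`, `presence`, and a
#'   `flags` list filled in by the filter functions.
#' @export
best_gain_clade <- function(tree, presence, focal_species) {
  tipn <- match(focal_species, tree$tip.label)
  if (is.na(tipn)) {
    stop("best_gain_clade: focal species ", focal_species, " not in tree")
  }
  if (focal_species %in% names(presence)) {
    stop("best_gain_clade: presence vector must not include the focal ",
         "species (it is present by definition)")
  }
  unknown <- setdiff(names(presence), tree$tip.label)
  if (length(unknown)) {
    stop("best_gain_clade: species not in tree: ",
         paste(unknown, collapse = ", "))
  }
  path <- c(tipn, phangorn::Ancestors(tree, tipn, "all"))
  ages <- if (!is.null(tree$edge.length)) node_ages(tree) else NULL
  best <- NULL
  for (node in path) {
    leaves <- if (node <= length(tree$tip.label)) {
      tree$tip.label[node]
    } else {
      tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    }
    st <- presence[names(presence) %in% leaves]
    R <- 1L + sum(st == "present")
    B <- sum(st == "absent")
    score <- R - B
    # path is ordered smallest-first, so strict improvement implements the
    # smallest-clade tie-break
    if (is.null(best) || score > best$score) {
      best <- list(node = node, clade_leaves = leaves, R = R, B = B,
                   score = score,
                   clade_age = if (!is.null(ages)) unname(ages[node]) else
                     NA_real_)
    }
  }
  structure(c(best, list(presence = presence, focal_species = focal_species,
                         gene = NA_character_, ordinal = NA_integer_,
                         fraction_unaligned = NA_real_,
                         flags = list(passed_70pct = NA,
                                      boundary_excluded = NA,
                                      paralog_rescued = character(0),
                                      retention = NA,
                                      rejected_reason = NA_character_))),
            class = "gain_event")
}

#' @export
print.gain_event <- function(x, ...) {
  cat(sprintf(
    "<gain_event> %s intron %s: clade of %d leaves (node %d), R=%d B=%d score=%d\n",
    x$gene, x$ordinal, length(x$clade_leaves), x$node, x$R, x$B, x$score))
  invisible(x)
}

#' Apply the minimum-unaligned-fraction candidate filter
#'
#' A candidate gained intron must be missing from at least `min_frac`
#' (default 70%) of all species with an ortholog: the filter computes
#' `absent / n_orthologs`, where the denominator counts every species in
#' the presence vector (uncovered species included) and the numerator only
#' the `absent` ones.  With no orthologs at all the event is rejected.
#'
#' @param event A `gain_event`.
#' @param presence Presence vector (default: the one stored in the event).
#' @param min_frac Minimum absent fraction (default 0.70; the comparison is
#'   `>=`, so exactly 70% passes).
#' @return The event with `fraction_unaligned` and `flags$passed_70pct` set.
#' @export
apply_70pct_filter <- function(event, presence = event$presence,
                               min_frac = 0.70) {
  n <- length(presence)
  if (n == 0L) {
    event$flags$passed_70pct <- FALSE
    event$flags$rejected_reason <- "no orthologs found"
    event$fraction_unaligned <- NA_real_
    return(event)
  }
  frac <- sum(presence == "absent") / n
  event$fraction_unaligned <- frac
  event$flags$passed_70pct <- frac >= min_frac
  if (!event$flags$passed_70pct && is.na(event$flags$rejected_reason)) {
    event$flags$rejected_reason <-
      sprintf("absent in %.0f%% of orthologous species (< %.0f%%)",
              100 * frac, 100 * min_frac)
  }
  event
}

#' Apply the protein-boundary exclusion filter
#'
#' Events supported mostly by orthologs that do not span the intron
#' position (status `uncovered`: the position falls beyond the annotated
#' start or end of the ortholog) are excluded: the event is dropped when the
#' fraction of uncovered species among non-clade species exceeds `cutoff`
#' (strict inequality; exactly at the cutoff is retained).
#'
#' @param event A `gain_event`.
#' @param presence Presence vector (default: stored in the event).
#' @param cutoff Maximum tolerated uncovered fraction among non-clade
#'   species (default 0.50).
#' @return The event with `flags$boundary_excluded` set.
#' @export
apply_boundary_filter <- function(event, presence = event$presence,
                                  cutoff = 0.50) {
  outside <- presence[!names(presence) %in% event$clade_leaves]
  frac <- if (length(outside) == 0L) 0 else mean(outside == "uncovered")
  event$flags$boundary_excluded <- frac > cutoff
  if (event$flags$boundary_excluded && is.na(event$flags$rejected_reason)) {
    event$flags$rejected_reason <-
      sprintf("intron position beyond the annotated ortholog boundary in %.0f%% of non-clade species", 100 * frac)
  }
  event
}

#' Rescue apparent absences using intron-bearing paralogs
#'
#' A species whose selected ortholog lacks the intron, but that carries a
#' paralog with the intron at the matching position, is re-marked as having
#' the intron; the gain clade and the unaligned-fraction filter are then
#' recomputed.  The operation is idempotent.
#'
#' @param event A `gain_event`.
#' @param paralog_lookup Named character vector over species with values
#'   `has`, `lacks` or `unknown`.
#' @param tree,focal_species Tree and focal species used to recompute the
#'   clade.
#' @param min_frac Passed to [apply_70pct_filter()].
#' @return Updated `gain_event`; rescued species are recorded in
#'   `flags$paralog_rescued`.
#' @export
paralog_rescue <- function(event, paralog_lookup, tree,
                           focal_species = event$focal_species,
                           min_frac = 0.70) {
  presence <- event$presence
  rescue <- names(paralog_lookup)[paralog_lookup == "has"]
  rescue <- intersect(rescue, names(presence)[presence == "absent"])
  if (length(rescue) == 0L) {
    event$flags$paralog_rescued <- character(0)
    return(event)
  }
  presence[rescue] <- "present"
  new_event <- best_gain_clade(tree, presence, focal_species)
  new_event$gene <- event$gene
  new_event$ordinal <- event$ordinal
  new_event$flags <- event$flags
  new_event$flags$rejected_reason <- NA_character_
  new_event$flags$paralog_rescued <- rescue
  for (f in c("intron_length", "protein_index")) {
    if (!is.null(event[[f]])) new_event[[f]] <- event[[f]]
  }
  apply_70pct_filter(new_event, min_frac = min_frac)
}

#' Flag introns retained by an alternative transcript
#'
#' Cross-check against alternative transcript annotations: the flag is true
#' when any transcript of the gene has an exon whose interval fully
#' contains the intron interval (an intron-retention isoform, suggesting
#' the apparent gain is an alternative-splicing artifact).
#'
#' @param models List of [gene_model] objects: all transcripts of the gene.
#' @param intron_start,intron_end 0-based half-open genomic interval of the
#'   intron.
#' @return Logical flag.
#' @export
check_intron_retention <- function(models, intron_start, intron_end) {
  for (m in models) {
    ex <- m$exons
    if (any(ex[, 1] <= intron_start & ex[, 2] >= intron_end)) return(TRUE)
  }
  FALSE
}

#' Run the intron-gain discovery pipeline on one gene family
#'
#' End to end: compute intron marks of the focal gene, select the single
#' best ortholog per species, mark every ortholog with its own introns,
#' build the marked multiple alignment, derive the presence/absence matrix,
#' locate the best gain clade per focal intron, and apply the
#' unaligned-fraction, boundary and paralog-rescue filters plus the
#' intron-retention cross-check.  Deterministic for fixed inputs; every
#' rejection is logged with its rule.
#'
#' @param family A `sim_family`, or any list with fields `models` (named
#'   list of [gene_model]), `proteins` (named character), `species_map`
#'   (named character accession to species), `tree` (`phylo`),
#'   `focal_accession`, `focal_species`.
#' @param threshold Ortholog significance threshold (default `1e-6`).
#' @param min_unaligned_frac Minimum absent fraction (default 0.70).
#' @param uncovered_cutoff Boundary-exclusion cutoff (default 0.50).
#' @param tolerance Column tolerance for shared intron positions.
#' @param rescue_paralogs Whether to run the paralog-rescue step.
#' @return List with `events` (list of accepted `gain_event`s), `candidates`
#'   (data.frame of all focal introns with scores, fractions and flags),
#'   `matrix` (the `presence_matrix`), `alignment`, `orthologs` (hit table)
#'   and `log` (data.frame of rejections).
#' @export
run_gain_pipeline <- function(family, threshold = 1e-6,
                              min_unaligned_frac = 0.70,
                              uncovered_cutoff = 0.50, tolerance = 0L,
                              rescue_paralogs = TRUE) {
  focal_acc <- family$focal_accession
  focal_sp <- family$focal_species
  tree <- family$tree
  model <- family$models[[focal_acc]]
  if (is.null(model)) stop("run_gain_pipeline: no model for ", focal_acc)
  marks <- intron_marks(model)
  raw <- family$proteins[[focal_acc]]
  focal_marked <- mark_protein(raw, marks, focal_acc, focal_sp)

  log <- data.frame(ordinal = integer(), rule = character(),
                    detail = character())
  note <- function(ordinal, rule, detail) {
    log <<- rbind(log, data.frame(ordinal = ordinal, rule = rule,
                                  detail = detail))
  }

  if (nrow(marks) == 0L) {
    return(list(events = list(), candidates = NULL, matrix = NULL,
                alignment = NULL, orthologs = .empty_hits(), log = log))
  }

  orth <- best_hit_per_species(raw, family$proteins, family$species_map,
                               threshold = threshold, query_id = focal_acc,
                               exclude_species = focal_sp)

  marked_rows <- list(focal_marked)
  for (i in seq_len(nrow(orth))) {
    acc <- orth$subject[i]
    om <- family$models[[acc]]
    if (is.null(om)) {
      note(NA_integer_, "no-annotation",
           paste0("ortholog ", acc, " has no gene model; species ",
                  orth$species[i], " skipped"))
      next
    }
    omk <- intron_marks(om)
    omk <- omk[omk$protein_index <= nchar(family$proteins[[acc]]), ,
               drop = FALSE]
    marked_rows[[length(marked_rows) + 1L]] <-
      mark_protein(family$proteins[[acc]], omk, acc, orth$species[i])
  }

  aln <- build_msa(marked_rows)
  pm <- presence_matrix(aln, focal_acc, tolerance = tolerance)
  row_species <- attr(pm, "species")

  # per-species paralog presence, computed once from pairwise marked
  # alignments of the focal protein with each passing paralog
  paralog_status <- NULL
  if (rescue_paralogs) {
    paralog_status <- matrix(NA_character_, 0L, nrow(marks))
    for (i in seq_len(nrow(orth))) {
      sp <- orth$species[i]
      sp_accs <- names(family$species_map)[family$species_map == sp]
      if (length(sp_accs) <= 1L) next
      hits <- find_paralogs(raw, family$proteins[sp_accs],
                            exclude = orth$subject[i],
                            threshold = threshold, query_id = focal_acc,
                            species = sp)
      st <- rep("lacks", nrow(marks))
      for (j in seq_len(nrow(hits))) {
        pacc <- hits$subject[j]
        pmdl <- family$models[[pacc]]
        if (is.null(pmdl)) next
        pmk <- intron_marks(pmdl)
        pmk <- pmk[pmk$protein_index <= nchar(family$proteins[[pacc]]), ,
                   drop = FALSE]
        pmarked <- mark_protein(family$proteins[[pacc]], pmk, pacc, sp)
        paln <- build_msa(list(focal_marked, pmarked))
        ppm <- presence_matrix(paln, focal_acc, tolerance = tolerance)
        st[ppm[1L, ] == "present"] <- "has"
      }
      paralog_status <- rbind(paralog_status, st)
      rownames(paralog_status)[nrow(paralog_status)] <- sp
    }
  }

  # focal gene's other transcripts, for the intron-retention cross-check
  alt_models <- Filter(function(m) {
    m$gene_id == model$gene_id && m$species == model$species &&
      m$transcript_id != model$transcript_id
  }, family$models)

  events <- list()
  cand_rows <- list()
  for (k in seq_len(nrow(marks))) {
    pres <- stats::setNames(unname(pm[, k]), unname(row_species))
    ev <- best_gain_clade(tree, pres, focal_sp)
    ev$gene <- focal_acc
    ev$ordinal <- k
    ev$intron_length <- marks$intron_length[k]
    ev$protein_index <- marks$protein_index[k]
    ev <- apply_70pct_filter(ev, min_frac = min_unaligned_frac)
    ev <- apply_boundary_filter(ev, cutoff = uncovered_cutoff)
    if (rescue_paralogs && !is.null(paralog_status) &&
        nrow(paralog_status) > 0L) {
      lookup <- stats::setNames(paralog_status[, k],
                                rownames(paralog_status))
      ev <- paralog_rescue(ev, lookup, tree, focal_sp,
                           min_frac = min_unaligned_frac)
      ev <- apply_boundary_filter(ev, cutoff = uncovered_cutoff)
    }
    ev$flags$retention <- check_intron_retention(alt_models,
                                                 marks$start[k],
                                                 marks$end[k])
    accept <- isTRUE(ev$flags$passed_70pct) &&
      !isTRUE(ev$flags$boundary_excluded)
    if (accept) {
      events[[length(events) + 1L]] <- ev
    } else {
      note(k, "filtered", ev$flags$rejected_reason)
    }
    cand_rows[[k]] <- data.frame(
      gene = ev$gene, intron_ordinal = k, clade_node = ev$node,
      clade_leaves = paste(ev$clade_leaves, collapse = ","),
      R = ev$R, B = ev$B, score = ev$score,
      fraction_unaligned = ev$fraction_unaligned,
      passed_70pct = isTRUE(ev$flags$passed_70pct),
      boundary_excluded = isTRUE(ev$flags$boundary_excluded),
      paralog_rescued = paste(ev$flags$paralog_rescued, collapse = ","),
      retention = ev$flags$retention,
      intron_length = marks$intron_length[k],
      protein_index = marks$protein_index[k],
      clade_age = ev$clade_age, accepted = accept)
  }

  list(events = events, candidates = do.call(rbind, cand_rows),
       matrix = pm, alignment = aln, orthologs = orth, log = log)
}
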