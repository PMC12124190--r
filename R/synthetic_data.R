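# Simulation of gene families along a species tree with planted intron
# gain, loss, paralogy and intronization events, plus ground-truth tables.
#
# The simulator works in ancestral coding coordinates: a single ancestral
# CDS is evolved along the tree at the amino-acid level (codons re-encoded
# after each substitution), introns are bookkept as (offset, sequence,
# present) records, and intronization excises a fixed ancestral segment in
# the gained lineage while outgroups keep it as coding sequence.  Every
# simulated intron begins GT and ends AG; for intronization events the
# splice dinucleotides are planted in the ancestral exon (a precondition of
# the mechanism) and the overlapping codons are held fixed so the signal is
# not destroyed by substitution.

#' Describe one planted intron gain event
#'
#' @param clade Character vector of leaf labels; the gain is placed on the
#'   branch leading to their most recent common ancestor, and the true gain
#'   clade is the full leaf set of that node.
#' @param at 1-based residue index of the ancestral protein that the new
#'   intron precedes.
#' @param mechanism `"generic"` (inserted intronic sequence) or
#'   `"intronization"` (a segment of ancestral coding sequence becomes the
#'   intron, shortening the protein by `intron_length/3` residues).
#' @param intron_length Intron length in nucleotides; must be a multiple of
#'   3 for intronization so no frameshift is introduced.
#' @param phase Intron phase (0, 1 or 2): number of coding nucleotides by
#'   which the intron interrupts the codon of residue `at`.
#' @return A list describing the event, for `gain_events` in [sim_config()].
#' @export
gain_event <- function(clade, at, mechanism = c("generic", "intronization"),
                       intron_length = 90L, phase = 0L) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "intronization" && intron_length %% 3L != 0L) {
    stop("invalid-config: intronization intron_length must be a multiple of 3")
  }
  if (!phase %in% 0:2) stop("invalid-config: phase must be 0, 1 or 2")
  if (intron_length < 6L) stop("invalid-config: intron_length too short")
  list(clade = as.character(clade), at = as.integer(at),
       mechanism = mechanism, intron_length = as.integer(intron_length),
       phase = as.integer(phase))
}

#' Simulation configuration
#'
#' @param n_species Number of leaves (>= 2).
#' @param birth_model `"pure-birth"` (Yule tree, depth scaled to 1) or
#'   `"fixed-topology"` (use `topology`).
#' @param topology Newick string, required for `"fixed-topology"`; branch
#'   lengths are taken from the string or, when absent, assigned with
#'   Grafen's method and scaled to unit depth.
#' @param focal_species Leaf label of the focal species (default `"sp1"`).
#' @param n_ancestral_introns Number of introns present in the family
#'   ancestor.
#' @param ancestral_intron_offsets Optional integer vector of coding-
#'   nucleotide offsets for the ancestral introns (overrides random
#'   placement; length must equal `n_ancestral_introns`).
#' @param gain_events List of [gain_event()] descriptions.
#' @param loss_rate Per-branch probability that an existing intron is lost
#'   (Dollo-style: no regain).
#' @param substitution_rate Expected amino-acid substitutions per site per
#'   unit branch length (intron interiors substitute at the same per-site
#'   rate at the nucleotide level).
#' @param paralog_rate Per-species probability of emitting a more diverged
#'   duplicate gene copy.
#' @param protein_length Length of the ancestral protein in residues.
#' @param intron_length_range Range (nt) from which ancestral and planted
#'   generic intron lengths default.
#' @param flank_length Length of random genomic sequence flanking the gene.
#' @param seed Integer seed; identical configurations produce identical
#'   families.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 12L,
                       birth_model = c("pure-birth", "fixed-topology"),
                       topology = NULL,
                       focal_species = "sp1",
                       n_ancestral_introns = 4L,
                       ancestral_intron_offsets = NULL,
                       gain_events = list(),
                       loss_rate = 0.02,
                       substitution_rate = 0.05,
                       paralog_rate = 0,
                       protein_length = 200L,
                       intron_length_range = c(60L, 240L),
                       flank_length = 100L,
                       seed = 1L) {
  birth_model <- match.arg(birth_model)
  if (n_species < 2L) stop("invalid-config: n_species must be >= 2")
  if (birth_model == "fixed-topology" && is.null(topology)) {
    stop("invalid-config: fixed-topology requires a topology")
  }
  if (loss_rate < 0 || loss_rate > 1) stop("invalid-config: loss_rate in [0,1]")
  if (paralog_rate < 0 || paralog_rate > 1) {
    stop("invalid-config: paralog_rate in [0,1]")
  }
  if (substitution_rate < 0) stop("invalid-config: substitution_rate >= 0")
  L <- as.integer(protein_length)
  for (ev in gain_events) {
    c_off <- 3L * (ev$at - 1L) + ev$phase
    if (c_off < 3L || c_off > 3L * L - 3L) {
      stop("invalid-config: insertion point at residue ", ev$at,
           " outside the ancestral protein")
    }
    if (ev$mechanism == "intronization" && c_off + ev$intron_length > 3L * L - 3L) {
      stop("invalid-config: intronization segment extends beyond the ",
           "ancestral protein")
    }
  }
  if (!is.null(ancestral_intron_offsets)) {
    ancestral_intron_offsets <- as.integer(ancestral_intron_offsets)
    if (length(ancestral_intron_offsets) != n_ancestral_introns) {
      stop("invalid-config: ancestral_intron_offsets length must equal ",
           "n_ancestral_introns")
    }
    if (any(ancestral_intron_offsets < 3L |
              ancestral_intron_offsets > 3L * L - 3L)) {
      stop("invalid-config: ancestral intron offset outside the protein")
    }
  }
  structure(list(n_species = as.integer(n_species),
                 birth_model = birth_model, topology = topology,
                 focal_species = focal_species,
                 n_ancestral_introns = as.integer(n_ancestral_introns),
                 ancestral_intron_offsets = ancestral_intron_offsets,
                 gain_events = gain_events, loss_rate = loss_rate,
                 substitution_rate = substitution_rate,
                 paralog_rate = paralog_rate, protein_length = L,
                 intron_length_range = as.integer(intron_length_range),
                 flank_length = as.integer(flank_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate expr with a local, restored RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a species taxonomy
#'
#' Pure-birth trees are simulated with [ape::rphylo()] and scaled to unit
#' root-to-tip depth, so node ages live in \[0, 1\] and branch lengths are in
#' units of total tree depth.  Fixed topologies are returned exactly as
#' given; missing branch lengths are assigned with Grafen's method and
#' scaled the same way.  Multifurcations are allowed and preserved.
#'
#' @param config A [sim_config()].
#' @return A rooted `phylo` tree with unique leaf labels and positive branch
#'   lengths; node ages are recoverable with [node_ages()].
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    if (config$birth_model == "pure-birth") {
      tr <- ape::rphylo(config$n_species, birth = 1, death = 0)
      tr$tip.label <- paste0("sp", seq_len(config$n_species))
    } else {
      tr <- ape::read.tree(text = config$topology)
      if (is.null(tr$edge.length)) {
        tr <- ape::compute.brlen(tr, method = "Grafen")
      }
    }
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
  })
}

#' Node ages of an ultrametric tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of ages (time before the leaves), indexed by node
#'   number; leaves have age 0 for ultrametric trees.
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

# ---- internal simulation machinery -----------------------------------------

.codons_by_aa <- function() {
  if (is.null(.pkg_cache$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons_by_aa
}

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

.random_codon <- function(aa) {
  opts <- .codons_by_aa()[[aa]]
  if (length(opts) == 1L) opts else sample(opts, 1L)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_intron_seq <- function(len) {
  paste0("GT", .random_dna(len - 4L), "AG")
}

# substitute interior nucleotides of an intron sequence, keeping GT..AG ends
.evolve_intron_seq <- function(seq, p) {
  n <- nchar(seq)
  if (n <= 4L || p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(n) < p)
  hit <- hit[hit > 2L & hit < n - 1L]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Build the ancestral CDS: random codons for a random protein, then plant
# GT..AG splice dinucleotides at every intronization segment and repair any
# stop codons this created (resampling only unforced positions).
.ancestral_cds <- function(L, intronization_events) {
  bg <- aa_background()
  aa <- sample(names(bg), L, replace = TRUE, prob = bg)
  nt <- unlist(strsplit(vapply(aa, .random_codon, ""), "", fixed = TRUE),
               use.names = FALSE)
  forced <- integer(0)
  for (ev in intronization_events) {
    c0 <- 3L * (ev$at - 1L) + ev$phase  # 0-based coding offset
    len <- ev$intron_length
    pos <- c(c0 + 1L, c0 + 2L, c0 + len - 1L, c0 + len)
    nt[pos] <- c("G", "T", "A", "G")
    forced <- c(forced, pos)
  }
  # repair stop codons among real codons and the fused codons that excision
  # would create; only unforced positions are touched
  repeat {
    changed <- FALSE
    for (q in seq_len(L)) {
      idx <- (3L * (q - 1L) + 1L):(3L * q)
      if (.is_stop(paste(nt[idx], collapse = ""))) {
        free <- setdiff(idx, forced)
        if (length(free) == 0L) stop("internal: unfixable stop codon")
        i <- free[length(free)]
        nt[i] <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1L)
        changed <- TRUE
      }
    }
    for (ev in intronization_events) {
      c0 <- 3L * (ev$at - 1L) + ev$phase
      p <- c0 %% 3L
      if (p == 0L) next
      pre <- (c0 - p + 1L):c0
      post <- (c0 + ev$intron_length + 1L):(c0 + ev$intron_length + 3L - p)
      fused <- paste(nt[c(pre, post)], collapse = "")
      if (.is_stop(fused)) {
        free <- setdiff(c(pre, post), forced)
        i <- free[1L]
        nt[i] <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1L)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  codons <- vapply(seq_len(L), function(q) {
    paste(nt[(3L * (q - 1L) + 1L):(3L * q)], collapse = "")
  }, "")
  aa <- unname(vapply(codons, function(cd) Biostrings::GENETIC_CODE[[cd]], ""))
  list(codons = codons, aa = aa, forced_nt = forced)
}

# residue indices overlapping any of the given 0-based nt offsets
.codon_of_nt <- function(nt_pos_1based) (nt_pos_1based - 1L) %/% 3L + 1L

#' Simulate one gene family along a species tree
#'
#' Evolves an ancestral gene along `tree`: amino-acid substitutions are drawn
#' per branch with probability `1 - exp(-substitution_rate * length)` per
#' site (replacement residues drawn from background frequencies, codons
#' re-encoded), intron interiors substitute at the same per-site rate at the
#' nucleotide level, existing introns are lost with per-branch probability
#' `loss_rate` (no regain), and planted gains appear on the branch leading to
#' the most recent common ancestor of their clade.  Planted gains are never
#' lost on the path to the focal species (the analysis ascertains introns
#' that are present in the focal species).  Intronization gains excise
#' `intron_length` nt of ancestral coding sequence into the new intron, so
#' carriers are `intron_length/3` residues shorter than outgroups.
#'
#' @param tree Species tree from [simulate_taxonomy()].
#' @param config The same [sim_config()].
#' @return A list with components `family` (class `sim_family`: tree, gene
#'   models, proteins, genomes, species map) and `truth` (class `sim_truth`:
#'   planted events, per-species intron status, per-species marks, paralog
#'   registry).
#' @export
simulate_gene_family <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!config$focal_species %in% tips) {
    stop("invalid-config: focal species ", config$focal_species,
         " is not a leaf of the tree")
  }
  for (ev in config$gain_events) {
    missing <- setdiff(ev$clade, tips)
    if (length(missing)) {
      stop("invalid-config: clade label(s) not in tree: ",
           paste(missing, collapse = ", "))
    }
  }
  with_seed(config$seed + 1L, .simulate_gene_family_impl(tree, config))
}

.simulate_gene_family_impl <- function(tree, config) {
  L <- config$protein_length
  ntip <- length(tree$tip.label)
  focal <- config$focal_species
  focal_tip <- match(focal, tree$tip.label)

  # resolve gain events to nodes and clades
  events <- config$gain_events
  intronization_events <- Filter(function(e) e$mechanism == "intronization",
                                 events)
  ev_meta <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    node <- if (length(ev$clade) == 1L) {
      match(ev$clade, tree$tip.label)
    } else {
      ape::getMRCA(tree, ev$clade)
    }
    leaves <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (!focal %in% leaves) {
      stop("invalid-config: gain clade for event ", i,
           " does not contain the focal species ", focal)
    }
    c0 <- 3L * (ev$at - 1L) + ev$phase
    ev_meta[[i]] <- list(id = paste0("gain", i), node = node, leaves = leaves,
                         c0 = c0, event = ev)
  }

  anc <- .ancestral_cds(L, intronization_events)
  protected_res <- sort(unique(.codon_of_nt(anc$forced_nt)))

  # segments (0-based half-open nt ranges) excised by intronization events
  seg_ranges <- lapply(ev_meta, function(m) {
    if (m$event$mechanism != "intronization") return(NULL)
    c(m$c0, m$c0 + m$event$intron_length)
  })

  inside_segment <- function(c0, buffer = 9L) {
    for (sr in seg_ranges) {
      if (!is.null(sr) && c0 > sr[1] - buffer && c0 < sr[2] + buffer) {
        return(TRUE)
      }
    }
    FALSE
  }

  # ancestral introns: distinct offsets, clear of gain offsets and segments
  gain_offsets <- vapply(ev_meta, function(m) m$c0, integer(1))
  if (length(gain_offsets) == 0L) gain_offsets <- integer(0)
  if (!is.null(config$ancestral_intron_offsets)) {
    anc_offsets <- sort(config$ancestral_intron_offsets)
    if (any(vapply(anc_offsets, inside_segment, logical(1))) ||
        any(anc_offsets %in% gain_offsets)) {
      stop("invalid-config: ancestral intron offset collides with a ",
           "planted gain")
    }
  } else {
    anc_offsets <- integer(0)
    cand <- setdiff(seq(3L, 3L * L - 3L), gain_offsets)
    guard <- function(c0, chosen) {
      all(abs(c0 - c(chosen, gain_offsets)) >= 9L) && !inside_segment(c0)
    }
    tries <- 0L
    while (length(anc_offsets) < config$n_ancestral_introns &&
             tries < 10000L) {
      c0 <- sample(cand, 1L)
      if (guard(c0, anc_offsets)) anc_offsets <- c(anc_offsets, c0)
      tries <- tries + 1L
    }
    if (length(anc_offsets) < config$n_ancestral_introns) {
      stop("invalid-config: could not place ancestral introns")
    }
    anc_offsets <- sort(anc_offsets)
  }

  lr <- config$intron_length_range
  root_introns <- list()
  for (i in seq_along(anc_offsets)) {
    len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
    root_introns[[paste0("anc", i)]] <-
      list(id = paste0("anc", i), c0 = anc_offsets[i], len = len,
           seq = .random_intron_seq(len), present = TRUE,
           mechanism = "ancestral")
  }

  root_state <- list(codons = anc$codons, aa = anc$aa,
                     introns = root_introns,
                     excised = stats::setNames(
                       rep(FALSE, length(ev_meta)),
                       vapply(ev_meta, `[[`, "", "id")))

  # edges protected from loss: planted gains on the gain-node -> focal path
  focal_line <- c(focal_tip, phangorn::Ancestors(tree, focal_tip, "all"))
  protected_loss <- list()  # intron id -> protected child nodes
  for (m in ev_meta) {
    desc <- c(m$node, unlist(phangorn::Descendants(tree, m$node, "all")))
    if (m$node <= ntip) desc <- m$node
    protected_loss[[m$id]] <- intersect(focal_line, desc)
  }

  children <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- stats::setNames(tree$edge.length,
                          paste(tree$edge[, 1], tree$edge[, 2]))

  excised_res_of <- function(state) {
    res <- integer(0)
    for (i in seq_along(ev_meta)) {
      if (state$excised[[ev_meta[[i]]$id]]) {
        sr <- seg_ranges[[i]]
        res <- c(res, .codon_of_nt(sr[1] + 1L):.codon_of_nt(sr[2]))
      }
    }
    res
  }

  evolve_branch <- function(state, t, child) {
    p <- 1 - exp(-config$substitution_rate * t)
    if (p > 0) {
      frozen <- unique(c(protected_res, excised_res_of(state)))
      eligible <- setdiff(seq_len(L), frozen)
      hit <- eligible[stats::runif(length(eligible)) < p]
      bg <- aa_background()
      for (q in hit) {
        cur <- state$aa[q]
        w <- bg[names(bg) != cur]
        new_aa <- sample(names(w), 1L, prob = w)
        state$aa[q] <- new_aa
        state$codons[q] <- .random_codon(new_aa)
      }
      for (id in names(state$introns)) {
        if (state$introns[[id]]$present) {
          state$introns[[id]]$seq <-
            .evolve_intron_seq(state$introns[[id]]$seq, p)
        }
      }
    }
    # losses
    for (id in names(state$introns)) {
      if (!state$introns[[id]]$present) next
      prot <- protected_loss[[id]]
      if (!is.null(prot) && child %in% prot) next
      if (stats::runif(1L) < config$loss_rate) {
        state$introns[[id]]$present <- FALSE
      }
    }
    # gains placed at this node
    for (i in seq_along(ev_meta)) {
      m <- ev_meta[[i]]
      if (m$node != child) next
      ev <- m$event
      if (ev$mechanism == "generic") {
        state$introns[[m$id]] <- list(id = m$id, c0 = m$c0,
                                      len = ev$intron_length,
                                      seq = .random_intron_seq(ev$intron_length),
                                      present = TRUE, mechanism = "generic")
      } else {
        sr <- seg_ranges[[i]]
        nt <- unlist(strsplit(state$codons, "", fixed = TRUE),
                     use.names = FALSE)
        state$introns[[m$id]] <- list(id = m$id, c0 = m$c0,
                                      len = ev$intron_length,
                                      seq = paste(nt[(sr[1] + 1L):sr[2]],
                                                  collapse = ""),
                                      present = TRUE,
                                      mechanism = "intronization")
        state$excised[[m$id]] <- TRUE
      }
    }
    state
  }

  tip_states <- vector("list", ntip)
  paralog_states <- vector("list", ntip)
  walk <- function(node, state) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {
      tip_states[[node]] <<- state
      if (config$paralog_rate > 0 && stats::runif(1L) < config$paralog_rate) {
        # duplicate evolved independently from the parent state over the
        # terminal branch, plus two extra branches of divergence so the
        # decoy is clearly further from the query than the true ortholog
        t <- attr(state, "terminal_t")
        ps <- attr(state, "parent_state")
        dup <- evolve_branch(ps, t, -1L)  # -1: never a gain node
        dup <- evolve_branch(dup, t, -1L)
        dup <- evolve_branch(dup, t, -1L)
        paralog_states[[node]] <<- dup
      }
      return(invisible())
    }
    for (k in kids) {
      st <- evolve_branch(state, elen[[paste(node, k)]], k)
      attr(st, "terminal_t") <- elen[[paste(node, k)]]
      attr(st, "parent_state") <- state
      walk(k, st)
    }
  }
  walk(ntip + 1L, root_state)

  # ---- emission -------------------------------------------------------------
  genomes <- character(0)
  models <- list()
  proteins <- character(0)
  species_map <- character(0)
  marks_by_acc <- list()
  status <- list()     # accession -> named status vector over intron ids
  all_ids <- c(names(root_introns), vapply(ev_meta, `[[`, "", "id"))

  emit <- function(state, sp, acc, contig) {
    excised_ids <- names(state$excised)[unlist(state$excised)]
    ex_ranges <- list()
    for (i in seq_along(ev_meta)) {
      if (ev_meta[[i]]$id %in% excised_ids) {
        ex_ranges[[length(ex_ranges) + 1L]] <- seg_ranges[[i]]
      }
    }
    nt <- unlist(strsplit(state$codons, "", fixed = TRUE), use.names = FALSE)
    keep <- rep(TRUE, length(nt))
    for (sr in ex_ranges) keep[(sr[1] + 1L):sr[2]] <- FALSE
    cds <- paste(c(nt[keep], "T", "A", "A"), collapse = "")
    protein <- translate_cds(cds)

    shift <- function(c0) {
      d <- 0L
      for (sr in ex_ranges) if (sr[2] <= c0) d <- d + (sr[2] - sr[1])
      c0 - d
    }
    pres <- Filter(function(x) x$present, state$introns)
    ord <- order(vapply(pres, function(x) shift(x$c0), integer(1)))
    pres <- pres[ord]

    # genomic assembly on the plus strand first
    flank1 <- .random_dna(config$flank_length)
    flank2 <- .random_dna(config$flank_length)
    offs <- vapply(pres, function(x) shift(x$c0), integer(1))
    seqs <- vapply(pres, function(x) x$seq, "")
    bounds <- c(0L, offs, nchar(cds))
    pieces <- character(0)
    exon_nt <- integer(0)
    for (i in seq_len(length(offs) + 1L)) {
      exon_nt <- c(exon_nt, bounds[i + 1L] - bounds[i])
      pieces <- c(pieces, substr(cds, bounds[i] + 1L, bounds[i + 1L]))
      if (i <= length(offs)) pieces <- c(pieces, seqs[i])
    }
    gene_seq <- paste(pieces, collapse = "")
    contig_seq <- paste0(flank1, gene_seq, flank2)

    # exon intervals on the plus strand
    pos <- config$flank_length
    ex <- matrix(integer(0), ncol = 2)
    for (i in seq_along(exon_nt)) {
      ex <- rbind(ex, c(pos, pos + exon_nt[i]))
      pos <- pos + exon_nt[i]
      if (i <= length(offs)) pos <- pos + nchar(seqs[i])
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      G <- nchar(contig_seq)
      contig_seq <- revcomp(contig_seq)
      ex <- cbind(G - ex[, 2], G - ex[, 1])  # still transcription order
    }
    model <- gene_model(species = sp, gene_id = paste0("gene_", acc),
                        transcript_id = acc, chrom = contig, strand = strand,
                        exons = ex, cds = ex)

    genomes[[contig]] <<- contig_seq
    models[[acc]] <<- model
    proteins[[acc]] <<- protein
    species_map[[acc]] <<- sp

    marks_by_acc[[acc]] <<- data.frame(
      intron_id = vapply(pres, `[[`, "", "id"),
      ordinal = seq_along(pres),
      coding_offset = offs,
      protein_index = offs %/% 3L + 1L,
      phase = offs %% 3L,
      intron_length = vapply(pres, function(x) nchar(x$seq), integer(1)),
      row.names = NULL)

    st <- stats::setNames(rep("absent", length(all_ids)), all_ids)
    for (id in names(state$introns)) {
      st[[id]] <- if (state$introns[[id]]$present) "present" else "lost"
    }
    status[[acc]] <<- st
  }

  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    emit(tip_states[[i]], sp, paste0(sp, "_g1"), paste0("chr_", sp))
    if (!is.null(paralog_states[[i]])) {
      emit(paralog_states[[i]], sp, paste0(sp, "_p1"), paste0("chr_", sp, "_p"))
    }
  }

  focal_acc <- paste0(focal, "_g1")
  focal_marks <- marks_by_acc[[focal_acc]]

  ev_rows <- list()
  add_row <- function(id, mech, leaves, c0, len, frame) {
    ord <- focal_marks$ordinal[match(id, focal_marks$intron_id)]
    ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
      intron_id = id, gene = focal_acc, mechanism = mech,
      clade_leaves = paste(leaves, collapse = ","),
      coding_offset = c0, intron_length = len,
      frame = frame, focal_ordinal = if (is.na(ord)) NA_integer_ else ord)
  }
  for (intr in root_introns) {
    add_row(intr$id, "ancestral", tree$tip.label, intr$c0, intr$len,
            NA_integer_)
  }
  for (m in ev_meta) {
    frame <- if (m$event$mechanism == "intronization") {
      (3L - m$c0 %% 3L) %% 3L
    } else NA_integer_
    add_row(m$id, m$event$mechanism, m$leaves, m$c0, m$event$intron_length,
            frame)
  }
  events_df <- do.call(rbind, ev_rows)

  pmat <- do.call(rbind, status)
  paralog_acc <- grep("_p1$", names(models), value = TRUE)
  paralogs_df <- data.frame(
    species = unname(species_map[paralog_acc]),
    accession = paralog_acc,
    introns_present = vapply(paralog_acc, function(a) {
      paste(names(which(status[[a]] == "present")), collapse = ",")
    }, ""),
    row.names = NULL)

  family <- structure(list(tree = tree, focal_species = focal,
                           focal_accession = focal_acc, models = models,
                           proteins = proteins, species_map = species_map,
                           genomes = genomes, config = config),
                      class = "sim_family")
  truth <- structure(list(events = events_df, status = pmat,
                          marks = marks_by_acc, paralogs = paralogs_df,
                          config = config),
                     class = "sim_truth")
  list(family = family, truth = truth)
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %d species (focal %s), %d gene(s), %d contig(s)\n",
              length(x$tree$tip.label), x$focal_species, length(x$models),
              length(x$genomes)))
  invisible(x)
}

#' Genomic DNA of one intron of a simulated (or parsed) gene
#'
#' @param family A `sim_family` (or any list with `models` and `genomes`).
#' @param accession Gene accession.
#' @param ordinal 1-based intron ordinal in transcription order.
#' @return Character scalar, the intron sequence in transcript orientation.
#' @export
intron_dna <- function(family, accession, ordinal) {
  model <- family$models[[accession]]
  if (is.null(model)) stop("intron_dna: unknown accession ", accession)
  mk <- intron_marks(model)
  if (!ordinal %in% mk$ordinal) {
    stop("intron_dna: intron ordinal ", ordinal, " not found in ", accession)
  }
  row <- mk[mk$ordinal == ordinal, ]
  g <- family$genomes[[model$chrom]]
  s <- substr(g, row$start + 1L, row$end)
  if (model$strand == "-") revcomp(s) else s
}

# ---- fixture writing -------------------------------------------------------

.write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gs <- min(m$exons[, 1]) + 1L
    ge <- max(m$exons[, 2])
    lines <- c(lines, paste(m$chrom, "introgain", "gene", gs, ge, ".",
                            m$strand, ".", paste0("ID=", m$gene_id),
                            sep = "\t"))
    lines <- c(lines, paste(m$chrom, "introgain", "mRNA", gs, ge, ".",
                            m$strand, ".",
                            paste0("ID=", m$transcript_id, ";Parent=",
                                   m$gene_id),
                            sep = "\t"))
    for (i in seq_len(nrow(m$exons))) {
      e <- m$exons[i, ]
      lines <- c(lines, paste(m$chrom, "introgain", "exon", e[1] + 1L, e[2],
                              ".", m$strand, ".",
                              paste0("ID=", m$transcript_id, ".exon", i,
                                     ";Parent=", m$transcript_id),
                              sep = "\t"))
    }
    cum <- 0L
    for (i in seq_len(nrow(m$cds))) {
      e <- m$cds[i, ]
      phase <- (3L - cum %% 3L) %% 3L
      lines <- c(lines, paste(m$chrom, "introgain", "CDS", e[1] + 1L, e[2],
                              ".", m$strand, phase,
                              paste0("ID=", m$transcript_id, ".cds",
                                     ";Parent=", m$transcript_id),
                              sep = "\t"))
      cum <- cum + (e[2] - e[1])
    }
  }
  writeLines(lines, path)
}

.write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
}

#' Write a simulated family and its truth tables to disk
#'
#' Writes `proteins.faa`, `species_map.tsv`, one `genome_<species>.fa` and
#' `annot_<species>.gff3` per species, `tree.nwk` and `truth.tsv` into
#' `directory`.  The files round-trip through [parse_gff()] and the FASTA
#' readers.
#'
#' @param family A `sim_family`.
#' @param truth The matching `sim_truth`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_fixtures <- function(family, truth, directory) {
  if (length(family$models) == 0L) {
    stop("write_fixtures: empty family")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_fixtures: cannot create directory ", directory)
  }
  files <- character(0)
  p <- file.path(directory, "proteins.faa")
  .write_fasta(family$proteins, p, "AA")
  files <- c(files, p)

  p <- file.path(directory, "species_map.tsv")
  utils::write.table(
    data.frame(accession = names(family$species_map),
               species = unname(family$species_map)),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)

  species <- unique(unname(family$species_map))
  for (sp in species) {
    accs <- names(family$species_map)[family$species_map == sp]
    contigs <- unique(vapply(family$models[accs], `[[`, "", "chrom"))
    p <- file.path(directory, paste0("genome_", sp, ".fa"))
    .write_fasta(family$genomes[contigs], p, "DNA")
    files <- c(files, p)
    p <- file.path(directory, paste0("annot_", sp, ".gff3"))
    .write_gff3(family$models[accs], p)
    files <- c(files, p)
  }

  p <- file.path(directory, "tree.nwk")
  ape::write.tree(family$tree, p)
  files <- c(files, p)

  p <- file.path(directory, "truth.tsv")
  ev <- truth$events
  utils::write.table(
    data.frame(gene = ev$gene, intron_ordinal = ev$focal_ordinal,
               clade_leaves = ev$clade_leaves, mechanism = ev$mechanism,
               intron_length = ev$intron_length),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  invisible(files)
}
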