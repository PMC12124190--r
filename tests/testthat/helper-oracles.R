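# Independent oracles used by the test suite.

# Brute-force search of the best gain clade: enumerate EVERY node of the
# tree (tips included), keep those whose leaf set contains the focal
# species, score R - B directly, break ties toward the smallest clade.
brute_force_gain_clade <- function(tree, presence, focal) {
  ntip <- length(tree$tip.label)
  best <- NULL
  for (nd in seq_len(ntip + tree$Nnode)) {
    leaves <- if (nd <= ntip) tree$tip.label[nd] else {
      tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
    }
    if (!focal %in% leaves) next
    st <- presence[names(presence) %in% leaves]
    sc <- 1L + sum(st == "present") - sum(st == "absent")
    if (is.null(best) || sc > best$score ||
        (sc == best$score && length(leaves) < length(best$leaves))) {
      best <- list(node = nd, leaves = leaves, score = sc,
                   R = 1L + sum(st == "present"), B = sum(st == "absent"))
    }
  }
  best
}

# Random rooted tree on n leaves, sometimes multifurcating (random internal
# branches collapsed to zero length and removed).
random_test_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("sp", seq_len(n))
  if (n > 3 && stats::runif(1) < 0.5) {
    internal <- which(tr$edge[, 2] > n)
    k <- sample(seq_along(internal), size = min(2L, length(internal)))
    tr$edge.length[internal[k]] <- 0
    tr <- ape::di2multi(tr)
  }
  tr
}

# Plain-R affine-gap global alignment score (full three-matrix recursion,
# computed independently of the compiled aligner).
oracle_global_affine_score <- function(a, b, open = 11, ext = 1) {
  m <- blosum62x()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  NEG <- -Inf
  H <- matrix(NEG, la + 1, lb + 1)
  E <- matrix(NEG, la + 1, lb + 1)
  F_ <- matrix(NEG, la + 1, lb + 1)
  H[1, 1] <- 0
  for (j in 2:(lb + 1)) E[1, j] <- H[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(la + 1)) F_[i, 1] <- H[i, 1] <- -(open + (i - 1) * ext)
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      H[i, j] <- max(H[i - 1, j - 1] + m[av[i - 1], bv[j - 1]],
                     E[i, j], F_[i, j])
    }
  }
  H[la + 1, lb + 1]
}

# Marking oracle: rebuild the marked protein by walking the CDS exon
# pieces codon by codon, emitting an X wherever an intron interrupts the
# codon stream.  Takes the nucleotide lengths of the CDS pieces between
# introns and the translated protein.
oracle_marked_from_pieces <- function(protein, piece_nt) {
  res <- character(0)
  aa <- strsplit(protein, "")[[1]]
  consumed <- 0
  ri <- 1
  for (p in seq_along(piece_nt)) {
    consumed <- consumed + piece_nt[p]
    if (p < length(piece_nt)) {
      # intron after this piece: X goes left of the residue whose codon
      # contains (or follows) coding position `consumed`
      idx <- consumed %/% 3 + 1
      while (ri < idx && ri <= length(aa)) {
        res <- c(res, aa[ri]); ri <- ri + 1
      }
      res <- c(res, "X")
    }
  }
  while (ri <= length(aa)) { res <- c(res, aa[ri]); ri <- ri + 1 }
  paste(res, collapse = "")
}

# A tiny hand-checkable family shared by several tests: 6 species, fixed
# topology, one generic gain in the {spE,spF} clade, no noise.
toy_family <- function(seed = 1, loss_rate = 0, substitution_rate = 0,
                       gain_clade = c("spE", "spF"), focal = "spF",
                       mechanism = "generic", intron_length = 90,
                       at = 60, paralog_rate = 0, phase = 0L) {
  cfg <- sim_config(
    n_species = 6, birth_model = "fixed-topology",
    topology = "((spA:1,spB:1):1,(spC:1.5,(spD:1,(spE:0.5,spF:0.5):0.5):0.5):0.5);",
    focal_species = focal, n_ancestral_introns = 3,
    gain_events = list(gain_event(gain_clade, at = at, mechanism = mechanism,
                                  intron_length = intron_length,
                                  phase = phase)),
    loss_rate = loss_rate, substitution_rate = substitution_rate,
    paralog_rate = paralog_rate, protein_length = 150, seed = seed)
  tr <- simulate_taxonomy(cfg)
  out <- simulate_gene_family(tr, cfg)
  out$tree <- tr
  out$config <- cfg
  out
}

# pick, deterministically from the current RNG stream, an ancestor clade of
# the focal species with size within [lo, hi]; returns its leaf labels
pick_focal_clade <- function(tree, focal, lo = 4, hi = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(hi)) hi <- ntip - 3
  tipn <- match(focal, tree$tip.label)
  anc <- phangorn::Ancestors(tree, tipn, "all")
  sizes <- vapply(anc, function(nd) {
    length(phangorn::Descendants(tree, nd, "tips")[[1]])
  }, integer(1))
  ok <- anc[sizes >= lo & sizes <= hi]
  if (length(ok) == 0L) ok <- anc[which.min(abs(sizes - lo))]
  nd <- if (length(ok) == 1L) ok else sample(ok, 1)
  tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
}
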