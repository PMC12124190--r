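# Gene-family simulator: configuration validation, taxonomy simulation,
# planted events, and file round-trips.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_species = 1), "invalid-config")
  expect_error(sim_config(loss_rate = 1.5), "invalid-config")
  expect_error(sim_config(paralog_rate = -0.1), "invalid-config")
  expect_error(gain_event("spA", at = 10, mechanism = "intronization",
                          intron_length = 91),
               "multiple of 3")
  expect_error(sim_config(gain_events = list(gain_event("spA", at = 1))),
               "outside the ancestral protein")
  expect_error(
    sim_config(protein_length = 100,
               gain_events = list(gain_event("spA", at = 95,
                                             mechanism = "intronization",
                                             intron_length = 90))),
    "beyond the ancestral protein")
})

test_that("taxonomy simulation: smallest tree, fixed topology, determinism", {
  cherry <- simulate_taxonomy(sim_config(n_species = 2, seed = 1))
  expect_s3_class(cherry, "phylo")
  expect_setequal(cherry$tip.label, c("sp1", "sp2"))
  expect_true(all(cherry$edge.length > 0))

  topo <- "((A,B),(C,(D,(E,F))));"
  cfg <- sim_config(n_species = 6, birth_model = "fixed-topology",
                    topology = topo, focal_species = "F", seed = 5)
  tr <- simulate_taxonomy(cfg)
  ref <- ape::read.tree(text = topo)
  expect_equal(phangorn::RF.dist(tr, ref), 0)
  expect_setequal(tr$tip.label, LETTERS[1:6])

  cfg2 <- sim_config(n_species = 9, seed = 42)
  t1 <- simulate_taxonomy(cfg2)
  t2 <- simulate_taxonomy(cfg2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # unit depth, positive ages at internal nodes
  expect_equal(max(ape::node.depth.edgelength(t1)), 1)
})

test_that("no-noise generic gain adds one intron in the gain clade only", {
  out <- toy_family(seed = 2)
  fam <- out$family
  n_introns <- vapply(paste0("sp", LETTERS[1:6], "_g1"), function(a) {
    nrow(intron_marks(fam$models[[a]]))
  }, integer(1))
  expect_equal(unname(n_introns), c(3, 3, 3, 3, 4, 4))
  # with no substitutions, proteins are identical (generic gain does not
  # touch the protein)
  expect_length(unique(unname(fam$proteins)), 1L)
})

test_that("intronization shortens carriers by length/3 with the removed
          codons inside the new intron", {
  out <- toy_family(seed = 3, gain_clade = "spF", mechanism = "intronization",
                    intron_length = 90, at = 70)
  fam <- out$family
  focal <- fam$proteins[["spF_g1"]]
  outg <- fam$proteins[["spA_g1"]]
  expect_equal(nchar(outg) - nchar(focal), 30)
  ord <- out$truth$events$focal_ordinal[
    out$truth$events$mechanism == "intronization"]
  dna <- intron_dna(fam, "spF_g1", ord)
  expect_equal(nchar(dna), 90)
  # translated in its original frame, the intron reproduces the outgroup's
  # extra residues exactly at substitution rate zero
  frame <- out$truth$events$frame[out$truth$events$mechanism ==
                                    "intronization"]
  pep <- translate_intron_frames(dna)[frame + 1]
  expect_equal(pep, substr(outg, 70, 99))
})

test_that("emitted genes are internally consistent and introns canonical", {
  for (seed in 1:5) {
    out <- toy_family(seed = seed, loss_rate = 0.05,
                      substitution_rate = 0.15, paralog_rate = 0.5)
    fam <- out$family
    for (acc in names(fam$models)) {
      m <- fam$models[[acc]]
      cds <- splice_cds(fam$genomes[[m$chrom]], m)
      expect_identical(translate_cds(cds), fam$proteins[[acc]])
      mk <- intron_marks(m)
      for (i in seq_len(nrow(mk))) {
        d <- intron_dna(fam, acc, i)
        expect_identical(substr(d, 1, 2), "GT")
        expect_identical(substr(d, nchar(d) - 1, nchar(d)), "AG")
      }
    }
  }
})

test_that("identical configuration and seed reproduce identical fixtures", {
  d1 <- file.path(tempdir(), "fixt1")
  d2 <- file.path(tempdir(), "fixt2")
  for (d in c(d1, d2)) {
    out <- toy_family(seed = 9, substitution_rate = 0.1, loss_rate = 0.05)
    write_fixtures(out$family, out$truth, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("fixtures round-trip through the package readers", {
  out <- toy_family(seed = 4, substitution_rate = 0.1)
  fam <- out$family
  d <- file.path(tempdir(), "fixt_rt")
  files <- write_fixtures(fam, out$truth, d)
  expect_true(all(file.exists(files)))

  prots <- Biostrings::readAAStringSet(file.path(d, "proteins.faa"))
  expect_identical(as.character(prots)[names(fam$proteins)], fam$proteins)

  tr <- ape::read.tree(file.path(d, "tree.nwk"))
  expect_equal(phangorn::RF.dist(tr, fam$tree), 0)

  for (sp in unique(unname(fam$species_map))) {
    models <- parse_gff(file.path(d, paste0("annot_", sp, ".gff3")),
                        species = sp)
    for (acc in names(models)) {
      orig <- fam$models[[acc]]
      expect_identical(models[[acc]]$exons, orig$exons, info = acc)
      expect_identical(models[[acc]]$cds, orig$cds, info = acc)
      expect_identical(models[[acc]]$strand, orig$strand, info = acc)
      expect_identical(models[[acc]]$chrom, orig$chrom, info = acc)
    }
  }
  unlink(d, recursive = TRUE)
})

test_that("an empty family refuses to write fixtures", {
  fam <- structure(list(models = list()), class = "sim_family")
  d <- file.path(tempdir(), "fixt_empty")
  expect_error(write_fixtures(fam, NULL, d), "empty family")
  expect_false(dir.exists(d))
})
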