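# Clade scoring on the taxonomy and the candidate filters.

six_tree <- ape::read.tree(text = "((A:1,B:1):2,(C:2,(D:1.2,(E:0.6,F:0.6):0.6):0.8):1);")

test_that("best gain clade maximizes R - B (hand case and degenerate cases)", {
  pres <- c(A = "absent", B = "absent", C = "absent",
            D = "present", E = "present")
  ev <- best_gain_clade(six_tree, pres, "F")
  expect_setequal(ev$clade_leaves, c("D", "E", "F"))
  expect_equal(c(ev$R, ev$B, ev$score), c(3, 0, 3))
  oracle <- brute_force_gain_clade(six_tree, pres, "F")
  expect_equal(ev$score, oracle$score)
  expect_setequal(ev$clade_leaves, oracle$leaves)

  # all present: the root clade
  all_p <- setNames(rep("present", 5), c("A", "B", "C", "D", "E"))
  ev2 <- best_gain_clade(six_tree, all_p, "F")
  expect_setequal(ev2$clade_leaves, LETTERS[1:6])
  expect_equal(c(ev2$R, ev2$B), c(6, 0))

  # only focal present: the leaf clade wins via the smallest-clade tie-break
  none <- setNames(rep("absent", 5), c("A", "B", "C", "D", "E"))
  ev3 <- best_gain_clade(six_tree, none, "F")
  expect_equal(ev3$clade_leaves, "F")
  expect_equal(c(ev3$R, ev3$B, ev3$score), c(1, 0, 1))

  expect_error(best_gain_clade(six_tree, pres, "Z"), "not in tree")
})

test_that("clade search equals brute-force enumeration on random trees", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tr <- random_test_tree(n)
    others <- setdiff(tr$tip.label, "sp1")
    covered <- sample(others, sample(seq_along(others), 1))
    pres <- setNames(sample(c("present", "absent", "uncovered"),
                            length(covered), replace = TRUE,
                            prob = c(0.4, 0.4, 0.2)), covered)
    ev <- best_gain_clade(tr, pres, "sp1")
    oracle <- brute_force_gain_clade(tr, pres, "sp1")
    expect_equal(ev$score, oracle$score)
    expect_setequal(ev$clade_leaves, oracle$leaves)
  }
})

test_that("flipping an absent in-clade leaf to present never lowers the
          optimum", {
  set.seed(37)
  for (rep in 1:20) {
    tr <- random_test_tree(8)
    others <- setdiff(tr$tip.label, "sp1")
    pres <- setNames(sample(c("present", "absent"), length(others),
                            replace = TRUE), others)
    ev <- best_gain_clade(tr, pres, "sp1")
    inside_absent <- intersect(names(pres)[pres == "absent"],
                               ev$clade_leaves)
    for (sp in inside_absent) {
      flipped <- pres
      flipped[sp] <- "present"
      expect_gte(best_gain_clade(tr, flipped, "sp1")$score, ev$score)
    }
  }
})

test_that("the 70% unaligned filter uses >= and counts uncovered in the
          denominator only", {
  pres7 <- setNames(c(rep("absent", 7), rep("present", 3)),
                    paste0("s", 1:10))
  pres6 <- setNames(c(rep("absent", 6), rep("present", 4)),
                    paste0("s", 1:10))
  tr <- ape::read.tree(text = paste0("(", paste(c(paste0("s", 1:10), "foc"),
                                                collapse = ","), ");"))
  ev <- best_gain_clade(tr, pres7, "foc")
  expect_true(apply_70pct_filter(ev)$flags$passed_70pct)
  ev6 <- best_gain_clade(tr, pres6, "foc")
  expect_false(apply_70pct_filter(ev6)$flags$passed_70pct)

  # uncovered counts in the denominator, not the numerator: 7 absent,
  # 2 uncovered, 1 present -> 7/10 passes
  presu <- setNames(c(rep("absent", 7), rep("uncovered", 2), "present"),
                    paste0("s", 1:10))
  evu <- best_gain_clade(tr, presu, "foc")
  expect_true(apply_70pct_filter(evu)$flags$passed_70pct)
  expect_equal(evu$fraction_unaligned, NA_real_)  # set by the filter only
  expect_equal(apply_70pct_filter(evu)$fraction_unaligned, 0.7)

  # no orthologs at all: rejected with a logged reason
  ev0 <- best_gain_clade(tr, setNames(character(0), character(0)), "foc")
  ev0 <- apply_70pct_filter(ev0)
  expect_false(ev0$flags$passed_70pct)
  expect_match(ev0$flags$rejected_reason, "no orthologs")
})

test_that("boundary exclusion triggers above, and only above, the cutoff", {
  tr <- six_tree
  # clade will be {F}; all non-clade species uncovered -> excluded
  pres <- setNames(rep("uncovered", 5), c("A", "B", "C", "D", "E"))
  ev <- apply_boundary_filter(best_gain_clade(tr, pres, "F"))
  expect_true(ev$flags$boundary_excluded)

  # no uncovered species: retained
  pres2 <- setNames(rep("absent", 5), c("A", "B", "C", "D", "E"))
  ev2 <- apply_boundary_filter(best_gain_clade(tr, pres2, "F"))
  expect_false(ev2$flags$boundary_excluded)

  # exactly at the cutoff (2 of 4 non-clade species uncovered): retained
  pres3 <- c(A = "uncovered", B = "uncovered", C = "absent", D = "absent",
             E = "present")
  ev3 <- best_gain_clade(tr, pres3, "F")
  expect_setequal(ev3$clade_leaves, c("E", "F"))
  ev3 <- apply_boundary_filter(ev3)
  expect_false(ev3$flags$boundary_excluded)
})

test_that("paralog rescue flips absences, recomputes, and is idempotent", {
  pres <- c(A = "absent", B = "absent", C = "absent",
            D = "absent", E = "present")
  ev <- apply_70pct_filter(best_gain_clade(six_tree, pres, "F"))
  expect_setequal(ev$clade_leaves, c("E", "F"))
  expect_equal(c(ev$R, ev$B), c(2, 0))

  # D's paralog carries the intron: inside the enlarged clade B drops, R rises
  lk <- c(D = "has")
  ev2 <- paralog_rescue(ev, lk, six_tree, "F")
  expect_setequal(ev2$clade_leaves, c("D", "E", "F"))
  expect_equal(c(ev2$R, ev2$B), c(3, 0))
  expect_equal(ev2$flags$paralog_rescued, "D")
  # idempotent
  ev3 <- paralog_rescue(ev2, lk, six_tree, "F")
  expect_equal(c(ev3$R, ev3$B, ev3$score), c(ev2$R, ev2$B, ev2$score))
  expect_setequal(ev3$clade_leaves, ev2$clade_leaves)

  # rescue can push the absent fraction below the threshold
  pres4 <- c(A = "absent", B = "absent", C = "absent", D = "absent")
  ev4 <- apply_70pct_filter(best_gain_clade(six_tree, pres4, "F"))
  expect_true(ev4$flags$passed_70pct)
  ev5 <- paralog_rescue(ev4, c(A = "has", B = "has"), six_tree, "F")
  expect_false(ev5$flags$passed_70pct)

  # no paralogs anywhere: unchanged
  ev6 <- paralog_rescue(ev, c(D = "lacks", A = "unknown"), six_tree, "F")
  expect_equal(ev6$score, ev$score)
  expect_length(ev6$flags$paralog_rescued, 0)
})

test_that("intron retention is flagged when any transcript exon spans the
          intron", {
  t1 <- gene_model("s", "g", "t1", "c", "+",
                   exons = rbind(c(0, 30), c(60, 90)),
                   cds = rbind(c(0, 30), c(60, 90)))
  t2 <- gene_model("s", "g", "t2", "c", "+",
                   exons = rbind(c(0, 90)), cds = rbind(c(0, 90)))
  expect_true(check_intron_retention(list(t2), 30, 60))
  expect_false(check_intron_retention(list(t1), 30, 60))
  expect_false(check_intron_retention(list(), 30, 60))
})

test_that("the pipeline recovers a planted gain and filters widespread
          introns", {
  out <- toy_family(seed = 21)
  res <- run_gain_pipeline(out$family)
  expect_length(res$events, 1L)
  ev <- res$events[[1]]
  truth <- out$truth$events[out$truth$events$mechanism == "generic", ]
  expect_equal(ev$ordinal, truth$focal_ordinal)
  expect_setequal(ev$clade_leaves,
                  strsplit(truth$clade_leaves, ",")[[1]])
  # ancestral introns are present everywhere and must not be reported
  anc_rows <- res$candidates[res$candidates$intron_ordinal != truth$focal_ordinal, ]
  expect_true(all(!anc_rows$accepted))
  expect_true(all(anc_rows$fraction_unaligned == 0))
})

test_that("an intron present in most species fails the 70% rule", {
  # gain planted at a clade covering 4 of 6 species: absent fraction 2/5
  out <- toy_family(seed = 22, gain_clade = c("spC", "spF"))
  res <- run_gain_pipeline(out$family)
  expect_length(res$events, 0L)
  expect_true(any(grepl("absent in", res$log$detail)))
})

test_that("paralog rescue changes the outcome on a constructed family", {
  # ortholog of spE loses the gained intron but a paralog keeps it
  found <- FALSE
  for (seed in 1:40) {
    out <- toy_family(seed = seed, loss_rate = 0.35, paralog_rate = 1)
    truth <- out$truth
    gid <- "gain1"
    st <- truth$status
    lost_sp <- rownames(st)[st[, gid] == "lost" & grepl("_g1$", rownames(st))]
    kept_para <- rownames(st)[st[, gid] == "present" &
                                grepl("_p1$", rownames(st))]
    lost_sp <- sub("_g1", "", lost_sp)
    kept_para <- sub("_p1", "", kept_para)
    hit <- intersect(lost_sp, kept_para)
    if (length(hit) == 0) next
    found <- TRUE
    res_on <- run_gain_pipeline(out$family, rescue_paralogs = TRUE)
    cand <- res_on$candidates
    grow <- cand[cand$intron_ordinal ==
                   truth$events$focal_ordinal[truth$events$intron_id == gid], ]
    expect_true(any(nzchar(grow$paralog_rescued)))
    break
  }
  expect_true(found)
})
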