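# Synthetic generator: template arithmetic, determinism, parameter
# semantics, and the semantics of planted histories.

test_that("taxonomy counts follow the template and degenerate input errors", {
  sc <- synthetic_scenario(seed = 1, n_families = 2,
                           genera_per_family = c(2, 2),
                           species_per_genus = c(3, 3))
  tax <- generate_taxonomy(sc)
  expect_identical(nrow(tax$table), 1L + 2L + 4L + 12L)
  expect_identical(sum(tax$table$rank == "species"), 12L)
  expect_error(synthetic_scenario(n_families = 0), "n_families")
})

test_that("the generator is deterministic in the seed", {
  sc <- synthetic_scenario(seed = 77)
  t1 <- generate_taxonomy(sc); t2 <- generate_taxonomy(sc)
  expect_identical(t1$table, t2$table)
  tr1 <- generate_tree(t1, sc); tr2 <- generate_tree(t2, sc)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  g <- generate_anatomy_template()
  th1 <- plant_trait_history(tr1, sc); th2 <- plant_trait_history(tr2, sc)
  expect_identical(th1$characters, th2$characters)
  a1 <- generate_annotations(th1, t1, g, sc)
  a2 <- generate_annotations(th2, t2, g, sc)
  expect_identical(a1, a2)
  # a different seed gives a different tree
  sc2 <- synthetic_scenario(seed = 78)
  expect_false(identical(ape::write.tree(tr1),
                         ape::write.tree(generate_tree(generate_taxonomy(sc2),
                                                       sc2))))
})

test_that("cross-reference coverage is binomial around the requested fraction", {
  fracs <- vapply(1:30, function(s) {
    sc <- synthetic_scenario(seed = s, n_families = 5,
                             genera_per_family = c(4, 4),
                             species_per_genus = c(5, 5),
                             xref_fraction = 0.5)
    tab <- generate_taxonomy(sc)$table
    mean(!is.na(tab$ncbi_id[tab$rank == "species"]))
  }, numeric(1))
  # 30 draws of Binomial(100, .5)/100: mean within 4 standard errors
  expect_lt(abs(mean(fracs) - 0.5), 4 * 0.05 / sqrt(30))
})

test_that("tree generation honors polytomy, mismatch and extra-tip knobs", {
  sc0 <- synthetic_scenario(seed = 5, polytomy_fraction = 0,
                            mismatch_rate = 0, extra_tip_rate = 0)
  tax <- generate_taxonomy(sc0)
  tr0 <- generate_tree(tax, sc0)
  expect_true(ape::is.binary(tr0))
  expect_setequal(gsub("_", " ", tr0$tip.label),
                  tax$table$name[tax$table$rank == "species"])
  sc1 <- synthetic_scenario(seed = 5, n_families = 5,
                            genera_per_family = c(4, 4),
                            species_per_genus = c(5, 5),
                            polytomy_fraction = 0.5, mismatch_rate = 0,
                            extra_tip_rate = 0.1)
  tr1 <- generate_tree(generate_taxonomy(sc1), sc1)
  tm <- attr(tr1, "tip_map")
  expect_identical(ape::Ntip(tr1), 100L + sum(tm$extra))
  expect_gt(ape::Ntip(tr1), 100L)
  expect_lt(ape::Ntip(tr1), 125L)
  expect_false(ape::is.binary(tr1))
  # taxonomy clades stay monophyletic in the unperturbed tree
  gen_sp <- tax$table$name[tax$table$rank == "species" &
                             tax$table$parent_id == "TAX:000003"]
  expect_true(ape::is.monophyletic(tr0, gsub(" ", "_", gen_sp)))
})

test_that("planted histories replay correctly", {
  sc <- small_scenario(9)
  tax <- generate_taxonomy(sc)
  tr <- generate_tree(tax, sc)
  # no events: all tips present
  sc0 <- small_scenario(9, event_count_loss = 0, event_count_regain = 0)
  th0 <- plant_trait_history(tr, sc0)
  expect_true(all(th0$characters[["pectoral fin"]]$tip_states == "1"))
  # losses and a nested regain: regained clade shows presence
  th <- plant_trait_history(tr, sc)
  for (ch in names(th$characters)) {
    ev <- th$characters[[ch]]$events
    expect_identical(sum(ev$type == "loss"), 4L)
    expect_identical(sum(ev$type == "regain"), 1L)
    # every planted transition lies on exactly one branch
    expect_false(anyDuplicated(ev$node) > 0)
    rg <- ev$node[ev$type == "regain"]
    below <- fintegrate:::subtree_tip_sets(tr)[[rg]]
    expect_true(all(th$characters[[ch]]$tip_states[tr$tip.label[below]] == "1"))
  }
  # sparse-mode length equals the planted event count (enumeration oracle,
  # small binary tree)
  sc_small <- synthetic_scenario(seed = 4, n_families = 2,
                                 genera_per_family = c(2, 2),
                                 species_per_genus = c(2, 3),
                                 event_count_loss = 3, event_count_regain = 0,
                                 polytomy_fraction = 0, mismatch_rate = 0,
                                 extra_tip_rate = 0)
  tax_s <- generate_taxonomy(sc_small)
  tr_s <- generate_tree(tax_s, sc_small)
  th_s <- plant_trait_history(tr_s, sc_small)
  o <- enumerate_parsimony(tr_s, th_s$characters[["pectoral fin"]]$tip_states)
  expect_identical(as.integer(o$length), 3L)
  # impossible sparse placement is an error, not a silent relaxation
  tiny <- synthetic_scenario(seed = 1, n_families = 1,
                             genera_per_family = c(1, 1),
                             species_per_genus = c(4, 4),
                             event_count_loss = 3, event_count_regain = 1,
                             polytomy_fraction = 0, mismatch_rate = 0,
                             extra_tip_rate = 0)
  tr_t <- generate_tree(generate_taxonomy(tiny), tiny)
  expect_error(plant_trait_history(tr_t, tiny), "placement impossible")
  expect_error(plant_trait_history(
    tr_t, small_scenario(1, event_count_loss = 1, event_count_regain = 2)),
    "regains")
})

test_that("annotation emission follows the scenario parameters", {
  # indirect_fraction = 1: presences only via part qualities, absences via
  # the girdle
  sc <- small_scenario(13, indirect_fraction = 1, higher_level_fraction = 0)
  tax <- generate_taxonomy(sc)
  g <- generate_anatomy_template()
  tr <- generate_tree(tax, sc)
  th <- plant_trait_history(tr, sc)
  ann <- generate_annotations(th, tax, g, sc)
  expect_false(any(ann$entity %in% c("pectoral fin", "pelvic fin")))
  expect_true(all(ann$provenance == "asserted"))

  # higher_level_fraction = 1: monomorphic conflict-free genera/families are
  # annotated at the higher rank instead of their species
  sc2 <- small_scenario(13, higher_level_fraction = 1)
  ann2 <- generate_annotations(th, tax, g, sc2)
  higher <- ann2$taxon_id %in%
    tax$table$id[tax$table$rank %in% c("genus", "family")]
  expect_gt(sum(higher), 0)
  for (ch in c("pectoral fin")) {
    side <- sub(" fin", "", ch)
    ents <- c(ch, paste(side, "fin ray"), paste(side, "girdle skeleton"))
    for (gid in unique(ann2$taxon_id[higher & ann2$entity %in% ents])) {
      members <- fintegrate:::species_under(tax, gid)
      expect_false(any(ann2$taxon_id %in% members & ann2$entity %in% ents))
    }
  }

  # conflict_rate > 0: the conflict detector finds exactly the planted set
  sc3 <- small_scenario(14, conflict_rate = 0.3)
  th3 <- plant_trait_history(generate_tree(tax, sc3), sc3)
  ann3 <- generate_annotations(th3, tax, g, sc3)
  cf <- detect_conflicts(infer_closure(ann3, g), tax)
  planted <- sort(unique(unlist(attr(ann3, "conflicted"))))
  expect_identical(sort(unique(cf$taxon_id)), planted)
  expect_gt(length(planted), 0)

  # conflict_rate = 0: never both states for one (species, fin)
  for (s in 15:17) {
    sc4 <- small_scenario(s, conflict_rate = 0)
    tax4 <- generate_taxonomy(sc4)
    th4 <- plant_trait_history(generate_tree(tax4, sc4), sc4)
    ann4 <- generate_annotations(th4, tax4, g, sc4)
    expect_identical(nrow(detect_conflicts(infer_closure(ann4, g), tax4)), 0L)
  }
})

test_that("matrix aggregation matches the generator's bookkeeping", {
  for (s in c(23, 24)) {
    sc <- synthetic_scenario(seed = s, n_families = 6,
                             genera_per_family = c(2, 4),
                             species_per_genus = c(2, 6),
                             species_coverage = 0.6, conflict_rate = 0,
                             higher_level_fraction = 0.3, mismatch_rate = 0,
                             extra_tip_rate = 0)
    tax <- generate_taxonomy(sc)
    g <- generate_anatomy_template()
    th <- plant_trait_history(generate_tree(tax, sc), sc)
    ann <- generate_annotations(th, tax, g, sc)
    book <- attr(ann, "bookkeeping")
    sm <- suppressMessages(assemble_supermatrix(
      infer_closure(ann, g), c("pectoral fin", "pelvic fin"), tax, g))
    ranks <- sm$taxa$rank[match(sm$cells$taxon_id, sm$taxa$taxon_id)]
    for (i in seq_len(nrow(book))) {
      ch <- book$character[i]
      sp <- sm$cells$character == ch & ranks == "species"
      expect_identical(sum(sp & sm$cells$symbol %in% c("0", "1")),
                       book$species_asserted[i])
      expect_identical(sum(sp & sm$cells$symbol %in% c("2", "3")),
                       book$species_inferred_only[i])
      expect_identical(sum(sm$cells$character == ch & ranks != "species"),
                       book$higher_rank_rows[i])
    }
  }
})
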