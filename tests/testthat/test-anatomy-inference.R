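# Anatomy graph validation and the asymmetric presence/absence inference
# rules, checked on the fin template and against an independent single-step
# fixpoint oracle on random graphs.

test_that("the fin template is a valid graph with the expected structure", {
  g <- generate_anatomy_template()
  e <- g$edges
  expect_true(any(e$subject == "pectoral fin ray" & e$relation == "part_of" &
                    e$object == "pectoral fin"))
  expect_true(any(e$subject == "pectoral fin" & e$relation == "depends_on" &
                    e$object == "pectoral girdle skeleton"))
  expect_true(any(e$subject == "pelvic fin" & e$relation == "develops_from" &
                    e$object == "larval pelvic fin bud"))
  # no directed part_of cycle: build_anatomy_graph would have thrown
  expect_s3_class(g, "anatomy_graph")
})

test_that("graph validation rejects cycles, bad relations, dangling terms", {
  expect_s3_class(build_anatomy_graph(
    data.frame(subject = "a", relation = "part_of", object = "b")),
    "anatomy_graph")
  expect_error(build_anatomy_graph(
    data.frame(subject = c("a", "b"), relation = "part_of",
               object = c("b", "a"))), "cycle")
  expect_error(build_anatomy_graph(
    data.frame(subject = "a", relation = "linked_to", object = "b")),
    "unknown relation")
  expect_error(build_anatomy_graph(
    data.frame(subject = "a", relation = "is_a", object = "b"),
    terms = data.frame(term = "a", label = "a")), "dangling")
})

test_that("presence is inferred up part_of/is_a but not from girdle or bud", {
  g <- generate_anatomy_template()
  # chain: quality on the ray implies ray, fin and paired fin present
  cl <- infer_closure(
    annotation_table("T1", "pectoral fin ray", "unbranched", study = "s"), g)
  for (ent in c("pectoral fin ray", "pectoral fin", "paired fin"))
    expect_true(any(cl$entity == ent & cl$quality == "present" &
                      cl$provenance == "inferred"))
  # girdle presence does not imply the fin
  cl2 <- infer_closure(
    annotation_table("T2", "pectoral girdle skeleton", "present",
                     study = "s"), g)
  expect_false(any(cl2$entity == "pectoral fin"))
  # larval bud presence does not imply the adult fin
  cl3 <- infer_closure(
    annotation_table("T3", "larval pectoral fin bud", "present",
                     study = "s"), g)
  expect_false(any(cl3$entity == "pectoral fin"))
  # fin presence does not imply any part
  cl4 <- infer_closure(
    annotation_table("T4", "pelvic fin", "present", study = "s"), g)
  expect_false(any(cl4$entity == "pelvic fin ray"))
  expect_false(any(cl4$entity == "pelvic radial element"))
})

test_that("absence flows down part_of and through necessity edges only", {
  g <- generate_anatomy_template()
  # no girdle -> no fin -> no fin ray
  cl <- infer_closure(
    annotation_table("T1", "pelvic girdle skeleton", "absent", study = "s"), g)
  expect_true(any(cl$entity == "pelvic fin" & cl$quality == "absent"))
  expect_true(any(cl$entity == "pelvic fin ray" & cl$quality == "absent"))
  # no larval bud -> no fin
  cl2 <- infer_closure(
    annotation_table("T2", "larval pectoral fin bud", "absent", study = "s"), g)
  expect_true(any(cl2$entity == "pectoral fin" & cl2$quality == "absent"))
  # fin absent leaves the girdle unknown
  cl3 <- infer_closure(
    annotation_table("T3", "pectoral fin", "absent", study = "s"), g)
  expect_false(any(cl3$entity == "pectoral girdle skeleton"))
  # part absent does not imply whole absent
  cl4 <- infer_closure(
    annotation_table("T4", "pectoral fin ray", "absent", study = "s"), g)
  expect_false(any(cl4$entity == "pectoral fin" & cl4$quality == "absent"))
})

test_that("closure equals a single-step fixpoint oracle on random graphs", {
  # independent oracle: repeatedly apply the one-edge rules until stable
  oracle_closure <- function(ann, g) {
    facts <- unique(data.frame(entity = ann$entity,
                               state = ifelse(ann$quality == "absent",
                                              "absent", "present"),
                               stringsAsFactors = FALSE))
    e <- g$edges
    repeat {
      new <- facts
      for (i in seq_len(nrow(facts))) {
        en <- facts$entity[i]; st <- facts$state[i]
        if (st == "present") {
          up <- e$object[e$subject == en & e$relation %in% c("part_of", "is_a")]
          if (length(up)) new <- rbind(new, data.frame(
            entity = up, state = "present", stringsAsFactors = FALSE))
        } else {
          dn <- e$subject[e$object == en]
          if (length(dn)) new <- rbind(new, data.frame(
            entity = dn, state = "absent", stringsAsFactors = FALSE))
        }
      }
      new <- unique(new)
      if (nrow(new) == nrow(facts)) return(new[order(new$entity, new$state), ])
      facts <- new
    }
  }
  set.seed(5)
  for (rep in 1:20) {
    nterm <- sample(5:30, 1)
    terms <- paste0("t", seq_len(nterm))
    # random acyclic edges: only from lower to higher index
    from <- sample(nterm - 1, min(2 * nterm, 40), replace = TRUE)
    to <- from + vapply(from, function(f) sample.int(nterm - f, 1), integer(1))
    edges <- data.frame(subject = terms[from],
                        relation = sample(fintegrate:::ANATOMY_RELATIONS,
                                          length(from), replace = TRUE),
                        object = terms[to], stringsAsFactors = FALSE)
    edges <- unique(edges)
    g <- build_anatomy_graph(edges, data.frame(term = terms, label = terms))
    ann <- annotation_table("TX", sample(terms, 3),
                            c("present", "absent", "round"), study = "s")
    cl <- infer_closure(ann, g)
    got <- unique(data.frame(entity = cl$entity,
                             state = ifelse(cl$quality == "absent",
                                            "absent", "present"),
                             stringsAsFactors = FALSE))
    got <- got[order(got$entity, got$state), ]
    want <- oracle_closure(ann, g)
    expect_identical(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("closure is a fixpoint and monotone", {
  g <- generate_anatomy_template()
  a1 <- annotation_table("T1", "pelvic girdle skeleton", "absent", study = "s")
  a2 <- annotation_table("T1", "pectoral fin ray", "unbranched", study = "s")
  cl1 <- infer_closure(a1, g)
  expect_identical(infer_closure(cl1, g), cl1)
  # adding annotations never removes inferable facts
  cl12 <- infer_closure(rbind(a1, a2), g)
  facts <- function(x) unique(paste(x$taxon_id, x$entity,
                                    fintegrate:::implied_state(x$quality)))
  expect_true(all(facts(cl1) %in% facts(cl12)))
})

test_that("conflicts are classified by rank and provenance", {
  tax <- tiny_taxonomy()
  g <- generate_anatomy_template()
  # species, both asserted -> true polymorphism
  ann <- rbind(
    annotation_table("S1", "pelvic fin", "present", study = "a"),
    annotation_table("S1", "pelvic fin", "absent", study = "a"),
    # family, opposing states -> apparent polymorphism
    annotation_table("F1", "pelvic fin", "present", study = "a"),
    annotation_table("F1", "pelvic fin", "absent", study = "b"),
    # species, asserted absence vs part-implied presence -> assert vs infer
    annotation_table("S4", "pelvic fin", "absent", study = "a"),
    annotation_table("S4", "pelvic fin ray", "unbranched", study = "b"))
  cf <- detect_conflicts(infer_closure(ann, g), tax)
  get_cat <- function(tx, ent)
    cf$category[cf$taxon_id == tx & cf$entity == ent]
  expect_identical(get_cat("S1", "pelvic fin"), "true_polymorphism")
  expect_identical(get_cat("F1", "pelvic fin"), "apparent_polymorphism")
  expect_identical(get_cat("S4", "pelvic fin"), "assert_vs_infer_conflict")
  # every reported conflict cites at least two annotations
  expect_true(all(cf$n_annotations >= 2))
})
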