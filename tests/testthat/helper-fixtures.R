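# Shared hand-built fixtures: a tiny two-family taxonomy and a minimal
# NeXML matrix, constructed in code at test time.

tiny_taxonomy <- function() {
  taxonomy(data.frame(
    id = c("R1", "F1", "F2", "G1", "G2", "G3",
           "S1", "S2", "S3", "S4", "S5", "S6", "S7"),
    name = c("Rootclade", "Alphaidae", "Betaidae", "Alphus", "Alphoides",
             "Betus", "Alphus unus", "Alphus duo", "Alphoides tres",
             "Betus quattuor", "Betus quinque", "Betus sextus",
             "Betus septimus"),
    rank = c("root", "family", "family", "genus", "genus", "genus",
             rep("species", 7)),
    parent_id = c(NA, "R1", "R1", "F1", "F1", "F2",
                  "G1", "G1", "G2", "G3", "G3", "G3", "G3"),
    ncbi_id = c(NA, NA, NA, NA, NA, NA, 101L, 102L, NA, 104L, NA, NA, NA),
    extinct = c(rep(FALSE, 10), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

# small recovery-style scenario used by propagation / recovery loops;
# named arguments in ... override the defaults below
small_scenario <- function(seed, ...) {
  args <- list(
    seed = seed, n_families = 6, genera_per_family = c(2, 4),
    species_per_genus = c(2, 6), event_count_loss = 4,
    event_count_regain = 1, species_coverage = 1, indirect_fraction = 0.5,
    higher_level_fraction = 0.4, conflict_rate = 0, polytomy_fraction = 0.25,
    mismatch_rate = 0, extra_tip_rate = 0, xref_fraction = 0.5)
  do.call(synthetic_scenario, utils::modifyList(args, list(...)))
}

write_nexml_fixture <- function(path, with_meta = TRUE) {
  meta1 <- if (with_meta)
    paste0('<meta xsi:type="nex:LiteralMeta" property="ps:asserted" ',
           'content="true"/>',
           '<meta xsi:type="nex:LiteralMeta" property="ps:inferred" ',
           'content="true"/>') else ""
  meta2 <- if (with_meta)
    '<meta xsi:type="nex:LiteralMeta" property="ps:inferred" content="true"/>'
    else ""
  writeLines(sprintf('<?xml version="1.0" encoding="UTF-8"?>
<nex:nexml xmlns:nex="http://www.nexml.org/2009"
           xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" version="0.9">
  <otus id="otus1">
    <otu id="t1" label="Alphus unus"/>
    <otu id="t2" label="Betus quattuor"/>
  </otus>
  <characters id="c1" otus="otus1" xsi:type="nex:StandardCells">
    <format>
      <states id="st1">
        <state id="s0" symbol="0"/>
        <state id="s1" symbol="1"/>
        <polymorphic_state_set id="s01" symbol="2">
          <member state="s0"/><member state="s1"/>
        </polymorphic_state_set>
      </states>
      <char id="ch1" states="st1" label="pectoral fin"/>
      <char id="ch2" states="st1" label="pelvic fin"/>
    </format>
    <matrix>
      <row id="r1" otu="t1">
        <cell char="ch1" state="s1">%s</cell>
        <cell char="ch2" state="s0">%s</cell>
      </row>
      <row id="r2" otu="t2">
        <cell char="ch1" state="s01">%s</cell>
      </row>
    </matrix>
  </characters>
</nex:nexml>', meta1, meta2, meta1), path)
  path
}

# run the synthetic front half of the pipeline in memory (through
# propagation), returning all intermediates
run_front_half <- function(scenario) {
  tax <- generate_taxonomy(scenario)
  graph <- generate_anatomy_template()
  tree <- generate_tree(tax, scenario)
  truth <- plant_trait_history(tree, scenario)
  ann <- generate_annotations(truth, tax, graph, scenario)
  closure <- infer_closure(ann, graph)
  sm <- suppressMessages(
    assemble_supermatrix(closure, c("pectoral fin", "pelvic fin"),
                         tax, graph))
  scr <- scrub_apparent_polymorphisms(sm, tax)
  prop <- propagate_to_species(scr$matrix, tax)
  list(tax = tax, graph = graph, tree = tree, truth = truth, ann = ann,
       closure = closure, assembled = sm, scrubbed = scr$matrix,
       scrub_log = scr$log, species = prop$matrix, prop_log = prop$log)
}
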