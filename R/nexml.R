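# Reader for the NeXML subset produced by ontology-driven supermatrix
# exporters: a standard-cells characters block whose cells carry metadata
# distinguishing asserted from inferred support. Only the elements needed to
# rebuild a provenance-tagged presence/absence matrix are consumed; this is
# deliberately not a general NeXML parser.

#' Read a presence/absence supermatrix from a NeXML subset
#'
#' Expects `otus`/`characters`/`format`/`matrix` elements per the NeXML
#' standard, with binary standard states (symbols `0`/`1`, optionally a
#' polymorphic state set). Cell-level `meta` elements mark provenance; the
#' property names are configurable because exporters differ in the predicate
#' they use. A populated cell without parseable provenance metadata is kept
#' with provenance `"unknown"` and a warning.
#'
#' @param path NeXML file path.
#' @param asserted_property,inferred_property `meta` property names whose
#'   content `"true"` marks asserted / inferred support for the cell.
#' @return a `supermatrix` (taxon ranks are `NA` until joined with a
#'   taxonomy, e.g. by [scrub_apparent_polymorphisms()]).
#' @export
read_nexml_matrix <- function(path,
                              asserted_property = "ps:asserted",
                              inferred_property = "ps:inferred") {
  doc <- xml2::read_xml(path)
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  attr1 <- function(nodes, a) xml2::xml_attr(nodes, a)

  otus <- find(doc, "otu")
  if (length(otus) == 0L) stop("no otu elements found")
  otu_label <- setNames(attr1(otus, "label"), attr1(otus, "id"))

  states_blocks <- find(doc, "states")
  if (length(states_blocks) == 0L) stop("states block missing")
  state_symbol <- character(0)
  poly_ids <- character(0)
  for (sb in states_blocks) {
    st <- xml2::xml_find_all(sb, "./*[local-name()='state']")
    state_symbol[attr1(st, "id")] <- attr1(st, "symbol")
    ps <- xml2::xml_find_all(sb, "./*[local-name()='polymorphic_state_set']")
    poly_ids <- c(poly_ids, attr1(ps, "id"))
    state_symbol[attr1(ps, "id")] <- "0&1"
  }

  chars <- find(doc, "char")
  char_label <- setNames(attr1(chars, "label"), attr1(chars, "id"))
  char_label[is.na(char_label)] <- names(char_label)[is.na(char_label)]

  rows <- find(doc, "row")
  cells <- list()
  unknown <- 0L
  for (r in rows) {
    otu <- xml2::xml_attr(r, "otu")
    taxon <- if (!is.na(otu) && otu %in% names(otu_label) &&
                 !is.na(otu_label[[otu]])) otu_label[[otu]] else otu
    for (cell in xml2::xml_find_all(r, "./*[local-name()='cell']")) {
      ch_id <- xml2::xml_attr(cell, "char")
      st_id <- xml2::xml_attr(cell, "state")
      sym <- state_symbol[st_id]
      if (is.na(sym)) next
      metas <- xml2::xml_find_all(cell, "./*[local-name()='meta']")
      props <- xml2::xml_attr(metas, "property")
      conts <- tolower(xml2::xml_attr(metas, "content"))
      asserted <- any(props == asserted_property & conts == "true",
                      na.rm = TRUE)
      inferred <- any(props == inferred_property & conts == "true",
                      na.rm = TRUE)
      prov <- if (asserted) "asserted" else if (inferred) "inferred"
              else { unknown <- unknown + 1L; "unknown" }
      ap <- aa <- ip <- ia <- 0L
      if (sym == "0&1") { ap <- aa <- as.integer(asserted | prov == "unknown") }
      else if (sym == "1") { if (asserted || prov == "unknown") ap <- 1L
                             if (inferred) ip <- 1L }
      else if (sym == "0") { if (asserted || prov == "unknown") aa <- 1L
                             if (inferred) ia <- 1L }
      # a cell marked inferred-only is recoded to the inferred symbols
      sym_out <- if (sym == "0&1") "0&1" else symbol_from_counts(ap, aa, ip, ia)
      ch_name <- if (!is.na(ch_id) && ch_id %in% names(char_label))
        char_label[[ch_id]] else ch_id
      cells[[length(cells) + 1L]] <- data.frame(
        taxon_id = taxon, character = ch_name,
        symbol = sym_out,
        n_assert_present = ap, n_assert_absent = aa,
        n_infer_present = ip, n_infer_absent = ia,
        provenance = prov, source_id = NA_character_,
        source_rank = NA_character_, source_provenance = NA_character_,
        studies = "", stringsAsFactors = FALSE)
    }
  }
  if (unknown > 0L)
    warning(unknown, " cell(s) lacked parseable provenance metadata; ",
            "kept with provenance 'unknown'")
  cells <- if (length(cells)) do.call(rbind, cells) else empty_cells()
  characters <- unname(char_label)
  taxa <- data.frame(taxon_id = unname(otu_label), name = unname(otu_label),
                     rank = NA_character_, stringsAsFactors = FALSE)
  new_supermatrix(cells, taxa, characters)
}
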