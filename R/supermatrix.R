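# Provenance-tagged presence/absence supermatrix.
#
# Cell symbols follow the coding of ontology-derived matrices:
#   "1"   asserted presence (possibly also inferred; assertion dominates)
#   "0"   asserted absence
#   "2"   inferred-only presence
#   "3"   inferred-only absence (reserved; produced and logged if it occurs)
#   "0&1" both states implied (species polymorphism or data conflict)
#   "?"   missing (cells without a row in `cells`)
#
# The object keeps a long-format cell table with per-provenance support
# counts so that later stages (scrubbing, propagation, merging) can
# distinguish assertion, inference and propagation without re-deriving the
# closure.

SUPERMATRIX_CELL_COLS <- c(
  "taxon_id", "character", "symbol",
  "n_assert_present", "n_assert_absent",
  "n_infer_present", "n_infer_absent",
  "provenance", "source_id", "source_rank", "source_provenance", "studies")

empty_cells <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)),
                                   length(SUPERMATRIX_CELL_COLS)),
                               SUPERMATRIX_CELL_COLS),
                      stringsAsFactors = FALSE)
  for (col in c("n_assert_present", "n_assert_absent",
                "n_infer_present", "n_infer_absent"))
    df[[col]] <- integer(0)
  df
}

new_supermatrix <- function(cells, taxa, characters) {
  if (is.null(cells) || nrow(cells) == 0L) cells <- empty_cells()
  if (is.null(taxa) || nrow(taxa) == 0L)
    taxa <- data.frame(taxon_id = character(0), name = character(0),
                       rank = character(0), stringsAsFactors = FALSE)
  for (col in SUPERMATRIX_CELL_COLS)
    if (!col %in% names(cells)) cells[[col]] <- rep(NA_character_, nrow(cells))
  rownames(cells) <- NULL
  rownames(taxa) <- NULL
  structure(list(cells = cells[, SUPERMATRIX_CELL_COLS],
                 taxa = taxa, characters = characters),
            class = "supermatrix")
}

symbol_from_counts <- function(ap, aa, ip, ia) {
  present <- ap + ip > 0
  absent <- aa + ia > 0
  ifelse(present & absent, "0&1",
  ifelse(present, ifelse(ap > 0, "1", "2"),
  ifelse(absent, ifelse(aa > 0, "0", "3"), "?")))
}

#' Assemble a supermatrix from closed annotations
#'
#' One row per annotated taxon (any rank), one column per character term. A
#' character cell aggregates all annotations whose entity equals the
#' character term or any `is_a` descendant of it (part-level evidence enters
#' only through the inference closure, never through column matching). A
#' cell supported by both implied states is coded `"0&1"`; a cell whose only
#' support is inferred presence is `"2"`; inferred-only absence yields the
#' reserved symbol `"3"` and a message.
#'
#' @param ann closed annotation data frame ([infer_closure()]).
#' @param characters character vector of anatomy terms used as columns.
#' @param taxonomy a [taxonomy()] for row names and ranks.
#' @param graph the `anatomy_graph` (for `is_a` descendant lookup).
#' @return a `supermatrix`.
#' @export
assemble_supermatrix <- function(ann, characters, taxonomy, graph) {
  taxa_ids <- unique(ann$taxon_id)
  cells <- list()
  for (ch in characters) {
    ents <- character_entity_set(graph, ch)
    sub <- ann[ann$entity %in% ents, , drop = FALSE]
    if (nrow(sub) == 0L) next
    st <- implied_state(sub$quality)
    for (tx in unique(sub$taxon_id)) {
      rows <- sub[sub$taxon_id == tx, , drop = FALSE]
      rst <- st[sub$taxon_id == tx]
      ap <- sum(rows$provenance == "asserted" & rst == "present")
      aa <- sum(rows$provenance == "asserted" & rst == "absent")
      ip <- sum(rows$provenance == "inferred" & rst == "present")
      ia <- sum(rows$provenance == "inferred" & rst == "absent")
      sym <- symbol_from_counts(ap, aa, ip, ia)
      if (sym == "?") next
      studies <- sort(unique(rows$study[rows$provenance == "asserted"]))
      cells[[length(cells) + 1L]] <- data.frame(
        taxon_id = tx, character = ch, symbol = sym,
        n_assert_present = ap, n_assert_absent = aa,
        n_infer_present = ip, n_infer_absent = ia,
        provenance = if (ap + aa > 0) "asserted" else "inferred",
        source_id = NA_character_, source_rank = NA_character_,
        source_provenance = NA_character_,
        studies = paste(studies, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else empty_cells()
  if (any(cells$symbol == "3"))
    message(sum(cells$symbol == "3"),
            " cell(s) contain only inferred absence (symbol '3')")
  ranks <- taxon_rank(taxonomy, taxa_ids)
  taxa <- data.frame(taxon_id = taxa_ids,
                     name = taxon_name(taxonomy, taxa_ids),
                     rank = ranks, stringsAsFactors = FALSE)
  taxa$name[is.na(taxa$name)] <- taxa$taxon_id[is.na(taxa$name)]
  new_supermatrix(cells, taxa, characters)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", nrow(x$taxa), "taxa x", length(x$characters),
      "characters;", nrow(x$cells), "populated cells\n")
  tab <- table(x$cells$symbol)
  if (length(tab))
    cat("  symbols:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.matrix.supermatrix <- function(x, ...) {
  out <- matrix("?", nrow(x$taxa), length(x$characters),
                dimnames = list(x$taxa$taxon_id, x$characters))
  if (nrow(x$cells))
    out[cbind(match(x$cells$taxon_id, x$taxa$taxon_id),
              match(x$cells$character, x$characters))] <- x$cells$symbol
  out
}

#' Blank apparent polymorphisms at higher ranks
#'
#' Every `"0&1"` cell on a higher-than-species row is replaced by missing
#' (`"?"`): such cells say only that some unidentified member species show
#' each state, which cannot inform species-level reconstruction. Species-rank
#' `"0&1"` cells are retained (they block propagation overwrites) and are
#' flagged in the log as `retained_species_polymorphism` (both states
#' asserted) or `retained_species_conflict`.
#'
#' @param matrix a `supermatrix`.
#' @param taxonomy a [taxonomy()].
#' @return list with `matrix` (scrubbed) and `log` (data frame of actions
#'   with taxon rank and character).
#' @export
scrub_apparent_polymorphisms <- function(matrix, taxonomy) {
  cells <- matrix$cells
  ranks <- matrix$taxa$rank[match(cells$taxon_id, matrix$taxa$taxon_id)]
  na_rank <- is.na(ranks)
  if (any(na_rank))
    ranks[na_rank] <- ifelse(
      is.na(taxon_rank(taxonomy, cells$taxon_id[na_rank])), "species",
      taxon_rank(taxonomy, cells$taxon_id[na_rank]))
  poly <- cells$symbol == "0&1"
  drop <- poly & ranks != "species"
  keep_poly <- poly & ranks == "species"
  log <- rbind(
    if (any(drop)) data.frame(
      taxon_id = cells$taxon_id[drop], rank = ranks[drop],
      character = cells$character[drop],
      action = "blanked_apparent_polymorphism", stringsAsFactors = FALSE),
    if (any(keep_poly)) data.frame(
      taxon_id = cells$taxon_id[keep_poly], rank = ranks[keep_poly],
      character = cells$character[keep_poly],
      action = ifelse(cells$n_assert_present[keep_poly] > 0 &
                        cells$n_assert_absent[keep_poly] > 0,
                      "retained_species_polymorphism",
                      "retained_species_conflict"),
      stringsAsFactors = FALSE))
  if (is.null(log))
    log <- data.frame(taxon_id = character(0), rank = character(0),
                      character = character(0), action = character(0),
                      stringsAsFactors = FALSE)
  matrix$cells <- cells[!drop, , drop = FALSE]
  rownames(matrix$cells) <- NULL
  list(matrix = matrix, log = log)
}

#' Missing-data statistics under an explicit denominator convention
#'
#' Percent missing depends on what counts as the full cell set: the species
#' in the final output matrix, or the tips of the tree the matrix is merged
#' with. The denominator is therefore an explicit argument, never implied.
#'
#' @param matrix a `supermatrix`.
#' @param n_taxa denominator taxon count (e.g. number of species in the
#'   final matrix, or number of tree tips). Must be positive.
#' @param denominator label recorded with the result.
#' @return data frame of class `missing_data_stats`: populated cells per
#'   character, total populated, denominator cells, percent missing
#'   (`100 * (1 - populated/denominator)`).
#' @export
missing_stats <- function(matrix, n_taxa,
                          denominator = c("final_species_set",
                                          "tree_tip_set")) {
  denominator <- match.arg(denominator)
  stopifnot_count(n_taxa, "n_taxa")
  per_char <- vapply(matrix$characters, function(ch)
    sum(matrix$cells$character == ch & matrix$cells$symbol != "?"),
    integer(1))
  total <- sum(per_char)
  denom_cells <- n_taxa * length(matrix$characters)
  out <- data.frame(
    character = c(matrix$characters, "(total)"),
    populated = c(per_char, total),
    denominator = denominator,
    denominator_cells = denom_cells,
    percent_missing = round(100 * (1 - c(per_char * length(matrix$characters),
                                         total) / denom_cells), 1),
    stringsAsFactors = FALSE)
  # per-character percentages are relative to the per-character cell count
  out$percent_missing[seq_along(per_char)] <-
    round(100 * (1 - per_char / n_taxa), 1)
  class(out) <- c("missing_data_stats", class(out))
  out
}

#' Write / read the native supermatrix TSV
#'
#' Wide table: `taxon_id`, `name`, `rank`, then one symbol column per
#' character. Reading back reconstructs minimal per-cell support counts from
#' the symbols (one supporting annotation per implied state), so a
#' write-read round trip preserves the symbol table exactly; full provenance
#' detail lives in the in-memory object and the pipeline logs.
#'
#' @param matrix a `supermatrix`.
#' @param path file path.
#' @export
write_supermatrix <- function(matrix, path) {
  wide <- data.frame(taxon_id = matrix$taxa$taxon_id,
                     name = matrix$taxa$name, rank = matrix$taxa$rank,
                     stringsAsFactors = FALSE, check.names = FALSE)
  sym <- as.matrix(matrix)
  for (ch in matrix$characters) wide[[ch]] <- unname(sym[, ch])
  write_tsv(wide, path)
}

#' @rdname write_supermatrix
#' @return [read_supermatrix()] returns a `supermatrix`.
#' @export
read_supermatrix <- function(path) {
  wide <- read_tsv(path)
  meta <- c("taxon_id", "name", "rank")
  characters <- setdiff(names(wide), meta)
  cells <- list()
  for (ch in characters) {
    sym <- as.character(wide[[ch]])
    sym[is.na(sym)] <- "?"
    pop <- sym != "?"
    if (!any(pop)) next
    cells[[length(cells) + 1L]] <- data.frame(
      taxon_id = wide$taxon_id[pop], character = ch, symbol = sym[pop],
      n_assert_present = as.integer(sym[pop] %in% c("1", "0&1")),
      n_assert_absent = as.integer(sym[pop] %in% c("0", "0&1")),
      n_infer_present = as.integer(sym[pop] == "2"),
      n_infer_absent = as.integer(sym[pop] == "3"),
      provenance = ifelse(sym[pop] %in% c("0", "1", "0&1"),
                          "asserted", "inferred"),
      source_id = NA_character_, source_rank = NA_character_,
      source_provenance = NA_character_, studies = "",
      stringsAsFactors = FALSE)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else empty_cells()
  taxa <- data.frame(taxon_id = wide$taxon_id, name = wide$name,
                     rank = wide$rank, stringsAsFactors = FALSE)
  new_supermatrix(cells, taxa, characters)
}

#' Write a merged tree + characters NEXUS file
#'
#' Writes a single NEXUS file with TAXA, CHARACTERS (standard data, symbols
#' `0 1 2`, missing `?`, polymorphism `{0 1}`) and TREES blocks — the merged
#' artifact a downstream phylogenetics program consumes.
#'
#' @param phy rooted `phylo` tree.
#' @param tip_states data frame from [merge_tip_states()] (rows = tip
#'   labels, columns = characters).
#' @param path output path.
#' @param seed optional integer recorded in a comment header.
#' @export
write_merged_nexus <- function(phy, tip_states, path, seed = NULL) {
  tips <- phy$tip.label
  safe <- gsub("[^A-Za-z0-9_.]", "_", tips)
  chars <- colnames(tip_states)
  rows <- vapply(seq_along(tips), function(i) {
    paste(vapply(chars, function(ch) {
      v <- tip_states[tips[i], ch]
      if (v == "0&1") "{0 1}" else v
    }, character(1)), collapse = "")
  }, character(1))
  phy2 <- phy
  phy2$tip.label <- safe
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    if (!is.null(seed)) sprintf("[ seed: %d ]", as.integer(seed)),
    "BEGIN TAXA;",
    sprintf("    DIMENSIONS NTAX=%d;", length(tips)),
    "    TAXLABELS",
    paste0("        ", safe),
    "    ;",
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("    DIMENSIONS NCHAR=%d;", length(chars)),
    "    FORMAT DATATYPE=STANDARD SYMBOLS=\"0 1 2\" MISSING=?;",
    "    CHARSTATELABELS",
    paste0("        ",
           paste(sprintf("%d %s", seq_along(chars),
                         gsub("[^A-Za-z0-9_.]", "_", chars)),
                 collapse = ", "), ";"),
    "    MATRIX",
    sprintf("        %s  %s", format(safe, width = max(nchar(safe))), rows),
    "    ;",
    "END;",
    "BEGIN TREES;",
    sprintf("    TREE merged = [&R] %s", ape::write.tree(phy2)),
    "END;"), con)
  invisible(path)
}
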