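# Taxonomic propagation: copy genus- and family-level character states down
# to member species that lack their own data, then drop all non-species rows.
#
# Rules:
#  * only genus and family rows are sources; ranks above family are ignored;
#  * existing species data (asserted, inferred, polymorphic or conflicted)
#    are never replaced — a disagreeing higher-level state is logged instead;
#  * when genus and family both carry data the nearest ancestor (genus) wins
#    and a disagreement is logged;
#  * a higher-level "0&1" cell (which scrubbing should already have blanked)
#    propagates nothing — both states at once would be uninformative — and
#    is logged defensively;
#  * propagated cells record their source taxon, rank and whether the source
#    state was asserted or inferred, so any individual propagation is
#    auditable.

state_of_symbol <- function(sym) {
  ifelse(sym %in% c("1", "2"), "present",
  ifelse(sym %in% c("0", "3"), "absent", sym))
}

#' Propagate genus/family data to member species
#'
#' @param matrix a scrubbed `supermatrix` (see
#'   [scrub_apparent_polymorphisms()]).
#' @param taxonomy a [taxonomy()] covering every matrix taxon.
#' @return list with `matrix` (species-only `supermatrix`) and `log` (data
#'   frame: `taxon_id` (species), `character`, `action`, `state`,
#'   `source_id`, `source_rank`, `source_provenance`, `conflict_with`).
#'   Actions: `propagated`, `blocked_overwrite` (species had a different
#'   state), `genus_over_family` (both ranks offered data and disagreed),
#'   `skipped_polymorphic_source`.
#' @export
propagate_to_species <- function(matrix, taxonomy) {
  cells <- matrix$cells
  taxa <- matrix$taxa
  ranks <- taxa$rank[match(cells$taxon_id, taxa$taxon_id)]
  miss <- is.na(ranks)
  if (any(miss)) ranks[miss] <- taxon_rank(taxonomy, cells$taxon_id[miss])
  in_tax <- cells$taxon_id %in% taxonomy$table$id |
    cells$taxon_id %in% taxonomy$table$name
  if (any(ranks == "species" & !in_tax, na.rm = TRUE))
    stop("species in matrix absent from taxonomy: ",
         paste(head(unique(cells$taxon_id[ranks == "species" & !in_tax])),
               collapse = ", "))

  sp_cells <- cells[!is.na(ranks) & ranks == "species", , drop = FALSE]
  have <- paste(sp_cells$taxon_id, sp_cells$character, sep = "\r")
  log <- list()
  newcells <- list()
  proposed <- list()  # key -> list(symbol, source_id, source_rank)

  add_log <- function(sp, ch, action, state = NA, src = NA, srank = NA,
                      sprov = NA, conflict = NA) {
    log[[length(log) + 1L]] <<- data.frame(
      taxon_id = sp, character = ch, action = action, state = state,
      source_id = src, source_rank = srank, source_provenance = sprov,
      conflict_with = conflict, stringsAsFactors = FALSE)
  }

  for (rk in c("genus", "family")) {
    src_rows <- which(!is.na(ranks) & ranks == rk)
    for (i in src_rows) {
      src <- cells$taxon_id[i]
      ch <- cells$character[i]
      sym <- cells$symbol[i]
      src_id <- if (src %in% taxonomy$table$id) src
                else taxon_id_by_name(taxonomy, src)
      if (is.na(src_id)) next
      members <- species_under(taxonomy, src_id)
      if (sym == "0&1") {
        add_log(NA_character_, ch, "skipped_polymorphic_source",
                src = src, srank = rk)
        next
      }
      if (!sym %in% c("0", "1", "2", "3")) next
      sprov <- if (sym %in% c("0", "1")) "asserted" else "inferred"
      for (sp in members) {
        key <- paste(sp, ch, sep = "\r")
        if (key %in% have) {
          j <- match(key, paste(sp_cells$taxon_id, sp_cells$character,
                                sep = "\r"))
          if (state_of_symbol(sp_cells$symbol[j]) != state_of_symbol(sym))
            add_log(sp, ch, "blocked_overwrite",
                    state = state_of_symbol(sym), src = src, srank = rk,
                    sprov = sprov,
                    conflict = sp_cells$provenance[j])
          next
        }
        prop <- proposed[[key]]
        if (!is.null(prop)) {
          # a genus proposal exists (genus processed first); family never
          # overrides, disagreement is logged
          if (state_of_symbol(prop$symbol) != state_of_symbol(sym))
            add_log(sp, ch, "genus_over_family",
                    state = state_of_symbol(prop$symbol), src = src,
                    srank = rk, sprov = sprov, conflict = prop$source_id)
          next
        }
        proposed[[key]] <- list(symbol = sym, source_id = src,
                                source_rank = rk, source_provenance = sprov)
        add_log(sp, ch, "propagated", state = state_of_symbol(sym),
                src = src, srank = rk, sprov = sprov)
      }
    }
  }

  for (key in names(proposed)) {
    p <- proposed[[key]]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    newcells[[length(newcells) + 1L]] <- data.frame(
      taxon_id = parts[1], character = parts[2], symbol = p$symbol,
      n_assert_present = 0L, n_assert_absent = 0L,
      n_infer_present = 0L, n_infer_absent = 0L,
      provenance = "propagated", source_id = p$source_id,
      source_rank = p$source_rank, source_provenance = p$source_provenance,
      studies = "", stringsAsFactors = FALSE)
  }

  out_cells <- rbind(sp_cells,
                     if (length(newcells)) do.call(rbind, newcells))
  sp_ids <- unique(out_cells$taxon_id)
  out_taxa <- data.frame(
    taxon_id = sp_ids,
    name = ifelse(is.na(taxon_name(taxonomy, sp_ids)), sp_ids,
                  taxon_name(taxonomy, sp_ids)),
    rank = "species", stringsAsFactors = FALSE)
  log <- if (length(log)) do.call(rbind, log) else data.frame(
    taxon_id = character(0), character = character(0), action = character(0),
    state = character(0), source_id = character(0),
    source_rank = character(0), source_provenance = character(0),
    conflict_with = character(0), stringsAsFactors = FALSE)
  list(matrix = new_supermatrix(out_cells, out_taxa, matrix$characters),
       log = log)
}

#' Summarize a propagation log
#'
#' @param log the log data frame from [propagate_to_species()].
#' @return list with `totals` (one-row data frame: species added,
#'   contributing genera and families, overwrite conflicts split by the
#'   provenance of the blocking species data, genus/family disagreements)
#'   and `per_character` (species added per character, split by source
#'   provenance).
#' @export
propagation_summary <- function(log) {
  added <- log[log$action == "propagated", , drop = FALSE]
  blocked <- log[log$action == "blocked_overwrite", , drop = FALSE]
  totals <- data.frame(
    species_added = length(unique(added$taxon_id)),
    cells_added = nrow(added),
    genus_sources = length(unique(added$source_id[added$source_rank == "genus"])),
    family_sources = length(unique(added$source_id[added$source_rank == "family"])),
    conflicts_vs_asserted = sum(blocked$conflict_with == "asserted"),
    conflicts_vs_inferred = sum(blocked$conflict_with == "inferred"),
    genus_family_disagreements = sum(log$action == "genus_over_family"),
    skipped_polymorphic_sources = sum(log$action == "skipped_polymorphic_source"))
  per_char <- if (nrow(added)) {
    agg <- as.data.frame(table(character = added$character,
                               source_provenance = added$source_provenance),
                         stringsAsFactors = FALSE)
    names(agg)[3] <- "cells_added"
    agg[agg$cells_added > 0 | TRUE, , drop = FALSE]
  } else data.frame(character = character(0),
                    source_provenance = character(0),
                    cells_added = integer(0), stringsAsFactors = FALSE)
  list(totals = totals, per_character = per_char)
}
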