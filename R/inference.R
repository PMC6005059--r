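# Ontology-based presence/absence inference.
#
# The rules are deliberately asymmetric:
#
# presence flows UP composition and subsumption:
#   a (non-absence) quality observed on entity E implies E is present, and so
#   is everything E is part_of (a fin ray implies its fin) and every is_a
#   supertype of E. Presence never flows through develops_from (a larval bud
#   does not imply the adult fin) nor through depends_on (a girdle does not
#   imply its fin), and never downward (a fin does not imply any given part).
#
# absence flows DOWN composition/subsumption and through necessity:
#   ABSENT(W) implies ABSENT(E) for every E part_of W and every E is_a W,
#   and ABSENT(D) implies ABSENT(A) whenever A depends_on D (no girdle, no
#   fin) or A develops_from D (no larval bud, no fin). Absence of a part
#   never implies absence of the whole.
#
# Both closures are transitive reachability over the edge set, so a single
# pass is already the fixpoint.

#' Infer presence annotations from qualities
#'
#' For every non-absence annotation on entity E, emits an inferred PRESENT
#' annotation for E and for every term reachable from E via `part_of` or
#' `is_a` edges. `develops_from` and `depends_on` are never followed for
#' presence.
#'
#' @param ann annotation data frame (see [annotation_table()]).
#' @param graph an `anatomy_graph`.
#' @return data frame of new inferred annotations (provenance `"inferred"`,
#'   derivation recorded in `chain`).
#' @export
infer_presence <- function(ann, graph) {
  seeds <- ann[implied_state(ann$quality) == "present", , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty_annotations())
  ents <- unique(seeds$entity)
  reach <- lapply(ents, reach_forward, graph = graph,
                  relations = c("part_of", "is_a"))
  names(reach) <- ents
  out <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    targets <- reach[[seeds$entity[i]]]
    data.frame(taxon_id = seeds$taxon_id[i], entity = targets,
               quality = "present", provenance = "inferred", study = "",
               chain = sprintf("present(%s[%s]) => present(%s)",
                               seeds$entity[i], seeds$quality[i], targets),
               stringsAsFactors = FALSE)
  }))
  unique_annotations(out)
}

#' Infer absence annotations
#'
#' For every ABSENT annotation on W, emits inferred ABSENT annotations for
#' every part of W (`part_of`, followed downward), every subtype of W
#' (`is_a`, downward), everything that `depends_on` W (girdle necessity) and
#' everything that `develops_from` W (precursor necessity), iterated to the
#' fixpoint. Presence of a whole never implies presence of its parts.
#'
#' @inheritParams infer_presence
#' @return data frame of new inferred annotations.
#' @export
infer_absence <- function(ann, graph) {
  seeds <- ann[implied_state(ann$quality) == "absent", , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty_annotations())
  ents <- unique(seeds$entity)
  reach <- lapply(ents, reach_backward, graph = graph,
                  relations = ANATOMY_RELATIONS)
  names(reach) <- ents
  out <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    targets <- reach[[seeds$entity[i]]]
    data.frame(taxon_id = seeds$taxon_id[i], entity = targets,
               quality = "absent", provenance = "inferred", study = "",
               chain = sprintf("absent(%s) => absent(%s)",
                               seeds$entity[i], targets),
               stringsAsFactors = FALSE)
  }))
  unique_annotations(out)
}

# drop inferred rows duplicating an existing (taxon, entity, state) fact,
# and internal duplicates
unique_annotations <- function(out) {
  key <- paste(out$taxon_id, out$entity, implied_state(out$quality))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full inference closure
#'
#' Original annotations plus all inferred presence and absence annotations.
#' Inferred rows that restate an existing (taxon, entity, state) fact are
#' kept only when no other row implies it, so rerunning the closure on its
#' own output adds nothing (fixpoint), and adding annotations never removes
#' previously inferable facts (monotonicity).
#'
#' @inheritParams infer_presence
#' @return combined annotation data frame.
#' @export
infer_closure <- function(ann, graph) {
  pres <- infer_presence(ann, graph)
  abs_ <- infer_absence(ann, graph)
  new <- rbind(pres, abs_)
  if (nrow(new)) {
    have <- paste(ann$taxon_id, ann$entity, implied_state(ann$quality),
                  "inferred" == ann$provenance)
    # drop an inferred fact only if the identical inferred fact is present;
    # asserted rows never block the inferred derivation record
    key_new <- paste(new$taxon_id, new$entity, implied_state(new$quality), TRUE)
    new <- new[!(key_new %in% have), , drop = FALSE]
  }
  out <- rbind(ann[, ANNOTATION_COLS], new[, ANNOTATION_COLS])
  rownames(out) <- NULL
  out
}

#' Detect per-taxon character conflicts
#'
#' Classifies every (taxon, entity) pair for which the closed annotation set
#' implies both presence and absence:
#' * `true_polymorphism` — both states asserted at species rank;
#' * `apparent_polymorphism` — both states at a higher-than-species taxon;
#' * `assert_vs_infer_conflict` — species rank, at least one side only
#'   inferred.
#' The report is exhaustive and conflicts are never auto-resolved.
#'
#' @param ann closed annotation data frame (run [infer_closure()] first).
#' @param taxonomy a [taxonomy()] used for rank lookup.
#' @return data frame of class `conflict_report` with columns `taxon_id`,
#'   `entity`, `rank`, `category`, `n_annotations`, `support`.
#' @export
detect_conflicts <- function(ann, taxonomy) {
  st <- implied_state(ann$quality)
  key <- paste(ann$taxon_id, ann$entity, sep = "\r")
  both <- intersect(unique(key[st == "present"]), unique(key[st == "absent"]))
  rows <- lapply(both, function(k) {
    sel <- key == k
    sub <- ann[sel, , drop = FALSE]
    sst <- st[sel]
    taxon <- sub$taxon_id[1]
    rank <- taxon_rank(taxonomy, taxon)
    if (is.na(rank)) {
      warning("taxon not in taxonomy, assuming species rank: ", taxon)
      rank <- "species"
    }
    cat_ <- if (rank != "species") "apparent_polymorphism"
      else if (any(sub$provenance == "asserted" & sst == "present") &&
               any(sub$provenance == "asserted" & sst == "absent"))
        "true_polymorphism"
      else "assert_vs_infer_conflict"
    data.frame(taxon_id = taxon, entity = sub$entity[1], rank = rank,
               category = cat_, n_annotations = nrow(sub),
               support = paste(sprintf("%s:%s(%s)", sub$provenance,
                                       sub$quality,
                                       ifelse(sub$provenance == "asserted",
                                              sub$study, sub$chain)),
                               collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(taxon_id = character(0), entity = character(0),
                         rank = character(0), category = character(0),
                         n_annotations = integer(0), support = character(0),
                         stringsAsFactors = FALSE)
  class(out) <- c("conflict_report", class(out))
  out
}
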