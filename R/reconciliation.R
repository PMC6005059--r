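# Two-pass taxon name reconciliation between matrix species and tree tips.
#
# Pass 1 pairs taxa sharing an external (NCBI-style) identifier — robust to
# spelling differences. Pass 2 pairs the remainder by exact equality of
# normalized names (underscores to spaces, collapsed whitespace, subspecies
# epithet stripped; case-sensitive thereafter). A taxon matched in pass 1 is
# excluded from pass 2, so identifier matches always take priority; when the
# two passes would disagree the identifier match is kept and the name
# discrepancy recorded. Duplicate identifiers and homonymous labels are
# never matched — they are flagged. No fuzzy matching, no synonym services.

#' Reconcile matrix species names with tree tip labels
#'
#' @param matrix_taxa data frame with columns `taxon_id`, `name` and
#'   optionally `ncbi_id` (external identifier, `NA` when absent).
#' @param tree_tips character vector of tip labels.
#' @param tip_xref optional data frame with columns `label`, `ncbi_id`
#'   giving external identifiers for tips.
#' @return object of class `reconciliation_report`: `matches` (data frame
#'   `taxon_id`, `name`, `tip`, `method` (`id`/`exact_name`),
#'   `name_discrepancy`), `unmatched_taxa` (`taxon_id`, `name`, `category`,
#'   filled by [classify_unmatched()]), `unmatched_tips`, and `flags`
#'   (duplicate identifiers, homonymous labels).
#' @details The mapping is injective in both directions; shuffling input
#'   order never changes the match set.
#' @export
reconcile_names <- function(matrix_taxa, tree_tips, tip_xref = NULL) {
  stopifnot(all(c("taxon_id", "name") %in% names(matrix_taxa)))
  if (!"ncbi_id" %in% names(matrix_taxa)) matrix_taxa$ncbi_id <- NA
  mt <- matrix_taxa[order(matrix_taxa$taxon_id), , drop = FALSE]
  tips <- sort(tree_tips)   # duplicates kept: homonyms must be detectable
  flags <- list()
  add_flag <- function(item, side, reason)
    flags[[length(flags) + 1L]] <<- data.frame(
      item = item, side = side, reason = reason, stringsAsFactors = FALSE)

  # --- pass 1: external identifiers -------------------------------------
  tip_id <- rep(NA_real_, length(tips))
  if (!is.null(tip_xref) && nrow(tip_xref)) {
    tip_id <- as.numeric(tip_xref$ncbi_id[match(tips, tip_xref$label)])
  }
  mat_id <- suppressWarnings(as.numeric(mt$ncbi_id))

  dup_m <- !is.na(mat_id) & mat_id %in% mat_id[duplicated(mat_id) & !is.na(mat_id)]
  dup_t <- !is.na(tip_id) & tip_id %in% tip_id[duplicated(tip_id) & !is.na(tip_id)]
  for (v in unique(mat_id[dup_m]))
    add_flag(as.character(v), "matrix", "duplicate_id")
  for (v in unique(tip_id[dup_t]))
    add_flag(as.character(v), "tree", "duplicate_id")

  usable_m <- !is.na(mat_id) & !dup_m
  usable_t <- !is.na(tip_id) & !dup_t
  pos <- match(mat_id, ifelse(usable_t, tip_id, NA))
  pos[!usable_m] <- NA
  id_matched <- !is.na(pos)
  m1 <- data.frame(
    taxon_id = mt$taxon_id[id_matched],
    name = mt$name[id_matched],
    tip = tips[pos[id_matched]],
    method = if (any(id_matched)) "id" else character(0),
    stringsAsFactors = FALSE)

  # --- pass 2: exact normalized names -----------------------------------
  rem_m <- mt[!id_matched, , drop = FALSE]
  rem_t <- tips[!(tips %in% m1$tip)]
  norm_m <- normalize_name(rem_m$name)
  norm_t <- normalize_name(rem_t)
  homonym <- norm_t %in% norm_t[duplicated(norm_t)]
  for (v in unique(rem_t[homonym]))
    add_flag(v, "tree", "homonymous_label")
  dup_name_m <- norm_m %in% norm_m[duplicated(norm_m)]
  for (v in unique(rem_m$name[dup_name_m]))
    add_flag(v, "matrix", "duplicate_name")
  pos2 <- match(norm_m, ifelse(homonym, NA, norm_t))
  pos2[dup_name_m] <- NA
  nm_matched <- !is.na(pos2)
  m2 <- data.frame(
    taxon_id = rem_m$taxon_id[nm_matched],
    name = rem_m$name[nm_matched],
    tip = rem_t[pos2[nm_matched]],
    method = if (any(nm_matched)) "exact_name" else character(0),
    stringsAsFactors = FALSE)

  matches <- rbind(m1, m2)
  matches$name_discrepancy <- normalize_name(matches$name) !=
    normalize_name(matches$tip)
  matches <- matches[order(matches$taxon_id), , drop = FALSE]
  rownames(matches) <- NULL

  un_m <- mt[!mt$taxon_id %in% matches$taxon_id, c("taxon_id", "name")]
  un_m$category <- rep(NA_character_, nrow(un_m))
  rownames(un_m) <- NULL
  structure(list(
    matches = matches,
    unmatched_taxa = un_m,
    unmatched_tips = tips[!(tips %in% matches$tip)],
    flags = if (length(flags)) do.call(rbind, flags) else data.frame(
      item = character(0), side = character(0), reason = character(0),
      stringsAsFactors = FALSE)),
    class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  tab <- table(x$matches$method)
  cat("Name reconciliation:", nrow(x$matches), "matched (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ");",
      nrow(x$unmatched_taxa), "matrix taxa and",
      length(x$unmatched_tips), "tips unmatched\n")
  if (!all(is.na(x$unmatched_taxa$category))) {
    ct <- table(x$unmatched_taxa$category)
    cat("  unmatched taxa:",
        paste(sprintf("%s: %d", names(ct), ct), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Categorize unmatched matrix taxa
#'
#' Labels each unmatched matrix taxon `fossil` (extinct flag in the
#' taxonomy), `unconventional_name` (fails the strict `Genus species`
#' binomial pattern after normalization), or `other`.
#'
#' @param report a `reconciliation_report`.
#' @param taxonomy a [taxonomy()] (source of the extinct flag).
#' @return the report with `unmatched_taxa$category` filled; the category
#'   counts are attached as attribute `counts`.
#' @export
classify_unmatched <- function(report, taxonomy) {
  un <- report$unmatched_taxa
  if (nrow(un)) {
    ext <- taxonomy$table$extinct[match(un$taxon_id, taxonomy$table$id)]
    ext[is.na(ext)] <-
      taxonomy$table$extinct[match(un$name[is.na(ext)], taxonomy$table$name)]
    ext[is.na(ext)] <- FALSE
    un$category <- ifelse(ext, "fossil",
                          ifelse(!is_binomial(normalize_name(un$name)),
                                 "unconventional_name", "other"))
  }
  report$unmatched_taxa <- un
  attr(report, "counts") <- table(factor(
    un$category, levels = c("fossil", "unconventional_name", "other")))
  report
}
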