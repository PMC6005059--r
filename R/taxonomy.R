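# Rank-annotated taxonomy (family -> genus -> species) with optional external
# (NCBI-style) identifier cross-references and an extinct flag. Stored as a
# parent-pointer table, the same shape the VTO-like input TSV has.

#' Construct a taxonomy object
#'
#' @param df data frame with columns `id`, `name`, `rank`
#'   (`root`/`family`/`genus`/`species` or other rank labels), `parent_id`
#'   (`NA` for the root), and optionally `ncbi_id` (integer cross-reference)
#'   and `extinct` (logical).
#' @return object of class `taxonomy`.
#' @export
taxonomy <- function(df) {
  need <- c("id", "name", "rank", "parent_id")
  if (!all(need %in% names(df)))
    stop("taxonomy needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate taxonomy ids")
  if (!"ncbi_id" %in% names(df)) df$ncbi_id <- NA_integer_
  if (!"extinct" %in% names(df)) df$extinct <- FALSE
  df$extinct[is.na(df$extinct)] <- FALSE
  known <- is.na(df$parent_id) | df$parent_id %in% df$id
  if (!all(known))
    stop("dangling parent_id(s): ",
         paste(unique(df$parent_id[!known]), collapse = ", "))
  rownames(df) <- NULL
  structure(list(table = df[, c("id", "name", "rank", "parent_id",
                                "ncbi_id", "extinct")]),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  tab <- table(x$table$rank)
  cat("Taxonomy with", nrow(x$table), "records (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

taxon_rank <- function(tax, ids) {
  x <- tax$table
  x$rank[match(ids, x$id)]
}

taxon_name <- function(tax, ids) {
  x <- tax$table
  x$name[match(ids, x$id)]
}

taxon_id_by_name <- function(tax, names) {
  x <- tax$table
  x$id[match(names, x$name)]
}

# all species-rank descendants of each id (themselves included if species)
species_under <- function(tax, id) {
  x <- tax$table
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    if (any(x$rank[match(frontier, x$id)] == "species", na.rm = TRUE))
      out <- c(out, frontier[x$rank[match(frontier, x$id)] == "species"])
    frontier <- x$id[!is.na(x$parent_id) & x$parent_id %in% frontier]
  }
  unique(out)
}

#' Read / write a taxonomy TSV
#'
#' Columns as in [taxonomy()]. `NA` cells are written empty.
#' @param path file path.
#' @return [read_taxonomy()] returns a `taxonomy`; [write_taxonomy()] its path.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  df$extinct <- as.logical(df$extinct)
  taxonomy(df)
}

#' @rdname read_taxonomy
#' @param tax a `taxonomy` object.
#' @export
write_taxonomy <- function(tax, path) {
  write_tsv(tax$table, path)
}
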