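# Phenotype annotations in a flattened Entity-Quality form.
#
# A row states that, in taxon `taxon_id`, anatomical entity `entity` shows
# quality `quality`. The special quality "absent" implies the entity is
# absent; any other quality (including "present") implies it is present.
# `provenance` is "asserted" (author statement, carries a `study` tag),
# "inferred" (produced by the ontology closure, carries a derivation `chain`)
# or "propagated" (copied from a higher taxon).

ANNOTATION_COLS <- c("taxon_id", "entity", "quality", "provenance",
                     "study", "chain")

#' Build a phenotype annotation table
#'
#' @param taxon_id,entity,quality,provenance,study,chain character vectors
#'   (recycled to a common length).
#' @return data frame with the standard annotation columns.
#' @export
annotation_table <- function(taxon_id, entity, quality,
                             provenance = "asserted", study = "", chain = "") {
  df <- data.frame(taxon_id = taxon_id, entity = entity, quality = quality,
                   provenance = provenance, study = study, chain = chain,
                   stringsAsFactors = FALSE)
  miss <- df$provenance == "asserted" & (is.na(df$study) | df$study == "")
  if (any(miss)) df$study[miss] <- "unspecified"
  df
}

empty_annotations <- function() {
  as.data.frame(setNames(rep(list(character(0)), length(ANNOTATION_COLS)),
                         ANNOTATION_COLS), stringsAsFactors = FALSE)
}

implied_state <- function(quality) ifelse(quality == "absent", "absent", "present")

#' Read / write annotation TSVs
#' @param path file path.
#' @return [read_annotations()] returns the annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  for (col in ANNOTATION_COLS)
    if (!col %in% names(df)) df[[col]] <- ""
  df[, ANNOTATION_COLS]
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  write_tsv(ann[, ANNOTATION_COLS], path)
}
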