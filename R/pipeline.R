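# End-to-end pipeline: inference -> assembly -> scrubbing -> propagation ->
# reconciliation -> merge -> ancestral state reconstruction, with every
# intermediate written to disk so each stage can be re-run and audited.

#' Pipeline configuration
#'
#' All inputs are files; all knobs are explicit. A single master seed fans
#' out to per-stage seeds by fixed offsets, so stages are individually
#' reproducible.
#'
#' @param annotations,taxonomy,tree paths to the annotation TSV, taxonomy
#'   TSV and newick/NEXUS tree.
#' @param anatomy_edges,anatomy_terms paths to the anatomy graph TSVs
#'   (term table optional).
#' @param tree_xref optional TSV (`label`, `ncbi_id`) with tip identifiers.
#' @param out_dir output directory (created if needed).
#' @param characters character terms to analyse.
#' @param mpr_samples MPRs sampled per character for the change summary.
#' @param polytomy_replicates random polytomy resolutions for the
#'   minimum-regain search (forced to 1 on a fully binary tree).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations, taxonomy, tree,
                            anatomy_edges, anatomy_terms = NULL,
                            tree_xref = NULL, out_dir = "pipeline_out",
                            characters = c("pectoral fin", "pelvic fin"),
                            mpr_samples = 1000L,
                            polytomy_replicates = 1000L,
                            seed = 1L) {
  cfg <- list(annotations = annotations, taxonomy = taxonomy, tree = tree,
              anatomy_edges = anatomy_edges, anatomy_terms = anatomy_terms,
              tree_xref = tree_xref, out_dir = out_dir,
              characters = characters,
              mpr_samples = as.integer(mpr_samples),
              polytomy_replicates = as.integer(polytomy_replicates),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

check_config <- function(cfg) {
  for (f in c("annotations", "taxonomy", "tree", "anatomy_edges")) {
    p <- cfg[[f]]
    if (!is.character(p) || !file.exists(p))
      stop("config path '", f, "' does not exist: ", p)
  }
  for (f in c("anatomy_terms", "tree_xref")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config path '", f, "' does not exist: ", p)
  }
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

species_only <- function(matrix) {
  keep <- matrix$taxa$taxon_id[matrix$taxa$rank == "species"]
  cells <- matrix$cells[matrix$cells$taxon_id %in% keep, , drop = FALSE]
  taxa <- matrix$taxa[matrix$taxa$rank == "species", , drop = FALSE]
  new_supermatrix(cells, taxa, matrix$characters)
}

#' Run the full integration pipeline
#'
#' Executes inference, matrix assembly, apparent-polymorphism scrubbing,
#' propagation, name reconciliation, tree merging and parsimony ancestral
#' state reconstruction, writing every intermediate artifact (matrices,
#' logs, the merged NEXUS, missing-data and change summaries, a
#' machine-readable run report) into the configured output directory.
#' Rerunning with the same inputs and seed reproduces every artifact
#' byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return the run report (a list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  check_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- run_stage("load_inputs", {
    list(ann = read_annotations(config$annotations),
         tax = read_taxonomy(config$taxonomy),
         graph = read_anatomy_graph(config$anatomy_edges,
                                    config$anatomy_terms),
         tree = if (grepl("\\.nex(us)?$", config$tree,
                          ignore.case = TRUE)) ape::read.nexus(config$tree)
                else ape::read.tree(config$tree),
         tip_xref = if (!is.null(config$tree_xref))
           read_tsv(config$tree_xref))
  })

  closure <- run_stage("inference", {
    cl <- infer_closure(inputs$ann, inputs$graph)
    write_annotations(cl, out("annotations_closure.tsv"))
    cl
  })

  conflicts <- run_stage("conflict_detection", {
    cf <- detect_conflicts(closure, inputs$tax)
    write_tsv(as.data.frame(cf), out("conflicts.tsv"))
    cf
  })

  assembled <- run_stage("assembly", {
    sm <- assemble_supermatrix(closure, config$characters, inputs$tax,
                               inputs$graph)
    write_supermatrix(sm, out("matrix_assembled.tsv"))
    sm
  })

  scrubbed <- run_stage("scrubbing", {
    sc <- scrub_apparent_polymorphisms(assembled, inputs$tax)
    write_supermatrix(sc$matrix, out("matrix_scrubbed.tsv"))
    write_tsv(sc$log, out("scrub_log.tsv"))
    sc$matrix
  })

  prop <- run_stage("propagation", {
    pr <- propagate_to_species(scrubbed, inputs$tax)
    write_supermatrix(pr$matrix, out("matrix_species.tsv"))
    write_tsv(pr$log, out("propagation_log.tsv"))
    ps <- propagation_summary(pr$log)
    write_tsv(ps$totals, out("propagation_summary.tsv"))
    write_tsv(ps$per_character, out("propagation_by_character.tsv"))
    c(pr, list(summary = ps))
  })

  n_tips <- ape::Ntip(inputs$tree)
  missing <- run_stage("missing_data", {
    before <- species_only(scrubbed)
    n_final <- nrow(prop$matrix$taxa)
    ms <- rbind(
      cbind(stage = "before_propagation",
            missing_stats(before, n_final, "final_species_set")),
      cbind(stage = "before_propagation",
            missing_stats(before, n_tips, "tree_tip_set")),
      cbind(stage = "after_propagation",
            missing_stats(prop$matrix, n_final, "final_species_set")),
      cbind(stage = "after_propagation",
            missing_stats(prop$matrix, n_tips, "tree_tip_set")))
    write_tsv(ms, out("missing_data.tsv"))
    ms
  })

  recon <- run_stage("reconciliation", {
    mt <- prop$matrix$taxa
    mt$ncbi_id <- inputs$tax$table$ncbi_id[match(mt$taxon_id,
                                                 inputs$tax$table$id)]
    rp <- reconcile_names(mt, inputs$tree$tip.label, inputs$tip_xref)
    rp <- classify_unmatched(rp, inputs$tax)
    write_tsv(rp$matches, out("reconciliation_matches.tsv"))
    write_tsv(rp$unmatched_taxa, out("reconciliation_unmatched_taxa.tsv"))
    write_tsv(data.frame(tip = rp$unmatched_tips),
              out("reconciliation_unmatched_tips.tsv"))
    rp
  })

  tip_states <- run_stage("merge", {
    ts <- merge_tip_states(prop$matrix, inputs$tree, recon)
    write_tsv(cbind(tip = rownames(ts), ts), out("tip_states.tsv"))
    write_merged_nexus(inputs$tree, ts, out("merged.nex"),
                       seed = config$seed)
    ts
  })

  asr <- run_stage("asr", {
    has_polytomy <- any(lengths(node_children(inputs$tree)) > 2L)
    n_res <- if (has_polytomy) config$polytomy_replicates else 1L
    res <- list()
    for (i in seq_along(config$characters)) {
      ch <- config$characters[i]
      states <- setNames(tip_states[[ch]], rownames(tip_states))
      summ <- asr_summary(inputs$tree, states,
                          n_samples = config$mpr_samples,
                          seed = mix_seed(config$seed, 500L + i))
      reg <- min_regains_over_resolutions(
        inputs$tree, states, n_resolutions = n_res,
        seed = mix_seed(config$seed, 600L + i))
      write_tsv(reg$replicates,
                out(sprintf("polytomy_replicates_%d.tsv", i)))
      res[[ch]] <- list(summary = summ, regains = reg)
    }
    tab <- do.call(rbind, lapply(names(res), function(ch) {
      s <- res[[ch]]$summary
      data.frame(character = ch, length = s$length,
                 mpr_count = format(s$mpr_count),
                 gain_min = s$gain["min"], gain_max = s$gain["max"],
                 loss_min = s$loss["min"], loss_max = s$loss["max"],
                 sampled_gain_mean = s$sampled$mean[1],
                 sampled_loss_mean = s$sampled$mean[2],
                 min_regains_over_resolutions = res[[ch]]$regains$min_regains,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(tab, out("asr_summary.tsv"))
    list(per_character = res, table = tab)
  })

  report <- list(
    seed = config$seed,
    characters = config$characters,
    n_annotations = nrow(inputs$ann),
    n_inferred = sum(closure$provenance == "inferred"),
    n_conflicts = nrow(conflicts),
    conflict_categories = as.list(table(conflicts$category)),
    matrix_taxa = nrow(assembled$taxa),
    species_in_final_matrix = nrow(prop$matrix$taxa),
    species_added_by_propagation = prop$summary$totals$species_added,
    tree_tips = n_tips,
    species_matched = nrow(recon$matches),
    missing_percent = setNames(
      missing$percent_missing[missing$character == "(total)"],
      paste(missing$stage[missing$character == "(total)"],
            missing$denominator[missing$character == "(total)"], sep = ":")),
    asr = lapply(asr$per_character, function(x) list(
      length = x$summary$length,
      mpr_count = format(x$summary$mpr_count),
      gain = as.list(x$summary$gain), loss = as.list(x$summary$loss),
      sampled_gain_mean = x$summary$sampled$mean[1],
      sampled_loss_mean = x$summary$sampled$mean[2],
      min_regains = x$regains$min_regains)))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(report, list(
    objects = list(closure = closure, conflicts = conflicts,
                   assembled = assembled, scrubbed = scrubbed,
                   propagated = prop, reconciliation = recon,
                   tip_states = tip_states, asr = asr,
                   tree = inputs$tree, taxonomy = inputs$tax))))
}

#' Write a ready-to-run synthetic fixture set
#'
#' Generates a taxonomy, the fin anatomy template, a tree, a planted trait
#' history and asserted annotations from a scenario, and writes them (plus
#' the ground-truth sidecars) into a directory that [run_pipeline()] can
#' consume directly.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory.
#' @return invisibly, a list with the generated objects and a
#'   [pipeline_config()] pointing at the written files.
#' @export
make_fixtures <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tax <- generate_taxonomy(scenario)
  graph <- generate_anatomy_template()
  tree <- generate_tree(tax, scenario)
  truth <- plant_trait_history(tree, scenario)
  ann <- generate_annotations(truth, tax, graph, scenario)

  write_taxonomy(tax, p("taxonomy.tsv"))
  write_anatomy_graph(graph, p("anatomy_edges.tsv"), p("anatomy_terms.tsv"))
  write_annotations(ann, p("annotations.tsv"))
  ape::write.tree(tree, p("tree.nwk"))

  tm <- truth$tip_map
  xref_sp <- tax$table[match(tm$species, tax$table$name), "ncbi_id"]
  ok <- !tm$perturbed & !tm$extra & !is.na(xref_sp)
  write_tsv(data.frame(label = tm$tip[ok], ncbi_id = xref_sp[ok]),
            p("tree_xref.tsv"))
  write_tsv(tm, p("tip_map.tsv"))
  states <- do.call(rbind, lapply(names(truth$characters), function(ch)
    data.frame(tip = names(truth$characters[[ch]]$tip_states),
               character = ch,
               state = unname(truth$characters[[ch]]$tip_states),
               stringsAsFactors = FALSE)))
  write_tsv(states, p("truth_tip_states.tsv"))
  events <- do.call(rbind, lapply(truth$characters, `[[`, "events"))
  write_tsv(events, p("truth_events.tsv"))
  yaml::write_yaml(unclass(scenario), p("scenario.yaml"))

  cfg <- pipeline_config(
    annotations = p("annotations.tsv"), taxonomy = p("taxonomy.tsv"),
    tree = p("tree.nwk"), anatomy_edges = p("anatomy_edges.tsv"),
    anatomy_terms = p("anatomy_terms.tsv"), tree_xref = p("tree_xref.tsv"),
    out_dir = file.path(dir, "out"), seed = scenario$seed)
  invisible(list(taxonomy = tax, graph = graph, tree = tree, truth = truth,
                 annotations = ann, config = cfg, dir = dir))
}
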