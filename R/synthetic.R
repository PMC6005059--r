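# Synthetic study system with known ground truth.
#
# The generator emulates the shape of the real inputs at desk scale: a
# 3-rank taxonomy (family/genus/species) with partial external-identifier
# coverage; a rooted species tree that respects taxonomy monophyly but has
# polytomies, perturbed tip names and extra tips unknown to the taxonomy;
# per-character presence/absence histories planted as loss and regain events
# on tree branches; and asserted phenotype annotations at mixed taxonomic
# levels, expressed directly ("fin absent") or indirectly (a quality on a
# fin ray, an absent girdle), with injected species-level conflicts.
#
# Everything is a pure function of the scenario (including its seed):
# identical scenarios give byte-identical outputs.

#' Define a synthetic scenario
#'
#' All stochastic choices in the generator derive from `seed`; every fraction
#' must lie in `[0, 1]` and every count must be positive.
#'
#' @param seed master seed.
#' @param n_families number of families.
#' @param genera_per_family,species_per_genus inclusive integer ranges
#'   (`c(min, max)`) sampled per family / per genus.
#' @param event_count_loss,event_count_regain number of presence-to-absence
#'   and absence-to-presence transitions planted per character.
#' @param species_coverage fraction of species receiving direct annotations.
#' @param indirect_fraction fraction of annotations expressed indirectly (a
#'   part-level quality for presence; an absent girdle for absence) rather
#'   than as a direct fin statement.
#' @param higher_level_fraction fraction of monomorphic genera/families whose
#'   member-species annotations are replaced by one higher-rank annotation.
#' @param conflict_rate fraction of annotated species given contradictory
#'   statements (asserted absence plus presence-implying part quality).
#' @param polytomy_fraction fraction of internal tree nodes collapsed into
#'   polytomies.
#' @param mismatch_rate fraction of tip names perturbed (deterministic
#'   suffix `"_x"`) so they no longer match the taxonomy.
#' @param extra_tip_rate expected fraction of extra tips with no taxonomy
#'   counterpart, inserted inside random clades.
#' @param xref_fraction fraction of species records carrying a synthetic
#'   NCBI-like integer cross-reference.
#' @param placement `"sparse"` (default; events on non-nested branches
#'   except that each regain sits inside its own loss clade, with structural
#'   guarantees that parsimony recovers exactly the planted counts) or
#'   `"nested"` (unconstrained nesting; recovery only bounds the length).
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_families = 12L,
                               genera_per_family = c(2L, 5L),
                               species_per_genus = c(2L, 8L),
                               event_count_loss = 6L,
                               event_count_regain = 2L,
                               species_coverage = 0.25,
                               indirect_fraction = 0.8,
                               higher_level_fraction = 0.3,
                               conflict_rate = 0.02,
                               polytomy_fraction = 0.25,
                               mismatch_rate = 0.05,
                               extra_tip_rate = 0.15,
                               xref_fraction = 0.5,
                               placement = c("sparse", "nested")) {
  stopifnot_count(seed, "seed", positive = FALSE)
  stopifnot_count(n_families, "n_families")
  stopifnot_count(genera_per_family, "genera_per_family")
  stopifnot_count(species_per_genus, "species_per_genus")
  stopifnot_count(event_count_loss, "event_count_loss", positive = FALSE)
  stopifnot_count(event_count_regain, "event_count_regain", positive = FALSE)
  for (f in c("species_coverage", "indirect_fraction",
              "higher_level_fraction", "conflict_rate", "polytomy_fraction",
              "mismatch_rate", "extra_tip_rate", "xref_fraction"))
    stopifnot_fraction(get(f), f)
  if (length(genera_per_family) == 1L)
    genera_per_family <- rep(genera_per_family, 2L)
  if (length(species_per_genus) == 1L)
    species_per_genus <- rep(species_per_genus, 2L)
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family[1:2]),
    species_per_genus = as.integer(species_per_genus[1:2]),
    event_count_loss = as.integer(event_count_loss),
    event_count_regain = as.integer(event_count_regain),
    species_coverage = species_coverage,
    indirect_fraction = indirect_fraction,
    higher_level_fraction = higher_level_fraction,
    conflict_rate = conflict_rate,
    polytomy_fraction = polytomy_fraction,
    mismatch_rate = mismatch_rate,
    extra_tip_rate = extra_tip_rate,
    xref_fraction = xref_fraction,
    placement = match.arg(placement)), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed ", x$seed, "): ", x$n_families,
      " families, losses=", x$event_count_loss, ", regains=",
      x$event_count_regain, ", coverage=", x$species_coverage,
      ", placement=", x$placement, "\n", sep = "")
  invisible(x)
}

# sample one integer from an inclusive range (safe when min == max)
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

# base-26 lowercase suffix: 1 -> "aa", 2 -> "ab", ...
alpha_suffix <- function(i, width = 2L) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k] - 1L
    s <- ""
    for (j in seq_len(width)) {
      s <- paste0(letters[v %% 26L + 1L], s)
      v <- v %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Generate a three-rank taxonomy
#'
#' Families, genera and species under a single supra-familial root; a
#' configurable fraction of species carry a synthetic integer
#' cross-reference. Same scenario, same output.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [taxonomy()].
#' @export
generate_taxonomy <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$n_families < 1L) stop("need at least one family")
  with_seed(mix_seed(scenario$seed, 101L), {
    rows <- list(data.frame(id = "TAX:000001", name = "Teleostei",
                            rank = "root", parent_id = NA_character_,
                            stringsAsFactors = FALSE))
    nid <- 1L
    next_id <- function() {
      nid <<- nid + 1L
      sprintf("TAX:%06d", nid)
    }
    gi <- 0L
    for (f in seq_len(scenario$n_families)) {
      fid <- next_id()
      rows[[length(rows) + 1L]] <- data.frame(
        id = fid, name = paste0("Fam", alpha_suffix(f), "idae"),
        rank = "family", parent_id = "TAX:000001", stringsAsFactors = FALSE)
      ng <- sample_range(scenario$genera_per_family[1],
                         scenario$genera_per_family[2])
      for (g in seq_len(ng)) {
        gi <- gi + 1L
        gid <- next_id()
        gname <- paste0("Gen", alpha_suffix(gi))
        rows[[length(rows) + 1L]] <- data.frame(
          id = gid, name = gname, rank = "genus", parent_id = fid,
          stringsAsFactors = FALSE)
        ns <- sample_range(scenario$species_per_genus[1],
                           scenario$species_per_genus[2])
        for (s in seq_len(ns)) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = next_id(), name = paste0(gname, " sp", alpha_suffix(s)),
            rank = "species", parent_id = gid, stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    df$ncbi_id <- NA_integer_
    sp <- which(df$rank == "species")
    gets <- sp[runif(length(sp)) < scenario$xref_fraction]
    # distinct pseudo-NCBI integers
    df$ncbi_id[gets] <- sample(100000L:999999L, length(gets))
    df$extinct <- FALSE
    taxonomy(df)
  })
}

#' Generate a species tree from a taxonomy
#'
#' Builds the tree by random sequential joining of species within each
#' genus, genera within each family, and families under the root, so every
#' taxon is monophyletic. A fraction of internal nodes is then collapsed
#' into polytomies, a fraction of tip names perturbed with the suffix
#' `"_x"`, and extra tips (no taxonomy counterpart) inserted inside random
#' clades. No branch lengths.
#'
#' @param taxonomy a [taxonomy()].
#' @param scenario a [synthetic_scenario()].
#' @return a rooted `phylo`; attribute `"tip_map"` maps each final tip label
#'   to its species name (`NA` for extra tips) and records perturbations.
#' @export
generate_tree <- function(taxonomy, scenario) {
  tab <- taxonomy$table
  with_seed(mix_seed(scenario$seed, 202L), {
    fam_frags <- character(0)
    for (fid in tab$id[tab$rank == "family"]) {
      gen_frags <- character(0)
      for (gid in tab$id[tab$rank == "genus" & tab$parent_id == fid]) {
        sp <- tab$name[tab$rank == "species" & tab$parent_id == gid]
        gen_frags <- c(gen_frags, random_join(gsub(" ", "_", sp)))
      }
      fam_frags <- c(fam_frags, random_join(gen_frags))
    }
    txt <- if (length(fam_frags) == 1L &&
               !grepl("^\\(", fam_frags)) paste0("(", fam_frags, ");")
           else if (length(fam_frags) == 1L) paste0(fam_frags, ";")
           else paste0(random_join(fam_frags), ";")
    phy <- ape::read.tree(text = txt)

    # polytomies: collapse a fraction of non-root internal nodes
    nt <- ape::Ntip(phy)
    internals <- setdiff(nt + seq_len(phy$Nnode), tree_root(phy))
    coll <- internals[runif(length(internals)) < scenario$polytomy_fraction]
    phy <- collapse_internal_nodes(phy, coll)

    # extra tips with no taxonomy counterpart, as extra children of random
    # internal nodes
    nt <- ape::Ntip(phy)
    n_extra <- rbinom(1L, nt, scenario$extra_tip_rate)
    if (n_extra > 0L) {
      pcl <- phylo_children_labels(phy)
      children <- pcl$children
      labels <- pcl$labels
      hosts <- sample(which(lengths(children) > 0L), n_extra, replace = TRUE)
      for (i in seq_len(n_extra)) {
        labels <- c(labels, paste0("Xenus_nov", alpha_suffix(i)))
        children[[length(labels)]] <- integer(0)
        children[[hosts[i]]] <- c(children[[hosts[i]]], length(labels))
      }
      phy <- ape::read.tree(text = children_to_newick(
        children, labels, tree_root(phy)))
    }

    # name perturbation: deterministic "_x" suffix
    species <- gsub("_", " ", phy$tip.label)
    is_extra <- grepl("^Xenus_nov", phy$tip.label)
    species[is_extra] <- NA_character_
    perturb <- !is_extra & runif(length(species)) < scenario$mismatch_rate
    phy$tip.label[perturb] <- paste0(phy$tip.label[perturb], "_x")

    attr(phy, "tip_map") <- data.frame(
      tip = phy$tip.label, species = species,
      perturbed = perturb, extra = is_extra, stringsAsFactors = FALSE)
    phy
  })
}

# ---------------------------------------------------------------------------
# trait history planting

# Maximal fully-absent fragments inside loss clade `croot` when subtree
# `rnode` is marked present again. Structural helper for sparse placement.
count_absent_fragments <- function(croot, rnode, children, tipsets) {
  in_r <- tipsets[[rnode]]
  frag <- 0L
  # walk the clade; a child subtree disjoint from Ri and fully inside Ci is
  # one absent fragment; a subtree containing Ri is descended into
  walk <- function(v) {
    for (ch in children[[v]]) {
      if (ch == rnode) next
      if (length(intersect(tipsets[[ch]], in_r)) == 0L) frag <<- frag + 1L
      else walk(ch)
    }
  }
  walk(croot)
  frag
}

place_events_sparse <- function(phy, L, R, max_tries = 40L) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  root <- tree_root(phy)
  children <- node_children(phy)
  parent <- integer(n)
  for (p in seq_len(n)) parent[children[[p]]] <- p
  tipsets <- subtree_tip_sets(phy)
  sizes <- lengths(tipsets)
  max_size <- max(2L, floor(nt / 3))
  cand <- setdiff(seq_len(n), root)
  cand <- cand[sizes[cand] <= max_size]

  try_once <- function() {
    forbidden <- integer(0)      # tips inside loss or witness subtrees
    used_parents <- integer(0)
    losses <- integer(0)
    regains <- integer(0)
    order_cand <- sample(cand)
    # regain hosts need room for >= 3 residual absent fragments
    if (R > 0L)
      order_cand <- order_cand[order(-(sizes[order_cand] >= 5L))]
    for (v in order_cand) {
      if (length(losses) == L) break
      need_host <- length(losses) < R
      if (need_host && sizes[v] < 5L) next
      if (parent[v] %in% used_parents) next
      if (length(intersect(tipsets[[v]], forbidden))) next
      sibs <- setdiff(children[[parent[v]]], v)
      ok_sib <- sibs[vapply(sibs, function(s)
        length(intersect(tipsets[[s]], forbidden)) == 0L &&
          length(intersect(tipsets[[s]], tipsets[[v]])) == 0L, logical(1))]
      if (length(ok_sib) == 0L) next
      rg <- NA_integer_
      if (need_host) {
        inside <- setdiff(which(vapply(seq_len(n), function(w)
          length(tipsets[[w]]) < sizes[v] &&
            all(tipsets[[w]] %in% tipsets[[v]]), logical(1))), v)
        feas <- inside[vapply(inside, function(w)
          count_absent_fragments(v, w, children, tipsets) >= 3L, logical(1))]
        if (length(feas) == 0L) next
        rg <- feas[sample.int(length(feas), 1L)]
      }
      witness <- ok_sib[sample.int(length(ok_sib), 1L)]
      losses <- c(losses, v)
      if (!is.na(rg)) regains <- c(regains, rg)
      used_parents <- c(used_parents, parent[v])
      forbidden <- c(forbidden, tipsets[[v]], tipsets[[witness]])
    }
    if (length(losses) == L && length(regains) == R)
      list(losses = losses, regains = regains)
    else NULL
  }
  for (k in seq_len(max_tries)) {
    res <- try_once()
    if (!is.null(res)) return(res)
  }
  stop("sparse placement impossible: cannot fit ", L, " losses and ", R,
       " regains on distinct, non-nested branches of this tree")
}

place_events_nested <- function(phy, L, R, max_tries = 40L) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  root <- tree_root(phy)
  children <- node_children(phy)
  parent <- integer(n)
  for (p in seq_len(n)) parent[children[[p]]] <- p
  for (k in seq_len(max_tries)) {
    losses <- sample(setdiff(seq_len(n), root), min(L, n - 1L))
    if (length(losses) < L) break
    st <- replay_states(phy, losses, integer(0))$node_state
    cand_r <- setdiff(which(st[parent] == 0L & seq_len(n) != root), losses)
    cand_r <- cand_r[!is.na(cand_r)]
    if (length(cand_r) >= R) {
      regains <- if (R > 0L) sample(cand_r, R) else integer(0)
      return(list(losses = losses, regains = regains))
    }
  }
  stop("nested placement impossible: no absent region to host ", R,
       " regain(s)")
}

# replay: presence at the root, events flip the state on their branch
replay_states <- function(phy, losses, regains) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  root <- tree_root(phy)
  st <- rep(NA_integer_, n)
  st[root] <- 1L
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in rev(seq_len(nrow(e)))) {   # preorder
    p <- e[k, 1]; ch <- e[k, 2]
    st[ch] <- if (ch %in% losses) 0L else if (ch %in% regains) 1L else st[p]
  }
  list(node_state = st,
       tip_state = setNames(as.character(st[seq_len(nt)]), phy$tip.label))
}

#' Plant a presence/absence history on a tree
#'
#' Assigns presence at the root and places the requested loss and regain
#' transitions on branches, once per character, deriving tip states by
#' replay. In `"sparse"` mode, losses are pairwise non-nested with distinct
#' parent nodes and a reserved presence-only sibling clade each, and every
#' regain sits inside its own loss clade leaving at least three disjoint
#' absent fragments around it; these conditions make the planted history the
#' unique-cost parsimony optimum, so the parsimony length equals the number
#' of planted events and the exact minimum gain count equals the number of
#' regains. Impossible placement is an error, never silently relaxed.
#'
#' @param tree a `phylo` from [generate_tree()] (its `"tip_map"` attribute,
#'   when present, links tips to species).
#' @param scenario a [synthetic_scenario()].
#' @param characters character names to plant independent histories for.
#' @return object of class `ground_truth`: per character the planted events
#'   (branch child node, type) and per-tip true states; plus the tip map.
#' @export
plant_trait_history <- function(tree, scenario,
                                characters = c("pectoral fin", "pelvic fin")) {
  stopifnot(inherits(tree, "phylo"))
  L <- scenario$event_count_loss
  R <- scenario$event_count_regain
  if (R > L) stop("each regain needs its own loss clade: regains must not ",
                  "exceed losses")
  tip_map <- attr(tree, "tip_map")
  if (is.null(tip_map))
    tip_map <- data.frame(tip = tree$tip.label,
                          species = gsub("_", " ", tree$tip.label),
                          perturbed = FALSE, extra = FALSE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_along(characters)) {
    ch <- characters[i]
    with_seed(mix_seed(scenario$seed, 300L + i), {
      ev <- if (L == 0L && R == 0L) list(losses = integer(0),
                                         regains = integer(0))
            else if (scenario$placement == "sparse")
              place_events_sparse(tree, L, R)
            else place_events_nested(tree, L, R)
      rp <- replay_states(tree, ev$losses, ev$regains)
      nodes <- c(ev$losses, ev$regains)
      out[[ch]] <- list(
        events = data.frame(
          character = rep(ch, length(nodes)),
          node = nodes,
          type = c(rep("loss", length(ev$losses)),
                   rep("regain", length(ev$regains))),
          stringsAsFactors = FALSE),
        tip_states = rp$tip_state)
    })
  }
  structure(list(characters = out, tip_map = tip_map,
                 placement = scenario$placement,
                 seed = scenario$seed), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  for (ch in names(x$characters)) {
    ev <- x$characters[[ch]]$events
    cat(sprintf("%s: %d losses, %d regains; %d/%d tips absent\n", ch,
                sum(ev$type == "loss"), sum(ev$type == "regain"),
                sum(x$characters[[ch]]$tip_states == "0"),
                length(x$characters[[ch]]$tip_states)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# annotations

#' Generate asserted annotations from a planted history
#'
#' Emits author-style asserted statements consistent with the ground truth:
#' direct statements ("fin present"/"fin absent") or indirect ones (a
#' structural quality on the fin ray implying presence; girdle absence
#' implying fin absence) at `indirect_fraction`; genus- or family-rank
#' statements replacing member-species annotations for monomorphic groups
#' at `higher_level_fraction`; and contradictory statements for
#' `conflict_rate` of the annotated species. Only asserted rows are
#' produced — inference is the pipeline's job.
#'
#' @param truth a `ground_truth` from [plant_trait_history()].
#' @param taxonomy the matching [taxonomy()].
#' @param anatomy an `anatomy_graph` (the fin template).
#' @param scenario the [synthetic_scenario()].
#' @return annotation data frame; attribute `"bookkeeping"` holds the
#'   per-character expected cell counts (species asserted, species
#'   inferred-only, higher-rank rows, planted conflicts) and attribute
#'   `"conflicted"` the planted conflict species per character.
#' @export
generate_annotations <- function(truth, taxonomy, anatomy, scenario) {
  tab <- taxonomy$table
  rows <- list()
  book <- list()
  conflicted <- list()
  studies <- c("studyA", "studyB", "studyC")
  for (i in seq_along(truth$characters)) {
    ch <- names(truth$characters)[i]
    fin <- ch
    side <- sub(" fin$", "", ch)
    ray <- paste(side, "fin ray")
    girdle <- paste(side, "girdle skeleton")
    states <- truth$characters[[ch]]$tip_states
    tm <- truth$tip_map
    sp_states <- setNames(states[tm$tip[!tm$extra]], tm$species[!tm$extra])
    with_seed(mix_seed(scenario$seed, 400L + i), {
      sp_names <- names(sp_states)
      covered <- runif(length(sp_states)) < scenario$species_coverage
      conflict <- covered & runif(length(sp_states)) < scenario$conflict_rate
      indirect <- runif(length(sp_states)) < scenario$indirect_fraction
      study <- sample(studies, length(sp_states), replace = TRUE)
      ann_level <- ifelse(covered, "species", "none")

      # higher-level replacement: monomorphic, conflict-free groups
      for (rk in c("genus", "family")) {
        for (hid in tab$id[tab$rank == rk]) {
          members <- taxon_name(taxonomy, species_under(taxonomy, hid))
          members <- members[members %in% sp_names]
          if (length(members) < 2L) next
          ms <- sp_states[members]
          sel <- match(members, sp_names)
          if (length(unique(ms)) != 1L || any(conflict[sel])) next
          if (runif(1) >= scenario$higher_level_fraction) next
          ann_level[sel] <- "higher"
          rows[[length(rows) + 1L]] <- local({
            st <- unique(ms)
            ind <- runif(1) < scenario$indirect_fraction
            std <- sample(studies, 1L)
            if (st == "1") {
              if (ind) annotation_table(hid, ray, "unbranched", study = std)
              else annotation_table(hid, fin, "present", study = std)
            } else {
              if (ind) annotation_table(hid, girdle, "absent", study = std)
              else annotation_table(hid, fin, "absent", study = std)
            }
          })
        }
      }

      n_assert <- 0L; n_infer_only <- 0L
      for (k in seq_along(sp_states)) {
        if (ann_level[k] != "species") next
        sid <- tab$id[match(sp_names[k], tab$name)]
        st <- sp_states[[k]]
        if (conflict[k]) {
          # asserted absence vs presence-implying part quality
          rows[[length(rows) + 1L]] <- annotation_table(
            sid, fin, "absent", study = study[k])
          rows[[length(rows) + 1L]] <- annotation_table(
            sid, ray, "unbranched",
            study = studies[(match(study[k], studies)) %% 3L + 1L])
          conflicted[[ch]] <- c(conflicted[[ch]], sid)
          next
        }
        if (st == "1") {
          if (indirect[k]) {
            rows[[length(rows) + 1L]] <- annotation_table(
              sid, ray, "unbranched", study = study[k])
            n_infer_only <- n_infer_only + 1L
          } else {
            rows[[length(rows) + 1L]] <- annotation_table(
              sid, fin, "present", study = study[k])
            n_assert <- n_assert + 1L
          }
        } else {
          if (indirect[k]) {
            rows[[length(rows) + 1L]] <- annotation_table(
              sid, girdle, "absent", study = study[k])
            n_infer_only <- n_infer_only + 1L
          } else {
            rows[[length(rows) + 1L]] <- annotation_table(
              sid, fin, "absent", study = study[k])
            n_assert <- n_assert + 1L
          }
        }
      }
      book[[ch]] <- data.frame(
        character = ch,
        species_asserted = n_assert,
        species_inferred_only = n_infer_only,
        species_conflicted = length(conflicted[[ch]]),
        higher_rank_rows = sum(vapply(
          rows, function(r) r$entity[1] %in% c(fin, ray, girdle) &&
            r$taxon_id[1] %in% tab$id[tab$rank %in% c("genus", "family")],
          logical(1))),
        stringsAsFactors = FALSE)
    })
  }
  ann <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
  rownames(ann) <- NULL
  attr(ann, "bookkeeping") <- do.call(rbind, book)
  attr(ann, "conflicted") <- conflicted
  ann
}
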