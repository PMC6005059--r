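# Low-level rooted-tree operations on ape "phylo" objects.
#
# Trees here carry no branch lengths; all operations are purely topological.
# Rebuilds go through newick text, which keeps the ape numbering invariants
# (tips 1..n, root n+1) without hand-maintaining edge matrices.

tree_root <- function(phy) {
  unique(phy$edge[!(phy$edge[, 1] %in% phy$edge[, 2]), 1])[1]
}

node_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  unname(split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n))))
}

# postorder node sequence (children before parents), tips included; each
# non-root node appears exactly once as a child in the postorder edge list
postorder_nodes <- function(phy) {
  e <- ape::reorder.phylo(phy, "postorder")$edge
  c(e[, 2], tree_root(phy))
}

# tip ids under each node (list indexed by node id)
subtree_tip_sets <- function(phy) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  kids <- node_children(phy)
  out <- vector("list", n)
  for (i in seq_len(nt)) out[[i]] <- i
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1]; ch <- e[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Join newick fragments into a binary subtree by repeatedly picking two
# lineages uniformly at random. With exactly one fragment, returns it as is.
# Uses the active RNG stream (callers wrap in with_seed()).
random_join <- function(frags) {
  while (length(frags) > 1L) {
    i <- sample(seq_along(frags), 2L)
    joined <- paste0("(", frags[i[1]], ",", frags[i[2]], ")")
    frags <- c(frags[-i], joined)
  }
  frags
}

# newick text for a children-list representation rooted at `root`
children_to_newick <- function(children, labels, root) {
  n <- length(children)
  frag <- character(n)
  # iterative postorder over the children structure
  stack <- root
  visited <- logical(n)
  order <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    kids <- children[[v]]
    if (!visited[v] && length(kids)) {
      visited[v] <- TRUE
      stack <- c(stack, kids)
    } else {
      order <- c(order, v)
      stack <- stack[-length(stack)]
    }
  }
  for (v in order) {
    kids <- children[[v]]
    frag[v] <- if (length(kids) == 0L) labels[v]
               else paste0("(", paste(frag[kids], collapse = ","), ")")
  }
  paste0(frag[root], ";")
}

phylo_children_labels <- function(phy) {
  nt <- ape::Ntip(phy)
  labels <- c(phy$tip.label, rep("", phy$Nnode))
  list(children = node_children(phy), labels = labels, ntip = nt)
}

# Remove the given internal nodes (never the root), reattaching their children
# to the surviving parent. Used to inject polytomies.
collapse_internal_nodes <- function(phy, nodes) {
  if (length(nodes) == 0L) return(phy)
  root <- tree_root(phy)
  nodes <- setdiff(unique(nodes), c(root, seq_len(ape::Ntip(phy))))
  if (length(nodes) == 0L) return(phy)
  pcl <- phylo_children_labels(phy)
  children <- pcl$children
  parent <- integer(length(children))
  for (p in seq_along(children)) parent[children[[p]]] <- p
  drop <- logical(length(children))
  drop[nodes] <- TRUE
  # process top-down so chains of dropped nodes dissolve correctly: a dropped
  # ancestor has already handed its children to a surviving node by the time
  # a dropped descendant is reached
  for (v in rev(postorder_nodes(phy))) {
    if (!drop[v]) next
    p <- parent[v]
    while (drop[p]) p <- parent[p]
    ch <- children[[p]]
    pos <- match(v, ch)
    children[[p]] <- append(ch[-pos], children[[v]], after = pos - 1L)
    for (k in children[[v]]) parent[k] <- p
    children[[v]] <- integer(0)
  }
  ape::read.tree(text = children_to_newick(children, pcl$labels, root))
}

#' Randomly resolve polytomies into a binary tree
#'
#' Every internal node with more than two children is replaced by a random
#' binary subtree, built by repeatedly joining two uniformly chosen child
#' lineages. Tip set and rooting are unchanged; already-binary input is
#' returned with identical topology.
#'
#' @param phy a rooted `phylo` tree (branch lengths, if any, are dropped).
#' @param seed integer seed; the same seed always yields the same resolution.
#' @return a rooted, fully binary `phylo` tree.
#' @examples
#' tr <- ape::read.tree(text = "(a,b,c,d);")
#' resolve_polytomies(tr, seed = 1)
#' @export
resolve_polytomies <- function(phy, seed) {
  stopifnot(inherits(phy, "phylo"))
  pcl <- phylo_children_labels(phy)
  children <- pcl$children
  root <- tree_root(phy)
  with_seed(seed, {
    n <- length(children)
    frag <- character(n)
    stack <- root; visited <- logical(n); order <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      kids <- children[[v]]
      if (!visited[v] && length(kids)) {
        visited[v] <- TRUE
        stack <- c(stack, kids)
      } else {
        order <- c(order, v)
        stack <- stack[-length(stack)]
      }
    }
    for (v in order) {
      kids <- children[[v]]
      frag[v] <- if (length(kids) == 0L) pcl$labels[v]
                 else if (length(kids) == 1L) frag[kids]
                 else if (length(kids) == 2L)
                   paste0("(", frag[kids[1]], ",", frag[kids[2]], ")")
                 else random_join(frag[kids])
    }
    ape::read.tree(text = paste0(frag[root], ";"))
  })
}
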