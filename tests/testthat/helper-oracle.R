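# Independent brute-force oracle for unordered parsimony on small trees:
# enumerates every assignment of states {0,1} to the internal nodes and
# scores it directly. Ambiguous ("0&1") and missing ("?") tips contribute
# the cheapest terminal choice given the parent state (zero, since both
# states are allowed), matching the convention that an MPR labels internal
# nodes only. Used to verify length, MPR count, per-type bounds and
# sampling frequencies; kept deliberately free of the package's DP code.

enumerate_parsimony <- function(phy, tip_states) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  allow <- fintegrate:::allow_matrix(tip_states, phy$tip.label)
  grid <- as.matrix(expand.grid(rep(list(0:1), nn)))  # row = labeling
  colnames(grid) <- as.character(nt + seq_len(nn))
  cost <- numeric(nrow(grid))
  gains <- numeric(nrow(grid))
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    ps <- grid[, p - nt]
    if (ch > nt) {
      cs <- grid[, ch - nt]
      cost <- cost + (ps != cs)
      gains <- gains + (ps == 0 & cs == 1)
    } else {
      a0 <- allow[ch, 1]; a1 <- allow[ch, 2]
      if (a0 && a1) next                 # ambiguous/missing tip: free
      t <- if (a1) 1 else 0
      cost <- cost + (ps != t)
      gains <- gains + (ps == 0 & t == 1)
    }
  }
  L <- min(cost)
  opt <- which(cost == L)
  list(length = L, count = length(opt),
       gain_min = min(gains[opt]), gain_max = max(gains[opt]),
       loss_min = L - max(gains[opt]), loss_max = L - min(gains[opt]),
       labelings = grid[opt, , drop = FALSE])
}

# random rooted test tree (binary or multifurcating) with random tip states
# including missing and polymorphic; everything driven by the seed
random_parsimony_instance <- function(seed, min_tips = 4, max_tips = 12,
                                      p_collapse = 0.3,
                                      state_probs = c(0.35, 0.35, 0.1, 0.2)) {
  fintegrate:::with_seed(seed, {
    nt <- sample(min_tips:max_tips, 1)
    phy <- ape::rtree(nt, rooted = TRUE, br = NULL)
    if (runif(1) < 0.5 && phy$Nnode > 1) {
      internals <- setdiff(nt + seq_len(phy$Nnode),
                           fintegrate:::tree_root(phy))
      coll <- internals[runif(length(internals)) < p_collapse]
      phy <- fintegrate:::collapse_internal_nodes(phy, coll)
    }
    states <- sample(c("0", "1", "0&1", "?"), ape::Ntip(phy),
                     replace = TRUE, prob = state_probs)
    # avoid the degenerate all-missing instance (tested separately)
    if (all(states == "?")) states[1] <- "1"
    list(phy = phy, states = setNames(states, phy$tip.label))
  })
}
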