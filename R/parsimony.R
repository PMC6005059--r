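# Unordered (Fitch-Hartigan) parsimony on rooted, possibly multifurcating
# trees, for a binary presence/absence character with missing and polymorphic
# tips. One dynamic program yields the minimum length, the exact number of
# most parsimonious reconstructions (MPRs), exact per-transition-type bounds
# (min/max gains and losses over all MPRs), and supports uniform sampling of
# MPRs by stochastic backtracking proportional to subtree counts.
#
# Model conventions:
#  * states are 0 = absent, 1 = present; every change costs one step;
#  * a polymorphic tip ("0&1") is state-ambiguous: either state costs nothing
#    at the tip, so the tip never forces a terminal change;
#  * a missing tip ("?") is compatible with both states at no cost;
#  * an MPR is an assignment of states to the *internal* nodes achieving the
#    minimum total number of changes; ambiguous tips resolve deterministically
#    to their parent's state (the unique zero-cost choice), so they neither
#    multiply the count nor contribute changes;
#  * polytomies are treated as hard: the DP is exact on multifurcations
#    (Hartigan's generalization), no implicit resolution happens.

TIP_STATE_LEVELS <- c("0", "1", "0&1", "?")

# named character vector -> nt x 2 logical allow matrix (col 1 = state 0)
allow_matrix <- function(tip_states, labels) {
  s <- tip_states[labels]
  s[is.na(s)] <- "?"
  s <- as.character(s)
  s[s %in% c("absent", "0")] <- "0"
  s[s %in% c("present", "1", "2")] <- "1"
  s[s %in% c("both", "01", "1&0", "{0,1}", "0&1")] <- "0&1"
  s[s %in% c("missing", "", "?", "-")] <- "?"
  bad <- !(s %in% TIP_STATE_LEVELS)
  if (any(bad))
    stop("unrecognized tip state(s): ", paste(unique(s[bad]), collapse = ", "))
  cbind(s %in% c("0", "0&1", "?"), s %in% c("1", "0&1", "?"))
}

# Core DP. Returns per-node minimum subtree costs for both root states,
# exact counts (big integers), and min/max gain tallies over optimal
# sub-labelings. Costs use a large finite sentinel for disallowed tip states;
# it can never propagate because one state of every tip costs 0.
fitch_dp <- function(phy, tip_states, counts = TRUE, bounds = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  nt <- ape::Ntip(phy)
  if (nt < 2L) stop("tree must have at least two tips")
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  n <- nt + phy$Nnode
  allow <- allow_matrix(tip_states, phy$tip.label)
  INF <- 1e9
  m0 <- numeric(n); m1 <- numeric(n)
  m0[seq_len(nt)] <- ifelse(allow[, 1], 0, INF)
  m1[seq_len(nt)] <- ifelse(allow[, 2], 0, INF)
  if (counts) {
    one <- bi_one()
    c0 <- rep(list(one), n)
    c1 <- rep(list(one), n)
  } else c0 <- c1 <- NULL
  g0min <- numeric(n); g1min <- numeric(n)
  g0max <- numeric(n); g1max <- numeric(n)
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    a <- m0[ch]; b <- m1[ch]
    # parent state 0: keep child at 0 (cost a) or flip child to 1 (cost b+1,
    # and that edge is a gain)
    w0 <- a; w1 <- b + 1
    if (w0 < w1) {
      m0[p] <- m0[p] + w0
      if (counts) c0[[p]] <- bi_mul(c0[[p]], c0[[ch]])
      if (bounds) { g0min[p] <- g0min[p] + g0min[ch]
                    g0max[p] <- g0max[p] + g0max[ch] }
    } else if (w1 < w0) {
      m0[p] <- m0[p] + w1
      if (counts) c0[[p]] <- bi_mul(c0[[p]], c1[[ch]])
      if (bounds) { g0min[p] <- g0min[p] + g1min[ch] + 1
                    g0max[p] <- g0max[p] + g1max[ch] + 1 }
    } else {
      m0[p] <- m0[p] + w0
      if (counts) c0[[p]] <- bi_mul(c0[[p]], bi_add(c0[[ch]], c1[[ch]]))
      if (bounds) { g0min[p] <- g0min[p] + min(g0min[ch], g1min[ch] + 1)
                    g0max[p] <- g0max[p] + max(g0max[ch], g1max[ch] + 1) }
    }
    # parent state 1: keep child at 1 (cost b) or flip child to 0 (cost a+1,
    # a loss edge: contributes to length but not to gains)
    v1 <- b; v0 <- a + 1
    if (v1 < v0) {
      m1[p] <- m1[p] + v1
      if (counts) c1[[p]] <- bi_mul(c1[[p]], c1[[ch]])
      if (bounds) { g1min[p] <- g1min[p] + g1min[ch]
                    g1max[p] <- g1max[p] + g1max[ch] }
    } else if (v0 < v1) {
      m1[p] <- m1[p] + v0
      if (counts) c1[[p]] <- bi_mul(c1[[p]], c0[[ch]])
      if (bounds) { g1min[p] <- g1min[p] + g0min[ch]
                    g1max[p] <- g1max[p] + g0max[ch] }
    } else {
      m1[p] <- m1[p] + v1
      if (counts) c1[[p]] <- bi_mul(c1[[p]], bi_add(c0[[ch]], c1[[ch]]))
      if (bounds) { g1min[p] <- g1min[p] + min(g0min[ch], g1min[ch])
                    g1max[p] <- g1max[p] + max(g0max[ch], g1max[ch]) }
    }
  }
  root <- E[nrow(E), 1]
  L <- min(m0[root], m1[root])
  opt0 <- m0[root] == L
  opt1 <- m1[root] == L
  count <- if (!counts) NULL
           else if (opt0 && opt1) bi_add(c0[[root]], c1[[root]])
           else if (opt0) c0[[root]] else c1[[root]]
  gmin <- min(if (opt0) g0min[root] else Inf, if (opt1) g1min[root] else Inf)
  gmax <- max(if (opt0) g0max[root] else -Inf, if (opt1) g1max[root] else -Inf)
  list(length = as.integer(L), count = count,
       gain_min = as.integer(gmin), gain_max = as.integer(gmax),
       loss_min = as.integer(L - gmax), loss_max = as.integer(L - gmin),
       root = root, m0 = m0, m1 = m1, c0 = c0, c1 = c1,
       edge = E, ntip = nt, allow = allow,
       all_missing = all(allow[, 1] & allow[, 2]))
}

#' Parsimony length of a binary character on a rooted tree
#'
#' Minimum number of state changes over all internal-node labelings of the
#' given (possibly multifurcating) rooted tree, under unit-cost unordered
#' parsimony. Exact on polytomies (Hartigan's dynamic program). Missing tips
#' cost nothing under either state; polymorphic tips are state-ambiguous.
#'
#' @param phy rooted `phylo` tree.
#' @param tip_states named character vector over tip labels with values
#'   `"0"` (absent), `"1"` (present), `"0&1"` (polymorphic) or `"?"`
#'   (missing). Unnamed tips are treated as missing. `"2"` (inferred-only
#'   presence) is accepted and read as presence.
#' @return integer number of steps.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' parsimony_length(tr, c(a = "1", b = "1", c = "0", d = "0"))
#' @seealso [count_mprs()], [change_bounds()], [asr_summary()]
#' @export
parsimony_length <- function(phy, tip_states) {
  dp <- fitch_dp(phy, tip_states, counts = FALSE, bounds = FALSE)
  if (dp$all_missing)
    warning("all tips missing: parsimony length is trivially 0")
  dp$length
}

#' Exact number of most parsimonious reconstructions
#'
#' Counts the internal-node labelings that achieve the minimum parsimony
#' length, in exact arbitrary-precision integer arithmetic (counts on large
#' unresolved trees overflow doubles; no floating point is used).
#'
#' @inheritParams parsimony_length
#' @return a `big_integer`; use `as.character()` for the exact decimal value
#'   and `as.double()` for an approximation.
#' @examples
#' tr <- ape::read.tree(text = "(a,b);")
#' as.character(count_mprs(tr, c(a = "1", b = "0")))  # "2"
#' @export
count_mprs <- function(phy, tip_states) {
  fitch_dp(phy, tip_states, counts = TRUE, bounds = FALSE)$count
}

#' Exact bounds on gains and losses over all MPRs
#'
#' For every most parsimonious reconstruction the number of gain edges
#' (0 to 1) plus loss edges (1 to 0) equals the parsimony length; this
#' function returns the exact minimum and maximum of each type over the whole
#' MPR set, via a secondary-objective dynamic program restricted to
#' minimum-length labelings.
#'
#' @inheritParams parsimony_length
#' @return list with `length`, and `gain`, `loss` (each `c(min =, max =)`).
#' @export
change_bounds <- function(phy, tip_states) {
  dp <- fitch_dp(phy, tip_states, counts = FALSE, bounds = TRUE)
  list(length = dp$length,
       gain = c(min = dp$gain_min, max = dp$gain_max),
       loss = c(min = dp$loss_min, max = dp$loss_max))
}

#' Sample most parsimonious reconstructions uniformly
#'
#' Draws `n` internal-node labelings uniformly from the set of MPRs by
#' stochastic backtracking: the root state and then each child state are
#' chosen among the locally optimal options with probability proportional to
#' the exact number of optimal sub-labelings they admit.
#'
#' @inheritParams parsimony_length
#' @param n number of samples (positive).
#' @param seed integer seed.
#' @return list with `length`, `labelings` (an `n` x `Nnode` matrix of 0/1
#'   internal states, columns named by node id), and per-sample `gains` and
#'   `losses` (integer vectors; `gains + losses == length` always).
#' @export
sample_mprs <- function(phy, tip_states, n, seed) {
  stopifnot_count(n, "n")
  dp <- fitch_dp(phy, tip_states, counts = TRUE, bounds = FALSE)
  E <- dp$edge
  nt <- dp$ntip
  nn <- phy$Nnode
  # reverse postorder: parents assigned before children
  ord <- rev(seq_len(nrow(E)))
  n0 <- vapply(dp$c0, as.double, numeric(1))
  n1 <- vapply(dp$c1, as.double, numeric(1))
  root <- dp$root
  L <- dp$length
  opt_root <- c(dp$m0[root] == L, dp$m1[root] == L)
  lab <- matrix(NA_integer_, n, nn,
                dimnames = list(NULL, as.character(nt + seq_len(nn))))
  gains <- integer(n); losses <- integer(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      st <- integer(nt + nn)
      st[root] <- if (opt_root[1] && opt_root[2]) {
        sample.int(2L, 1L, prob = c(n0[root], n1[root])) - 1L
      } else if (opt_root[1]) 0L else 1L
      g <- 0L; l <- 0L
      for (k in ord) {
        p <- E[k, 1]; ch <- E[k, 2]
        s <- st[p]
        if (s == 0L) { w0 <- dp$m0[ch]; w1 <- dp$m1[ch] + 1 }
        else         { w0 <- dp$m0[ch] + 1; w1 <- dp$m1[ch] }
        t <- if (w0 < w1) 0L
             else if (w1 < w0) 1L
             else sample.int(2L, 1L, prob = c(n0[ch], n1[ch])) - 1L
        st[ch] <- t
        if (s == 0L && t == 1L) g <- g + 1L
        if (s == 1L && t == 0L) l <- l + 1L
      }
      lab[i, ] <- st[nt + seq_len(nn)]
      gains[i] <- g; losses[i] <- l
    }
  })
  list(length = L, labelings = lab, gains = gains, losses = losses,
       seed = as.integer(seed))
}

#' Full parsimony reconstruction summary for one character
#'
#' Bundles the exact analytics (length, MPR count, per-type bounds) with
#' observed statistics over a uniform sample of MPRs, in the style of a
#' "summary of state changes" table: per transition type, exact min and max,
#' and sampled min / mean / max.
#'
#' @inheritParams parsimony_length
#' @param n_samples number of MPRs to sample (default 1000).
#' @param seed integer seed for the sampler.
#' @return object of class `mpr_summary`.
#' @export
asr_summary <- function(phy, tip_states, n_samples = 1000L, seed = 1L) {
  dp <- fitch_dp(phy, tip_states, counts = TRUE, bounds = TRUE)
  smp <- sample_mprs(phy, tip_states, n_samples, seed)
  structure(list(
    length = dp$length,
    mpr_count = dp$count,
    gain = c(min = dp$gain_min, max = dp$gain_max),
    loss = c(min = dp$loss_min, max = dp$loss_max),
    sampled = data.frame(
      type = c("gain", "loss"),
      min = c(min(smp$gains), min(smp$losses)),
      mean = c(mean(smp$gains), mean(smp$losses)),
      max = c(max(smp$gains), max(smp$losses))),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed)), class = "mpr_summary")
}

#' @export
print.mpr_summary <- function(x, ...) {
  cat("Unordered parsimony reconstruction\n")
  cat("  length (steps): ", x$length, "\n", sep = "")
  cat("  MPR count:      ", format(x$mpr_count), "\n", sep = "")
  cat(sprintf("  gains (0->1):   exact [%d, %d]; sampled min %d mean %.1f max %d\n",
              x$gain["min"], x$gain["max"],
              x$sampled$min[1], x$sampled$mean[1], x$sampled$max[1]))
  cat(sprintf("  losses (1->0):  exact [%d, %d]; sampled min %d mean %.1f max %d\n",
              x$loss["min"], x$loss["max"],
              x$sampled$min[2], x$sampled$mean[2], x$sampled$max[2]))
  cat("  samples: ", x$n_samples, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Minimum regains across random polytomy resolutions
#'
#' Repeatedly resolves all polytomies at random ([resolve_polytomies()]),
#' computes the exact minimum number of gain edges over all MPRs on each
#' binary resolution, and reports the minimum across replicates together with
#' the replicate table and the achieving topology. A "regain" is a 0-to-1
#' edge in a most parsimonious reconstruction; with presence ancestral this
#' is a re-evolution of the structure after loss.
#'
#' @inheritParams parsimony_length
#' @param n_resolutions number of random resolutions.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return list with `min_regains`, `replicates` (data frame: replicate,
#'   seed, length, gain_min, gain_max, loss_min, loss_max), `best_replicate`
#'   and `best_tree` (the first topology achieving the minimum).
#' @export
min_regains_over_resolutions <- function(phy, tip_states, n_resolutions = 1000L,
                                         seed = 1L) {
  stopifnot_count(n_resolutions, "n_resolutions")
  rows <- vector("list", n_resolutions)
  best <- NULL; best_g <- Inf; best_i <- NA_integer_
  for (i in seq_len(n_resolutions)) {
    rs <- mix_seed(seed, i)
    tr <- resolve_polytomies(phy, rs)
    dp <- fitch_dp(tr, tip_states, counts = FALSE, bounds = TRUE)
    rows[[i]] <- data.frame(replicate = i, seed = rs, length = dp$length,
                            gain_min = dp$gain_min, gain_max = dp$gain_max,
                            loss_min = dp$loss_min, loss_max = dp$loss_max)
    if (dp$gain_min < best_g) { best_g <- dp$gain_min; best <- tr; best_i <- i }
  }
  list(min_regains = as.integer(best_g),
       replicates = do.call(rbind, rows),
       best_replicate = best_i, best_tree = best)
}

#' Merge a species-level matrix onto tree tips
#'
#' Recodes matrix cells into tip state sets for ancestral state
#' reconstruction, using a name reconciliation to link matrix species to tip
#' labels. Matched tips receive: `1`/`2` (asserted or inferred-only presence)
#' as presence; `0` as absence; `3` (inferred-only absence) as absence with a
#' warning; a species-level true polymorphism as the two-state set; a
#' species-level assertion-vs-inference conflict as missing. Unmatched tips
#' are coded unknown (`?`).
#'
#' @param matrix a species-level `supermatrix`.
#' @param phy rooted `phylo` tree.
#' @param reconciliation result of [reconcile_names()].
#' @return data frame, one row per tip label, one column per character, with
#'   values `"0"`, `"1"`, `"0&1"` or `"?"`.
#' @export
merge_tip_states <- function(matrix, phy, reconciliation) {
  stopifnot(inherits(matrix, "supermatrix"))
  tips <- phy$tip.label
  out <- as.data.frame(
    matrix(rep("?", length(tips) * length(matrix$characters)),
           nrow = length(tips),
           dimnames = list(tips, matrix$characters)),
    stringsAsFactors = FALSE, check.names = FALSE)
  mm <- reconciliation$matches
  cells <- matrix$cells
  warned3 <- FALSE
  for (j in seq_len(nrow(mm))) {
    tx <- mm$taxon_id[j]; tip <- mm$tip[j]
    if (!(tip %in% tips)) next
    rows <- cells[cells$taxon_id == tx, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      sym <- rows$symbol[k]
      val <- if (sym %in% c("1", "2")) "1"
        else if (sym == "0") "0"
        else if (sym == "3") {
          if (!warned3) {
            warning("inferred-only absence ('3') merged as absence")
            warned3 <- TRUE
          }
          "0"
        } else if (sym == "0&1") {
          # true species polymorphism stays ambiguous; an
          # assertion-vs-inference conflict is down-coded to missing
          if (rows$n_assert_present[k] > 0 && rows$n_assert_absent[k] > 0)
            "0&1" else "?"
        } else "?"
      out[tip, rows$character[k]] <- val
    }
  }
  out
}
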