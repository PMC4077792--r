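# Independent oracles used by the tests. These deliberately share no code
# with the package internals they check.

ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_can_pair <- function(a, b) paste0(a, b) %in% ORACLE_PAIRS

# number of pseudoknot-free structures over allowed pairs with min loop 3,
# via the standard non-crossing recursion
# N(i,j) = N(i+1,j) + sum_{k pairable with i} N(i+1,k-1) * N(k+1,j)
oracle_count_structures <- function(residues, min_hp = 3) {
  ch <- strsplit(residues, "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(1)
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- rec(i + 1, j)
    ks <- seq_len(n)
    ks <- ks[ks > i + min_hp & ks <= j]
    for (k in ks)
      if (oracle_can_pair(ch[i], ch[k]))
        total <- total + rec(i + 1, k - 1) * rec(k + 1, j)
    memo[[key]] <- total
    total
  }
  rec(1, n)
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# exhaustive minimum-change oracle for parsimony on a rooted tree;
# enumerates every assignment of states to internal nodes
oracle_fitch <- function(tree, tip_states) {
  states <- sort(unique(unlist(tip_states)))
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grid <- expand.grid(rep(list(states), nn), stringsAsFactors = FALSE)
  best <- Inf
  best_roots <- character(0)
  for (r in seq_len(nrow(grid))) {
    asg <- as.character(unlist(grid[r, ]))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; k <- tree$edge[e, 2]
      ps <- asg[p - ntip]
      if (k <= ntip) {
        cost <- cost + !(ps %in% tip_states[[tree$tip.label[k]]])
      } else {
        cost <- cost + (ps != asg[k - ntip])
      }
    }
    rs <- asg[1]  # node ntip+1 is the root
    if (cost < best) { best <- cost; best_roots <- rs }
    else if (cost == best) best_roots <- union(best_roots, rs)
  }
  list(score = best, root_states = sort(best_roots))
}

# random rooted tree on k tips, possibly multifurcating
random_tree <- function(k, collapse_prob = 0.3) {
  tr <- ape::rtree(k, rooted = TRUE)
  tr$edge.length <- NULL
  internal <- which(tr$edge[, 2] > length(tr$tip.label))
  if (length(internal) && stats::runif(1) < collapse_prob) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    drop <- sample(internal, max(1, floor(length(internal) / 2)))
    tr$edge.length[drop] <- 0
    tr <- ape::di2multi(tr)
    tr$edge.length <- NULL
  }
  tr
}

# metric table with a pure-noise response under the two-way design
null_metric_table <- function(n_per_class = 50) {
  data.frame(class = rep(c("ITS", "RANDOM"), each = n_per_class),
             half = rep(rep(c("ITS1", "ITS2"), each = n_per_class / 2), 2),
             y = rnorm(2 * n_per_class))
}

# energy band ceiling used by the suboptimal enumeration, in kcal/mol
band_ceiling <- function(mfe, pct) mfe + abs(mfe) * pct / 100
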