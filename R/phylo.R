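#' Read a rooted phylogeny from a newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: polytomies are
#' preserved, duplicate tip labels and malformed newick are rejected.
#'
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Read a tip-state table of hairpin counts
#'
#' Two-column tab-separated file: taxon and state. A state is an integer
#' count, `NA` for taxa without data, or a slash-separated set like `6/7`
#' for tribes whose sampled species show different counts (an ambiguous
#' tip, handled natively by the parsimony set operations).
#'
#' @param path tab-separated file with columns `taxon` and `state`.
#' @return named list of character state vectors (length 0 for `NA`).
#' @export
read_tip_states <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("taxon", "state") %in% names(df)))
    stop("tip-state file needs columns 'taxon' and 'state'")
  states <- lapply(df$state, function(s) {
    if (is.na(s) || s %in% c("", "NA")) character(0)
    else strsplit(s, "/", fixed = TRUE)[[1]]
  })
  names(states) <- df$taxon
  states
}

#' Parsimony ancestral states by the Fitch-Hartigan algorithm
#'
#' Bottom-up pass of Hartigan's generalization of Fitch parsimony for
#' unordered characters on a rooted, possibly multifurcating tree: each
#' node's state set is the set of states occurring in the maximal number of
#' its children's sets, and the parsimony score grows by the number of
#' children not covered by that choice. Returns the set of equally
#' parsimonious root states and the minimum number of state changes.
#'
#' Tips with no observed state (empty set / `NA`) are pruned before the
#' pass; they constrain nothing. Ambiguous tips carry their full state set.
#'
#' @param tree a rooted `phylo` object (polytomies allowed).
#' @param tip_states named list (or atomic vector) mapping tip labels to a
#'   state or set of states; see [read_tip_states()].
#' @return list with `root_states` (sorted character vector), `score`
#'   (integer), and `node_states` (per retained node, tips first).
#' @export
fitch_root_states <- function(tree, tip_states) {
  if (is.atomic(tip_states))
    tip_states <- lapply(stats::setNames(as.list(tip_states),
                                         names(tip_states)), as.character)
  tip_states <- lapply(tip_states, as.character)
  stated <- names(tip_states)[lengths(tip_states) > 0]
  stated <- intersect(tree$tip.label, stated)
  if (length(stated) == 0) stop("no tip has an observed state")
  if (length(stated) < 2) stop("need at least 2 tips with states")
  if (length(stated) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, stated)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (k in seq_len(ntip)) sets[[k]] <- unique(tip_states[[tree$tip.label[k]]])
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(po$edge[, 1])  # postorder: children before parents
  score <- 0L
  for (nd in parents) {
    kids <- po$edge[po$edge[, 1] == nd, 2]
    cnt <- table(unlist(lapply(kids, function(k) sets[[k]])))
    kmax <- max(cnt)
    sets[[nd]] <- sort(names(cnt)[cnt == kmax])
    score <- score + length(kids) - kmax
  }
  root <- ntip + 1L
  list(root_states = sort(sets[[root]]), score = score, node_states = sets,
       tree = tree)
}

#' Annotate a tree's internal nodes with parsimony state sets
#'
#' Writes the (pruned) tree used in the parsimony pass with internal node
#' labels carrying the reconstructed state sets, e.g. `5|6`.
#'
#' @param fit result of [fitch_root_states()].
#' @param path output newick file.
#' @return the annotated `phylo` object, invisibly when writing.
#' @export
write_annotated_newick <- function(fit, path) {
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  lab <- vapply(seq_len(tree$Nnode) + ntip,
                function(nd) paste(fit$node_states[[nd]], collapse = "|"),
                character(1))
  tree$node.label <- lab
  ape::write.tree(tree, file = path)
  invisible(tree)
}
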