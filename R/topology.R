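#' Decompose a secondary structure into its loop/helix element tree
#'
#' Builds the unique element decomposition of a pseudoknot-free structure:
#' one exterior (root) node, helices (maximal runs of stacked pairs --
#' bulge or internal-loop interruptions end a helix), and the loops they
#' close (hairpin, bulge, internal, multibranch). Helices alternate with
#' loops along every root-to-leaf path.
#'
#' @param structure a [secondary_structure()].
#' @param seq_length sequence length; defaults to the structure's own.
#' @return object of class `element_tree`: a data frame of nodes with
#'   columns `id`, `type`, `parent`, `n_pairs` (helices), `loop_size`
#'   (unpaired bases in loops), `outer_i`, `outer_j` (outermost pair of a
#'   helix).
#' @export
build_element_tree <- function(structure, seq_length = structure$length) {
  validate_pairs(structure$pairs, seq_length)
  pt <- pair_table(structure$pairs, seq_length)
  nodes <- list()
  add_node <- function(type, parent, n_pairs = NA_integer_,
                       loop_size = NA_integer_, outer_i = NA_integer_,
                       outer_j = NA_integer_) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- data.frame(id = id, type = type, parent = parent,
                               n_pairs = n_pairs, loop_size = loop_size,
                               outer_i = outer_i, outer_j = outer_j)
    id
  }
  scan_branches <- function(a, b) {
    ch <- matrix(integer(0), 0, 2); k <- a
    while (k <= b) {
      if (pt[k] == 0) k <- k + 1L
      else { ch <- rbind(ch, c(k, pt[k])); k <- pt[k] + 1L }
    }
    ch
  }
  process_helix <- function(i, j, parent) {
    i2 <- i; j2 <- j; np <- 1L
    while (i2 + 1L < j2 - 1L && pt[i2 + 1L] == j2 - 1L) {
      i2 <- i2 + 1L; j2 <- j2 - 1L; np <- np + 1L
    }
    hid <- add_node("helix", parent, n_pairs = np, outer_i = i, outer_j = j)
    br <- scan_branches(i2 + 1L, j2 - 1L)
    if (nrow(br) == 0L) {
      add_node("hairpin_loop", hid, loop_size = j2 - i2 - 1L)
    } else if (nrow(br) == 1L) {
      p <- br[1, 1]; q <- br[1, 2]
      n1 <- p - i2 - 1L; n2 <- j2 - q - 1L
      type <- if (n1 == 0L || n2 == 0L) "bulge" else "internal"
      lid <- add_node(type, hid, loop_size = n1 + n2)
      process_helix(p, q, lid)
    } else {
      unp <- (j2 - i2 - 1L) - sum(br[, 2] - br[, 1] + 1L)
      mid <- add_node("multibranch", hid, loop_size = unp)
      for (k in seq_len(nrow(br))) process_helix(br[k, 1], br[k, 2], mid)
    }
    hid
  }
  root <- add_node("exterior", NA_integer_)
  ext <- scan_branches(1L, seq_length)
  for (k in seq_len(nrow(ext))) process_helix(ext[k, 1], ext[k, 2], root)
  out <- do.call(rbind, nodes)
  structure(out, class = c("element_tree", "data.frame"))
}

# classify every exterior-anchored candidate substructure
#
# A candidate is rooted at each child helix of the exterior loop. Per
# candidate we record the total base pairs in its subtree, the pairs in the
# anchor helix alone, and the smallest number of loop elements (bulge,
# internal, multibranch) standing between the anchor helix and any hairpin
# loop of the subtree.
candidate_classes <- function(tree, min_bonds = 4,
                              bond_rule = c("substructure", "anchor"),
                              max_sep = Inf) {
  bond_rule <- match.arg(bond_rule)
  df <- as.data.frame(tree)
  root <- df$id[df$type == "exterior"]
  anchors <- df$id[df$type == "helix" & !is.na(df$parent) & df$parent == root]
  kids <- split(df$id, factor(df$parent, levels = df$id))
  res <- lapply(anchors, function(a) {
    # walk the subtree, tracking loop-element depth from the anchor
    total_bp <- 0L; min_sep <- Inf
    stack <- list(c(a, 0L))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nid <- top[1]; depth <- top[2]
      ty <- df$type[nid]
      if (ty == "helix") total_bp <- total_bp + df$n_pairs[nid]
      if (ty == "hairpin_loop") min_sep <- min(min_sep, depth)
      ndepth <- depth + (ty %in% c("bulge", "internal", "multibranch"))
      for (k in kids[[as.character(nid)]]) stack[[length(stack) + 1L]] <- c(k, ndepth)
    }
    data.frame(anchor = a, total_bp = total_bp, anchor_bp = df$n_pairs[a],
               min_sep = min_sep)
  })
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(anchor = integer(0), total_bp = integer(0),
               anchor_bp = integer(0), min_sep = numeric(0))
  bp <- if (bond_rule == "substructure") res$total_bp else res$anchor_bp
  res$class <- ifelse(bp < min_bonds, "none",
                      ifelse(res$min_sep <= max_sep, "hairpin", "stem"))
  res
}

#' Census hairpins and stems in an element tree
#'
#' Counts follow the census rules for manually scored structures: each child
#' helix of the exterior loop roots one candidate substructure; a candidate
#' counts as ONE hairpin when it contains at least `min_bonds` base pairs
#' in total ("four nucleotide bonds, i.e. eight nucleotides") and closes at
#' least one loop -- single and branched substructures both count once, no
#' matter how deeply the nested structure sits (the default `max_sep = Inf`).
#'
#' Setting a finite `max_sep` switches to a stricter reading in which the
#' anchor helix must reach a hairpin loop through at most `max_sep`
#' intervening loop elements; candidates with enough pairs that fail it are
#' counted as stems instead ("structures that do not form immediate loops").
#' Hairpin and stem are mutually exclusive, so `count_hairpins() +
#' count_stems()` never exceeds the number of exterior-anchored candidates;
#' under the default reading every counted candidate is a hairpin and the
#' stem count is zero.
#'
#' @param tree an [build_element_tree()] result.
#' @param min_bonds minimum base pairs for a candidate to count.
#' @param bond_rule apply `min_bonds` to the whole candidate substructure
#'   (default) or to the anchor helix alone.
#' @param max_sep largest number of loop elements allowed between the anchor
#'   helix and the nearest hairpin loop for a hairpin call.
#' @return integer count.
#' @export
count_hairpins <- function(tree, min_bonds = 4,
                           bond_rule = c("substructure", "anchor"),
                           max_sep = Inf) {
  cls <- candidate_classes(tree, min_bonds, match.arg(bond_rule), max_sep)
  sum(cls$class == "hairpin")
}

#' @rdname count_hairpins
#' @export
count_stems <- function(tree, min_bonds = 4,
                        bond_rule = c("substructure", "anchor"),
                        max_sep = Inf) {
  cls <- candidate_classes(tree, min_bonds, match.arg(bond_rule), max_sep)
  sum(cls$class == "stem")
}

#' Paired-base statistics of a structure
#'
#' @param structure a [secondary_structure()].
#' @param seq_length sequence length.
#' @return list with `n_paired` (bases participating in pairs, always even)
#'   and `pct_paired` (percentage of all positions).
#' @export
paired_stats <- function(structure, seq_length = structure$length) {
  n_paired <- 2L * nrow(structure$pairs)
  list(n_paired = n_paired, pct_paired = 100 * n_paired / seq_length)
}

#' Per-sequence structural census of a set of sequences
#'
#' Folds each record, optionally enumerates its suboptimal ensemble, and
#' censuses the MFE structure. This is the metric table consumed by the
#' class-comparison statistics.
#'
#' @param records a record table (see [sequence_records()]).
#' @param model an [energy_model()].
#' @param subopt enumerate suboptimal ensembles (slower) to fill
#'   `n_structures`?
#' @param min_bonds,bond_rule,max_sep hairpin census settings, see
#'   [count_hairpins()].
#' @param ... passed to [enumerate_suboptimal()].
#' @return data frame with one row per sequence: `seq_id`, `region`,
#'   `length`, `mfe_energy`, `n_structures`, `n_paired`, `pct_paired`,
#'   `n_hairpins`, `n_stems`.
#' @export
structure_census <- function(records, model = default_energy_model(),
                             subopt = TRUE, min_bonds = 4,
                             bond_rule = "substructure", max_sep = Inf, ...) {
  rows <- lapply(seq_len(nrow(records)), function(k) {
    rec <- records[k, , drop = FALSE]
    n <- nchar(rec$residues)
    if (subopt) {
      ens <- enumerate_suboptimal(rec, model, ...)
      st <- ens$structures[[1]]
      n_structures <- ens$count
    } else {
      st <- fold_mfe(rec, model)
      n_structures <- NA_integer_
    }
    tree <- build_element_tree(st)
    ps <- paired_stats(st)
    data.frame(seq_id = rec$id, region = rec$region, length = n,
               mfe_energy = st$energy, n_structures = n_structures,
               n_paired = ps$n_paired, pct_paired = ps$pct_paired,
               n_hairpins = count_hairpins(tree, min_bonds, bond_rule, max_sep),
               n_stems = count_stems(tree, min_bonds, bond_rule, max_sep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
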