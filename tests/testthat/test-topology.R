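db_tree <- function(db) {
  build_element_tree(secondary_structure(dotbracket_to_pairs(db), nchar(db)))
}

test_that("element decomposition of canonical shapes", {
  open <- build_element_tree(secondary_structure(matrix(integer(0), 0, 2), 20))
  expect_equal(as.data.frame(open)$type, "exterior")

  tr <- db_tree("((((....))))")
  df <- as.data.frame(tr)
  expect_equal(sort(df$type), sort(c("exterior", "helix", "hairpin_loop")))
  expect_equal(df$n_pairs[df$type == "helix"], 4L)
  expect_equal(df$loop_size[df$type == "hairpin_loop"], 4L)

  # branched: one anchor helix, a multibranch, two child helices
  tr <- db_tree("((((..((((....))))..((((....))))..))))")
  df <- as.data.frame(tr)
  expect_equal(sum(df$type == "multibranch"), 1L)
  expect_equal(sum(df$type == "helix"), 3L)
  expect_equal(sum(df$type == "hairpin_loop"), 2L)
  mb <- df$id[df$type == "multibranch"]
  expect_equal(sum(df$parent == mb, na.rm = TRUE), 2L)  # two child helices

  # helix interrupted by a bulge splits into two helix elements
  tr <- db_tree("((.((....))))")
  df <- as.data.frame(tr)
  expect_equal(sum(df$type == "bulge"), 1L)
  expect_equal(df$n_pairs[df$type == "helix"], c(2L, 2L))
})

test_that("helices and loops alternate and pairs are fully accounted for", {
  set.seed(3)
  m <- energy_model()
  for (r in 1:20) {
    s <- random_rna(sample(40:90, 1), gc = 0.6)
    st <- fold_mfe(s, m)
    df <- as.data.frame(build_element_tree(st))
    expect_equal(2 * sum(df$n_pairs, na.rm = TRUE), 2 * nrow(st$pairs))
    loops <- c("hairpin_loop", "bulge", "internal", "multibranch")
    for (k in seq_len(nrow(df))) {
      pa <- df$parent[k]
      if (is.na(pa)) next
      if (df$type[k] == "helix")
        expect_true(df$type[pa] %in% c("exterior", loops))
      else expect_equal(df$type[pa], "helix")
    }
    # hairpin loops are leaves; every helix has exactly one loop child
    hl <- df$id[df$type == "hairpin_loop"]
    expect_false(any(df$parent %in% hl))
  }
})

test_that("hairpin census follows the four counting rules", {
  # >= 4 bonds counts as one hairpin
  expect_equal(count_hairpins(db_tree("((((....))))")), 1L)
  # below the 4-bond threshold
  expect_equal(count_hairpins(db_tree("(((....)))")), 0L)
  # branched substructures count once
  expect_equal(count_hairpins(db_tree("((((..((((....))))..((((....))))..))))")), 1L)
  # independent exterior-anchored candidates count separately
  expect_equal(count_hairpins(db_tree("((((....))))..((((....))))")), 2L)
  # open chain has none
  expect_equal(count_hairpins(db_tree(".........")), 0L)
})

test_that("the bond threshold can apply per substructure or per anchor helix", {
  # 2 bp + bulge + 2 bp: four bonds in total, two in the anchor
  tr <- db_tree("((.((....))))")
  expect_equal(count_hairpins(tr, bond_rule = "substructure"), 1L)
  expect_equal(count_hairpins(tr, bond_rule = "anchor"), 0L)
})

test_that("stems are anchored candidates without an immediate loop", {
  # under the default census every loop-closing candidate is a hairpin,
  # however deep the nesting (branched/nested structures count once)
  deep <- "((((..((((..((((....))))..))))..))))"
  expect_equal(count_hairpins(db_tree(deep)), 1L)
  expect_equal(count_stems(db_tree(deep)), 0L)
  # the strict separation reading: anchor -> internal -> helix -> internal ->
  # helix -> hairpin loop puts the nearest hairpin loop two loop elements
  # away, which the switch classifies as a stem
  expect_equal(count_stems(db_tree(deep), max_sep = 1), 1L)
  expect_equal(count_hairpins(db_tree(deep), max_sep = 1), 0L)
  # a plain hairpin is not a stem under either reading; nor the open chain
  expect_equal(count_stems(db_tree("((((....))))"), max_sep = 1), 0L)
  expect_equal(count_stems(db_tree("......"), max_sep = 1), 0L)
  # classification is exclusive: counts never exceed the candidates
  set.seed(13)
  m <- energy_model()
  for (r in 1:15) {
    st <- fold_mfe(random_rna(sample(60:120, 1), gc = 0.6), m)
    tr <- build_element_tree(st)
    df <- as.data.frame(tr)
    root <- df$id[df$type == "exterior"]
    n_cand <- sum(df$type == "helix" & df$parent == root, na.rm = TRUE)
    expect_lte(count_hairpins(tr) + count_stems(tr), n_cand)
    expect_lte(count_hairpins(tr), floor(st$length / 8))
  }
})

test_that("min_bonds = 1 degenerates to counting anchored loop-closing candidates", {
  dbs <- c("((((....))))..(((...)))", "(((....)))", "((..((...))..((...))..))")
  for (db in dbs) {
    tr <- db_tree(db)
    df <- as.data.frame(tr)
    root <- df$id[df$type == "exterior"]
    anchors <- df$id[df$type == "helix" & !is.na(df$parent) & df$parent == root]
    expect_equal(count_hairpins(tr, min_bonds = 1),
                 length(anchors), info = db)
  }
})

test_that("hairpin counts depend on topology, not sequence identity", {
  pr <- dotbracket_to_pairs("((((....))))..((((....))))")
  st <- secondary_structure(pr, 26)
  expect_equal(count_hairpins(build_element_tree(st)), 2L)
  # same pairing on any sequence gives the same census
  ps <- paired_stats(st)
  expect_equal(ps$n_paired, 16L)
  expect_equal(ps$pct_paired, 100 * 16 / 26)
})

test_that("paired statistics are exact arithmetic", {
  open <- secondary_structure(matrix(integer(0), 0, 2), 100)
  expect_equal(paired_stats(open), list(n_paired = 0L, pct_paired = 0))
  st <- secondary_structure(dotbracket_to_pairs("((((....))))"), 12)
  ps <- paired_stats(st)
  expect_equal(ps$n_paired, 8L)
  expect_equal(round(ps$pct_paired, 2), 66.67)
  # recount from the pair table
  set.seed(8)
  m <- energy_model()
  st <- fold_mfe(random_rna(50, 0.7), m)
  pt <- rep(0L, 50); pt[st$pairs[, 1]] <- st$pairs[, 2]; pt[st$pairs[, 2]] <- st$pairs[, 1]
  expect_equal(paired_stats(st)$n_paired, sum(pt > 0))
})
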