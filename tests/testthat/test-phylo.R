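write_tree_file <- function(nwk) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(nwk, f)
  f
}

test_that("newick reading validates and round-trips", {
  tr <- read_newick(write_tree_file("(A,B);"))
  expect_equal(sort(tr$tip.label), c("A", "B"))
  tr3 <- read_newick(write_tree_file("((A,B),C);"))
  expect_equal(tr3$Nnode, 2)
  expect_error(read_newick(write_tree_file("((A,B,C;")), "malformed")
  expect_error(read_newick(write_tree_file("(A,A);")), "duplicate")
  # write/read round trip preserves the topology
  out <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr3, out)
  expect_true(ape::all.equal.phylo(read_newick(out), tr3))
})

test_that("tip-state files support counts, missing data and ambiguity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tstate", "Camelineae\t6/7", "Aethionemeae\t5",
               "Unknowneae\tNA"), f)
  st <- read_tip_states(f)
  expect_equal(st$Camelineae, c("6", "7"))
  expect_equal(st$Aethionemeae, "5")
  expect_length(st$Unknowneae, 0)
})

test_that("parsimony handles the textbook cases", {
  tr <- read_newick(write_tree_file("((A,B),(C,D));"))
  fit <- fitch_root_states(tr, list(A = 4, B = 4, C = 4, D = 4))
  expect_equal(fit$root_states, "4")
  expect_equal(fit$score, 0)

  tr2 <- read_newick(write_tree_file("(A,B);"))
  fit <- fitch_root_states(tr2, list(A = 5, B = 6))
  expect_equal(fit$root_states, c("5", "6"))
  expect_equal(fit$score, 1)

  # missing tips are pruned but do not error; ambiguous tips constrain softly
  tr3 <- read_newick(write_tree_file("((A,B),(C,D));"))
  fit <- fitch_root_states(tr3, list(A = 5, B = "5", C = c("5", "6")))
  expect_equal(fit$root_states, "5")
  expect_equal(fit$score, 0)
  expect_error(fitch_root_states(tr3, list(A = 5)), "at least 2")
  expect_error(fitch_root_states(tr3, list(X = 5)), "no tip")
})

test_that("a six-tip tree matches the exhaustive minimization", {
  tr <- read_newick(write_tree_file("(((A,B),(C,D)),(E,F));"))
  tips <- list(A = "5", B = "6", C = "6", D = "7", E = "5", F = "4")
  fit <- fitch_root_states(tr, tips)
  oracle <- oracle_fitch(tr, tips)
  expect_equal(fit$score, oracle$score)
  expect_equal(fit$root_states, oracle$root_states)
})

test_that("root sets and scores equal brute force on random small trees", {
  set.seed(55)
  for (r in 1:30) {
    k <- sample(3:8, 1)
    tr <- random_tree(k)
    tips <- stats::setNames(
      lapply(seq_len(k), function(i)
        as.character(sample(1:4, sample(1:2, 1, prob = c(0.8, 0.2))))),
      tr$tip.label)
    fit <- fitch_root_states(tr, tips)
    oracle <- oracle_fitch(tr, tips)
    expect_equal(fit$score, oracle$score, info = ape::write.tree(tr))
    expect_equal(fit$root_states, oracle$root_states,
                 info = ape::write.tree(tr))
  }
})

test_that("scores agree with phangorn on binary trees with single states", {
  skip_if_not_installed("phangorn")
  set.seed(66)
  for (r in 1:15) {
    k <- sample(4:10, 1)
    tr <- ape::rtree(k)
    states <- sample(as.character(1:4), k, replace = TRUE)
    names(states) <- tr$tip.label
    fit <- fitch_root_states(tr, as.list(states))
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = as.character(1:4))
    expect_equal(fit$score, phangorn::fitch(tr, dat))
  }
})

test_that("adding a tip supported by its parent set never raises the score", {
  base <- read_newick(write_tree_file("((A,B),C);"))
  fit0 <- fitch_root_states(base, list(A = 5, B = 5, C = 6))
  grown <- read_newick(write_tree_file("((A,B),C,D);"))
  fit1 <- fitch_root_states(grown, list(A = 5, B = 5, C = 6, D = 5))
  expect_lte(fit1$score, fit0$score)
})

test_that("annotated trees carry the reconstructed state sets", {
  tr <- read_newick(write_tree_file("((A,B),(C,D));"))
  fit <- fitch_root_states(tr, list(A = 5, B = 6, C = 6, D = 6))
  out <- withr::local_tempfile(fileext = ".nwk")
  ann <- write_annotated_newick(fit, out)
  expect_true(file.exists(out))
  back <- ape::read.tree(out)
  expect_equal(sort(back$node.label)[1], sort(ann$node.label)[1])
  expect_true(any(grepl("|", back$node.label, fixed = TRUE) |
                    back$node.label %in% c("5", "6")))
})
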