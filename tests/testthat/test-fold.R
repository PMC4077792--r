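model <- energy_model()

test_that("sequences without allowed pairs fold to the open chain", {
  st <- fold_mfe("AAAAAAA", model)
  expect_equal(nrow(st$pairs), 0)
  expect_equal(st$energy, 0)
  expect_equal(fold_mfe("AC", model)$energy, 0)  # shorter than any hairpin
})

test_that("a designed GC hairpin folds as expected and matches the hand-sum", {
  st <- fold_mfe("GGGGAAAACCCC", model)
  expect_equal(pairs_to_dotbracket(st$pairs, 12), "((((....))))")
  # 3 GC/GC stacks closing a 4-loop, GC closure has no terminal penalty
  hand <- 3 * model$stack["GC", "GC"] + model$loops$hairpin[model$loops$size == 4]
  expect_equal(st$energy, hand)
  expect_equal(energy_of("GGGGAAAACCCC", st, model), hand)
})

test_that("the loop-decomposition scorer obeys its building blocks", {
  # open chain scores zero
  open <- secondary_structure(matrix(integer(0), 0, 2), 10)
  expect_equal(energy_of("GGGGGAAAAA", open, model), 0)
  # terminal AU penalty applies at the exterior helix end
  s <- "AGGGAAAACCCU"
  st <- secondary_structure(rbind(c(1, 12), c(2, 11), c(3, 10), c(4, 9)), 12)
  hand <- model$stack["AU", "GC"] + 2 * model$stack["GC", "GC"] +
    model$loops$hairpin[model$loops$size == 4] + model$terminal_au
  expect_equal(energy_of(s, st, model), hand)
  # additivity over exterior-disjoint substructures
  one <- "GGGGAAAACCCC"
  two <- paste0(one, "AAA", one)
  st1 <- fold_mfe(one, model)
  st2 <- secondary_structure(rbind(st1$pairs, st1$pairs + 15L), nchar(two))
  expect_equal(energy_of(two, st2, model), 2 * st1$energy)
  # disallowed pairs are rejected
  bad <- secondary_structure(cbind(1, 12), 12)
  expect_error(energy_of("AAAAAAAAAAAA", bad, model), "disallowed")
})

test_that("brute-force enumeration matches hand counts and the recursion", {
  expect_length(brute_force_structures("GGCC", model), 1)   # no 3-loop fits
  bf <- brute_force_structures("GAAAC", model)
  expect_length(bf, 2)
  expect_equal(vapply(bf, function(s) nrow(s$pairs), 1L) %in% c(0L, 1L),
               c(TRUE, TRUE))
  set.seed(21)
  for (r in 1:25) {
    s <- random_rna(sample(6:14, 1))
    expect_equal(length(brute_force_structures(s, model)),
                 oracle_count_structures(s),
                 info = s)
  }
  expect_error(brute_force_structures(random_rna(30), model), "25 nt")
})

test_that("dynamic programming equals the exhaustive minimum", {
  set.seed(33)
  for (r in 1:60) {
    s <- random_rna(sample(5:16, 1), gc = runif(1, 0.3, 0.7))
    dp <- fold_mfe(s, model)
    bf <- brute_force_structures(s, model)
    expect_equal(dp$energy, bf[[1]]$energy, info = s)
    expect_equal(energy_of(s, dp, model), dp$energy, info = s)
  }
})

test_that("folding is deterministic and monotone under extension", {
  set.seed(5)
  s <- random_rna(60)
  a <- fold_mfe(s, model); b <- fold_mfe(s, model)
  expect_identical(a$pairs, b$pairs)
  for (r in 1:10) {
    s <- random_rna(sample(20:50, 1))
    ext <- paste0(s, random_rna(sample(5:15, 1)))
    expect_lte(fold_mfe(ext, model)$energy, fold_mfe(s, model)$energy)
  }
})

test_that("suboptimal ensembles start at the MFE and respect the band", {
  ens <- enumerate_suboptimal("AAAAAAA", model)
  expect_equal(ens$count, 1)  # open chain only
  expect_equal(nrow(ens$structures[[1]]$pairs), 0)
  set.seed(9)
  s <- random_rna(70, gc = 0.55)
  ens <- enumerate_suboptimal(s, model, max_pct_diff = 10, max_count = 25)
  mfe <- fold_mfe(s, model)
  expect_identical(ens$structures[[1]]$pairs, mfe$pairs)
  energies <- vapply(ens$structures, function(x) x$energy, 0)
  expect_true(all(diff(energies) >= 0))
  expect_true(all(energies <= band_ceiling(mfe$energy, 10) + 1e-9))
  expect_lte(ens$count, 25)
})

test_that("window-0 enumeration is the complete band enumeration", {
  set.seed(17)
  for (r in 1:12) {
    s <- random_rna(sample(9:14, 1), gc = 0.6)
    bf <- brute_force_structures(s, model)
    mfe <- bf[[1]]$energy
    keep <- Filter(function(x) x$energy <= band_ceiling(mfe, 20) + 1e-9, bf)
    ens <- enumerate_suboptimal(s, model, max_pct_diff = 20,
                                max_count = 100000, window = 0)
    expect_equal(ens$count, length(keep), info = s)
    key <- function(st) paste(t(st$pairs), collapse = ",")
    expect_setequal(vapply(ens$structures, key, ""), vapply(keep, key, ""))
  }
})

test_that("windowed ensembles are mutually distinct under the window rule", {
  set.seed(29)
  s <- random_rna(90, gc = 0.55)
  w <- 3
  ens <- enumerate_suboptimal(s, model, max_pct_diff = 15, max_count = 15,
                              window = w)
  expect_gt(ens$count, 1)
  for (k in 2:ens$count) {
    pk <- ens$structures[[k]]$pairs
    novel_pair <- FALSE
    for (row in seq_len(nrow(pk))) {
      dmin <- Inf
      for (j in 1:(k - 1)) {
        pj <- ens$structures[[j]]$pairs
        d <- min(pmax(abs(pj[, 1] - pk[row, 1]), abs(pj[, 2] - pk[row, 2])))
        dmin <- min(dmin, d)
      }
      if (dmin >= w) { novel_pair <- TRUE; break }
    }
    expect_true(novel_pair, info = paste("structure", k))
  }
})

test_that("mean MFE of matched random sequences decreases with length", {
  set.seed(41)
  mean_mfe <- vapply(c(40, 80, 160), function(len) {
    recs <- generate_matched(null_spec(rep(len, 8), 0.549, seed = len))
    mean(vapply(seq_len(8), function(k) fold_mfe(recs[k, ], model)$energy, 0))
  }, 0)
  expect_true(all(diff(mean_mfe) < 0))
  expect_lt(mean_mfe[1], 0)
})
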