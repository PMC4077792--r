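#' Fold a sequence to its minimum-free-energy secondary structure
#'
#' Computes the pseudoknot-free structure of minimal free energy under the
#' nearest-neighbor model by dynamic programming. The open chain has energy
#' 0.0, so sequences admitting no favorable pair return the open chain.
#' Traceback ties are broken deterministically (fixed case order, fixed
#' insertion order in the search queue), so identical input always yields
#' the identical structure.
#'
#' @param seq a sequence string or a one-row record table.
#' @param model an [energy_model()]; the packaged default when omitted.
#' @return a [secondary_structure()] with its energy in kcal/mol.
#' @export
fold_mfe <- function(seq, model = default_energy_model()) {
  rec <- as_seq_record(seq)
  n <- nchar(rec$residues)
  res <- c_fold(encode_residues(rec$residues), .model_params_int(model, n))
  st <- res$structures[[1]]
  secondary_structure(st$pairs, n, seq_id = rec$id,
                      energy = st$energy_tenths / 10)
}

#' Enumerate the suboptimal structure ensemble of a sequence
#'
#' Generates distinct structures in non-decreasing energy order within a
#' percentage band of the MFE: every returned structure has energy no worse
#' than `MFE + |MFE| * max_pct_diff / 100`. With `window >= 1`, each
#' accepted structure after the first must contain at least one base pair
#' whose distance (Chebyshev, in sequence positions) from every pair of
#' every previously accepted structure is at least `window` -- the
#' distinctness criterion of mfold-style suboptimal folding. `window = 0`
#' disables the novelty filter, so the ensemble is the complete set of
#' distinct structures in the band (exhaustive; only sensible for short
#' sequences).
#'
#' The underlying best-first search is exhaustive within the band but
#' resource-bounded: enumeration stops after `max_count` accepted
#' structures, `max_gen` search-node expansions, or `max_queue` frontier
#' states, whichever comes first; `truncated` in the result records whether
#' a bound was hit before the band was exhausted.
#'
#' @inheritParams fold_mfe
#' @param max_pct_diff energy band width as a percentage of the MFE.
#' @param max_count maximum number of structures returned.
#' @param window distinctness window in nt; `NULL` selects 3 for sequences
#'   shorter than 200 nt and 5 otherwise.
#' @param max_gen,max_queue resource bounds on the best-first search.
#' @return an object of class `structure_ensemble`: a ranked list of
#'   [secondary_structure()] objects (first element is the MFE structure),
#'   the count, and search diagnostics.
#' @export
enumerate_suboptimal <- function(seq, model = default_energy_model(),
                                 max_pct_diff = 10, max_count = 50,
                                 window = NULL, max_gen = 2e6,
                                 max_queue = 2e6) {
  stopifnot(max_pct_diff >= 0, max_count >= 1)
  rec <- as_seq_record(seq)
  n <- nchar(rec$residues)
  if (is.null(window)) window <- if (n < 200) 3L else 5L
  res <- c_subopt(encode_residues(rec$residues), .model_params_int(model, n),
                  max_pct_diff, as.integer(max_count), as.integer(window),
                  max_gen, max_queue)
  structures <- lapply(res$structures, function(st)
    secondary_structure(st$pairs, n, seq_id = rec$id,
                        energy = st$energy_tenths / 10))
  structure(list(seq_id = rec$id, structures = structures,
                 count = length(structures), mfe = res$mfe_tenths / 10,
                 window = window, truncated = res$truncated,
                 popped = res$popped),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure ensemble of %s: %d structures, MFE %.1f kcal/mol%s\n",
              x$seq_id, x$count, x$mfe,
              if (x$truncated) " (search truncated)" else ""))
  invisible(x)
}

#' Score a structure under the nearest-neighbor loop decomposition
#'
#' Decomposes a structure into its loops (stacked pairs, hairpin, bulge,
#' internal and multibranch loops, and the exterior loop) and sums the model
#' terms. This scorer is implemented independently of the folding engine --
#' a plain recursive decomposition in R -- and doubles as the reference
#' used by the exhaustive enumeration oracle in the tests.
#'
#' @inheritParams fold_mfe
#' @param structure a [secondary_structure()] valid for `seq`.
#' @return free energy in kcal/mol.
#' @export
energy_of <- function(seq, structure, model = default_energy_model()) {
  rec <- as_seq_record(seq)
  n <- nchar(rec$residues)
  if (n != structure$length) stop("structure length does not match sequence")
  validate_pairs(structure$pairs, n, min_hairpin = model$min_hairpin)
  codes <- encode_residues(rec$residues)
  pairs <- structure$pairs
  if (nrow(pairs)) {
    ptypes <- pair_type_of(codes[pairs[, 1]], codes[pairs[, 2]])
    if (any(ptypes == 0))
      stop("structure contains a disallowed base pair")
  }
  par <- .model_params_int(model, n)
  pt <- pair_table(pairs, n)
  tau <- function(p) if (p == 3 || p == 4) 0L else par$terminal_au
  ptype <- function(i, j) pair_type_of(codes[i], codes[j])
  # direct children (branches) between positions a..b, plus unpaired count
  scan_children <- function(a, b) {
    ch <- matrix(integer(0), 0, 2); unp <- 0L; k <- a
    while (k <= b) {
      if (pt[k] == 0) { unp <- unp + 1L; k <- k + 1L }
      else { ch <- rbind(ch, c(k, pt[k])); k <- pt[k] + 1L }
    }
    list(children = ch, unpaired = unp)
  }
  interior_int <- function(i, j, p, q) {
    n1 <- p - i - 1L; n2 <- j - q - 1L
    po <- ptype(i, j); pi_ <- ptype(p, q)
    if (n1 == 0L && n2 == 0L) return(par$stack[po, pi_])
    len <- n1 + n2
    if (n1 == 0L || n2 == 0L) {
      if (len == 1L) return(par$bulge[1] + par$stack[po, pi_])
      return(par$bulge[len] + tau(po) + tau(pi_))
    }
    par$internal[len] + min(par$ninio * abs(n1 - n2), par$ninio_max) +
      tau(po) + tau(pi_)
  }
  total <- 0L
  # exterior loop: terminal penalties of exterior-anchored helices
  ext <- scan_children(1L, n)
  if (nrow(ext$children))
    for (k in seq_len(nrow(ext$children)))
      total <- total + tau(ptype(ext$children[k, 1], ext$children[k, 2]))
  # one loop per closing pair
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    inner <- scan_children(i + 1L, j - 1L)
    nb <- nrow(inner$children)
    if (nb == 0L) {
      total <- total + par$hairpin[j - i - 1L] + tau(ptype(i, j))
    } else if (nb == 1L) {
      total <- total + interior_int(i, j, inner$children[1, 1],
                                    inner$children[1, 2])
    } else {
      total <- total + par$ml_close + tau(ptype(i, j)) +
        nb * par$ml_branch + inner$unpaired * par$ml_unpaired
      for (k in seq_len(nb))
        total <- total + tau(ptype(inner$children[k, 1], inner$children[k, 2]))
    }
  }
  total / 10
}

#' Exhaustively enumerate and score all structures of a short sequence
#'
#' Brute-force oracle: generates every pseudoknot-free structure over the
#' allowed pairs with the minimum hairpin loop, scores each with
#' [energy_of()], and returns them sorted by energy. Combinatorial guard:
#' sequences longer than 25 nt are rejected.
#'
#' @inheritParams fold_mfe
#' @return list of [secondary_structure()] objects sorted by ascending
#'   energy.
#' @export
brute_force_structures <- function(seq, model = default_energy_model()) {
  rec <- as_seq_record(seq)
  n <- nchar(rec$residues)
  if (n > 25) stop("brute-force enumeration is limited to 25 nt")
  codes <- encode_residues(rec$residues)
  min_hp <- model$min_hairpin
  pairable <- outer(seq_len(n), seq_len(n), function(i, j)
    j - i - 1 >= min_hp) &
    matrix(pair_type_of(rep(codes, n), rep(codes, each = n)) > 0, n, n)
  memo <- new.env(parent = emptyenv())
  rec_enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec_enum(i + 1L, j)  # i unpaired
    ks <- seq_len(n)[seq_len(n) > i & seq_len(n) <= j]
    ks <- ks[pairable[i, ks]]
    for (k in ks) {
      inner <- rec_enum(i + 1L, k - 1L)
      outer_ <- rec_enum(k + 1L, j)
      for (a in inner) for (b in outer_)
        out <- c(out, list(rbind(c(i, k), a, b)))
    }
    memo[[key]] <- out
    out
  }
  all_pairs <- rec_enum(1L, n)
  structs <- lapply(all_pairs, function(p) {
    st <- secondary_structure(p, n, seq_id = rec$id)
    st$energy <- energy_of(rec, st, model)
    st
  })
  structs[order(vapply(structs, function(s) s$energy, numeric(1)))]
}
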